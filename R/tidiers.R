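# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a contact map into long format
#'
#' @param x An `fs_contact_map`.
#' @param ... Unused.
#' @return A tibble: `res_a`, `res_b`, `freq` (all pairs, including
#'   zeros).
#' @export
tidy.fs_contact_map <- function(x, ...) {
  tibble::tibble(
    res_a = as.integer(rep(rownames(x$freq), times = ncol(x$freq))),
    res_b = as.integer(rep(colnames(x$freq), each = nrow(x$freq))),
    freq = as.numeric(x$freq))
}

#' Tidy a free-energy landscape into long format
#'
#' @param x An `fs_landscape`.
#' @param ... Unused.
#' @return A tibble: `x`, `y` (bin centres), `count`, `F` (kcal/mol;
#'   `Inf` for empty bins).
#' @export
tidy.fs_landscape <- function(x, ...) {
  cx <- bin_centers(x$x_edges); cy <- bin_centers(x$y_edges)
  counts <- as.numeric(x$counts); F <- as.numeric(x$F)
  tibble::tibble(x = rep(cx, times = length(cy)),
                 y = rep(cy, each = length(cx)),
                 count = counts, F = F)
}

#' One-row summary of a landscape
#'
#' @param x An `fs_landscape`.
#' @param ... Unused.
#' @return A tibble: `n_points`, `n_bins`, `n_occupied`, `temperature`,
#'   `max_F`.
#' @export
glance.fs_landscape <- function(x, ...) {
  fin <- is.finite(x$F)
  tibble::tibble(n_points = sum(x$counts), n_bins = length(x$F),
                 n_occupied = sum(fin), temperature = x$temperature,
                 max_F = max(x$F[fin]))
}

#' Tidy basins into a table
#'
#' @param x An `fs_basins`.
#' @param ... Unused.
#' @return A tibble: `label`, `min_x`, `min_y`, `min_F`, `n_bins`.
#' @export
tidy.fs_basins <- function(x, ...) {
  tibble::tibble(
    label = vapply(x, `[[`, character(1), "label"),
    min_x = vapply(x, `[[`, numeric(1), "min_x"),
    min_y = vapply(x, `[[`, numeric(1), "min_y"),
    min_F = vapply(x, `[[`, numeric(1), "min_F"),
    n_bins = vapply(x, function(b) nrow(b$bins), integer(1)))
}

#' Plot a free-energy landscape
#'
#' @param object An `fs_landscape`.
#' @param f_cap Cap (kcal/mol) above which bins are blanked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_landscape <- function(object, f_cap = 4, ...) {
  df <- tidy(object)
  df$F[!is.finite(df$F) | df$F > f_cap] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "F (kcal/mol)") +
    ggplot2::labs(x = "beta-RMSD (Å)", y = "alpha-RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a contact-probability map
#'
#' @param object An `fs_contact_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_contact_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_a, y = .data$res_b,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy",
                                 limits = c(0, 1), name = "P(contact)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue") +
    ggplot2::theme_minimal()
}

#' Plot an inter-chain contact-pair time series
#'
#' @param object An `fs_contact_series`.
#' @param ... Unused.
#' @return A ggplot of contact pairs against time.
#' @export
autoplot.fs_contact_series <- function(object, ...) {
  p <- object$pairs
  p$pair <- p$res_a * 100 + p$res_b
  ggplot2::ggplot(p, ggplot2::aes(x = .data$time_ps / 1000,
                                  y = .data$pair)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.4) +
    ggplot2::labs(x = "time (ns)", y = "contact pair (res_a * 100 + res_b)") +
    ggplot2::theme_minimal()
}
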