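# 2D free-energy landscapes over order-parameter pairs: histogram
# estimator, Gaussian count smoothing, basin detection, minimax barrier
# between basins, point classification, representative-frame sampling.

new_landscape <- function(x_edges, y_edges, counts, temperature) {
  p <- counts / sum(counts)
  F <- -kB * temperature * log(p)
  F[!is.finite(F)] <- Inf
  fin <- is.finite(F)
  F[fin] <- F[fin] - min(F[fin])
  structure(list(x_edges = x_edges, y_edges = y_edges, counts = counts,
                 F = F, temperature = temperature),
            class = "fs_landscape")
}

#' Build a 2D free-energy landscape from order-parameter points
#'
#' Bins the points on a half-open grid (`[lo, hi)`, last bin closed) and
#' converts bin probabilities to free energies,
#' `F = -kB * T * log(count / N)`, offset so the lowest occupied bin is at
#' 0 kcal/mol; empty bins are `+Inf`. Only free-energy differences between
#' bins are physically meaningful.
#'
#' @param points A data frame with the two order parameters in columns
#'   `x` and `y` (or the columns named by `x`/`y`).
#' @param x_edges,y_edges Strictly increasing bin boundaries.
#' @param temperature Temperature in Kelvin.
#' @param x,y Column names to use from `points`.
#' @return An `fs_landscape`: `x_edges`, `y_edges`, `counts`, `F`
#'   (kcal/mol), `temperature`.
#' @export
build_landscape <- function(points, x_edges, y_edges, temperature,
                            x = "x", y = "y") {
  if (temperature <= 0) abort("temperature must be positive")
  px <- points[[x]]; py <- points[[y]]
  if (is.null(px) || is.null(py)) abort("points must have the two order-parameter columns")
  ix <- findInterval(px, x_edges, left.open = FALSE)
  iy <- findInterval(py, y_edges, left.open = FALSE)
  nx <- length(x_edges) - 1L; ny <- length(y_edges) - 1L
  # last bin closed on the right
  ix[px == x_edges[nx + 1L]] <- nx
  iy[py == y_edges[ny + 1L]] <- ny
  inside <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  if (!any(inside)) abort("all points fall outside the grid")
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(ix[inside], levels = seq_len(nx)),
               factor(iy[inside], levels = seq_len(ny)))
  counts[] <- as.integer(tab)
  new_landscape(x_edges, y_edges, counts, temperature)
}

#' @export
print.fs_landscape <- function(x, ...) {
  cat(sprintf("<fs_landscape> %d x %d bins, %d points, T = %.1f K, max finite F = %.2f kcal/mol\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$temperature,
              max(x$F[is.finite(x$F)])))
  invisible(x)
}

bin_centers <- function(edges) (head(edges, -1) + tail(edges, -1)) / 2

#' Smooth a landscape's counts with a Gaussian kernel
#'
#' Smoothing happens on the counts, before the free-energy conversion, so
#' total mass is conserved (up to truncation of the kernel at 4 sigma);
#' `sigma_bins = 0` is the identity.
#'
#' @param grid An `fs_landscape`.
#' @param sigma_bins Kernel standard deviation in bins.
#' @return A smoothed `fs_landscape`.
#' @export
smooth_landscape <- function(grid, sigma_bins) {
  if (sigma_bins < 0) abort("sigma_bins must be >= 0")
  if (sigma_bins == 0) return(grid)
  half <- ceiling(4 * sigma_bins)
  k1 <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k1 <- k1 / sum(k1)
  sm_axis <- function(M, along_rows) {
    if (!along_rows) M <- t(M)
    n <- nrow(M)
    out <- matrix(0, n, ncol(M))
    for (o in seq_along(k1)) {
      sh <- o - half - 1L
      src <- seq_len(n) - sh
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k1[o] * M[src[ok], , drop = FALSE]
    }
    if (!along_rows) t(out) else out
  }
  counts <- sm_axis(sm_axis(grid$counts, TRUE), FALSE)
  new_landscape(grid$x_edges, grid$y_edges, counts, grid$temperature)
}

neighbors8 <- function(ix, iy, nx, ny) {
  dx <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  dy <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  x <- ix + dx; y <- iy + dy
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
  cbind(x[ok], y[ok])
}

#' Detect free-energy basins
#'
#' Watershed-by-flooding over the bin set `{F <= global_min + f_max}`
#' (8-connectivity): bins are flooded in order of increasing F and join
#' the basin of their lowest assigned neighbour; where two basins meet,
#' the shallower one is merged into the deeper unless its relief (saddle
#' F minus its minimum) reaches `merge_depth`. Local minima separated by
#' less than `merge_depth` therefore collapse into one basin.
#'
#' @param grid An `fs_landscape`.
#' @param f_max Free-energy ceiling above the global minimum (kcal/mol).
#' @param merge_depth Minimum relief (kcal/mol) for a minimum to count
#'   as its own basin.
#' @param labels Optional basin labels, assigned in order of increasing
#'   basin minimum; defaults to `B1`, `B2`, ...
#' @return An `fs_basins` object: a list of basins, each with `label`,
#'   `bins` (matrix of (ix, iy)), `min_bin`, `min_F`, `min_x`, `min_y`.
#'   Empty list if nothing lies below the ceiling.
#' @export
find_basins <- function(grid, f_max = 1.0, merge_depth = 0.5,
                        labels = NULL) {
  F <- grid$F
  nx <- nrow(F); ny <- ncol(F)
  fin <- is.finite(F)
  if (!any(fin)) abort("grid has no finite bins")
  ceiling_abs <- min(F[fin]) + f_max
  cand <- which(fin & F <= ceiling_abs)
  if (!length(cand)) return(structure(list(), class = "fs_basins"))
  comp <- matrix(0L, nx, ny)
  basin_min <- numeric(0)
  alias <- integer(0)   # union-find: basin id -> surviving id
  find_id <- function(k) { while (alias[k] != k) k <- alias[k]; k }
  for (cur in cand[order(F[cand])]) {
    ix <- (cur - 1L) %% nx + 1L; iy <- (cur - 1L) %/% nx + 1L
    nb <- neighbors8(ix, iy, nx, ny)
    ids <- comp[nb[, 1] + (nb[, 2] - 1L) * nx]
    ids <- unique(vapply(ids[ids > 0L], find_id, integer(1)))
    if (length(ids) == 0L) {
      basin_min <- c(basin_min, F[cur])
      alias <- c(alias, length(basin_min))
      comp[cur] <- length(basin_min)
    } else if (length(ids) == 1L) {
      comp[cur] <- ids
    } else {
      deepest <- ids[which.min(basin_min[ids])]
      for (k in setdiff(ids, deepest)) {
        if (F[cur] - basin_min[k] < merge_depth) alias[k] <- deepest
      }
      comp[cur] <- deepest
    }
  }
  comp[comp > 0L] <- vapply(comp[comp > 0L], find_id, integer(1))
  kept <- sort(unique(comp[comp > 0L]))
  basins <- lapply(kept, function(k) {
    lin <- which(comp == k)
    ix <- (lin - 1L) %% nx + 1L; iy <- (lin - 1L) %/% nx + 1L
    j <- which.min(F[lin])
    list(label = NA_character_, bins = cbind(ix = ix, iy = iy),
         min_bin = c(ix[j], iy[j]), min_F = F[lin[j]],
         min_x = bin_centers(grid$x_edges)[ix[j]],
         min_y = bin_centers(grid$y_edges)[iy[j]])
  })
  ord <- order(vapply(basins, `[[`, numeric(1), "min_F"))
  basins <- basins[ord]
  if (is.null(labels)) labels <- paste0("B", seq_along(basins))
  if (length(labels) < length(basins)) {
    labels <- c(labels, paste0("B", seq(length(labels) + 1, length(basins))))
  }
  for (k in seq_along(basins)) basins[[k]]$label <- labels[k]
  structure(basins, class = "fs_basins")
}

#' @export
print.fs_basins <- function(x, ...) {
  cat(sprintf("<fs_basins> %d basin(s)\n", length(x)))
  if (length(x)) print(tidy(x))
  invisible(x)
}

basin_by_label <- function(basins, label) {
  labs <- vapply(basins, `[[`, character(1), "label")
  k <- match(label, labs)
  if (is.na(k)) abort(sprintf("no basin labelled '%s'", label))
  basins[[k]]
}

#' Minimax barrier between two basins
#'
#' Over all 8-connected paths of finite-F bins from the minimum bin of
#' basin `from` to that of basin `to`, finds the path whose maximum F is
#' smallest (a widest-path / Dijkstra-with-max search). The barrier is
#' that saddle F minus `min_F(from)`; `+Inf` when no finite path exists.
#'
#' @param grid An `fs_landscape`.
#' @param basins An `fs_basins` object.
#' @param from,to Basin labels.
#' @return A list: `from`, `to`, `saddle_bin`, `saddle_x`, `saddle_y`,
#'   `saddle_F`, `barrier` (kcal/mol).
#' @export
minimax_barrier <- function(grid, basins, from, to) {
  a <- basin_by_label(basins, from); b <- basin_by_label(basins, to)
  F <- grid$F
  nx <- nrow(F); ny <- ncol(F)
  lin <- function(bin) bin[1] + (bin[2] - 1L) * nx
  src <- lin(a$min_bin); dst <- lin(b$min_bin)
  best <- rep(Inf, nx * ny)   # minimax value to reach each bin
  best[src] <- F[src]
  pred <- rep(NA_integer_, nx * ny)
  visited <- rep(FALSE, nx * ny)
  repeat {
    cand <- which(!visited & is.finite(best))
    if (!length(cand)) break
    cur <- cand[which.min(best[cand])]
    if (cur == dst) break
    visited[cur] <- TRUE
    ix <- (cur - 1L) %% nx + 1L; iy <- (cur - 1L) %/% nx + 1L
    nb <- neighbors8(ix, iy, nx, ny)
    nl <- nb[, 1] + (nb[, 2] - 1L) * nx
    nl <- nl[is.finite(F[nl]) & !visited[nl]]
    val <- pmax(best[cur], F[nl])
    upd <- val < best[nl]
    best[nl[upd]] <- val[upd]
    pred[nl[upd]] <- cur
  }
  if (!is.finite(best[dst])) {
    return(list(from = from, to = to, saddle_bin = c(NA, NA),
                saddle_x = NA_real_, saddle_y = NA_real_,
                saddle_F = Inf, barrier = Inf))
  }
  saddle_F <- best[dst]
  # walk the predecessor chain back from the destination; the saddle is
  # the bin attaining the path maximum
  path <- dst
  while (!is.na(pred[path[1]])) path <- c(pred[path[1]], path)
  sb <- path[which.max(F[path])]
  six <- (sb - 1L) %% nx + 1L; siy <- (sb - 1L) %/% nx + 1L
  list(from = from, to = to, saddle_bin = c(six, siy),
       saddle_x = bin_centers(grid$x_edges)[six],
       saddle_y = bin_centers(grid$y_edges)[siy],
       saddle_F = saddle_F, barrier = saddle_F - a$min_F)
}

#' Classify points against basins
#'
#' A point is `"in"` a basin when its bin belongs to the basin's bin set,
#' `"near"` when within a Chebyshev distance of `near_margin_bins` bins of
#' one, and `"far"` otherwise (including outside the grid). Ties go to
#' the basin with the lowest minimum.
#'
#' @param grid An `fs_landscape`.
#' @param basins An `fs_basins`.
#' @param points Data frame with columns `x` and `y`.
#' @param near_margin_bins Chebyshev margin (bins) for `"near"`.
#' @return A tibble: `x`, `y`, `status` (`in`/`near`/`far`), `label`
#'   (basin label or `NA` when far).
#' @export
classify_points <- function(grid, basins, points, near_margin_bins = 1L) {
  nx <- nrow(grid$F); ny <- ncol(grid$F)
  res <- tibble::tibble(x = points$x, y = points$y,
                        status = "far", label = NA_character_)
  if (length(basins) == 0L) return(res)
  ix <- findInterval(res$x, grid$x_edges)
  iy <- findInterval(res$y, grid$y_edges)
  ix[res$x == grid$x_edges[nx + 1L]] <- nx
  iy[res$y == grid$y_edges[ny + 1L]] <- ny
  for (p in seq_len(nrow(res))) {
    if (ix[p] < 1 || ix[p] > nx || iy[p] < 1 || iy[p] > ny) next
    stat <- "far"; lab <- NA_character_
    for (b in basins) {  # basins already sorted by min_F: ties to lowest
      cheb <- pmax(abs(b$bins[, "ix"] - ix[p]), abs(b$bins[, "iy"] - iy[p]))
      if (any(cheb == 0)) { stat <- "in"; lab <- b$label; break }
      if (stat == "far" && any(cheb <= near_margin_bins)) {
        stat <- "near"; lab <- b$label
      }
    }
    res$status[p] <- stat; res$label[p] <- lab
  }
  res
}

#' Sample representative frames from a basin
#'
#' Greedy earliest-first selection of frames whose order-parameter pair
#' falls in the basin's bins, enforcing a minimum time spacing. When fewer
#' than `min_count` frames qualify the full qualifying set is returned
#' with a shortfall flag.
#'
#' @param params A data frame with `time_ps` and the two order-parameter
#'   columns `x` and `y` (one row per frame, frame order).
#' @param grid An `fs_landscape`.
#' @param basin One element of an `fs_basins` (or a label plus `basins`).
#' @param basins Needed when `basin` is given as a label.
#' @param min_count Target number of frames.
#' @param min_spacing_ps Minimum time separation between selected frames.
#' @return Integer frame indices with attribute `shortfall` (logical).
#' @export
sample_basin_frames <- function(params, grid, basin, basins = NULL,
                                min_count = 100L, min_spacing_ps = 100) {
  if (is.character(basin)) basin <- basin_by_label(basins, basin)
  nx <- nrow(grid$F); ny <- ncol(grid$F)
  ix <- findInterval(params$x, grid$x_edges)
  iy <- findInterval(params$y, grid$y_edges)
  ix[params$x == grid$x_edges[nx + 1L]] <- nx
  iy[params$y == grid$y_edges[ny + 1L]] <- ny
  keys <- paste(ix, iy)
  bkeys <- paste(basin$bins[, "ix"], basin$bins[, "iy"])
  qual <- which(keys %in% bkeys)
  sel <- integer(0)
  last_t <- -Inf
  for (i in qual) {
    if (params$time_ps[i] - last_t >= min_spacing_ps) {
      sel <- c(sel, i)
      last_t <- params$time_ps[i]
    }
  }
  structure(sel, shortfall = length(sel) < min_count)
}
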