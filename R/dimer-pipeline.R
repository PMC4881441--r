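# Two-chain aggregation analysis: binding detection, flat-stage
# windowing, interface maps and common-segment reports, average and
# representative structures, and projection of bound monomers onto the
# monomer folding landscape.

split_chains <- function(frame) {
  chains <- sort(unique(frame$chain))
  if (length(chains) != 2L) abort("frame must contain exactly two chains")
  list(A = frame[frame$chain == chains[1], ],
       B = frame[frame$chain == chains[2], ])
}

#' Minimum inter-chain heavy-atom distance
#'
#' @param frame A two-chain structure.
#' @return Distance in Angstrom.
#' @export
min_interchain_distance <- function(frame) {
  ch <- split_chains(frame)
  min_cross_distance(coords(heavy(ch$A)), coords(heavy(ch$B)))
}

#' Minimum inter-chain distance along a trajectory
#'
#' @param traj A two-chain trajectory.
#' @return A tibble: `time_ps`, `min_dist`.
#' @export
interchain_distance_series <- function(traj) {
  n <- n_frames(traj)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- min_interchain_distance(traj_frame(traj, i))
  tibble::tibble(time_ps = traj$times_ps, min_dist = d)
}

#' Detect a binding event
#'
#' The binding time is the earliest time t such that the minimum
#' inter-chain heavy-atom distance stays below `contact_cutoff` for every
#' frame in `[t, t + persist_ns]`; a persistence window of 0 degenerates
#' to the first sub-cutoff frame. Returns `NULL` when the chains never
#' bind by this criterion.
#'
#' @param traj A two-chain trajectory.
#' @param contact_cutoff Heavy-atom distance cutoff (A).
#' @param persist_ns Required persistence (ns).
#' @param dist_series Optional precomputed [interchain_distance_series()].
#' @return A list (`t_bind_ns`, `sustained`) or `NULL`.
#' @export
detect_binding <- function(traj, contact_cutoff = 4.5, persist_ns = 5,
                           dist_series = NULL) {
  ds <- if (is.null(dist_series)) interchain_distance_series(traj) else dist_series
  t_ns <- ds$time_ps / 1000
  below <- ds$min_dist < contact_cutoff
  n <- length(below)
  for (i in seq_len(n)) {
    if (!below[i]) next
    win <- which(t_ns >= t_ns[i] & t_ns <= t_ns[i] + persist_ns)
    if (t_ns[n] < t_ns[i] + persist_ns) break  # window exceeds trajectory
    if (all(below[win])) {
      return(list(t_bind_ns = t_ns[i], sustained = TRUE))
    }
  }
  NULL
}

#' Detect the flat stage of a contact-count series
#'
#' Finds the earliest window of length `window_ns` over which the
#' least-squares slope of the inter-chain contact count is at most
#' `slope_tol` in magnitude, then extends it while consecutive windows
#' keep passing; this is the plateau ("flat stage") over which interface
#' statistics are collected.
#'
#' @param counts A tibble (`time_ps`, `n_contacts`), typically the
#'   `counts` element of [contact_pair_timeseries()] restricted to
#'   post-binding times.
#' @param window_ns Sliding-window length (ns).
#' @param slope_tol Slope tolerance (contacts/ns).
#' @param t_from_ns Ignore frames before this time (e.g. the binding
#'   time).
#' @return A list (`t_start_ns`, `t_end_ns`) or `NULL` when no window is
#'   flat.
#' @export
detect_flat_stage <- function(counts, window_ns = 50, slope_tol = 0.05,
                              t_from_ns = 0) {
  t_ns <- counts$time_ps / 1000
  keep <- t_ns >= t_from_ns
  t_ns <- t_ns[keep]; y <- counts$n_contacts[keep]
  n <- length(t_ns)
  if (n < 3L) return(NULL)
  ok <- rep(NA, n)
  for (i in seq_len(n)) {
    win <- which(t_ns >= t_ns[i] & t_ns <= t_ns[i] + window_ns)
    if (t_ns[n] < t_ns[i] + window_ns) break
    if (length(win) < 3L) next
    slope <- stats::coef(lsfit(t_ns[win], y[win]))[2]
    ok[i] <- abs(slope) <= slope_tol
  }
  starts <- which(ok)
  if (!length(starts)) return(NULL)
  i1 <- starts[1]
  i2 <- i1
  while (i2 + 1L <= n && isTRUE(ok[i2 + 1L])) i2 <- i2 + 1L
  list(t_start_ns = t_ns[i1],
       t_end_ns = min(t_ns[i2] + window_ns, t_ns[n]))
}

#' Inter-chain interface map over a flat stage
#'
#' The inter-chain residue contact-probability map over the first
#' `window_ns` of the flat stage, with per-residue marginal contact
#' frequencies for each chain and the maximal runs of residues whose
#' marginal exceeds `seg_threshold` (the candidate binding segments).
#'
#' @param traj A two-chain trajectory.
#' @param stage A flat stage from [detect_flat_stage()].
#' @param window_ns Statistics window from the stage start (400 ns).
#' @param cutoff Heavy-atom contact cutoff (A).
#' @param seg_threshold Marginal-frequency threshold for segments.
#' @return A list of class `fs_interface_summary`: `map`
#'   (`fs_contact_map`, kind `"inter"`), `marginals` (tibble: `chain`,
#'   `residue`, `freq`), `segments` (tibble: `chain`, `start`, `end`,
#'   `mean_freq`), `truncated` (TRUE when the stage was shorter than
#'   `window_ns`).
#' @export
interface_map <- function(traj, stage, window_ns = 400, cutoff = 4.5,
                          seg_threshold = 0.3) {
  t_ns <- traj$times_ps / 1000
  t_hi <- stage$t_start_ns + window_ns
  truncated <- stage$t_end_ns < t_hi
  idx <- which(t_ns >= stage$t_start_ns & t_ns <= min(t_hi, stage$t_end_ns))
  if (!length(idx)) abort("flat stage contains no frames")
  chains <- sort(unique(traj$atoms$chain))
  res_a <- sort(unique(traj$atoms$resid[traj$atoms$chain == chains[1]]))
  res_b <- sort(unique(traj$atoms$resid[traj$atoms$chain == chains[2]]))
  acc <- matrix(0, length(res_a), length(res_b),
                dimnames = list(res_a, res_b))
  marg_a <- setNames(numeric(length(res_a)), res_a)
  marg_b <- setNames(numeric(length(res_b)), res_b)
  for (i in idx) {
    p <- inter_chain_contacts(traj_frame(traj, i), cutoff)
    if (nrow(p)) {
      ka <- match(p$res_a, res_a); kb <- match(p$res_b, res_b)
      for (k in seq_along(ka)) acc[ka[k], kb[k]] <- acc[ka[k], kb[k]] + 1
      marg_a[as.character(unique(p$res_a))] <-
        marg_a[as.character(unique(p$res_a))] + 1
      marg_b[as.character(unique(p$res_b))] <-
        marg_b[as.character(unique(p$res_b))] + 1
    }
  }
  nf <- length(idx)
  marginals <- dplyr::bind_rows(
    tibble::tibble(chain = chains[1], residue = res_a, freq = marg_a / nf),
    tibble::tibble(chain = chains[2], residue = res_b, freq = marg_b / nf))
  runs_of <- function(ch, resv, fr) {
    above <- fr >= seg_threshold
    if (!any(above)) {
      return(tibble::tibble(chain = character(), start = integer(),
                            end = integer(), mean_freq = numeric()))
    }
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    tibble::tibble(chain = ch, start = resv[starts[hit]],
                   end = resv[ends[hit]],
                   mean_freq = vapply(hit, function(k) {
                     mean(fr[starts[k]:ends[k]])
                   }, numeric(1)))
  }
  segments <- dplyr::bind_rows(runs_of(chains[1], res_a, marg_a / nf),
                               runs_of(chains[2], res_b, marg_b / nf))
  structure(list(map = new_contact_map(acc / nf, "inter", nf, cutoff),
                 marginals = marginals, segments = segments,
                 truncated = truncated),
            class = "fs_interface_summary")
}

#' @export
print.fs_interface_summary <- function(x, ...) {
  cat(sprintf("<fs_interface_summary> %d frame(s), %d candidate segment(s)%s\n",
              x$map$n_frames, nrow(x$segments),
              if (x$truncated) " [stage shorter than window]" else ""))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

#' Common binding-segment report across simulations
#'
#' For every residue, counts in how many simulations it lies inside a
#' detected interface segment on either chain, and reports the maximal
#' residue runs whose support reaches `support_min` (default: a majority
#' of the simulations).
#'
#' @param summaries A list of [interface_map()] results.
#' @param n_residues Number of residues per chain.
#' @param support_min Minimum support for a reported common segment.
#' @return A list: `support` (tibble: `residue`, `support`), `common`
#'   (tibble: `start`, `end`, `min_support`, `max_support`), and
#'   `support_min`.
#' @export
common_segment_report <- function(summaries, n_residues = 36L,
                                  support_min = NULL) {
  if (!length(summaries)) abort("need at least one interface summary")
  if (is.null(support_min)) support_min <- floor(length(summaries) / 2) + 1L
  support <- integer(n_residues)
  for (s in summaries) {
    hit <- rep(FALSE, n_residues)
    segs <- s$segments
    for (k in seq_len(nrow(segs))) {
      hit[segs$start[k]:segs$end[k]] <- TRUE
    }
    support <- support + hit
  }
  above <- support >= support_min
  common <- tibble::tibble(start = integer(), end = integer(),
                           min_support = integer(), max_support = integer())
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    common <- tibble::tibble(
      start = starts[hit], end = ends[hit],
      min_support = vapply(hit, function(k) min(support[starts[k]:ends[k]]),
                           integer(1)),
      max_support = vapply(hit, function(k) max(support[starts[k]:ends[k]]),
                           integer(1)))
    common <- dplyr::arrange(common, dplyr::desc(.data$max_support),
                             dplyr::desc(.data$end - .data$start))
  }
  list(support = tibble::tibble(residue = seq_len(n_residues),
                                support = support),
       common = common, support_min = support_min)
}

#' Count simulations whose interface involves a residue range
#'
#' The number of interface summaries in which, on at least one chain, at
#' least `min_residues` residues of `range` have a marginal contact
#' frequency of `threshold` or more -- e.g. how many runs bind through
#' the N-terminal beta-strand residues 5-10.
#'
#' @param summaries A list of [interface_map()] results (`NULL` entries,
#'   e.g. unbound runs, are skipped).
#' @param range `c(start, end)` residue range.
#' @param min_residues Minimum participating residues within the range.
#' @param threshold Marginal contact-frequency threshold.
#' @return Integer count.
#' @export
count_segment_interfaces <- function(summaries, range = c(5L, 10L),
                                     min_residues = 4L, threshold = 0.3) {
  hit <- vapply(summaries, function(s) {
    if (is.null(s)) return(FALSE)
    m <- s$marginals[s$marginals$residue >= range[1] &
                       s$marginals$residue <= range[2], ]
    any(vapply(split(m$freq >= threshold, m$chain), sum,
               numeric(1)) >= min_residues)
  }, logical(1))
  sum(hit)
}

#' Primary interface segment of a simulation
#'
#' The detected segment with the largest (length x mean frequency)
#' product over both chains: the dominant binding patch of that run.
#'
#' @param summary An [interface_map()] result.
#' @return One row of the segment table (or zero rows if no segments).
#' @export
primary_interface_segment <- function(summary) {
  segs <- summary$segments
  if (nrow(segs) == 0L) return(segs)
  w <- (segs$end - segs$start + 1) * segs$mean_freq
  segs[which.max(w), ]
}

#' Iteratively superposed average structure over a stage
#'
#' Superposes every stage frame onto the running mean (heavy atoms) and
#' recomputes the mean until it moves by less than `tol` Angstrom
#' (mean per-atom displacement), returning the converged mean
#' coordinates.
#'
#' @param traj A trajectory.
#' @param stage A flat stage (or `NULL` to use all frames).
#' @param window_ns Restrict to the first `window_ns` of the stage.
#' @param tol Convergence threshold (A).
#' @param max_iter Iteration cap.
#' @return A structure with attribute `iterations`.
#' @export
average_structure <- function(traj, stage = NULL, window_ns = 400,
                              tol = 0.01, max_iter = 20L) {
  idx <- seq_len(n_frames(traj))
  if (!is.null(stage)) {
    t_ns <- traj$times_ps / 1000
    idx <- which(t_ns >= stage$t_start_ns &
                   t_ns <= min(stage$t_start_ns + window_ns, stage$t_end_ns))
  }
  if (length(idx) < 2L) abort("need at least two frames to average")
  hrows <- which(traj$atoms$element != "H")
  mean_xyz <- traj$xyz[idx[1], , ]
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    acc <- matrix(0, nrow(traj$atoms), 3)
    for (i in idx) {
      fx <- traj$xyz[i, , ]
      fit <- kabsch_superpose(fx[hrows, ], mean_xyz[hrows, ])
      acc <- acc + sweep(fx %*% t(fit$rotation), 2, fit$translation, "+")
    }
    new_mean <- acc / length(idx)
    shift <- mean(sqrt(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol) break
  }
  out <- set_coords(traj_frame(traj, idx[1]), mean_xyz)
  attr(out, "iterations") <- iterations
  out
}

#' Representative snapshot closest to the average structure
#'
#' The stage frame with the smallest heavy-atom RMSD (after
#' superposition) to the average structure; the earliest frame wins ties.
#'
#' @param traj A trajectory.
#' @param stage A flat stage (or `NULL` for all frames).
#' @param avg The [average_structure()].
#' @param window_ns Restrict to the first `window_ns` of the stage.
#' @return A list: `frame` (index), `time_ns`, `rmsd`.
#' @export
representative_snapshot <- function(traj, stage, avg, window_ns = 400) {
  idx <- seq_len(n_frames(traj))
  if (!is.null(stage)) {
    t_ns <- traj$times_ps / 1000
    idx <- which(t_ns >= stage$t_start_ns &
                   t_ns <= min(stage$t_start_ns + window_ns, stage$t_end_ns))
  }
  hrows <- which(traj$atoms$element != "H")
  axyz <- coords(avg)[hrows, ]
  r <- vapply(idx, function(i) {
    kabsch_superpose(traj$xyz[i, hrows, ], axyz)$rmsd
  }, numeric(1))
  k <- idx[which.min(r)]
  list(frame = k, time_ns = traj$times_ps[k] / 1000, rmsd = min(r))
}

#' Project the monomers of a dimer snapshot onto the monomer landscape
#'
#' Extracts each chain as a monomer, computes its alpha-RMSD and
#' beta-RMSD against the monomer reference, and classifies the resulting
#' point against the basins of the monomer folding landscape.
#'
#' @param snapshot A two-chain structure.
#' @param ref Monomer reference structure.
#' @param grid Monomer `fs_landscape` over (beta-RMSD, alpha-RMSD).
#' @param basins Monomer `fs_basins`.
#' @param near_margin_bins Margin for the `"near"` classification.
#' @return A tibble: `chain`, `alpha_rmsd`, `beta_rmsd`, `status`,
#'   `label`.
#' @export
project_monomers <- function(snapshot, ref, grid, basins,
                             near_margin_bins = 1L) {
  ch <- split_chains(snapshot)
  one <- function(s, tag) {
    s$chain <- unique(ref$chain)
    if (!setequal(unique(s$resid), unique(ref$resid))) {
      abort(sprintf("chain %s residues do not match the reference", tag))
    }
    a <- segment_rmsd(new_structure(s), ref, sel_helix())
    b <- segment_rmsd(new_structure(s), ref, sel_sheet())
    cls <- classify_points(grid, basins, tibble::tibble(x = b, y = a),
                           near_margin_bins)
    tibble::tibble(chain = tag, alpha_rmsd = a, beta_rmsd = b,
                   status = cls$status, label = cls$label)
  }
  tags <- sort(unique(snapshot$chain))
  dplyr::bind_rows(one(ch$A, tags[1]), one(ch$B, tags[2]))
}
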