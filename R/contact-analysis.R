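# Residue-contact analysis: heavy-atom contact search (neighbour-grid or
# brute force), intra-chain contact-probability maps, inter-chain contact
# pairs and time series, mainchain hydrogen bonds between segments.

# All heavy-atom index pairs (i < j) closer than `cutoff` (strict).
atom_pairs_within <- function(xyz, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(), 0, 2))
  if (method == "brute") {
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
    hit <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
    return(unname(hit))
  }
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- cell[, 1] + 4096 * (cell[, 2] + 4096 * cell[, 3])
  buckets <- split(seq_len(n), key)
  cell_of <- lapply(buckets, function(ix) cell[ix[1], ])
  keyset <- as.numeric(names(buckets))
  pairs <- list()
  # half-space neighbour offsets (13) + the cell itself
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[with(offs, dz > 0 | (dz == 0 & dy > 0) |
                            (dz == 0 & dy == 0 & dx > 0)), ]
  c2 <- cutoff^2
  for (b in seq_along(buckets)) {
    ia <- buckets[[b]]
    # within-cell pairs
    if (length(ia) > 1L) {
      A <- xyz[ia, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(A^2), "+") - 2 * A %*% t(A)
      hit <- which(upper.tri(d2) & d2 < c2, arr.ind = TRUE)
      if (nrow(hit)) {
        pairs[[length(pairs) + 1L]] <- cbind(ia[hit[, 1]], ia[hit[, 2]])
      }
    }
    cc <- cell_of[[b]]
    for (o in seq_len(nrow(offs))) {
      nk <- (cc[1] + offs$dx[o]) + 4096 * ((cc[2] + offs$dy[o]) +
                                             4096 * (cc[3] + offs$dz[o]))
      j <- match(nk, keyset)
      if (is.na(j)) next
      ib <- buckets[[j]]
      A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      hit <- which(d2 < c2, arr.ind = TRUE)
      if (nrow(hit)) {
        pairs[[length(pairs) + 1L]] <- cbind(ia[hit[, 1]], ib[hit[, 2]])
      }
    }
  }
  if (!length(pairs)) return(matrix(integer(), 0, 2))
  out <- do.call(rbind, pairs)
  cbind(pmin(out[, 1], out[, 2]), pmax(out[, 1], out[, 2]))
}

# Heavy-atom residue contact pairs of one frame. Returns a tibble with
# chain_a, res_a, chain_b, res_b (canonical order, unique).
frame_residue_contacts <- function(frame, cutoff = 4.5,
                                   method = c("cell", "brute")) {
  h <- heavy(frame)
  ap <- atom_pairs_within(coords(h), cutoff, method)
  if (nrow(ap) == 0L) {
    return(tibble::tibble(chain_a = character(), res_a = integer(),
                          chain_b = character(), res_b = integer()))
  }
  ca <- h$chain[ap[, 1]]; ra <- h$resid[ap[, 1]]
  cb <- h$chain[ap[, 2]]; rb <- h$resid[ap[, 2]]
  swap <- ca > cb | (ca == cb & ra > rb)
  t1 <- ifelse(swap, cb, ca); r1 <- ifelse(swap, rb, ra)
  t2 <- ifelse(swap, ca, cb); r2 <- ifelse(swap, ra, rb)
  dplyr::distinct(tibble::tibble(chain_a = t1, res_a = r1,
                                 chain_b = t2, res_b = r2))
}

#' Are two residues in heavy-atom contact?
#'
#' True when the minimum distance over heavy-atom pairs of the two
#' residues is strictly below `cutoff`.
#'
#' @param frame A structure.
#' @param i,j 1-based residue indices.
#' @param cutoff Contact cutoff in Angstrom (4.5).
#' @param chain_i,chain_j Optional chain restriction for each residue.
#' @return Logical.
#' @export
residues_in_contact <- function(frame, i, j, cutoff = 4.5,
                                chain_i = NULL, chain_j = NULL) {
  pick <- function(res, ch) {
    s <- heavy(frame)[heavy(frame)$resid == res, ]
    if (!is.null(ch)) s <- s[s$chain == ch, ]
    if (nrow(s) == 0L) abort(sprintf("residue %d not found", res))
    coords(s)
  }
  A <- pick(i, chain_i); B <- pick(j, chain_j)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  min(d2) < cutoff^2
}

new_contact_map <- function(freq, kind, n_frames, cutoff, min_seq_sep = NA) {
  structure(list(freq = freq, kind = kind, n_frames = n_frames,
                 cutoff = cutoff, min_seq_sep = min_seq_sep),
            class = "fs_contact_map")
}

#' @export
print.fs_contact_map <- function(x, ...) {
  cat(sprintf("<fs_contact_map> %s, %d x %d residues, %d frame(s), cutoff %.2f A\n",
              x$kind, nrow(x$freq), ncol(x$freq), x$n_frames, x$cutoff))
  invisible(x)
}

#' Intra-chain residue contact-probability map
#'
#' `freq[i, j]` is the fraction of frames in which residues i and j are in
#' heavy-atom contact (< `cutoff`) and separated along the sequence by at
#' least `min_seq_sep` residues (`|i - j| >= min_seq_sep`).
#'
#' @param x A trajectory, a structure, or a list of structures (an
#'   ensemble of models treated as frames).
#' @param cutoff Heavy-atom contact cutoff, Angstrom.
#' @param min_seq_sep Minimum sequence separation (3: i and i+3 can touch).
#' @param chain Chain to analyse when several are present.
#' @return An `fs_contact_map` (kind `"intra"`) whose rows/columns are
#'   residues 1..n in order.
#' @export
intra_contact_map <- function(x, cutoff = 4.5, min_seq_sep = 3L,
                              chain = NULL) {
  frames <- as_frame_list(x)
  if (length(frames) == 0L) abort("empty ensemble")
  f1 <- frames[[1]]
  if (!is.null(chain)) frames <- lapply(frames, function(f) f[f$chain == chain, ])
  chains <- unique(frames[[1]]$chain)
  if (length(chains) > 1L) {
    abort("multiple chains present: give `chain`")
  }
  resids <- sort(unique(frames[[1]]$resid))
  n <- length(resids)
  acc <- matrix(0, n, n, dimnames = list(resids, resids))
  for (f in frames) {
    if (!identical(sort(unique(f$resid)), resids)) {
      abort("frames/models do not share the same residue set")
    }
    ct <- frame_residue_contacts(f, cutoff)
    keep <- abs(ct$res_a - ct$res_b) >= min_seq_sep
    ia <- match(ct$res_a[keep], resids); ib <- match(ct$res_b[keep], resids)
    for (k in seq_along(ia)) {
      acc[ia[k], ib[k]] <- acc[ia[k], ib[k]] + 1
      acc[ib[k], ia[k]] <- acc[ib[k], ia[k]] + 1
    }
  }
  new_contact_map(acc / length(frames), "intra", length(frames), cutoff,
                  min_seq_sep)
}

as_frame_list <- function(x) {
  if (inherits(x, "fs_traj")) {
    lapply(seq_len(n_frames(x)), function(i) traj_frame(x, i))
  } else if (inherits(x, "fs_structure")) {
    list(x)
  } else if (is.list(x)) {
    x
  } else {
    abort("expected a trajectory, structure, or list of structures")
  }
}

#' Native contact frequency over an ensemble of models
#'
#' The intra-chain contact map of a set of (e.g. NMR) models treated as
#' frames of equal weight.
#'
#' @param models A list of at least two structures with a common residue
#'   set.
#' @inheritParams intra_contact_map
#' @return An `fs_contact_map` (kind `"intra"`).
#' @export
native_contact_frequency <- function(models, cutoff = 4.5, min_seq_sep = 3L) {
  if (!is.list(models) || length(models) < 2L) {
    abort("need a list of at least two models")
  }
  intra_contact_map(models, cutoff, min_seq_sep)
}

#' Inter-chain residue contact pairs of a two-chain frame
#'
#' All cross-chain residue pairs whose closest heavy atoms are closer than
#' `cutoff`; no sequence-separation filter applies across chains.
#'
#' @param frame A structure with exactly two chains.
#' @param cutoff Heavy-atom cutoff, Angstrom.
#' @return A tibble with columns `res_a` (first chain), `res_b` (second
#'   chain), sorted.
#' @export
inter_chain_contacts <- function(frame, cutoff = 4.5) {
  chains <- sort(unique(frame$chain))
  if (length(chains) != 2L) abort("frame must contain exactly two chains")
  h <- heavy(frame)
  A <- h[h$chain == chains[1], ]; B <- h[h$chain == chains[2], ]
  xa <- coords(A); xb <- coords(B)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(tibble::tibble(res_a = integer(), res_b = integer()))
  }
  out <- dplyr::distinct(tibble::tibble(res_a = A$resid[hit[, 1]],
                                        res_b = B$resid[hit[, 2]]))
  dplyr::arrange(out, .data$res_a, .data$res_b)
}

#' Inter-chain contact pairs along a trajectory
#'
#' Per-frame [inter_chain_contacts()] plus the scalar contact-count series
#' used for flat-stage (plateau) detection.
#'
#' @param traj A two-chain trajectory.
#' @param cutoff Heavy-atom cutoff, Angstrom.
#' @return An `fs_contact_series`: a list with `pairs` (tibble: `time_ps`,
#'   `res_a`, `res_b`) and `counts` (tibble: `time_ps`, `n_contacts`).
#' @export
contact_pair_timeseries <- function(traj, cutoff = 4.5) {
  n <- n_frames(traj)
  pairs <- vector("list", n)
  counts <- integer(n)
  for (i in seq_len(n)) {
    p <- inter_chain_contacts(traj_frame(traj, i), cutoff)
    counts[i] <- nrow(p)
    if (nrow(p)) p$time_ps <- traj$times_ps[i]
    pairs[[i]] <- p
  }
  structure(list(
    pairs = dplyr::bind_rows(pairs)[, c("time_ps", "res_a", "res_b")],
    counts = tibble::tibble(time_ps = traj$times_ps, n_contacts = counts)),
    class = "fs_contact_series")
}

#' @export
print.fs_contact_series <- function(x, ...) {
  cat(sprintf("<fs_contact_series> %d frames, %d contact records\n",
              nrow(x$counts), nrow(x$pairs)))
  invisible(x)
}

# normalise a segment argument: a selection, or c(start, end) residues
as_segment_selection <- function(seg) {
  if (inherits(seg, "fs_selection")) return(seg)
  selection(seg, atom_class = "mainchain")
}

#' Mainchain hydrogen bonds between two segments
#'
#' All Kabsch-Sander bonds (E < -0.5 kcal/mol) whose donor lies in one
#' segment and acceptor in the other, in both directions. Segments may be
#' on different chains.
#'
#' @param frame A structure.
#' @param seg_a,seg_b Segments: [selection()] objects or `c(start, end)`
#'   residue ranges (mainchain implied).
#' @return A tibble: `donor_chain`, `donor_res`, `acceptor_chain`,
#'   `acceptor_res`, `energy` (kcal/mol, all < -0.5).
#' @export
mainchain_hbonds_between <- function(frame, seg_a, seg_b) {
  seg_a <- as_segment_selection(seg_a); seg_b <- as_segment_selection(seg_b)
  bb <- backbone_table(frame)
  if (!any(bb$complete)) abort("no complete backbone residues in frame")
  in_seg <- function(seg) {
    hit <- rep(FALSE, nrow(bb))
    for (k in seq_len(nrow(seg$ranges))) {
      hit <- hit | (bb$resid >= seg$ranges[k, 1] & bb$resid <= seg$ranges[k, 2])
    }
    if (!is.null(seg$chain_id)) hit <- hit & bb$chain == seg$chain_id
    hit
  }
  a <- in_seg(seg_a); b <- in_seg(seg_b)
  if (!any(a) || !any(b)) abort("segment resolves to zero residues")
  E <- ks_energy_matrix(bb)
  rec <- which((outer(a, b) | outer(b, a)) & E < .hb_cutoff, arr.ind = TRUE)
  tibble::tibble(
    donor_chain = bb$chain[rec[, 1]], donor_res = bb$resid[rec[, 1]],
    acceptor_chain = bb$chain[rec[, 2]], acceptor_res = bb$resid[rec[, 2]],
    energy = E[rec])
}

#' Longest persistence of a mainchain hydrogen bond between segments
#'
#' The longest contiguous run of frames in which at least one mainchain
#' hydrogen bond links the two segments; a single bond-free frame breaks
#' a run. Duration is `t_end - t_start` of the run.
#'
#' @inheritParams mainchain_hbonds_between
#' @param traj A trajectory.
#' @return Longest duration in nanoseconds, with attributes `t_start_ps`
#'   and `t_end_ps` of the run (0 when no frame is bonded).
#' @export
hbond_persistence <- function(traj, seg_a, seg_b) {
  n <- n_frames(traj)
  bonded <- logical(n)
  for (i in seq_len(n)) {
    bonded[i] <- nrow(mainchain_hbonds_between(traj_frame(traj, i),
                                               seg_a, seg_b)) > 0L
  }
  if (!any(bonded)) {
    return(structure(0, t_start_ps = NA_real_, t_end_ps = NA_real_))
  }
  r <- rle(bonded)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  durations <- traj$times_ps[ends[runs]] - traj$times_ps[starts[runs]]
  k <- runs[which.max(durations)]
  structure(max(durations) / 1000,
            t_start_ps = traj$times_ps[starts[k] ],
            t_end_ps = traj$times_ps[ends[k] ])
}
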