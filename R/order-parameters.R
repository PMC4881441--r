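# Per-frame order parameters: least-squares superposition and RMSD,
# segment RMSDs, radius of gyration, Trp-Trp ring distance, hydrophobic
# core SASA, helix content.

#' Least-squares (Kabsch) superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) squared deviation of `X` onto `Y`; reflections are corrected
#' so that `det(rotation) = +1`.
#'
#' @param X,Y Numeric N x 3 coordinate matrices with matched rows (N >= 3).
#' @param weights Optional non-negative per-atom weights.
#' @return A list of class `fs_superposition` with elements `rotation`
#'   (3 x 3), `translation` (length 3) and `rmsd` (Angstrom); the fitted
#'   coordinates are `X %*% t(rotation) + translation` (row-wise).
#' @examples
#' X <- matrix(rnorm(12), 4, 3)
#' kabsch_superpose(X, X)$rmsd
#' @export
kabsch_superpose <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || ncol(X) != 3 || ncol(Y) != 3) {
    abort("X and Y must be N x 3 matrices with matching N")
  }
  n <- nrow(X)
  if (n < 3) abort("at least 3 points are required for superposition")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  mx <- colSums(X * w); my <- colSums(Y * w)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  H <- t(Xc * w) %*% Yc
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    abort("degenerate (collinear) coordinates: rotation is not determined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Yc)^2)))
  structure(list(rotation = R, translation = as.numeric(my - R %*% mx),
                 rmsd = rmsd),
            class = "fs_superposition")
}

#' @export
print.fs_superposition <- function(x, ...) {
  cat(sprintf("<fs_superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

# align two structures' atoms on (chain, resid, atom) keys restricted to a
# selection; returns matched coordinate matrices
matched_selection_coords <- function(frame, ref, sel) {
  fi <- resolve_selection(frame, sel)
  ri <- resolve_selection(ref, sel)
  fk <- paste(frame$chain[fi], frame$resid[fi], frame$atom[fi])
  rk <- paste(ref$chain[ri], ref$resid[ri], ref$atom[ri])
  m <- match(rk, fk)
  if (anyNA(m) || length(fi) != length(ri)) {
    abort("selection does not resolve to corresponding atoms in frame and reference")
  }
  list(frame = coords(frame)[fi[m], , drop = FALSE],
       ref = coords(ref)[ri, , drop = FALSE])
}

#' Segment RMSD against a reference
#'
#' Superposes the selected atoms of `frame` onto the same atoms of `ref`
#' and reports the minimised RMSD over exactly those atoms: the fit set
#' and the measure set coincide. With [sel_helix()] this is the
#' alpha-RMSD, with [sel_sheet()] the beta-RMSD, and with [sel_fold()]
#' the whole-protein RMSD (mainchain of residues 5-10, 14-27, 29-34).
#'
#' @param frame,ref Structures with corresponding atoms.
#' @param sel A [selection()].
#' @return RMSD in Angstrom.
#' @export
segment_rmsd <- function(frame, ref, sel) {
  m <- matched_selection_coords(frame, ref, sel)
  kabsch_superpose(m$frame, m$ref)$rmsd
}

#' Radius of gyration
#'
#' Mass-weighted over heavy atoms: `sqrt(sum(m_i |r_i - r_cm|^2) / sum(m_i))`.
#'
#' @param frame A structure.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame) {
  h <- heavy(frame)
  if (nrow(h) == 0L) abort("no heavy atoms")
  m <- .element_mass[h$element]
  xyz <- coords(h)
  cm <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, cm)^2)) / sum(m))
}

#' Distance between tryptophan indole-ring centroids
#'
#' The Euclidean distance between the centroids of the nine indole-ring
#' heavy atoms (CG, CD1, CD2, NE1, CE2, CE3, CZ2, CZ3, CH2) of two Trp
#' residues; with the defaults this is the W9-W34 order parameter of
#' DS119.
#'
#' @param frame A structure.
#' @param res_a,res_b Residue indices of the two tryptophans.
#' @param chain Optional chain restriction.
#' @return Distance in Angstrom.
#' @export
aromatic_distance <- function(frame, res_a = 9L, res_b = 34L, chain = NULL) {
  ring_centroid <- function(res) {
    s <- frame[frame$resid == res, ]
    if (!is.null(chain)) s <- s[s$chain == chain, ]
    if (nrow(s) == 0L) abort(sprintf("residue %d not found", res))
    if (!all(s$resname == "TRP")) {
      abort(sprintf("residue %d is %s, not TRP", res, s$resname[1]))
    }
    ring <- s[s$atom %in% .trp_ring_atoms, ]
    if (nrow(ring) != length(.trp_ring_atoms)) {
      abort(sprintf("residue %d has incomplete indole ring (%d of 9 atoms)",
                    res, nrow(ring)))
    }
    colMeans(coords(ring))
  }
  sqrt(sum((ring_centroid(res_a) - ring_centroid(res_b))^2))
}

# deterministic quasi-uniform sphere points (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area of the hydrophobic core
#'
#' Shrake-Rupley point-sampling SASA, summed over the heavy atoms of the
#' core residues; occlusion is computed against all heavy atoms of the
#' frame (both chains if present).
#'
#' @param frame A structure.
#' @param core Integer residue indices, default [core_definition()].
#' @param probe Probe radius in Angstrom (water, 1.4).
#' @param n_points Sphere sample points per atom.
#' @return SASA in Angstrom^2.
#' @export
shrake_rupley_sasa <- function(frame, core = core_definition(),
                               probe = 1.4, n_points = 960L) {
  h <- heavy(frame)
  bad <- !h$element %in% names(.vdw_radius)
  if (any(bad)) {
    abort(sprintf("no van der Waals radius for element(s): %s",
                  paste(unique(h$element[bad]), collapse = ", ")))
  }
  radii <- .vdw_radius[h$element]
  xyz <- coords(h)
  pts <- sphere_points(n_points)
  core_idx <- which(h$resid %in% core)
  if (length(core_idx) == 0L) abort("core selection resolves to zero atoms")
  total <- 0
  rmax <- max(radii)
  for (i in core_idx) {
    ri <- radii[i] + probe
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + rmax + probe)^2 & d2 > 1e-12)
    nb <- nb[d2[nb] < (ri + radii[nb] + probe)^2]
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      rj2 <- (radii[j] + probe)^2
      dj <- rowSums(sweep(p[exposed, , drop = FALSE], 2, xyz[j, ])^2)
      exposed[exposed] <- dj >= rj2
    }
    total <- total + 4 * pi * ri^2 * mean(exposed)
  }
  unname(total)
}

#' Helix content of a secondary-structure string
#'
#' @param ss A character vector of per-residue labels (`H`, `E`, `C`, or
#'   `X` for unassignable residues, which are excluded from the
#'   denominator).
#' @return Fraction of assignable residues labelled `H`, in `[0, 1]`.
#' @export
helix_content <- function(ss) {
  if (length(ss) == 1L && nchar(ss[1]) > 1L) ss <- strsplit(ss, "")[[1]]
  ok <- ss != "X"
  if (!any(ok)) return(NA_real_)
  mean(ss[ok] == "H")
}

#' Order parameters for every frame of a trajectory
#'
#' Computes, per frame: whole-protein RMSD (mainchain of residues
#' 5-10 + 14-27 + 29-34), alpha-RMSD (14-27), beta-RMSD (5-10 + 29-34),
#' radius of gyration, W9-W34 indole distance, hydrophobic-core SASA and
#' helix content.
#'
#' @param traj A single-chain trajectory.
#' @param ref Reference structure (same residue numbering).
#' @param sasa,ss Logical; compute the SASA / secondary-structure columns
#'   (the two expensive ones). Skipped columns are `NA`.
#' @param sasa_points Sphere points for the SASA calculation.
#' @return A tibble with one row per frame: `time_ps`, `rmsd`,
#'   `alpha_rmsd`, `beta_rmsd`, `rg`, `w9_w34`, `core_sasa`,
#'   `helix_content`.
#' @export
compute_order_params <- function(traj, ref, sasa = TRUE, ss = TRUE,
                                 sasa_points = 240L) {
  if (length(unique(traj$atoms$chain)) > 1L) {
    abort("compute_order_params expects a single-chain trajectory; extract chains first")
  }
  n <- n_frames(traj)
  out <- tibble::tibble(
    time_ps = traj$times_ps,
    rmsd = NA_real_, alpha_rmsd = NA_real_, beta_rmsd = NA_real_,
    rg = NA_real_, w9_w34 = NA_real_, core_sasa = NA_real_,
    helix_content = NA_real_)
  has_trp <- all(c(9L, 34L) %in% traj$atoms$resid[traj$atoms$resname == "TRP"])
  for (i in seq_len(n)) {
    f <- traj_frame(traj, i)
    out$rmsd[i] <- segment_rmsd(f, ref, sel_fold())
    out$alpha_rmsd[i] <- segment_rmsd(f, ref, sel_helix())
    out$beta_rmsd[i] <- segment_rmsd(f, ref, sel_sheet())
    out$rg[i] <- radius_of_gyration(f)
    if (has_trp) out$w9_w34[i] <- aromatic_distance(f)
    if (sasa) out$core_sasa[i] <- shrake_rupley_sasa(f, n_points = sasa_points)
    if (ss) out$helix_content[i] <- helix_content(assign_secondary_structure(f))
  }
  out
}
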