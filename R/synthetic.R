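# Synthetic-ensemble generation: a mock DS119 native reference built from
# the printed sequence with ideal secondary-structure geometry, extended
# (unfolded) templates, planted two-dimensional free-energy landscapes
# with Metropolis sampling, order-parameter-faithful conformational
# decoration, and scripted two-chain association trajectories. Every
# generator is exactly reproducible from (spec, seed) and emits
# machine-readable ground truth.

#' Build a mock DS119 native reference structure
#'
#' Constructs a 36-residue backbone (N, CA, C, O, CB stub, full indole
#' rings on tryptophans) with idealised geometry: the 14-27 helix at
#' (phi, psi) = (-57, -47) degrees, strands 5-10 and 29-34 as a paired
#' parallel beta-sheet (inter-strand spacing close to 4.8 A, register
#' chosen to maximise mainchain hydrogen bonds), and loops as geometric
#' connectors. This stands in for an experimental reference model so the
#' package builds and tests without downloads; a real NMR model read with
#' [read_pdb()] is a drop-in replacement.
#'
#' @param sequence One-letter sequence, 36 residues (the DS119 default).
#' @param chain_id Chain identifier.
#' @return A structure.
#' @export
build_mock_reference <- function(sequence = ds119_sequence(),
                                 chain_id = "A") {
  seq1 <- strsplit(sequence, "")[[1]]
  if (length(seq1) != 36L) abort("mock reference expects a 36-residue sequence")

  strand_phi <- -119; strand_psi <- 113
  # --- segment 1: residues 1-10 (N-tail coil + strand 5-10)
  phiA <- c(-70, -130, -70, -130, rep(strand_phi, 6))
  psiA <- c(150, 120, 150, 120, rep(strand_psi, 6))
  segA <- build_peptide(paste(seq1[1:10], collapse = ""), phiA, psiA,
                        chain_id, resid_offset = 0L)
  # orient strand 5-10 into a standard pose from its own backbone frame:
  # axis -> +x, alternating carbonyl (hydrogen-bond) direction -> +y,
  # side-chain pleat -> +/-z
  strand_pose <- function(seg, resids) {
    ca <- coords(seg[seg$atom == "CA" & seg$resid %in% resids, ])
    cw <- coords(seg[seg$atom == "C" & seg$resid %in% resids, ])
    ow <- coords(seg[seg$atom == "O" & seg$resid %in% resids, ])
    u <- unit3(ca[nrow(ca), ] - ca[1, ])
    co <- colSums((ow - cw) * (-1)^(seq_along(resids)))
    co <- unit3(co - sum(co * u) * u)
    M <- cbind(u, co, cross3(u, co))
    pivot <- colMeans(ca)
    set_coords(seg, sweep(coords(seg), 2, pivot) %*% M)
  }
  segA <- strand_pose(segA, 5:10)
  # keep the Trp9 side chain on the outer face of the sheet (-y, away
  # from the partner strand placed at +y)
  cb_dir_y <- function(seg, r) {
    seg$y[seg$resid == r & seg$atom == "CB"] -
      seg$y[seg$resid == r & seg$atom == "CA"]
  }
  if (cb_dir_y(segA, 9) > 0) {
    segA <- transform_structure(segA, rot_axis_angle(c(1, 0, 0), pi))
  }
  caA <- coords(segA[segA$atom == "CA" & segA$resid %in% 5:10, ])

  # --- segment 2: residues 29-36 (strand 29-34 + C-tail coil)
  phiB <- c(rep(strand_phi, 6), -70, -130)
  psiB <- c(rep(strand_psi, 6), 150, 120)
  segB0 <- build_peptide(paste(seq1[29:36], collapse = ""), phiB, psiB,
                         chain_id, resid_offset = 28L)
  caB0 <- coords(segB0[segB0$atom == "CA" & segB0$resid %in% 29:34, ])
  # scan register/pleat for the hydrogen-bond-richest parallel pairing
  strand_pair_energy <- function(segB) {
    both <- dplyr::bind_rows(segA[segA$resid %in% 5:10, ],
                             segB[segB$resid %in% 29:34, ])
    hb <- try(mainchain_hbonds_between(both, c(5, 10), c(29, 34)),
              silent = TRUE)
    if (inherits(hb, "try-error")) 0L else nrow(hb)
  }
  segB1 <- strand_pose(segB0, 29:34)
  gapA <- coords(heavy(segA[segA$resid %in% 5:10 &
                               !segA$atom %in% .trp_ring_atoms, ]))
  best <- NULL; best_n <- -1L; best_gap <- 0
  for (flip in c(FALSE, TRUE)) {
    base <- if (flip) transform_structure(segB1, rot_axis_angle(c(1, 0, 0), pi))
            else segB1
    for (dy in seq(4.4, 5.6, by = 0.2)) {
      if (cb_dir_y(base, 34) < 0) next  # Trp34 must face the outer (+y) side
      for (dx in seq(-4, 4, by = 0.25)) {
        cand <- transform_structure(base, diag(3), c(dx, dy, 0))
        gapB <- coords(heavy(cand[cand$resid %in% 29:34 &
                                    !cand$atom %in% .trp_ring_atoms, ]))
        gap <- min_cross_distance(gapA, gapB)
        if (gap < 2.4) next  # steric veto (rings re-oriented later)
        nhb <- strand_pair_energy(cand)
        if (nhb > best_n || (nhb == best_n && gap > best_gap)) {
          best_n <- nhb; best <- cand; best_gap <- gap
        }
      }
    }
  }
  if (is.null(best)) abort("no clash-free strand pairing found")
  segB <- best
  caB <- coords(segB[segB$atom == "CA" & segB$resid %in% 29:34, ])

  # --- helix: residues 14-27, placed above the sheet, its C-end dipping
  # toward the start of strand 2 so residue 28 can bridge it
  helix <- build_peptide(paste(seq1[14:27], collapse = ""),
                         rep(-57, 14), rep(-47, 14), chain_id,
                         resid_offset = 13L)
  ca10 <- caA[6, ]; ca29 <- caB[1, ]
  p_start <- ca10 + c(5.0, 2.8, 8.5)
  p_aim <- ca29 + c(0.5, -2.6, 5.5)
  hca <- coords(helix[helix$atom == "CA", ])
  a0 <- unit3(hca[14, ] - hca[1, ])
  R <- rot_between(a0, unit3(p_aim - p_start))
  helix <- transform_structure(helix, R, c(0, 0, 0))
  hca1 <- coords(helix[helix$atom == "CA", ])[1, ]
  helix <- transform_structure(helix, diag(3), p_start - hca1)
  hca <- coords(helix[helix$atom == "CA", ])

  # --- loops as geometric connectors
  centroid <- colMeans(rbind(coords(segA), coords(segB), coords(helix)))
  bezier <- function(p0, p2, bulge, t) {
    m <- (p0 + p2) / 2
    ctrl <- m + bulge * unit3(m - centroid)
    (1 - t)^2 %o% p0 + 2 * t * (1 - t) %o% ctrl + t^2 %o% p2
  }
  loop_atoms <- function(resids, ca_path, prev_C, next_N) {
    # sequential placement: each N continues from the previous carbonyl
    # carbon, each C points at the next residue, O and CB face outward
    rows <- vector("list", length(resids))
    pc <- prev_C
    for (k in seq_along(resids)) {
      ca <- ca_path[k, ]
      nxt <- if (k < length(resids)) ca_path[k + 1L, ] else next_N
      N <- pc + 1.33 * unit3(ca - pc)
      C <- ca + 1.52 * unit3(nxt - ca)
      u <- unit3(nxt - (if (k == 1) prev_C else ca_path[k - 1L, ]))
      refv <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      p <- unit3(cross3(u, refv))
      q <- unit3(cross3(u, p))
      outv <- ca - centroid
      if (sum(p * outv) < 0) p <- -p
      if (sum(q * outv) < 0) q <- -q
      O <- C + 1.23 * q
      res3 <- .aa3[[seq1[resids[k]]]]
      at <- rbind(N, ca, C, O)
      nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
      if (seq1[resids[k]] != "G") {
        at <- rbind(at, ca + 1.53 * p); nm <- c(nm, "CB"); el <- c(el, "C")
      }
      rows[[k]] <- tibble::tibble(atom = nm, element = el,
                                  resid = resids[k], resname = res3,
                                  chain = chain_id,
                                  x = at[, 1], y = at[, 2], z = at[, 3])
      pc <- C
    }
    dplyr::bind_rows(rows)
  }
  atom_of <- function(s, resid, name) {
    coords(s[s$resid == resid & s$atom == name, ])[1, ]
  }
  loop1 <- loop_atoms(11:13, bezier(ca10, hca[1, ], 5.5, c(0.22, 0.46, 0.72)),
                      prev_C = atom_of(segA, 10L, "C"),
                      next_N = atom_of(helix, 14L, "N"))
  loop2 <- loop_atoms(28L, bezier(hca[14, ], ca29, 1.5, 0.5),
                      prev_C = atom_of(helix, 27L, "C"),
                      next_N = atom_of(segB, 29L, "N"))

  s <- new_structure(dplyr::bind_rows(
    segA, loop1, helix, loop2, segB))
  s <- s[order(s$resid), ]
  s <- new_structure(s)

  # re-orient the Trp rings to the least-crowded rotamer
  for (w in which(seq1 == "W")) s <- orient_trp_ring(s, w)

  # closure sanity: consecutive CA spacing must stay peptide-like
  ca_all <- coords(s[s$atom == "CA", ])
  gaps <- sqrt(rowSums(diff(ca_all)^2))
  if (any(gaps > 4.6)) {
    abort(sprintf("loop closure failed near residue %d (CA gap %.2f A)",
                  which.max(gaps), max(gaps)))
  }
  s
}

# Re-place the indole ring of a Trp residue, scanning chi1 for the
# orientation that maximises its clearance from the rest of the
# structure (clearance capped at 3.5 A so distant rotamers tie).
orient_trp_ring <- function(s, resid) {
  rows <- which(s$resid == resid)
  ring_rows <- rows[s$atom[rows] %in% .trp_ring_atoms]
  if (!length(ring_rows)) return(s)
  gN <- coords(s[s$resid == resid & s$atom == "N", ])[1, ]
  gCA <- coords(s[s$resid == resid & s$atom == "CA", ])[1, ]
  gCB <- coords(s[s$resid == resid & s$atom == "CB", ])[1, ]
  # clearance is judged against non-adjacent residues (covalent neighbours
  # are legitimately close)
  other <- coords(s[abs(s$resid - resid) >= 2L, ])
  tmpl <- get_indole_2d()
  best_xyz <- NULL; best_clear <- -Inf
  for (chi in seq(-180, 150, by = 15)) {
    CG <- nerf_place(gN, gCA, gCB, 1.5, deg(114), deg(chi))
    ex <- unit3(CG - gCB)
    nref <- cross3(gCB - gCA, CG - gCB)
    ey <- unit3(cross3(nref, ex))
    ring <- t(apply(tmpl, 1, function(p) CG + p[1] * ex + p[2] * ey))
    d2 <- outer(rowSums(ring^2), rowSums(other^2), "+") -
      2 * ring %*% t(other)
    clear <- min(3.5, sqrt(max(min(d2), 0)))
    if (clear > best_clear) { best_clear <- clear; best_xyz <- ring }
  }
  ord <- match(s$atom[ring_rows], rownames(tmpl))
  s$x[ring_rows] <- best_xyz[ord, 1]
  s$y[ring_rows] <- best_xyz[ord, 2]
  s$z[ring_rows] <- best_xyz[ord, 3]
  s
}

#' Minimum distance between non-bonded heavy atoms
#'
#' The smallest heavy-atom distance between residues separated by at
#' least two positions in sequence (or on different chains); used as a
#' steric-clash diagnostic for built structures.
#'
#' @param s A structure.
#' @return Distance in Angstrom.
#' @export
min_nonbonded_distance <- function(s) {
  h <- heavy(s)
  xyz <- coords(h)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  same <- outer(h$chain, h$chain, "==") &
    abs(outer(h$resid, h$resid, "-")) <= 1L
  d2[same] <- Inf
  sqrt(max(min(d2), 0))
}

#' Build an extended (unfolded) chain
#'
#' A fully extended template (phi = psi = 180 degrees) with optional
#' per-residue dihedral jitter; same atom complement as
#' [build_mock_reference()], so the two can be blended atom-by-atom.
#'
#' @param sequence One-letter sequence.
#' @param jitter_deg Standard deviation of dihedral jitter (degrees).
#' @param seed Seed used when `jitter_deg > 0`.
#' @param chain_id Chain identifier.
#' @return A structure.
#' @export
build_extended_chain <- function(sequence = ds119_sequence(),
                                 jitter_deg = 0, seed = NULL,
                                 chain_id = "A") {
  n <- nchar(sequence)
  if (jitter_deg > 0) {
    if (!is.null(seed)) set.seed(seed)
    phi <- 180 + rnorm(n, sd = jitter_deg)
    psi <- 180 + rnorm(n, sd = jitter_deg)
  } else {
    phi <- rep(180, n); psi <- rep(180, n)
  }
  build_peptide(sequence, phi, psi, chain_id)
}

#' Specify a planted free-energy landscape
#'
#' The surface is a Gaussian-well mixture,
#' `F(x, y) = background - sum_b depth_b * exp(-((x-cx)^2+(y-cy)^2) / (2 w_b^2))`,
#' in kcal/mol over the (beta-RMSD, alpha-RMSD) plane.
#'
#' @param basins A data frame with columns `label`, `x`, `y` (centres, A),
#'   `depth` (kcal/mol, > 0), `width` (A, > 0).
#' @param background_F Background free energy (kcal/mol).
#' @param temperatures Temperature ladder (K) the spec is meant for.
#' @param xlim,ylim Sampling domain.
#' @return A `planted_landscape_spec`.
#' @export
planted_landscape_spec <- function(basins, background_F,
                                   temperatures = 300,
                                   xlim = c(0, 20), ylim = c(0, 8)) {
  basins <- tibble::as_tibble(basins)
  stopifnot(all(c("label", "x", "y", "depth", "width") %in% names(basins)),
            all(basins$depth > 0), all(basins$width > 0),
            nrow(basins) >= 1)
  structure(list(basins = basins, background_F = background_F,
                 temperatures = temperatures, xlim = xlim, ylim = ylim),
            class = "planted_landscape_spec")
}

#' The default DS119 five-state planted landscape
#'
#' Emulates the monomer folding landscape over (beta-RMSD, alpha-RMSD)
#' near the folding transition: a native-like state F' at (6.0, 1.8) A,
#' intermediates I1 (6.0, 5.0), I2 (6.0, 3.5) and I3 (15.0, 1.9), and an
#' unfolded state U (15.0, 3.6). Planted minima follow the relative
#' stabilities of the states (only differences are meaningful; the
#' absolute offset is arbitrary).
#'
#' @return A `planted_landscape_spec`.
#' @export
ds119_landscape_spec <- function() {
  minima <- c("F'" = 3.72, I1 = 2.96, I2 = 3.33, I3 = 3.62, U = 3.81)
  background <- 5.5
  planted_landscape_spec(
    basins = tibble::tibble(
      label = names(minima),
      x = c(6.0, 6.0, 6.0, 15.0, 15.0),
      y = c(1.8, 5.0, 3.5, 1.9, 3.6),
      depth = background - unname(minima),
      width = 0.45),
    background_F = background,
    temperatures = c(290.3, 319.3, 330.2, 352.3),
    xlim = c(0, 20), ylim = c(0, 8))
}

#' A planted two-basin calibration surface
#'
#' Two well-separated Gaussian wells with a free-energy difference of
#' `delta_F` between their minima and a barrier of `barrier` kcal/mol
#' from the shallow minimum to the flat background ridge separating them.
#'
#' @param delta_F Planted free-energy difference (kcal/mol).
#' @param barrier Planted barrier from the shallow basin (kcal/mol).
#' @param width Well width (A).
#' @return A `planted_landscape_spec` with basins `deep` and `shallow`.
#' @export
two_basin_spec <- function(delta_F = 1.0, barrier = 2.0, width = 1.5) {
  planted_landscape_spec(
    basins = tibble::tibble(
      label = c("deep", "shallow"),
      x = c(5, 15), y = c(2, 2),
      depth = c(barrier + delta_F, barrier),
      width = width),
    background_F = barrier + delta_F,
    temperatures = 300,
    xlim = c(0, 20), ylim = c(-2, 6))
}

#' Evaluate a planted free-energy surface
#'
#' @param spec A `planted_landscape_spec`.
#' @param x,y Coordinates (vectorised).
#' @return F in kcal/mol.
#' @export
planted_free_energy <- function(spec, x, y) {
  F <- rep(spec$background_F, length(x))
  for (b in seq_len(nrow(spec$basins))) {
    w2 <- 2 * spec$basins$width[b]^2
    F <- F - spec$basins$depth[b] *
      exp(-((x - spec$basins$x[b])^2 + (y - spec$basins$y[b])^2) / w2)
  }
  F
}

# exact planted observables on a fine grid: basin minima and the minimax
# saddle between two labelled basins
planted_ground_truth <- function(spec, from = NULL, to = NULL,
                                 res = 0.05) {
  xs <- seq(spec$xlim[1], spec$xlim[2], by = res)
  ys <- seq(spec$ylim[1], spec$ylim[2], by = res)
  minima <- tibble::tibble(
    label = spec$basins$label,
    x = spec$basins$x, y = spec$basins$y,
    min_F = planted_free_energy(spec, spec$basins$x, spec$basins$y))
  out <- list(minima = minima)
  if (!is.null(from) && !is.null(to)) {
    # the analytic saddle along any path is bounded by the background;
    # approximate via the best bridge on the fine 1D line between centres
    # plus a fine 2D sweep of the connecting corridor
    i <- match(from, spec$basins$label); j <- match(to, spec$basins$label)
    t <- seq(0, 1, length.out = 400)
    lx <- spec$basins$x[i] + t * (spec$basins$x[j] - spec$basins$x[i])
    ly <- spec$basins$y[i] + t * (spec$basins$y[j] - spec$basins$y[i])
    # allow vertical detours off the straight line
    best_max <- Inf
    for (dy in seq(-2, 2, by = 0.1)) {
      f <- planted_free_energy(spec, lx, ly + dy * sin(pi * t))
      best_max <- min(best_max, max(f))
    }
    out$saddle_F <- best_max
    out$barrier <- best_max - out$minima$min_F[i]
    out$delta_F <- abs(out$minima$min_F[i] - out$minima$min_F[j])
  }
  out
}

#' Metropolis-sample points from a planted landscape
#'
#' Runs several independent Metropolis walkers on the Boltzmann density
#' `exp(-F(x, y) / kB T)`, discards a burn-in, and thins; labels each
#' point by the nearest planted basin within two widths, else `"U"`.
#' Bit-identical output for a fixed seed.
#'
#' @param spec A `planted_landscape_spec`.
#' @param temperature Temperature (K).
#' @param n Number of points to return.
#' @param seed Integer seed.
#' @param step_sd Proposal standard deviation (A).
#' @param n_walkers Number of independent walkers.
#' @param burn_in Discarded sweeps per walker.
#' @param thin Keep every `thin`-th sweep.
#' @return A list: `points` (tibble `x`, `y`, `label`) and `truth`
#'   (planted minima table and the spec).
#' @export
sample_planted_points <- function(spec, temperature, n, seed,
                                  step_sd = 1.3, n_walkers = 50L,
                                  burn_in = 300L, thin = 8L) {
  if (n <= 0) abort("n must be positive")
  set.seed(seed)
  kT <- kB * temperature
  sweeps <- burn_in + thin * ceiling(n / n_walkers)
  x <- runif(n_walkers, spec$xlim[1], spec$xlim[2])
  y <- runif(n_walkers, spec$ylim[1], spec$ylim[2])
  f <- planted_free_energy(spec, x, y)
  keep_x <- matrix(NA_real_, ceiling(n / n_walkers), n_walkers)
  keep_y <- keep_x
  k <- 0L
  for (s in seq_len(sweeps)) {
    px <- x + rnorm(n_walkers, sd = step_sd)
    py <- y + rnorm(n_walkers, sd = step_sd)
    inside <- px >= spec$xlim[1] & px <= spec$xlim[2] &
      py >= spec$ylim[1] & py <= spec$ylim[2]
    pf <- planted_free_energy(spec, px, py)
    acc <- inside & (log(runif(n_walkers)) < (f - pf) / kT)
    x[acc] <- px[acc]; y[acc] <- py[acc]; f[acc] <- pf[acc]
    if (s > burn_in && (s - burn_in) %% thin == 0L) {
      k <- k + 1L
      keep_x[k, ] <- x; keep_y[k, ] <- y
    }
  }
  pts <- tibble::tibble(x = as.numeric(t(keep_x))[seq_len(n)],
                        y = as.numeric(t(keep_y))[seq_len(n)])
  # label by nearest basin within 2 widths
  d2 <- sapply(seq_len(nrow(spec$basins)), function(b) {
    (pts$x - spec$basins$x[b])^2 + (pts$y - spec$basins$y[b])^2
  })
  d2 <- matrix(d2, nrow = nrow(pts))
  nearest <- max.col(-d2)
  within <- d2[cbind(seq_len(nrow(pts)), nearest)] <=
    (2 * spec$basins$width[nearest])^2
  pts$label <- ifelse(within, spec$basins$label[nearest], "U")
  list(points = pts, truth = c(planted_ground_truth(spec), list(spec = spec)))
}

# lean superposed-RMSD from the Kabsch singular values (no rotation
# matrix materialised); used only in the decoration inner loop
kabsch_rmsd_fast <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  H <- crossprod(Xc, Yc)
  d <- svd(H, nu = 0, nv = 0)$d
  s <- sign(det(H))
  if (s == 0) s <- 1
  e2 <- (sum(Xc^2) + sum(Yc^2) - 2 * (d[1] + d[2] + s * d[3])) / n
  sqrt(max(e2, 0))
}

# search for the blend factor lambda whose segment RMSD hits the target;
# f(lambda) = rmsd((1-lambda) ref + lambda tmpl vs ref)
solve_blend <- function(ref_seg, tmpl_seg, noise_seg, target, tol = 0.1,
                        lambda_cap = 1.6, max_iter = 25L) {
  f <- function(l) {
    kabsch_rmsd_fast((1 - l) * ref_seg + l * tmpl_seg + noise_seg, ref_seg)
  }
  solve_custom(f, target, tol, lambda_cap, max_iter)
}

solve_custom <- function(f, target, tol = 0.1, lambda_cap = 1.6,
                         max_iter = 25L) {
  # bracket the target on a coarse grid, then bisect; f is continuous in
  # lambda but need not be exactly monotone
  grid <- seq(0, lambda_cap, length.out = 9L)
  fg <- vapply(grid, f, numeric(1))
  if (target > max(fg) + tol) {
    abort(sprintf("decoration target %.2f A unreachable (max %.2f A)",
                  target, max(fg)))
  }
  k <- which(fg >= target)[1]
  if (is.na(k)) k <- which.max(fg)
  if (abs(fg[k] - target) < tol) return(grid[k])
  lo <- if (k == 1L) 0 else grid[k - 1L]; hi <- grid[k]
  flo <- if (k == 1L) fg[1] else fg[k - 1L]
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target) < tol) return(mid)
    if ((fm - target) * (flo - target) < 0) hi <- mid
    else { lo <- mid; flo <- fm }
  }
  abort(sprintf("decoration failed to converge on target %.2f A", target))
}

#' Decorate order-parameter points with 3D conformations
#'
#' For each planted (beta-RMSD, alpha-RMSD) target, builds a conformation
#' by blending the reference with a globally aligned unfolded template --
#' helix residues (14-27) toward the alpha target, and the C-terminal
#' strand, loops and termini toward the beta target -- plus small
#' Cartesian noise, and verifies that the computed order parameters land
#' within `tol` of the target. The N-terminal strand (5-10) keeps its
#' native internal geometry: the beta-RMSD deviation is realised as a
#' displacement of the partner strand, which mirrors the dominant sheet
#' deformation of the planted states (native-like N-strand, broken
#' pairing). The decoration is geometric, not physical: fidelity is
#' measured in order parameters, not energetics.
#'
#' @param points Data frame with columns `x` (beta-RMSD target) and `y`
#'   (alpha-RMSD target), Angstrom.
#' @param ref Reference structure (e.g. [build_mock_reference()]).
#' @param unfolded Unfolded template (e.g. [build_extended_chain()]).
#' @param seed Integer seed.
#' @param noise_sd Cartesian noise, Angstrom.
#' @param tol Acceptance half-width on each achieved order parameter.
#' @param dt_ps Frame spacing for the emitted trajectory.
#' @param temperature Temperature label (K).
#' @return A list: `traj` (trajectory, frames in point order) and
#'   `achieved` (tibble of achieved alpha/beta-RMSD per frame).
#' @export
decorate_conformations <- function(points, ref, unfolded, seed,
                                   noise_sd = 0.05, tol = 0.15,
                                   dt_ps = 2, temperature = NA_real_) {
  set.seed(seed)
  # align the template onto the reference once, on CA atoms
  ca_r <- which(ref$atom == "CA"); ca_u <- which(unfolded$atom == "CA")
  fit <- kabsch_superpose(coords(unfolded)[ca_u, ], coords(ref)[ca_r, ])
  uxyz <- sweep(coords(unfolded) %*% t(fit$rotation), 2, fit$translation, "+")
  rxyz <- coords(ref)
  helix_rows <- ref$resid >= 14 & ref$resid <= 27
  nstrand_rows <- ref$resid >= 5 & ref$resid <= 10  # kept native
  beta_rows <- !helix_rows & !nstrand_rows
  a_idx <- resolve_selection(ref, sel_helix())
  b_idx <- resolve_selection(ref, sel_sheet())
  n_atoms <- nrow(ref)
  # the beta blend leaves the 5-10 rows at their reference positions,
  # so the solve operates on the mixed coordinate set
  blend_b <- function(l, noise) {
    out <- rxyz[b_idx, ]
    move <- !nstrand_rows[b_idx]
    out[move, ] <- (1 - l) * rxyz[b_idx, ][move, ] +
      l * uxyz[b_idx, ][move, ]
    out + noise
  }
  frames <- vector("list", nrow(points))
  ach_a <- numeric(nrow(points)); ach_b <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    noise <- matrix(rnorm(3 * n_atoms, sd = noise_sd), n_atoms, 3)
    la <- solve_blend(rxyz[a_idx, ], uxyz[a_idx, ], noise[a_idx, ],
                      target = points$y[i], tol = tol)
    fb <- function(l) kabsch_rmsd_fast(blend_b(l, noise[b_idx, ]),
                                       rxyz[b_idx, ])
    lb <- solve_custom(fb, target = points$x[i], tol = tol)
    xyz <- rxyz
    xyz[helix_rows, ] <- (1 - la) * rxyz[helix_rows, ] +
      la * uxyz[helix_rows, ]
    xyz[beta_rows, ] <- (1 - lb) * rxyz[beta_rows, ] +
      lb * uxyz[beta_rows, ]
    xyz <- xyz + noise
    fr <- set_coords(ref, xyz)
    frames[[i]] <- fr
    ach_a[i] <- kabsch_superpose(xyz[a_idx, ], rxyz[a_idx, ])$rmsd
    ach_b[i] <- kabsch_superpose(xyz[b_idx, ], rxyz[b_idx, ])$rmsd
  }
  traj <- as_trajectory(frames, dt_ps * (seq_len(nrow(points)) - 1),
                        temperature)
  list(traj = traj,
       achieved = tibble::tibble(alpha_rmsd = ach_a, beta_rmsd = ach_b,
                                 target_alpha = points$y,
                                 target_beta = points$x))
}

#' Script for a synthetic two-chain association trajectory
#'
#' @param t_end_ns Trajectory length (ns).
#' @param dt_ns Frame spacing (ns).
#' @param t_approach_ns End of the free-diffusion phase (ns).
#' @param t_bind_ns Binding time (ns); the two chains are in heavy-atom
#'   contact from this frame on. `NA` scripts a never-binding run.
#' @param interface_a,interface_b `c(start, end)` residue ranges held at
#'   the interface for each chain.
#' @param state_a,state_b Planted-state labels (from `spec`) from which
#'   each chain's internal conformation is decorated.
#' @param spec The planted landscape providing state centres.
#' @param start_separation Extra initial separation along the approach
#'   axis (A); the initial minimum inter-chain distance is at least 10 A.
#' @param noise_sd Per-frame Cartesian thermal noise (A).
#' @return A `dimer_script` list.
#' @export
dimer_script <- function(t_end_ns = 1200, dt_ns = 2, t_approach_ns = 60,
                         t_bind_ns = 100, interface_a = c(5, 10),
                         interface_b = c(5, 10), state_a = "I2",
                         state_b = "I3", spec = ds119_landscape_spec(),
                         start_separation = 30, noise_sd = 0.12,
                         rock_deg = 0, rock_shift = 0) {
  if (!is.na(t_bind_ns) &&
      !(t_approach_ns < t_bind_ns && t_bind_ns < t_end_ns)) {
    abort("need t_approach_ns < t_bind_ns < t_end_ns")
  }
  structure(list(t_end_ns = t_end_ns, dt_ns = dt_ns,
                 t_approach_ns = t_approach_ns, t_bind_ns = t_bind_ns,
                 interface_a = interface_a, interface_b = interface_b,
                 state_a = state_a, state_b = state_b, spec = spec,
                 start_separation = start_separation, noise_sd = noise_sd,
                 rock_deg = rock_deg, rock_shift = rock_shift),
            class = "dimer_script")
}

# minimum cross-chain heavy-atom distance between two coordinate sets
min_cross_distance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

#' Generate a scripted two-chain association trajectory
#'
#' Phase 1 (to `t_approach_ns`): the chains diffuse with at least 10 A
#' separation. Phase 2: rigid-body approach along the inter-interface
#' axis. Phase 3 (from `t_bind_ns`): the scripted interface residues are
#' held in heavy-atom contact under thermal noise, each chain keeping the
#' internal conformation decorated from its planted state.
#'
#' @param script A [dimer_script()].
#' @param ref Reference structure (chain A template).
#' @param unfolded Unfolded template with matching atoms.
#' @param seed Integer seed.
#' @return A list: `traj` (two-chain trajectory, ns times stored in ps)
#'   and `truth` (phase per frame, binding time, interfaces, states).
#' @export
generate_dimer_trajectory <- function(script, ref, unfolded, seed) {
  set.seed(seed)
  spec <- script$spec
  state_xy <- function(lab) {
    b <- spec$basins[spec$basins$label == lab, ]
    if (nrow(b) != 1L) abort(sprintf("unknown planted state '%s'", lab))
    c(b$x, b$y)
  }
  xy_a <- state_xy(script$state_a); xy_b <- state_xy(script$state_b)
  dec <- decorate_conformations(
    tibble::tibble(x = c(xy_a[1], xy_b[1]), y = c(xy_a[2], xy_b[2])),
    ref, unfolded, seed = seed + 1L, noise_sd = 0.03)
  chainA <- traj_frame(dec$traj, 1)
  chainB <- traj_frame(dec$traj, 2)
  chainB$chain <- "B"

  # bound pose: rotate B so its interface faces A's, then close the gap
  int_rows <- function(s, rng) {
    which(s$resid >= rng[1] & s$resid <= rng[2] & s$element != "H")
  }
  ia <- int_rows(chainA, script$interface_a)
  ib <- int_rows(chainB, script$interface_b)
  Axyz <- coords(chainA)
  cintA <- colMeans(Axyz[ia, , drop = FALSE])
  cintB <- colMeans(coords(chainB)[ib, , drop = FALSE])
  # outward normal of each interface patch: away from its local
  # (9 A) structural environment
  local_out <- function(xyz, cint, cen_fallback) {
    env <- xyz[rowSums(sweep(xyz, 2, cint)^2) < 81, , drop = FALSE]
    v <- cint - colMeans(env)
    if (sqrt(sum(v * v)) < 0.5) v <- cint - cen_fallback
    unit3(v)
  }
  uA <- local_out(Axyz, cintA, colMeans(Axyz))
  uB <- local_out(coords(chainB), cintB, colMeans(coords(chainB)))
  # dock by antiparallel segment apposition: lay chain B's interface
  # backbone alongside chain A's (reversed order) at a scanned normal
  # offset and register shift, with a steric veto; the pose with the
  # most interface residues in heavy-atom contact wins
  ca_of <- function(s, rng) {
    sub <- s[s$atom == "CA" & s$resid >= rng[1] & s$resid <= rng[2], ]
    coords(sub[order(sub$resid), ])
  }
  intA_ca <- ca_of(chainA, script$interface_a)
  intB_ca <- ca_of(chainB, script$interface_b)
  if (nrow(intA_ca) != nrow(intB_ca)) {
    abort("interface segments must have equal lengths")
  }
  uS <- unit3(intA_ca[nrow(intA_ca), ] - intA_ca[1, ])
  # balanced engagement score: strongly favour poses where BOTH scripted
  # interfaces have most residues in heavy-atom contact, and penalise
  # contacts made by residues well outside the scripted interfaces
  in_rng <- function(r, rng, pad = 2) r >= rng[1] - pad & r <= rng[2] + pad
  score_pose <- function(Bx) {
    d2 <- outer(rowSums(Axyz^2), rowSums(Bx^2), "+") - 2 * Axyz %*% t(Bx)
    hit <- d2 < 4.2^2
    ra <- unique(chainA$resid[rowSums(hit) > 0])
    rb <- unique(chainB$resid[colSums(hit) > 0])
    na <- sum(ra >= script$interface_a[1] & ra <= script$interface_a[2])
    nb <- sum(rb >= script$interface_b[1] & rb <= script$interface_b[2])
    extra <- sum(!in_rng(ra, script$interface_a)) +
      sum(!in_rng(rb, script$interface_b))
    10 * min(na, nb) + na + nb - 2 * extra
  }
  Bxyz <- coords(chainB)
  # translate a pose along the approach normal until the closest
  # heavy-atom pair sits at `target` Angstrom
  settle <- function(Bx, target = 3.2) {
    lo <- -10; hi <- 25
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      if (min_cross_distance(Axyz, sweep(Bx, 2, mid * uA, "+")) < target) {
        lo <- mid
      } else hi <- mid
    }
    sweep(Bx, 2, (lo + hi) / 2 * uA, "+")
  }
  tgt0 <- intA_ca[rev(seq_len(nrow(intA_ca))), ] +
    matrix(5 * uA, nrow(intA_ca), 3, byrow = TRUE)
  piv <- colMeans(tgt0)
  tax <- unit3(tgt0[nrow(tgt0), ] - tgt0[1, ])
  pose_at <- function(Bfit, roll, shift, target = 2.2) {
    Rr <- rot_axis_angle(tax, deg(roll))
    Bx <- sweep(sweep(Bfit, 2, piv) %*% t(Rr), 2, piv, "+")
    settle(sweep(Bx, 2, shift * uS, "+"), target)
  }
  # both antiparallel and parallel apposition of the two segments; the
  # near-collinear CA fit leaves the roll about the segment axis
  # undetermined, so it is scanned explicitly together with the register
  best_fit <- NULL; best_roll <- 0; best_shift <- 0; best_score <- -1L
  for (ord in list(rev(seq_len(nrow(intB_ca))), seq_len(nrow(intB_ca)))) {
    fit <- kabsch_superpose(intB_ca[ord, ], tgt0)
    Bfit <- sweep(Bxyz %*% t(fit$rotation), 2, fit$translation, "+")
    for (shift in seq(-2.25, 2.25, by = 0.75)) {
      for (roll in seq(0, 345, by = 15)) {
        sc <- score_pose(pose_at(Bfit, roll, shift))
        if (sc > best_score) {
          best_score <- sc; best_fit <- Bfit
          best_roll <- roll; best_shift <- shift
        }
      }
    }
  }
  # optional bound-phase rocking: the chains keep adjusting around the
  # docked pose, sweeping the contact patch along the interface
  n_rock <- 25L
  ph <- 2 * pi * (seq_len(n_rock) - 1) / n_rock
  rock_cycle <- lapply(seq_len(n_rock), function(k) {
    pose_at(best_fit, best_roll + script$rock_deg * sin(ph[k]),
            best_shift + script$rock_shift * cos(ph[k]))
  })
  best_B <- rock_cycle[[1]]
  place_B <- function(g) sweep(best_B, 2, g * uA, "+")

  times_ns <- seq(0, script$t_end_ns, by = script$dt_ns)
  nfr <- length(times_ns)
  binds <- !is.na(script$t_bind_ns)
  s_of_t <- function(t) {
    if (!binds) return(script$start_separation + 3 * sin(t / 150))
    if (t >= script$t_bind_ns) return(0)
    if (t <= script$t_approach_ns) {
      return(script$start_separation + 2 * sin(t / 40))
    }
    frac <- (t - script$t_approach_ns) /
      (script$t_bind_ns - script$t_approach_ns)
    script$start_separation * (1 - frac) + 6 * frac
  }
  phase <- if (!binds) {
    rep("search", nfr)
  } else {
    ifelse(times_ns >= script$t_bind_ns, "bound",
           ifelse(times_ns > script$t_approach_ns, "approach", "search"))
  }
  frames <- vector("list", nfr)
  na <- nrow(chainA)
  for (i in seq_len(nfr)) {
    Bx <- if (phase[i] == "bound") {
      rock_cycle[[(i - 1L) %% n_rock + 1L]]
    } else {
      place_B(s_of_t(times_ns[i]))
    }
    noise <- matrix(rnorm(3 * (na + nrow(chainB)), sd = script$noise_sd),
                    ncol = 3)
    fr <- dplyr::bind_rows(chainA, set_coords(chainB, Bx))
    fr <- set_coords(fr, coords(fr) + noise)
    frames[[i]] <- new_structure(fr, model_id = i)
  }
  traj <- as_trajectory(frames, times_ns * 1000, NA_real_)
  truth <- list(phase = phase, t_bind_ns = script$t_bind_ns,
                interface_a = script$interface_a,
                interface_b = script$interface_b,
                state_a = script$state_a, state_b = script$state_b,
                achieved = dec$achieved)
  list(traj = traj, truth = truth)
}

#' Counter-ions needed to neutralise a peptide system
#'
#' Formal charge per chain is `(#Lys + #Arg) - (#Asp + #Glu)` with
#' zwitterionic termini contributing net zero; histidine is treated as
#' neutral. Returns the number and species of monovalent counter-ions for
#' `n_chains` copies.
#'
#' @param sequence One-letter sequence.
#' @param n_chains Number of chains in the box.
#' @return A list: `n_ions`, `species` (`"Cl-"` or `"Na+"`, `NA` when the
#'   system is already neutral), `net_charge`.
#' @examples
#' neutralizing_ion_count(ds119_sequence(), n_chains = 2)
#' @export
neutralizing_ion_count <- function(sequence, n_chains = 1L) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- !seq1 %in% names(.aa3)
  if (any(bad)) {
    abort(sprintf("nonstandard residue letter(s): %s",
                  paste(unique(seq1[bad]), collapse = ", ")))
  }
  per_chain <- sum(seq1 %in% c("K", "R")) - sum(seq1 %in% c("D", "E"))
  net <- per_chain * n_chains
  list(n_ions = abs(net),
       species = if (net > 0) "Cl-" else if (net < 0) "Na+" else NA_character_,
       net_charge = net)
}

#' Total replica-exchange campaign time
#'
#' Bookkeeping helper: the summed simulated time of a replica ladder.
#'
#' @param n_replicas Number of replicas.
#' @param t_each_ns Simulated time per replica (ns).
#' @return Total time in nanoseconds.
#' @export
remd_total_time_ns <- function(n_replicas = 26L, t_each_ns = 500) {
  n_replicas * t_each_ns
}

#' Recover planted landscape parameters from sampled points
#'
#' Samples a planted surface with [sample_planted_points()], rebuilds the
#' landscape by histogramming, and measures the free-energy difference
#' between the two lowest basin minima (on the raw grid) and the minimax
#' barrier from the shallow to the deep basin (on a lightly smoothed
#' grid, which stabilises the saddle estimate without biasing the flat
#' ridge).
#'
#' @param spec A two-basin `planted_landscape_spec` (default
#'   [two_basin_spec()]).
#' @param temperature Sampling temperature (K).
#' @param n Number of Metropolis samples.
#' @param seed Integer seed.
#' @param bin_width Grid bin width (A).
#' @param sigma_bins Count-smoothing sigma for the barrier grid.
#' @param f_max Basin ceiling above the global minimum (kcal/mol).
#' @return A list: `delta_F`, `barrier`, `truth` (analytic planted
#'   values), `grid`, `basins`.
#' @export
recover_planted_landscape <- function(spec = two_basin_spec(),
                                      temperature = 300, n = 1e5,
                                      seed = 1, bin_width = 0.5,
                                      sigma_bins = 0.6, f_max = 1.5,
                                      region_bins = 2L, ...) {
  samp <- sample_planted_points(spec, temperature, n, seed, ...)
  xe <- seq(spec$xlim[1], spec$xlim[2], by = bin_width)
  ye <- seq(spec$ylim[1], spec$ylim[2], by = bin_width)
  raw <- build_landscape(samp$points, xe, ye, temperature)
  sm <- smooth_landscape(raw, sigma_bins)
  basins <- find_basins(sm, f_max = f_max)
  if (length(basins) < 2L) {
    abort("fewer than two basins recovered from the sampled landscape")
  }
  # minima are read from the raw grid at each basin's smoothed argmin bin
  # (single-bin estimates avoid the min-selection bias of scanning noisy
  # bins; the smoothed argmin pins the location)
  kT <- kB * temperature
  # each well minimum: count-weighted quadratic fit of -kT log p over the
  # 5x5 core around the (smoothed) argmin -- interpolates away the bin
  # discretisation and curvature biases of a single-bin estimate
  fit_min <- function(b) {
    ix <- b$min_bin[1] + seq(-region_bins, region_bins)
    iy <- b$min_bin[2] + seq(-region_bins, region_bins)
    ix <- ix[ix >= 1 & ix <= nrow(raw$counts)]
    iy <- iy[iy >= 1 & iy <= ncol(raw$counts)]
    cc <- raw$counts[ix, iy]
    gx <- bin_centers(raw$x_edges)[ix]; gy <- bin_centers(raw$y_edges)[iy]
    df <- expand.grid(x = gx - mean(gx), y = gy - mean(gy))
    df$c <- as.numeric(cc)
    df <- df[df$c > 0, ]
    single <- -kT * log(max(cc) / sum(raw$counts))
    if (nrow(df) < 8) return(single)
    df$f <- -kT * log(df$c / sum(raw$counts))
    X <- with(df, cbind(1, x, y, x^2, y^2, x * y))
    beta <- tryCatch(
      solve(crossprod(X * sqrt(df$c)) / 1, crossprod(X * df$c, df$f)),
      error = function(e) NULL)
    if (is.null(beta)) return(single)
    A <- matrix(c(2 * beta[4], beta[6], beta[6], 2 * beta[5]), 2, 2)
    if (det(A) <= 0 || beta[4] <= 0) return(single)
    v <- -solve(A, beta[2:3])
    if (max(abs(v)) > region_bins * diff(raw$x_edges[1:2])) return(single)
    as.numeric(beta[1] + beta[2:3] %*% v + 0.5 * t(v) %*% A %*% v)
  }
  min_F_abs <- vapply(basins, fit_min, numeric(1))
  # basins come sorted by smoothed min_F: [1] deep, [2] shallow
  delta_F <- min_F_abs[2] - min_F_abs[1]
  # the saddle is located by the minimax search on the lightly smoothed
  # grid (the ridge is flat, where smoothing is locally unbiased); the
  # barrier compares the saddle probability with the fitted shallow
  # minimum on the same absolute -kT log p scale
  bar <- minimax_barrier(sm, basins, from = basins[[2]]$label,
                         to = basins[[1]]$label)
  p_saddle <- sm$counts[bar$saddle_bin[1], bar$saddle_bin[2]] /
    sum(sm$counts)
  barrier <- -kT * log(p_saddle) - min_F_abs[2]
  truth <- planted_ground_truth(spec, from = spec$basins$label[2],
                                to = spec$basins$label[1])
  list(delta_F = delta_F, barrier = barrier, truth = truth,
       grid = raw, smoothed = sm, basins = basins)
}
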