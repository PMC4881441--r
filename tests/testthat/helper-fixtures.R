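# Shared fixtures and independent oracles for the test suite.

# a small artificial structure: n_res residues of n_atoms_per heavy atoms
# at random positions in a box
random_structure <- function(n_res, n_atoms_per = 4, box = 15, seed = 1) {
  set.seed(seed)
  n <- n_res * n_atoms_per
  as_structure(tibble::tibble(
    atom = rep(c("N", "CA", "C", "O"), length.out = n),
    resid = rep(seq_len(n_res), each = n_atoms_per),
    resname = "ALA", chain = "A",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box)))
}

random_rigid_motion <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); th <- runif(1, 0, pi)
  R <- foldscape:::rot_axis_angle(ax, th)
  list(R = R, t = rnorm(3, sd = 10))
}

apply_rigid <- function(s, rm) {
  xyz <- cbind(s$x, s$y, s$z) %*% t(rm$R)
  s$x <- xyz[, 1] + rm$t[1]; s$y <- xyz[, 2] + rm$t[2]
  s$z <- xyz[, 3] + rm$t[3]
  s
}

# brute-force all-pairs atom contact oracle
brute_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sum((xyz[i, ] - xyz[j, ])^2) < cutoff^2) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

# independent minimax-barrier oracle: the saddle between two bins is the
# smallest threshold f at which they become 8-connected in {F <= f}
threshold_saddle <- function(F, src, dst) {
  nx <- nrow(F); ny <- ncol(F)
  connected_at <- function(f) {
    ok <- is.finite(F) & F <= f
    if (!ok[src[1], src[2]] || !ok[dst[1], dst[2]]) return(FALSE)
    seen <- matrix(FALSE, nx, ny)
    queue <- list(src); seen[src[1], src[2]] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (all(cur == dst)) return(TRUE)
      for (dx in -1:1) for (dy in -1:1) {
        x <- cur[1] + dx; y <- cur[2] + dy
        if (x < 1 || x > nx || y < 1 || y > ny) next
        if (ok[x, y] && !seen[x, y]) {
          seen[x, y] <- TRUE
          queue[[length(queue) + 1L]] <- c(x, y)
        }
      }
    }
    FALSE
  }
  for (f in sort(unique(F[is.finite(F)]))) {
    if (connected_at(f)) return(f)
  }
  Inf
}

# wrap a bare F matrix as a landscape object (counts are a consistent
# Boltzmann back-transform; only F matters for basin/barrier code)
grid_from_F <- function(F, bin = 1) {
  structure(list(
    x_edges = seq(0, by = bin, length.out = nrow(F) + 1),
    y_edges = seq(0, by = bin, length.out = ncol(F) + 1),
    counts = ifelse(is.finite(F), exp(-F), 0),
    F = F, temperature = 300),
    class = "fs_landscape")
}

fake_basin <- function(F, ix, iy, label = "a") {
  list(label = label, bins = cbind(ix = ix, iy = iy),
       min_bin = c(ix[1], iy[1]), min_F = F[ix[1], iy[1]],
       min_x = ix[1] - 0.5, min_y = iy[1] - 0.5)
}

as_basins <- function(...) structure(list(...), class = "fs_basins")

# rotation-grid RMSD oracle: coarse-to-fine search over Euler angles of
# the superposed RMSD of two centred point sets
grid_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rmsd_of <- function(a, b, c) {
    R <- foldscape:::rot_axis_angle(c(0, 0, 1), c) %*%
      foldscape:::rot_axis_angle(c(0, 1, 0), b) %*%
      foldscape:::rot_axis_angle(c(1, 0, 0), a)
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  ctr <- c(0, 0, 0); span <- pi
  best <- Inf
  for (pass in 1:4) {
    gr <- seq(-span, span, length.out = 9)
    for (a in ctr[1] + gr) for (b in ctr[2] + gr) for (c in ctr[3] + gr) {
      v <- rmsd_of(a, b, c)
      if (v < best) { best <- v; ctr <- c(a, b, c) }
    }
    span <- span / 6
  }
  best
}

# two ideal antiparallel paired strands as separate chains, placed by
# scanning offset, register and twist for the pose with the most
# strand-paired residues (computed once, cached for the whole run)
.paired_strands_cache <- NULL
build_paired_strands <- function() {
  if (!is.null(.paired_strands_cache)) return(.paired_strands_cache)
  s1 <- foldscape:::build_peptide("VAVAVA", rep(-139, 6), rep(135, 6),
                                  chain_id = "A")
  s2 <- foldscape:::build_peptide("AVAVAV", rep(-139, 6), rep(135, 6),
                                  chain_id = "B")
  # antiparallel: rotate the second strand 180 degrees about z
  s2 <- foldscape:::transform_structure(
    s2, foldscape:::rot_axis_angle(c(0, 0, 1), pi))
  best <- NULL; best_n <- -1
  for (g in seq(-30, 30, 10)) {
    s2g <- foldscape:::transform_structure(
      s2, foldscape:::rot_axis_angle(c(1, 0, 0), g * pi / 180))
    for (dy in seq(4.0, 5.6, 0.2)) for (dx in seq(-4, 4, 0.5)) {
      for (dz in seq(-1.5, 1.5, 0.5)) {
        cand <- foldscape:::transform_structure(s2g, diag(3), c(dx, dy, dz))
        both <- as_structure(dplyr::bind_rows(s1, cand))
        bb <- foldscape:::backbone_table(both)
        nhb <- sum(foldscape:::ks_energy_matrix(bb) < -0.5)
        if (nhb < 2) next
        ne <- sum(assign_secondary_structure(both) == "E")
        score <- 10 * ne + nhb
        if (score > best_n) { best_n <- score; best <- both }
      }
    }
  }
  .paired_strands_cache <<- best
  best
}

# a two-TRP toy frame from the planar indole template
two_trp_frame <- function(shift = c(3, 4, 0)) {
  tmpl <- foldscape:::get_indole_2d()
  ring <- cbind(tmpl, 0)
  mk <- function(resid, offset) {
    tibble::tibble(atom = rownames(tmpl),
                   element = ifelse(rownames(tmpl) == "NE1", "N", "C"),
                   resid = resid, resname = "TRP", chain = "A",
                   x = ring[, 1] + offset[1], y = ring[, 2] + offset[2],
                   z = ring[, 3] + offset[3])
  }
  as_structure(dplyr::bind_rows(mk(9L, c(0, 0, 0)), mk(34L, shift)))
}
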