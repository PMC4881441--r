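# Internal geometry: vector helpers, NeRF chain extension, idealised
# peptide construction (backbone + O + CB stub + Trp indole rings).

unit3 <- function(v) v / sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rot_axis_angle <- function(axis, theta) {
  a <- unit3(axis)
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * (a %o% a)
}

# rotation taking unit vector u onto unit vector v
rot_between <- function(u, v) {
  u <- unit3(u); v <- unit3(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rot_axis_angle(cross3(u, p), pi))
  }
  rot_axis_angle(cross3(u, v), acos(c_))
}

# Natural extension reference frame: place atom D bonded to C, with
# bond length L, angle theta = angle(B, C, D) and dihedral chi = (A,B,C,D).
nerf_place <- function(A, B, C, L, theta, chi) {
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-L * cos(theta),
         L * sin(theta) * cos(chi),
         L * sin(theta) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

deg <- function(x) x * pi / 180

# idealised backbone geometry (Engh-Huber-like)
.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.53,
  ang_n_ca_c = deg(111.2), ang_ca_c_n = deg(116.2), ang_c_n_ca = deg(121.7),
  ang_ca_c_o = deg(120.5), omega = deg(180))

# 2D idealised indole template: fused pentagon + hexagon, bond 1.42 A.
# Returns a 9 x 2 matrix with rows CG, CD1, NE1, CE2, CD2, CE3, CZ3, CH2,
# CZ2; CG at the origin with the ring extending along +x.
indole_template <- function() {
  side <- 1.42
  r5 <- side / (2 * sin(pi / 5))
  ang <- pi + seq(0, 4) * 2 * pi / 5  # pentagon around origin
  pent <- cbind(cos(ang), sin(ang)) * r5
  rownames(pent) <- c("CG", "CD1", "NE1", "CE2", "CD2")
  # fuse hexagon on the CE2-CD2 edge, centred away from the pentagon
  m <- (pent["CE2", ] + pent["CD2", ]) / 2
  d <- m / sqrt(sum(m * m))
  hex_c <- m + d * side * sqrt(3) / 2
  hex_ring <- function(sgn) {
    t(vapply(0:5, function(k) {
      R <- rot_axis_angle(c(0, 0, 1), sgn * k * pi / 3)[1:2, 1:2]
      hex_c + as.numeric(R %*% (pent["CD2", ] - hex_c))
    }, numeric(2)))
  }
  hex_pts <- hex_ring(1)
  # pick the rotation direction that walks away from CE2 first
  if (sum((hex_pts[2, ] - pent["CE2", ])^2) < 0.01) hex_pts <- hex_ring(-1)
  rownames(hex_pts) <- c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2")
  ring <- rbind(pent, hex_pts[c("CE3", "CZ3", "CH2", "CZ2"), ])
  # shift so CG is the origin, rotate so the centroid lies along +x
  ring <- sweep(ring, 2, ring["CG", ])
  cen <- colMeans(ring)
  phi <- atan2(cen[2], cen[1])
  R <- matrix(c(cos(-phi), sin(-phi), -sin(-phi), cos(-phi)), 2, 2)
  ring %*% t(R)
}

.indole_2d <- indole_template()

get_indole_2d <- function() .indole_2d

# Build a peptide with prescribed per-residue (phi, psi), idealised bond
# geometry, carbonyl O, CB on non-Gly residues and indole rings on Trp.
# phi[1] and psi[n] still shape terminal atom placement. Returns a
# structure tibble.
build_peptide <- function(sequence, phi, psi, chain_id = "A",
                          resid_offset = 0L, trp_chi1 = NULL) {
  seq1 <- strsplit(sequence, "")[[1]]
  n <- length(seq1)
  stopifnot(length(phi) == n, length(psi) == n)
  phi <- deg(phi); psi <- deg(psi)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  # seed frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.bb$n_ca, 0, 0)
  # C1 in the xy plane with angle N-CA-C = ang_n_ca_c
  C[1, ] <- CA[1, ] + .bb$ca_c *
    c(cos(pi - .bb$ang_n_ca_c), sin(pi - .bb$ang_n_ca_c), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], .bb$c_n,
                             .bb$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], .bb$n_ca,
                              .bb$ang_c_n_ca, .bb$omega)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], .bb$ca_c,
                             .bb$ang_n_ca_c, phi[i + 1])
    # carbonyl O of residue i: external bisector of CA-C-N(i+1)
    O[i, ] <- C[i, ] + .bb$c_o *
      unit3(unit3(C[i, ] - CA[i, ]) + unit3(C[i, ] - N[i + 1, ]))
  }
  O[n, ] <- nerf_place(N[n, ], CA[n, ], C[n, ], .bb$c_o, .bb$ang_ca_c_o,
                       psi[n] + pi)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res3 <- .aa3[[seq1[i]]]
    at <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    if (seq1[i] != "G") {
      CB <- nerf_place(N[i, ], C[i, ], CA[i, ], .bb$ca_cb,
                       deg(110.6), deg(-122.6))
      at <- rbind(at, CB); nm <- c(nm, "CB"); el <- c(el, "C")
      if (seq1[i] == "W") {
        chi1 <- -60
        if (!is.null(trp_chi1)) {
          key <- as.character(i + resid_offset)
          if (key %in% names(trp_chi1)) chi1 <- trp_chi1[[key]]
        }
        CG <- nerf_place(N[i, ], CA[i, ], CB, 1.5, deg(114), deg(chi1))
        ex <- unit3(CG - CB)
        nref <- cross3(CB - CA[i, ], CG - CB)
        ey <- unit3(cross3(nref, ex))
        tmpl <- get_indole_2d()
        ring <- t(apply(tmpl, 1, function(p) CG + p[1] * ex + p[2] * ey))
        at <- rbind(at, ring)
        nm <- c(nm, rownames(tmpl))
        el <- c(el, ifelse(rownames(tmpl) == "NE1", "N", "C"))
      }
    }
    rows[[i]] <- tibble::tibble(
      atom = nm, element = el, resid = i + resid_offset, resname = res3,
      chain = chain_id, x = at[, 1], y = at[, 2], z = at[, 3])
  }
  new_structure(dplyr::bind_rows(rows))
}

# rigidly transform a structure: x -> x %*% t(R) + t
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  set_coords(s, sweep(coords(s) %*% t(R), 2, t, "+"))
}
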