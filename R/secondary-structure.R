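# Kabsch-Sander mainchain hydrogen-bond energies and a minimal
# secondary-structure assignment over the {H, E, C} alphabet.
#
# E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, and a bond
# exists when E < -0.5 kcal/mol. The amide H is rebuilt from the previous
# residue's carbonyl when absent: H = N + unit(C_prev - O_prev).

.hb_cutoff <- -0.5

# Per-residue backbone table for a frame: one row per (chain, resid) with
# N, CA, C, O and reconstructed H coordinates. Rows with missing backbone
# atoms get complete = FALSE.
backbone_table <- function(frame) {
  key <- paste(frame$chain, frame$resid)
  res <- !duplicated(key)
  tbl <- tibble::tibble(chain = frame$chain[res], resid = frame$resid[res],
                        resname = frame$resname[res])
  tbl <- tbl[order(tbl$chain, tbl$resid), ]
  nres <- nrow(tbl)
  get_atom <- function(name) {
    m <- match(paste(tbl$chain, tbl$resid, name),
               paste(frame$chain, frame$resid, frame$atom))
    cbind(frame$x[m], frame$y[m], frame$z[m])
  }
  N <- get_atom("N"); CA <- get_atom("CA"); C <- get_atom("C")
  O <- get_atom("O")
  complete <- stats::complete.cases(N) & stats::complete.cases(CA) &
    stats::complete.cases(C) & stats::complete.cases(O)
  H_exp <- get_atom("H")
  H <- H_exp
  for (i in seq_len(nres)) {
    if (!is.na(H[i, 1])) next
    j <- i - 1L
    if (i > 1L && tbl$chain[j] == tbl$chain[i] &&
        tbl$resid[j] == tbl$resid[i] - 1L && complete[j] && complete[i]) {
      H[i, ] <- N[i, ] + unit3(C[j, ] - O[j, ])
    }
  }
  has_donor <- complete & !is.na(H[, 1]) & tbl$resname != "PRO"
  tbl$complete <- complete
  tbl$has_donor <- has_donor
  tbl$N <- N; tbl$CA <- CA; tbl$C <- C; tbl$O <- O; tbl$H <- H
  tbl
}

# Kabsch-Sander energy matrix: E[d, a] = energy of the bond donated by the
# NH of residue d to the CO of residue a (kcal/mol; +Inf where undefined).
ks_energy_matrix <- function(bb) {
  nres <- nrow(bb)
  E <- matrix(Inf, nres, nres)
  don <- which(bb$has_donor)
  acc <- which(bb$complete)
  if (!length(don) || !length(acc)) return(E)
  pdist <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 1e-12))
  }
  r_on <- pdist(bb$N[don, , drop = FALSE], bb$O[acc, , drop = FALSE])
  r_ch <- pdist(bb$H[don, , drop = FALSE], bb$C[acc, , drop = FALSE])
  r_oh <- pdist(bb$H[don, , drop = FALSE], bb$O[acc, , drop = FALSE])
  r_cn <- pdist(bb$N[don, , drop = FALSE], bb$C[acc, , drop = FALSE])
  e <- 27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  e[r_oh < 0.5] <- -9.9  # near-contact clamp, as in the original scheme
  E[don, acc] <- e
  # exclude self and covalently adjacent residues within a chain
  for (i in seq_len(nres)) {
    near <- which(bb$chain == bb$chain[i] & abs(bb$resid - bb$resid[i]) <= 1L)
    E[i, near] <- Inf
  }
  E
}

#' Assign secondary structure (minimal DSSP)
#'
#' A minimal dictionary-of-secondary-structure assignment over the
#' three-letter alphabet `H` (alpha-helix), `E` (strand/bridge) and `C`
#' (coil). Helices come from runs of i -> i+4 mainchain hydrogen bonds
#' and strands from parallel/antiparallel bridge patterns, both using the
#' Kabsch-Sander energy criterion (bond when E < -0.5 kcal/mol). Residues
#' with missing backbone atoms are labelled `X` and excluded from
#' [helix_content()] denominators. Bridges may cross chains; helix runs
#' cannot.
#'
#' @param frame A structure with mainchain N, CA, C, O atoms.
#' @return A character vector of per-residue labels, ordered by
#'   (chain, resid), with names `chain:resid`.
#' @export
assign_secondary_structure <- function(frame) {
  bb <- backbone_table(frame)
  nres <- nrow(bb)
  E <- ks_energy_matrix(bb)
  hb <- E < .hb_cutoff  # hb[d, a]: NH of d bonded to CO of a
  lab <- rep("C", nres)
  lab[!bb$complete] <- "X"

  # contiguity helper: position of (chain, resid + k) in the table
  succ <- function(i, k) {
    j <- match(paste(bb$chain[i], bb$resid[i] + k), paste(bb$chain, bb$resid))
    j
  }
  # alpha-helix: turn4(i) iff NH(i+4) -> CO(i); residues i..i+3 are H when
  # turn4(i-1) and turn4(i)
  turn4 <- rep(FALSE, nres)
  for (i in seq_len(nres)) {
    j <- succ(i, 4L)
    if (!is.na(j) && hb[j, i]) turn4[i] <- TRUE
  }
  for (i in seq_len(nres)) {
    p <- succ(i, -1L)
    if (turn4[i] && !is.na(p) && turn4[p]) {
      for (k in 0:3) {
        j <- succ(i, k)
        if (!is.na(j) && lab[j] != "X") lab[j] <- "H"
      }
    }
  }
  # bridges (strand label E); |i - j| >= 3 within a chain, any cross-chain.
  # Candidate (i, j) pairs are generated from the observed bonds, then each
  # candidate is verified against the full parallel/antiparallel patterns.
  hbond <- function(a, d) !is.na(a) && !is.na(d) && hb[d, a]  # CO(a)<-NH(d)
  bonds <- which(hb, arr.ind = TRUE)  # columns: donor, acceptor
  cand <- list()
  for (b in seq_len(nrow(bonds))) {
    d <- bonds[b, 1]; a <- bonds[b, 2]
    cand[[length(cand) + 1L]] <- rbind(
      c(succ(a, 1L), d),            # parallel:     Hbond(i-1, j)
      c(d, succ(a, -1L)),           # parallel:     Hbond(j, i+1) -> j = d
      c(a, d),                      # antiparallel: Hbond(i, j)
      c(succ(a, 1L), succ(d, -1L))) # antiparallel: Hbond(i-1, j+1)
  }
  if (length(cand)) {
    cand <- unique(do.call(rbind, cand))
    cand <- cand[stats::complete.cases(cand), , drop = FALSE]
    for (b in seq_len(nrow(cand))) {
      i <- min(cand[b, ]); j <- max(cand[b, ])
      if (i == j) next
      if (bb$chain[i] == bb$chain[j] && abs(bb$resid[i] - bb$resid[j]) < 3L) next
      im <- succ(i, -1L); ip <- succ(i, 1L)
      jm <- succ(j, -1L); jp <- succ(j, 1L)
      par <- (hbond(im, j) && hbond(j, ip)) || (hbond(jm, i) && hbond(i, jp))
      anti <- (hbond(i, j) && hbond(j, i)) || (hbond(im, jp) && hbond(jm, ip))
      if (par || anti) {
        if (lab[i] == "C") lab[i] <- "E"
        if (lab[j] == "C") lab[j] <- "E"
      }
    }
  }
  names(lab) <- paste(bb$chain, bb$resid, sep = ":")
  lab
}
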