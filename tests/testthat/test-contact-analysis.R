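test_that("contact threshold is strict and symmetric", {
  mk <- function(d) as_structure(tibble::tibble(
    atom = c("CA", "CA"), resid = c(1L, 5L), resname = "ALA", chain = "A",
    x = c(0, d), y = 0, z = 0))
  expect_true(residues_in_contact(mk(4.49), 1, 5))
  expect_false(residues_in_contact(mk(4.51), 1, 5))
  expect_identical(residues_in_contact(mk(4.0), 1, 5),
                   residues_in_contact(mk(4.0), 5, 1))
})

test_that("the neighbour-grid contact search equals brute force", {
  for (seed in 1:50) {
    s <- random_structure(20, n_atoms_per = 3, box = 12, seed = seed)
    xyz <- coords(s)
    got <- foldscape:::atom_pairs_within(xyz, 4.5, method = "cell")
    want <- brute_pairs(xyz, 4.5)
    expect_setequal(paste(got[, 1], got[, 2]),
                    paste(want[, 1], want[, 2]))
  }
})

test_that("intra-chain maps honour the sequence-separation rule and symmetry", {
  ref <- build_mock_reference()
  cm <- intra_contact_map(ref)
  expect_true(all(cm$freq %in% c(0, 1)))  # single frame
  expect_identical(cm$freq, t(cm$freq))
  # |i - j| < 3 band is zero by construction
  for (d in 0:2) {
    expect_true(all(cm$freq[col(cm$freq) - row(cm$freq) == d] == 0))
  }
  # the beta-sheet corner: strand 5-10 touches strand 29-34
  expect_gt(sum(cm$freq[5:10, 29:34]), 5)
})

test_that("ensemble maps average per-frame maps and ignore frame order", {
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 5)
  dec <- decorate_conformations(
    tibble::tibble(x = c(1, 8, 14), y = c(0.6, 3, 5)), ref, unf, seed = 6)
  frames <- lapply(1:3, function(i) traj_frame(dec$traj, i))
  m_all <- intra_contact_map(frames)
  per <- lapply(frames, intra_contact_map)
  avg <- Reduce(`+`, lapply(per, `[[`, "freq")) / 3
  expect_equal(m_all$freq, avg)
  m_perm <- intra_contact_map(frames[c(3, 1, 2)])
  expect_equal(m_perm$freq, m_all$freq)
})

test_that("native contact frequency treats models as frames", {
  ref <- build_mock_reference()
  moved <- ref
  rows <- moved$resid >= 29
  moved$y[rows] <- moved$y[rows] + 30  # break the sheet in model 2
  nm <- native_contact_frequency(list(ref, as_structure(moved)))
  expect_equal(nm$n_frames, 2)
  # sheet contacts present in exactly one of the two models
  sheet <- nm$freq[5:10, 29:34]
  expect_true(all(sheet[sheet > 0] == 0.5))
  expect_error(native_contact_frequency(list(ref)), "two models")
})

test_that("inter-chain contacts need two chains and match brute force", {
  ref <- build_mock_reference()
  expect_error(inter_chain_contacts(ref), "two chains")
  b <- ref; b$chain <- "B"; b$x <- b$x + 100
  far <- as_structure(dplyr::bind_rows(ref, b))
  expect_equal(nrow(inter_chain_contacts(far)), 0)

  b2 <- ref; b2$chain <- "B"; b2$y <- b2$y - 6
  pair <- as_structure(dplyr::bind_rows(ref, b2))
  got <- inter_chain_contacts(pair)
  expect_gt(nrow(got), 0)
  # brute-force oracle over residue pairs
  want <- list()
  for (i in 1:36) for (j in 1:36) {
    if (residues_in_contact(pair, i, j, chain_i = "A", chain_j = "B")) {
      want[[length(want) + 1L]] <- c(i, j)
    }
  }
  want <- do.call(rbind, want)
  expect_setequal(paste(got$res_a, got$res_b),
                  paste(want[, 1], want[, 2]))
})

test_that("hydrogen-bond persistence follows the scripted on/off pattern", {
  both <- build_paired_strands()
  apart <- both
  rows <- apart$chain == "B"
  apart$x[rows] <- apart$x[rows] + 50
  apart <- as_structure(apart)
  # pattern: on on off on on on off  (2 ps spacing)
  frames <- list(both, both, apart, both, both, both, apart)
  traj <- as_trajectory(frames, seq(0, by = 2000, length.out = 7))
  segA <- selection(c(1, 6), chain_id = "A")
  segB <- selection(c(1, 6), chain_id = "B")
  dur <- hbond_persistence(traj, segA, segB)
  expect_equal(as.numeric(dur), 4)  # frames 4..6 span 4 ns
  expect_equal(attr(dur, "t_start_ps"), 6000)

  all_on <- as_trajectory(list(both, both, both), c(0, 2000, 4000))
  expect_equal(as.numeric(hbond_persistence(all_on, segA, segB)), 4)
  none <- as_trajectory(list(apart, apart), c(0, 2000))
  expect_equal(as.numeric(hbond_persistence(none, segA, segB)), 0)
})
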