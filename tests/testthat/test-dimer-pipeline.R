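# Small scripted trajectories exercise each dimer-analysis operation;
# the full eight-simulation campaign lives in the acceptance suite.

make_two_chain <- function(offset) {
  ref <- build_mock_reference()
  b <- ref; b$chain <- "B"
  b$x <- b$x + offset[1]; b$y <- b$y + offset[2]; b$z <- b$z + offset[3]
  as_structure(dplyr::bind_rows(ref, b))
}

test_that("minimum inter-chain distance matches brute force", {
  near <- make_two_chain(c(0, -15, 0))
  h <- foldscape:::heavy(near)
  A <- coords(h[h$chain == "A", ]); B <- coords(h[h$chain == "B", ])
  brute <- sqrt(min(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
  expect_equal(min_interchain_distance(near), brute, tolerance = 1e-9)
  far <- make_two_chain(c(150, 0, 0))
  expect_gte(min_interchain_distance(far), 100)
  expect_error(min_interchain_distance(build_mock_reference()), "two chains")
})

test_that("binding detection applies the persistence window", {
  near <- make_two_chain(c(0, -15, 0))   # in contact (about 3.4 A)
  far <- make_two_chain(c(150, 0, 0))
  # contact at frames 3-4 only (times 0,5,10,15,20,25 ns): a 5-ns window
  # needs two consecutive contact frames
  frames <- list(far, far, near, near, far, far)
  traj <- as_trajectory(frames, seq(0, by = 5000, length.out = 6))
  expect_equal(detect_binding(traj, persist_ns = 5)$t_bind_ns, 10)
  expect_null(detect_binding(traj, persist_ns = 10))
  # degenerate window: first sub-cutoff frame
  expect_equal(detect_binding(traj, persist_ns = 0)$t_bind_ns, 10)
  all_far <- as_trajectory(list(far, far, far), c(0, 5000, 10000))
  expect_null(detect_binding(all_far))
})

test_that("a two-chain frame in loose contact registers its closest residues", {
  near <- make_two_chain(c(0, -15, 0))
  got <- inter_chain_contacts(near)
  expect_gt(nrow(got), 0)
})

test_that("flat-stage detection finds plateaus and rejects drifts", {
  t_ps <- seq(0, 300, by = 2) * 1000
  const <- tibble::tibble(time_ps = t_ps, n_contacts = 12L)
  st <- detect_flat_stage(const, window_ns = 50, slope_tol = 0.05)
  expect_equal(st$t_start_ns, 0)
  expect_equal(st$t_end_ns, 300)

  rising <- tibble::tibble(time_ps = t_ps,
                           n_contacts = as.integer(seq_along(t_ps)))
  expect_null(detect_flat_stage(rising, window_ns = 50, slope_tol = 0))

  # grow-then-plateau: the detected start sits at the breakpoint
  y <- c(seq(0, 30, length.out = 51), rep(30, 100))
  gp <- tibble::tibble(time_ps = t_ps[seq_along(y)], n_contacts = y)
  st2 <- detect_flat_stage(gp, window_ns = 50, slope_tol = 0.05)
  expect_equal(st2$t_start_ns, 100, tolerance = 4)
})

test_that("stage statistics ignore constant time offsets", {
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 30)
  sc <- dimer_script(t_end_ns = 200, t_approach_ns = 20, t_bind_ns = 40)
  g <- generate_dimer_trajectory(sc, ref, unf, seed = 31)
  series <- contact_pair_timeseries(g$traj)
  stage <- detect_flat_stage(series$counts, t_from_ns = 40)
  im <- interface_map(g$traj, stage)

  shifted <- g$traj
  shifted$times_ps <- shifted$times_ps + 5e5
  series2 <- contact_pair_timeseries(shifted)
  stage2 <- detect_flat_stage(series2$counts, t_from_ns = 40 + 500)
  im2 <- interface_map(shifted, stage2)
  expect_equal(im2$map$freq, im$map$freq)
  expect_equal(im2$segments$start, im$segments$start)
})

test_that("interface maps expose marginals consistent with the pair map", {
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 32)
  sc <- dimer_script(t_end_ns = 200, t_approach_ns = 20, t_bind_ns = 40)
  g <- generate_dimer_trajectory(sc, ref, unf, seed = 33)
  stage <- list(t_start_ns = 40, t_end_ns = 200)
  im <- interface_map(g$traj, stage)
  expect_true(im$truncated)  # 160 ns < the 400 ns statistics window
  expect_true(all(im$map$freq >= 0 & im$map$freq <= 1))
  # a residue's marginal can never exceed the sum of its pair rows
  mA <- im$marginals[im$marginals$chain == "A", ]
  expect_true(all(mA$freq <= rowSums(im$map$freq) + 1e-9))
  # the scripted interface dominates
  expect_true(any(im$segments$start <= 6 & im$segments$end >= 9))
})

test_that("common-segment support is bounded by the number of simulations", {
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 34)
  sims <- lapply(1:2, function(i) {
    sc <- dimer_script(t_end_ns = 160, t_approach_ns = 20, t_bind_ns = 40)
    g <- generate_dimer_trajectory(sc, ref, unf, seed = 40 + i)
    interface_map(g$traj, list(t_start_ns = 40, t_end_ns = 160))
  })
  rep2 <- common_segment_report(sims)
  expect_true(all(rep2$support$support <= 2))
  expect_true(all(rep2$support$support[5:9] >= 1))
  rep1 <- common_segment_report(sims[1])
  expect_true(all(rep1$support$support %in% 0:1))
})

test_that("the average structure is an isometry-respecting fixed point", {
  ref <- build_mock_reference()
  b <- ref; b$chain <- "B"; b$y <- b$y - 8
  frame <- as_structure(dplyr::bind_rows(ref, b))
  # identical frames -> that frame
  traj_same <- as_trajectory(list(frame, frame, frame), c(0, 2000, 4000))
  avg <- average_structure(traj_same, NULL)
  expect_equal(coords(avg), coords(frame), tolerance = 1e-6)

  # frames differing by a rigid motion -> internal distances preserved
  moved <- apply_rigid(frame, random_rigid_motion(50))
  traj_rm <- as_trajectory(list(frame, as_structure(moved)), c(0, 2000))
  avg2 <- average_structure(traj_rm, NULL)
  idx <- seq(1, nrow(frame), by = 25)
  d_ref <- dist(coords(frame)[idx, ])
  d_avg <- dist(coords(avg2)[idx, ])
  expect_equal(as.numeric(d_avg), as.numeric(d_ref), tolerance = 1e-4)
  expect_lte(attr(avg2, "iterations"), 20)
})

test_that("the representative snapshot matches an exhaustive scan", {
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 35)
  sc <- dimer_script(t_end_ns = 120, t_approach_ns = 20, t_bind_ns = 40)
  g <- generate_dimer_trajectory(sc, ref, unf, seed = 36)
  stage <- list(t_start_ns = 40, t_end_ns = 120)
  avg <- average_structure(g$traj, stage)
  snap <- representative_snapshot(g$traj, stage, avg)
  # linear-scan oracle
  hrows <- which(g$traj$atoms$element != "H")
  t_ns <- g$traj$times_ps / 1000
  idx <- which(t_ns >= 40 & t_ns <= 120)
  r <- vapply(idx, function(i) {
    kabsch_superpose(g$traj$xyz[i, hrows, ], coords(avg)[hrows, ])$rmsd
  }, numeric(1))
  expect_equal(snap$frame, idx[which.min(r)])
  expect_identical(snap, representative_snapshot(g$traj, stage, avg))
})

test_that("monomer projection treats the two chains independently", {
  spec <- ds119_landscape_spec()
  mono <- run_monomer_pipeline(list(seed = 3, n_points = 30000,
                                    decorate = FALSE), spec = spec)
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 37)
  dec <- decorate_conformations(tibble::tibble(x = c(6, 15), y = c(1.8, 1.9)),
                                ref, unf, seed = 38)
  a <- traj_frame(dec$traj, 1)
  b <- traj_frame(dec$traj, 2); b$chain <- "B"; b$x <- b$x + 60
  snap <- as_structure(dplyr::bind_rows(a, b))
  pr <- project_monomers(snap, ref, mono$smoothed, mono$basins)
  expect_equal(nrow(pr), 2)
  expect_identical(pr$label, c("F'", "I3"))
  expect_true(all(pr$status %in% c("in", "near")))
  # swapping chain labels swaps the rows
  swapped <- snap
  swapped$chain <- ifelse(snap$chain == "A", "B", "A")
  pr2 <- project_monomers(as_structure(swapped), ref, mono$smoothed,
                          mono$basins)
  expect_identical(pr2$label, rev(pr$label))
})
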