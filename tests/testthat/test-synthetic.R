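test_that("the mock reference reproduces the designed DS119 fold", {
  ref <- build_mock_reference()
  expect_identical(extract_sequence(ref), ds119_sequence())
  ss <- assign_secondary_structure(ref)
  expect_gte(sum(ss[14:27] == "H"), 12)
  expect_true(all(ss[c(5:10, 29:34)] != "H"))
  expect_gte(sum(ss[5:10] == "E"), 4)
  expect_gte(sum(ss[29:34] == "E"), 4)
  # paired sheet shows up as the off-diagonal contact block
  cm <- intra_contact_map(ref)
  expect_gt(sum(cm$freq[5:10, 29:34] > 0), 4)
  # the build is sterically sane and self-consistent
  expect_gte(min_nonbonded_distance(ref), 2.0)
  expect_equal(segment_rmsd(ref, ref, sel_helix()), 0, tolerance = 1e-9)
  expect_equal(segment_rmsd(ref, ref, sel_sheet()), 0, tolerance = 1e-9)
  expect_error(build_mock_reference("GSG"), "36-residue")
})

test_that("generators are exactly reproducible from their seed", {
  spec <- two_basin_spec()
  a <- sample_planted_points(spec, 300, 500, seed = 7)
  b <- sample_planted_points(spec, 300, 500, seed = 7)
  expect_identical(a$points, b$points)
  c <- sample_planted_points(spec, 300, 500, seed = 8)
  expect_false(identical(a$points$x, c$points$x))

  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 1)
  pts <- tibble::tibble(x = c(3, 9), y = c(1, 4))
  d1 <- decorate_conformations(pts, ref, unf, seed = 3)
  d2 <- decorate_conformations(pts, ref, unf, seed = 3)
  expect_identical(d1$traj$xyz, d2$traj$xyz)
})

test_that("Metropolis sampling honours the Boltzmann weights", {
  # a single deep well captures nearly all points
  lone <- planted_landscape_spec(
    tibble::tibble(label = "w", x = 5, y = 2, depth = 4, width = 1.2),
    background_F = 4, xlim = c(0, 10), ylim = c(-2, 6))
  samp <- sample_planted_points(lone, 300, 4000, seed = 5)
  expect_gte(mean(samp$points$label == "w"), 0.95)

  # the relative occupancy of two wells follows their planted depths
  spec <- two_basin_spec(delta_F = 1.0, barrier = 2.0)
  samp2 <- sample_planted_points(spec, 300, 30000, seed = 6)
  occ <- table(samp2$points$label)
  # occupancy ratio ~ exp(dF/kT) * (width ratio term); with equal widths
  # the log-ratio of peak densities is the planted delta-F
  rec <- recover_planted_landscape(spec, n = 30000, seed = 6)
  expect_equal(rec$delta_F, 1.0, tolerance = 0.25)
  expect_gt(occ[["deep"]], occ[["shallow"]])

  # high-temperature limit flattens the occupancies
  hot <- sample_planted_points(spec, 3e4, 20000, seed = 7)
  frac_deep_hot <- mean(hot$points$label == "deep")
  frac_deep_cold <- mean(samp2$points$label == "deep")
  expect_lt(frac_deep_hot, frac_deep_cold)
})

test_that("decoration hits its order-parameter targets", {
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 11)
  set.seed(12)
  pts <- tibble::tibble(x = runif(40, 1, 16), y = runif(40, 0.4, 6))
  dec <- decorate_conformations(pts, ref, unf, seed = 13)
  err_a <- abs(dec$achieved$alpha_rmsd - dec$achieved$target_alpha)
  err_b <- abs(dec$achieved$beta_rmsd - dec$achieved$target_beta)
  expect_gte(mean(err_a <= 0.75 & err_b <= 0.75), 0.99)

  # near-native target -> near-native whole-protein RMSD
  nat <- decorate_conformations(tibble::tibble(x = 0.5, y = 0.5),
                                ref, unf, seed = 14)
  expect_lt(segment_rmsd(traj_frame(nat$traj, 1), ref, sel_fold()), 2)

  # I3-like target: helix intact, terminals separated
  i3 <- decorate_conformations(tibble::tibble(x = 15, y = 1.9),
                               ref, unf, seed = 15)
  f <- traj_frame(i3$traj, 1)
  expect_lt(segment_rmsd(f, ref, sel_helix()), 2.7)
  expect_gt(segment_rmsd(f, ref, sel_sheet()), 13)

  # unreachable targets are refused loudly
  expect_error(decorate_conformations(tibble::tibble(x = 80, y = 1),
                                      ref, unf, seed = 16),
               "unreachable")
})

test_that("decorated ensembles recover the planted landscape", {
  # like the calibration surface, but confined to physically decodable
  # (positive) order-parameter space
  spec <- planted_landscape_spec(
    tibble::tibble(label = c("deep", "shallow"), x = c(5, 15),
                   y = c(2.5, 2.5), depth = c(3, 2), width = 1.2),
    background_F = 3, xlim = c(0.5, 19), ylim = c(0.4, 6))
  samp <- sample_planted_points(spec, 300, 6000, seed = 17)
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 18)
  dec <- decorate_conformations(samp$points, ref, unf, seed = 19)
  p <- compute_order_params(dec$traj, ref, sasa = FALSE, ss = FALSE)
  xe <- seq(spec$xlim[1], spec$xlim[2], 0.5)
  ye <- seq(spec$ylim[1], spec$ylim[2], 0.5)
  g <- build_landscape(tibble::tibble(x = p$beta_rmsd, y = p$alpha_rmsd),
                       xe, ye, 300)
  sm <- smooth_landscape(g, 0.6)
  basins <- find_basins(sm, f_max = 1.5)
  expect_length(basins, 2)
  tb <- tidy(basins)
  # planted centres recovered within one bin
  expect_equal(tb$min_x[1], 5, tolerance = 0.55)
  expect_equal(tb$min_y[1], 2.5, tolerance = 0.55)
  expect_equal(tb$min_x[2], 15, tolerance = 0.55)
  # planted free-energy difference (tolerance widened from the n = 1e5
  # figure by the sqrt(n) factor for this 6e3-frame ensemble)
  expect_equal(tb$min_F[2] - tb$min_F[1], 1.0, tolerance = 0.3)
})

test_that("dimer scripts produce the scripted association phenomenology", {
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 20)
  sc <- dimer_script(t_end_ns = 240, t_approach_ns = 30, t_bind_ns = 60)
  g <- generate_dimer_trajectory(sc, ref, unf, seed = 21)
  ds <- interchain_distance_series(g$traj)
  # >= 10 A separation at t = 0, no contacts before the scripted binding
  expect_gte(ds$min_dist[1], 10)
  pre <- ds$min_dist[g$traj$times_ps < 60000]
  expect_true(all(pre >= 4.5))
  bind <- detect_binding(g$traj)
  expect_equal(bind$t_bind_ns, 60)
  # ground truth covers every frame
  expect_length(g$truth$phase, n_frames(g$traj))
  # a never-binding script stays apart
  none <- generate_dimer_trajectory(
    dimer_script(t_end_ns = 120, t_bind_ns = NA), ref, unf, seed = 22)
  expect_null(detect_binding(none$traj))
  expect_error(dimer_script(t_bind_ns = 20, t_approach_ns = 30),
               "t_approach")
})

test_that("charge bookkeeping matches the printed system setup", {
  expect_equal(neutralizing_ion_count("GGGG", 3)$n_ions, 0)
  expect_equal(neutralizing_ion_count("KKDD", 1)$n_ions, 0)
  ion <- neutralizing_ion_count(ds119_sequence(), n_chains = 2)
  expect_equal(ion$n_ions, 4)
  expect_identical(ion$species, "Cl-")
  expect_equal(ion$net_charge, 4)
  neg <- neutralizing_ion_count("DDEE", 1)
  expect_identical(neg$species, "Na+")
  expect_error(neutralizing_ion_count("GXZ"), "nonstandard")
})
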