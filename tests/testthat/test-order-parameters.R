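test_that("superposition recovers rigid motions and matches a grid oracle", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3)
  rm <- random_rigid_motion(12)
  Y <- sweep(X %*% t(rm$R), 2, rm$t, "+")
  fit <- kabsch_superpose(X, Y)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # symmetry of the minimised deviation
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
  expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
               tolerance = 1e-10)

  # two fixed 4-point toy sets against exhaustive rotation-grid search
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1.2), 4, 3,
              byrow = TRUE)
  Q <- matrix(c(0.1, -0.2, 0, 1.2, 0.3, 0.1, -0.4, 1.1, -0.3,
                0.5, 0.6, 1.0), 4, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(P, Q)$rmsd, grid_rmsd(P, Q),
               tolerance = 1e-3)

  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line * 2), "collinear")
})

test_that("segment RMSD superposes on the selected atoms only", {
  ref <- build_mock_reference()
  expect_equal(segment_rmsd(ref, ref, sel_helix()), 0, tolerance = 1e-9)
  expect_equal(segment_rmsd(ref, ref, sel_sheet()), 0, tolerance = 1e-9)

  # rigidly displacing the helix does not change alpha-RMSD (the fit is
  # internal to the segment) but does change the whole-fold RMSD
  moved <- ref
  rows <- moved$resid >= 14 & moved$resid <= 27
  moved$x[rows] <- moved$x[rows] + 8
  moved$z[rows] <- moved$z[rows] + 5
  expect_equal(segment_rmsd(moved, ref, sel_helix()), 0, tolerance = 1e-9)
  expect_gt(segment_rmsd(moved, ref, sel_fold()), 1)

  # an unfolded chain is far from the native helix
  unf <- build_extended_chain()
  expect_gt(segment_rmsd(unf, ref, sel_helix()), 3)
})

test_that("radius of gyration follows its closed form and isometries", {
  two <- as_structure(tibble::tibble(
    atom = c("C1", "C2"), resid = c(1L, 2L), resname = "ALA", chain = "A",
    x = c(0, 2), y = 0, z = 0))
  expect_equal(radius_of_gyration(two), 1.0)

  pt <- as_structure(tibble::tibble(
    atom = "CA", resid = 1L, resname = "GLY", chain = "A",
    x = 1, y = 2, z = 3))
  expect_equal(radius_of_gyration(pt), 0)

  ref <- build_mock_reference()
  for (k in 1:4) {
    expect_equal(radius_of_gyration(apply_rigid(ref, random_rigid_motion(k))),
                 radius_of_gyration(ref), tolerance = 1e-9)
  }
})

test_that("the tryptophan ring distance uses the indole centroids", {
  expect_equal(aromatic_distance(two_trp_frame(c(0, 0, 0))), 0)
  expect_equal(aromatic_distance(two_trp_frame(c(3, 4, 0))), 5.0)
  f <- two_trp_frame()
  expect_equal(aromatic_distance(f, 9, 34), aromatic_distance(f, 34, 9))
  broken <- f[-3, ]
  expect_error(aromatic_distance(as_structure(broken)), "incomplete")
  notrp <- f; notrp$resname <- "PHE"
  expect_error(aromatic_distance(as_structure(notrp)), "not TRP")
})

test_that("SASA matches the isolated-sphere closed form and saturates when buried", {
  lone <- as_structure(tibble::tibble(
    atom = "C", resid = 8L, resname = "ILE", chain = "A",
    x = 0, y = 0, z = 0))
  expect_equal(shrake_rupley_sasa(lone, core = 8L, probe = 1.4),
               4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  # a tight octahedral-plus cage buries the central atom
  shell <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2))
  shell <- shell[!(shell$x == 0 & shell$y == 0 & shell$z == 0), ]
  caged <- as_structure(tibble::tibble(
    atom = c("C", rep("C", nrow(shell))),
    resid = c(8L, rep(1L, nrow(shell))), resname = "ILE", chain = "A",
    x = c(0, shell$x), y = c(0, shell$y), z = c(0, shell$z)))
  expect_lt(shrake_rupley_sasa(caged, core = 8L), 1)

  # monotone decrease as a neighbour approaches
  two_at <- function(d) as_structure(tibble::tibble(
    atom = c("C", "C"), resid = c(8L, 1L), resname = "ILE", chain = "A",
    x = c(0, d), y = 0, z = 0))
  sasas <- vapply(c(6, 5, 4, 3), function(d) {
    shrake_rupley_sasa(two_at(d), core = 8L)
  }, numeric(1))
  expect_true(all(diff(sasas) < 0))

  # sampling convergence: doubling the point count changes < 2%
  ref <- build_mock_reference()
  a <- shrake_rupley_sasa(ref, n_points = 480L)
  b <- shrake_rupley_sasa(ref, n_points = 960L)
  expect_lt(abs(a - b) / b, 0.02)
})

test_that("helix content counts assignable residues", {
  expect_equal(helix_content(rep("C", 10)), 0)
  expect_equal(helix_content(rep("H", 4)), 1)
  expect_equal(helix_content(c(rep("H", 3), rep("C", 5), "X", "X")),
               3 / 8)
  ref_ss <- assign_secondary_structure(build_mock_reference())
  expect_equal(helix_content(ref_ss), sum(ref_ss == "H") / 36)
})

test_that("order parameters are invariant under rigid motion", {
  ref <- build_mock_reference()
  base <- c(rmsd = segment_rmsd(ref, ref, sel_fold()),
            rg = radius_of_gyration(ref),
            w = aromatic_distance(ref),
            sasa = shrake_rupley_sasa(ref, n_points = 960L))
  for (k in 5:7) {
    m <- apply_rigid(ref, random_rigid_motion(k))
    expect_equal(segment_rmsd(m, ref, sel_fold()), base["rmsd"],
                 ignore_attr = TRUE, tolerance = 1e-6)
    expect_equal(radius_of_gyration(m), base["rg"], ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(aromatic_distance(m), base["w"], ignore_attr = TRUE,
                 tolerance = 1e-9)
    # the sphere-point lattice is fixed in the lab frame, so a rotated
    # molecule sees a slightly different sampling: agree to ~2%
    expect_equal(shrake_rupley_sasa(m, n_points = 960L), base["sasa"],
                 ignore_attr = TRUE, tolerance = 0.02)
  }
})

test_that("compute_order_params emits one tidy row per frame", {
  ref <- build_mock_reference()
  unf <- build_extended_chain(jitter_deg = 8, seed = 3)
  dec <- decorate_conformations(
    tibble::tibble(x = c(1, 6, 15), y = c(0.6, 1.8, 5)), ref, unf, seed = 8)
  p <- compute_order_params(dec$traj, ref, sasa_points = 120L)
  expect_equal(nrow(p), 3)
  expect_named(p, c("time_ps", "rmsd", "alpha_rmsd", "beta_rmsd", "rg",
                    "w9_w34", "core_sasa", "helix_content"))
  expect_equal(p$alpha_rmsd, c(0.6, 1.8, 5), tolerance = 0.2)
  expect_equal(p$beta_rmsd, c(1, 6, 15), tolerance = 0.2)
  expect_true(all(p$helix_content >= 0 & p$helix_content <= 1))
  expect_true(all(p$core_sasa > 0))
})
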