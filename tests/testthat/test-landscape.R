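test_that("the free-energy estimator matches its closed form", {
  pts <- tibble::tibble(x = c(rep(0.5, 1000), rep(1.5, 135)),
                        y = rep(0.5, 1135))
  g <- build_landscape(pts, x_edges = 0:2, y_edges = 0:1,
                       temperature = 300)
  expect_equal(g$F[1, 1], 0)
  expect_equal(g$F[2, 1], -kB * 300 * log(135 / 1000), tolerance = 1e-9)
  expect_equal(g$F[2, 1], 1.19, tolerance = 0.01)
  expect_equal(sum(g$counts), 1135)

  one_bin <- build_landscape(tibble::tibble(x = rep(0.2, 10), y = 0.2),
                             0:2, 0:1, 300)
  expect_equal(one_bin$F[1, 1], 0)
  expect_true(is.infinite(one_bin$F[2, 1]))
  expect_error(build_landscape(tibble::tibble(x = 9, y = 9), 0:2, 0:1, 300),
               "outside")
})

test_that("free-energy differences are offset-independent", {
  set.seed(21)
  pts <- tibble::tibble(x = runif(5000, 0, 4), y = runif(5000, 0, 2))
  g <- build_landscape(pts, seq(0, 4, 0.5), seq(0, 2, 0.5), 300)
  fin <- which(is.finite(g$F), arr.ind = TRUE)
  dF <- g$F[fin[1, 1], fin[1, 2]] - g$F[fin[5, 1], fin[5, 2]]
  # rebuilding from doubled counts changes the normalisation, not deltas
  g2 <- foldscape:::new_landscape(g$x_edges, g$y_edges, g$counts * 2, 300)
  expect_equal(g2$F[fin[1, 1], fin[1, 2]] - g2$F[fin[5, 1], fin[5, 2]], dF)
})

test_that("count smoothing conserves mass and has bounded support", {
  counts <- matrix(0, 21, 21); counts[11, 11] <- 1000
  g <- foldscape:::new_landscape(0:21, 0:21, counts, 300)
  expect_identical(smooth_landscape(g, 0)$counts, g$counts)
  sm <- smooth_landscape(g, 1)
  expect_equal(sum(sm$counts), 1000, tolerance = 1)
  far <- abs(row(counts) - 11) > 4 | abs(col(counts) - 11) > 4
  expect_true(all(sm$counts[far] < 1e-6))
})

test_that("watershed basin detection recovers planted wells", {
  rec <- recover_planted_landscape(n = 2e4, seed = 31)
  expect_length(rec$basins, 2)
  tb <- tidy(rec$basins)
  expect_equal(tb$min_x[1], 5, tolerance = 0.6)   # deep well centre
  expect_equal(tb$min_x[2], 15, tolerance = 0.6)  # shallow well centre

  # single-well surface, infinite ceiling -> one basin
  F1 <- matrix(2, 7, 7); F1[4, 4] <- 0; F1[4, 3] <- 0.5; F1[3, 4] <- 0.6
  g1 <- grid_from_F(F1)
  expect_length(find_basins(g1, f_max = Inf), 1)

  # basin count is non-increasing as the ceiling is lowered
  sm <- rec$smoothed
  counts <- vapply(c(2.0, 1.5, 1.0, 0.6, 0.3),
                   function(fm) length(find_basins(sm, f_max = fm)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))

  # a ceiling below everything finds nothing
  expect_length(find_basins(g1, f_max = -1), 0)
})

test_that("minimax barriers agree with exhaustive threshold connectivity", {
  set.seed(41)
  for (trial in 1:100) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    F <- matrix(round(runif(nx * ny, 0, 5), 2), nx, ny)
    F[sample(length(F), 2)] <- Inf
    src <- c(1, 1); dst <- c(nx, ny)
    F[1, 1] <- 0; F[nx, ny] <- 0.1
    g <- grid_from_F(F)
    basins <- as_basins(fake_basin(F, 1, 1, "a"),
                        fake_basin(F, nx, ny, "b"))
    got <- minimax_barrier(g, basins, "a", "b")
    saddle <- threshold_saddle(F, src, dst)
    expect_equal(got$saddle_F, saddle, tolerance = 1e-9)
    expect_equal(got$barrier, saddle - F[1, 1], tolerance = 1e-9)
  }
})

test_that("the forward and reverse barriers share one saddle", {
  rec <- recover_planted_landscape(n = 2e4, seed = 32)
  labs <- vapply(rec$basins, `[[`, character(1), "label")
  ab <- minimax_barrier(rec$smoothed, rec$basins, labs[1], labs[2])
  ba <- minimax_barrier(rec$smoothed, rec$basins, labs[2], labs[1])
  expect_equal(ab$saddle_F, ba$saddle_F, tolerance = 1e-9)
  expect_equal(ab$barrier - ba$barrier,
               rec$basins[[2]]$min_F - rec$basins[[1]]$min_F,
               tolerance = 1e-9)
})

test_that("disconnected basins report an infinite barrier", {
  F <- matrix(Inf, 5, 5)
  F[1, 1] <- 0; F[5, 5] <- 0.2
  g <- grid_from_F(F)
  basins <- as_basins(fake_basin(F, 1, 1, "a"), fake_basin(F, 5, 5, "b"))
  expect_identical(minimax_barrier(g, basins, "a", "b")$barrier, Inf)
})

test_that("point classification distinguishes in, near and far", {
  F <- matrix(3, 9, 9)
  F[4:6, 4:6] <- 1; F[5, 5] <- 0
  g <- grid_from_F(F)
  basins <- find_basins(g, f_max = 1.5)
  expect_length(basins, 1)
  got <- classify_points(g, basins, tibble::tibble(
    x = c(4.5, 2.5, 0.5, 20), y = c(4.5, 2.5, 0.5, 20)))
  expect_identical(got$status, c("in", "near", "far", "far"))
  expect_identical(got$label[1:2], rep(basins[[1]]$label, 2))

  # the planted native-like centre classifies to its own basin
  spec <- ds119_landscape_spec()
  res <- run_monomer_pipeline(list(seed = 5, n_points = 30000,
                                   decorate = FALSE), spec = spec)
  cl <- classify_points(res$smoothed, res$basins,
                        tibble::tibble(x = 6.0, y = 1.8))
  expect_identical(cl$label, "F'")
  expect_true(cl$status %in% c("in", "near"))
})

test_that("basin frame sampling respects spacing and flags shortfalls", {
  F <- matrix(2, 5, 5); F[3, 3] <- 0
  g <- grid_from_F(F)
  basins <- find_basins(g, f_max = 0.5)
  params <- tibble::tibble(time_ps = seq(0, by = 2, length.out = 500),
                           x = 2.5, y = 2.5)
  sel <- sample_basin_frames(params, g, basins[[1]], min_count = 5,
                             min_spacing_ps = 100)
  expect_identical(as.integer(sel)[1:3], c(1L, 51L, 101L))
  expect_false(attr(sel, "shortfall"))
  expect_identical(sel, sample_basin_frames(params, g, basins[[1]],
                                            min_count = 5,
                                            min_spacing_ps = 100))

  none <- sample_basin_frames(tibble::tibble(time_ps = 0, x = 0.1, y = 0.1),
                              g, basins[[1]])
  expect_length(as.integer(none), 0)
  expect_true(attr(none, "shortfall"))
})
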