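mb_minima_sorted <- function() {
  census <- mb_census_cached()
  census$minima[order(census$minima$energy), ]
}

test_that("band interpolation includes endpoints and averages the midpoint", {
  m <- mueller_brown()
  band <- interpolate_band(m, c(0, 0), c(1, 2), n_images = 3)
  expect_identical(band[[1]], c(0, 0))
  expect_identical(band[[3]], c(1, 2))
  expect_equal(band[[2]], c(0.5, 1))
})

test_that("interpolating between identical endpoints gives identical images", {
  m <- mueller_brown()
  band <- interpolate_band(m, c(0.2, 0.3), c(0.2, 0.3), n_images = 5)
  for (img in band) expect_identical(img, c(0.2, 0.3))
})

test_that("the clash-repair pass separates beads swapped through each other", {
  m <- lj_cluster(2)
  x_a <- c(0, 0, 0, 1.5, 0, 0)
  x_b <- c(1.5, 0, 0, 0, 0, 0)  # swapped: the linear midpoint is coincident
  band <- interpolate_band(m, x_a, x_b, n_images = 5)
  for (img in band) {
    xyz <- matrix(img, ncol = 3, byrow = TRUE)
    expect_gt(sqrt(sum((xyz[1, ] - xyz[2, ])^2)), 0.5)
  }
})

test_that("the band search brackets the known saddle between adjacent minima", {
  m <- mueller_brown()
  census <- mb_census_cached()
  mins <- mb_minima_sorted()
  # deepest minimum and the shallow middle minimum are joined by one saddle
  cand <- dneb(m, c(mins$x[1], mins$y[1]), c(mins$x[3], mins$y[3]))
  expect_gte(length(cand), 1)
  d <- vapply(cand, function(x)
    min(sqrt((census$saddles$x - x[1])^2 + (census$saddles$y - x[2])^2)), numeric(1))
  expect_lt(min(d), 0.15)
})

test_that("degenerate and convex band searches return no candidates", {
  m <- mueller_brown()
  expect_length(dneb(m, c(0, 0.5), c(0, 0.5)), 0)
  bowl <- quadratic_bowl(2)
  expect_length(dneb(bowl, c(-2, 0), c(2, 1)), 0)
})

test_that("eigenvector following converges band candidates to true saddles", {
  m <- mueller_brown()
  census <- mb_census_cached()
  mins <- mb_minima_sorted()
  cand <- dneb(m, c(mins$x[1], mins$y[1]), c(mins$x[3], mins$y[3]))
  ts <- hybrid_ef_refine(m, cand[[1]])
  d <- sqrt((census$saddles$x - ts$coordinates[1])^2 +
            (census$saddles$y - ts$coordinates[2])^2)
  expect_lt(min(d), 1e-4)
  expect_lt(abs(ts$energy - census$saddles$energy[which.min(d)]), 1e-6)
  expect_lt(sqrt(sum(model_gradient(m, ts$coordinates)^2)), 1e-5)
  expect_lt(ts$lowest_eigenvalue, 0)
})

test_that("refinement started at a minimum signals a rejected candidate", {
  m <- mueller_brown()
  mn <- local_minimise(m, c(0, 0.5))
  expect_error(hybrid_ef_refine(m, mn$coordinates), class = "pelkit_not_a_saddle")
})

test_that("the one-dimensional double well saddle sits at the origin", {
  m <- double_well_1d()
  ts <- hybrid_ef_refine(m, 0.1)
  expect_equal(ts$coordinates, 0, tolerance = 1e-6)
  expect_equal(ts$energy, 0, tolerance = 1e-12)
  ends <- descend_from_ts(m, ts)
  got <- sort(c(ends$minimum_minus$coordinates, ends$minimum_plus$coordinates))
  expect_equal(got, c(-1, 1) / sqrt(2), tolerance = 1e-6)
})

test_that("descent from each saddle reaches the census-connected minima", {
  m <- mueller_brown()
  census <- mb_census_cached()
  # connectivity oracle: descend with plain steepest descent from +/- tiny
  # displacements along the numerically computed negative eigenvector
  for (s in seq_len(nrow(census$saddles))) {
    xs <- c(census$saddles$x[s], census$saddles$y[s])
    eg <- eigen(model_hessian(m, xs), symmetric = TRUE)
    v <- eg$vectors[, which.min(eg$values)]
    ts <- new_transition_state(model_energy(m, xs), xs, min(eg$values), v)
    ends <- descend_from_ts(m, ts)
    for (mn in list(ends$minimum_minus, ends$minimum_plus)) {
      d <- sqrt((census$minima$x - mn$coordinates[1])^2 +
                (census$minima$y - mn$coordinates[2])^2)
      expect_lt(min(d), 1e-4)
    }
    expect_gte(ts$energy, max(ends$minimum_minus$energy, ends$minimum_plus$energy) - 1e-6)
    # exactly one negative eigenvalue at the saddle
    expect_identical(sum(eg$values < -1e-6), 1L)
  }
})

test_that("the sampled stationary points equal the independent census", {
  m <- mueller_brown()
  census <- mb_census_cached()
  res <- basin_hop(m, c(0, 0.5),
                   basin_hopping_config(n_steps = 400, temperature = 10,
                                        step_size = 1.0, rng_seed = 8))
  k <- ktn_new(m$name)
  for (mn in res) add_stationary_point(k, mn)
  connect_minima(k, m, 1L, 2L)
  expect_true(k$last_connect$connected)
  expect_identical(length(k$minima), nrow(census$minima))
  ts_e <- sort(vapply(k$ts, function(t) t$energy, numeric(1)))
  expect_equal(ts_e, sort(census$saddles$energy), tolerance = 1e-6)
})
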