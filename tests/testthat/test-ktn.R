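test_that("re-adding a stationary point matches instead of duplicating", {
  k <- ktn_new("t")
  m <- new_minimum(-1.5, c(0, 0), 1e-9)
  id1 <- add_stationary_point(k, m)
  id2 <- add_stationary_point(k, m)
  expect_identical(id1, id2)
  expect_length(k$minima, 1)
  expect_identical(k$minima[[1]]$discovery_count, 2L)
})

test_that("a rotated copy of a cluster minimum is recognised as the same point", {
  lj <- lj_cluster(7)
  set.seed(2)
  mn <- local_minimise(lj, as.vector(t(matrix(rnorm(21, sd = 0.8), 7, 3))))
  k <- ktn_new("lj7", cartesian3d = TRUE, criteria = match_criteria(permutations = TRUE))
  id1 <- add_stationary_point(k, mn)
  rot <- mn
  rot$coordinates <- rotate_config(mn$coordinates, random_rotation(5), c(3, -1, 2))
  id2 <- add_stationary_point(k, rot)
  expect_identical(id1, id2)
  expect_length(k$minima, 1)
})

test_that("equal energies at different geometries stay distinct", {
  k <- ktn_new("chain", cartesian3d = TRUE)
  xa <- as.vector(t(cbind(1:4, 0, 0)))
  xb <- as.vector(t(cbind(1:4, 3, 0)))  # same shape shifted: aligns to rmsd 0
  xc <- as.vector(t(matrix(c(0, 0, 0, 3, 0, 0, 3, 3, 0, 0, 3, 3), 4, 3, byrow = TRUE)))
  id1 <- add_stationary_point(k, new_minimum(-2, xa, 1e-9))
  id2 <- add_stationary_point(k, new_minimum(-2, xc, 1e-9))
  expect_false(id1 == id2)
  expect_identical(add_stationary_point(k, new_minimum(-2, xb, 1e-9)), id1)
})

test_that("unconverged points are rejected", {
  k <- ktn_new("t")
  bad <- new_minimum(0, c(0, 0), NA_real_)
  expect_error(add_stationary_point(k, bad), "unconverged")
})

test_that("rigid superposition recovers rotated-translated copies and flags chirality", {
  set.seed(11)
  xa <- as.vector(t(matrix(rnorm(12), 4, 3)))
  xb <- rotate_config(xa, random_rotation(3), c(1, 2, 3))
  res <- align_rmsd(xa, xb)
  expect_lt(res$rmsd, 1e-9)
  expect_false(res$degenerate)
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)

  # one displaced site of N: optimal rmsd can't exceed d/sqrt(N)
  d <- 0.8; N <- 4
  xc <- xa; xc[1] <- xc[1] + d
  expect_lte(align_rmsd(xa, xc)$rmsd, d / sqrt(N) + 1e-9)

  # a chiral tetrahedral arrangement cannot be superposed on its mirror image
  tet <- as.vector(t(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.2, 0.3, 1.1), 4, 3, byrow = TRUE)))
  mir <- tet; mir[seq(3, 12, 3)] <- -mir[seq(3, 12, 3)]
  expect_gt(align_rmsd(tet, mir)$rmsd, 0.1)

  # collinear configurations fall back to translation-only, flagged
  lin <- as.vector(t(cbind(1:4, 0, 0)))
  expect_true(align_rmsd(lin, lin)$degenerate)
})

test_that("connecting minima that already share a transition state is a no-op", {
  k <- hand_ktn()
  connect_minima(k, mueller_brown(), 1L, 2L)
  expect_true(k$last_connect$connected)
  expect_identical(k$last_connect$new_ts, 0L)
  expect_identical(k$last_connect$cycles, 0L)
})

test_that("connecting the outer surface minima routes through the middle one", {
  m <- mueller_brown()
  res <- basin_hop(m, c(0, 0.5),
                   basin_hopping_config(n_steps = 400, temperature = 10,
                                        step_size = 1.0, rng_seed = 8))
  k <- ktn_new(m$name)
  for (mn in res) add_stationary_point(k, mn)
  connect_minima(k, m, 1L, 2L)   # ids 1, 2 = two deepest minima (the outer pair)
  expect_true(k$last_connect$connected)
  expect_identical(length(k$ts), 2L)
  ends <- sort(unlist(lapply(k$ts, function(t) c(t$minus_id, t$plus_id))))
  expect_identical(sum(ends == 3L), 2L)  # both paths end at the middle minimum
})

test_that("an infinite ridge leaves the endpoints unconnected, flagged", {
  # two wells separated by a 1/x^2 spike: no finite saddle exists
  spike <- potential_model(
    "spiked-double-well", 1L,
    energy_fn = function(x) (x^2 - 1)^2 + 0.1 / x^2,
    gradient_fn = function(x) 4 * x * (x^2 - 1) - 0.2 / x^3,
    validate_fn = function(x) if (abs(x) < 1e-3) "on the singular ridge" else TRUE)
  k <- ktn_new("spiked")
  a <- add_stationary_point(k, local_minimise(spike, -1.1))
  b <- add_stationary_point(k, local_minimise(spike, 1.1))
  expect_identical(length(k$minima), 2L)
  connect_minima(k, spike, a, b, max_cycles = 4L)
  expect_false(k$last_connect$connected)
})

test_that("connection is independent of endpoint order", {
  m <- mueller_brown()
  build <- function(a, b) {
    res <- basin_hop(m, c(0, 0.5),
                     basin_hopping_config(n_steps = 300, temperature = 10,
                                          step_size = 1.0, rng_seed = 8))
    k <- ktn_new(m$name)
    for (mn in res) add_stationary_point(k, mn)
    connect_minima(k, m, a, b)
    k
  }
  k1 <- build(1L, 2L); k2 <- build(2L, 1L)
  expect_identical(k1$last_connect$connected, k2$last_connect$connected)
  e1 <- sort(vapply(k1$ts, function(t) t$energy, numeric(1)))
  e2 <- sort(vapply(k2$ts, function(t) t$energy, numeric(1)))
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("seeding picks the lowest-energy member of each order-parameter band", {
  k <- ktn_new("seeds")
  q <- c(1.0, 0.5, 0.0, 0.95, 0.45)
  e <- c(-5, -3, -1, -6, -2)
  for (i in seq_along(q)) add_stationary_point(k, new_minimum(e[i], c(i * 10, 0), 1e-9))
  op <- function(m) q[[m$id]]
  reps <- seed_representatives(k, op)
  expect_identical(reps$folded, 4L)    # lower energy than the other folded minimum
  expect_identical(reps$partial, 2L)
  expect_identical(reps$unfolded, 3L)
})

test_that("an empty band raises a missing-representative signal", {
  k <- ktn_new("folded-only")
  for (i in 1:3) add_stationary_point(k, new_minimum(-i, c(i * 10, 0), 1e-9))
  expect_error(seed_representatives(k, function(m) 1.0),
               class = "pelkit_missing_representative")
})

test_that("chain sampling yields three seeds with strictly decreasing fold fraction", {
  fx <- toy_fixture_cached()
  op <- native_contact_fraction(fx$topology)
  reps <- seed_representatives(fx$ktn, op)
  qs <- c(op(fx$ktn$minima[[reps$folded]]),
          op(fx$ktn$minima[[reps$partial]]),
          op(fx$ktn$minima[[reps$unfolded]]))
  expect_true(all(diff(qs) < 0))
})

test_that("KTN referential integrity survives random operation sequences", {
  set.seed(99)
  for (trial in 1:10) {
    k <- ktn_new("prop")
    for (op in 1:40) {
      if (length(k$minima) < 2 || runif(1) < 0.6) {
        add_stationary_point(k, new_minimum(runif(1, -10, 0),
                                            c(runif(1, 0, 100), runif(1, 0, 100)), 1e-9))
      } else {
        ij <- sample(length(k$minima), 2)
        e_ts <- max(vapply(ij, function(i) k$minima[[i]]$energy, numeric(1))) + runif(1, 0, 3)
        add_stationary_point(k, new_transition_state(e_ts, c(runif(1, 200, 300), 0), -1,
                                                     minus_id = ij[1], plus_id = ij[2]))
      }
    }
    # every TS references existing minima
    for (t in k$ts) {
      expect_lte(t$minus_id, length(k$minima))
      expect_lte(t$plus_id, length(k$minima))
    }
    # no two stored minima within both matching tolerances
    if (length(k$minima) > 1) {
      for (i in 1:(length(k$minima) - 1)) for (j in (i + 1):length(k$minima)) {
        same_e <- abs(k$minima[[i]]$energy - k$minima[[j]]$energy) <= k$criteria$energy_tol
        same_x <- sqrt(mean((k$minima[[i]]$coordinates - k$minima[[j]]$coordinates)^2)) <=
          k$criteria$distance_tol
        expect_false(same_e && same_x)
      }
    }
    # ids are unique and stored energies finite
    expect_identical(anyDuplicated(vapply(k$minima, function(m) m$id, integer(1))), 0L)
    expect_true(all(is.finite(ktn_min_energies(k))))
  }
})

test_that("identical consecutive snapshots assess as converged", {
  k <- hand_ktn()
  rep1 <- convergence_report(list(k, k))
  expect_true(rep1$converged)
})

test_that("a high-energy minimum inside an existing funnel keeps convergence", {
  k1 <- hand_ktn()
  k2 <- hand_ktn()
  # new shallow minimum linked into the existing low-energy funnel
  add_stationary_point(k2, new_minimum(0.5, c(1, 1), 1e-9))
  add_stationary_point(k2, new_transition_state(1.2, c(0.5, 0.5), -1,
                                                minus_id = 1L, plus_id = 4L))
  rep2 <- convergence_report(list(k1, k2))
  expect_true(rep2$converged)
  expect_identical(rep2$table$n_funnels[1], rep2$table$n_funnels[2])
})

test_that("a newly discovered deep funnel breaks convergence", {
  k1 <- hand_ktn()
  k2 <- hand_ktn()
  add_stationary_point(k2, new_minimum(-8, c(20, 0), 1e-9))
  add_stationary_point(k2, new_transition_state(6, c(15, 0), -1,
                                                minus_id = 1L, plus_id = 4L))
  rep3 <- convergence_report(list(k1, k2))
  expect_false(rep3$converged)
})

test_that("fewer than two snapshots is not assessable", {
  expect_error(convergence_report(list(hand_ktn())), class = "pelkit_not_assessable")
})
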