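test_that("sampling is reproducible, exhaustive at n = |minima|, and stratifiable", {
  k <- random_ktn(12, seed = 4)
  expect_identical(sample_minima(k, 12, rng_seed = 1), 1:12)
  expect_identical(sample_minima(k, 5, rng_seed = 9), sample_minima(k, 5, rng_seed = 9))
  expect_error(sample_minima(k, 13), "exceeds")

  strat <- sample_minima(k, 9, rng_seed = 2, stratify_by_energy = TRUE)
  e <- pelkit:::ktn_min_energies(k)
  tert <- cut(rank(e, ties.method = "first"), 3, labels = FALSE)
  expect_identical(as.integer(table(tert[strat])), rep(3L, 3))
})

test_that("re-scoring under the same or a scaled model behaves exactly", {
  fx <- toy_fixture_cached()
  ids <- sample_minima(fx$ktn, 8, rng_seed = 1)
  e_same <- rescore(ids, fx$ktn, fx$model)
  expect_equal(as.numeric(e_same),
               vapply(ids, function(i) fx$ktn$minima[[i]]$energy, numeric(1)),
               tolerance = 1e-12)
  doubled <- external_adapter(function(x) 2 * fx$model$energy_fn(x), NULL,
                              fx$model$dimension, cartesian3d = TRUE)
  e_twice <- rescore(ids, fx$ktn, doubled)
  expect_equal(as.numeric(e_twice), 2 * as.numeric(e_same), tolerance = 1e-9)
  expect_identical(order(e_twice), order(e_same))
})

test_that("evaluation failures exclude and report the affected members", {
  fx <- toy_fixture_cached()
  flaky <- external_adapter(function(x) {
    if (abs(x[1] - fx$ktn$minima[[1]]$coordinates[1]) < 1e-12) stop("boom")
    fx$model$energy_fn(x)
  }, NULL, fx$model$dimension, cartesian3d = TRUE)
  expect_warning(e <- rescore(c(1L, 2L, 3L), fx$ktn, flaky), "excluded")
  expect_identical(attr(e, "failed"), 1L)
  expect_length(e, 2)
})

test_that("rank correlation reproduces hand-enumerated pair counts", {
  rc <- rank_correlation(1:5, 1:5)
  expect_identical(rc$kendall_tau, 1)
  expect_identical(rc$n_discordant_pairs, 0L)
  expect_identical(rank_correlation(1:5, 5:1)$kendall_tau, -1)
  rc2 <- rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(rc2$kendall_tau, 2 / 3, tolerance = 1e-12)
  expect_identical(rc2$n_discordant_pairs, 1L)
  expect_identical(unname(rc2$discordant_pairs[1, ]), c(2L, 3L))
  expect_error(rank_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "pelkit_undefined_correlation")
})

test_that("implemented tau matches the brute-force oracle and the stats library", {
  set.seed(31)
  for (trial in 1:60) {
    n <- sample(2:8, 1)
    a <- sample(1:5, n, replace = TRUE) + runif(n) * (trial %% 2)  # ties when even
    b <- sample(1:5, n, replace = TRUE) + runif(n) * (trial %% 2)
    if (var(a) == 0 || var(b) == 0) next
    tau <- rank_correlation(a, b)$kendall_tau
    expect_equal(tau, brute_tau_b(a, b), tolerance = 1e-12)
    expect_equal(tau, stats::cor(a, b, method = "kendall"), tolerance = 1e-10)
  }
})

test_that("tau and rho are invariant under strictly monotone transforms", {
  set.seed(8)
  a <- rnorm(12); b <- rnorm(12)
  rc <- rank_correlation(a, b)
  rc2 <- rank_correlation(exp(a), b^3 + 5 * b)
  expect_equal(rc2$kendall_tau, rc$kendall_tau, tolerance = 1e-12)
  expect_equal(rc2$spearman_rho, rc$spearman_rho, tolerance = 1e-12)
})

test_that("solvent-analogue perturbation preserves order; torsion swap reorders", {
  fx <- toy_fixture_cached()
  n <- min(15, length(fx$ktn$minima))
  ids <- sample_minima(fx$ktn, n, rng_seed = 3, stratify_by_energy = TRUE)
  e_a <- vapply(ids, function(i) fx$ktn$minima[[i]]$energy, numeric(1))

  m_screen <- make_toy_rna(fx$sequence, perturb_screening_length("cgA", 1.1))$model
  rc_screen <- rank_correlation(e_a, as.numeric(rescore(ids, fx$ktn, m_screen)), ids = ids)
  expect_gte(rc_screen$kendall_tau, 0.9)

  m_swap <- make_toy_rna(fx$sequence, "cgB")$model
  rc_swap <- rank_correlation(e_a, as.numeric(rescore(ids, fx$ktn, m_swap)), ids = ids)
  expect_lt(rc_swap$kendall_tau, rc_screen$kendall_tau)
  expect_gte(rc_swap$n_discordant_pairs, 1L)

  # the reordering specifically involves partially folded minima
  q <- vapply(ids, function(i)
    native_contact_fraction(fx$topology)(fx$ktn$minima[[i]]), numeric(1))
  partial <- ids[q >= 0.3 & q <= 0.7]
  dp <- rc_swap$discordant_pairs
  expect_gte(sum(apply(dp, 1, function(r) all(r %in% partial))), 1L)
})
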