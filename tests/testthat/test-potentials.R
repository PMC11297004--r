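test_that("analytic gradients match centred finite differences for every shipped model", {
  models <- list(
    list(m = mueller_brown(), spread = 1.5),
    list(m = quadratic_bowl(4), spread = 2),
    list(m = double_well_1d(), spread = 1.5),
    list(m = lj_cluster(5), spread = 0.4),
    list(m = make_toy_rna("GACU", "cgA")$model, spread = 0.3),
    list(m = make_toy_rna("GACU", "cgB")$model, spread = 0.3))
  for (entry in models) {
    m <- entry$m
    set.seed(42)
    base_x <- if (m$cartesian3d) {
      if (startsWith(m$name, "lj")) {
        local_minimise(m, as.vector(t(matrix(rnorm(m$dimension, sd = 0.7),
                                             m$dimension / 3, 3))))$coordinates
      } else toy_rna_extended(make_toy_rna("GACU")$topology)
    } else rep(0, m$dimension)
    for (rep_i in 1:100) {
      x <- base_x + runif(m$dimension, -entry$spread, entry$spread)
      ok <- tryCatch({ validate_configuration(m, x); TRUE }, error = function(e) FALSE)
      if (!ok) next
      g <- model_gradient(m, x)
      gf <- pelkit:::fd_gradient(m$energy_fn, x)
      expect_lt(max(abs(g - gf)) / max(abs(gf), 1), 1e-5)
    }
  }
})

test_that("two LJ beads at the pair minimum give -epsilon and zero gradient", {
  m <- lj_cluster(2, epsilon = 0.7, sigma = 1.3)
  x <- c(0, 0, 0, 2^(1/6) * 1.3, 0, 0)
  expect_equal(model_energy(m, x), -0.7, tolerance = 1e-12)
  expect_lt(max(abs(model_gradient(m, x))), 1e-10)
})

test_that("a chain with every bonded term at equilibrium has zero energy", {
  tr <- make_toy_rna("A")
  # beads P, S, B: bonds P-S 4.0 and S-B 3.5, angle P-S-B 110 deg; the only
  # nonbonded pair (P, B) is a 1-3 exclusion
  th <- 110 * pi / 180
  x <- c(0, 0, 0,
         4, 0, 0,
         4 + 3.5 * cos(pi - th), 3.5 * sin(pi - th), 0)
  expect_equal(model_energy(tr$model, x), 0, tolerance = 1e-20)
})

test_that("the surface gradient vanishes at the refined global minimum", {
  census <- mb_census_cached()
  m <- mueller_brown()
  gm <- census$minima[1, ]
  expect_lt(sqrt(sum(model_gradient(m, c(gm$x, gm$y))^2)), 1e-6)
})

test_that("cluster and chain energies are invariant under rigid-body motion", {
  lj <- lj_cluster(7)
  set.seed(3)
  x <- local_minimise(lj, as.vector(t(matrix(rnorm(21, sd = 0.8), 7, 3))))$coordinates
  tr <- make_toy_rna("GGAACC")
  xr <- toy_rna_extended(tr$topology)
  for (seed in 1:5) {
    R <- random_rotation(seed)
    shift <- c(seed, -2 * seed, 0.5)
    expect_lt(abs(model_energy(lj, rotate_config(x, R, shift)) - model_energy(lj, x)), 1e-9)
    expect_lt(abs(model_energy(tr$model, rotate_config(xr, R, shift)) -
                  model_energy(tr$model, xr)), 1e-9)
  }
  # gradient components along the zero modes vanish after projection
  g <- project_zero_modes(lj, x, model_gradient(lj, x))
  B <- zero_mode_basis(lj, x)
  expect_lt(max(abs(crossprod(B, g))), 1e-9)
})

test_that("the two shipped parameter sets rank fixture configurations differently", {
  fx <- toy_fixture_cached()
  trA <- make_toy_rna(fx$sequence, "cgA")
  trB <- make_toy_rna(fx$sequence, "cgB")
  expect_identical(trA$topology[c("beads", "bonds", "angles", "torsions")],
                   trB$topology[c("beads", "bonds", "angles", "torsions")])
  # a fixed set of quenched minima of the reference set, re-scored: the two
  # torsion parameterisations must order them differently
  ids <- seq_len(min(12, length(fx$ktn$minima)))
  configs <- lapply(ids, function(i) fx$ktn$minima[[i]]$coordinates)
  eA <- vapply(configs, function(x) model_energy(trA$model, x), numeric(1))
  eB <- vapply(configs, function(x) model_energy(trB$model, x), numeric(1))
  expect_gte(length(configs), 10)
  expect_false(identical(order(eA), order(eB)))
  expect_false(isTRUE(all.equal(eA, eB)))
})

test_that("configuration validation flags dimension and degeneracy errors", {
  m <- lj_cluster(3)
  expect_error(energy_gradient(m, c(0, 0)), class = "pelkit_dimension_error")
  x <- c(0, 0, 0, 0, 0, 0, 1, 1, 1)
  expect_error(energy_gradient(m, x), class = "pelkit_degenerate_geometry")
})

test_that("the external adapter reproduces a wrapped model exactly", {
  mb <- mueller_brown()
  wrapped <- external_adapter(mb$energy_fn, mb$gradient_fn, 2, name = "wrapped-mb")
  set.seed(1)
  for (i in 1:20) {
    x <- runif(2, -1.5, 1.5)
    expect_identical(model_energy(wrapped, x), model_energy(mb, x))
  }
})

test_that("basin-hopping a wrapped quadratic bowl finds its single minimum", {
  bowl <- quadratic_bowl(3, centre = c(1, -2, 0.5))
  wrapped <- external_adapter(bowl$energy_fn, bowl$gradient_fn, 3)
  res <- basin_hop(wrapped, c(5, 5, 5), basin_hopping_config(n_steps = 30, rng_seed = 4))
  expect_length(res, 1)
  expect_equal(res[[1]]$coordinates, c(1, -2, 0.5), tolerance = 1e-5)
})

test_that("an energy-only adapter recovers the analytic quadratic gradient", {
  k <- 2.5; ctr <- c(0.3, -0.7)
  ad <- external_adapter(function(x) 0.5 * k * sum((x - ctr)^2), NULL, 2)
  x <- c(1.1, 0.4)
  expect_equal(model_gradient(ad, x), k * (x - ctr), tolerance = 1e-6)
})

test_that("adapter callback failures carry the configuration", {
  ad <- external_adapter(function(x) stop("engine exploded"), NULL, 2)
  err <- tryCatch(model_energy(ad, c(1, 2)), error = function(e) e)
  expect_s3_class(err, "pelkit_potential_error")
  expect_identical(err$configuration, c(1, 2))
})

test_that("parameter sets serialise to and from the config format losslessly", {
  for (id in rna_parameter_sets()) {
    ps <- rna_parameter_set(id)
    path <- tempfile(fileext = ".yaml")
    write_parameter_set(ps, path)
    back <- read_parameter_set(path)
    expect_equal(back, ps[c("id", "beads", "bonds", "angles", "torsions", "nonbonded")])
  }
})

test_that("chain construction counts beads and rejects bad input", {
  t1 <- make_toy_rna("A")
  expect_identical(nrow(t1$topology$torsions), 0L)
  expect_identical(nrow(t1$topology$beads), 3L)
  t21 <- make_toy_rna(paste0(strrep("GACU", 5), "G"))
  expect_identical(nrow(t21$topology$beads), 21L * t21$topology$beads_per_nucleotide)
  expect_error(make_toy_rna("GAXC"), "unknown nucleotide")
  expect_error(make_toy_rna("GA", "nope"), "unknown parameter set")
})
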