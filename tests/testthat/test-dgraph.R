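merge_level <- function(tree, a, b) {
  for (n in tree$nodes) if (a %in% n$members && b %in% n$members)
    return(tree$levels[n$level])
  NA_real_
}

test_that("the hand-built network merges at the hand-computed levels", {
  k <- hand_ktn()
  tree <- build_superbasins(k, delta_e = 1, e_ref = 0)
  expect_equal(merge_level(tree, 2, 3), 3)  # b joins c once the 3 kcal/mol TS opens
  expect_equal(merge_level(tree, 1, 3), 5)  # a joins only at the 5 kcal/mol TS
  expect_equal(minimax_barrier(k, 1, 3), 5)
  expect_equal(minimax_barrier(k, 2, 3), 3)
  # self-barrier convention: the minimum's own energy
  expect_equal(minimax_barrier(k, 2, 2), 2)
})

test_that("a single minimum gives a single unbranched tree and one funnel", {
  k <- ktn_new("one")
  add_stationary_point(k, new_minimum(-1, c(0, 0), 1e-9))
  tree <- build_superbasins(k, delta_e = 1)
  expect_true(all(vapply(tree$nodes, function(n) identical(n$members, 1L), logical(1))))
  f <- identify_funnels(tree, min_depth = 1)
  expect_length(f, 1)
  expect_identical(f[[1]]$label, "A")
})

test_that("the sampled benchmark-surface tree has three leaves under one root", {
  m <- mueller_brown()
  census <- mb_census_cached()
  res <- basin_hop(m, c(0, 0.5),
                   basin_hopping_config(n_steps = 400, temperature = 10,
                                        step_size = 1.0, rng_seed = 8))
  k <- ktn_new(m$name)
  for (mn in res) add_stationary_point(k, mn)
  connect_minima(k, m, 1L, 2L)
  tree <- build_superbasins(k, delta_e = 1)
  top <- tree$nodes[vapply(tree$nodes, function(n) is.na(n$parent), logical(1))]
  expect_identical(length(top), 1L)
  expect_identical(sort(top[[1]]$members), 1:3)
  drawing <- render_disconnectivity(tree)
  expect_identical(nrow(drawing$leaves), 3L)
  expect_equal(sort(drawing$leaves$y), sort(census$minima$energy), tolerance = 1e-6)
})

test_that("minimax barriers equal exhaustive path enumeration on random networks", {
  n_checked <- 0
  for (trial in 1:200) {
    n <- sample(2:20, 1)
    k <- random_ktn(n, seed = 1000 + trial, split = trial %% 10 == 0)
    ed <- pelkit:::ktn_edges(k)
    a <- sample(n, 1); others <- setdiff(seq_len(n), a); b <- others[sample.int(length(others), 1)]
    oracle <- brute_minimax(ed, a, b, n)
    if (is.finite(oracle)) {
      got <- minimax_barrier(k, a, b)
      expect_equal(got, oracle, tolerance = 1e-12)
      # the discrete merge level brackets the continuous barrier
      tree <- build_superbasins(k, delta_e = 1)
      ml <- merge_level(tree, a, b)
      expect_gte(ml, oracle - 1e-9)
      expect_lt(ml, oracle + 1 + 1e-9)
      n_checked <- n_checked + 1
    } else {
      expect_error(minimax_barrier(k, a, b), class = "pelkit_unreachable")
    }
  }
  expect_gt(n_checked, 150)
})

test_that("funnel identification applies the hand-checked depth rule", {
  k <- hand_ktn()
  tree <- build_superbasins(k, delta_e = 1, e_ref = 0)
  f <- identify_funnels(tree, min_depth = 1.5)
  expect_length(f, 2)
  expect_identical(f[[1]]$members, 1L)          # the global minimum alone
  expect_identical(sort(f[[2]]$members), 2:3)   # b drains into c (depth 1 < 1.5)
  expect_identical(vapply(f, function(x) x$label, character(1)), c("A", "B"))
})

test_that("wells merging below the depth threshold form one funnel", {
  k <- ktn_new("shallow")
  add_stationary_point(k, new_minimum(0, c(0, 0), 1e-9))
  add_stationary_point(k, new_minimum(0, c(10, 0), 1e-9))
  add_stationary_point(k, new_transition_state(0.5, c(5, 0), -1,
                                               minus_id = 1L, plus_id = 2L))
  tree <- build_superbasins(k, delta_e = 0.25)
  expect_length(identify_funnels(tree, min_depth = 1.5), 1)
})

test_that("funnel membership partitions the minima", {
  for (trial in 1:20) {
    n <- sample(3:15, 1)
    k <- random_ktn(n, seed = 300 + trial)
    tree <- build_superbasins(k, delta_e = 0.8)
    f <- identify_funnels(tree, min_depth = 2)
    members <- sort(unlist(lapply(f, function(x) x$members)))
    expect_identical(members, seq_len(n))
  }
})

test_that("funnel labels are stable under database re-serialisation", {
  k <- random_ktn(12, seed = 77)
  tree <- build_superbasins(k, delta_e = 1)
  f1 <- identify_funnels(tree, min_depth = 2)
  dir <- tempfile()
  write_ktn(k, dir)
  k2 <- read_ktn(dir)
  f2 <- identify_funnels(build_superbasins(k2, delta_e = 1), min_depth = 2)
  expect_identical(lapply(f1, function(x) x[c("label", "members", "lowest_id")]),
                   lapply(f2, function(x) x[c("label", "members", "lowest_id")]))
})

test_that("the drawing is valid SVG whose leaf heights are the minimum energies", {
  k <- hand_ktn()
  tree <- build_superbasins(k, delta_e = 1, e_ref = 0)
  d <- render_disconnectivity(tree, list(highlight = identify_funnels(tree, 1.5)))
  expect_identical(nrow(d$leaves), 3L)
  expect_equal(sort(d$leaves$y), c(0, 1, 2))
  expect_silent(xml2::read_xml(d$svg))
  # JSON round-trip reproduces the tree topology
  pj <- parse_disconnectivity_json(d$json)
  expect_equal(pj$levels, tree$levels)
  for (i in seq_along(tree$nodes)) {
    expect_identical(pj$nodes[[i]]$members, sort(tree$nodes[[i]]$members))
    expect_identical(pj$nodes[[i]]$level, tree$nodes[[i]]$level)
    expect_identical(pj$nodes[[i]]$parent, tree$nodes[[i]]$parent)
  }
})

test_that("two drawings with a shared scale span the same energy range", {
  k1 <- hand_ktn()
  k2 <- random_ktn(6, seed = 5)
  scale <- list(e_min = -12, e_max = 8)
  d1 <- render_disconnectivity(build_superbasins(k1, 1), scale)
  d2 <- render_disconnectivity(build_superbasins(k2, 1), scale)
  expect_identical(d1$energy_range, d2$energy_range)
})
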