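# Independent oracles used across the suite. These deliberately avoid the
# code paths they are used to check.

# exhaustive minimax barrier by depth-first enumeration of all simple paths
brute_minimax <- function(edges, a, b, n) {
  # edges: data.frame(minus, plus, energy)
  best <- Inf
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$minus[k]; j <- edges$plus[k]; e <- edges$energy[k]
    adj[[i]] <- rbind(adj[[i]], c(j, e))
    adj[[j]] <- rbind(adj[[j]], c(i, e))
  }
  visited <- rep(FALSE, n)
  dfs <- function(u, cur_max) {
    if (u == b) { best <<- min(best, cur_max); return(invisible()) }
    visited[u] <<- TRUE
    nb <- adj[[u]]
    for (k in seq_len(NROW(nb))) {
      v <- nb[k, 1]; e <- nb[k, 2]
      if (!visited[v] && max(cur_max, e) < best) dfs(v, max(cur_max, e))
    }
    visited[u] <<- FALSE
  }
  dfs(a, -Inf)
  best
}

# tie-corrected Kendall tau-b by explicit pair enumeration
brute_tau_b <- function(a, b) {
  n <- length(a)
  C <- 0; D <- 0; Ta <- 0; Tb <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- sign(a[i] - a[j]); sb <- sign(b[i] - b[j])
    if (sa == 0 && sb == 0) next
    if (sa == 0) { Ta <- Ta + 1; next }
    if (sb == 0) { Tb <- Tb + 1; next }
    if (sa * sb > 0) C <- C + 1 else D <- D + 1
  }
  (C - D) / sqrt((C + D + Ta) * (C + D + Tb))
}

# random KTN generator: a spanning tree plus a few extra edges over n minima
# (two components when split = TRUE)
random_ktn <- function(n, seed, split = FALSE) {
  set.seed(seed)
  k <- ktn_new("random", cartesian3d = FALSE)
  e_min <- stats::runif(n, -10, 0)
  for (i in seq_len(n))
    add_stationary_point(k, new_minimum(e_min[i], c(10 * i, seed %% 7), 1e-9))
  groups <- if (split && n >= 4) list(1:(n %/% 2), (n %/% 2 + 1):n) else list(seq_len(n))
  for (g in groups) {
    if (length(g) < 2) next
    perm <- sample(g)
    for (t in 2:length(perm)) {
      i <- perm[t]; j <- perm[sample.int(t - 1, 1)]
      e_ts <- max(e_min[i], e_min[j]) + stats::runif(1, 0.1, 6)
      add_stationary_point(k, new_transition_state(e_ts, c(5 * (i + j), 1), -1,
                                                   minus_id = i, plus_id = j))
    }
    extra <- sample.int(4, 1) - 1L
    for (x in seq_len(extra)) {
      ij <- sample(g, 2)
      e_ts <- max(e_min[ij]) + stats::runif(1, 0.1, 6)
      add_stationary_point(k, new_transition_state(e_ts, c(stats::runif(1, 100, 200), 2), -1,
                                                   minus_id = ij[1], plus_id = ij[2]))
    }
  }
  k
}

# shared Mueller-Brown census (grid + Newton refinement), computed once
mb_census_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- mb_census()
    val
  }
})

# shared small toy-RNA fixture KTN for the re-ranking tests, built once
toy_fixture_cached <- local({
  val <- NULL
  function(n_steps = 120) {
    if (!is.null(val)) return(val)
    tr <- make_toy_rna("GGGAAAACCC", "cgA")
    minima <- basin_hop(tr$model, toy_rna_extended(tr$topology),
                        basin_hopping_config(n_steps = n_steps, temperature = 2.5,
                                             step_size = 1.5, rng_seed = 11))
    k <- ktn_new(tr$model$name, cartesian3d = TRUE)
    for (m in minima) add_stationary_point(k, m)
    topo <- set_native_from_reference(tr$topology, k$minima[[1]])
    val <<- list(ktn = k, topology = topo, model = tr$model, sequence = "GGGAAAACCC")
    val
  }
})

# random rotation matrix (proper) from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotate_config <- function(x, R, shift = c(0, 0, 0)) {
  xyz <- matrix(x, ncol = 3, byrow = TRUE)
  as.vector(t(sweep(xyz %*% t(R), 2, shift, `+`)))
}
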