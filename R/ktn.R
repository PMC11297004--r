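#' Create an empty kinetic transition network
#'
#' A KTN is the persistent landscape database: deduplicated minima, the
#' transition states linking them, and a provenance log (model identifier,
#' seeds, tolerances). It has reference semantics (an environment), so
#' operations such as [add_stationary_point()] and [connect_minima()] update
#' it in place, mirroring how stationary-point databases are grown
#' incrementally during discrete path sampling.
#'
#' @param model_name identifier of the generating potential model.
#' @param units energy/length units string, recorded in the manifest.
#' @param cartesian3d whether coordinates are flattened 3-D bead positions
#'   (enables rigid-body superposition during matching).
#' @param criteria default [match_criteria()] for deduplication.
#' @return an environment of class `ktn`.
#' @export
ktn_new <- function(model_name = "unknown", units = "kcal/mol, Angstrom",
                    cartesian3d = FALSE, criteria = match_criteria()) {
  k <- new.env(parent = emptyenv())
  k$minima <- list()
  k$ts <- list()
  k$model_name <- model_name
  k$units <- units
  k$cartesian3d <- isTRUE(cartesian3d)
  k$criteria <- criteria
  k$provenance <- list(model = model_name, events = list())
  class(k) <- "ktn"
  k
}

#' Stationary-point matching tolerances
#'
#' Two stationary points of the same kind are identified when their energies
#' differ by at most `energy_tol` AND their aligned structural distance is at
#' most `distance_tol`. Defaults (1e-4 kcal/mol, 0.1 Angstrom) separate the
#' distinct minima of every shipped model robustly while absorbing
#' convergence noise, which is orders of magnitude smaller at the default
#' minimisation tolerance.
#'
#' @param energy_tol kcal/mol, > 0.
#' @param distance_tol Angstrom (RMSD after optimal superposition), > 0.
#' @param permutations reserved flag for permutational alignment of
#'   identical beads (off: beads are distinguishable, exact for chains).
#' @return a `match_criteria` list.
#' @export
match_criteria <- function(energy_tol = 1e-4, distance_tol = 0.1,
                           permutations = FALSE) {
  stopifnot(energy_tol > 0, distance_tol > 0)
  structure(list(energy_tol = energy_tol, distance_tol = distance_tol,
                 permutations = isTRUE(permutations)),
            class = "match_criteria")
}

#' @export
print.ktn <- function(x, ...) {
  cat(sprintf("<ktn '%s': %d minima, %d transition states [%s]>\n",
              x$model_name, length(x$minima), length(x$ts), x$units))
  invisible(x)
}

#' @export
summary.ktn <- function(object, ...) {
  emin <- vapply(object$minima, function(m) m$energy, numeric(1))
  ets <- vapply(object$ts, function(t) t$energy, numeric(1))
  out <- list(n_minima = length(emin), n_ts = length(ets),
              global_min = if (length(emin)) min(emin) else NA_real_,
              energy_range = if (length(emin)) range(emin) else c(NA_real_, NA_real_),
              max_ts_energy = if (length(ets)) max(ets) else NA_real_)
  class(out) <- "summary.ktn"
  out
}

#' @export
print.summary.ktn <- function(x, ...) {
  cat(sprintf("KTN: %d minima (global minimum %.6f), %d transition states\n",
              x$n_minima, x$global_min, x$n_ts))
  invisible(x)
}

#' Construct a transition-state record
#'
#' Normally produced by [hybrid_ef_refine()]; exported for hand-built
#' networks. `minus_id` and `plus_id` are the ids of the two minima reached
#' by downhill descent from the saddle (see [descend_from_ts()]).
#'
#' @param energy energy in kcal/mol.
#' @param coordinates configuration vector.
#' @param lowest_eigenvalue the single negative Hessian eigenvalue.
#' @param eigenvector its eigenvector (optional in stored records).
#' @param minus_id,plus_id connected minimum ids.
#' @param gradient_rms gradient RMS at convergence.
#' @param id integer id (assigned by the KTN when `NA`).
#' @return object of class `transition_state`.
#' @export
new_transition_state <- function(energy, coordinates, lowest_eigenvalue,
                                 eigenvector = NULL, minus_id = NA_integer_,
                                 plus_id = NA_integer_, gradient_rms = NA_real_,
                                 id = NA_integer_) {
  structure(list(id = id, energy = energy, coordinates = coordinates,
                 lowest_eigenvalue = lowest_eigenvalue,
                 eigenvector = eigenvector,
                 minus_id = minus_id, plus_id = plus_id,
                 gradient_rms = gradient_rms),
            class = "transition_state")
}

#' @export
print.transition_state <- function(x, ...) {
  cat(sprintf("<transition state%s: E = %.6f kcal/mol, lambda_min = %.4g, links %s-%s>\n",
              if (is.na(x$id)) "" else paste0(" #", x$id),
              x$energy, x$lowest_eigenvalue, x$minus_id, x$plus_id))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Superposes configuration `x_a` onto `x_b` with the optimal translation and
#' proper rotation (determinant +1, so mirror images are *not* matched) and
#' returns the residual RMSD. Coordinates are flattened `n x 3` matrices.
#' Degenerate (collinear or fewer than 3 sites) configurations fall back to
#' translation-only superposition and are flagged.
#'
#' @param x_a,x_b numeric vectors of equal length divisible by 3.
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3), and logical
#'   `degenerate`.
#' @export
align_rmsd <- function(x_a, x_b) {
  stopifnot(length(x_a) == length(x_b))
  if (length(x_a) %% 3 != 0)
    stop("align_rmsd expects flattened n x 3 coordinates")
  A <- matrix(x_a, ncol = 3, byrow = TRUE)
  B <- matrix(x_b, ncol = 3, byrow = TRUE)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  degen <- nrow(A) < 3 || svd(A, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(A, nu = 0, nv = 0)$d[1])
  if (degen) {
    return(list(rmsd = sqrt(mean(rowSums((A - B)^2))), rotation = diag(3),
                degenerate = TRUE))
  }
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  rmsd <- sqrt(mean(rowSums((A %*% R - B)^2)))
  list(rmsd = rmsd, rotation = R, degenerate = FALSE)
}

ktn_distance <- function(ktn, xa, xb, criteria = NULL) {
  criteria <- criteria %||% ktn$criteria
  if (!ktn$cartesian3d) return(sqrt(mean((xa - xb)^2)))
  if (isTRUE(criteria$permutations)) sorted_pairdist_distance(xa, xb)
  else align_rmsd(xa, xb)$rmsd
}

#' Permutation- and rotation-invariant structural distance
#'
#' Root-mean-square difference between the sorted interatomic-distance
#' multisets of two configurations of interchangeable beads. Zero for any
#' permuted, rotated or translated copy; used as the matching metric when
#' [match_criteria()] has `permutations = TRUE` (the exact assignment problem
#' is unnecessary for deduplication, where only same-structure recognition
#' matters and energies already separate distinct isomers).
#'
#' @param x_a,x_b flattened `n x 3` configurations.
#' @return non-negative scalar (Angstrom).
#' @export
sorted_pairdist_distance <- function(x_a, x_b) {
  pd <- function(x) {
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    sort(stats::dist(xyz))
  }
  da <- pd(x_a); db <- pd(x_b)
  sqrt(mean((da - db)^2))
}

#' Insert a stationary point into a KTN, deduplicating
#'
#' Returns the id of the matching stored point of the same kind (energy
#' within `criteria$energy_tol` and aligned distance within
#' `criteria$distance_tol`), incrementing its `discovery_count`; otherwise
#' inserts the point under a fresh id. Transition states additionally carry
#' their two connected minimum ids, which must already exist.
#'
#' @param ktn a [ktn_new()] database.
#' @param point a `minimum` or `transition_state`.
#' @param criteria a [match_criteria()]; defaults to the KTN's own.
#' @return the integer id (new or matched).
#' @export
add_stationary_point <- function(ktn, point, criteria = NULL) {
  criteria <- criteria %||% ktn$criteria
  if (inherits(point, "minimum")) {
    if (is.na(point$gradient_rms) || !is.finite(point$energy))
      stop("rejected: unconverged or non-finite minimum")
    store <- "minima"
  } else if (inherits(point, "transition_state")) {
    if (!is.finite(point$energy))
      stop("rejected: non-finite transition state energy")
    store <- "ts"
  } else stop("point must be a minimum or transition_state")
  pts <- ktn[[store]]
  for (k in seq_along(pts)) {
    if (abs(pts[[k]]$energy - point$energy) <= criteria$energy_tol &&
        ktn_distance(ktn, pts[[k]]$coordinates, point$coordinates, criteria) <= criteria$distance_tol) {
      if (store == "minima")
        ktn$minima[[k]]$discovery_count <- pts[[k]]$discovery_count + 1L
      return(pts[[k]]$id)
    }
  }
  id <- length(pts) + 1L
  point$id <- id
  if (store == "ts") {
    nm <- length(ktn$minima)
    if (is.na(point$minus_id) || is.na(point$plus_id) ||
        point$minus_id > nm || point$plus_id > nm)
      stop("transition state references unknown minima")
  }
  ktn[[store]][[id]] <- point
  id
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ktn_min_energies <- function(ktn) vapply(ktn$minima, function(m) m$energy, numeric(1))

# one row per TS: minus, plus, energy (degenerate TS with minus == plus kept
# but flagged; path queries skip them)
ktn_edges <- function(ktn, include_degenerate = FALSE) {
  if (!length(ktn$ts))
    return(data.frame(minus = integer(), plus = integer(), energy = numeric(),
                      ts_id = integer()))
  df <- data.frame(
    minus = vapply(ktn$ts, function(t) as.integer(t$minus_id), integer(1)),
    plus = vapply(ktn$ts, function(t) as.integer(t$plus_id), integer(1)),
    energy = vapply(ktn$ts, function(t) t$energy, numeric(1)),
    ts_id = vapply(ktn$ts, function(t) as.integer(t$id), integer(1)))
  if (!include_degenerate) df <- df[df$minus != df$plus, , drop = FALSE]
  df
}

#' Grow a KTN until two minima are connected by transition states
#'
#' The connection driver of discrete path sampling: repeatedly pick the most
#' promising unconnected gap on the current best candidate path (Dijkstra on
#' a graph whose missing edges are penalised by squared structural distance,
#' inflated on repeated failures), bridge it with a band search
#' ([dneb()] + [hybrid_ef_refine()] + [descend_from_ts()]), insert the
#' results, and stop once a path of true transition-state edges links the two
#' endpoint minima (or the cycle budget is exhausted).
#'
#' @param ktn the database (updated in place).
#' @param model the [potential_model()] the database belongs to.
#' @param min_a_id,min_b_id endpoint minimum ids.
#' @param max_cycles connection-attempt budget.
#' @param band_config a [band_config()] for the DNEB searches.
#' @return the KTN, invisibly, with a `last_connect` field recording
#'   `connected`, the number of cycles used, and the number of new
#'   transition states.
#' @export
connect_minima <- function(ktn, model, min_a_id, min_b_id, max_cycles = 20L,
                           band_config = NULL) {
  stopifnot(min_a_id <= length(ktn$minima), min_b_id <= length(ktn$minima))
  band_config <- band_config %||% band_config_default()
  attempts <- new.env(parent = emptyenv())
  n_new_ts <- 0L
  cycles <- 0L
  connected <- ktn_path_exists(ktn, min_a_id, min_b_id)
  while (!connected && cycles < max_cycles) {
    cycles <- cycles + 1L
    path <- ktn_gap_path(ktn, min_a_id, min_b_id, attempts)
    if (is.null(path)) break
    gaps <- ktn_path_gaps(ktn, path)
    if (!nrow(gaps)) { connected <- TRUE; break }
    progress <- FALSE
    for (gi in seq_len(nrow(gaps))) {
      u <- gaps$from[gi]; v <- gaps$to[gi]
      key <- paste(min(u, v), max(u, v))
      attempts[[key]] <- (attempts[[key]] %||% 0L) + 1L
      res <- try_bridge(ktn, model, u, v, band_config)
      n_new_ts <- n_new_ts + res
      if (res > 0) progress <- TRUE
    }
    connected <- ktn_path_exists(ktn, min_a_id, min_b_id)
    if (!progress && !connected) {
      # every gap on the best path failed; if no alternative path improves,
      # further cycles cannot succeed
      if (all_gaps_exhausted(ktn, min_a_id, min_b_id, attempts, max_attempts = 3L))
        break
    }
  }
  ktn$last_connect <- list(a = min_a_id, b = min_b_id, connected = connected,
                           cycles = cycles, new_ts = n_new_ts)
  ktn$provenance$events <- c(ktn$provenance$events,
                             list(sprintf("connect %d-%d: %s after %d cycles",
                                          min_a_id, min_b_id,
                                          if (connected) "connected" else "UNCONNECTED",
                                          cycles)))
  invisible(ktn)
}

try_bridge <- function(ktn, model, u, v, band_config) {
  xa <- ktn$minima[[u]]$coordinates
  xb <- ktn$minima[[v]]$coordinates
  cands <- tryCatch(dneb(model, xa, xb, band_config), error = function(e) list())
  added <- 0L
  for (cx in cands) {
    ts <- tryCatch(hybrid_ef_refine(model, cx), error = function(e) NULL)
    if (is.null(ts)) next
    ends <- tryCatch(descend_from_ts(model, ts), error = function(e) NULL)
    if (is.null(ends)) next
    ia <- add_stationary_point(ktn, ends$minimum_minus)
    ib <- add_stationary_point(ktn, ends$minimum_plus)
    ts$minus_id <- ia; ts$plus_id <- ib
    add_stationary_point(ktn, ts)
    added <- added + 1L
  }
  added
}

# TRUE when a path of non-degenerate TS edges joins a and b
ktn_path_exists <- function(ktn, a, b) {
  if (a == b) return(TRUE)
  n <- length(ktn$minima)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ed <- ktn_edges(ktn)
  for (k in seq_len(nrow(ed))) {
    ri <- find(ed$minus[k]); rj <- find(ed$plus[k])
    if (ri != rj) parent[ri] <- rj
  }
  find(a) == find(b)
}

# Dijkstra on the mixed graph: TS edges weight 0, missing edges weight
# aligned RMSD^2 inflated 4x per failed attempt; returns node path or NULL
ktn_gap_path <- function(ktn, a, b, attempts, max_attempts = 3L) {
  n <- length(ktn$minima)
  W <- matrix(Inf, n, n)
  coords <- lapply(ktn$minima, function(m) m$coordinates)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    key <- paste(i, j)
    att <- attempts[[key]] %||% 0L
    if (att >= max_attempts) next
    d <- ktn_distance(ktn, coords[[i]], coords[[j]])
    W[i, j] <- W[j, i] <- (d^2 + 1e-12) * 4^att
  }
  ed <- ktn_edges(ktn)
  for (k in seq_len(nrow(ed))) {
    W[ed$minus[k], ed$plus[k]] <- 0
    W[ed$plus[k], ed$minus[k]] <- 0
  }
  dist <- rep(Inf, n); dist[a] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    if (u == b) break
    nd <- dist[u] + W[u, ]
    upd <- which(!done & nd < dist)
    dist[upd] <- nd[upd]
    prev[upd] <- u
  }
  if (!is.finite(dist[b])) return(NULL)
  path <- b
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  if (path[1] != a) return(NULL)
  path
}

ktn_path_gaps <- function(ktn, path) {
  ed <- ktn_edges(ktn)
  haveEdge <- function(u, v) any((ed$minus == u & ed$plus == v) | (ed$minus == v & ed$plus == u))
  from <- integer(); to <- integer()
  for (k in seq_len(length(path) - 1)) {
    if (!haveEdge(path[k], path[k + 1])) { from <- c(from, path[k]); to <- c(to, path[k + 1]) }
  }
  data.frame(from = from, to = to)
}

all_gaps_exhausted <- function(ktn, a, b, attempts, max_attempts = 3L) {
  is.null(ktn_gap_path(ktn, a, b, attempts, max_attempts = max_attempts))
}

#' Pick folded / partially folded / unfolded representatives
#'
#' Given an order parameter mapping each minimum to `[0, 1]` (for the chain
#' models, the native-contact fraction is the natural choice), returns the
#' lowest-energy minimum in each of the bands `[0.8, 1]` (folded),
#' `[0.3, 0.7]` (partially folded) and `[0, 0.2]` (unfolded). These three
#' structures are the canonical seeds when re-exploring the landscape under a
#' different parameter set.
#'
#' @param ktn a non-empty KTN.
#' @param order_param function(minimum) -> value in `[0, 1]`.
#' @return list with integer ids `folded`, `partial`, `unfolded`.
#' @export
seed_representatives <- function(ktn, order_param) {
  if (!length(ktn$minima)) stop("empty KTN")
  q <- vapply(ktn$minima, function(m) order_param(m), numeric(1))
  if (any(q < -1e-9 | q > 1 + 1e-9)) stop("order parameter must map to [0, 1]")
  e <- ktn_min_energies(ktn)
  pick <- function(lo, hi, band) {
    sel <- which(q >= lo & q <= hi)
    if (!length(sel))
      stop(structure(class = c("pelkit_missing_representative", "error", "condition"),
                     list(message = sprintf("no minimum with order parameter in [%g, %g] (%s band)",
                                            lo, hi, band), call = NULL, band = band)))
    sel[which.min(e[sel])]
  }
  list(folded = pick(0.8, 1, "folded"),
       partial = pick(0.3, 0.7, "partially folded"),
       unfolded = pick(0, 0.2, "unfolded"))
}

#' Convergence assessment over a sequence of KTN snapshots
#'
#' Landscape exploration is judged converged when adding stationary points no
#' longer changes the topography or the thermodynamics: per snapshot the
#' report tracks the funnel count at a fixed level spacing, the
#' global-minimum energy, the minimax barrier matrix between funnel-bottom
#' minima, and the harmonic-superposition occupation probability of the
#' lowest funnel at a reference temperature. Converged means every metric is
#' stable (relative change < 1 percent, and unchanged integer counts) over
#' the last two snapshots.
#'
#' @param snapshots ordered list of [ktn_new()] databases sharing a model.
#' @param delta_e level spacing (kcal/mol) for the superbasin analysis.
#' @param min_depth funnel depth threshold; defaults to `5 * delta_e`.
#' @param temperature reference temperature (kcal/mol) for occupation
#'   probabilities.
#' @return list of class `ktn_convergence_report` with a per-snapshot metric
#'   table and a logical `converged`.
#' @export
convergence_report <- function(snapshots, delta_e = 1.0, min_depth = 5 * delta_e,
                               temperature = 1.0) {
  if (length(snapshots) < 2)
    stop(structure(class = c("pelkit_not_assessable", "error", "condition"),
                   list(message = "need at least two snapshots to assess convergence",
                        call = NULL)))
  metrics <- lapply(snapshots, function(k) {
    e <- ktn_min_energies(k)
    tree <- build_superbasins(k, delta_e = delta_e)
    fun <- identify_funnels(tree, min_depth = min_depth)
    bottoms <- vapply(fun, function(f) f$lowest_id, integer(1))
    bm <- matrix(NA_real_, length(bottoms), length(bottoms))
    if (length(bottoms) > 1) {
      for (i in seq_along(bottoms)) for (j in seq_along(bottoms)) if (i != j)
        bm[i, j] <- tryCatch(minimax_barrier(k, bottoms[i], bottoms[j]),
                             error = function(e) NA_real_)
    }
    w <- exp(-(e - min(e)) / temperature)
    occ <- sum(w[fun[[1]]$members]) / sum(w)
    list(n_funnels = length(fun), gm_energy = min(e), barriers = bm,
         occupation_lowest = occ)
  })
  last <- metrics[[length(metrics)]]
  prev <- metrics[[length(metrics) - 1]]
  relch <- function(a, b) {
    if (length(a) != length(b)) return(Inf)
    denom <- pmax(abs(a), abs(b), 1e-12)
    d <- abs(a - b) / denom
    d[is.na(a) & is.na(b)] <- 0
    max(d, na.rm = FALSE)
  }
  stable <- last$n_funnels == prev$n_funnels &&
    relch(last$gm_energy, prev$gm_energy) < 0.01 &&
    relch(as.vector(last$barriers), as.vector(prev$barriers)) < 0.01 &&
    relch(last$occupation_lowest, prev$occupation_lowest) < 0.01
  tab <- data.frame(
    snapshot = seq_along(metrics),
    n_minima = vapply(snapshots, function(k) length(k$minima), integer(1)),
    n_ts = vapply(snapshots, function(k) length(k$ts), integer(1)),
    n_funnels = vapply(metrics, function(m) m$n_funnels, integer(1)),
    gm_energy = vapply(metrics, function(m) m$gm_energy, numeric(1)),
    occupation_lowest = vapply(metrics, function(m) m$occupation_lowest, numeric(1)))
  structure(list(table = tab, barriers = lapply(metrics, function(m) m$barriers),
                 converged = isTRUE(stable)),
            class = "ktn_convergence_report")
}

#' @export
print.ktn_convergence_report <- function(x, ...) {
  print(x$table)
  cat(if (x$converged) "converged: topography and thermodynamics stable\n"
      else "NOT converged\n")
  invisible(x)
}
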