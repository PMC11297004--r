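#' Basin-hopping configuration
#'
#' @param n_steps number of perturbation/quench/Metropolis cycles (>= 1).
#' @param temperature Metropolis temperature in kcal/mol (> 0); the
#'   acceptance test is applied to quenched minimum energies.
#' @param step_size initial Cartesian displacement amplitude in Angstrom;
#'   every coordinate is displaced uniformly within `[-step_size, step_size]`.
#' @param adaptive_step logical; when `TRUE` the step size is rescaled every
#'   `adapt_interval` steps towards a 50 percent acceptance ratio.
#' @param adapt_interval steps between step-size updates.
#' @param rng_seed integer seed recorded in all outputs; runs with the same
#'   seed, start and model are byte-reproducible.
#' @param tol gradient-RMS convergence tolerance (kcal/mol/Angstrom) for the
#'   local quenches.
#' @param container_radius optional radius (Angstrom) about the centroid
#'   beyond which quenched cluster configurations are discarded; keeps
#'   basin-hopping of clusters from wandering into dissociated fragments.
#'   `Inf` disables the container.
#' @return a `basin_hopping_config` list.
#' @export
basin_hopping_config <- function(n_steps = 500L, temperature = 1.0,
                                 step_size = 0.4, adaptive_step = TRUE,
                                 adapt_interval = 50L, rng_seed = 1L,
                                 tol = 1e-6, container_radius = Inf) {
  stopifnot(n_steps >= 1, temperature > 0, step_size > 0, tol > 0)
  structure(list(n_steps = as.integer(n_steps), temperature = temperature,
                 step_size = step_size, adaptive_step = isTRUE(adaptive_step),
                 adapt_interval = as.integer(adapt_interval),
                 rng_seed = as.integer(rng_seed), tol = tol,
                 container_radius = container_radius),
            class = "basin_hopping_config")
}

#' Construct a minimum record
#'
#' Normally produced by [local_minimise()] / [basin_hop()]; the constructor
#' is exported so hand-built networks (e.g. test fixtures or imported
#' databases) can be assembled directly.
#'
#' @param energy energy in kcal/mol.
#' @param coordinates configuration vector.
#' @param gradient_rms gradient RMS at convergence (must be finite for the
#'   point to be accepted into a KTN).
#' @param id integer id (assigned by the KTN when `NA`).
#' @param discovery_count how often the point has been found.
#' @return object of class `minimum`.
#' @export
new_minimum <- function(energy, coordinates, gradient_rms, id = NA_integer_,
                        discovery_count = 1L) {
  structure(list(id = id, energy = energy, coordinates = coordinates,
                 gradient_rms = gradient_rms,
                 discovery_count = as.integer(discovery_count)),
            class = "minimum")
}

#' @export
print.minimum <- function(x, ...) {
  cat(sprintf("<minimum%s: E = %.6f kcal/mol, |grad|_rms = %.2e, seen %dx>\n",
              if (is.na(x$id)) "" else paste0(" #", x$id),
              x$energy, x$gradient_rms, x$discovery_count))
  invisible(x)
}

nonconvergence_error <- function(msg, trajectory_tail = NULL) {
  structure(class = c("pelkit_nonconvergence", "error", "condition"),
            list(message = msg, call = NULL, trajectory_tail = trajectory_tail))
}

#' Local minimisation to database-grade tolerance
#'
#' Quasi-Newton (L-BFGS-B) descent followed, when needed, by Newton polish
#' steps on the zero-mode-projected Hessian, until the projected gradient
#' RMS drops below `tol`. The default tolerance (1e-6 kcal/mol/Angstrom) is
#' deliberately much tighter than the stationary-point matching tolerances
#' so that deduplication is unambiguous.
#'
#' @param model a [potential_model()].
#' @param x0 starting configuration.
#' @param tol gradient-RMS convergence tolerance.
#' @param max_iter L-BFGS iteration cap.
#' @return a `minimum` object (energy, coordinates, gradient_rms).
#' @export
local_minimise <- function(model, x0, tol = 1e-6, max_iter = 2000L) {
  validate_configuration(model, x0)
  e0 <- model_energy(model, x0)
  fn <- function(x) {
    e <- tryCatch(model$energy_fn(x), error = function(e) NA_real_)
    if (!is.finite(e)) 1e12 else e
  }
  gr <- function(x) {
    g <- tryCatch(model_gradient(model, x), error = function(e) rep(0, length(x)))
    g[!is.finite(g)] <- 0
    g
  }
  res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 10, pgtol = tol / 3))
  x <- res$par
  # Newton polish on the projected Hessian down to tol
  for (it in seq_len(25L)) {
    g <- model_gradient(model, x)
    rms <- gradient_rms(model, x, g)
    if (rms <= tol) break
    H <- model_hessian(model, x)
    B <- zero_mode_basis(model, x)
    if (ncol(B) > 0) H <- H + 1e6 * tcrossprod(B)
    eg <- eigen(H, symmetric = TRUE)
    lam <- pmax(abs(eg$values), 1e-8)
    step <- -eg$vectors %*% ((crossprod(eg$vectors, g)) / lam)
    sn <- sqrt(sum(step^2))
    if (sn > 0.5) step <- step * (0.5 / sn)
    e_cur <- model_energy(model, x)
    alpha <- 1
    repeat {
      x_try <- x + alpha * as.vector(step)
      e_try <- tryCatch(model_energy(model, x_try), error = function(e) Inf)
      g_try <- tryCatch(gradient_rms(model, x_try), error = function(e) Inf)
      if (g_try < rms || e_try < e_cur) break
      alpha <- alpha / 2
      if (alpha < 1e-6) break
    }
    if (alpha < 1e-6) break
    x <- x + alpha * as.vector(step)
  }
  g <- model_gradient(model, x)
  rms <- gradient_rms(model, x, g)
  if (rms > tol)
    stop(nonconvergence_error(
      sprintf("local minimisation stalled at gradient RMS %.3e (tol %.1e)", rms, tol),
      trajectory_tail = list(x = x, energy = model_energy(model, x), gradient = g)))
  e <- model_energy(model, x)
  if (e > e0 + 1e-9)
    stop(nonconvergence_error("minimisation increased the energy"))
  new_minimum(e, x, rms)
}

#' Basin-hopping global optimisation
#'
#' Iterates random Cartesian perturbation, local quench, and a Metropolis
#' accept/reject test on the quenched minimum energies. All quenched minima
#' (accepted or not) enter the returned census, deduplicated by energy and
#' structural distance.
#'
#' @param model a [potential_model()].
#' @param x0 starting configuration.
#' @param config a [basin_hopping_config()].
#' @param energy_tol,distance_tol deduplication tolerances for the census
#'   (kcal/mol; Angstrom RMSD after optimal superposition for 3-D bead
#'   models, plain Euclidean distance otherwise).
#' @return list of `minimum` objects sorted by increasing energy, each with
#'   its `discovery_count`; attribute `accept_rate` records the Metropolis
#'   acceptance ratio and attribute `config` the configuration used.
#' @export
basin_hop <- function(model, x0, config = basin_hopping_config(),
                      energy_tol = 1e-4, distance_tol = 0.1) {
  validate_configuration(model, x0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$rng_seed)

  quench <- function(x) tryCatch(local_minimise(model, x, tol = config$tol),
                                 error = function(e) NULL)
  inside_container <- function(m) {
    if (!is.finite(config$container_radius) || !model$cartesian3d) return(TRUE)
    xyz <- matrix(m$coordinates, ncol = 3, byrow = TRUE)
    rel <- sweep(xyz, 2, colMeans(xyz))
    max(sqrt(rowSums(rel^2))) <= config$container_radius
  }

  cur <- quench(x0)
  if (is.null(cur)) stop(nonconvergence_error("initial quench failed"))
  census <- list(cur)
  step <- config$step_size
  n_acc <- 0L; n_try <- 0L; acc_window <- 0L
  floored <- FALSE
  trace <- list()

  for (s in seq_len(config$n_steps)) {
    prop <- cur$coordinates + stats::runif(model$dimension, -step, step)
    m <- quench(prop)
    n_try <- n_try + 1L
    if (!is.null(m) && inside_container(m)) {
      census <- census_add(census, m, model, energy_tol, distance_tol)
      dE <- m$energy - cur$energy
      accepted <- dE <= 0 || stats::runif(1) < exp(-dE / config$temperature)
      trace[[length(trace) + 1L]] <- c(step = s, energy = m$energy, accepted = accepted)
      if (accepted) {
        cur <- m
        n_acc <- n_acc + 1L
        acc_window <- acc_window + 1L
      }
    }
    if (config$adaptive_step && s %% config$adapt_interval == 0L) {
      rate <- acc_window / config$adapt_interval
      step <- step * if (rate > 0.5) 1.05 else 0.95
      if (step < 1e-4) { step <- 1e-4; floored <- TRUE }
      acc_window <- 0L
    }
  }
  if (floored && n_acc == 0L)
    warning("all basin-hopping moves rejected with the step size floored; returning partial census")

  ord <- order(vapply(census, function(m) m$energy, numeric(1)))
  census <- census[ord]
  for (k in seq_along(census)) census[[k]]$id <- k
  attr(census, "accept_rate") <- if (n_try > 0) n_acc / n_try else NA_real_
  attr(census, "config") <- config
  attr(census, "trace") <- if (length(trace)) as.data.frame(do.call(rbind, trace))
                           else data.frame(step = numeric(), energy = numeric(),
                                           accepted = numeric())
  census
}

# add a quenched minimum to a census, deduplicating by energy + distance
census_add <- function(census, m, model, energy_tol, distance_tol) {
  for (k in seq_along(census)) {
    if (abs(census[[k]]$energy - m$energy) <= energy_tol &&
        structural_distance(model, census[[k]]$coordinates, m$coordinates) <= distance_tol) {
      census[[k]]$discovery_count <- census[[k]]$discovery_count + 1L
      return(census)
    }
  }
  c(census, list(m))
}

# RMSD after optimal superposition for 3-D bead models (permutation-invariant
# sorted-pair-distance metric when beads are interchangeable), per-coordinate
# RMS deviation otherwise
structural_distance <- function(model, xa, xb) {
  if (!model$cartesian3d) return(sqrt(mean((xa - xb)^2)))
  if (model$identical_beads) sorted_pairdist_distance(xa, xb) else align_rmsd(xa, xb)$rmsd
}
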