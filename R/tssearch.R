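#' Band configuration for doubly nudged elastic band searches
#'
#' @param n_images number of band images including the two fixed endpoints
#'   (>= 3). Default 11.
#' @param k spring constant, (kcal/mol)/Angstrom^2. Default 10.
#' @param dneb logical; keep the doubly nudged portion of the perpendicular
#'   spring gradient (plain NEB when `FALSE`).
#' @param scheme interpolation scheme id; `"linear"` (straight Cartesian
#'   interpolation with a steric clash-repair pass) is the only shipped
#'   scheme.
#' @param tol convergence threshold on the per-image projected gradient RMS.
#' @param max_iter band relaxation iteration cap.
#' @return a `band_config` list.
#' @export
band_config <- function(n_images = 11L, k = 10, dneb = TRUE,
                        scheme = "linear", tol = 1e-3, max_iter = 3000L) {
  stopifnot(n_images >= 3)
  structure(list(n_images = as.integer(n_images), k = k, dneb = isTRUE(dneb),
                 scheme = scheme, tol = tol, max_iter = as.integer(max_iter)),
            class = "band_config")
}

band_config_default <- band_config

#' Interpolate a band of images between two configurations
#'
#' Straight Cartesian interpolation including both endpoints. For 3-D bead
#' models a repair pass then displaces any image in which two beads come
#' closer than `clash_tol` apart: the offending pair is pushed apart along
#' its separation vector (along a fixed axis if exactly coincident) until the
#' clash clears. An image that cannot be repaired raises an error naming it.
#'
#' @param model a [potential_model()].
#' @param x_a,x_b endpoint configurations (same dimension).
#' @param n_images number of images including endpoints (>= 3).
#' @param scheme interpolation scheme id (only `"linear"`).
#' @param clash_tol minimum allowed inter-bead distance in repaired images;
#'   defaults to half the model's length scale (`parameters$sigma` when
#'   present, 1 Angstrom otherwise).
#' @return list of configurations of length `n_images`.
#' @export
interpolate_band <- function(model, x_a, x_b, n_images = 11L, scheme = "linear",
                             clash_tol = NULL) {
  stopifnot(length(x_a) == length(x_b), n_images >= 3)
  if (!identical(scheme, "linear")) stop("unknown interpolation scheme: ", scheme)
  if (is.null(clash_tol))
    clash_tol <- 0.5 * (model$parameters$sigma %||% 1)
  ts <- seq(0, 1, length.out = n_images)
  band <- lapply(ts, function(t) (1 - t) * x_a + t * x_b)
  if (model$cartesian3d) {
    for (i in seq_along(band)[-c(1, n_images)]) {
      band[[i]] <- repair_clashes(band[[i]], clash_tol, image = i)
    }
  }
  band
}

repair_clashes <- function(x, clash_tol, image, max_passes = 100L) {
  xyz <- matrix(x, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  if (n < 2) return(x)
  for (pass in seq_len(max_passes)) {
    fixed <- TRUE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- xyz[j, ] - xyz[i, ]
      r <- sqrt(sum(d^2))
      if (r < clash_tol) {
        fixed <- FALSE
        dir <- if (r < 1e-12) c(0, 0, 1) else d / r
        push <- (clash_tol * 1.05 - r) / 2
        xyz[i, ] <- xyz[i, ] - dir * push
        xyz[j, ] <- xyz[j, ] + dir * push
      }
    }
    if (fixed) return(as.vector(t(xyz)))
  }
  stop(sprintf("unrepairable steric clash in band image %d", image))
}

#' Doubly nudged elastic band transition-state candidate search
#'
#' Relaxes a band of images between two minima under the projected true
#' gradient plus the nudged spring gradient; the doubly nudged variant also
#' retains the component of the perpendicular spring gradient orthogonal to
#' the perpendicular true gradient, which stabilises the band against
#' corner-cutting. Interior images that are local energy maxima along the
#' relaxed band are returned as transition-state candidates for
#' [hybrid_ef_refine()].
#'
#' @param model a [potential_model()].
#' @param min_a,min_b endpoint configurations (converged minima).
#' @param config a [band_config()].
#' @return list of candidate configurations (possibly empty); attribute
#'   `converged` is `FALSE` when the relaxation hit the iteration cap (the
#'   best candidates are still returned, flagged).
#' @export
dneb <- function(model, min_a, min_b, config = band_config()) {
  stopifnot(length(min_a) == model$dimension, length(min_b) == model$dimension)
  if (sqrt(mean((min_a - min_b)^2)) < 1e-8) {
    out <- list(); attr(out, "converged") <- TRUE; return(out)
  }
  band <- interpolate_band(model, min_a, min_b, config$n_images, config$scheme)
  n <- config$n_images
  interior <- 2:(n - 1)
  eta <- 0.005
  prev_rms <- Inf
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    G <- band_forces(model, band, config)
    rms <- sqrt(mean(unlist(G)^2))
    if (rms <= config$tol) { converged <- TRUE; break }
    if (rms < prev_rms) eta <- min(eta * 1.1, 0.05) else eta <- max(eta * 0.5, 1e-5)
    prev_rms <- rms
    for (i in seq_along(interior)) {
      step <- eta * G[[i]]
      sn <- sqrt(sum(step^2))
      if (sn > 0.2) step <- step * (0.2 / sn)
      band[[interior[i]]] <- band[[interior[i]]] + step
    }
  }
  e <- vapply(band, function(x) model_energy(model, x), numeric(1))
  cand <- list()
  for (i in interior) {
    if (e[i] > e[i - 1] && e[i] > e[i + 1]) cand[[length(cand) + 1L]] <- band[[i]]
  }
  attr(cand, "converged") <- converged
  attr(cand, "band_energies") <- e
  cand
}

# force (negative DNEB gradient) on each interior image
band_forces <- function(model, band, config) {
  n <- length(band)
  g <- lapply(band, function(x) model_gradient(model, x))
  out <- vector("list", n - 2)
  for (ii in 2:(n - 1)) {
    tau <- band[[ii + 1]] - band[[ii - 1]]
    tau <- tau / sqrt(sum(tau^2))
    gperp <- g[[ii]] - sum(g[[ii]] * tau) * tau
    f_true <- -gperp
    dplus <- band[[ii + 1]] - band[[ii]]
    dminus <- band[[ii]] - band[[ii - 1]]
    f_spring_par <- config$k * (sqrt(sum(dplus^2)) - sqrt(sum(dminus^2))) * tau
    f <- f_true + f_spring_par
    if (config$dneb) {
      f_spring <- config$k * (dplus - dminus)
      f_sp_perp <- f_spring - sum(f_spring * tau) * tau
      gp_norm <- sqrt(sum(gperp^2))
      if (gp_norm > 1e-12) {
        ghat <- gperp / gp_norm
        f_sp_perp <- f_sp_perp - sum(f_sp_perp * ghat) * ghat
      }
      f <- f + f_sp_perp
    }
    out[[ii - 1]] <- f
  }
  out
}

not_a_saddle_error <- function(msg) {
  structure(class = c("pelkit_not_a_saddle", "error", "condition"),
            list(message = msg, call = NULL))
}

higher_order_saddle_error <- function(msg) {
  structure(class = c("pelkit_higher_order_saddle", "error", "condition"),
            list(message = msg, call = NULL))
}

# projected Hessian eigendecomposition; zero modes pushed to +1e6
projected_eigen <- function(model, x) {
  H <- model_hessian(model, x)
  B <- zero_mode_basis(model, x)
  if (ncol(B) > 0) H <- H + 1e6 * tcrossprod(B)
  eigen(H, symmetric = TRUE)
}

#' Hybrid eigenvector-following refinement of a transition-state candidate
#'
#' Alternates uphill steps along the lowest-eigenvalue eigenvector of the
#' (zero-mode-projected) Hessian with Newton minimisation in the orthogonal
#' subspace, until the projected gradient RMS drops below `tol`. The
#' converged point is accepted only if its projected Hessian has exactly one
#' negative eigenvalue: convergence to a minimum signals a rejected
#' candidate, and a persisting second negative eigenvalue signals a
#' higher-order saddle.
#'
#' @param model a [potential_model()].
#' @param x_guess candidate configuration (e.g. a [dneb()] image).
#' @param tol gradient-RMS convergence tolerance (kcal/mol/Angstrom).
#' @param max_iter iteration cap.
#' @param max_step trust-radius cap on each step (Angstrom).
#' @param neg_tol eigenvalues below `-neg_tol` count as negative.
#' @return a `transition_state` (minus/plus minima not yet assigned; see
#'   [descend_from_ts()]).
#' @export
hybrid_ef_refine <- function(model, x_guess, tol = 1e-6, max_iter = 300L,
                             max_step = 0.2, neg_tol = 1e-5) {
  validate_configuration(model, x_guess)
  x <- x_guess
  for (it in seq_len(max_iter)) {
    g <- model_gradient(model, x)
    gp <- project_zero_modes(model, x, g)
    rms <- sqrt(mean(gp^2))
    eg <- projected_eigen(model, x)
    nneg <- sum(eg$values < -neg_tol)
    if (rms <= tol) {
      if (nneg == 1L) {
        i1 <- which.min(eg$values)
        return(new_transition_state(model_energy(model, x), x,
                                    eg$values[i1], eg$vectors[, i1],
                                    gradient_rms = rms))
      }
      if (nneg == 0L)
        stop(not_a_saddle_error("candidate converged to a minimum; rejected"))
      stop(higher_order_saddle_error(
        sprintf("candidate converged to an order-%d saddle", nneg)))
    }
    V <- eg$vectors
    lam <- eg$values
    h <- as.vector(crossprod(V, gp))
    i1 <- which.min(lam)
    step <- numeric(length(x))
    # uphill along the lowest mode
    if (lam[i1] < -neg_tol) {
      step <- step - (h[i1] / lam[i1]) * V[, i1]
    } else if (abs(h[i1]) > 1e-14) {
      step <- step + sign(h[i1]) * min(max_step / 2, 0.1) * V[, i1]
    }
    # Newton minimisation in the orthogonal subspace
    rest <- setdiff(seq_along(lam), i1)
    lam_r <- pmax(lam[rest], 1e-2)
    step <- step - V[, rest, drop = FALSE] %*% (h[rest] / lam_r)
    step <- as.vector(step)
    sn <- sqrt(sum(step^2))
    if (sn > max_step) step <- step * (max_step / sn)
    x <- x + step
  }
  stop(nonconvergence_error(
    sprintf("hybrid eigenvector following did not converge in %d iterations", max_iter)))
}

# short damped steepest-descent relaxation: keeps the descent on the true
# downhill path near the saddle before handing over to quasi-Newton, so the
# connected basin is not overshot
steepest_relax <- function(model, x, n_steps = 400L, max_disp = 0.05) {
  e <- model_energy(model, x)
  for (it in seq_len(n_steps)) {
    g <- project_zero_modes(model, x, model_gradient(model, x))
    gn <- sqrt(sum(g^2))
    if (gn < 1e-8) break
    step <- -g * min(max_disp / gn, 0.2 / gn^0.5)
    x_try <- x + step
    e_try <- tryCatch(model_energy(model, x_try), error = function(e) Inf)
    tries <- 0L
    while (e_try > e && tries < 30L) {
      step <- step / 2
      x_try <- x + step
      e_try <- tryCatch(model_energy(model, x_try), error = function(e) Inf)
      tries <- tries + 1L
    }
    if (e_try > e) break
    if (abs(e - e_try) < 1e-10 * max(1, abs(e))) { x <- x_try; break }
    x <- x_try; e <- e_try
  }
  x
}

#' Find the two minima connected by a transition state
#'
#' Displaces the transition state by `displacement` along both senses of its
#' negative-curvature eigenvector and minimises each side. On descent
#' failure the displacement is doubled, up to four times.
#'
#' @param model a [potential_model()].
#' @param ts a converged `transition_state` from [hybrid_ef_refine()].
#' @param displacement initial displacement along the eigenvector (Angstrom).
#' @param tol minimisation tolerance.
#' @return list with `minimum_minus`, `minimum_plus` (possibly structurally
#'   identical for degenerate rearrangements) and the input `ts` with its
#'   energy checked against both minima.
#' @export
descend_from_ts <- function(model, ts, displacement = 0.05, tol = 1e-6) {
  stopifnot(inherits(ts, "transition_state"))
  v <- ts$eigenvector
  if (is.null(v)) stop("transition state carries no eigenvector")
  one_side <- function(sgn, side) {
    d <- displacement
    for (k in 1:5) {
      x0 <- steepest_relax(model, ts$coordinates + sgn * d * v, max_disp = displacement)
      m <- tryCatch(local_minimise(model, x0, tol = tol),
                    error = function(e) NULL)
      # reject descents that fell straight back onto the saddle
      if (!is.null(m) && abs(m$energy - ts$energy) > 1e-12) return(m)
      if (!is.null(m) && sqrt(mean((m$coordinates - ts$coordinates)^2)) > 1e-6) return(m)
      d <- d * 2
    }
    stop(nonconvergence_error(sprintf("descent from transition state failed on the %s side", side)))
  }
  mm <- one_side(-1, "minus")
  mp <- one_side(+1, "plus")
  if (ts$energy < max(mm$energy, mp$energy) - 1e-6)
    stop("transition state energy below a connected minimum; inconsistent stationary points")
  list(minimum_minus = mm, minimum_plus = mp, ts = ts)
}
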