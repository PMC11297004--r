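#' Potential-energy model contract
#'
#' A `potential_model` wraps an energy function (and, optionally, analytic
#' gradient and Hessian functions) together with the metadata the landscape
#' machinery needs: the coordinate dimension, the number of zero modes
#' (invariant rigid-body motions to project out of curvature analyses), and an
#' opaque parameter block. All energies are in kcal/mol and all lengths in
#' Angstrom unless a model documents otherwise.
#'
#' @param name identifier for the model.
#' @param dimension number of coordinates a configuration carries.
#' @param energy_fn function(x) returning a finite scalar energy.
#' @param gradient_fn optional function(x) returning the analytic gradient;
#'   when `NULL`, centred finite differences of `energy_fn` are used.
#' @param hessian_fn optional function(x) returning the analytic Hessian;
#'   when `NULL`, finite differences of the gradient (step 1e-4) are used.
#' @param n_zero_modes number of invariant motions (overall translations and
#'   rotations) with zero curvature; 0 for fixed-frame analytic surfaces,
#'   6 for a 3-D cluster or chain (5 for a linear arrangement, not handled
#'   specially).
#' @param validate_fn optional function(x) returning `TRUE` or a character
#'   string describing why the configuration is degenerate.
#' @param parameters opaque parameter block stored with the model.
#' @param cartesian3d logical; `TRUE` when coordinates are a flattened
#'   `n_sites x 3` matrix of bead positions, enabling rigid-body alignment
#'   and zero-mode projection.
#' @param identical_beads logical; `TRUE` when all beads are interchangeable
#'   (e.g. single-species clusters), so structural comparisons must be
#'   permutation-invariant.
#' @return an object of class `potential_model`.
#' @export
potential_model <- function(name, dimension, energy_fn, gradient_fn = NULL,
                            hessian_fn = NULL, n_zero_modes = 0L,
                            validate_fn = NULL, parameters = list(),
                            cartesian3d = FALSE, identical_beads = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(dimension), dimension >= 1, is.function(energy_fn))
  if (cartesian3d && dimension %% 3 != 0)
    stop("cartesian3d models need a dimension divisible by 3")
  structure(list(
    name = name,
    dimension = as.integer(dimension),
    energy_fn = energy_fn,
    gradient_fn = gradient_fn,
    hessian_fn = hessian_fn,
    n_zero_modes = as.integer(n_zero_modes),
    validate_fn = validate_fn,
    parameters = parameters,
    cartesian3d = isTRUE(cartesian3d),
    identical_beads = isTRUE(identical_beads)
  ), class = "potential_model")
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model '%s': %d coordinates, %d zero modes, %s gradient>\n",
              x$name, x$dimension, x$n_zero_modes,
              if (is.null(x$gradient_fn)) "finite-difference" else "analytic"))
  invisible(x)
}

#' Validate a configuration against a model
#'
#' Checks dimension, finiteness, and the model's own degeneracy test (for
#' bead models: no coincident interaction sites).
#'
#' @param model a [potential_model()].
#' @param x numeric configuration vector.
#' @return `TRUE` invisibly; signals a condition of class
#'   `pelkit_dimension_error` or `pelkit_degenerate_geometry` otherwise.
#' @export
validate_configuration <- function(model, x) {
  if (!is.numeric(x) || length(x) != model$dimension)
    stop(dimension_error(model, x))
  if (!all(is.finite(x)))
    stop(degenerate_geometry("non-finite coordinates"))
  if (!is.null(model$validate_fn)) {
    ok <- model$validate_fn(x)
    if (!isTRUE(ok)) stop(degenerate_geometry(as.character(ok)))
  }
  invisible(TRUE)
}

dimension_error <- function(model, x) {
  structure(class = c("pelkit_dimension_error", "error", "condition"),
            list(message = sprintf("configuration has %d coordinates; model '%s' expects %d",
                                   length(x), model$name, model$dimension),
                 call = NULL))
}

degenerate_geometry <- function(msg) {
  structure(class = c("pelkit_degenerate_geometry", "error", "condition"),
            list(message = paste("degenerate geometry:", msg), call = NULL))
}

potential_eval_error <- function(msg, x) {
  structure(class = c("pelkit_potential_error", "error", "condition"),
            list(message = msg, call = NULL, configuration = x))
}

#' Evaluate energy and gradient
#'
#' @param model a [potential_model()].
#' @param x configuration vector of length `model$dimension`.
#' @return list with elements `energy` (kcal/mol) and `gradient`.
#' @export
energy_gradient <- function(model, x) {
  validate_configuration(model, x)
  e <- model$energy_fn(x)
  if (!is.finite(e)) stop(degenerate_geometry("energy is not finite"))
  g <- model_gradient(model, x)
  list(energy = e, gradient = g)
}

#' Energy only
#' @rdname energy_gradient
#' @export
model_energy <- function(model, x) {
  validate_configuration(model, x)
  e <- model$energy_fn(x)
  if (!is.finite(e)) stop(degenerate_geometry("energy is not finite"))
  e
}

#' Gradient only (analytic if available, otherwise centred finite differences)
#' @rdname energy_gradient
#' @export
model_gradient <- function(model, x) {
  if (!is.null(model$gradient_fn)) return(model$gradient_fn(x))
  fd_gradient(model$energy_fn, x)
}

#' Hessian (analytic if available, otherwise finite differences of the
#' gradient with step 1e-4 in model units)
#' @rdname energy_gradient
#' @export
model_hessian <- function(model, x, h = 1e-4) {
  if (!is.null(model$hessian_fn)) return(model$hessian_fn(x))
  n <- length(x)
  gf <- function(y) model_gradient(model, y)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    H[, i] <- (gf(xp) - gf(xm)) / (2 * h)
  }
  (H + t(H)) / 2
}

fd_gradient <- function(f, x, h = 1e-6) {
  n <- length(x)
  g <- numeric(n)
  for (i in seq_len(n)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + hi
    xm <- x; xm[i] <- xm[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

#' Orthonormal basis of rigid-body zero modes at a configuration
#'
#' For cartesian3d models, returns the (at most 6) orthonormalised
#' infinitesimal translations and rotations about the centroid; for other
#' models returns a zero-column matrix.
#'
#' @param model a [potential_model()].
#' @param x configuration at which rotations are linearised.
#' @return matrix with `model$dimension` rows, one column per zero mode.
#' @export
zero_mode_basis <- function(model, x) {
  n <- model$dimension
  if (!model$cartesian3d || model$n_zero_modes == 0L)
    return(matrix(0, n, 0))
  xyz <- matrix(x, ncol = 3, byrow = TRUE)
  ns <- nrow(xyz)
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  cols <- list()
  for (k in 1:3) {
    v <- matrix(0, ns, 3); v[, k] <- 1
    cols[[length(cols) + 1L]] <- as.vector(t(v))
  }
  # infinitesimal rotations: dr_i = e_k x (r_i - centre)
  axes <- diag(3)
  for (k in 1:3) {
    v <- t(apply(rel, 1, function(r) cross3(axes[k, ], r)))
    cols[[length(cols) + 1L]] <- as.vector(t(v))
  }
  B <- do.call(cbind, cols)
  q <- qr(B)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  Q
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project rigid-body zero modes out of a vector
#'
#' @param model a [potential_model()].
#' @param x configuration (defines the rotation generators).
#' @param v vector to project (e.g. a gradient or eigenvector).
#' @return `v` minus its components along the zero-mode basis.
#' @export
project_zero_modes <- function(model, x, v) {
  B <- zero_mode_basis(model, x)
  if (ncol(B) == 0) return(v)
  v - B %*% crossprod(B, v)
}

#' Root-mean-square gradient after zero-mode projection
#' @noRd
gradient_rms <- function(model, x, g = NULL) {
  if (is.null(g)) g <- model_gradient(model, x)
  g <- project_zero_modes(model, x, g)
  sqrt(mean(g^2))
}

# ---------------------------------------------------------------------------
# Built-in analytic benchmark surfaces
# ---------------------------------------------------------------------------

#' Mueller-Brown benchmark surface
#'
#' The standard two-dimensional four-Gaussian surface with constants
#' A = (-200, -100, -170, 15), a = (-1, -1, -6.5, 0.7), b = (0, 0, 11, 0.6),
#' c = (-10, -10, -6.5, 0.7), centres (1,0), (0,0.5), (-0.5,1.5), (-1,1).
#' It has three minima and two first-order saddles and is the classic
#' fixture for stationary-point searches.
#'
#' @return a [potential_model()] of dimension 2.
#' @export
mueller_brown <- function() {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  terms <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
  }
  efn <- function(x) sum(terms(x))
  gfn <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    tt <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    c(sum(tt * (2 * a * dx + b * dy)), sum(tt * (b * dx + 2 * cc * dy)))
  }
  hfn <- function(x) {
    dx <- x[1] - x0; dy <- x[2] - y0
    tt <- A * exp(a * dx^2 + b * dx * dy + cc * dy^2)
    u <- 2 * a * dx + b * dy
    v <- b * dx + 2 * cc * dy
    matrix(c(sum(tt * (u^2 + 2 * a)), sum(tt * (u * v + b)),
             sum(tt * (u * v + b)), sum(tt * (v^2 + 2 * cc))), 2, 2)
  }
  potential_model("mueller-brown", 2L, efn, gfn, hfn,
                  parameters = list(A = A, a = a, b = b, c = cc, x0 = x0, y0 = y0))
}

#' Isotropic quadratic bowl
#'
#' V(x) = k/2 * |x - centre|^2; a single-minimum convex test surface.
#'
#' @param dimension number of coordinates.
#' @param centre minimum location (recycled to `dimension`).
#' @param k force constant.
#' @return a [potential_model()].
#' @export
quadratic_bowl <- function(dimension = 2L, centre = 0, k = 1) {
  ctr <- rep_len(centre, dimension)
  potential_model("quadratic-bowl", dimension,
                  energy_fn = function(x) 0.5 * k * sum((x - ctr)^2),
                  gradient_fn = function(x) k * (x - ctr),
                  hessian_fn = function(x) diag(k, dimension),
                  parameters = list(centre = ctr, k = k))
}

#' One-dimensional double well
#'
#' V(x) = x^4 - x^2, with minima at +/- 1/sqrt(2) (energy -1/4) and a saddle
#' at x = 0 (energy 0).
#'
#' @return a [potential_model()] of dimension 1.
#' @export
double_well_1d <- function() {
  potential_model("double-well-1d", 1L,
                  energy_fn = function(x) x^4 - x^2,
                  gradient_fn = function(x) 4 * x^3 - 2 * x,
                  hessian_fn = function(x) matrix(12 * x^2 - 2, 1, 1))
}

#' Lennard-Jones cluster
#'
#' N identical atoms interacting through the 12-6 Lennard-Jones pair
#' potential V(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6). Coordinates are a
#' flattened N x 3 matrix. The model carries 6 zero modes (overall
#' translation and rotation).
#'
#' @param n_atoms number of atoms (>= 2).
#' @param epsilon pair well depth (energy unit of the model).
#' @param sigma pair length scale.
#' @return a [potential_model()] of dimension `3 * n_atoms`.
#' @export
lj_cluster <- function(n_atoms, epsilon = 1, sigma = 1) {
  stopifnot(n_atoms >= 2)
  pr <- utils::combn(n_atoms, 2)
  i <- pr[1, ]; j <- pr[2, ]
  np <- ncol(pr)
  # pair -> atom incidence matrix so the gradient is a single matrix product
  M <- matrix(0, n_atoms, np)
  M[cbind(i, seq_len(np))] <- 1
  M[cbind(j, seq_len(np))] <- -1
  efn <- function(x) {
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    r2 <- rowSums(d^2)
    s6 <- (sigma^2 / r2)^3
    sum(4 * epsilon * (s6^2 - s6))
  }
  gfn <- function(x) {
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    r2 <- rowSums(d^2)
    s6 <- (sigma^2 / r2)^3
    # dV/dr2 = 4 eps (-12 s12 + 6 s6) / (2 r2)
    coef <- 4 * epsilon * (-12 * s6^2 + 6 * s6) / (2 * r2)
    g <- M %*% (d * (2 * coef))
    as.vector(t(g))
  }
  vfn <- function(x) {
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    d <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    if (min(rowSums(d^2)) < (0.05 * sigma)^2) "coincident beads" else TRUE
  }
  potential_model(sprintf("lj%d", n_atoms), 3L * n_atoms, efn, gfn,
                  n_zero_modes = 6L, validate_fn = vfn,
                  parameters = list(n_atoms = n_atoms, epsilon = epsilon, sigma = sigma),
                  cartesian3d = TRUE, identical_beads = TRUE)
}

#' Wrap external energy/gradient callbacks as a potential model
#'
#' Adapter for plugging external engines (for instance an all-atom force
#' field with a Generalised Born solvent term) into the landscape machinery.
#' Everything downstream only sees the `potential_model` contract.
#'
#' @param energy_fn function(x) returning a scalar energy in kcal/mol.
#' @param gradient_fn optional function(x); when `NULL` a centred
#'   finite-difference gradient of `energy_fn` is used.
#' @param dimension coordinate count the callbacks accept.
#' @param name identifier for provenance logs.
#' @param n_zero_modes,cartesian3d,validate_fn passed to [potential_model()].
#' @return a [potential_model()]. Callback errors are re-signalled as
#'   potential-evaluation errors carrying the offending configuration.
#' @export
external_adapter <- function(energy_fn, gradient_fn = NULL, dimension,
                             name = "external", n_zero_modes = 0L,
                             cartesian3d = FALSE, validate_fn = NULL) {
  wrap <- function(f, what) {
    if (is.null(f)) return(NULL)
    function(x) {
      tryCatch(f(x), error = function(e)
        stop(potential_eval_error(
          sprintf("external %s callback failed: %s", what, conditionMessage(e)), x)))
    }
  }
  potential_model(name, dimension, wrap(energy_fn, "energy"),
                  wrap(gradient_fn, "gradient"),
                  n_zero_modes = n_zero_modes, cartesian3d = cartesian3d,
                  validate_fn = validate_fn)
}
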