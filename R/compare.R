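#' Draw a reproducible sample of minima from a KTN
#'
#' Uniform or energy-stratified (tertile-balanced) sampling of minimum ids,
#' reproducible from the seed.
#'
#' @param ktn a [ktn_new()] database.
#' @param n sample size (<= number of minima).
#' @param rng_seed integer seed.
#' @param stratify_by_energy when `TRUE`, the energy range is split into
#'   three equal-count tertiles and `n` is divided as evenly as possible
#'   among them.
#' @return integer vector of minimum ids.
#' @export
sample_minima <- function(ktn, n, rng_seed = 1L, stratify_by_energy = FALSE) {
  nm <- length(ktn$minima)
  if (n > nm) stop("sample size exceeds the number of minima")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(rng_seed)
  if (!stratify_by_energy) return(sort(sample.int(nm, n)))
  e <- ktn_min_energies(ktn)
  tert <- cut(rank(e, ties.method = "first"), breaks = 3, labels = FALSE)
  per <- rep(n %/% 3, 3)
  extra <- n %% 3
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  ids <- integer()
  for (t in 1:3) {
    pool <- which(tert == t)
    take <- min(per[t], length(pool))
    ids <- c(ids, if (take > 0) pool[sample.int(length(pool), take)] else integer())
  }
  sort(ids)
}

#' Re-score sampled minima under another potential model
#'
#' Single-point energies of the stored geometries under `model_b` (the
#' default, so the two models are compared on identical configurations), or
#' energies after local re-minimisation under `model_b` when `reminimise` is
#' set. Members whose evaluation fails are flagged, excluded and reported
#' via the `failed` attribute.
#'
#' @param sample integer vector of minimum ids.
#' @param ktn the source database.
#' @param model_b a [potential_model()] accepting the stored coordinates.
#' @param reminimise logical.
#' @param tol minimisation tolerance when `reminimise = TRUE`.
#' @return named numeric vector of energies (names = minimum ids), with
#'   attribute `failed` listing excluded ids.
#' @export
rescore <- function(sample, ktn, model_b, reminimise = FALSE, tol = 1e-6) {
  out <- numeric(0); failed <- integer(0)
  for (id in sample) {
    x <- ktn$minima[[id]]$coordinates
    e <- tryCatch({
      if (reminimise) local_minimise(model_b, x, tol = tol)$energy
      else model_energy(model_b, x)
    }, error = function(err) NA_real_)
    if (is.na(e)) failed <- c(failed, id)
    else out[as.character(id)] <- e
  }
  if (length(failed))
    warning(sprintf("%d sample member(s) could not be evaluated and were excluded: %s",
                    length(failed), paste(failed, collapse = ", ")))
  attr(out, "failed") <- failed
  out
}

#' Rank correlation between two energy orderings
#'
#' Tie-corrected Kendall tau (tau-b) and Spearman rho between two energy
#' vectors over the same sample, plus the explicit list of discordant pairs
#' (pairs ordered one way by the first model and the other way by the
#' second).
#'
#' @param energies_a,energies_b numeric vectors of equal length >= 2.
#' @param ids optional identifiers for reporting (default positions).
#' @return object of class `rank_comparison`: `kendall_tau`, `spearman_rho`,
#'   `n_discordant_pairs`, `discordant_pairs` (two-column matrix of ids),
#'   `n`.
#' @export
rank_correlation <- function(energies_a, energies_b, ids = NULL) {
  stopifnot(length(energies_a) == length(energies_b), length(energies_a) >= 2)
  n <- length(energies_a)
  ids <- ids %||% seq_len(n)
  if (stats::var(energies_a) == 0 || stats::var(energies_b) == 0)
    stop(structure(class = c("pelkit_undefined_correlation", "error", "condition"),
                   list(message = "constant energy vector: rank correlation undefined",
                        call = NULL)))
  rho <- stats::cor(energies_a, energies_b, method = "spearman")
  # tau-b by explicit pair counting: exact (+/-1 really means identical or
  # exactly reversed orderings) and it hands back the discordant pairs
  C <- 0L; D <- 0L; Ta <- 0L; Tb <- 0L
  disc <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- sign(energies_a[i] - energies_a[j])
    sb <- sign(energies_b[i] - energies_b[j])
    if (sa == 0 && sb == 0) next
    if (sa == 0) Ta <- Ta + 1L
    else if (sb == 0) Tb <- Tb + 1L
    else if (sa * sb > 0) C <- C + 1L
    else { D <- D + 1L; disc[[length(disc) + 1L]] <- c(ids[i], ids[j]) }
  }
  tau <- (C - D) / sqrt(as.numeric(C + D + Ta) * as.numeric(C + D + Tb))
  disc <- if (length(disc)) do.call(rbind, disc) else matrix(integer(), 0, 2)
  structure(list(kendall_tau = tau, spearman_rho = rho,
                 n_discordant_pairs = nrow(disc), discordant_pairs = disc,
                 n = n, energies_a = energies_a, energies_b = energies_b,
                 ids = ids),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("<rank_comparison over %d minima: Kendall tau = %.4f, Spearman rho = %.4f, %d discordant pair(s)>\n",
              x$n, x$kendall_tau, x$spearman_rho, x$n_discordant_pairs))
  invisible(x)
}
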