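#' Write a KTN to a plain-text file set
#'
#' The persistent stationary-point database layout: a directory holding
#' `manifest.yaml` (format version, units, model spec, matching tolerances,
#' provenance), `minima.tsv` and `ts.tsv` (one record per stationary point
#' with energies as shortest round-trip decimals), and `coords.txt` (one
#' whitespace-separated coordinate block per line; the tables reference
#' blocks by line offset). Energies and coordinates round-trip bit-exactly.
#'
#' @param ktn a [ktn_new()] database.
#' @param dir target directory (created; refuses to clobber an existing
#'   non-KTN directory).
#' @param model_spec optional list describing how to rebuild the model
#'   (e.g. `list(kind = "toy-rna", sequence = ..., parameter_set = "cgA")`),
#'   stored in the manifest for the command-line drivers.
#' @return `dir`, invisibly.
#' @export
write_ktn <- function(ktn, dir, model_spec = NULL) {
  if (dir.exists(dir) && length(list.files(dir)) &&
      !file.exists(file.path(dir, "manifest.yaml")))
    stop("refusing to write a KTN into a non-empty, non-KTN directory: ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) sprintf("%.17g", x)
  coords <- character()
  mrows <- character()
  for (m in ktn$minima) {
    coords <- c(coords, paste(fmt(m$coordinates), collapse = " "))
    mrows <- c(mrows, paste(m$id, fmt(m$energy), fmt(m$gradient_rms),
                            m$discovery_count, length(coords), sep = "\t"))
  }
  trows <- character()
  for (t in ktn$ts) {
    coords <- c(coords, paste(fmt(t$coordinates), collapse = " "))
    trows <- c(trows, paste(t$id, fmt(t$energy), fmt(t$lowest_eigenvalue),
                            t$minus_id, t$plus_id, length(coords), sep = "\t"))
  }
  writeLines(c("id\tenergy\tgradient_rms\tdiscovery_count\tcoord_offset", mrows),
             file.path(dir, "minima.tsv"))
  writeLines(c("id\tenergy\tlowest_eigenvalue\tminus_id\tplus_id\tcoord_offset", trows),
             file.path(dir, "ts.tsv"))
  writeLines(coords, file.path(dir, "coords.txt"))
  manifest <- list(format = "pelkit-ktn-v1",
                   units = ktn$units,
                   model = ktn$model_name,
                   cartesian3d = ktn$cartesian3d,
                   criteria = unclass(ktn$criteria),
                   n_minima = length(ktn$minima),
                   n_ts = length(ktn$ts),
                   provenance = ktn$provenance,
                   model_spec = model_spec)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"), precision = 17)
  invisible(dir)
}

#' Read a KTN file set written by [write_ktn()]
#'
#' @param dir KTN directory.
#' @return a [ktn_new()] database; the manifest's `model_spec` (if any) is
#'   attached as field `model_spec`.
#' @export
read_ktn <- function(dir) {
  mf_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf_path)) stop("not a KTN file set (no manifest.yaml): ", dir)
  mf <- yaml::read_yaml(mf_path)
  if (!identical(mf$format, "pelkit-ktn-v1"))
    stop("unsupported KTN format version: ", mf$format %||% "<missing>")
  crit <- match_criteria(energy_tol = mf$criteria$energy_tol,
                         distance_tol = mf$criteria$distance_tol,
                         permutations = isTRUE(mf$criteria$permutations))
  k <- ktn_new(mf$model, units = mf$units, cartesian3d = isTRUE(mf$cartesian3d),
               criteria = crit)
  k$provenance <- mf$provenance
  k$model_spec <- mf$model_spec
  coords <- readLines(file.path(dir, "coords.txt"))
  getc <- function(off) as.numeric(strsplit(coords[off], " +")[[1]])
  mt <- utils::read.delim(file.path(dir, "minima.tsv"), colClasses = "character")
  for (r in seq_len(nrow(mt))) {
    m <- new_minimum(as.numeric(mt$energy[r]), getc(as.integer(mt$coord_offset[r])),
                     as.numeric(mt$gradient_rms[r]),
                     id = as.integer(mt$id[r]),
                     discovery_count = as.integer(mt$discovery_count[r]))
    k$minima[[m$id]] <- m
  }
  tt <- utils::read.delim(file.path(dir, "ts.tsv"), colClasses = "character")
  for (r in seq_len(nrow(tt))) {
    t <- new_transition_state(as.numeric(tt$energy[r]),
                              getc(as.integer(tt$coord_offset[r])),
                              as.numeric(tt$lowest_eigenvalue[r]),
                              minus_id = as.integer(tt$minus_id[r]),
                              plus_id = as.integer(tt$plus_id[r]),
                              id = as.integer(tt$id[r]))
    k$ts[[t$id]] <- t
  }
  k
}

#' Rebuild a potential model from a KTN manifest model spec
#'
#' @param spec list with `kind` (`"mueller-brown"`, `"quadratic-bowl"`,
#'   `"lj-cluster"` or `"toy-rna"`) and kind-specific fields.
#' @return list with `model` and (for chains) `topology`.
#' @export
model_from_spec <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  switch(spec$kind,
         "mueller-brown" = list(model = mueller_brown(), topology = NULL),
         "quadratic-bowl" = list(model = quadratic_bowl(spec$dimension %||% 2L),
                                 topology = NULL),
         "lj-cluster" = list(model = lj_cluster(spec$n_atoms %||% 7L,
                                                epsilon = spec$epsilon %||% 1,
                                                sigma = spec$sigma %||% 1),
                             topology = NULL),
         "toy-rna" = {
           tr <- make_toy_rna(spec$sequence,
                              spec$parameter_set %||% "cgA",
                              native_pairs = if (!is.null(spec$native_pairs))
                                matrix(unlist(spec$native_pairs), ncol = 2, byrow = TRUE))
           list(model = tr$model, topology = tr$topology)
         },
         stop("unknown model kind: ", spec$kind))
}
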