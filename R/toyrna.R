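#' Shipped coarse-grained RNA parameter sets
#'
#' The chain model uses three beads per nucleotide — phosphate (P), sugar
#' (S) and base (R for purines A/G, Y for pyrimidines C/U) — with harmonic
#' bonds and angles, sinusoidal torsion terms, a Lennard-Jones nonbonded
#' term, and Debye-Hueckel screened-Coulomb electrostatics standing in for
#' an implicit solvent. Two parameter sets are shipped that share every
#' bonded equilibrium and nonbonded radius but differ in their torsion
#' terms, mirroring how RNA force-field variants mostly reparameterise the
#' dihedral potentials:
#'
#' * `"cgA"` — threefold backbone torsions, twofold glycosidic-like terms;
#' * `"cgB"` — lower-periodicity, phase-shifted, stronger torsions.
#'
#' @return character vector of registered parameter-set ids.
#' @export
rna_parameter_sets <- function() names(.pelkit_parameter_sets)

.pelkit_parameter_sets <- local({
  # reduced phosphate charge (counterion condensation) and a short Debye
  # length (high ionic strength) so that compact folds are reachable at
  # desk-scale sampling; pairing attraction as a deep purine-pyrimidine
  # cross-class Lennard-Jones well standing in for base-pair hydrogen bonds
  base_beads <- list(
    P = list(epsilon = 0.20, sigma = 4.0, charge = -0.5),
    S = list(epsilon = 0.25, sigma = 4.2, charge = 0.0),
    R = list(epsilon = 0.30, sigma = 4.6, charge = 0.1),
    Y = list(epsilon = 0.30, sigma = 4.2, charge = 0.1))
  base_bonds <- list(
    PS = list(k = 20, r0 = 4.0),
    SB = list(k = 20, r0 = 3.5),
    SP = list(k = 20, r0 = 3.8))
  base_angles <- list(
    PSB = list(k = 5, theta0 = 110),
    PSP = list(k = 5, theta0 = 95),
    SPS = list(k = 5, theta0 = 105),
    BSP = list(k = 5, theta0 = 110))
  base_nonbonded <- list(pair_epsilon_RY = 3.0, screening_length = 3.0,
                         coulomb_constant = 332.0637)
  list(
    cgA = list(
      id = "cgA", beads = base_beads, bonds = base_bonds, angles = base_angles,
      torsions = list(
        PSPS = list(list(amplitude = 1.5, periodicity = 3L, phase = 0.0)),
        SPSP = list(list(amplitude = 1.2, periodicity = 3L, phase = pi)),
        BSPS = list(list(amplitude = 0.8, periodicity = 2L, phase = 0.0)),
        SPSB = list(list(amplitude = 0.8, periodicity = 2L, phase = 0.0))),
      nonbonded = base_nonbonded),
    cgB = list(
      id = "cgB", beads = base_beads, bonds = base_bonds, angles = base_angles,
      torsions = list(
        PSPS = list(list(amplitude = 2.5, periodicity = 2L, phase = pi / 2),
                    list(amplitude = 0.8, periodicity = 1L, phase = 0.0)),
        SPSP = list(list(amplitude = 2.0, periodicity = 1L, phase = 0.0)),
        BSPS = list(list(amplitude = 1.5, periodicity = 3L, phase = pi)),
        SPSB = list(list(amplitude = 1.5, periodicity = 3L, phase = pi))),
      nonbonded = base_nonbonded))
})

#' Fetch a registered coarse-grained RNA parameter set
#'
#' @param id parameter-set id (see [rna_parameter_sets()]), or a parameter
#'   set list previously read with [read_parameter_set()].
#' @return the parameter-set list (sections `beads`, `bonds`, `angles`,
#'   `torsions`, `nonbonded`).
#' @export
rna_parameter_set <- function(id) {
  if (is.list(id)) return(validate_parameter_set(id))
  ps <- .pelkit_parameter_sets[[id]]
  if (is.null(ps)) stop("unknown parameter set: ", id)
  ps
}

validate_parameter_set <- function(ps) {
  stopifnot(is.list(ps$beads), is.list(ps$torsions), is.list(ps$nonbonded))
  for (tc in ps$torsions) for (term in tc) {
    if (term$periodicity < 1 || term$periodicity != round(term$periodicity))
      stop("torsion periodicities must be positive integers")
  }
  for (b in ps$beads) if (b$sigma <= 0) stop("LJ radii must be positive")
  ps
}

#' Write / read a parameter set as a key-value config file
#'
#' The file is YAML with the five documented sections (`beads`, `bonds`,
#' `angles`, `torsions`, `nonbonded`); energies kcal/mol, lengths Angstrom,
#' angles degrees, torsion phases radians. Round-trips losslessly.
#'
#' @param ps a parameter set (see [rna_parameter_set()]).
#' @param path file path.
#' @return `read_parameter_set` returns the parameter-set list.
#' @export
write_parameter_set <- function(ps, path) {
  yaml::write_yaml(c(list(format = "pelkit-parameter-set-v1",
                          units = "kcal/mol, Angstrom, degrees (angles), radians (phases)"),
                     ps[c("id", "beads", "bonds", "angles", "torsions", "nonbonded")]),
                   path, precision = 17)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!identical(raw$format, "pelkit-parameter-set-v1"))
    stop("not a pelkit parameter-set file: ", path)
  ps <- raw[c("id", "beads", "bonds", "angles", "torsions", "nonbonded")]
  ps$torsions <- lapply(ps$torsions, function(tc)
    lapply(tc, function(term) {
      term$periodicity <- as.integer(term$periodicity); term
    }))
  validate_parameter_set(ps)
}

#' Build the coarse-grained RNA chain model for a sequence
#'
#' Three beads per nucleotide (phosphate, sugar, base). Bonds join P-S and
#' S-B within a nucleotide and S-P between consecutive nucleotides; angles
#' cover every bonded triple and torsions every connected 4-path along the
#' bond graph, classed by their bead-type pattern. Nonbonded terms (LJ plus
#' screened Coulomb) act between all bead pairs except bonded 1-2 and 1-3
#' neighbours.
#'
#' @param sequence string over A, C, G, U.
#' @param parameter_set a parameter-set id (e.g. `"cgA"`) or list.
#' @param native_pairs optional integer matrix/2-column data of nucleotide
#'   index pairs regarded as native contacts (order-parameter bookkeeping;
#'   does not change the energy).
#' @return list with `model` (a [potential_model()]) and `topology` (a
#'   `chain_topology` list: beads, bonds, angles, torsions, native_pairs).
#' @export
make_toy_rna <- function(sequence, parameter_set = "cgA", native_pairs = NULL) {
  ps <- rna_parameter_set(parameter_set)
  nts <- strsplit(toupper(sequence), "")[[1]]
  if (!length(nts)) stop("empty sequence")
  bad <- setdiff(unique(nts), c("A", "C", "G", "U"))
  if (length(bad)) stop("unknown nucleotide letter(s): ", paste(bad, collapse = ", "))
  n <- length(nts)
  base_class <- ifelse(nts %in% c("A", "G"), "R", "Y")
  # bead order per nucleotide: P, S, B
  bead_type <- character(3 * n)
  bead_nt <- integer(3 * n)
  for (i in seq_len(n)) {
    bead_type[3 * i - 2] <- "P"
    bead_type[3 * i - 1] <- "S"
    bead_type[3 * i] <- base_class[i]
    bead_nt[3 * (i - 1) + 1:3] <- i
  }
  P <- function(i) 3L * i - 2L; S <- function(i) 3L * i - 1L; B <- function(i) 3L * i

  bonds <- list()
  for (i in seq_len(n)) {
    bonds[[length(bonds) + 1L]] <- c(P(i), S(i))
    bonds[[length(bonds) + 1L]] <- c(S(i), B(i))
    if (i < n) bonds[[length(bonds) + 1L]] <- c(S(i), P(i + 1L))
  }
  bonds <- do.call(rbind, bonds)
  bond_class <- apply(bonds, 1, function(b) {
    t1 <- sub("[RY]", "B", bead_type[b[1]]); t2 <- sub("[RY]", "B", bead_type[b[2]])
    paste0(t1, t2)
  })
  bond_class[bond_class == "BS"] <- "SB"  # orientation-free

  adj <- vector("list", 3L * n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds[k, 1]]] <- c(adj[[bonds[k, 1]]], bonds[k, 2])
    adj[[bonds[k, 2]]] <- c(adj[[bonds[k, 2]]], bonds[k, 1])
  }
  angles <- list()
  for (j in seq_len(3L * n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      for (c_ in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- c(cmb[1, c_], j, cmb[2, c_])
    }
  }
  angles <- do.call(rbind, angles)
  simple_type <- function(i) sub("[RY]", "B", bead_type[i])
  angle_class <- apply(angles, 1, function(a) {
    cls <- paste0(simple_type(a[1]), simple_type(a[2]), simple_type(a[3]))
    rev_cls <- paste0(simple_type(a[3]), simple_type(a[2]), simple_type(a[1]))
    if (cls %in% names(rna_parameter_set("cgA")$angles)) cls else rev_cls
  })

  torsions <- list(); torsion_class <- character()
  for (k in seq_len(nrow(bonds))) {
    jb <- bonds[k, 1]; kb <- bonds[k, 2]
    for (ib in setdiff(adj[[jb]], kb)) for (lb in setdiff(adj[[kb]], jb)) {
      if (ib == lb) next
      quad <- c(ib, jb, kb, lb)
      cls <- paste0(simple_type(ib), simple_type(jb), simple_type(kb), simple_type(lb))
      rcls <- paste(rev(strsplit(cls, "")[[1]]), collapse = "")
      use <- if (cls %in% names(ps$torsions)) cls
             else if (rcls %in% names(ps$torsions)) { quad <- rev(quad); rcls }
             else NA_character_
      if (is.na(use)) next
      # keep each physical torsion once (canonical orientation)
      key <- paste(quad, collapse = "-")
      rkey <- paste(rev(quad), collapse = "-")
      if (any(vapply(torsions, function(q) paste(q, collapse = "-") %in% c(key, rkey), logical(1))))
        next
      torsions[[length(torsions) + 1L]] <- quad
      torsion_class <- c(torsion_class, use)
    }
  }
  torsions <- if (length(torsions)) do.call(rbind, torsions) else matrix(integer(), 0, 4)

  if (!is.null(native_pairs)) {
    native_pairs <- matrix(as.integer(as.matrix(native_pairs)), ncol = 2)
    stopifnot(all(native_pairs >= 1), all(native_pairs <= n))
  }
  topology <- structure(list(
    sequence = paste(nts, collapse = ""), n_nucleotides = n,
    beads_per_nucleotide = 3L,
    beads = data.frame(index = seq_len(3L * n), nucleotide = bead_nt,
                       type = bead_type, stringsAsFactors = FALSE),
    bonds = bonds, bond_class = bond_class,
    angles = angles, angle_class = angle_class,
    torsions = torsions, torsion_class = torsion_class,
    native_pairs = native_pairs), class = "chain_topology")

  model <- chain_model(topology, ps)
  list(model = model, topology = topology)
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("<chain_topology: %s (%d nt, %d beads, %d bonds, %d angles, %d torsions)>\n",
              x$sequence, x$n_nucleotides, nrow(x$beads), nrow(x$bonds),
              nrow(x$angles), nrow(x$torsions)))
  invisible(x)
}

# assemble the potential_model for a topology + parameter set
chain_model <- function(topology, ps) {
  nb <- nrow(topology$beads)
  tp <- topology$beads$type
  # bonded tables
  b_i <- topology$bonds[, 1]; b_j <- topology$bonds[, 2]
  b_k <- vapply(topology$bond_class, function(cl) ps$bonds[[cl]]$k, numeric(1))
  b_r0 <- vapply(topology$bond_class, function(cl) ps$bonds[[cl]]$r0, numeric(1))
  a_i <- topology$angles[, 1]; a_j <- topology$angles[, 2]; a_k <- topology$angles[, 3]
  a_kf <- vapply(topology$angle_class, function(cl) ps$angles[[cl]]$k, numeric(1))
  a_t0 <- vapply(topology$angle_class, function(cl) ps$angles[[cl]]$theta0, numeric(1)) * pi / 180
  has_tors <- nrow(topology$torsions) > 0
  if (has_tors) {
    t_idx <- topology$torsions
    # expand (torsion, term) pairs into flat vectors for vectorised evaluation
    t_terms <- lapply(topology$torsion_class, function(cl) ps$torsions[[cl]])
    t_of <- rep(seq_along(t_terms), vapply(t_terms, length, integer(1)))
    flat <- unlist(t_terms, recursive = FALSE)
    t_amp <- vapply(flat, function(z) z$amplitude, numeric(1))
    t_per <- vapply(flat, function(z) as.numeric(z$periodicity), numeric(1))
    t_pha <- vapply(flat, function(z) z$phase, numeric(1))
  }
  # nonbonded pair list excluding 1-2 and 1-3
  excl <- new.env(parent = emptyenv())
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  for (k in seq_len(nrow(topology$bonds))) mark(b_i[k], b_j[k])
  for (k in seq_len(nrow(topology$angles))) mark(a_i[k], a_k[k])
  pr <- utils::combn(nb, 2)
  keep <- !vapply(seq_len(ncol(pr)), function(c_)
    exists(paste(pr[1, c_], pr[2, c_]), envir = excl), logical(1))
  nb_i <- pr[1, keep]; nb_j <- pr[2, keep]
  eps_class <- vapply(ps$beads, function(b) b$epsilon, numeric(1))
  sig_class <- vapply(ps$beads, function(b) b$sigma, numeric(1))
  q_class <- vapply(ps$beads, function(b) b$charge, numeric(1))
  ei <- eps_class[tp[nb_i]]; ej <- eps_class[tp[nb_j]]
  nb_eps <- sqrt(ei * ej)
  ry <- (tp[nb_i] == "R" & tp[nb_j] == "Y") | (tp[nb_i] == "Y" & tp[nb_j] == "R")
  nb_eps[ry] <- ps$nonbonded$pair_epsilon_RY
  nb_sig <- (sig_class[tp[nb_i]] + sig_class[tp[nb_j]]) / 2
  nb_qq <- q_class[tp[nb_i]] * q_class[tp[nb_j]] * ps$nonbonded$coulomb_constant
  lambda <- ps$nonbonded$screening_length
  np <- length(nb_i)
  Mnb <- NULL
  if (np > 0) {
    Mnb <- matrix(0, nb, np)
    Mnb[cbind(nb_i, seq_len(np))] <- 1
    Mnb[cbind(nb_j, seq_len(np))] <- -1
  }
  Mb <- matrix(0, nb, length(b_i))
  Mb[cbind(b_i, seq_along(b_i))] <- 1
  Mb[cbind(b_j, seq_along(b_i))] <- -1

  eval_all <- function(x, want_grad) {
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    e <- 0
    g <- if (want_grad) matrix(0, nb, 3) else NULL
    # bonds
    d <- xyz[b_i, , drop = FALSE] - xyz[b_j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    e <- e + sum(b_k * (r - b_r0)^2)
    if (want_grad) {
      coef <- 2 * b_k * (r - b_r0) / r
      g <- g + Mb %*% (d * coef)
    }
    # angles
    u <- xyz[a_i, , drop = FALSE] - xyz[a_j, , drop = FALSE]
    v <- xyz[a_k, , drop = FALSE] - xyz[a_j, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ct <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(u * v) / (nu * nv)))
    th <- acos(ct)
    e <- e + sum(a_kf * (th - a_t0)^2)
    if (want_grad) {
      st <- sqrt(1 - ct^2)
      pref <- -2 * a_kf * (th - a_t0) / pmax(st, 1e-8)
      dci <- v / (nu * nv) - ct * u / nu^2
      dck <- u / (nu * nv) - ct * v / nv^2
      gi <- dci * pref; gk <- dck * pref
      for (col in 1:3) {
        vals <- c(gi[, col], gk[, col], -gi[, col] - gk[, col])
        s <- rowsum(vals, c(a_i, a_k, a_j))
        g[as.integer(rownames(s)), col] <- g[as.integer(rownames(s)), col] + s[, 1]
      }
    }
    # torsions
    if (has_tors) {
      ai <- t_idx[, 1]; bi <- t_idx[, 2]; ci <- t_idx[, 3]; di <- t_idx[, 4]
      b1 <- xyz[bi, , drop = FALSE] - xyz[ai, , drop = FALSE]
      b2 <- xyz[ci, , drop = FALSE] - xyz[bi, , drop = FALSE]
      b3 <- xyz[di, , drop = FALSE] - xyz[ci, , drop = FALSE]
      n1 <- rowcross(b1, b2); n2 <- rowcross(b2, b3)
      nb2 <- sqrt(rowSums(b2^2))
      m1 <- rowcross(n1, b2 / nb2)
      xphi <- rowSums(n1 * n2)
      yphi <- rowSums(m1 * n2)
      phi <- atan2(yphi, xphi)
      arg <- t_per * phi[t_of] - t_pha
      e <- e + sum(t_amp * (1 + cos(arg)))
      dEdphi <- numeric(length(phi))
      dcontrib <- rowsum(-t_amp * t_per * sin(arg), t_of)
      dEdphi[as.integer(rownames(dcontrib))] <- dcontrib[, 1]
      if (want_grad) {
        n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
        ta <- n1 * (nb2 / n1sq)
        td <- -n2 * (nb2 / n2sq)
        f1 <- rowSums(b1 * b2) / nb2^2
        f2 <- rowSums(b3 * b2) / nb2^2
        tb <- (-1 - f1) * ta + f2 * td
        tc <- f1 * ta + (-1 - f2) * td
        for (col in 1:3) {
          vals <- c(ta[, col], tb[, col], tc[, col], td[, col]) * rep(dEdphi, 4)
          idxs <- c(ai, bi, ci, di)
          s <- rowsum(vals, idxs)
          g[as.integer(rownames(s)), col] <- g[as.integer(rownames(s)), col] + s[, 1]
        }
      }
    }
    # nonbonded
    if (np > 0) {
      d <- xyz[nb_i, , drop = FALSE] - xyz[nb_j, , drop = FALSE]
      r2 <- rowSums(d^2)
      r <- sqrt(r2)
      s6 <- (nb_sig^2 / r2)^3
      e_lj <- 4 * nb_eps * (s6^2 - s6)
      scr <- exp(-r / lambda)
      e_c <- nb_qq * scr / r
      e <- e + sum(e_lj) + sum(e_c)
      if (want_grad) {
        dlj_dr2 <- 4 * nb_eps * (-12 * s6^2 + 6 * s6) / (2 * r2)
        dc_dr <- nb_qq * scr * (-1 / (lambda * r) - 1 / r2)
        coef <- 2 * dlj_dr2 + dc_dr / r
        g <- g + Mnb %*% (d * coef)
      }
    }
    list(e = e, g = if (want_grad) as.vector(t(g)) else NULL)
  }

  vfn <- function(x) {
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    if (min(stats::dist(xyz)) < 0.3) "coincident beads" else TRUE
  }
  potential_model(
    name = sprintf("toy-rna[%s|%s]", topology$sequence, ps$id %||% "custom"),
    dimension = 3L * nb,
    energy_fn = function(x) eval_all(x, FALSE)$e,
    gradient_fn = function(x) eval_all(x, TRUE)$g,
    n_zero_modes = 6L, validate_fn = vfn,
    parameters = list(parameter_set = ps, sigma = min(sig_class)),
    cartesian3d = TRUE)
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Deterministic extended-chain starting configuration
#'
#' Zig-zag placement satisfying the bonded equilibria approximately; the
#' canonical starting point for basin-hopping runs on the chain model.
#'
#' @param topology a `chain_topology` from [make_toy_rna()].
#' @return numeric configuration vector (flattened beads x 3).
#' @export
toy_rna_extended <- function(topology) {
  n <- topology$n_nucleotides
  a <- 3.38
  xyz <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    x0 <- a * (i - 1)
    xyz[3 * i - 2, ] <- c(x0, 0, 0)
    xyz[3 * i - 1, ] <- c(x0 + 1.9, 3.5, 0.1 * (-1)^i)
    xyz[3 * i, ] <- c(x0 + 1.9, 7.0, 0.2 * (-1)^i)
  }
  as.vector(t(xyz))
}

#' Native-contact order parameter for chain minima
#'
#' Returns a function mapping a minimum to the fraction of the topology's
#' native pairs whose base beads lie within `cutoff` of each other; 1 is
#' fully folded, 0 fully unfolded.
#'
#' @param topology a `chain_topology` with a `native_pairs` table.
#' @param cutoff contact distance (Angstrom) between base beads.
#' @return function(minimum or coordinate vector) -> value in `[0, 1]`.
#' @export
native_contact_fraction <- function(topology, cutoff = 6.5) {
  np <- topology$native_pairs
  if (is.null(np) || !nrow(np)) stop("topology has no native pairs")
  function(m) {
    x <- if (inherits(m, "minimum")) m$coordinates else m
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    bi <- 3L * np[, 1]; bj <- 3L * np[, 2]
    d <- sqrt(rowSums((xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE])^2))
    mean(d <= cutoff)
  }
}

#' Base-base contacts of a chain configuration
#'
#' Residue pairs (separated by at least `min_sep` in sequence) whose base
#' beads lie within `cutoff` of each other.
#'
#' @param topology a `chain_topology`.
#' @param x configuration vector.
#' @param cutoff contact distance (Angstrom).
#' @param min_sep minimum sequence separation.
#' @return two-column integer matrix of nucleotide index pairs.
#' @export
base_contacts <- function(topology, x, cutoff = 6.5, min_sep = 3L) {
  n <- topology$n_nucleotides
  xyz <- matrix(x, ncol = 3, byrow = TRUE)
  out <- list()
  for (i in seq_len(max(0, n - min_sep))) for (j in (i + min_sep):n) {
    d <- sqrt(sum((xyz[3 * i, ] - xyz[3 * j, ])^2))
    if (d <= cutoff) out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) matrix(integer(), 0, 2) else do.call(rbind, out)
}

#' Adopt a reference structure's contacts as the native-pair list
#'
#' The chain model has no experimentally defined fold, so — as in Go-type
#' models — the native state is defined structurally: the base-base contact
#' map of a reference configuration (typically the global minimum of the
#' reference parameter set).
#'
#' @param topology a `chain_topology`.
#' @param reference a `minimum` or configuration vector.
#' @param cutoff,min_sep passed to [base_contacts()].
#' @return the topology with `native_pairs` set.
#' @export
set_native_from_reference <- function(topology, reference, cutoff = 6.5, min_sep = 3L) {
  x <- if (inherits(reference, "minimum")) reference$coordinates else reference
  topology$native_pairs <- base_contacts(topology, x, cutoff, min_sep)
  topology
}

#' Variant of a parameter set with a perturbed screening length
#'
#' The in-toolkit analogue of swapping the implicit-solvent model while
#' keeping the force field: only the Debye-Hueckel screening length changes.
#'
#' @param ps parameter set (id or list).
#' @param factor multiplicative perturbation (e.g. 1.1 for +10 percent).
#' @return the perturbed parameter-set list (id suffixed with the factor).
#' @export
perturb_screening_length <- function(ps, factor = 1.1) {
  ps <- rna_parameter_set(ps)
  ps$nonbonded$screening_length <- ps$nonbonded$screening_length * factor
  ps$id <- sprintf("%s-screen%.3g", ps$id, factor)
  ps
}
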