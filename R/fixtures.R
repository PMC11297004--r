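#' Idealised planar base geometry (synthetic)
#'
#' Constructs an idealised, strictly planar heavy-atom geometry for one RNA
#' base in a local frame (z = 0): a regular hexagon of side 1.39 A for the
#' pyrimidine ring, a fused regular pentagon for purines, exocyclic N/O
#' substituents placed radially (C-N 1.34 A, C=O 1.23 A) and the C1'
#' glycosidic attachment on N1/N9 (1.47 A). These synthetic geometries are
#' internally consistent stand-ins for library base templates, good enough
#' for pairing/stacking annotation; they are not crystallographic averages.
#'
#' @param base one of "A", "C", "G", "U".
#' @return matrix of atom coordinates (rows named by atom).
#' @export
ideal_base <- function(base) {
  side <- 1.39
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ang <- (90 - 60 * (0:5)) * pi / 180
  hex <- cbind(side * cos(ang), side * sin(ang), 0)
  rownames(hex) <- hex_names
  radial <- function(ctr, at, len) at + (at - ctr) / sqrt(sum((at - ctr)^2)) * len
  hex_ctr <- c(0, 0, 0)
  if (base %in% c("C", "U")) {
    atoms <- hex
    atoms <- rbind(atoms, O2 = radial(hex_ctr, hex["C2", ], 1.23))
    if (base == "C") atoms <- rbind(atoms, N4 = radial(hex_ctr, hex["C4", ], 1.34))
    else atoms <- rbind(atoms, O4 = radial(hex_ctr, hex["C4", ], 1.23))
    atoms <- rbind(atoms, "C1'" = radial(hex_ctr, hex["N1", ], 1.47))
    return(atoms)
  }
  # purine: fuse a regular pentagon on the C4-C5 edge, outside the hexagon
  p1 <- hex["C4", 1:2]; p2 <- hex["C5", 1:2]
  e <- p2 - p1; L <- sqrt(sum(e^2))
  mid <- (p1 + p2) / 2
  nrm <- c(e[2], -e[1]) / L
  if (sum((mid + nrm) ^ 2) < sum((mid - nrm)^2)) nrm <- -nrm  # point away from hexagon centre
  # regular pentagon with side L: apothem and circumradius
  Rp <- L / (2 * sin(pi / 5))
  ap <- L / (2 * tan(pi / 5))
  ctr5 <- mid + nrm * ap
  base_ang <- atan2(p1[2] - ctr5[2], p1[1] - ctr5[1])
  # order around: C4, N9, C8, N7, C5 (C4 -> N9 adjacent, C5 -> N7 adjacent)
  sgn <- sign(atan2(p2[2] - ctr5[2], p2[1] - ctr5[1]) - base_ang)
  if (sgn == 0) sgn <- 1
  penta_ang <- base_ang - sgn * 2 * pi / 5 * (1:3)
  penta <- cbind(Rp * cos(penta_ang) + ctr5[1], Rp * sin(penta_ang) + ctr5[2], 0)
  rownames(penta) <- c("N9", "C8", "N7")
  atoms <- rbind(hex, penta)
  if (base == "A") atoms <- rbind(atoms, N6 = radial(hex_ctr, hex["C6", ], 1.34))
  else atoms <- rbind(atoms, O6 = radial(hex_ctr, hex["C6", ], 1.23),
                      N2 = radial(hex_ctr, hex["C2", ], 1.34))
  ctr5_3 <- c(ctr5, 0)
  atoms <- rbind(atoms, "C1'" = radial(ctr5_3, atoms["N9", ], 1.47))
  atoms
}

.pelkit_fixture_cache <- new.env(parent = emptyenv())

# hydrogen-bond atom pairings used to assemble idealised pairs
pair_contact_atoms <- function(kind) {
  switch(kind,
         "GC-WC" = list(bases = c("G", "C"),
                        contacts = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2"))),
         "AU-WC" = list(bases = c("A", "U"),
                        contacts = list(c("N1", "N3"), c("N6", "O4"))),
         "GU-wobble" = list(bases = c("G", "U"),
                            contacts = list(c("O6", "N3"), c("N1", "O2"))),
         "AU-Hoogsteen" = list(bases = c("A", "U"),
                               contacts = list(c("N7", "N3"), c("N6", "O4"))),
         stop("unknown pair kind: ", kind))
}

#' Idealised base-pair geometry (synthetic)
#'
#' Places two [ideal_base()] geometries coplanarly so that the designated
#' hydrogen-bond donor-acceptor atom pairs sit at 2.9 A: the second base is
#' flipped over (rotated 180 degrees about the in-plane x axis, as in an
#' antiparallel pair) and its in-plane rigid placement is then optimised.
#'
#' @param kind one of "GC-WC", "AU-WC", "GU-wobble", "AU-Hoogsteen".
#' @return list of two atom matrices (`first`, `second`) with base letters
#'   as the `bases` attribute.
#' @export
ideal_pair <- function(kind) {
  cached <- .pelkit_fixture_cache[[kind]]
  if (!is.null(cached)) return(cached)
  spec <- pair_contact_atoms(kind)
  a <- ideal_base(spec$bases[1])
  b_plain <- ideal_base(spec$bases[2])
  b_flip <- b_plain; b_flip[, 2] <- -b_flip[, 2]  # flipped over (180 deg about x)
  ia <- match(vapply(spec$contacts, `[`, character(1), 1), rownames(a))
  # pair classes for the soft potential shaping the placement
  polar_a <- rownames(a) %in% base_polar_atoms(spec$bases[1])
  polar_b <- rownames(b_plain) %in% base_polar_atoms(spec$bases[2])
  desigM <- matrix(FALSE, nrow(a), nrow(b_plain),
                   dimnames = list(rownames(a), rownames(b_plain)))
  for (ct in spec$contacts) desigM[ct[1], ct[2]] <- TRUE
  polarM <- outer(polar_a, polar_b, `&`) & !desigM
  ring_a <- intersect(base_ring_atoms(spec$bases[1]), rownames(a))
  ring_b <- intersect(base_ring_atoms(spec$bases[2]), rownames(b_plain))
  ctr_a <- colMeans(a[ring_a, , drop = FALSE])
  ib <- match(vapply(spec$contacts, `[`, character(1), 2), rownames(b_plain))
  make_obj <- function(b0) {
    place <- function(par) {
      th <- par[3]
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      b <- b0
      b[, 1:2] <- b0[, 1:2] %*% t(R)
      b[, 1] <- b[, 1] + par[1]; b[, 2] <- b[, 2] + par[2]
      b
    }
    obj <- function(par) {
      b <- place(par)
      D <- sqrt(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b))
      s <- 10 * sum((D[cbind(ia, ib)] - 2.9)^2)
      s <- s + 2 * sum(pmax(0, 3.2 - D[polarM])^2)
      s <- s + 2 * sum(pmax(0, 2.6 - D[!polarM & !desigM])^2)
      ctr_b <- colMeans(b[ring_b, , drop = FALSE])
      s + 0.05 * (sqrt(sum((ctr_a - ctr_b)^2)) - 5.5)^2
    }
    list(place = place, obj = obj)
  }
  best <- NULL
  for (flip in c(TRUE, FALSE)) {
    fns <- make_obj(if (flip) b_flip else b_plain)
    for (th0 in seq(0, 2 * pi, length.out = 9)[-9]) {
      fit <- stats::optim(c(6.5, 0, th0), fns$obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      fit <- stats::optim(fit$par, fns$obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value)
        best <- list(value = fit$value, par = fit$par, place = fns$place)
    }
  }
  out <- list(first = a, second = best$place(best$par))
  attr(out, "bases") <- spec$bases
  attr(out, "objective") <- best$value
  .pelkit_fixture_cache[[kind]] <- out
  out
}

#' Idealised ribose ring (synthetic)
#'
#' Five ring atoms (C1', C2', C3', C4', O4') on a pentagon of circumradius
#' 1.29 A with out-of-plane displacements following the pseudorotation
#' model; the construction phase is scanned so the Altona-Sundaralingam
#' phase computed from the resulting ring torsions matches `phase_deg`.
#'
#' @param phase_deg target pseudorotation phase in degrees (default 18,
#'   mid C3'-endo / A-form).
#' @param q out-of-plane puckering amplitude in Angstrom.
#' @return matrix of 5 atom coordinates (rows named).
#' @export
ideal_ribose <- function(phase_deg = 18, q = 0.38) {
  build <- function(phi0) {
    # ring order around the cycle: C1' C2' C3' C4' O4'
    names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
    ang <- 2 * pi * (0:4) / 5
    R <- 1.29
    z <- sqrt(2 / 5) * q * cos(phi0 + 2 * ang)
    m <- cbind(R * cos(ang), R * sin(ang), z)
    rownames(m) <- names
    m
  }
  measure <- function(m) {
    res <- list(atoms = m, base = "A")
    pucker(res)$phase
  }
  phis <- seq(0, 2 * pi, length.out = 721)[-721]
  got <- vapply(phis, function(p) measure(build(p)), numeric(1))
  dd <- abs(((got - phase_deg + 180) %% 360) - 180)
  build(phis[which.min(dd)])
}

backbone_atoms <- c("O3'", "C5'", "O5'", "P")

# full idealised nucleotide: base + ribose attached through C1', plus
# approximate backbone atoms (O3', C5', O5', P) so the backbone dihedrals
# are defined on fixture structures
ideal_nucleotide <- function(base) {
  b <- ideal_base(base)
  rib <- ideal_ribose()
  # move ribose so its C1' coincides with the base frame C1' and the ring
  # sits away from the base (along the glycosidic direction)
  nref <- if (base %in% c("A", "G")) "N9" else "N1"
  gly <- b["C1'", ] - b[nref, ]
  gly <- gly / sqrt(sum(gly^2))
  ctr <- colMeans(rib)
  v <- rib["C1'", ] - ctr
  v <- v / sqrt(sum(v^2))
  R <- rotation_between(v, -gly)
  rib_r <- t(apply(rib, 1, function(p) as.vector(R %*% (p - rib["C1'", ]))))
  rib_r <- sweep(rib_r, 2, -b["C1'", ], `-`)
  rownames(rib_r) <- rownames(rib)
  ctr_r <- colMeans(rib_r)
  unitv <- function(u) u / sqrt(sum(u^2))
  up <- unitv(cross3(rib_r["C2'", ] - rib_r["C1'", ], rib_r["O4'", ] - rib_r["C1'", ]))
  o3 <- rib_r["C3'", ] + 1.42 * unitv(rib_r["C3'", ] - ctr_r)
  c5 <- rib_r["C4'", ] + 1.51 * unitv(unitv(rib_r["C4'", ] - ctr_r) + up)
  o5 <- c5 + 1.44 * unitv(unitv(c5 - rib_r["C4'", ]) + 0.5 * up)
  p <- o5 + 1.60 * unitv(unitv(o5 - c5) + c(0.3, 0, 0))
  bb <- rbind("O3'" = o3, "C5'" = c5, "O5'" = o5, "P" = p)
  rbind(b[setdiff(rownames(b), "C1'"), , drop = FALSE], rib_r, bb)
}

# proper rotation taking unit vector u to unit vector v
rotation_between <- function(u, v) {
  w <- cross3(u, v)
  s <- sqrt(sum(w^2)); c_ <- sum(u * v)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) cross3(u, c(1, 0, 0)) else cross3(u, c(0, 1, 0))
    p <- p / sqrt(sum(p^2))
    return(2 * tcrossprod(p) - diag(3))
  }
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Idealised A-form-like stem of k canonical pairs (synthetic)
#'
#' Stacks `k` idealised Watson-Crick pairs with a 3.4 A rise and a 32.7
#' degree twist about the pair midpoint. Residues 1..k are the 5' strand,
#' residues k+1..2k the partner strand, pairing (i, 2k+1-i).
#'
#' @param k number of base pairs (1..6 exercised in tests).
#' @param sequence optional 5'-strand sequence of length k over G/A (G gives
#'   G-C pairs, A gives A-U); default all G.
#' @return `rna_structure` of 2k residues.
#' @export
ideal_stem <- function(k, sequence = strrep("G", k)) {
  s <- strsplit(sequence, "")[[1]]
  stopifnot(length(s) == k, all(s %in% c("G", "A")))
  rise <- 3.4; twist <- 32.7 * pi / 180
  res1 <- vector("list", k); res2 <- vector("list", k)
  for (i in seq_len(k)) {
    kind <- if (s[i] == "G") "GC-WC" else "AU-WC"
    pr <- ideal_pair(kind)
    both <- rbind(pr$first, pr$second)
    mid <- colMeans(both[, , drop = FALSE])
    th <- twist * (i - 1)
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    tf <- function(m) {
      out <- t(apply(m, 1, function(p) as.vector(Rz %*% (p - mid))))
      out[, 3] <- out[, 3] + rise * (i - 1)
      rownames(out) <- rownames(m)
      out
    }
    res1[[i]] <- list(index = i, base = s[i], atoms = tf(pr$first))
    res2[[i]] <- list(index = 2 * k + 1 - i,
                      base = attr(pr, "bases")[2], atoms = tf(pr$second))
  }
  residues <- c(res1, rev(res2))
  structure(list(residues = residues, model_id = 1L, chain = "A",
                 sequence = paste(vapply(residues, function(r) r$base, character(1)),
                                  collapse = "")),
            class = "rna_structure")
}

#' Write rna_structure objects to a (multi-model) PDB file
#'
#' Minimal fixed-width ATOM/MODEL/ENDMDL records (coordinates in Angstrom,
#' 1-based residue numbers); sufficient for round-tripping the package's
#' synthetic fixtures through standard PDB readers.
#'
#' @param structures an `rna_structure` or list of them (models).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(structures, path) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(structures) > 1
  for (m in seq_along(structures)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (r in structures[[m]]$residues) {
      for (an in rownames(r$atoms)) {
        serial <- serial + 1L
        el <- substr(gsub("[^A-Za-z]", "", an), 1, 1)
        writeLines(sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                           serial, an, paste0("  ", r$base),
                           structures[[m]]$chain %||% "A", r$index,
                           r$atoms[an, 1], r$atoms[an, 2], r$atoms[an, 3],
                           1.0, 0.0, el), con)
      }
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Hand-built three-minimum KTN fixture
#'
#' Minima a, b, c at 0, 2 and 1 kcal/mol with transition states a-b at 5 and
#' b-c at 3 kcal/mol: the minimal example where the merge order and the
#' minimax barriers can be verified by hand.
#'
#' @return a [ktn_new()] database.
#' @export
hand_ktn <- function() {
  k <- ktn_new("hand-ktn", cartesian3d = FALSE)
  add_stationary_point(k, new_minimum(0, c(0, 0), 1e-9))
  add_stationary_point(k, new_minimum(2, c(4, 0), 1e-9))
  add_stationary_point(k, new_minimum(1, c(8, 0), 1e-9))
  add_stationary_point(k, new_transition_state(5, c(2, 0), -1, minus_id = 1L, plus_id = 2L))
  add_stationary_point(k, new_transition_state(3, c(6, 0), -1, minus_id = 2L, plus_id = 3L))
  k
}

#' Pseudoknot-like NMR-style ensemble fixture (synthetic)
#'
#' A 14-model PDB of a 21-residue chain whose first stem pairs residues 1-4
#' with 13-10 and whose second stem pairs 6-8 with 21-19, mimicking the
#' shape of a small H-type pseudoknot ensemble: per model the atoms carry a
#' small deterministic jitter. Entirely synthetic coordinates built from the
#' idealised pair geometries; loop residues are placed on a connecting arc.
#'
#' @param n_models number of models (default 14).
#' @param jitter per-model coordinate jitter amplitude in Angstrom.
#' @param seed RNG seed for the jitter.
#' @return list of `rna_structure` objects.
#' @export
nmr_like_ensemble <- function(n_models = 14L, jitter = 0.08, seed = 1L) {
  base_struct <- pk_like_structure()
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    s <- base_struct
    for (r in seq_along(s$residues)) {
      s$residues[[r]]$atoms <- s$residues[[r]]$atoms +
        matrix(stats::runif(length(s$residues[[r]]$atoms), -jitter, jitter),
               nrow = nrow(s$residues[[r]]$atoms))
    }
    s$model_id <- m
    out[[m]] <- s
  }
  out
}

# deterministic 21-residue pseudoknot-shaped structure from two idealised
# stems placed coaxially, loops on connecting arcs
pk_like_structure <- function() {
  seq21 <- strsplit("GGGGUGCCUCCCCAAAACGGC", "")[[1]]
  # stem 1: residues 1-4 with 13-10; stem 2: residues 6-8 with 21-19
  stem1 <- ideal_stem(4)   # G-C pairs; indices 1..4 / 5..8 internally
  stem2 <- ideal_stem(3)
  res <- vector("list", 21)
  # stem1 occupies z = 0..; stem2 stacked on top (coaxial), offset upward
  s1 <- stem1$residues   # indices 1..4 (strand 1), 5..8 (partner, = res 13..10)
  s2 <- stem2$residues   # indices 1..3 (strand 1 = res 6..8), partner = res 21..19
  lift <- function(at, dz) { at[, 3] <- at[, 3] + dz; at }
  for (i in 1:4) res[[i]] <- list(index = i, base = "G", atoms = s1[[i]]$atoms)
  # partner strand of stem 1: residues 13,12,11,10 pair 1,2,3,4
  partners1 <- c(13, 12, 11, 10)
  for (i in 1:4) {
    pr <- s1[[which(vapply(s1, function(r) r$index == 9 - i, logical(1)))]]
    res[[partners1[i]]] <- list(index = partners1[i], base = "C", atoms = pr$atoms)
  }
  for (i in 1:3) {
    at <- lift(s2[[i]]$atoms, 4 * 3.4 + 3.4)
    res[[5 + i]] <- list(index = 5 + i, base = "G", atoms = at)
  }
  partners2 <- c(21, 20, 19)
  for (i in 1:3) {
    pr <- s2[[which(vapply(s2, function(r) r$index == 7 - i, logical(1)))]]
    at <- lift(pr$atoms, 4 * 3.4 + 3.4)
    res[[partners2[i]]] <- list(index = partners2[i], base = "C", atoms = at)
  }
  # remaining loop residues: place far from the helical core on wide arcs so
  # they neither pair nor stack
  loops <- which(vapply(res, is.null, logical(1)))
  for (li in seq_along(loops)) {
    i <- loops[li]
    base <- seq21[i]
    nt <- ideal_nucleotide(base)
    th <- 2 * pi * li / (length(loops) + 1)
    shift <- c(14 * cos(th), 14 * sin(th), 8 + 2.5 * li)
    nt <- sweep(nt, 2, shift, `+`)
    res[[i]] <- list(index = i, base = base, atoms = nt)
  }
  # attach ribose rings to all stem residues too (pucker defined everywhere)
  for (i in seq_len(21)) {
    at <- res[[i]]$atoms
    if (!all(sugar_ring_atoms %in% rownames(at))) {
      nt <- ideal_nucleotide(res[[i]]$base)
      rib <- nt[c(sugar_ring_atoms, backbone_atoms), , drop = FALSE]
      # align the template through the C1' position already present
      if ("C1'" %in% rownames(at)) {
        shift <- at["C1'", ] - nt["C1'", ]
        rib <- sweep(rib, 2, shift, `+`)
        at <- rbind(at[setdiff(rownames(at), "C1'"), , drop = FALSE], rib)
      } else {
        at <- rbind(at, rib)
      }
      res[[i]]$atoms <- at
    }
  }
  structure(list(residues = res, model_id = 1L, chain = "A",
                 sequence = paste(vapply(res, function(r) r$base, character(1)),
                                  collapse = "")),
            class = "rna_structure")
}

#' Generate deterministic fixture files
#'
#' The synthetic-data entry point: writes the named fixture to `dir` and
#' returns the file path(s).
#'
#' * `mueller-brown` — YAML with the surface's stationary points located by
#'   dense-grid Newton refinement;
#' * `lj-cluster` — XYZ-style text of a quenched random Lennard-Jones
#'   cluster;
#' * `toy-rna` — parameter-set YAML plus an extended-chain configuration;
#' * `ideal-stem-pdb` — PDB of an idealised `params$k`-pair stem;
#' * `hand-ktn` — the three-minimum KTN as a KTN file set;
#' * `nmr-like-ensemble` — 14-model PDB of the 21-residue pseudoknot-like
#'   chain.
#'
#' @param kind fixture kind (see above).
#' @param dir output directory (created if needed).
#' @param params kind-specific parameters (e.g. `k` for stems, `n_atoms`).
#' @param seed RNG seed where randomness is involved.
#' @return character vector of file paths, invisibly.
#' @export
make_fixtures <- function(kind, dir = tempdir(), params = list(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  switch(kind,
    "mueller-brown" = {
      census <- mb_census()
      path <- file.path(dir, "mueller-brown-census.yaml")
      yaml::write_yaml(census, path, precision = 17)
      invisible(path)
    },
    "lj-cluster" = {
      n <- params$n_atoms %||% 7L
      model <- lj_cluster(n)
      old_seed <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
      set.seed(seed)
      x0 <- as.vector(t(matrix(stats::rnorm(3 * n, sd = 0.8), n, 3)))
      m <- local_minimise(model, x0)
      path <- file.path(dir, sprintf("lj%d.xyz", n))
      xyz <- matrix(m$coordinates, ncol = 3, byrow = TRUE)
      writeLines(c(as.character(n), sprintf("energy %.17g", m$energy),
                   sprintf("X %12.6f %12.6f %12.6f", xyz[, 1], xyz[, 2], xyz[, 3])),
                 path)
      invisible(path)
    },
    "toy-rna" = {
      ps <- rna_parameter_set(params$parameter_set %||% "cgA")
      p1 <- file.path(dir, sprintf("%s.yaml", ps$id))
      write_parameter_set(ps, p1)
      seqn <- params$sequence %||% "GGGGAAAACCCC"
      tr <- make_toy_rna(seqn, ps)
      p2 <- file.path(dir, "toy-rna-extended.txt")
      writeLines(c("# toy RNA extended-chain configuration (Angstrom)",
                   paste("# sequence:", seqn),
                   sprintf("%.17g", toy_rna_extended(tr$topology))), p2)
      invisible(c(p1, p2))
    },
    "ideal-stem-pdb" = {
      k <- params$k %||% 4L
      path <- file.path(dir, sprintf("ideal-stem-%dbp.pdb", k))
      write_pdb_models(ideal_stem(k), path)
      invisible(path)
    },
    "hand-ktn" = {
      invisible(write_ktn(hand_ktn(), file.path(dir, "hand-ktn")))
    },
    "nmr-like-ensemble" = {
      path <- file.path(dir, "nmr-like-ensemble.pdb")
      write_pdb_models(nmr_like_ensemble(params$n_models %||% 14L, seed = seed), path)
      invisible(path)
    },
    stop("unknown fixture kind: ", kind))
}

#' Independent stationary-point census of the Mueller-Brown surface
#'
#' Newton refinement of every point of a dense grid, classified by Hessian
#' eigenvalue signature and deduplicated: the oracle against which the
#' sampling pipeline is checked.
#'
#' @param nx,ny grid resolution.
#' @return list with `minima` and `saddles`, each a data frame of x, y,
#'   energy.
#' @export
mb_census <- function(nx = 60, ny = 60) {
  model <- mueller_brown()
  xs <- seq(-1.7, 1.2, length.out = nx)
  ys <- seq(-0.4, 2.2, length.out = ny)
  pts <- list()
  for (x in xs) for (y in ys) {
    p <- c(x, y)
    ok <- TRUE
    for (it in 1:80) {
      g <- model$gradient_fn(p)
      H <- model$hessian_fn(p)
      step <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      if (sqrt(sum(step^2)) > 1) step <- step / sqrt(sum(step^2))
      p <- p + step
      if (sqrt(sum(model$gradient_fn(p)^2)) < 1e-10) break
    }
    if (!ok) next
    if (sqrt(sum(model$gradient_fn(p)^2)) > 1e-8) next
    if (p[1] < -2 || p[1] > 1.5 || p[2] < -1 || p[2] > 2.5) next
    ev <- eigen(model$hessian_fn(p), symmetric = TRUE)$values
    kind <- if (all(ev > 1e-8)) "minimum" else if (sum(ev < -1e-8) == 1) "saddle" else "other"
    if (kind == "other") next
    pts[[length(pts) + 1L]] <- list(kind = kind, x = p[1], y = p[2],
                                    energy = model$energy_fn(p))
  }
  dedup <- function(kind) {
    sel <- Filter(function(p) p$kind == kind, pts)
    out <- list()
    for (p in sel) {
      dup <- FALSE
      for (q in out) if (abs(p$x - q$x) < 1e-5 && abs(p$y - q$y) < 1e-5) { dup <- TRUE; break }
      if (!dup) out[[length(out) + 1L]] <- p
    }
    df <- do.call(rbind, lapply(out, function(p) data.frame(x = p$x, y = p$y, energy = p$energy)))
    df[order(df$energy), , drop = FALSE]
  }
  list(minima = dedup("minimum"), saddles = dedup("saddle"))
}
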