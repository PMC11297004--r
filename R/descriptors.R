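#' Read RNA structures from a (possibly multi-model) PDB file
#'
#' One `rna_structure` per MODEL record (a single model when the file has
#' none). Alternate locations keep the first altloc; only standard RNA
#' residues (A, C, G, U and common aliases) are retained. Parsing is done
#' with the bio3d reader after a light line-level sanity check so malformed
#' ATOM records are reported with their line number.
#'
#' @param path PDB file path.
#' @return list of `rna_structure` objects (fields `residues`, `model_id`,
#'   `chain`, `sequence`).
#' @export
read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- grep("^(ATOM|HETATM)", lines)
  for (ln in at) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                            substr(l, 47, 54))))))
      stop(sprintf("malformed ATOM record at line %d of %s", ln, path))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  keep_alt <- is.na(atom$alt) | atom$alt %in% c("", "A")
  rna_map <- c(A = "A", C = "C", G = "G", U = "U",
               RA = "A", RC = "C", RG = "G", RU = "U",
               ADE = "A", CYT = "C", GUA = "G", URA = "U",
               A3 = "A", A5 = "A", C3 = "C", C5 = "C",
               G3 = "G", G5 = "G", U3 = "U", U5 = "U")
  keep <- keep_alt & atom$resid %in% names(rna_map)
  if (!any(keep))
    stop(structure(class = c("pelkit_empty_structure", "error", "condition"),
                   list(message = sprintf("no RNA residues found in %s", path),
                        call = NULL)))
  atom <- atom[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  sel_idx <- which(keep)
  res_key <- paste(atom$chain, atom$resno, atom$insert)
  res_order <- unique(res_key)
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    coords <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[sel_idx, , drop = FALSE]
    residues <- vector("list", length(res_order))
    for (r in seq_along(res_order)) {
      sel <- which(res_key == res_order[r])
      xyz_r <- coords[sel, , drop = FALSE]
      rownames(xyz_r) <- atom$elety[sel]
      residues[[r]] <- list(index = atom$resno[sel[1]],
                            base = unname(rna_map[atom$resid[sel[1]]]),
                            atoms = xyz_r)
    }
    out[[m]] <- structure(list(residues = residues, model_id = m,
                               chain = atom$chain[1],
                               sequence = paste(vapply(residues, function(r) r$base,
                                                       character(1)), collapse = "")),
                          class = "rna_structure")
  }
  out
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure model %s: %d residues (%s)>\n",
              x$model_id, length(x$residues), x$sequence))
  invisible(x)
}

# dihedral angle (degrees) of four points given as rows of a matrix
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

sugar_ring_atoms <- c("C1'", "C2'", "C3'", "C4'", "O4'")

#' Sugar pucker pseudorotation from the five ring torsions
#'
#' The pseudorotation phase in the Altona-Sundaralingam convention:
#' `P = atan2((nu4 + nu1) - (nu3 + nu0), 2 nu2 (sin 36 + sin 72))`, mapped
#' to `[0, 360)` degrees, with amplitude `nu2 / cos(P)`. Phases in
#' `[0, 36)` are C3'-endo (N-type, A-form), around 162 C2'-endo (S-type).
#'
#' @param nu numeric length-5 vector of ring torsions nu0..nu4 in degrees.
#' @return list with `phase` (degrees in `[0, 360)`) and `amplitude`
#'   (degrees).
#' @export
pucker_from_torsions <- function(nu) {
  stopifnot(length(nu) == 5)
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  P <- atan2(num, den) * 180 / pi
  list(phase = P %% 360, amplitude = nu[3] / cos(P * pi / 180))
}

#' Sugar pucker of a residue
#'
#' Computes the five ring torsions (nu0: C4'-O4'-C1'-C2' ... nu4:
#' C3'-C4'-O4'-C1') from the residue's ribose ring atoms and applies
#' [pucker_from_torsions()].
#'
#' @param residue a residue entry of an `rna_structure` (needs the five
#'   ring atoms).
#' @return list with `phase` and `amplitude` in degrees, or both `NA` with
#'   attribute `undefined = TRUE` when a ring atom is missing.
#' @export
pucker <- function(residue) {
  a <- residue$atoms
  if (!all(sugar_ring_atoms %in% rownames(a))) {
    out <- list(phase = NA_real_, amplitude = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  g <- function(n) a[n, ]
  nu <- c(dihedral_angle(g("C4'"), g("O4'"), g("C1'"), g("C2'")),
          dihedral_angle(g("O4'"), g("C1'"), g("C2'"), g("C3'")),
          dihedral_angle(g("C1'"), g("C2'"), g("C3'"), g("C4'")),
          dihedral_angle(g("C2'"), g("C3'"), g("C4'"), g("O4'")),
          dihedral_angle(g("C3'"), g("C4'"), g("O4'"), g("C1'")))
  pucker_from_torsions(nu)
}

base_ring_atoms <- function(base) {
  if (base %in% c("A", "G")) c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

# polar (N/O) base atoms eligible for hydrogen-bond-like contacts
base_polar_atoms <- function(base) {
  switch(base,
         A = c("N1", "N3", "N6", "N7"),
         G = c("N1", "N2", "N3", "O6", "N7"),
         C = c("N3", "N4", "O2"),
         U = c("N3", "O2", "O4"))
}

# heavy-atom edge membership (three-edge scheme: WC / Hoogsteen / Sugar)
base_edge_atoms <- function(base) {
  switch(base,
         A = list(WC = c("N1", "N6"), Hoogsteen = c("N7", "N6"), Sugar = c("N3")),
         G = list(WC = c("N1", "N2", "O6"), Hoogsteen = c("N7", "O6"), Sugar = c("N3", "N2")),
         C = list(WC = c("N3", "N4", "O2"), Hoogsteen = c("N4", "C5"), Sugar = c("O2")),
         U = list(WC = c("N3", "O4"), Hoogsteen = c("O4"), Sugar = c("O2")))
}

ring_centre_normal <- function(residue) {
  nm <- intersect(base_ring_atoms(residue$base), rownames(residue$atoms))
  if (length(nm) < 3) return(NULL)
  pts <- residue$atoms[nm, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(centre = ctr, normal = sv$v[, 3])
}

#' Default geometric cutoffs for pairing and stacking annotation
#'
#' @param max_centre_dist maximum base-centre separation for a pair (A).
#' @param max_plane_angle maximum inter-plane angle for a pair (degrees).
#' @param max_vertical_offset maximum out-of-plane offset for a pair (A);
#'   separates in-plane pairing from stacking contacts.
#' @param hbond_dist maximum donor-acceptor (N/O to N/O) distance (A).
#' @param min_hbonds minimum polar-contact count for a pair.
#' @param stack_dist maximum ring-centre distance for stacking (A).
#' @param stack_angle maximum inter-plane angle for stacking (degrees).
#' @param stack_offset maximum in-plane centre offset for stacking (A).
#' @return list of cutoffs.
#' @export
geometry_cutoffs <- function(max_centre_dist = 6.5, max_plane_angle = 35,
                             max_vertical_offset = 2.0, hbond_dist = 3.5,
                             min_hbonds = 1L, stack_dist = 4.5,
                             stack_angle = 30, stack_offset = 2.5) {
  as.list(environment())
}

plane_angle <- function(n1, n2) {
  ca <- abs(sum(n1 * n2))
  acos(pmin(1, ca)) * 180 / pi
}

#' Annotate base pairs in a structure
#'
#' Pairs are base pairs when their ring centres are close, their base planes
#' near-parallel and near-coplanar, and at least `min_hbonds` polar N/O
#' atom pairs lie within hydrogen-bonding distance. Each partner is
#' assigned the edge (Watson-Crick, Hoogsteen or Sugar) contributing most of
#' its contact atoms; the pair category is `canonical-WC` for G-C / A-U on
#' WC/WC edges with at least two contacts, `wobble` for G-U on WC/WC edges,
#' `non-canonical` otherwise.
#'
#' @param structure an `rna_structure`.
#' @param cutoffs a [geometry_cutoffs()] list.
#' @return list of `base_pair` objects (`i`, `j`, `category`, `edges`,
#'   `n_hbonds`); empty list when nothing pairs.
#' @export
annotate_pairs <- function(structure, cutoffs = geometry_cutoffs()) {
  res <- structure$residues
  n <- length(res)
  geo <- lapply(res, ring_centre_normal)
  pairs <- list()
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    if (i >= j) next
    gi <- geo[[i]]; gj <- geo[[j]]
    if (is.null(gi) || is.null(gj)) next
    dvec <- gj$centre - gi$centre
    dist <- sqrt(sum(dvec^2))
    if (dist > cutoffs$max_centre_dist) next
    if (plane_angle(gi$normal, gj$normal) > cutoffs$max_plane_angle) next
    voff <- max(abs(sum(dvec * gi$normal)), abs(sum(dvec * gj$normal)))
    if (voff > cutoffs$max_vertical_offset) next
    pi_names <- intersect(base_polar_atoms(res[[i]]$base), rownames(res[[i]]$atoms))
    pj_names <- intersect(base_polar_atoms(res[[j]]$base), rownames(res[[j]]$atoms))
    if (!length(pi_names) || !length(pj_names)) next
    ai <- res[[i]]$atoms[pi_names, , drop = FALSE]
    aj <- res[[j]]$atoms[pj_names, , drop = FALSE]
    # one-to-one greedy donor/acceptor matching: each polar atom takes part
    # in at most one hydrogen-bond-like contact
    cand <- list()
    for (a in seq_len(nrow(ai))) for (b in seq_len(nrow(aj))) {
      d <- sqrt(sum((ai[a, ] - aj[b, ])^2))
      if (d <= cutoffs$hbond_dist) cand[[length(cand) + 1L]] <- c(a, b, d)
    }
    touch_i <- character(); touch_j <- character(); nhb <- 0L
    if (length(cand)) {
      cand <- cand[order(vapply(cand, `[`, numeric(1), 3))]
      used_a <- logical(nrow(ai)); used_b <- logical(nrow(aj))
      for (cb in cand) {
        if (!used_a[cb[1]] && !used_b[cb[2]]) {
          used_a[cb[1]] <- used_b[cb[2]] <- TRUE
          nhb <- nhb + 1L
          touch_i <- c(touch_i, pi_names[cb[1]]); touch_j <- c(touch_j, pj_names[cb[2]])
        }
      }
    }
    if (nhb < cutoffs$min_hbonds) next
    ei <- classify_edge(res[[i]]$base, touch_i)
    ej <- classify_edge(res[[j]]$base, touch_j)
    bi <- res[[i]]$base; bj <- res[[j]]$base
    combo <- paste(sort(c(bi, bj)), collapse = "")
    category <- if (ei == "WC" && ej == "WC" && combo %in% c("CG", "AU") && nhb >= 2)
      "canonical-WC"
    else if (ei == "WC" && ej == "WC" && combo == "GU") "wobble"
    else "non-canonical"
    pairs[[length(pairs) + 1L]] <- structure(
      list(i = res[[i]]$index, j = res[[j]]$index, category = category,
           edges = stats::setNames(c(ei, ej), c(res[[i]]$base, res[[j]]$base)),
           n_hbonds = nhb),
      class = "base_pair")
  }
  pairs
}

classify_edge <- function(base, touched) {
  edges <- base_edge_atoms(base)
  counts <- vapply(edges, function(at) sum(unique(touched) %in% at), integer(1))
  names(counts)[which.max(counts)]  # ties resolve WC > Hoogsteen > Sugar by order
}

#' @export
print.base_pair <- function(x, ...) {
  cat(sprintf("<base_pair %d-%d: %s (%s/%s edges, %d polar contacts)>\n",
              x$i, x$j, x$category, x$edges[1], x$edges[2], x$n_hbonds))
  invisible(x)
}

#' Annotate base-base stacking
#'
#' Residues i and j stack when their ring centres are within `stack_dist`,
#' their planes within `stack_angle` of parallel, and the centre-centre
#' vector projected onto either base plane is within `stack_offset` (i.e.
#' one ring sits above the other rather than beside it).
#'
#' @param structure an `rna_structure`.
#' @param cutoffs a [geometry_cutoffs()] list.
#' @return two-column integer matrix of stacked residue index pairs (i < j).
#' @export
annotate_stacking <- function(structure, cutoffs = geometry_cutoffs()) {
  res <- structure$residues
  n <- length(res)
  geo <- lapply(res, ring_centre_normal)
  out <- list()
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    gi <- geo[[i]]; gj <- geo[[j]]
    if (is.null(gi) || is.null(gj)) next
    dvec <- gj$centre - gi$centre
    dist <- sqrt(sum(dvec^2))
    if (dist > cutoffs$stack_dist) next
    if (plane_angle(gi$normal, gj$normal) > cutoffs$stack_angle) next
    off_i <- sqrt(max(0, dist^2 - sum(dvec * gi$normal)^2))
    off_j <- sqrt(max(0, dist^2 - sum(dvec * gj$normal)^2))
    if (min(off_i, off_j) > cutoffs$stack_offset) next
    out[[length(out) + 1L]] <- c(res[[i]]$index, res[[j]]$index)
  }
  if (!length(out)) matrix(integer(), 0, 2) else do.call(rbind, out)
}

#' Dot-bracket string for a set of base pairs
#'
#' Canonical (and, by default, wobble) pairs only. Residues claimed by more
#' than one pair keep the pair with the most polar contacts (conflicts are
#' recorded in the `conflicts` attribute). Crossing pairs — pseudoknots —
#' are assigned to successive bracket tiers `()`, `[]`, `{}`, `<>` by greedy
#' page assignment on the crossing graph; more than four tiers raises an
#' overflow error.
#'
#' @param pairs list of `base_pair` objects, or a two-column matrix of
#'   residue index pairs (then all treated as canonical).
#' @param n_residues total residue count.
#' @param include_wobble count G-U wobble pairs as paired (default `TRUE`).
#' @return character scalar of length `n_residues`.
#' @export
dot_bracket <- function(pairs, n_residues, include_wobble = TRUE) {
  pm <- pairs_to_matrix(pairs, include_wobble)
  conflicts <- character()
  if (nrow(pm)) {
    # resolve residues claimed twice: keep highest n_hbonds, then first
    ord <- order(-pm[, 3])
    taken <- logical(n_residues)
    keep <- logical(nrow(pm))
    for (k in ord) {
      if (!taken[pm[k, 1]] && !taken[pm[k, 2]]) {
        keep[k] <- TRUE
        taken[pm[k, 1]] <- taken[pm[k, 2]] <- TRUE
      } else conflicts <- c(conflicts, sprintf("%d-%d", pm[k, 1], pm[k, 2]))
    }
    pm <- pm[keep, , drop = FALSE]
    pm <- pm[order(pm[, 1]), , drop = FALSE]
  }
  openers <- c("(", "[", "{", "<"); closers <- c(")", "]", "}", ">")
  tier <- integer(nrow(pm))
  for (k in seq_len(nrow(pm))) {
    t <- 1L
    repeat {
      clash <- FALSE
      for (m in seq_len(k - 1)) {
        if (tier[m] == t && crosses(pm[k, 1:2], pm[m, 1:2])) { clash <- TRUE; break }
      }
      if (!clash) break
      t <- t + 1L
      if (t > 4L) stop("more than four bracket tiers needed for this pair set")
    }
    tier[k] <- t
  }
  s <- rep(".", n_residues)
  for (k in seq_len(nrow(pm))) {
    s[pm[k, 1]] <- openers[tier[k]]
    s[pm[k, 2]] <- closers[tier[k]]
  }
  out <- paste(s, collapse = "")
  attr(out, "conflicts") <- conflicts
  out
}

crosses <- function(p, q) {
  (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
    (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
}

pairs_to_matrix <- function(pairs, include_wobble = TRUE) {
  if (is.matrix(pairs)) {
    if (!nrow(pairs)) return(matrix(integer(), 0, 3))
    return(cbind(t(apply(pairs[, 1:2, drop = FALSE], 1, sort)), 3L))
  }
  rows <- list()
  for (p in pairs) {
    okcat <- p$category == "canonical-WC" || (include_wobble && p$category == "wobble")
    if (okcat) rows[[length(rows) + 1L]] <- c(min(p$i, p$j), max(p$i, p$j), p$n_hbonds)
  }
  if (!length(rows)) matrix(integer(), 0, 3) else do.call(rbind, rows)
}

#' Parse a dot-bracket string back into a pair matrix
#'
#' @param s dot-bracket string over `.()[]{}<>`.
#' @return two-column integer matrix of pairs (i < j), ordered by i.
#' @export
parse_dot_bracket <- function(s) {
  chars <- strsplit(s, "")[[1]]
  openers <- c("(", "[", "{", "<"); closers <- c(")", "]", "}", ">")
  stacks <- list(integer(), integer(), integer(), integer())
  out <- list()
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch %in% openers) {
      t <- match(ch, openers)
      stacks[[t]] <- c(stacks[[t]], k)
    } else if (ch %in% closers) {
      t <- match(ch, closers)
      if (!length(stacks[[t]])) stop("unbalanced brackets at position ", k)
      i <- stacks[[t]][length(stacks[[t]])]
      stacks[[t]] <- stacks[[t]][-length(stacks[[t]])]
      out[[length(out) + 1L]] <- c(i, k)
    } else if (ch != ".") stop("unexpected character: ", ch)
  }
  if (any(vapply(stacks, length, integer(1)) > 0)) stop("unbalanced brackets")
  pm <- if (!length(out)) matrix(integer(), 0, 2) else do.call(rbind, out)
  pm[order(pm[, 1]), , drop = FALSE]
}

#' Arc-diagram drawing data for a pair set
#'
#' Arcs over a 1..n baseline, one per pair, styled by category (solid for
#' canonical/wobble stems, dashed for non-canonical interactions), plus the
#' unpaired residues, optionally flagged as pointing outward.
#'
#' @param pairs list of `base_pair` objects or a two-column matrix.
#' @param n_residues residue count.
#' @param config list; `outward` may name residue indices to flag.
#' @return object of class `arc_diagram` with `arcs` (data frame), `json`
#'   and `svg` strings.
#' @export
arc_diagram <- function(pairs, n_residues, config = list()) {
  if (is.matrix(pairs)) {
    arcs <- if (nrow(pairs))
      data.frame(i = pairs[, 1], j = pairs[, 2], category = "canonical-WC",
                 style = "solid")
    else data.frame(i = integer(), j = integer(), category = character(),
                    style = character())
  } else {
    arcs <- do.call(rbind, c(list(
      data.frame(i = integer(), j = integer(), category = character(),
                 style = character())),
      lapply(pairs, function(p)
        data.frame(i = min(p$i, p$j), j = max(p$i, p$j), category = p$category,
                   style = if (p$category == "non-canonical") "dashed" else "solid"))))
  }
  paired <- unique(c(arcs$i, arcs$j))
  unpaired <- setdiff(seq_len(n_residues), paired)
  outward <- intersect(unpaired, config$outward %||% integer())
  W <- 20 * (n_residues + 1); H <- 10 * n_residues / 2 + 60
  px <- function(i) 20 * i
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', W, H),
           sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black"/>',
                   px(1), H - 20, px(n_residues), H - 20))
  for (k in seq_len(nrow(arcs))) {
    r <- (arcs$j[k] - arcs$i[k]) * 10
    svg <- c(svg, sprintf(
      '<path d="M %d %d A %d %d 0 0 1 %d %d" fill="none" stroke="%s"%s class="%s"/>',
      px(arcs$i[k]), H - 20, r, r, px(arcs$j[k]), H - 20,
      if (arcs$style[k] == "dashed") "red" else "blue",
      if (arcs$style[k] == "dashed") ' stroke-dasharray="4 3"' else "",
      arcs$style[k]))
  }
  for (u in outward)
    svg <- c(svg, sprintf('<circle cx="%d" cy="%d" r="3" fill="green"/>', px(u), H - 12))
  svg <- c(svg, "</svg>")
  json <- jsonlite::toJSON(list(n_residues = n_residues, arcs = arcs,
                                unpaired = unpaired, outward = outward),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(arcs = arcs, unpaired = unpaired, outward = outward,
                 svg = paste(svg, collapse = "\n"), json = as.character(json)),
            class = "arc_diagram")
}

#' @export
print.arc_diagram <- function(x, ...) {
  cat(sprintf("<arc_diagram: %d arcs (%d dashed), %d unpaired residues>\n",
              nrow(x$arcs), sum(x$arcs$style == "dashed"), length(x$unpaired)))
  invisible(x)
}

standard_dihedral_atoms <- list(
  alpha = list(c(-1, "O3'"), c(0, "P"), c(0, "O5'"), c(0, "C5'")),
  beta  = list(c(0, "P"), c(0, "O5'"), c(0, "C5'"), c(0, "C4'")),
  gamma = list(c(0, "O5'"), c(0, "C5'"), c(0, "C4'"), c(0, "C3'")),
  delta = list(c(0, "C5'"), c(0, "C4'"), c(0, "C3'"), c(0, "O3'")),
  epsilon = list(c(0, "C4'"), c(0, "C3'"), c(0, "O3'"), c(1, "P")),
  zeta  = list(c(0, "C3'"), c(0, "O3'"), c(1, "P"), c(1, "O5'")))

#' Per-nucleotide structural descriptors
#'
#' For every residue: pseudorotation phase and amplitude, the six backbone
#' dihedrals and the glycosidic angle chi (degrees; `NA` with no imputation
#' when atoms are missing, e.g. alpha of the 5' terminus), and the counts of
#' stacking partners, canonical (+ wobble) pairs and non-canonical pairs.
#'
#' @param structure an `rna_structure`.
#' @param cutoffs a [geometry_cutoffs()] list.
#' @param wobble_is_canonical count G-U wobble toward the canonical tally.
#' @return data frame, one row per residue.
#' @export
nucleotide_descriptors <- function(structure, cutoffs = geometry_cutoffs(),
                                   wobble_is_canonical = TRUE) {
  res <- structure$residues
  n <- length(res)
  pairs <- annotate_pairs(structure, cutoffs)
  stacks <- annotate_stacking(structure, cutoffs)
  idx <- vapply(res, function(r) r$index, numeric(1))
  get_atom <- function(ri, name) {
    if (ri < 1 || ri > n) return(NULL)
    a <- res[[ri]]$atoms
    if (!name %in% rownames(a)) return(NULL)
    a[name, ]
  }
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    pk <- pucker(res[[r]])
    dihs <- vapply(standard_dihedral_atoms, function(spec) {
      pts <- lapply(spec, function(s) get_atom(r + as.integer(s[1]), s[2]))
      if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
      dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }, numeric(1))
    base <- res[[r]]$base
    chi_atoms <- if (base %in% c("A", "G")) c("O4'", "C1'", "N9", "C4")
                 else c("O4'", "C1'", "N1", "C2")
    chi_pts <- lapply(chi_atoms, function(nm) get_atom(r, nm))
    chi <- if (any(vapply(chi_pts, is.null, logical(1)))) NA_real_
           else dihedral_angle(chi_pts[[1]], chi_pts[[2]], chi_pts[[3]], chi_pts[[4]])
    my_idx <- idx[r]
    n_stack <- if (nrow(stacks)) sum(stacks[, 1] == my_idx | stacks[, 2] == my_idx) else 0L
    cats <- vapply(pairs, function(p) p$category, character(1))
    mine <- vapply(pairs, function(p) p$i == my_idx || p$j == my_idx, logical(1))
    canonical_cats <- c("canonical-WC", if (wobble_is_canonical) "wobble")
    rows[[r]] <- data.frame(
      residue = my_idx, base = base,
      pucker_phase = pk$phase, pucker_amplitude = pk$amplitude,
      alpha = dihs[["alpha"]], beta = dihs[["beta"]], gamma = dihs[["gamma"]],
      delta = dihs[["delta"]], epsilon = dihs[["epsilon"]], zeta = dihs[["zeta"]],
      chi = chi,
      n_stacking = n_stack,
      n_canonical_bp = sum(mine & cats %in% canonical_cats),
      n_noncanonical_bp = sum(mine & cats == "non-canonical"))
  }
  do.call(rbind, rows)
}

circular_mean_deg <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  out <- (atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi) %% 360
  if (out >= 360 - 1e-9) 0 else out
}

circular_sd_deg <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  if (length(x) == 1) return(0)
  R <- sqrt(mean(sin(x * pi / 180))^2 + mean(cos(x * pi / 180))^2)
  sqrt(pmax(0, -2 * log(pmax(min(R, 1), 1e-12)))) * 180 / pi
}

#' Ensemble-averaged per-nucleotide profile
#'
#' Averages [nucleotide_descriptors()] over a set of structures of the same
#' sequence: circular means and circular standard deviations for all
#' angular fields, arithmetic means and standard deviations for the
#' interaction counts. Also reports the dominant dot-bracket string across
#' the ensemble and its frequency.
#'
#' @param structures list of `rna_structure` objects with identical
#'   sequences.
#' @param cutoffs a [geometry_cutoffs()] list.
#' @return object of class `ensemble_profile`: `profile` (data frame with
#'   `<field>_mean` / `<field>_sd` columns), `n_structures`,
#'   `dominant_dot_bracket`, `dot_bracket_frequency`.
#' @export
ensemble_profile <- function(structures, cutoffs = geometry_cutoffs()) {
  stopifnot(length(structures) >= 1)
  seqs <- vapply(structures, function(s) s$sequence, character(1))
  if (length(unique(seqs)) != 1)
    stop("all structures must share one sequence")
  descs <- lapply(structures, nucleotide_descriptors, cutoffs = cutoffs)
  n_res <- nrow(descs[[1]])
  angular <- c("pucker_phase", "alpha", "beta", "gamma", "delta", "epsilon",
               "zeta", "chi")
  linear <- c("pucker_amplitude", "n_stacking", "n_canonical_bp", "n_noncanonical_bp")
  prof <- data.frame(residue = descs[[1]]$residue, base = descs[[1]]$base)
  for (f in c(angular, linear)) {
    vals <- sapply(descs, function(d) d[[f]])
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = n_res)
    if (f %in% angular) {
      prof[[paste0(f, "_mean")]] <- apply(vals, 1, circular_mean_deg)
      prof[[paste0(f, "_sd")]] <- apply(vals, 1, circular_sd_deg)
    } else {
      prof[[paste0(f, "_mean")]] <- rowMeans(vals, na.rm = TRUE)
      prof[[paste0(f, "_sd")]] <- apply(vals, 1, function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2) 0 else stats::sd(v)
      })
    }
  }
  dbs <- vapply(structures, function(s)
    as.character(dot_bracket(annotate_pairs(s, cutoffs), length(s$residues))),
    character(1))
  tab <- sort(table(dbs), decreasing = TRUE)
  structure(list(profile = prof, n_structures = length(structures),
                 dominant_dot_bracket = names(tab)[1],
                 dot_bracket_frequency = as.numeric(tab[1]) / length(dbs)),
            class = "ensemble_profile")
}

#' @export
print.ensemble_profile <- function(x, ...) {
  cat(sprintf("<ensemble_profile over %d structure(s); dominant dot-bracket %s (%.0f%%)>\n",
              x$n_structures, x$dominant_dot_bracket, 100 * x$dot_bracket_frequency))
  invisible(x)
}
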