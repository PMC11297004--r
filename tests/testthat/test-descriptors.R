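pair_structure <- function(kind) {
  pr <- ideal_pair(kind)
  b <- attr(pr, "bases")
  structure(list(residues = list(list(index = 1, base = b[1], atoms = pr$first),
                                 list(index = 2, base = b[2], atoms = pr$second)),
                 model_id = 1L, chain = "A",
                 sequence = paste(b, collapse = "")),
            class = "rna_structure")
}

pk1_pairs <- rbind(cbind(1:4, 13:10), cbind(6:8, 21:19))

test_that("multi-model PDB files round-trip through the reader", {
  td <- tempdir()
  one <- file.path(td, "one.pdb")
  write_pdb_models(pk_like <- pelkit:::pk_like_structure(), one)
  got <- read_pdb_models(one)
  expect_length(got, 1)
  expect_length(got[[1]]$residues, 21)
  expect_identical(got[[1]]$sequence, pk_like$sequence)

  many <- file.path(td, "many.pdb")
  write_pdb_models(nmr_like_ensemble(14), many)
  ens <- read_pdb_models(many)
  expect_length(ens, 14)
  expect_true(all(vapply(ens, function(s) length(s$residues), integer(1)) == 21))
})

test_that("non-RNA and malformed files are rejected informatively", {
  td <- tempdir()
  prot <- file.path(td, "prot.pdb")
  writeLines(c("ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
               "END"), prot)
  expect_error(read_pdb_models(prot), class = "pelkit_empty_structure")

  bad <- file.path(td, "bad.pdb")
  writeLines(c("ATOM      1  N1    G A   1      11.104   6.134  -6.504  1.00  0.00           N",
               "ATOM      2  C2    G A   1      garbage  6.134", "END"), bad)
  expect_error(read_pdb_models(bad), "line 2")
})

test_that("pseudorotation formula handles the hand-checkable cases", {
  # numerator zero with positive nu2: phase exactly 0, amplitude nu2
  p0 <- pucker_from_torsions(c(10, 20, 30, 20, 10))
  expect_equal(p0$phase, 0)
  expect_equal(p0$amplitude, 30)
  # negating every torsion shifts the phase by half a cycle
  set.seed(4)
  for (i in 1:20) {
    nu <- runif(5, -40, 40)
    if (abs(nu[3]) < 1) next
    a <- pucker_from_torsions(nu)
    b <- pucker_from_torsions(-nu)
    expect_equal((b$phase - a$phase) %% 360, 180, tolerance = 1e-9)
  }
})

test_that("the idealised ribose is C3'-endo (N-type)", {
  rib <- ideal_ribose()
  pk <- pucker(list(atoms = rib, base = "A"))
  expect_gte(pk$phase, 0)
  expect_lt(pk$phase, 36)
  expect_gt(pk$amplitude, 0)
  # a residue missing a ring atom is flagged, not imputed
  partial <- list(atoms = rib[-1, , drop = FALSE], base = "A")
  expect_true(is.na(pucker(partial)$phase))
})

test_that("idealised pairs annotate with the expected category, edges and bonds", {
  gc <- annotate_pairs(pair_structure("GC-WC"))
  expect_length(gc, 1)
  expect_identical(gc[[1]]$category, "canonical-WC")
  expect_identical(gc[[1]]$n_hbonds, 3L)
  expect_identical(unname(gc[[1]]$edges), c("WC", "WC"))

  au <- annotate_pairs(pair_structure("AU-WC"))
  expect_identical(au[[1]]$category, "canonical-WC")
  expect_identical(au[[1]]$n_hbonds, 2L)

  gu <- annotate_pairs(pair_structure("GU-wobble"))
  expect_identical(gu[[1]]$category, "wobble")

  hg <- annotate_pairs(pair_structure("AU-Hoogsteen"))
  expect_identical(hg[[1]]$category, "non-canonical")
  expect_identical(unname(hg[[1]]$edges["A"]), "Hoogsteen")
})

test_that("bases pulled apart stop pairing", {
  st <- pair_structure("GC-WC")
  st$residues[[2]]$atoms <- st$residues[[2]]$atoms + rep(10, 3)
  expect_length(annotate_pairs(st), 0)
})

test_that("stacking requires near-parallel overlapping rings", {
  g <- ideal_base("G")
  mk <- function(second) {
    structure(list(residues = list(list(index = 1, base = "G", atoms = g),
                                   list(index = 2, base = "G", atoms = second)),
                   model_id = 1, chain = "A", sequence = "GG"),
              class = "rna_structure")
  }
  above <- g; above[, 3] <- above[, 3] + 3.4
  expect_identical(nrow(annotate_stacking(mk(above))), 1L)
  beside <- g; beside[, 1] <- beside[, 1] + 6
  expect_identical(nrow(annotate_stacking(mk(beside))), 0L)
  perp <- g %*% matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3)
  rownames(perp) <- rownames(g)
  perp[, 3] <- perp[, 3] + 3.4
  expect_identical(nrow(annotate_stacking(mk(perp))), 0L)
})

test_that("idealised stems annotate exactly k canonical pairs for k = 1..6", {
  for (k in 1:6) {
    ps <- annotate_pairs(ideal_stem(k))
    expect_length(ps, k)
    expect_true(all(vapply(ps, function(p) p$category == "canonical-WC", logical(1))))
  }
})

test_that("the pseudoknot pair set yields the hand-derived two-tier string", {
  expect_identical(as.character(dot_bracket(pk1_pairs, 21)),
                   "((((.[[[.)))).....]]]")
  expect_identical(as.character(dot_bracket(matrix(integer(), 0, 2), 5)), ".....")
  expect_identical(as.character(dot_bracket(rbind(c(1, 6), c(2, 5)), 6)), "((..))")
})

test_that("dot-bracket strings parse back to their pair sets", {
  expect_identical(parse_dot_bracket("((((.[[[.)))).....]]]"),
                   pk1_pairs[order(pk1_pairs[, 1]), ])
  # property: random nested + crossing pair sets round-trip
  set.seed(21)
  done <- 0
  while (done < 40) {
    n <- sample(8:30, 1)
    avail <- seq_len(n)
    pm <- NULL
    for (tries in 1:6) {
      if (length(avail) < 2) break
      ij <- sort(sample(avail, 2))
      pm <- rbind(pm, ij)
      avail <- setdiff(avail, ij)
    }
    pm <- pm[order(pm[, 1]), , drop = FALSE]
    s <- tryCatch(dot_bracket(pm, n), error = function(e) NULL)
    if (is.null(s)) next  # needed more than four tiers; not representable
    back <- parse_dot_bracket(s)
    dimnames(back) <- NULL; dimnames(pm) <- NULL
    expect_identical(back, pm)
    done <- done + 1
  }
  expect_identical(done, 40)
})

test_that("more than four mutually crossing stems overflow explicitly", {
  pm <- rbind(c(1, 11), c(3, 13), c(5, 15), c(7, 17), c(9, 19))
  expect_error(dot_bracket(pm, 20), "four bracket tiers")
})

test_that("arc diagrams style arcs by category", {
  ad <- arc_diagram(pk1_pairs, 21)
  expect_identical(nrow(ad$arcs), 7L)
  expect_true(all(ad$arcs$style == "solid"))
  expect_silent(xml2::read_xml(ad$svg))

  empty <- arc_diagram(matrix(integer(), 0, 2), 5)
  expect_identical(nrow(empty$arcs), 0L)
  expect_length(empty$unpaired, 5)

  nc <- arc_diagram(annotate_pairs(pair_structure("AU-Hoogsteen")), 2)
  expect_identical(nc$arcs$style, "dashed")
})

test_that("descriptors are invariant under global rotation and translation", {
  st <- pelkit:::pk_like_structure()
  d0 <- nucleotide_descriptors(st)
  R <- random_rotation(9)
  st2 <- st
  for (r in seq_along(st2$residues)) {
    at <- st2$residues[[r]]$atoms
    st2$residues[[r]]$atoms <- sweep(at %*% t(R), 2, c(5, -3, 2), `+`)
  }
  d1 <- nucleotide_descriptors(st2)
  for (col in setdiff(names(d0), c("residue", "base"))) {
    a <- d0[[col]]; b <- d1[[col]]
    expect_true(all(is.na(a) == is.na(b)))
    if (all(is.na(a))) next  # e.g. backbone dihedrals absent from the fixture
    diffs <- abs(((b - a + 180) %% 360) - 180)  # angular fields wrap
    diffs2 <- abs(b - a)
    expect_lt(max(pmin(diffs, diffs2), na.rm = TRUE), 1e-6)
  }
})

test_that("ensemble profiles average angles circularly and counts linearly", {
  st <- pelkit:::pk_like_structure()
  single <- ensemble_profile(list(st))
  expect_identical(single$n_structures, 1L)
  expect_true(all(single$profile$chi_sd == 0 | is.na(single$profile$chi_sd)))
  d <- nucleotide_descriptors(st)
  expect_equal(single$profile$n_stacking_mean, d$n_stacking)

  dup <- ensemble_profile(list(st, st))
  expect_equal(dup$profile, single$profile, tolerance = 1e-5)
  expect_identical(dup$dominant_dot_bracket, single$dominant_dot_bracket)

  # wrap-around averaging
  expect_equal(pelkit:::circular_mean_deg(c(170, -170)), 180)
  expect_equal(pelkit:::circular_mean_deg(c(10, 350)), 0)

  # undefined terminal dihedrals are excluded, not imputed
  expect_true(is.na(d$alpha[1]))
  expect_true(is.na(single$profile$alpha_mean[1]))

  ens <- nmr_like_ensemble(5)
  mixed <- ens
  mixed[[2]]$sequence <- sub("G", "A", mixed[[2]]$sequence)
  expect_error(ensemble_profile(mixed), "share one sequence")
})
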