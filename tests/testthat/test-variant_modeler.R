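test_that("same-base substitution is the identity up to rounding", {
  s <- ladder("GACU")
  for (rn in 1:4) {
    s2 <- substitute_base(s, rn, nucleotide_table(s)$base[rn])
    expect_lt(max_atom_shift(s, s2), 1e-3)
  }
})

test_that("pyrimidine swap keeps the shared ring atoms in place", {
  s <- ladder("GACU")
  s2 <- substitute_base(s, 3, "U")   # C -> U
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  shifts <- vapply(ring, function(a)
    sqrt(sum((mc3dqsar:::.atom_pos(s2, "A", 3, a) -
                mc3dqsar:::.atom_pos(s, "A", 3, a))^2)), numeric(1))
  expect_lt(max(shifts), 0.1)
  # residual agrees with an independent least-squares superposition of the
  # idealized templates (bio3d's quaternion-free rotation fit)
  tplC <- mc3dqsar:::.nt_templates[mc3dqsar:::.nt_templates$base == "C", ]
  tplU <- mc3dqsar:::.nt_templates[mc3dqsar:::.nt_templates$base == "U", ]
  P <- as.matrix(tplU[match(ring, tplU$atom), c("x", "y", "z")])
  Q <- as.matrix(tplC[match(ring, tplC$atom), c("x", "y", "z")])
  fitted <- matrix(bio3d::fit.xyz(fixed = as.numeric(t(Q)),
                                  mobile = as.numeric(t(P)),
                                  fixed.inds = 1:18, mobile.inds = 1:18),
                   ncol = 3, byrow = TRUE)
  oracle_rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  expect_lt(oracle_rmsd, 0.1)
  # and our Kabsch reaches the same optimum
  ours <- mc3dqsar:::.kabsch(P, Q)$rmsd
  expect_equal(ours, oracle_rmsd, tolerance = 1e-6)
})

test_that("substitution is local, deterministic and leaves the backbone fixed", {
  s <- ladder("GACU")
  s2 <- substitute_base(s, 2, "U")
  # all other residues bit-identical
  for (rn in c(1, 3, 4))
    expect_identical(res_df(s, rn), res_df(s2, rn))
  # sugar/backbone of the substituted residue untouched
  for (at in c("P", "O5'", "C4'", "C1'", "O2'"))
    expect_identical(mc3dqsar:::.atom_pos(s2, "A", 2, at),
                     mc3dqsar:::.atom_pos(s, "A", 2, at))
  expect_equal(superpose(s2, s)$rmsd, 0, tolerance = 1e-9)
  # determinism
  s3 <- substitute_base(s, 2, "U")
  expect_identical(s2$atoms, s3$atoms)
  # errors
  expect_error(substitute_base(s, 9, "A"), "no residue")
  expect_error(substitute_base(s, 1, "T"), "unknown base")
})

test_that("purine placed into a pyrimidine-sized gap clashes; pyrimidines fit", {
  pair <- wc_facing_pair()
  expect_equal(nrow(detect_clashes(pair)$pairs), 0L)
  cu <- substitute_base(pair, 2, "U")
  expect_equal(nrow(detect_clashes(cu)$pairs), 0L)
  gg <- substitute_base(substitute_base(pair, 1, "G"), 2, "G")
  rep <- detect_clashes(gg)
  expect_gt(nrow(rep$pairs), 0L)
  expect_lt(rep$worst_distance, 2.0)
  expect_true(all(rep$pairs$distance < 2.0))
})

test_that("clash detection honours its cutoff and exclusions", {
  s <- ladder("GA")
  expect_equal(nrow(detect_clashes(s)$pairs), 0L)       # well-formed geometry
  expect_equal(nrow(detect_clashes(s, cutoff = 0)$pairs), 0L)
  # two isolated atoms planted 1.0 A apart across residues
  two <- rna_structure("two", data.frame(
    chain = "A", resno = 1:2, base = "G", atom = "P",
    x = c(0, 1), y = 0, z = 0, stringsAsFactors = FALSE), validate = FALSE)
  rep <- detect_clashes(two)
  expect_equal(nrow(rep$pairs), 1L)
  expect_equal(rep$worst_distance, 1.0, tolerance = 1e-9)
  # the bonded O3'(i)-P(i+1) linkage is never a clash
  link <- rna_structure("link", data.frame(
    chain = "A", resno = 1:2, base = "G", atom = c("O3'", "P"),
    x = c(0, 1.6), y = 0, z = 0, stringsAsFactors = FALSE), validate = FALSE)
  expect_equal(nrow(detect_clashes(link)$pairs), 0L)
  # same-residue contacts are never clashes (covalent geometry)
  expect_equal(nrow(detect_clashes(s, cutoff = 1.6)$pairs), 0L)
})

test_that("superposition recovers rigid motions and reports RMSD", {
  s <- ladder("GACU")
  expect_equal(superpose(s, s)$rmsd, 0, tolerance = 1e-12)
  moved <- rigid_move(s, 50, c(7, 3, -4))
  sp <- superpose(moved, s)
  expect_lt(sp$rmsd, 1e-6)
  expect_lt(max_atom_shift(sp$structure, s), 1e-6)
  # pose invariance of the RMSD
  moved2 <- rigid_move(s, 160, c(-20, 4, 9))
  expect_equal(superpose(moved, s)$rmsd, superpose(moved2, s)$rmsd,
               tolerance = 1e-9)
  # residue mismatch is refused
  expect_error(superpose(ladder("GAC"), s), "residue count")
})

test_that("variant models apply exactly the requested substitutions", {
  s <- ladder("GACU")
  v0 <- variant_spec("seed-like", character(0), label = "active")
  m0 <- build_variant_model(s, v0)
  expect_equal(max_atom_shift(add_hydrogens(s), m0$structure), 0)
  expect_false(m0$clashed)
  v2 <- variant_spec("double", c("2" = "G", "4" = "C"), label = "inactive")
  m2 <- build_variant_model(s, v2)
  nt <- nucleotide_table(m2$structure)
  expect_identical(nt$base, c("G", "G", "C", "C"))
  # untouched residues identical to the protonated seed
  sh <- add_hydrogens(s)
  for (rn in c(1, 3))
    expect_identical(res_df(m2$structure, rn), res_df(sh, rn))
  expect_error(build_variant_model(s, variant_spec("bad", c("7" = "A"))),
               "residue 7")
})

test_that("variant tables parse substitution tokens and labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsubstitutions\tlabel\tnote",
               "seed\t\tactive\treference",
               "v1\t2U,4C\tinactive\t",
               "v2\t3G\tunknown\tassay pending"), f)
  vars <- read_variants(f)
  expect_length(vars, 3L)
  expect_identical(vars[[2]]$substitutions, c("2" = "U", "4" = "C"))
  expect_identical(vars[[1]]$substitutions, character(0))
  expect_identical(vars[[3]]$label, "unknown")
  expect_error(parse_substitutions("12X"), "malformed")
  expect_error(variant_spec("x", c("1" = "B")), "invalid base")
})
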