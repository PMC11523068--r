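# Torsion identification, dihedral measurement, label assembly and
# canonicalization.

test_that("identify_torsion_bonds implements the strict dialect", {
  # ethane: both atoms terminal
  expect_equal(nrow(identify_torsion_bonds(parse_smiles("CC"))), 0)

  # n-pentane: exactly the two inner bonds, checked against an exhaustive
  # application of the definition over all four bonds
  pent <- parse_smiles("CCCCC")
  tb <- identify_torsion_bonds(pent)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$a1, c(2L, 3L))
  expect_equal(tb$a2, c(3L, 4L))
  deg <- tabulate(c(pent$bonds$a1, pent$bonds$a2), 5)
  manual <- which(deg[pent$bonds$a1] >= 2 & deg[pent$bonds$a2] >= 2)
  expect_equal(nrow(tb), length(manual))

  # cyclohexane: all six ring bonds
  tb <- identify_torsion_bonds(parse_smiles("C1CCCCC1"))
  expect_equal(nrow(tb), 6)
  expect_true(all(tb$in_ring))

  # aromatic ring bonds are not torsions
  expect_equal(nrow(identify_torsion_bonds(parse_smiles("c1ccccc1"))), 0)

  # amide C-N: excluded in strict, admitted in permissive
  nma <- parse_smiles("CC(=O)NC")
  expect_equal(nrow(identify_torsion_bonds(nma, strict = TRUE)), 0)
  expect_equal(nrow(identify_torsion_bonds(nma, strict = FALSE)), 1)

  # deterministic order and repeatability
  teb <- parse_smiles("CCc1cc(CC)cc(CC)c1")
  expect_identical(identify_torsion_bonds(teb), identify_torsion_bonds(teb))
})

test_that("measure_dihedral handles planar and constructed cases", {
  # planar cis (eclipsed): 0 degrees
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(measure_dihedral(cis, 1:4), 0, tolerance = 1e-10)
  # planar trans: 180 degrees
  trans <- rbind(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(measure_dihedral(trans, 1:4), 180, tolerance = 1e-10)

  # butane built with its torsion driven to 60: re-measured 60
  but <- parse_smiles("CCCC")
  but$conformers <- list(tabstrings:::embed_tree(but))
  tors <- match_torsions(but, list())
  conf <- tabstrings:::set_torsion(but, but$conformers[[1]],
                                   tors[[1]]$quad, 60)
  expect_equal(measure_dihedral(conf, tors[[1]]$quad), 60, tolerance = 1e-6)

  # collinear triple is rejected
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(measure_dihedral(lin, 1:4), "collinear")
})

test_that("assign_state respects the wraparound bin and m = 1", {
  b <- default_bins()
  expect_equal(assign_state(60, b), bin_membership_oracle(60, b$boundaries))
  expect_equal(assign_state(0, b), 6)
  one <- derive_bins(synthetic_profile(1))
  for (a in c(0, 90.5, 180, 359.9)) expect_equal(assign_state(a, one), 1)
})

test_that("canonicalization picks the lowest-integer arrangement", {
  swap <- structure(list(perms = list(1:2, 2:1), n_positions = 2L),
                    class = "torsion_perm_group")
  expect_equal(canonicalize_states(c(2L, 1L), swap), c(1L, 2L))
  expect_equal(canonicalize_states(c(1L, 2L), swap), c(1L, 2L))
  # idempotent
  expect_equal(canonicalize_states(canonicalize_states(c(2L, 1L), swap), swap),
               c(1L, 2L))

  trivial <- structure(list(perms = list(1:3), n_positions = 3L),
                       class = "torsion_perm_group")
  expect_equal(canonicalize_states(c(3L, 1L, 2L), trivial), c(3L, 1L, 2L))

  # full S3: (3,1,2) -> sorted (1,2,3), the minimum over all 6 images
  perms <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L),
                c(3L,1L,2L), c(3L,2L,1L))
  s3 <- structure(list(perms = perms, n_positions = 3L),
                  class = "torsion_perm_group")
  expect_equal(canonicalize_states(c(3L, 1L, 2L), s3), c(1L, 2L, 3L))

  expect_error(canonicalize_states(c(1L, 2L, 3L), swap), "length")
})

test_that("chair and boat cyclohexane get different canonical labels", {
  cb <- build_fixture("cyclohexane_chair_boat")
  lib <- builtin_profile_library()
  tors <- match_torsions(cb, lib)
  grp <- induce_torsion_permutations(graph_automorphisms(cb), tors)
  chair <- tabs(cb, tors, grp, 1)
  boat <- tabs(cb, tors, grp, 2)
  expect_false(identical(chair$canonical, boat$canonical))
  # chair shows the two-valued alternating pattern: exactly 2 distinct states
  expect_length(unique(chair$states), 2)
  # determinism: same conformer, same label
  expect_identical(tabs(cb, tors, grp, 1)$canonical, chair$canonical)
})

test_that("butane rotamers at different bin centers differ in that digit", {
  but <- build_fixture("butane_rotamers")
  lib <- list(synthetic_profile(3))
  tors <- match_torsions(but, lib)
  expect_equal(tors[[1]]$bins$multiplicity, 3)
  grp <- induce_torsion_permutations(graph_automorphisms(but), tors)
  labs <- vapply(1:3, function(c) format_tabs(tabs(but, tors, grp, c)), "")
  expect_length(unique(labs), 3)   # 60, 180, 300 in a 3-fold profile
})

test_that("group_ensemble partitions conformers and reports coverage", {
  lib <- builtin_profile_library()

  # 10 copies of one conformer: one group of size 10
  but <- build_fixture("butane_rotamers")
  but$conformers <- rep(but$conformers[1], 10)
  g <- group_ensemble(but, lib)
  expect_length(g$groups, 1)
  expect_length(g$groups[[1]], 10)

  # exhaustive butane rotamers at the 3 bin centers: 3 groups
  but3 <- build_fixture("butane_rotamers")
  g3 <- group_ensemble(but3, lib)
  expect_length(g3$groups, 3)
  # every conformer in exactly one group
  expect_setequal(unlist(g3$groups), 1:3)

  # chair + boat: two groups
  cb <- build_fixture("cyclohexane_chair_boat")
  gcb <- group_ensemble(cb, lib)
  expect_length(gcb$groups, 2)

  # coverage is distinct labels / nTABS, in (0, 1]
  expect_equal(gcb$coverage, 2 / 15)
  expect_true(g3$coverage > 0 && g3$coverage <= 1)

  expect_error(group_ensemble(parse_smiles("CCCC"), lib), "conformer")
})

test_that("labeling performs exactly n x M dihedral measurements", {
  pent <- enumerate_rotamers(build_fixture("pentane"), list(synthetic_profile(3)))
  n <- n_conformers(pent)
  tors <- match_torsions(pent, list(synthetic_profile(3)))
  M <- length(tors)
  counter <- local({
    count <- 0L
    real <- measure_dihedral
    function(conf, quad) { count <<- count + 1L; real(conf, quad) }
  })
  local_mocked_bindings(measure_dihedral = counter, .package = "tabstrings")
  grp <- induce_torsion_permutations(graph_automorphisms(pent), tors)
  for (c in seq_len(n)) tabs(pent, tors, grp, c)
  expect_equal(environment(counter)$count, n * M)
})

test_that("canonical TABS are invariant under atom renumbering", {
  lib <- builtin_profile_library()
  set.seed(42)
  for (name in c("pentane", "butane_rotamers", "symmetric_two_torsion_chain",
                 "cyclohexane_chair_boat")) {
    mol <- build_fixture(name)
    for (trial in 1:10) {
      perm <- sample(length(mol$elements))
      res <- realigned_canonical(mol, perm, lib)
      expect_equal(res$realigned, res$original,
                   info = sprintf("%s trial %d", name, trial))
    }
  }
})

test_that("distinct labels never exceed the naive label space (pigeonhole)", {
  lib <- list(synthetic_profile(3))
  pent <- enumerate_rotamers(build_fixture("pentane"), lib)
  tors <- match_torsions(pent, lib)
  grp <- induce_torsion_permutations(graph_automorphisms(pent), tors)
  labs <- vapply(seq_len(n_conformers(pent)), function(c)
    format_tabs(tabs(pent, tors, grp, c)), "")
  naive <- prod(vapply(tors, function(t) t$bins$multiplicity, 1L))
  expect_lte(length(unique(labs)), naive)
})
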