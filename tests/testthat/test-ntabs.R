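# Ring classification, state-space collapse, Burnside counting.

lib <- builtin_profile_library()

test_that("classify_rings separates aromatic, small/medium and macrocyclic rings", {
  expect_equal(nrow(classify_rings(parse_smiles("c1ccccc1"))), 0)

  ch <- classify_rings(parse_smiles("C1CCCCC1"))
  expect_equal(ch$size, 6)
  expect_equal(ch$class, "small_medium")

  cd <- classify_rings(parse_smiles("C1CCCCCCCCCCC1"))
  expect_equal(cd$size, 12)
  expect_equal(cd$class, "macrocycle")

  big <- parse_smiles(paste0("C1", strrep("C", 16), "1"))  # 17-ring
  expect_warning(classify_rings(big), "not recommended")
})

test_that("state_space collapses rings and keeps acyclic torsions", {
  # n-butane with a 3-fold profile: one singleton position
  but <- parse_smiles("CCCC")
  sp <- state_space(but, match_torsions(but, list(synthetic_profile(3))))
  expect_equal(sp$positions$multiplicity, 3)
  expect_equal(sp$positions$kind, "torsion")

  # cyclohexane: a single ring position worth 15 states
  ch <- parse_smiles("C1CCCCC1")
  sp <- state_space(ch, match_torsions(ch, lib))
  expect_equal(sp$positions$multiplicity, 15)
  expect_equal(sp$positions$kind, "ring")
  expect_true(all(!is.na(sp$torsion_map)))

  # ethylcyclohexane: ring position + one chain torsion
  ec <- parse_smiles("CCC1CCCCC1")
  tors <- match_torsions(ec, lib)
  sp <- state_space(ec, tors)
  expect_setequal(sp$positions$kind, c("ring", "torsion"))
  expect_setequal(sp$positions$multiplicity, c(15, 3))
})

test_that("ntabs_naive is the product of multiplicities", {
  # six ring torsions at 3 bins each: the raw label space is 3^6 = 729
  tors <- match_torsions(parse_smiles("C1CCCCC1"), lib)
  raw <- vapply(tors, function(t) t$bins$multiplicity, 1L)
  expect_equal(ntabs_naive(raw), 729)

  expect_equal(ntabs_naive(numeric(0)), 1)   # rigid molecule
  expect_equal(ntabs_naive(c(2, 2, 2, 3, 4)), 96)
  expect_error(ntabs_naive(c(3, 0)), ">= 1")
})

test_that("ntabs wires the ring tables through (cyclohexane 15, cyclododecane 16549)", {
  expect_equal(ntabs(parse_smiles("C1CCCCC1"), lib)$ntabs, 15)
  expect_equal(ntabs(parse_smiles("C1CCCCCCCCCCC1"), lib)$ntabs, 16549)
  # a rigid aromatic: exactly one conformer class
  expect_equal(ntabs(parse_smiles("c1ccccc1"), lib)$ntabs, 1)
})

test_that("Burnside count matches closed forms and reduces correctly", {
  # trivial group: naive product
  expect_equal(burnside_count(c(3, 4), list(1:2)), 12)
  # 2 positions multiplicity m, swap group: m(m+1)/2
  for (m in c(2, 3, 6)) {
    expect_equal(burnside_count(c(m, m), list(1:2, 2:1)), m * (m + 1) / 2)
  }
  # 3 positions of multiplicity 2 under S3: 4 orbits (multisets of {1,2}^3)
  s3 <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L),
             c(3L,1L,2L), c(3L,2L,1L))
  expect_equal(burnside_count(c(2, 2, 2), s3), 4)
  # mismatched multiplicity within a cycle is an internal error
  expect_error(burnside_count(c(2, 3), list(1:2, 2:1)), "cycle")
})

test_that("Burnside equals explicit orbit enumeration on random groups", {
  set.seed(7)
  for (trial in 1:60) {
    P <- sample(2:6, 1)
    mult <- sample(1:6, P, replace = TRUE)
    perms <- random_perm_group(mult)
    enum <- enumerate_orbits(mult, perms)
    expect_equal(burnside_count(mult, perms), enum$n_orbits)
    # orbit sizes sum to the naive product
    expect_equal(sum(enum$orbit_sizes), prod(mult))
    if (prod(mult) <= 300) {
      expect_equal(enum$n_orbits, orbit_count_bruteforce(mult, perms))
    }
  }
})

test_that("the orbit decomposition satisfies the counting identities", {
  eth <- build_fixture("symmetric_two_torsion_chain")
  res <- ntabs(eth, lib)
  # two 6-state positions under swap: 6*7/2 = 21
  expect_equal(res$ntabs, 21)
  expect_equal(res$ntabs_naive, 36)
  expect_equal(sum(res$orbit_sizes), res$ntabs_naive)
  expect_equal(length(res$orbit_sizes), res$ntabs)
  expect_lte(res$ntabs, res$ntabs_naive)
  # no symmetry, no rings: naive == reduced
  asym <- parse_smiles("CCCCO")
  r2 <- ntabs(asym, lib)
  expect_equal(r2$ntabs, r2$ntabs_naive)
})

test_that("nTABS upper-bounds the distinct labels of exhaustive rotamer grids", {
  prof <- list(synthetic_profile(3))
  for (smi in c("CCCC", "CCCCC", "CCCCCC")) {
    mol <- enumerate_rotamers(parse_smiles(smi), prof)
    g <- group_ensemble(mol, prof)
    expect_lte(length(g$groups), g$ntabs$ntabs)
  }
  # diethyl ether: default bins, 36 rotamers, 21 canonical labels
  eth <- enumerate_rotamers(build_fixture("symmetric_two_torsion_chain"), lib)
  g <- group_ensemble(eth, lib)
  expect_equal(length(g$groups), 21)
  expect_equal(g$ntabs$ntabs, 21)
})

test_that("nTABS is invariant under atom renumbering", {
  set.seed(11)
  for (smi in c("CCCCC", "CCOCC", "C1CCCCC1", "CCc1cc(CC)cc(CC)c1")) {
    mol <- parse_smiles(smi)
    ref <- ntabs(mol, lib)$ntabs
    for (k in 1:5) {
      perm <- sample(length(mol$elements))
      expect_equal(ntabs(permute_atoms(mol, perm), lib)$ntabs, ref, info = smi)
    }
  }
})

test_that("flexibility categories follow the 500 / 10,000 cuts", {
  expect_equal(flexibility_category(499), "low")
  expect_equal(flexibility_category(500), "medium")
  expect_equal(flexibility_category(9999), "medium")
  expect_equal(flexibility_category(10000), "high")
  expect_error(flexibility_category(0), ">= 1")
})

test_that("symmetric multi-ring molecules reduce over ring positions", {
  # bicyclohexyl: two equivalent 6-rings (15 states each) joined by one
  # rotatable bond matching the acyclic alkane 3-fold profile; the swap
  # automorphism exchanges the ring positions and fixes the torsion
  bch <- parse_smiles("C1CCCCC1C1CCCCC1")
  res <- ntabs(bch, lib)
  expect_equal(res$ntabs_naive, 15 * 15 * 3)
  # Burnside with group {id, swap-rings}: (15*15*3 + 15*3)/2
  expect_equal(res$ntabs, (15 * 15 * 3 + 15 * 3) / 2)
})
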