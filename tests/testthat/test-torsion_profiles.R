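# Fourier torsion potentials, bin derivation, library I/O and matching.

test_that("evaluate_potential follows the closed form and is periodic", {
  zero <- torsion_profile("[CX4:1][CX4:2][CX4:3][CX4:4]", rep(0, 6))
  expect_equal(evaluate_potential(zero, 123.4), 0)

  one <- torsion_profile("[CX4:1][CX4:2][CX4:3][CX4:4]",
                         c(1, 0, 0, 0, 0, 0))
  expect_equal(evaluate_potential(one, 0), 2.0)

  three <- synthetic_profile(3)
  expect_equal(evaluate_potential(three, c(60, 180, 300)), c(0, 0, 0),
               tolerance = 1e-12)

  # periodicity on a mixed profile
  mixed <- torsion_profile("[CX4:1][CX4:2][CX4:3][CX4:4]",
                           K = c(0.5, 1.2, 0.8, 0, 0.3, 0.1),
                           s = c(-1, 1, 1, 1, -1, 1))
  phi <- seq(-720, 720, by = 7.3)
  expect_equal(evaluate_potential(mixed, phi),
               evaluate_potential(mixed, phi + 360), tolerance = 1e-9)

  expect_error(evaluate_potential(mixed, NaN), "non-finite")
})

test_that("profile construction enforces the 6-term contract", {
  expect_error(torsion_profile("[C:1][C:2][C:3][C:4]", K = c(1, 0, 0)),
               "6")
  expect_error(torsion_profile("[C:1][C:2][C:3][C:4]", K = rep(0, 6),
                               s = c(0, 1, 1, 1, 1, 1)),
               "-1 or \\+1")
})

test_that("derive_bins recovers extrema of pure n-fold terms (closed-form check)", {
  for (n in 1:6) {
    bins <- derive_bins(synthetic_profile(n))
    expect_equal(bins$multiplicity, n)
    # analytic positions for K (1 + cos n phi)
    expect_equal(bins$centers, (2 * seq_len(n) - 1) * 180 / n, tolerance = 1e-5)
    expect_equal(bins$boundaries, (seq_len(n) - 1) * 360 / n, tolerance = 1e-5)
  }
})

test_that("derive_bins agrees with the dense grid-scan oracle", {
  profiles <- list(
    synthetic_profile(3),
    torsion_profile("[C:1][C:2][C:3][C:4]", c(0, 1, 0, 0, 0, 0),
                    c(1, -1, 1, 1, 1, 1)),                      # minima 90/270
    torsion_profile("[C:1][C:2][C:3][C:4]", c(0.4, 0, 1, 0, 0, 0),
                    c(1, 1, 1, 1, 1, 1)),                       # skewed 3-fold
    torsion_profile("[C:1][C:2][C:3][C:4]", c(0, 0.7, 0, 0, 0, 0.2),
                    c(1, 1, 1, 1, 1, -1))
  )
  for (p in profiles) {
    bins <- derive_bins(p)
    oracle <- grid_extrema_oracle(p)
    expect_equal(length(bins$centers), length(oracle$minima))
    # centers are bin-ordered (wraparound bin last); compare as sorted sets
    expect_equal(sort(bins$centers), sort(oracle$minima), tolerance = 0.02)
    expect_equal(sort(bins$boundaries), sort(oracle$maxima), tolerance = 0.02)
    # minima and maxima alternate: equal counts is implied, check the order
    all_ext <- sort(c(bins$centers, bins$boundaries))
    kinds <- all_ext %in% bins$centers
    expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  }
})

test_that("K2 = 1, s2 = -1 yields minima at 0/180 (2-fold with shifted phase)", {
  p <- torsion_profile("[C:1][C:2][C:3][C:4]", c(0, 1, 0, 0, 0, 0),
                       c(1, -1, 1, 1, 1, 1))
  bins <- derive_bins(p)
  expect_equal(bins$multiplicity, 2)
  # V = 1 - cos(2 phi): minima where cos(2 phi) = 1
  expect_equal(sort(bins$centers %% 360), c(0, 180), tolerance = 1e-5)
  expect_equal(sort(bins$boundaries), c(90, 270), tolerance = 1e-5)
})

test_that("flat profiles are rejected as unbinnable", {
  flat <- torsion_profile("[C:1][C:2][C:3][C:4]", rep(0, 6))
  expect_error(derive_bins(flat), "unbinnable")
})

test_that("default bins are the six-state 30..330 partition", {
  b <- default_bins()
  expect_equal(b$multiplicity, 6)
  expect_equal(b$boundaries, c(30, 90, 150, 210, 270, 330))
  expect_equal(b$centers, c(60, 120, 180, 240, 300, 0))
  expect_equal(assign_state(0, b), 6)     # wraparound bin owns 330 -> 30
  expect_equal(assign_state(30, b), 1)    # boundary belongs to its upper bin
  expect_equal(assign_state(60, b), 1)
  expect_equal(assign_state(329.999, b), 5)
  expect_equal(assign_state(330, b), 6)
})

test_that("every angle maps to exactly one bin (partition sweep)", {
  for (bins in list(default_bins(), derive_bins(synthetic_profile(3)),
                    derive_bins(synthetic_profile(1)))) {
    sweep_angles <- seq(0, 359.9, by = 0.1)
    states <- vapply(sweep_angles, assign_state, 1L, bins = bins)
    expect_true(all(states >= 1 & states <= bins$multiplicity))
    oracle <- vapply(sweep_angles, bin_membership_oracle, 1L,
                     boundaries = bins$boundaries)
    # the oracle numbers bins 1..m-1 plus wraparound m; identical when the
    # first boundary is 0, otherwise angles below boundary 1 are bin m
    expect_equal(states, oracle)
  }
})

test_that("profile library round-trips and rejects malformed records", {
  lib <- list(
    torsion_profile("[CX4:1][CX4:2]!@[CX4:3][CX4:4]",
                    c(0, 0, 1, 0, 0, 0), rep(1L, 6), tag = "alkane")
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_library(lib, path)
  back <- load_profile_library(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$pattern, lib[[1]]$pattern)
  expect_equal(back[[1]]$K, lib[[1]]$K)
  expect_equal(back[[1]]$s, lib[[1]]$s)

  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("[]", empty)
  expect_length(load_profile_library(empty), 0)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"smarts": "[C:1][C:2][C:3][C:4]", "K": [0,1,0,0,0,0],
               "s": [1,0,1,1,1,1], "tag": "broken"}]', bad)
  expect_error(load_profile_library(bad), "record 1")

  nosmarts <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"smarts": "[C:1][C:2][C:3]", "K": [0,1,0,0,0,0],
               "s": [1,1,1,1,1,1]}]', nosmarts)
  expect_error(load_profile_library(nosmarts), "4 bracket atoms")
})

test_that("match_torsions applies the library hierarchy and default fallback", {
  lib <- builtin_profile_library()

  # n-butane with an empty library: one torsion, default 6 bins
  but <- parse_smiles("CCCC")
  mt <- match_torsions(but, list())
  expect_length(mt, 1)
  expect_equal(mt[[1]]$bins$multiplicity, 6)
  expect_equal(mt[[1]]$bins$boundaries, c(30, 90, 150, 210, 270, 330))
  expect_null(mt[[1]]$profile)

  # ethane: no rotatable bond
  expect_length(match_torsions(parse_smiles("CC"), lib), 0)

  # cyclohexane with the in-ring 3-fold pattern: 6 matched ring torsions
  ch <- parse_smiles("C1CCCCC1")
  mt <- match_torsions(ch, lib)
  expect_length(mt, 6)
  expect_true(all(vapply(mt, function(t) t$context, "") == "small_ring"))
  expect_true(all(vapply(mt, function(t) t$ring_size, 1L) == 6L))
  expect_true(all(vapply(mt, function(t) t$bins$multiplicity, 1L) == 3L))
  # independent count: ring bonds of the 6-ring
  expect_equal(length(mt), sum(identify_torsion_bonds(ch)$in_ring))

  # determinism
  mt2 <- match_torsions(ch, lib)
  expect_identical(mt, mt2)

  # first match wins: two patterns both matching butane's central bond
  lib2 <- list(
    torsion_profile("[CX4:1][CX4:2]!@[CX4:3][CX4:4]",
                    c(0, 1, 0, 0, 0, 0), rep(1L, 6), tag = "first"),
    torsion_profile("[CX4:1][CX4:2]!@[CX4:3][CX4:4]",
                    c(0, 0, 1, 0, 0, 0), rep(1L, 6), tag = "second")
  )
  mt3 <- match_torsions(but, lib2)
  expect_equal(mt3[[1]]$profile$tag, "first")
  expect_equal(mt3[[1]]$bins$multiplicity, 2)
})
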