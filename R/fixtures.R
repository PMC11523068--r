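# ---------------------------------------------------------------------------
# Programmatic fixtures: every test input is built in code, bit-for-bit
# reproducible.  Chains are embedded from idealized internal coordinates
# (C-C 1.54 A, angles 111 deg) and driven to target torsions exactly;
# rings are closed by a light relaxation of an idealized pattern.
# ---------------------------------------------------------------------------

FIXTURE_CATALOG <- c("cyclohexane_chair_boat", "butane_rotamers", "pentane",
                     "triethylbenzene", "cyclododecane",
                     "symmetric_two_torsion_chain")

#' Build a named fixture molecule (with conformers where meaningful)
#'
#' Catalog:
#' \describe{
#'   \item{cyclohexane_chair_boat}{cyclohexane with 2 conformers: chair
#'     (ring torsions alternating +55/-55 deg) and boat (pattern
#'     0, +55, -55, 0, +55, -55), idealized sp3 geometry lightly relaxed
#'     to close the ring.}
#'   \item{butane_rotamers}{n-butane with 3 conformers at the 3-fold bin
#'     centers 60, 180, 300 deg.}
#'   \item{pentane}{n-pentane, single all-anti conformer.}
#'   \item{triethylbenzene}{1,3,5-triethylbenzene, topology only.}
#'   \item{cyclododecane}{12-membered carbocycle, topology only.}
#'   \item{symmetric_two_torsion_chain}{diethyl ether: exactly two
#'     symmetry-equivalent torsions (the C-O bonds) whose induced group is
#'     \{id, swap\}; single conformer at (180, 180).}
#' }
#'
#' @param name fixture name from the catalog.
#' @return a `tabs_mol`.
#' @export
build_fixture <- function(name) {
  switch(name,
    cyclohexane_chair_boat = fixture_cyclohexane(),
    butane_rotamers = fixture_chain("CCCC", "butane",
                                    torsion_grids = list(c(60), c(180), c(300))),
    pentane = fixture_chain("CCCCC", "pentane",
                            torsion_grids = list(c(180, 180))),
    triethylbenzene = parse_smiles("CCc1cc(CC)cc(CC)c1", name = "1,3,5-triethylbenzene"),
    cyclododecane = parse_smiles("C1CCCCCCCCCCC1", name = "cyclododecane"),
    symmetric_two_torsion_chain = fixture_chain("CCOCC", "diethyl ether",
                                                torsion_grids = list(c(180, 180))),
    stop("unknown fixture '", name, "'; catalog: ",
         paste(FIXTURE_CATALOG, collapse = ", "))
  )
}

# chain fixture: embed all-anti, then drive the identified torsions to the
# requested values; one conformer per torsion vector
fixture_chain <- function(smiles, name, torsion_grids) {
  mol <- parse_smiles(smiles, name = name)
  torsions <- match_torsions(mol, list())
  base <- embed_tree(mol)
  confs <- lapply(torsion_grids, function(targets) {
    stopifnot(length(targets) == length(torsions))
    conf <- base
    for (t in seq_along(torsions))
      conf <- set_torsion(mol, conf, torsions[[t]]$quad, targets[t])
    conf
  })
  mol$conformers <- confs
  mol
}

#' Set the acyclic torsions of a molecule's conformer to exact values
#'
#' @param mol a `tabs_mol` with at least one conformer.
#' @param targets numeric vector, degrees, one per torsion of
#'   [match_torsions()] order (acyclic torsions only).
#' @param conf_id conformer to start from.
#' @return new conformer matrix.
#' @export
drive_torsions <- function(mol, targets, conf_id = 1L) {
  torsions <- match_torsions(mol, list())
  stopifnot(length(targets) == length(torsions))
  conf <- mol$conformers[[conf_id]]
  for (t in seq_along(torsions))
    conf <- set_torsion(mol, conf, torsions[[t]]$quad, targets[t])
  conf
}

# -- cyclohexane chair/boat -------------------------------------------------

fixture_cyclohexane <- function() {
  mol <- parse_smiles("C1CCCCC1", name = "cyclohexane")
  chair <- relax_ring(ring_targets(c(55, -55, 55, -55, 55, -55)))
  boat <- relax_ring(ring_targets(c(0, 55, -55, 0, 55, -55)))
  mol$conformers <- list(chair, boat)
  mol
}

ring_targets <- function(torsions, n = length(torsions),
                         bond = 1.54, angle = 111) {
  list(n = n, torsions = torsions, bond = bond, angle = angle)
}

# Build an n-ring by NeRF from the target internal coordinates, then
# minimize deviations from target bonds/angles/torsions including the
# ring-closure terms (the idealized pattern cannot close exactly).
relax_ring <- function(tgt) {
  n <- tgt$n
  conf <- matrix(0, n, 3)
  conf[1, ] <- c(0, 0, 0)
  conf[2, ] <- c(tgt$bond, 0, 0)
  th <- (180 - tgt$angle) * pi / 180
  conf[3, ] <- conf[2, ] + tgt$bond * c(cos(pi - th) * -1, sin(th), 0)
  for (k in 4:n) {
    conf[k, ] <- nerf_place(conf[k - 3, ], conf[k - 2, ], conf[k - 1, ],
                            tgt$bond, tgt$angle, tgt$torsions[k - 3])
  }
  obj <- function(par) {
    x <- matrix(par, n, 3)
    e <- 0
    for (k in 1:n) {
      k2 <- k %% n + 1; k3 <- (k + 1) %% n + 1; k4 <- (k + 2) %% n + 1
      d <- sqrt(sum((x[k2, ] - x[k, ])^2))
      e <- e + 100 * (d - tgt$bond)^2
      v1 <- x[k, ] - x[k2, ]; v2 <- x[k3, ] - x[k2, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      e <- e + 50 * (acos(pmin(1, pmax(-1, cosang))) * 180 / pi - tgt$angle)^2 / 100
      phi <- measure_dihedral(x, c(k, k2, k3, k4))
      diff <- circular_diff(phi, tgt$torsions[k] %% 360)
      e <- e + 1 * (diff / 10)^2
    }
    e
  }
  res <- stats::optim(as.vector(conf), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  matrix(res$par, n, 3)
}

circular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  if (d > 180) d <- 360 - d
  d
}

#' Pure n-fold synthetic torsion profile
#'
#' A single Fourier term K_n (1 + cos(n phi)): its minima sit at the
#' analytic positions (2k+1) * 180/n and [derive_bins()] yields exactly n
#' bins.
#'
#' @param n multiplicity, 1..6.
#' @param K force constant (> 0).
#' @param pattern SMARTS the profile should match (default: acyclic
#'   aliphatic C-C).
#' @return a `torsion_profile`.
#' @export
synthetic_profile <- function(n, K = 1,
                              pattern = "[CX4:1][CX4:2]!@[CX4:3][CX4:4]") {
  if (!n %in% 1:6) stop("multiplicity must be in 1..6")
  if (K <= 0) stop("force constant must be positive")
  Kv <- numeric(6); Kv[n] <- K
  torsion_profile(pattern, Kv, rep(1L, 6), tag = sprintf("synthetic-%dfold", n))
}

#' Exhaustively enumerate bin-center rotamers
#'
#' One conformer per combination of bin centers over all (acyclic)
#' torsions; the oracle for the upper-bound property of nTABS.
#'
#' @param mol a `tabs_mol` with one starting conformer and only acyclic
#'   torsions.
#' @param library profile library used to bin the torsions.
#' @param max_states refusal guard on the product of multiplicities.
#' @return the molecule with one conformer per rotamer combination.
#' @export
enumerate_rotamers <- function(mol, library = list(), max_states = 1e5) {
  torsions <- match_torsions(mol, library)
  if (any(vapply(torsions, function(t) t$context != "acyclic", TRUE)))
    stop("enumerate_rotamers handles acyclic torsions only")
  if (n_conformers(mol) == 0) {
    mol$conformers <- list(embed_tree(mol))
  }
  mults <- vapply(torsions, function(t) t$bins$multiplicity, 1L)
  if (length(mults) == 0) return(mol)
  if (prod(mults) > max_states)
    stop("state space too large to enumerate (", prod(mults), " rotamers)")
  grid <- expand.grid(lapply(torsions, function(t) t$bins$centers),
                      KEEP.OUT.ATTRS = FALSE)
  base <- mol$conformers[[1]]
  confs <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    conf <- base
    for (t in seq_along(torsions))
      conf <- set_torsion(mol, conf, torsions[[t]]$quad, grid[r, t])
    confs[[r]] <- conf
  }
  mol$conformers <- confs
  mol
}
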