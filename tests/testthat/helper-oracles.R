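# Independent oracles used across the suite.

# dense grid scan of the closed-form potential: extrema located by local
# comparison, independent of the derivative-based implementation
grid_extrema_oracle <- function(profile, step = 0.01) {
  grid <- seq(0, 360 - step, by = step)
  v <- evaluate_potential(profile, grid)
  n <- length(v)
  prev <- c(v[n], v[-n])
  nxt <- c(v[-1], v[1])
  list(minima = grid[v < prev & v < nxt],
       maxima = grid[v > prev & v > nxt])
}

# interval-membership oracle for circular half-open bins
bin_membership_oracle <- function(angle, boundaries) {
  m <- length(boundaries)
  for (k in seq_len(m - 1)) {
    if (angle >= boundaries[k] && angle < boundaries[k + 1]) return(k)
  }
  m   # wraparound bin
}

# igraph automorphism count with bond colors via edge subdivision
igraph_automorphism_count <- function(mol) {
  nb <- nrow(mol$bonds)
  na <- length(mol$elements)
  el <- rbind(cbind(mol$bonds$a1, na + seq_len(nb)),
              cbind(mol$bonds$a2, na + seq_len(nb)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  vc <- c(as.integer(factor(paste(mol$elements, mol$charges))),
          100L + as.integer(factor(paste(mol$bonds$order, mol$bonds$aromatic))))
  as.numeric(igraph::count_automorphisms(g, colors = vc)$group_size)
}

# brute-force orbit count by canonical-representative hashing over the
# full product space (list-based, independent of the vectorized version)
orbit_count_bruteforce <- function(mult, perms) {
  P <- length(mult)
  if (P == 0) return(1)
  states <- do.call(expand.grid, lapply(mult, seq_len))
  reps <- apply(states, 1, function(s) {
    imgs <- vapply(perms, function(p) {
      img <- integer(P); img[p] <- s
      paste(img, collapse = ",")
    }, "")
    min(imgs)
  })
  length(unique(reps))
}

# random mult-preserving permutation group on P positions
random_perm_group <- function(mult) {
  P <- length(mult)
  gens <- list()
  for (g in 1:2) {
    p <- seq_len(P)
    # swap two positions with equal multiplicity, if any
    classes <- split(seq_len(P), mult)
    cl <- classes[lengths(classes) >= 2]
    if (length(cl)) {
      pick <- cl[[sample.int(length(cl), 1)]]
      sw <- sample(pick, 2)
      p[sw] <- rev(p[sw])
    }
    gens[[g]] <- p
  }
  tabstrings:::close_permutation_group(gens)
}

# realign a canonical label computed on a renumbered molecule back to the
# original torsion order, then canonicalize in the original group
realigned_canonical <- function(mol, perm, library) {
  tors <- match_torsions(mol, library)
  autos <- graph_automorphisms(mol)
  grp <- induce_torsion_permutations(autos, tors)
  pm <- permute_atoms(mol, perm)
  tors_p <- match_torsions(pm, library)
  grp_p <- induce_torsion_permutations(graph_automorphisms(pm), tors_p)
  bonds_p <- vapply(tors_p, function(t) paste(sort(t$bond), collapse = "-"), "")
  lab_orig <- vapply(seq_len(n_conformers(mol)), function(ci)
    format_tabs(tabs(mol, tors, grp, ci)), "")
  lab_re <- vapply(seq_len(n_conformers(pm)), function(ci) {
    raw_p <- tabs(pm, tors_p, grp_p, ci)$states
    realigned <- vapply(seq_along(tors), function(t) {
      key <- paste(sort(perm[tors[[t]]$bond]), collapse = "-")
      raw_p[match(key, bonds_p)]
    }, 1L)
    format_tabs(canonicalize_states(realigned, grp))
  }, "")
  list(original = lab_orig, realigned = lab_re)
}
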