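# ---------------------------------------------------------------------------
# Topological symmetry: graph automorphisms and the permutation group they
# induce on torsion (TABS digit) positions.
#
# Automorphisms are substructure matches of the molecule onto itself that
# preserve element, charge, aromaticity, bond order and specified
# tetrahedral stereocenters.  Unspecified stereocenters match both ways.
# The search is a backtracking matcher over color-refined vertex classes;
# molecules at desk scale have tiny automorphism groups, and a hard cap
# guards against pathological inputs.
# ---------------------------------------------------------------------------

#' Graph automorphisms of a molecule
#'
#' @param mol a `tabs_mol`.
#' @param max_count cap on the number of automorphisms collected; if the
#'   cap is reached a warning is emitted and a partial (but
#'   identity-containing) list returned.
#' @return list of integer permutations p (atom i maps to p[i]); always
#'   contains the identity.
#' @examples
#' length(graph_automorphisms(parse_smiles("c1ccccc1")))  # 12 for benzene
#' @export
graph_automorphisms <- function(mol, max_count = 10000L) {
  n <- n_atoms(mol)
  if (n == 0) return(list(seq_len(0)))
  color <- canonical_ranks(mol)
  adj <- adjacency(mol)
  bond_key <- function(i, j) {
    b <- bond_index(mol, i, j)
    if (length(b) == 0) return(NA_real_)
    mol$bonds$order[b] + if (isTRUE(mol$bonds$aromatic[b])) 0.5 else 0
  }
  # precompute bond keys in a matrix for speed
  bk <- matrix(NA_real_, n, n)
  for (b in seq_len(n_bonds(mol))) {
    key <- mol$bonds$order[b] + if (isTRUE(mol$bonds$aromatic[b])) 0.5 else 0
    bk[mol$bonds$a1[b], mol$bonds$a2[b]] <- key
    bk[mol$bonds$a2[b], mol$bonds$a1[b]] <- key
  }
  results <- list()
  capped <- FALSE
  mapping <- integer(n)     # 0 = unassigned
  used <- logical(n)
  # order atoms for assignment: rarest color class first, then by degree
  ord <- order(ave(color, color, FUN = length), -heavy_degree(mol))

  recurse <- function(pos) {
    if (capped) return()
    if (pos > n) {
      if (stereo_consistent(mol, mapping, adj)) {
        results[[length(results) + 1L]] <<- mapping
        if (length(results) >= max_count) capped <<- TRUE
      }
      return()
    }
    v <- ord[pos]
    for (w in which(color == color[v] & !used)) {
      ok <- TRUE
      for (u in adj[[v]]) {
        if (mapping[u] != 0L) {
          if (!identical(bk[v, u], bk[w, mapping[u]])) { ok <- FALSE; break }
        }
      }
      if (ok && length(adj[[v]]) != length(adj[[w]])) ok <- FALSE
      if (ok) {
        # mapped neighbors of w must all be images of neighbors of v
        for (u2 in adj[[w]]) {
          pre <- which(mapping == u2)
          if (length(pre) && !(pre %in% adj[[v]])) { ok <- FALSE; break }
        }
      }
      if (ok) {
        mapping[v] <<- w; used[w] <<- TRUE
        recurse(pos + 1L)
        mapping[v] <<- 0L; used[w] <<- FALSE
        if (capped) return()
      }
    }
  }
  recurse(1L)
  if (capped) warning("automorphism cap (", max_count, ") reached; group may be incomplete")
  if (length(results) == 0) results <- list(seq_len(n))   # defensive
  results
}

# specified tetrahedral centers must map to centers of consistent parity:
# even neighbor permutation -> same tag, odd -> opposite tag
stereo_consistent <- function(mol, mapping, adj) {
  centers <- which(!is.na(mol$stereo))
  for (a in centers) {
    b <- mapping[a]
    if (is.na(mol$stereo[b])) return(FALSE)
    nb_a <- adj[[a]]
    nb_b <- adj[[b]]
    if (length(nb_a) < 3) next
    img <- mapping[nb_a]
    perm <- match(img, nb_b)
    if (any(is.na(perm))) return(FALSE)
    even <- permutation_sign(perm) > 0
    same <- mol$stereo[a] == mol$stereo[b]
    if (even != same) return(FALSE)
  }
  TRUE
}

permutation_sign <- function(p) {
  n <- length(p)
  visited <- logical(n)
  sign <- 1L
  for (i in seq_len(n)) {
    if (visited[i]) next
    j <- i; len <- 0L
    while (!visited[j]) { visited[j] <- TRUE; j <- p[j]; len <- len + 1L }
    if (len %% 2 == 0) sign <- -sign
  }
  sign
}

#' Induce torsion-position permutations from atom automorphisms
#'
#' Each automorphism maps every torsion's central bond onto some bond; if
#' all images are themselves torsion bonds, the automorphism induces a
#' permutation of digit positions, which enters the group.  Automorphisms
#' mapping a torsion bond onto a non-torsion bond are discarded with a
#' warning (they indicate inconsistent profile matching).  The collected
#' permutations are closed under composition.
#'
#' @param automorphisms list of atom permutations from
#'   [graph_automorphisms()].
#' @param torsions a `matched_torsions` object (fixed digit order).
#' @return an object of class `torsion_perm_group`: list with
#'   `perms` (list of integer position permutations, identity first) and
#'   `n_positions`.
#' @export
induce_torsion_permutations <- function(automorphisms, torsions) {
  M <- length(torsions)
  bonds <- vapply(torsions, function(t) paste(sort(t$bond), collapse = "-"), "")
  perms <- list()
  seen <- character(0)
  dropped <- 0L
  for (sigma in automorphisms) {
    img <- integer(M)
    ok <- TRUE
    for (t in seq_len(M)) {
      jk <- sort(sigma[torsions[[t]]$bond])
      pos <- match(paste(jk, collapse = "-"), bonds)
      if (is.na(pos)) { ok <- FALSE; break }
      img[t] <- pos
    }
    if (!ok) { dropped <- dropped + 1L; next }
    key <- paste(img, collapse = ",")
    if (!key %in% seen) {
      # a digit position may only map to a position with identical bins
      comp <- vapply(seq_len(M), function(t)
        identical(torsions[[t]]$bins$boundaries, torsions[[img[t]]]$bins$boundaries), TRUE)
      if (!all(comp)) { dropped <- dropped + 1L; next }
      seen <- c(seen, key)
      perms[[length(perms) + 1L]] <- img
    }
  }
  if (dropped > 0)
    warning(dropped, " automorphism(s) mapped a torsion bond onto a ",
            "non-torsion bond or incompatible bins and were discarded")
  if (length(perms) == 0) perms <- list(seq_len(M))
  perms <- close_permutation_group(perms)
  structure(list(perms = perms, n_positions = M), class = "torsion_perm_group")
}

#' @export
print.torsion_perm_group <- function(x, ...) {
  cat(sprintf("<torsion_perm_group: order %d on %d position(s)>\n",
              length(x$perms), x$n_positions))
  invisible(x)
}

# explicit closure under composition (and hence inverse, the group being
# finite); identity is guaranteed present
close_permutation_group <- function(perms, cap = 100000L) {
  M <- length(perms[[1]])
  id <- seq_len(M)
  keys <- vapply(perms, paste, "", collapse = ",")
  perms <- perms[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  if (!paste(id, collapse = ",") %in% keys) {
    perms <- c(list(id), perms)
    keys <- c(paste(id, collapse = ","), keys)
  }
  repeat {
    added <- FALSE
    for (p in perms) {
      for (q in perms) {
        r <- p[q]
        key <- paste(r, collapse = ",")
        if (!key %in% keys) {
          perms[[length(perms) + 1L]] <- r
          keys <- c(keys, key)
          added <- TRUE
          if (length(perms) > cap) stop("permutation group closure exceeded cap")
        }
      }
      if (added) break
    }
    if (!added) break
  }
  # deterministic order: identity first, then lexicographic
  ord <- order(keys)
  perms <- perms[ord]
  idk <- which(vapply(perms, function(p) identical(p, id), TRUE))
  c(perms[idk], perms[-idk])
}
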