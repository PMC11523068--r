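# ---------------------------------------------------------------------------
# Torsion-bond identification and profile matching.
#
# The torsion set of a molecule is the union of
#   (a) acyclic rotatable bonds: single, non-ring, non-aromatic bonds
#       whose two atoms each carry at least one other non-terminal heavy
#       substituent (strict dialect additionally excludes amide C-N), and
#   (b) every non-aromatic ring bond of rings of size >= 3, including
#       macrocycles.
# Ring torsions keep their individual states in the label; the ring
# correlation is only applied when counting (see ntabs).
# ---------------------------------------------------------------------------

#' Identify the torsion bonds of a molecule
#'
#' @param mol a `tabs_mol`.
#' @param strict if `TRUE` (default), amide C-N single bonds are not
#'   rotatable (the strict rotatable-bond dialect); `FALSE` re-admits them.
#' @return data.frame with columns `a1`, `a2` (atom indices, a1 < a2),
#'   `in_ring` (logical) and `ring_size` (smallest containing ring, NA for
#'   acyclic), ordered by (a1, a2).
#' @examples
#' identify_torsion_bonds(parse_smiles("CCCCC"))   # the two inner bonds
#' @export
identify_torsion_bonds <- function(mol, strict = TRUE) {
  out <- data.frame(a1 = integer(0), a2 = integer(0), in_ring = logical(0),
                    ring_size = integer(0))
  if (n_bonds(mol) == 0) return(out)
  ring_flags <- ring_bond_flags(mol)
  deg <- heavy_degree(mol)
  for (b in seq_len(n_bonds(mol))) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    if (ring_flags[b]) {
      if (isTRUE(mol$bonds$aromatic[b])) next
      rs <- smallest_ring_size_for_bond(mol, b)
      out <- rbind(out, data.frame(a1 = a1, a2 = a2, in_ring = TRUE,
                                   ring_size = rs))
    } else {
      if (mol$bonds$order[b] != 1 || isTRUE(mol$bonds$aromatic[b])) next
      # both atoms must be non-terminal (heavy degree >= 2) and not part of
      # a triple bond (linear sp centers have no torsional state)
      if (deg[a1] < 2 || deg[a2] < 2) next
      if (in_triple_bond(mol, a1) || in_triple_bond(mol, a2)) next
      if (strict && is_amide_bond(mol, a1, a2)) next
      out <- rbind(out, data.frame(a1 = a1, a2 = a2, in_ring = FALSE,
                                   ring_size = NA_integer_))
    }
  }
  out <- out[order(out$a1, out$a2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

in_triple_bond <- function(mol, a) {
  any(mol$bonds$order[mol$bonds$a1 == a | mol$bonds$a2 == a] == 3)
}

is_amide_bond <- function(mol, a1, a2) {
  for (pair in list(c(a1, a2), c(a2, a1))) {
    cc <- pair[1]; nn <- pair[2]
    if (mol$elements[cc] != "C" || mol$elements[nn] != "N") next
    adj <- adjacency(mol)
    for (o in adj[[cc]]) {
      if (mol$elements[o] == "O" && bond_order_between(mol, cc, o) == 2)
        return(TRUE)
    }
  }
  FALSE
}

#' Match torsion bonds to a profile library
#'
#' For each torsion bond the library is scanned in order; the first
#' pattern whose mapped central bond (:2-:3) matches assigns the profile,
#' the bins derived from it, and the dihedral quadruple from the pattern's
#' outer atom maps.  Unmatched bonds fall back to the default six-state
#' bins with a deterministically chosen quadruple (highest canonical-rank
#' heavy neighbor on each side, ties broken by atom index).
#'
#' @param mol a sanitized `tabs_mol` (ring perception is done at
#'   construction); conformers are not required, matching is topological.
#' @param library a `profile_library` (possibly empty list).
#' @param strict passed to [identify_torsion_bonds()].
#' @return an object of class `matched_torsions`: a list with one entry
#'   per torsion bond, each holding `quad`, `bond`, `profile` (or NULL for
#'   the fallback), `bins`, and `context` (`"acyclic"`,
#'   `"small_ring"`, `"macrocycle"`) plus `ring_size`.
#' @export
match_torsions <- function(mol, library = list(), strict = TRUE) {
  bonds <- identify_torsion_bonds(mol, strict = strict)
  conn <- connectivity(mol)
  arom <- if (is.null(mol$aromatic_atom)) infer_aromatic_atoms(mol) else mol$aromatic_atom
  ring_flags <- ring_bond_flags(mol)
  ranks <- canonical_ranks(mol)
  adj <- adjacency(mol)
  pats <- lapply(library, function(p) parse_torsion_smarts(p$pattern))
  bins_cache <- list()
  out <- vector("list", nrow(bonds))
  for (t in seq_len(nrow(bonds))) {
    j <- bonds$a1[t]; k <- bonds$a2[t]
    hit <- NULL
    for (pidx in seq_along(pats)) {
      quad <- match_pattern_to_bond(mol, pats[[pidx]], j, k, conn, arom,
                                    ring_flags, ranks, adj)
      if (!is.null(quad)) { hit <- list(pidx = pidx, quad = quad); break }
    }
    if (is.null(hit)) {
      quad <- fallback_quadruple(mol, j, k, ranks, adj, bonds$in_ring[t])
      bins <- default_bins()
      profile <- NULL
    } else {
      quad <- hit$quad
      key <- as.character(hit$pidx)
      if (is.null(bins_cache[[key]]))
        bins_cache[[key]] <- derive_bins(library[[hit$pidx]])
      bins <- bins_cache[[key]]
      profile <- library[[hit$pidx]]
    }
    context <- if (!bonds$in_ring[t]) "acyclic"
      else if (bonds$ring_size[t] <= 11) "small_ring" else "macrocycle"
    out[[t]] <- list(quad = quad, bond = c(j, k), profile = profile,
                     bins = bins, context = context,
                     ring_size = bonds$ring_size[t])
  }
  structure(out, class = "matched_torsions", bonds = bonds)
}

#' @export
print.matched_torsions <- function(x, ...) {
  cat(sprintf("<matched_torsions: %d torsion(s)>\n", length(x)))
  for (t in seq_along(x)) {
    mt <- x[[t]]
    cat(sprintf("  %d: bond %d-%d  quad (%s)  m=%d  %s  [%s]\n", t,
                mt$bond[1], mt$bond[2], paste(mt$quad, collapse = ","),
                mt$bins$multiplicity, mt$context,
                if (is.null(mt$profile)) "default" else mt$profile$tag))
  }
  invisible(x)
}

# deterministic fallback quadruple: highest-canonical-rank heavy neighbor
# on each side (tie -> lowest atom index); ring bonds prefer neighbors in
# the same smallest ring so ring torsions trace the ring path
fallback_quadruple <- function(mol, j, k, ranks, adj, in_ring) {
  pick <- function(a, excl, prefer = integer(0)) {
    cands <- setdiff(adj[[a]], excl)
    if (length(cands) == 0)
      stop("cannot build dihedral: atom ", a, " has no other heavy neighbor")
    pref <- intersect(cands, prefer)
    if (length(pref)) cands <- pref
    cands[order(-ranks[cands], cands)][1]
  }
  prefer_i <- prefer_l <- integer(0)
  if (in_ring) {
    b <- bond_index(mol, j, k)
    rs <- smallest_ring_size_for_bond(mol, b)
    for (ring in mol$rings) {
      if (length(ring) == rs && j %in% ring && k %in% ring) {
        prefer_i <- prefer_l <- ring
        break
      }
    }
  }
  i <- pick(j, k, prefer_i)
  l <- pick(k, c(j, i), prefer_l)
  c(i, j, k, l)
}
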