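# ---------------------------------------------------------------------------
# Restricted SMARTS dialect for torsion patterns.
#
# Torsion-library patterns are linear four-atom chains
#     [expr:1][expr:2]<bond>[expr:3]<bond>[expr:4]
# where each atom expression is a conjunction of the primitives
#   element symbol (C, N, O, ... / aromatic lowercase c, n, o, s),
#   #<n>  atomic number,  X<n>  total connectivity (heavy + implicit H),
#   a / A aromatic / aliphatic,  *  any atom,
# joined by juxtaposition, '&' or ';'.  Bond specifiers between bracket
# atoms: '' or '-' (single), '=', '#', ':' (aromatic), '@' (ring),
# '!@' (non-ring), '-!@' (single non-ring).  This covers the torsion
# archetype patterns the package ships and the dialect users are asked to
# write libraries in; it is not a general SMARTS engine.
# ---------------------------------------------------------------------------

parse_torsion_smarts <- function(smarts) {
  rx <- gregexpr("\\[[^]]*\\]", smarts)[[1]]
  if (length(rx) != 4 || rx[1] == -1)
    stop("torsion SMARTS must contain exactly 4 bracket atoms: ", smarts)
  lens <- attr(rx, "match.length")
  atoms <- substring(smarts, rx + 1, rx + lens - 2)
  # bond specs are whatever sits between consecutive brackets
  bonds <- character(3)
  for (k in 1:3) {
    from <- rx[k] + lens[k]
    to <- rx[k + 1] - 1
    bonds[k] <- if (to >= from) substr(smarts, from, to) else ""
  }
  maps <- integer(4)
  exprs <- vector("list", 4)
  for (k in 1:4) {
    parts <- strsplit(atoms[k], ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !grepl("^[0-9]+$", parts[2]))
      stop("bracket atom ", k, " lacks an atom map :1..:4 in ", smarts)
    maps[k] <- as.integer(parts[2])
    exprs[[k]] <- parse_atom_expr(parts[1], smarts)
  }
  if (!setequal(maps, 1:4))
    stop("atom maps must be exactly 1..4 in ", smarts)
  ord <- order(maps)
  list(atoms = exprs[ord], bonds = bonds, smarts = smarts)
}

parse_atom_expr <- function(txt, smarts) {
  prims <- list()
  toks <- strsplit(txt, "[&;]")[[1]]
  for (tok in toks) {
    t <- tok
    while (nzchar(t)) {
      if (substr(t, 1, 1) == "*") {
        prims[[length(prims) + 1L]] <- list(kind = "any"); t <- substring(t, 2)
      } else if (grepl("^#[0-9]+", t)) {
        m <- regmatches(t, regexpr("^#[0-9]+", t))
        prims[[length(prims) + 1L]] <- list(kind = "anum", value = as.integer(substring(m, 2)))
        t <- substring(t, nchar(m) + 1)
      } else if (grepl("^X[0-9]+", t)) {
        m <- regmatches(t, regexpr("^X[0-9]+", t))
        prims[[length(prims) + 1L]] <- list(kind = "conn", value = as.integer(substring(m, 2)))
        t <- substring(t, nchar(m) + 1)
      } else if (grepl("^(Cl|Br|Si)", t)) {
        m <- regmatches(t, regexpr("^(Cl|Br|Si)", t))
        prims[[length(prims) + 1L]] <- list(kind = "elem", value = m, aromatic = FALSE)
        t <- substring(t, nchar(m) + 1)
      } else if (grepl("^[BCNOPSFI]", t)) {
        sym <- substr(t, 1, 1)
        prims[[length(prims) + 1L]] <- list(kind = "elem", value = sym, aromatic = FALSE)
        t <- substring(t, 2)
      } else if (grepl("^[bcnops]", t)) {
        sym <- toupper(substr(t, 1, 1))
        prims[[length(prims) + 1L]] <- list(kind = "elem", value = sym, aromatic = TRUE)
        t <- substring(t, 2)
      } else if (substr(t, 1, 1) == "a") {
        prims[[length(prims) + 1L]] <- list(kind = "arom", value = TRUE); t <- substring(t, 2)
      } else if (substr(t, 1, 1) == "A") {
        prims[[length(prims) + 1L]] <- list(kind = "arom", value = FALSE); t <- substring(t, 2)
      } else {
        stop("unsupported SMARTS atom primitive '", t, "' in ", smarts)
      }
    }
  }
  prims
}

atom_matches <- function(mol, idx, prims, conn, arom) {
  for (p in prims) {
    ok <- switch(p$kind,
      any = TRUE,
      # uppercase element = aliphatic atom, lowercase = aromatic
      elem = mol$elements[idx] == p$value && isTRUE(arom[idx]) == p$aromatic,
      anum = atomic_number(mol$elements[idx]) == p$value,
      conn = conn[idx] == p$value,
      arom = isTRUE(arom[idx]) == p$value,
      FALSE)
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

bond_matches <- function(mol, i, j, spec, ring_flags) {
  b <- bond_index(mol, i, j)
  if (length(b) == 0) return(FALSE)
  in_ring <- ring_flags[b]
  arom <- mol$bonds$aromatic[b]
  ord <- mol$bonds$order[b]
  spec <- gsub(" ", "", spec)
  want_nonring <- grepl("!@", spec, fixed = TRUE)
  spec2 <- gsub("!@", "", spec, fixed = TRUE)
  want_ring <- grepl("@", spec2, fixed = TRUE)
  spec2 <- gsub("@", "", spec2, fixed = TRUE)
  if (want_nonring && in_ring) return(FALSE)
  if (want_ring && !in_ring) return(FALSE)
  if (spec2 == "" ) return(TRUE)          # default: single or aromatic
  if (spec2 == "-") return(ord == 1 && !arom)
  if (spec2 == "=") return(ord == 2)
  if (spec2 == "#") return(ord == 3)
  if (spec2 == ":") return(isTRUE(arom))
  if (spec2 == "~") return(TRUE)
  FALSE
}

# Try to match a 4-atom torsion pattern onto central bond (j, k) of mol.
# Returns the quadruple (i, j, k, l) or NULL.  Neighbor candidates for the
# outer atoms are ranked by canonical rank (descending), ties by atom
# index, making the choice deterministic.
match_pattern_to_bond <- function(mol, pat, j, k, conn, arom, ring_flags, ranks,
                                  adj) {
  for (dir in 1:2) {
    a2 <- if (dir == 1) j else k
    a3 <- if (dir == 1) k else j
    if (!atom_matches(mol, a2, pat$atoms[[2]], conn, arom)) next
    if (!atom_matches(mol, a3, pat$atoms[[3]], conn, arom)) next
    if (!bond_matches(mol, a2, a3, pat$bonds[2], ring_flags)) next
    i_cands <- setdiff(adj[[a2]], a3)
    i_cands <- i_cands[vapply(i_cands, function(x)
      atom_matches(mol, x, pat$atoms[[1]], conn, arom) &&
        bond_matches(mol, x, a2, pat$bonds[1], ring_flags), TRUE)]
    if (length(i_cands) == 0) next
    l_cands <- setdiff(adj[[a3]], a2)
    l_cands <- l_cands[vapply(l_cands, function(x)
      atom_matches(mol, x, pat$atoms[[4]], conn, arom) &&
        bond_matches(mol, x, a3, pat$bonds[3], ring_flags), TRUE)]
    if (length(l_cands) == 0) next
    i_pick <- i_cands[order(-ranks[i_cands], i_cands)][1]
    l_cands <- setdiff(l_cands, i_pick)
    if (length(l_cands) == 0) next
    l_pick <- l_cands[order(-ranks[l_cands], l_cands)][1]
    return(c(i_pick, a2, a3, l_pick))
  }
  NULL
}
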