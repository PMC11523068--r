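# ---------------------------------------------------------------------------
# Minimal heavy-atom molecule model.
#
# A `tabs_mol` stores the molecular graph (elements, charges, aromatic
# flags, bonds with integer orders) plus zero or more conformers as n x 3
# coordinate matrices.  Hydrogens are implicit: they are inferred from
# default valences and only enter the model through the connectivity count
# X used in SMARTS matching.  This is sufficient for torsion labelling,
# which operates on heavy atoms only.
# ---------------------------------------------------------------------------

DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                     Cl = 1, Br = 1, I = 1, Si = 4, H = 1)

#' Construct a molecule object
#'
#' @param elements character vector of element symbols (heavy atoms).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2, 3) and `aromatic` (logical).
#' @param charges integer vector of formal charges (default all 0).
#' @param stereo character vector of tetrahedral tags per atom:
#'   `NA`, `"@"` or `"@@"`.
#' @param name molecule title.
#' @return an object of class `tabs_mol`.
#' @export
tabs_mol <- function(elements, bonds, charges = NULL, stereo = NULL,
                     name = "") {
  n <- length(elements)
  if (is.null(charges)) charges <- integer(n)
  if (is.null(stereo)) stereo <- rep(NA_character_, n)
  if (nrow(bonds) > 0) {
    swap <- bonds$a1 > bonds$a2
    tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
    bonds <- bonds[order(bonds$a1, bonds$a2), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  mol <- structure(list(
    elements = as.character(elements),
    charges = as.integer(charges),
    stereo = as.character(stereo),
    bonds = bonds,
    conformers = list(),
    name = name
  ), class = "tabs_mol")
  mol$rings <- perceive_rings(mol)
  mol
}

n_atoms <- function(mol) length(mol$elements)
n_bonds <- function(mol) nrow(mol$bonds)

#' Number of conformers stored on a molecule
#' @param mol a `tabs_mol`.
#' @export
n_conformers <- function(mol) length(mol$conformers)

#' @export
print.tabs_mol <- function(x, ...) {
  cat(sprintf("<tabs_mol%s: %d heavy atoms, %d bonds, %d ring(s), %d conformer(s)>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              n_atoms(x), n_bonds(x), length(x$rings), n_conformers(x)))
  invisible(x)
}

# adjacency list: for each atom, data.frame(nbr, order, aromatic)
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (i in seq_len(n_atoms(mol))) adj[[i]] <- integer(0)
  if (n_bonds(mol) > 0) {
    for (b in seq_len(n_bonds(mol))) {
      a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
      adj[[a1]] <- c(adj[[a1]], a2)
      adj[[a2]] <- c(adj[[a2]], a1)
    }
  }
  adj
}

heavy_degree <- function(mol) {
  deg <- integer(n_atoms(mol))
  if (n_bonds(mol) > 0) {
    t1 <- tabulate(mol$bonds$a1, nbins = n_atoms(mol))
    t2 <- tabulate(mol$bonds$a2, nbins = n_atoms(mol))
    deg <- t1 + t2
  }
  deg
}

bond_index <- function(mol, i, j) {
  a1 <- pmin(i, j); a2 <- pmax(i, j)
  which(mol$bonds$a1 == a1 & mol$bonds$a2 == a2)
}

bond_order_between <- function(mol, i, j) {
  b <- bond_index(mol, i, j)
  if (length(b) == 0) return(0)
  mol$bonds$order[b]
}

# implicit hydrogen count from default valences; aromatic bonds count 1.5
implicit_h <- function(mol) {
  n <- n_atoms(mol)
  used <- numeric(n)
  if (n_bonds(mol) > 0) {
    ord <- ifelse(mol$bonds$aromatic, 1.5, mol$bonds$order)
    for (b in seq_len(n_bonds(mol))) {
      used[mol$bonds$a1[b]] <- used[mol$bonds$a1[b]] + ord[b]
      used[mol$bonds$a2[b]] <- used[mol$bonds$a2[b]] + ord[b]
    }
  }
  val <- DEFAULT_VALENCE[mol$elements]
  val[is.na(val)] <- 0
  h <- val + mol$charges * ifelse(mol$elements %in% c("N", "P"), 1L,
                                  ifelse(mol$elements %in% c("O", "S"), -1L, 0L)) -
    ceiling(used)
  pmax(0L, as.integer(round(h)))
}

# total connection count (heavy neighbors + implicit H) -> SMARTS X primitive
connectivity <- function(mol) heavy_degree(mol) + implicit_h(mol)

atomic_number <- function(sym) {
  tbl <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
           S = 16, Cl = 17, Br = 35, I = 53)
  unname(tbl[sym])
}

# ---------------------------------------------------------------------------
# SSSR ring perception: for every edge on a cycle, the shortest cycle
# through it; greedily keep rings that are linearly independent over GF(2)
# in edge space until E - V + C rings are collected.
# ---------------------------------------------------------------------------
perceive_rings <- function(mol) {
  nb <- n_bonds(mol); na <- n_atoms(mol)
  if (nb == 0 || na == 0) return(list())
  adj <- adjacency(mol)
  comp <- components_count(adj, na)
  n_rings <- nb - na + comp
  if (n_rings <= 0) return(list())

  candidates <- list()
  for (b in seq_len(nb)) {
    i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
    path <- bfs_shortest_path(adj, i, j, forbid = b, mol)
    if (!is.null(path)) candidates[[length(candidates) + 1L]] <- path
  }
  if (length(candidates) == 0) return(list())
  candidates <- unique(lapply(candidates, canonical_ring))
  sizes <- vapply(candidates, length, 1L)
  candidates <- candidates[order(sizes)]

  basis <- matrix(FALSE, nrow = 0, ncol = nb)
  rings <- list()
  for (ring in candidates) {
    vec <- ring_edge_vector(mol, ring, nb)
    red <- gf2_reduce(basis, vec)
    if (any(red$residual)) {
      basis <- red$basis
      rings[[length(rings) + 1L]] <- ring
      if (length(rings) == n_rings) break
    }
  }
  rings
}

components_count <- function(adj, n) {
  seen <- logical(n); comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
  }
  comp
}

# shortest path i..j avoiding bond `forbid`; returns the cycle atom list
bfs_shortest_path <- function(adj, i, j, forbid, mol) {
  n <- length(adj)
  prev <- integer(n); dist <- rep(NA_integer_, n)
  dist[i] <- 0L
  queue <- i
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      b <- bond_index(mol, v, w)
      if (length(b) && b == forbid) next
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  if (is.na(dist[j])) return(NULL)
  path <- j
  while (path[1] != i) path <- c(prev[path[1]], path)
  path
}

canonical_ring <- function(atoms) {
  m <- length(atoms)
  k <- which.min(atoms)
  rot <- c(atoms[k:m], if (k > 1) atoms[1:(k - 1)])
  rev_rot <- c(rot[1], rev(rot[-1]))
  if (paste(rev_rot, collapse = ",") < paste(rot, collapse = ",")) rev_rot else rot
}

ring_edge_vector <- function(mol, ring, nb) {
  vec <- logical(nb)
  m <- length(ring)
  for (k in seq_len(m)) {
    b <- bond_index(mol, ring[k], ring[k %% m + 1])
    vec[b] <- TRUE
  }
  vec
}

gf2_reduce <- function(basis, vec) {
  v <- vec
  if (nrow(basis) > 0) {
    for (r in seq_len(nrow(basis))) {
      pivot <- which(basis[r, ])[1]
      if (v[pivot]) v <- xor(v, basis[r, ])
    }
  }
  if (any(v)) basis <- rbind(basis, v)
  list(basis = basis, residual = v)
}

ring_bond_flags <- function(mol) {
  flags <- logical(n_bonds(mol))
  for (ring in mol$rings) {
    m <- length(ring)
    for (k in seq_len(m)) {
      b <- bond_index(mol, ring[k], ring[k %% m + 1])
      flags[b] <- TRUE
    }
  }
  # bonds in cycles not captured by the chosen SSSR basis (fused systems)
  # are still ring bonds; mark every bond whose removal keeps endpoints
  # connected
  adj <- adjacency(mol)
  for (b in seq_len(n_bonds(mol))) {
    if (flags[b]) next
    path <- bfs_shortest_path(adj, mol$bonds$a1[b], mol$bonds$a2[b], b, mol)
    if (!is.null(path)) flags[b] <- TRUE
  }
  flags
}

# smallest ring size containing bond b, NA if acyclic bond
smallest_ring_size_for_bond <- function(mol, b) {
  i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
  sizes <- vapply(mol$rings, function(r) {
    m <- length(r)
    for (k in seq_len(m)) {
      u <- r[k]; v <- r[k %% m + 1]
      if ((u == i && v == j) || (u == j && v == i)) return(m)
    }
    NA_integer_
  }, 1L)
  if (all(is.na(sizes))) NA_integer_ else min(sizes, na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# Canonical atom ranks by iterative neighborhood refinement (Morgan-like),
# used for deterministic neighbor choice in torsion quadruples.  Ties that
# survive refinement are genuinely symmetry-equivalent atoms; they are
# broken by atom index at the point of use.
# ---------------------------------------------------------------------------
canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(integer(0))
  adj <- adjacency(mol)
  inv <- paste(mol$elements, mol$charges, heavy_degree(mol), implicit_h(mol),
               vapply(seq_len(n), function(i) {
                 bs <- vapply(adj[[i]], function(j) bond_order_between(mol, i, j), 0)
                 paste(sort(bs), collapse = "")
               }, ""))
  color <- as.integer(factor(inv))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      paste(color[i], paste(sort(color[adj[[i]]]), collapse = ","), sep = "|")
    }, "")
    new_color <- as.integer(factor(sig))
    if (length(unique(new_color)) == length(unique(color))) break
    color <- new_color
  }
  color
}

#' Renumber the atoms of a molecule
#'
#' Applies an atom permutation to the graph and (consistently) to every
#' conformer: new atom `perm[i]` is old atom `i`.  Used to test that TABS
#' and nTABS are invariant under atom renumbering.
#'
#' @param mol a `tabs_mol`.
#' @param perm integer permutation of `1:n_atoms(mol)`.
#' @return the renumbered `tabs_mol`.
#' @export
permute_atoms <- function(mol, perm) {
  n <- n_atoms(mol)
  stopifnot(length(perm) == n, setequal(perm, seq_len(n)))
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  bonds <- mol$bonds
  bonds$a1 <- perm[bonds$a1]
  bonds$a2 <- perm[bonds$a2]
  out <- tabs_mol(mol$elements[inv], bonds, mol$charges[inv],
                  mol$stereo[inv], name = mol$name)
  if (!is.null(mol$aromatic_atom)) out$aromatic_atom <- mol$aromatic_atom[inv]
  out$conformers <- lapply(mol$conformers, function(x) x[inv, , drop = FALSE])
  out
}
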