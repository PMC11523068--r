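# ---------------------------------------------------------------------------
# nTABS: upper bound on the number of distinct TABS of a molecule.
#
# The naive count is the product of all state multiplicities.  Highly
# correlated substructures (small/medium rings and macrocycles) are
# collapsed to a single position whose state count comes from literature
# tables of cycloalkane conformer counts; topological symmetry is then
# divided out by counting orbits of the state space under the induced
# position-permutation group (Burnside's lemma).
# ---------------------------------------------------------------------------

#' Ring state-count tables
#'
#' Maximum number of conformational states contributed by one aliphatic
#' ring, by ring size: sizes 3-11 from cycloalkane conformer literature,
#' sizes 12-16 corrected upper bounds for macrocycles.  Rings above 16 are
#' outside the method's recommended domain.
#'
#' @return named list with integer vectors `small_medium` (names "3".."11")
#'   and `macrocycle` (names "12".."16").
#' @export
ring_state_table <- function() {
  list(
    small_medium = c(`3` = 1, `4` = 3, `5` = 11, `6` = 15, `7` = 29,
                     `8` = 45, `9` = 115, `10` = 181, `11` = 331),
    macrocycle = c(`12` = 16549, `13` = 44934, `14` = 122002,
                   `15` = 331251, `16` = 899394)
  )
}

#' Classify the non-aromatic rings of a molecule
#'
#' @param mol a `tabs_mol`.
#' @return data.frame with one row per non-aromatic smallest-set ring:
#'   `size`, `class` (`"small_medium"` for 3-11, `"macrocycle"` for >= 12)
#'   and `atoms` (list column of ring atom indices).  Rings larger than 16
#'   are flagged with a warning (outside the recommended domain).
#' @export
classify_rings <- function(mol) {
  arom <- if (is.null(mol$aromatic_atom)) infer_aromatic_atoms(mol) else mol$aromatic_atom
  rings <- list(); sizes <- integer(0); classes <- character(0)
  for (ring in mol$rings) {
    aromatic_ring <- all(arom[ring])
    if (aromatic_ring) next
    sz <- length(ring)
    rings[[length(rings) + 1L]] <- ring
    sizes <- c(sizes, sz)
    classes <- c(classes, if (sz <= 11) "small_medium" else "macrocycle")
  }
  if (any(sizes > 16))
    warning("ring(s) of size > 16 present; nTABS is not recommended for ",
            "macrocycles larger than 16 and these rings are excluded from the count")
  out <- data.frame(size = sizes, class = classes)
  out$atoms <- rings
  out
}

#' Collapsed state space of a molecule
#'
#' Positions partition the torsion set: each acyclic torsion is a
#' singleton position with its bin multiplicity; all torsions inside one
#' non-aromatic ring collapse to a single position whose multiplicity is
#' the ring-size state count from [ring_state_table()].  Rings of size
#' > 16 are excluded (with `excluded_rings` recording them).
#'
#' @param mol a `tabs_mol`.
#' @param torsions a `matched_torsions`.
#' @return list with `positions` (data.frame: `multiplicity`, `kind`,
#'   `ring_size`), `ring_atoms` (list of atom sets per ring position, NULL
#'   for torsion positions), `torsion_map` (per torsion: its position id or
#'   NA if excluded) and `excluded_rings` (sizes).
#' @export
state_space <- function(mol, torsions) {
  tbl <- ring_state_table()
  rings <- classify_rings(mol)
  M <- length(torsions)
  torsion_map <- rep(NA_integer_, M)
  mult <- numeric(0); kind <- character(0); ring_size <- integer(0)
  ring_atoms <- list()
  excluded <- integer(0)

  ring_pos_of_ring <- integer(nrow(rings))
  for (r in seq_len(nrow(rings))) {
    sz <- rings$size[r]
    if (sz > 16) { excluded <- c(excluded, sz); ring_pos_of_ring[r] <- NA_integer_; next }
    m <- if (sz <= 11) tbl$small_medium[[as.character(sz)]]
         else tbl$macrocycle[[as.character(sz)]]
    mult <- c(mult, m); kind <- c(kind, "ring"); ring_size <- c(ring_size, sz)
    ring_atoms[[length(mult)]] <- rings$atoms[[r]]
    ring_pos_of_ring[r] <- length(mult)
  }
  for (t in seq_len(M)) {
    mt <- torsions[[t]]
    if (mt$context == "acyclic") {
      mult <- c(mult, mt$bins$multiplicity)
      kind <- c(kind, "torsion"); ring_size <- c(ring_size, NA_integer_)
      ring_atoms[length(mult)] <- list(NULL)
      torsion_map[t] <- length(mult)
    } else {
      # assign the torsion to the first classified ring containing its bond
      assigned <- FALSE
      for (r in seq_len(nrow(rings))) {
        if (all(mt$bond %in% rings$atoms[[r]]) &&
            adjacent_in_ring(rings$atoms[[r]], mt$bond)) {
          torsion_map[t] <- ring_pos_of_ring[r]
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        # ring bond whose smallest ring was excluded (> 16) or bridging bond
        torsion_map[t] <- NA_integer_
      }
    }
  }
  list(positions = data.frame(multiplicity = mult, kind = kind,
                              ring_size = ring_size),
       ring_atoms = ring_atoms,
       torsion_map = torsion_map,
       excluded_rings = excluded)
}

adjacent_in_ring <- function(ring, bond) {
  m <- length(ring)
  for (k in seq_len(m)) {
    u <- ring[k]; v <- ring[k %% m + 1]
    if ((u == bond[1] && v == bond[2]) || (u == bond[2] && v == bond[1]))
      return(TRUE)
  }
  FALSE
}

#' Naive TABS count
#'
#' Product of the multiplicities of all state-space positions.  A rigid
#' molecule (empty state space) has exactly one conformer class, so the
#' empty product is 1.
#'
#' @param space a state space from [state_space()], or a bare numeric
#'   vector of multiplicities.
#' @return the product (double; exact for values below 2^53).
#' @export
ntabs_naive <- function(space) {
  mult <- if (is.list(space)) space$positions$multiplicity else space
  if (length(mult) == 0) return(1)
  if (any(mult < 1)) stop("multiplicities must be >= 1")
  p <- prod(mult)
  if (p > 2^53) warning("state-space product exceeds 2^53; count is approximate")
  p
}

#' Symmetry-reduced TABS count (nTABS)
#'
#' Counts the orbits of the collapsed state space under the position
#' permutation group induced by the molecule's graph automorphisms, via
#' Burnside's lemma: orbits = (1/|G|) sum over g of the product of m over
#' the cycles of g (multiplicity is constant on every cycle, which is
#' asserted).  With a trivial group this reduces to the naive product.
#'
#' @param mol a `tabs_mol`.
#' @param library a `profile_library`.
#' @param strict passed to [identify_torsion_bonds()].
#' @param enumerate_below explicit orbit enumeration is also run (as
#'   decomposition bookkeeping, giving orbit sizes p_i) when the naive
#'   count is at most this bound.
#' @return an object of class `ntabs_result`: `ntabs`, `ntabs_naive`,
#'   `n_positions`, `group_order`, `category` (flexibility class),
#'   `excluded_rings`, and — when enumerated — `N_poss` (number of orbit
#'   cases) with `orbit_sizes` (the p_i, summing to the naive count).
#' @examples
#' ntabs(parse_smiles("C1CCCCC1"))$ntabs   # 15, the six-ring state count
#' @export
ntabs <- function(mol, library = list(), strict = TRUE,
                  enumerate_below = 20000) {
  torsions <- match_torsions(mol, library, strict = strict)
  space <- state_space(mol, torsions)
  autos <- graph_automorphisms(mol)
  perms <- induce_position_permutations(mol, autos, torsions, space)
  mult <- space$positions$multiplicity
  naive <- ntabs_naive(space)
  n <- burnside_count(mult, perms)
  dec <- NULL
  if (naive <= enumerate_below && length(mult) > 0) {
    dec <- enumerate_orbits(mult, perms)
    if (dec$n_orbits != n)
      stop("internal error: Burnside count ", n,
           " disagrees with explicit enumeration ", dec$n_orbits)
  }
  structure(list(ntabs = n, ntabs_naive = naive,
                 n_positions = length(mult),
                 group_order = length(perms),
                 category = flexibility_category(n),
                 excluded_rings = space$excluded_rings,
                 N_poss = if (is.null(dec)) NA_integer_ else dec$n_orbits,
                 orbit_sizes = if (is.null(dec)) NULL else dec$orbit_sizes),
            class = "ntabs_result")
}

#' @export
print.ntabs_result <- function(x, ...) {
  cat(sprintf("<ntabs: %s (naive %s), %d position(s), group order %d, %s flexibility>\n",
              format(x$ntabs, big.mark = ","),
              format(x$ntabs_naive, big.mark = ","),
              x$n_positions, x$group_order, x$category))
  if (length(x$excluded_rings))
    cat("  ! rings of size", paste(x$excluded_rings, collapse = ", "),
        "excluded (larger than 16)\n")
  invisible(x)
}

# Automorphisms act on collapsed positions: a torsion position maps via
# its bond, a ring position via its atom set.  Automorphisms that do not
# stabilise the position structure are discarded.
induce_position_permutations <- function(mol, automorphisms, torsions, space) {
  P <- nrow(space$positions)
  if (P == 0) return(list(integer(0)))
  mult <- space$positions$multiplicity
  ring_keys <- vapply(seq_len(P), function(p) {
    if (space$positions$kind[p] == "ring")
      paste(sort(space$ring_atoms[[p]]), collapse = ",") else NA_character_
  }, "")
  torsion_pos <- which(space$positions$kind == "torsion")
  # map position -> torsion index (first torsion at that position)
  pos_torsion <- match(seq_len(P), space$torsion_map)
  bonds_key <- vapply(torsions, function(t) paste(sort(t$bond), collapse = "-"), "")

  perms <- list(); seen <- character(0)
  for (sigma in automorphisms) {
    img <- integer(P)
    ok <- TRUE
    for (p in seq_len(P)) {
      if (space$positions$kind[p] == "ring") {
        key <- paste(sort(sigma[space$ring_atoms[[p]]]), collapse = ",")
        q <- match(key, ring_keys)
      } else {
        t <- pos_torsion[p]
        jk <- paste(sort(sigma[torsions[[t]]$bond]), collapse = "-")
        t2 <- match(jk, bonds_key)
        q <- if (is.na(t2)) NA_integer_ else space$torsion_map[t2]
      }
      if (is.na(q) || mult[q] != mult[p]) { ok <- FALSE; break }
      img[p] <- q
    }
    if (!ok || anyDuplicated(img)) next
    key <- paste(img, collapse = ",")
    if (!key %in% seen) { seen <- c(seen, key); perms[[length(perms) + 1L]] <- img }
  }
  if (length(perms) == 0) perms <- list(seq_len(P))
  close_permutation_group(perms)
}

#' Burnside orbit count
#'
#' @param mult multiplicities per position.
#' @param perms list of position permutations forming a group.
#' @return number of orbits of the product space under the group.
#' @export
burnside_count <- function(mult, perms) {
  P <- length(mult)
  if (P == 0) return(1)
  total <- 0
  for (p in perms) {
    visited <- logical(P)
    term <- 1
    for (i in seq_len(P)) {
      if (visited[i]) next
      j <- i
      cyc_mult <- mult[i]
      while (!visited[j]) {
        visited[j] <- TRUE
        if (mult[j] != cyc_mult)
          stop("multiplicity varies within a permutation cycle; ",
               "library matching is inconsistent")
        j <- p[j]
      }
      term <- term * cyc_mult
    }
    total <- total + term
  }
  total / length(perms)
}

#' Explicit orbit enumeration (oracle-grade, vectorized)
#'
#' Enumerates the whole product space as mixed-radix indices and maps each
#' state to the minimum of its group images; distinct minima are the
#' orbits.  Intended for state spaces up to ~1e6.
#'
#' @param mult multiplicities per position.
#' @param perms list of position permutations.
#' @param max_states refusal guard.
#' @return list with `n_orbits` and `orbit_sizes` (the p_i of the orbit
#'   decomposition; they sum to prod(mult)).
#' @export
enumerate_orbits <- function(mult, perms, max_states = 1e6) {
  P <- length(mult)
  if (P == 0) return(list(n_orbits = 1, orbit_sizes = 1))
  N <- prod(mult)
  if (N > max_states) stop("state space too large to enumerate (", N, ")")
  base <- cumprod(c(1, mult[-P]))
  idx <- 0:(N - 1)
  digits <- matrix(0L, N, P)
  for (k in seq_len(P)) digits[, k] <- (idx %/% base[k]) %% mult[k]
  canon <- rep(Inf, N)
  for (p in perms) {
    img_idx <- numeric(N)
    for (k in seq_len(P)) img_idx <- img_idx + digits[, k] * base[p[k]]
    canon <- pmin(canon, img_idx)
  }
  sizes <- table(canon)
  list(n_orbits = length(sizes), orbit_sizes = as.integer(sizes))
}

#' Flexibility category from an nTABS value
#'
#' Low: nTABS < 500; medium: 500 <= nTABS < 10,000; high: nTABS >= 10,000.
#'
#' @param ntabs_value a count >= 1.
#' @return one of `"low"`, `"medium"`, `"high"`.
#' @export
flexibility_category <- function(ntabs_value) {
  if (ntabs_value < 1) stop("nTABS must be >= 1")
  if (ntabs_value < 500) "low"
  else if (ntabs_value < 10000) "medium"
  else "high"
}
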