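# ---------------------------------------------------------------------------
# TABS labels: measure, bin, assemble, canonicalize, group.
# ---------------------------------------------------------------------------

#' Canonicalize a TABS state vector under a digit-permutation group
#'
#' Returns the lexicographically smallest image of the state tuple under
#' the induced permutation group, i.e. the arrangement of digits with the
#' lowest integer value when read as a number.  Idempotent.
#'
#' @param states integer vector of 1-based state indices.
#' @param group a `torsion_perm_group`.
#' @return integer vector (the canonical states).
#' @examples
#' grp <- structure(list(perms = list(1:2, 2:1), n_positions = 2L),
#'                  class = "torsion_perm_group")
#' canonicalize_states(c(2L, 1L), grp)   # -> c(1L, 2L)
#' @export
canonicalize_states <- function(states, group) {
  M <- length(states)
  if (M != group$n_positions)
    stop("label length ", M, " does not match group positions ", group$n_positions)
  if (M == 0) return(integer(0))
  best <- states
  for (p in group$perms) {
    img <- integer(M)
    img[p] <- states          # digit at position t moves to position p[t]
    if (lex_less(img, best)) best <- img
  }
  best
}

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Compute the TABS label of one conformer
#'
#' Measures each matched torsion's dihedral, bins it, assembles the state
#' vector in the fixed torsion order, and canonicalizes it under the
#' induced symmetry group.
#'
#' @param mol a `tabs_mol` with at least `conf_id` conformers.
#' @param torsions a `matched_torsions` from [match_torsions()].
#' @param group a `torsion_perm_group` from
#'   [induce_torsion_permutations()]; `NULL` means the trivial group.
#' @param conf_id 1-based conformer index.
#' @return an object of class `tabs_label` with fields `states` (raw),
#'   `canonical` (canonicalized states) and `angles` (measured dihedrals,
#'   degrees).
#' @export
tabs <- function(mol, torsions, group = NULL, conf_id = 1L) {
  if (n_conformers(mol) < conf_id)
    stop("molecule has no conformer ", conf_id)
  conf <- mol$conformers[[conf_id]]
  M <- length(torsions)
  states <- integer(M)
  angles <- numeric(M)
  for (t in seq_len(M)) {
    ang <- measure_dihedral(conf, torsions[[t]]$quad)
    angles[t] <- ang
    states[t] <- assign_state(ang, torsions[[t]]$bins)
  }
  if (is.null(group))
    group <- structure(list(perms = list(seq_len(M)), n_positions = M),
                       class = "torsion_perm_group")
  canonical <- canonicalize_states(states, group)
  structure(list(states = states, canonical = canonical, angles = angles),
            class = "tabs_label")
}

#' Render a TABS label as a string
#'
#' Digits are joined with a separator because ring-context multiplicities
#' can exceed 9; for all-single-digit labels the separator-free rendering
#' equals the integer reading used for canonicalization.
#'
#' @param x a `tabs_label` or integer vector of states.
#' @param sep separator between digits.
#' @param canonical render the canonical (default) or raw states.
#' @return a string like `"1-2-3"`.
#' @export
format_tabs <- function(x, sep = "-", canonical = TRUE) {
  states <- if (inherits(x, "tabs_label")) {
    if (canonical) x$canonical else x$states
  } else x
  paste(states, collapse = sep)
}

#' @export
print.tabs_label <- function(x, ...) {
  cat(sprintf("<tabs_label: raw %s | canonical %s>\n",
              format_tabs(x, canonical = FALSE), format_tabs(x)))
  invisible(x)
}

#' @export
format.tabs_label <- function(x, ...) format_tabs(x)

#' Group a conformer ensemble by canonical TABS
#'
#' Labels every conformer, groups conformers with equal canonical TABS,
#' and reports coverage = distinct labels / nTABS.
#'
#' @param mol a `tabs_mol` with >= 1 conformer.
#' @param library a `profile_library` (default: empty, all bonds fall back
#'   to the six-state default bins).
#' @param strict passed to [identify_torsion_bonds()].
#' @return an object of class `tabs_grouping`: list with `groups` (named
#'   list canonical-label-string -> integer conformer ids), `labels`
#'   (per-conformer label strings), `ntabs` (the [ntabs()] decomposition)
#'   and `coverage`.
#' @export
group_ensemble <- function(mol, library = list(), strict = TRUE) {
  if (n_conformers(mol) == 0) stop("group_ensemble needs at least one conformer")
  torsions <- match_torsions(mol, library, strict = strict)
  autos <- graph_automorphisms(mol)
  group <- induce_torsion_permutations(autos, torsions)
  labels <- character(n_conformers(mol))
  for (c in seq_len(n_conformers(mol)))
    labels[c] <- format_tabs(tabs(mol, torsions, group, conf_id = c))
  groups <- split(seq_len(n_conformers(mol)), labels)
  nt <- ntabs(mol, library = library, strict = strict)
  coverage <- if (is.finite(nt$ntabs) && nt$ntabs > 0)
    length(groups) / nt$ntabs else NA_real_
  structure(list(groups = groups, labels = labels, ntabs = nt,
                 coverage = coverage),
            class = "tabs_grouping")
}

#' @export
print.tabs_grouping <- function(x, ...) {
  cat(sprintf("<tabs_grouping: %d conformer(s) in %d group(s); nTABS %s; coverage %s>\n",
              length(x$labels), length(x$groups),
              format(x$ntabs$ntabs, big.mark = ","),
              if (is.na(x$coverage)) "NA" else sprintf("%.3g", x$coverage)))
  for (lab in names(x$groups))
    cat(sprintf("  %s: %s\n", lab, paste(x$groups[[lab]], collapse = " ")))
  invisible(x)
}

#' @export
summary.tabs_grouping <- function(object, ...) {
  sizes <- lengths(object$groups)
  cat(sprintf("conformers: %d\ndistinct canonical TABS: %d\nnTABS: %s\ncoverage: %s\n",
              length(object$labels), length(object$groups),
              format(object$ntabs$ntabs, big.mark = ","),
              if (is.na(object$coverage)) "NA" else sprintf("%.4f", object$coverage)))
  cat("group sizes:", paste(sort(sizes, decreasing = TRUE), collapse = " "), "\n")
  invisible(object)
}
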