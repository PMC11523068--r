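# ---------------------------------------------------------------------------
# Fourier torsion profiles and circular state bins.
#
# A torsion potential is a truncated Fourier series
#     V(phi) = sum_{i=1..6} K_i * (1 + s_i * cos(i * phi)),  s_i in {-1, +1},
# the functional form used by classical force fields and by the
# crystallographic torsion-preference fits that drive knowledge-based
# conformer generators.  Minima of V define the rotameric states (bin
# centers), maxima the bin boundaries; the number of minima over one full
# rotation is the multiplicity.
# ---------------------------------------------------------------------------

#' Create a Fourier torsion profile
#'
#' @param pattern SMARTS string with mapped atoms :1..:4 identifying the
#'   dihedral (the central bond is between the atoms mapped :2 and :3).
#' @param K numeric vector of 6 force constants (dimensionless energy
#'   units); unused terms are 0.
#' @param s integer vector of 6 phase signs, each -1 or +1.
#' @param tag free-text source tag.
#' @return an object of class `torsion_profile`.
#' @examples
#' p <- torsion_profile("[CX4:1][CX4:2]!@[CX4:3][CX4:4]",
#'                      K = c(0, 0, 1, 0, 0, 0), s = rep(1L, 6))
#' evaluate_potential(p, 60)   # a minimum of the 3-fold cosine
#' @export
torsion_profile <- function(pattern, K, s = rep(1L, 6), tag = "user") {
  if (length(K) != 6 || length(s) != 6)
    stop("a torsion profile needs exactly 6 (K, s) pairs")
  if (!all(is.finite(K))) stop("non-finite force constant")
  if (!all(s %in% c(-1, 1))) stop("phase signs must be -1 or +1")
  structure(list(pattern = pattern, K = as.numeric(K), s = as.integer(s),
                 tag = tag),
            class = "torsion_profile")
}

#' @export
print.torsion_profile <- function(x, ...) {
  act <- which(x$K != 0)
  terms <- if (length(act) == 0) "flat (all K = 0)" else
    paste(sprintf("K%d=%g(s=%+d)", act, x$K[act], x$s[act]), collapse = ", ")
  cat(sprintf("<torsion_profile [%s] %s | %s>\n", x$tag, x$pattern, terms))
  invisible(x)
}

#' Evaluate a torsion potential
#'
#' @param profile a `torsion_profile`.
#' @param angle angle(s) in degrees; any finite real, reduced mod 360.
#' @return potential value(s), dimensionless; periodic with period 360.
#' @export
evaluate_potential <- function(profile, angle) {
  if (any(!is.finite(angle))) stop("non-finite torsion angle")
  phi <- angle * pi / 180
  v <- numeric(length(phi))
  for (i in 1:6) {
    if (profile$K[i] == 0) next
    v <- v + profile$K[i] * (1 + profile$s[i] * cos(i * phi))
  }
  v
}

# analytic derivative dV/dphi (per radian)
potential_derivative <- function(profile, angle) {
  phi <- angle * pi / 180
  d <- numeric(length(phi))
  for (i in 1:6) {
    if (profile$K[i] == 0) next
    d <- d - profile$K[i] * profile$s[i] * i * sin(i * phi)
  }
  d
}

#' Torsion state bins
#'
#' A circular partition of [0, 360) into `multiplicity` half-open bins.
#' Bin k spans [boundaries[k], boundaries[k+1]); the last bin wraps through
#' 360/0 back to boundaries[1].  An angle exactly on a boundary belongs to
#' the bin whose lower edge it is.
#'
#' @param boundaries strictly increasing angles in [0, 360) (bin lower
#'   edges, at potential maxima).
#' @param centers one angle per bin (potential minima).
#' @return an object of class `torsion_bins`.
#' @export
torsion_bins <- function(boundaries, centers) {
  m <- length(boundaries)
  if (length(centers) != m) stop("boundaries and centers must have equal length")
  if (m == 0) stop("empty bin set")
  if (is.unsorted(boundaries, strictly = TRUE)) stop("boundaries must be strictly increasing")
  if (any(boundaries < 0 | boundaries >= 360)) stop("boundaries must lie in [0, 360)")
  b <- structure(list(boundaries = boundaries, centers = centers,
                      multiplicity = m), class = "torsion_bins")
  for (k in seq_len(m)) {
    if (assign_state(centers[k] %% 360, b) != k)
      stop("center ", centers[k], " does not lie inside bin ", k)
  }
  b
}

#' @export
print.torsion_bins <- function(x, ...) {
  cat(sprintf("<torsion_bins m=%d | boundaries: %s | centers: %s>\n",
              x$multiplicity,
              paste(round(x$boundaries, 2), collapse = ", "),
              paste(round(x$centers, 2), collapse = ", ")))
  invisible(x)
}

#' Derive state bins from a torsion potential
#'
#' Locates the extrema of the potential on [0, 360) by scanning the
#' analytic derivative on a dense grid (0.1 deg) and refining each sign
#' change by bisection to 1e-6 deg.  Minima become bin centers, maxima
#' bin boundaries; the multiplicity is the number of minima.
#'
#' @param profile a `torsion_profile` with at least one nonzero term.
#' @param grid_step scan resolution in degrees.
#' @return a `torsion_bins` object.
#' @export
derive_bins <- function(profile, grid_step = 0.1) {
  if (all(profile$K == 0))
    stop("unbinnable: flat torsion potential (all K = 0); use default_bins()",
         call. = FALSE)
  grid <- seq(0, 360, by = grid_step)
  d <- potential_derivative(profile, grid)
  tol <- 1e-12 * max(abs(profile$K))
  roots <- numeric(0)
  n <- length(grid)
  i <- 1
  while (i < n) {
    if (abs(d[i]) <= tol) {
      j <- i
      while (j < n && abs(d[j + 1]) <= tol) j <- j + 1
      if (j > i + 1)
        warning("plateau in torsion potential derivative; using midpoint")
      roots <- c(roots, (grid[i] + grid[j]) / 2)
      i <- j + 1
    } else if (d[i] * d[i + 1] < 0) {
      roots <- c(roots, bisect_root(profile, grid[i], grid[i + 1]))
      i <- i + 1
    } else i <- i + 1
  }
  roots <- sort(unique(round(roots %% 360, 6)))
  # drop near-duplicates across the 0/360 seam
  if (length(roots) > 1 && (360 - roots[length(roots)] + roots[1]) < grid_step / 2)
    roots <- roots[-length(roots)]
  vals <- evaluate_potential(profile, roots)
  eps <- 1e-4
  is_min <- evaluate_potential(profile, roots - eps) > vals &
    evaluate_potential(profile, roots + eps) > vals
  is_max <- evaluate_potential(profile, roots - eps) < vals &
    evaluate_potential(profile, roots + eps) < vals
  centers <- roots[is_min]
  boundaries <- roots[is_max]
  if (length(centers) == 0 || length(boundaries) == 0)
    stop("degenerate torsion potential: could not identify alternating extrema")
  if (length(centers) != length(boundaries))
    stop("extrema of torsion potential do not alternate (", length(centers),
         " minima vs ", length(boundaries), " maxima)")
  # order centers so center k sits in bin k
  ord <- vapply(centers, function(cc) assign_state(cc, structure(
    list(boundaries = boundaries, centers = rep(NA_real_, length(boundaries)),
         multiplicity = length(boundaries)), class = "torsion_bins")), 1L)
  torsion_bins(boundaries, centers[order(ord)])
}

bisect_root <- function(profile, lo, hi) {
  flo <- potential_derivative(profile, lo)
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    fm <- potential_derivative(profile, mid)
    if (hi - lo < 1e-6) break
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' Default six-state bins for unmatched torsions
#'
#' Rotatable bonds not covered by the profile library are assigned a
#' multiplicity of six, with the circle cut arbitrarily at 30, 90, 150,
#' 210, 270 and 330 degrees.  The sixth bin wraps from 330 through 0 to
#' 30 degrees, so its center is 0.
#'
#' @return a `torsion_bins` with multiplicity 6.
#' @export
default_bins <- function() {
  torsion_bins(boundaries = c(30, 90, 150, 210, 270, 330),
               centers = c(60, 120, 180, 240, 300, 0))
}

#' Assign an angle to its state bin
#'
#' Bins are numbered 1..m in increasing order of lower boundary; the
#' wraparound bin (lower edge = largest boundary) is bin m.  Angles below
#' the first boundary belong to the wraparound bin.
#'
#' @param angle angle in degrees in [0, 360).
#' @param bins a `torsion_bins`.
#' @return 1-based integer state index.
#' @export
assign_state <- function(angle, bins) {
  if (angle < 0 || angle >= 360) angle <- angle %% 360
  idx <- findInterval(angle, bins$boundaries)
  if (idx == 0L) idx <- bins$multiplicity
  idx
}

# ---------------------------------------------------------------------------
# Profile library I/O: a JSON array of records
#   {"smarts": str, "K": [6 floats], "s": [6 ints], "tag": str}
# File order defines match precedence (first match wins), standing in for
# the most-specific-first hierarchy of SMARTS-keyed torsion libraries.
# ---------------------------------------------------------------------------

#' Load a torsion-profile library
#'
#' @param path path to a JSON library file (UTF-8).
#' @return an ordered list of `torsion_profile` objects (class
#'   `profile_library`); order defines match precedence.
#' @export
load_profile_library <- function(path) {
  if (!file.exists(path)) stop("profile library not found: ", path)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) stop("profile library must be a JSON array")
  lib <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    ok <- tryCatch({
      if (is.null(r$smarts) || is.null(r$K) || is.null(r$s))
        stop("missing field")
      parse_torsion_smarts(r$smarts)   # validates the pattern
      lib[[k]] <- torsion_profile(r$smarts, unlist(r$K), unlist(r$s),
                                  tag = if (is.null(r$tag)) sprintf("record %d", k) else r$tag)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("invalid profile record ", k,
           if (!is.null(r$tag)) paste0(" (tag '", r$tag, "')") else "",
           ": ", conditionMessage(ok), call. = FALSE)
  }
  structure(lib, class = "profile_library")
}

#' Write a torsion-profile library
#' @param lib a list of `torsion_profile` objects.
#' @param path output JSON path.
#' @export
write_profile_library <- function(lib, path) {
  recs <- lapply(lib, function(p)
    list(smarts = p$pattern, K = p$K, s = p$s, tag = p$tag))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The small curated profile library shipped with the package
#'
#' Four archetype profiles: acyclic alkane C-C (3-fold), amide C-N
#' (2-fold, minima at 0/180), biaryl (2-fold, minima at 90/270) and
#' in-ring aliphatic C-C (3-fold).  Users with a fuller SMARTS hierarchy
#' extracted from their conformer generator can load it with
#' [load_profile_library()].
#'
#' @return a `profile_library`.
#' @export
builtin_profile_library <- function() {
  load_profile_library(system.file("extdata", "torsion_profiles.json",
                                   package = "tabstrings", mustWork = TRUE))
}
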