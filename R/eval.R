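# ---------------------------------------------------------------------------
# Evaluation protocol: heavy-atom RMSD ground truth vs TABS prediction.
#
# Two conformers are predicted "same" when their canonical TABS are equal;
# the ground truth calls them same when their best-fit heavy-atom RMSD is
# at or below a threshold.  Confusion matrices over all conformer pairs
# are scanned across thresholds and summarized by PPV (precision) and NPV.
# ---------------------------------------------------------------------------

#' Best-fit heavy-atom RMSD between two conformers
#'
#' Minimum RMSD over optimal rigid-body superposition (Kabsch), minimized
#' over all graph-automorphism atom correspondences, so symmetric
#' molecules (e.g. cyclohexane) are compared sensibly.
#'
#' @param mol a `tabs_mol` with >= 3 heavy atoms.
#' @param conf_a,conf_b conformer indices (1-based).
#' @param automorphisms optional precomputed list from
#'   [graph_automorphisms()].
#' @return RMSD in the coordinate units of the conformers (Angstrom for
#'   the shipped fixtures).
#' @export
best_rmsd <- function(mol, conf_a, conf_b, automorphisms = NULL) {
  if (n_atoms(mol) < 3) stop("best_rmsd needs at least 3 heavy atoms")
  x <- mol$conformers[[conf_a]]
  y <- mol$conformers[[conf_b]]
  if (is.null(automorphisms)) automorphisms <- graph_automorphisms(mol)
  best <- Inf
  for (sigma in automorphisms) {
    # correspondence: atom i of conf_a vs atom sigma[i] of conf_b
    r <- kabsch_rmsd(x, y[sigma, , drop = FALSE])
    if (r < best) best <- r
  }
  best
}

#' Pairwise best-fit RMSD matrix for an ensemble
#' @param mol a `tabs_mol` with >= 2 conformers.
#' @return symmetric matrix of RMSDs with zero diagonal.
#' @export
rmsd_matrix <- function(mol) {
  nc <- n_conformers(mol)
  autos <- graph_automorphisms(mol)
  m <- matrix(0, nc, nc)
  for (a in seq_len(nc - 1)) {
    for (b in (a + 1):nc) {
      m[a, b] <- m[b, a] <- best_rmsd(mol, a, b, autos)
    }
  }
  m
}

#' Confusion counts of TABS vs RMSD categorization at one threshold
#'
#' Over all unordered conformer pairs, with RMSD as ground truth
#' (positive = same conformer, RMSD <= threshold) and TABS equality as
#' prediction: TP = same TABS and RMSD <= t; FP = same TABS and RMSD > t;
#' TN = different TABS and RMSD > t; FN = different TABS and RMSD <= t.
#'
#' @param labels character vector of canonical TABS per conformer.
#' @param rmsds symmetric RMSD matrix over the same conformers.
#' @param threshold RMSD threshold (> 0).
#' @return list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`,
#'   `PPV`, `NPV` (predictive values `NA` when their denominator is 0).
#' @export
confusion <- function(labels, rmsds, threshold) {
  n <- length(labels)
  if (n < 2) stop("confusion needs at least 2 conformers")
  if (!isTRUE(all.equal(dim(rmsds), c(n, n))))
    stop("rmsd matrix does not match the label vector")
  if (threshold <= 0) stop("threshold must be > 0")
  tp <- fp <- tn <- fn <- 0L
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      same_tabs <- labels[a] == labels[b]
      same_rmsd <- rmsds[a, b] <= threshold
      if (same_tabs && same_rmsd) tp <- tp + 1L
      else if (same_tabs && !same_rmsd) fp <- fp + 1L
      else if (!same_tabs && !same_rmsd) tn <- tn + 1L
      else fn <- fn + 1L
    }
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP %d FP %d TN %d FN %d | PPV %s NPV %s>\n",
              x$TP, x$FP, x$TN, x$FN,
              if (is.na(x$PPV)) "NA" else sprintf("%.3f", x$PPV),
              if (is.na(x$NPV)) "NA" else sprintf("%.3f", x$NPV)))
  invisible(x)
}

#' Add confusion matrices across molecules
#' @param ... `confusion_counts` objects (or a list of them).
#' @return pooled `confusion_counts`.
#' @export
pool_confusion <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "confusion_counts")) xs <- xs[[1]]
  tp <- sum(vapply(xs, `[[`, 0L, "TP"))
  fp <- sum(vapply(xs, `[[`, 0L, "FP"))
  tn <- sum(vapply(xs, `[[`, 0L, "TN"))
  fn <- sum(vapply(xs, `[[`, 0L, "FN"))
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_),
            class = "confusion_counts")
}

#' Scan RMSD thresholds and locate the PPV/NPV crossing
#'
#' Computes the confusion matrix at each threshold of the grid (default
#' 0.2 to 2.4 Angstrom in steps of 0.1, the interval scanned in the
#' evaluation protocol).  PPV is non-decreasing and NPV non-increasing in
#' the threshold because the prediction is fixed while the ground-truth
#' positives grow.  The crossing threshold is located by linear
#' interpolation between the bracketing grid points; thresholds with an
#' undefined predictive value are excluded from the search.
#'
#' @param labels canonical TABS strings per conformer.
#' @param rmsds symmetric RMSD matrix.
#' @param thresholds threshold grid in Angstrom.
#' @return object of class `threshold_scan`: data.frame `scan` (threshold,
#'   TP, FP, TN, FN, PPV, NPV) plus `crossing` (threshold where PPV and
#'   NPV cross, NA if the curves never bracket).
#' @export
threshold_scan <- function(labels, rmsds, thresholds = seq(0.2, 2.4, by = 0.1)) {
  rows <- lapply(thresholds, function(t) {
    cc <- confusion(labels, rmsds, t)
    data.frame(threshold = t, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               PPV = cc$PPV, NPV = cc$NPV)
  })
  scan <- do.call(rbind, rows)
  crossing <- NA_real_
  d <- scan$PPV - scan$NPV
  ok <- which(!is.na(d))
  for (k in seq_along(ok)[-1]) {
    i <- ok[k - 1]; j <- ok[k]
    if (d[i] == 0) { crossing <- scan$threshold[i]; break }
    if (d[i] * d[j] < 0) {
      crossing <- scan$threshold[i] +
        (scan$threshold[j] - scan$threshold[i]) * (-d[i]) / (d[j] - d[i])
      break
    }
    if (d[j] == 0) { crossing <- scan$threshold[j]; break }
  }
  structure(list(scan = scan, crossing = crossing), class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan: %d threshold(s), PPV/NPV crossing at %s>\n",
              nrow(x$scan),
              if (is.na(x$crossing)) "NA" else sprintf("%.3f A", x$crossing)))
  print(x$scan, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.threshold_scan <- function(x, ...) {
  plot(x$scan$threshold, x$scan$PPV, type = "b", ylim = c(0, 1), pch = 16,
       xlab = "RMSD threshold [A]", ylab = "predictive value", ...)
  lines(x$scan$threshold, x$scan$NPV, type = "b", pch = 1)
  if (!is.na(x$crossing)) abline(v = x$crossing, lty = 2, col = "grey50")
  legend("right", legend = c("PPV", "NPV"), pch = c(16, 1), bty = "n")
  invisible(x)
}

#' Rotatable-bond count (strict acyclic dialect)
#'
#' The classical flexibility descriptor: acyclic single bonds whose atoms
#' each bear at least one other non-terminal heavy substituent; ring bonds
#' are excluded, as are amide C-N bonds in the strict dialect.
#'
#' @param mol a `tabs_mol`.
#' @param strict exclude amide C-N bonds (default).
#' @return integer count.
#' @export
rotatable_bond_count <- function(mol, strict = TRUE) {
  bonds <- identify_torsion_bonds(mol, strict = strict)
  sum(!bonds$in_ring)
}

# Kier alpha contributions: covalent-radius ratio to Csp3 minus one.
KIER_RADII <- c(C.sp3 = 0.77, C.sp2 = 0.67, C.sp = 0.60,
                N.sp3 = 0.74, N.sp2 = 0.62, N.sp = 0.55,
                O.sp3 = 0.74, O.sp2 = 0.62,
                F.sp3 = 0.72, Cl.sp3 = 0.99, Br.sp3 = 1.14, I.sp3 = 1.33,
                P.sp3 = 1.10, S.sp3 = 1.04, B.sp3 = 0.82, Si.sp3 = 1.17)

#' Kier flexibility index phi
#'
#' Graph-based flexibility descriptor: phi = (1-kappa_alpha *
#' 2-kappa_alpha) / A, where A is the heavy-atom count, 1-kappa encodes
#' branching via the 1-bond fragment count, 2-kappa encodes cyclicity via
#' the 2-bond fragment count, and alpha corrects for non-Csp3 atoms via
#' covalent-radius ratios.  The reference point is the infinite Csp3
#' chain: for a linear alkane of A atoms, phi = A - 1.
#'
#' @param mol a `tabs_mol` with >= 3 heavy atoms.
#' @return object of class `kier_phi`: `A`, `alpha`, `P1` (bond count),
#'   `P2` (2-bond path count), `kappa1_alpha`, `kappa2_alpha`, `phi`.
#' @examples
#' kier_phi(parse_smiles("CCCCCC"))$phi   # 5 for n-hexane
#' @export
kier_phi <- function(mol) {
  A <- n_atoms(mol)
  if (A < 3) stop("Kier phi needs at least 3 heavy atoms")
  alpha <- sum(vapply(seq_len(A), function(i) kier_alpha_atom(mol, i), 0))
  P1 <- n_bonds(mol)
  deg <- heavy_degree(mol)
  P2 <- sum(deg * (deg - 1) / 2)
  k1 <- (A + alpha) * (A + alpha - 1)^2 / (P1 + alpha)^2
  k2 <- (A + alpha - 1) * (A + alpha - 2)^2 / (P2 + alpha)^2
  structure(list(A = A, alpha = alpha, P1 = P1, P2 = P2,
                 kappa1_alpha = k1, kappa2_alpha = k2,
                 phi = k1 * k2 / A),
            class = "kier_phi")
}

kier_alpha_atom <- function(mol, i) {
  el <- mol$elements[i]
  hyb <- "sp3"
  arom <- if (is.null(mol$aromatic_atom)) infer_aromatic_atoms(mol) else mol$aromatic_atom
  orders <- mol$bonds$order[mol$bonds$a1 == i | mol$bonds$a2 == i]
  if (any(orders == 3)) hyb <- "sp"
  else if (any(orders == 2) || isTRUE(arom[i])) hyb <- "sp2"
  key <- paste(el, hyb, sep = ".")
  r <- KIER_RADII[key]
  if (is.na(r)) r <- KIER_RADII[paste(el, "sp3", sep = ".")]
  if (is.na(r)) r <- KIER_RADII["C.sp3"]
  unname(r / KIER_RADII["C.sp3"] - 1)
}

#' @export
print.kier_phi <- function(x, ...) {
  cat(sprintf("<kier_phi: A %d alpha %.3f | 1k_a %.3f 2k_a %.3f | phi %.3f>\n",
              x$A, x$alpha, x$kappa1_alpha, x$kappa2_alpha, x$phi))
  invisible(x)
}
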