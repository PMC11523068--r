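# ---------------------------------------------------------------------------
# Restricted SMILES parser and SDF V2000 reader/writer.
#
# The SMILES subset covers the organic subset (B C N O P S F Cl Br I),
# aromatic lowercase (b c n o p s), brackets with charge / H-count /
# tetrahedral @ tags, bond symbols - = # :, branches and ring-closure
# digits (including %nn).  Hydrogens are never materialised.  cis/trans
# bond stereo (/ \) is accepted but ignored.
# ---------------------------------------------------------------------------

ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_SYMS <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string
#'
#' Supports the organic subset, aromatic lowercase atoms, brackets with
#' formal charge and tetrahedral tags, branches and ring closures.
#' Explicit hydrogens inside brackets are dropped (the model is heavy-atom
#' only); directional bond stereo is ignored.
#'
#' @param smiles a single SMILES string.
#' @param name optional molecule title.
#' @return a `tabs_mol`.
#' @examples
#' parse_smiles("C1CCCCC1")   # cyclohexane
#' @export
parse_smiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elements <- character(0); charges <- integer(0)
  aromatic_atom <- logical(0); stereo <- character(0)
  bonds <- list()
  ring_open <- list()     # digit label -> c(atom, pending bond order)
  stack <- integer(0)     # branch stack of previous-atom indices
  prev <- 0L
  pending <- NA           # explicit bond symbol waiting for next atom

  add_atom <- function(sym, arom, charge, st) {
    elements[length(elements) + 1L] <<- sym
    aromatic_atom[length(aromatic_atom) + 1L] <<- arom
    charges[length(charges) + 1L] <<- charge
    stereo[length(stereo) + 1L] <<- st
    idx <- length(elements)
    if (prev > 0L) {
      ord <- pending
      arom_bond <- FALSE
      if (is.na(ord)) {
        if (arom && aromatic_atom[prev]) { ord <- 1L; arom_bond <- TRUE } else ord <- 1L
      } else if (ord == 0L) { ord <- 1L; arom_bond <- TRUE }
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord, arom_bond)
    }
    pending <<- NA
    prev <<- idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 0L,
                        "/" = 1L, "\\" = 1L)
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      add_atom(at$sym, at$aromatic, at$charge, at$stereo)
      i <- j + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        lbl <- paste(chars[(i + 1L):(i + 2L)], collapse = ""); i <- i + 3L
      } else { lbl <- ch; i <- i + 1L }
      if (!is.null(ring_open[[lbl]])) {
        op <- ring_open[[lbl]]
        ord <- pending
        if (is.na(ord)) ord <- op[2]
        arom_bond <- FALSE
        if (is.na(ord)) {
          if (aromatic_atom[op[1]] && aromatic_atom[prev]) { ord <- 1L; arom_bond <- TRUE } else ord <- 1L
        } else if (ord == 0L) { ord <- 1L; arom_bond <- TRUE }
        bonds[[length(bonds) + 1L]] <- c(op[1], prev, ord, arom_bond)
        ring_open[[lbl]] <- NULL
        pending <- NA
      } else {
        ring_open[[lbl]] <- c(prev, if (is.na(pending)) NA else pending)
        pending <- NA
      }
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% ORGANIC_SUBSET) {
        add_atom(two, FALSE, 0L, NA_character_); i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(ch, FALSE, 0L, NA_character_); i <- i + 1L
      } else if (ch %in% AROMATIC_SYMS) {
        add_atom(toupper(ch), TRUE, 0L, NA_character_); i <- i + 1L
      } else if (ch == ".") {
        stop("disconnected SMILES (.) not supported: ", smiles)
      } else {
        stop("unsupported SMILES token '", ch, "' in: ", smiles)
      }
    }
  }
  if (length(ring_open)) stop("unclosed ring bond in SMILES: ", smiles)
  bdf <- if (length(bonds)) {
    m <- do.call(rbind, bonds)
    data.frame(a1 = m[, 1], a2 = m[, 2], order = m[, 3], aromatic = as.logical(m[, 4]))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                    aromatic = logical(0))
  mol <- tabs_mol(elements, bdf, charges, stereo, name = name)
  mol$aromatic_atom <- aromatic_atom
  mol
}

parse_bracket_atom <- function(body, smiles) {
  st <- NA_character_
  if (grepl("@@", body)) { st <- "@@"; body <- sub("@@", "", body) }
  else if (grepl("@", body)) { st <- "@"; body <- sub("@", "", body) }
  charge <- 0L
  if (grepl("\\+", body)) {
    charge <- sum(strsplit(body, "")[[1]] == "+")
    d <- regmatches(body, regexpr("\\+[0-9]+", body))
    if (length(d)) charge <- as.integer(sub("\\+", "", d))
    body <- gsub("\\+[0-9]*", "", body)
  } else if (grepl("-", body)) {
    charge <- -sum(strsplit(body, "")[[1]] == "-")
    d <- regmatches(body, regexpr("-[0-9]+", body))
    if (length(d)) charge <- -as.integer(sub("-", "", d))
    body <- gsub("-[0-9]*", "", body)
  }
  body <- gsub("H[0-9]*", "", body)       # implicit-H model: drop explicit H counts
  body <- gsub("^[0-9]+", "", body)       # isotope labels ignored
  sym <- body
  arom <- FALSE
  if (sym %in% AROMATIC_SYMS) { sym <- toupper(sym); arom <- TRUE }
  if (!sym %in% names(DEFAULT_VALENCE) && sym != "") {
    if (!sym %in% c("Si", "Se", "As")) stop("unsupported bracket atom [", body, "] in: ", smiles)
  }
  if (sym == "") stop("empty bracket atom in: ", smiles)
  list(sym = sym, aromatic = arom, charge = as.integer(charge), stereo = st)
}

# ---------------------------------------------------------------------------
# SDF / MOL V2000
# ---------------------------------------------------------------------------

#' Read a (multi-conformer) SDF file
#'
#' Consecutive records with identical connectivity and title are merged into
#' one molecule carrying multiple conformers, mirroring the usual handling
#' of conformer ensembles in multi-record SD files.  Explicit hydrogens in
#' the file are dropped (heavy-atom model).
#'
#' @param path path to an uncompressed V2000 SD file.
#' @return a list of `tabs_mol` objects.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  mols <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4 || !any(nzchar(rec))) next
    m <- parse_molblock(rec)
    if (is.null(m)) next
    if (length(mols) > 0) {
      last <- mols[[length(mols)]]
      if (identical(last$elements, m$elements) &&
          identical(last$bonds, m$bonds) && identical(last$name, m$name)) {
        last$conformers <- c(last$conformers, m$conformers)
        mols[[length(mols)]] <- last
        next
      }
    }
    mols[[length(mols) + 1L]] <- m
  }
  mols
}

parse_molblock <- function(rec) {
  title <- trimws(rec[1])
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) return(NULL)
  atoms <- rec[5:(4 + na)]
  xyz <- matrix(0, na, 3)
  elems <- character(na)
  for (k in seq_len(na)) {
    ln <- atoms[k]
    xyz[k, ] <- c(as.numeric(substr(ln, 1, 10)), as.numeric(substr(ln, 11, 20)),
                  as.numeric(substr(ln, 21, 30)))
    elems[k] <- trimws(substr(ln, 32, 34))
  }
  bl <- if (nb > 0) rec[(5 + na):(4 + na + nb)] else character(0)
  b1 <- b2 <- ord <- integer(nb); arom <- logical(nb)
  for (k in seq_len(nb)) {
    ln <- bl[k]
    b1[k] <- as.integer(substr(ln, 1, 3))
    b2[k] <- as.integer(substr(ln, 4, 6))
    o <- as.integer(substr(ln, 7, 9))
    if (o == 4) { ord[k] <- 1L; arom[k] <- TRUE } else ord[k] <- o
  }
  heavy <- which(elems != "H")
  remap <- integer(na); remap[heavy] <- seq_along(heavy)
  keep <- b1 %in% heavy & b2 %in% heavy
  bdf <- data.frame(a1 = remap[b1[keep]], a2 = remap[b2[keep]],
                    order = ord[keep], aromatic = arom[keep])
  mol <- tabs_mol(elems[heavy], bdf, name = title)
  mol$aromatic_atom <- infer_aromatic_atoms(mol)
  mol$conformers <- list(xyz[heavy, , drop = FALSE])
  mol
}

infer_aromatic_atoms <- function(mol) {
  arom <- logical(n_atoms(mol))
  if (n_bonds(mol) > 0) {
    for (b in which(mol$bonds$aromatic)) {
      arom[mol$bonds$a1[b]] <- TRUE
      arom[mol$bonds$a2[b]] <- TRUE
    }
  }
  arom
}

#' Write molecules to an SDF file
#'
#' Each conformer of each molecule becomes one V2000 record; aromatic
#' bonds are written with bond type 4.
#'
#' @param mols a `tabs_mol` or list of them.
#' @param path output path.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "tabs_mol")) mols <- list(mols)
  out <- character(0)
  for (mol in mols) {
    confs <- mol$conformers
    if (length(confs) == 0) confs <- list(matrix(0, n_atoms(mol), 3))
    for (xyz in confs) {
      out <- c(out, mol$name, "  tabstrings", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       n_atoms(mol), n_bonds(mol)))
      for (k in seq_len(n_atoms(mol))) {
        out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              xyz[k, 1], xyz[k, 2], xyz[k, 3], mol$elements[k]))
      }
      arom <- if (is.null(mol$aromatic_atom)) infer_aromatic_atoms(mol) else mol$aromatic_atom
      for (b in seq_len(n_bonds(mol))) {
        o <- if (isTRUE(mol$bonds$aromatic[b])) 4L else mol$bonds$order[b]
        out <- c(out, sprintf("%3d%3d%3d  0", mol$bonds$a1[b], mol$bonds$a2[b], o))
      }
      out <- c(out, "M  END", "$$$$")
    }
  }
  writeLines(out, path)
  invisible(path)
}
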