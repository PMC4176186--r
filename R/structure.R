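#' @title RNA structure container
#' @description An `rna_structure` holds an ordered set of nucleotides, each
#'   with named atoms and 3D coordinates, as a flat atom table. PDB author
#'   numbering and chain identifiers are preserved verbatim and never
#'   renumbered.
#' @name rna_structure
NULL

# Fixed van der Waals radius set (Angstroms). A single published set shipped
# as data; recorded in every output artifact. Changing it is a config option.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, H = 1.20)

#' van der Waals radii used throughout the package
#'
#' @return Named numeric vector of radii in Angstroms, by element.
#' @export
vdw_radii <- function() .vdw_radii

# Infer the element from a PDB atom name: the first alphabetic character
# (RNA atoms are all single-letter elements: C, N, O, P, H).
.element_of <- function(atom_name) {
  el <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", atom_name)
  toupper(el)
}

.radius_of <- function(element) {
  r <- .vdw_radii[element]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Construct an RNA structure from an atom table
#'
#' @param id Free-text structure identifier.
#' @param atoms data.frame with columns `chain`, `resno`, `base`, `atom`,
#'   `x`, `y`, `z`. Optional columns `element`, `is_h`, `vdw`, `occluder`
#'   are filled in when missing. Occluder rows are inert pseudo-atoms used
#'   only by synthetic fixtures; they occlude solvent but carry no roles.
#' @param validate Check base-ring completeness (default TRUE).
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(id, atoms, validate = TRUE) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "base", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$occluder)) atoms$occluder <- FALSE
  if (is.null(atoms$element)) atoms$element <- .element_of(atoms$atom)
  if (is.null(atoms$is_h)) atoms$is_h <- atoms$element == "H"
  if (is.null(atoms$vdw)) atoms$vdw <- .radius_of(atoms$element)
  rownames(atoms) <- NULL
  s <- structure(list(id = id, atoms = atoms), class = "rna_structure")
  if (validate) validate_structure(s)
  s
}

#' @export
print.rna_structure <- function(x, ...) {
  nt <- nucleotide_table(x)
  cat(sprintf("<rna_structure '%s': %d nucleotides, %d atoms%s>\n",
              x$id, nrow(nt), sum(!x$atoms$occluder),
              if (any(x$atoms$occluder))
                sprintf(" (+%d occluders)", sum(x$atoms$occluder)) else ""))
  invisible(x)
}

#' Per-nucleotide summary of a structure
#'
#' @param s An `rna_structure`.
#' @return data.frame with one row per nucleotide (`chain`, `resno`, `base`),
#'   in the order residues appear in the atom table.
#' @export
nucleotide_table <- function(s) {
  a <- s$atoms[!s$atoms$occluder, , drop = FALSE]
  key <- paste(a$chain, a$resno)
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], resno = a$resno[idx], base = a$base[idx],
             stringsAsFactors = FALSE)
}

# Rows of the atom table for one residue (occluders excluded).
.res_rows <- function(s, chain, resno) {
  which(!s$atoms$occluder & s$atoms$chain == chain & s$atoms$resno == resno)
}

#' Validate an RNA structure
#'
#' Checks that the structure is non-empty, that each (chain, residue) pair is
#' contiguous and unique, that base letters are canonical and that every
#' nucleotide carries its complete base-ring heavy-atom set (purines:
#' N1,C2,N3,C4,C5,C6,N7,C8,N9; pyrimidines: N1,C2,N3,C4,C5,C6). Exocyclic
#' atoms may be absent (a fixture may delete them); ring atoms may not.
#'
#' @param s An `rna_structure`.
#' @return Invisibly `TRUE`; errors name the offending residue.
#' @export
validate_structure <- function(s) {
  nt <- nucleotide_table(s)
  if (nrow(nt) == 0L) stop("structure '", s$id, "' contains no nucleotides")
  key <- paste(nt$chain, nt$resno)
  if (anyDuplicated(key))
    stop("duplicated residue id(s): ", paste(key[duplicated(key)], collapse = ", "))
  a <- s$atoms[!s$atoms$occluder, , drop = FALSE]
  akey <- paste(a$chain, a$resno, a$atom)
  if (anyDuplicated(akey))
    stop("duplicated atom record(s): ",
         paste(unique(akey[duplicated(akey)]), collapse = ", "))
  bad <- !nt$base %in% c("A", "C", "G", "U")
  if (any(bad))
    stop("non-canonical base for residue(s): ",
         paste(key[bad], "(", nt$base[bad], ")", collapse = ", "))
  for (i in seq_len(nrow(nt))) {
    rows <- .res_rows(s, nt$chain[i], nt$resno[i])
    have <- s$atoms$atom[rows]
    ring <- .base_ring[[nt$base[i]]]
    miss <- setdiff(ring, have)
    if (length(miss))
      stop(sprintf("residue %s%d (%s) lacks base ring atom(s): %s",
                   nt$chain[i], nt$resno[i], nt$base[i],
                   paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read an RNA fragment from a PDB file
#'
#' Keeps ATOM records of the requested chain and inclusive residue range
#' (author numbering). Alternate locations are resolved to the
#' highest-occupancy conformer; waters, ions, hetero residues and ANISOU
#' records are ignored. Hydrogens present in the file are discarded: every
#' structure is (re)protonated identically by [add_hydrogens()], so crystal
#' structures, substituted models and synthetic fixtures are treated alike.
#'
#' @param path PDB file path.
#' @param chain Chain identifier (single character).
#' @param residue_range Inclusive integer pair `c(first, last)`; `NULL` keeps
#'   the whole chain.
#' @param id Identifier for the returned structure (default: file base name).
#' @return An `rna_structure`.
#' @export
read_pdb <- function(path, chain, residue_range = NULL, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM" & a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain '", chain, "' not found in ", path)
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    a <- a[a$resno >= residue_range[1] & a$resno <= residue_range[2], , drop = FALSE]
    if (nrow(a) == 0L)
      stop(sprintf("no residues %d-%d on chain '%s' in %s",
                   residue_range[1], residue_range[2], chain, path))
    found <- sort(unique(a$resno))
    want <- residue_range[1]:residue_range[2]
    miss <- setdiff(want, found)
    if (length(miss))
      stop("missing residue(s) on chain '", chain, "': ",
           paste(miss, collapse = ", "))
  }
  # canonical RNA residue names only (strips ions/modified residues that
  # slipped into ATOM records)
  resid <- trimws(a$resid)
  a <- a[resid %in% c("A", "C", "G", "U"), , drop = FALSE]
  if (nrow(a) == 0L) stop("no canonical RNA residues in selection")
  # highest-occupancy alternate location per (resno, atom name)
  o <- a$o
  o[is.na(o)] <- 1
  ord <- order(a$resno, a$elety, -o, a$alt, method = "radix")
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$resno, a$elety)), , drop = FALSE]
  a <- a[order(match(a$resno, unique(a$resno))), , drop = FALSE]
  # restore file order within residue via eleno
  a <- a[order(a$resno, a$eleno), , drop = FALSE]
  el <- .element_of(a$elety)
  a <- a[el != "H", , drop = FALSE]
  atoms <- data.frame(chain = a$chain, resno = a$resno,
                      base = trimws(a$resid), atom = a$elety,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(path))
  rna_structure(id, atoms)
}

#' Write an RNA structure to a PDB file
#'
#' Standard ATOM records, coordinates to three decimals. Re-reading the file
#' with [read_pdb()] reproduces the structure up to coordinate rounding
#' (hydrogens, which [read_pdb()] discards, are written but not round-tripped;
#' occluder pseudo-atoms are written as HETATM `OCC` records and likewise
#' dropped on re-read).
#'
#' @param s An `rna_structure` (non-empty).
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "rna_structure"))
  a <- s$atoms
  if (nrow(a) == 0L || all(a$occluder)) stop("refusing to write an empty structure")
  type <- ifelse(a$occluder, "HETATM", "ATOM")
  resid <- ifelse(a$occluder, "OCC", a$base)
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = round(xyz, 3), type = type,
                   resno = a$resno, resid = resid, chain = a$chain,
                   elety = a$atom, eleno = seq_len(nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

# Coordinate matrix (n x 3) for selected rows of the atom table.
.coords <- function(s, rows = seq_len(nrow(s$atoms))) {
  as.matrix(s$atoms[rows, c("x", "y", "z"), drop = FALSE])
}

# Position of one named atom in one residue; NULL if absent.
.atom_pos <- function(s, chain, resno, atom) {
  r <- which(!s$atoms$occluder & s$atoms$chain == chain &
               s$atoms$resno == resno & s$atoms$atom == atom)
  if (length(r) == 0L) return(NULL)
  c(s$atoms$x[r[1]], s$atoms$y[r[1]], s$atoms$z[r[1]])
}
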