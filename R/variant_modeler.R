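# Variant 3D models by atomic superimposition of idealized base templates
# onto a reference structure, plus clash detection and rigid superposition
# of training structures.

# Kabsch least-squares rigid fit: rotation + translation taking P onto Q
# (both n x 3), with the usual determinant correction against reflections.
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rot = R, trans = t, rmsd = rmsd)
}

.apply_rigid <- function(xyz, fit) sweep(xyz %*% t(fit$rot), 2, fit$trans, "+")

# backbone atoms used for whole-structure superposition
.backbone_atoms <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

#' Superpose one structure onto another
#'
#' Optimal least-squares rigid-body fit over the shared backbone atoms
#' (P, O5', C5', C4', C3', O3') of common residues. Models built by
#' [substitute_base()] keep the seed backbone and so are already superposed
#' (RMSD 0).
#'
#' @param mobile,reference `rna_structure`s with identical residue numbering.
#' @return list with the transformed `structure` and the backbone `rmsd` (A).
#' @export
superpose <- function(mobile, reference) {
  ntm <- nucleotide_table(mobile); ntr <- nucleotide_table(reference)
  if (nrow(ntm) != nrow(ntr) ||
      !all(paste(ntm$chain, ntm$resno) == paste(ntr$chain, ntr$resno)))
    stop("mobile and reference structures differ in residue count or numbering")
  am <- mobile$atoms; ar <- reference$atoms
  km <- paste(am$chain, am$resno, am$atom)
  kr <- paste(ar$chain, ar$resno, ar$atom)
  sel <- which(am$atom %in% .backbone_atoms & !am$occluder & km %in% kr)
  if (length(sel) < 3L) stop("fewer than three shared backbone atoms")
  P <- as.matrix(am[sel, c("x", "y", "z")])
  Q <- as.matrix(ar[match(km[sel], kr), c("x", "y", "z")])
  fit <- .kabsch(P, Q)
  out <- mobile
  new_xyz <- .apply_rigid(as.matrix(am[, c("x", "y", "z")]), fit)
  out$atoms$x <- new_xyz[, 1]; out$atoms$y <- new_xyz[, 2]; out$atoms$z <- new_xyz[, 3]
  list(structure = out, rmsd = fit$rmsd)
}

# atoms used to fit the new base template onto the old base frame:
# same-class substitutions share all ring atoms; purine<->pyrimidine
# substitutions map the glycosidic nitrogen and its two ring neighbours
# (N9->N1, C8->C6, C4->C2), conserving base position and orientation about
# the glycosidic bond.
.frame_mapping <- function(old_base, new_base) {
  pur <- c("A", "G")
  old_pur <- old_base %in% pur; new_pur <- new_base %in% pur
  if (old_pur == new_pur) {
    ring <- .base_ring[[new_base]]
    cbind(new = ring, old = ring)
  } else if (new_pur) {
    cbind(new = c("N9", "C8", "C4"), old = c("N1", "C6", "C2"))
  } else {
    cbind(new = c("N1", "C6", "C2"), old = c("N9", "C8", "C4"))
  }
}

#' Substitute the base of one residue
#'
#' Replaces the residue's base atoms by an idealized template of the new base,
#' rigid-body superposed onto the old base frame, conserving base position and
#' orientation. Sugar, backbone and all other residues are untouched;
#' hydrogens of the residue are dropped (rebuild with [add_hydrogens()]).
#'
#' @param s An `rna_structure`.
#' @param resno Residue number to substitute.
#' @param new_base Target base letter.
#' @param chain Chain id; default: the first chain carrying `resno`.
#' @return The substituted `rna_structure`.
#' @export
substitute_base <- function(s, resno, new_base, chain = NULL) {
  stopifnot(inherits(s, "rna_structure"))
  if (!new_base %in% c("A", "C", "G", "U")) stop("unknown base letter: ", new_base)
  if (is.null(chain)) {
    cand <- s$atoms$chain[!s$atoms$occluder & s$atoms$resno == resno]
    if (length(cand) == 0L) stop("no residue numbered ", resno)
    chain <- cand[1]
  }
  rows <- .res_rows(s, chain, resno)
  if (length(rows) == 0L) stop(sprintf("no residue %s%d", chain, resno))
  old_base <- s$atoms$base[rows[1]]
  map <- .frame_mapping(old_base, new_base)
  tpl <- .nt_templates[.nt_templates$base == new_base, ]
  P <- as.matrix(tpl[match(map[, "new"], tpl$atom), c("x", "y", "z")])
  Q <- t(vapply(map[, "old"], function(a) {
    p <- .atom_pos(s, chain, resno, a)
    if (is.null(p)) stop(sprintf("residue %s%d lacks frame atom %s", chain, resno, a))
    p
  }, numeric(3)))
  fit <- .kabsch(P, Q)
  new_atoms <- .base_heavy[[new_base]]
  tb <- tpl[match(new_atoms, tpl$atom), ]
  pos <- .apply_rigid(as.matrix(tb[, c("x", "y", "z")]), fit)
  base_df <- data.frame(chain = chain, resno = resno, base = new_base,
                        atom = new_atoms, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        element = .element_of(new_atoms), stringsAsFactors = FALSE)
  base_df$is_h <- FALSE
  base_df$vdw <- .radius_of(base_df$element)
  base_df$occluder <- FALSE
  a <- s$atoms
  # drop the residue's old base atoms and hydrogens, keep sugar/backbone
  is_res <- seq_len(nrow(a)) %in% rows
  drop <- is_res & (a$atom %in% .base_heavy[[old_base]] | a$is_h)
  keep_res_rows <- which(is_res & !drop)
  a$base[is_res] <- new_base
  # insert the new base after the residue's retained atoms
  last_kept <- max(keep_res_rows)
  out <- rbind(a[seq_len(last_kept), , drop = FALSE][!drop[seq_len(last_kept)], , drop = FALSE],
               base_df[, names(a)],
               if (last_kept < nrow(a))
                 a[(last_kept + 1):nrow(a), , drop = FALSE][!drop[(last_kept + 1):nrow(a)], , drop = FALSE])
  rownames(out) <- NULL
  s$atoms <- out
  s
}

#' Detect steric clashes between non-bonded heavy atoms
#'
#' All heavy-atom pairs from different residues closer than `cutoff`,
#' excluding the bonded O3'(i)-P(i+1) backbone linkage of sequence-adjacent
#' residues and fixture occluder pseudo-atoms.
#'
#' @param s An `rna_structure`.
#' @param cutoff Distance cutoff in Angstroms (default 2.0).
#' @return A `clash_report`: data.frame `pairs` (atom identifiers and
#'   distance) and `worst_distance` (smallest pair distance, NA if clean).
#' @export
detect_clashes <- function(s, cutoff = 2.0) {
  stopifnot(inherits(s, "rna_structure"))
  a <- s$atoms[!s$atoms$is_h & !s$atoms$occluder, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  pairs <- list()
  if (cutoff > 0 && n > 1) {
    nt <- nucleotide_table(s)
    res_idx <- match(paste(a$chain, a$resno), paste(nt$chain, nt$resno))
    for (i in seq_len(n - 1)) {
      d2 <- rowSums(sweep(xyz[(i + 1):n, , drop = FALSE], 2, xyz[i, ])^2)
      hits <- which(d2 < cutoff^2) + i
      for (j in hits) {
        if (res_idx[i] == res_idx[j]) next
        # bonded backbone linkage between sequence-adjacent residues
        adj <- abs(res_idx[i] - res_idx[j]) == 1L
        lk <- sort(c(paste(a$atom[i]), paste(a$atom[j])))
        if (adj && identical(lk, c("O3'", "P"))) next
        pairs[[length(pairs) + 1L]] <- data.frame(
          atom1 = sprintf("%s%d:%s", a$chain[i], a$resno[i], a$atom[i]),
          atom2 = sprintf("%s%d:%s", a$chain[j], a$resno[j], a$atom[j]),
          distance = sqrt(d2[j - i]), stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(atom1 = character(0), atom2 = character(0), distance = numeric(0))
  rep <- list(pairs = pairs,
              worst_distance = if (nrow(pairs)) min(pairs$distance) else NA_real_,
              cutoff = cutoff)
  class(rep) <- "clash_report"
  rep
}

#' @export
print.clash_report <- function(x, ...) {
  if (nrow(x$pairs) == 0L) {
    cat(sprintf("<clash_report: clean (cutoff %.2f A)>\n", x$cutoff))
  } else {
    cat(sprintf("<clash_report: %d pair(s) < %.2f A, worst %.2f A>\n",
                nrow(x$pairs), x$cutoff, x$worst_distance))
  }
  invisible(x)
}

#' Specify a sequence variant
#'
#' @param id Variant identifier.
#' @param substitutions Named character vector, residue number -> base letter
#'   (e.g. `c("2658" = "U", "2663" = "C")`); empty means the seed sequence.
#' @param label `"active"`, `"inactive"` or `"unknown"`.
#' @param note Free text (e.g. measured activity).
#' @return A `variant_spec`.
#' @export
variant_spec <- function(id, substitutions = character(0),
                         label = c("unknown", "active", "inactive"),
                         note = "") {
  label <- match.arg(label)
  if (length(substitutions)) {
    stopifnot(!is.null(names(substitutions)))
    bad <- !substitutions %in% c("A", "C", "G", "U")
    if (any(bad)) stop("invalid base letter(s): ", paste(substitutions[bad], collapse = ", "))
  }
  structure(list(id = id, substitutions = substitutions, label = label,
                 note = note), class = "variant_spec")
}

#' Build the 3D model of a sequence variant
#'
#' Applies every base substitution of the variant to the seed with
#' [substitute_base()], re-adds hydrogens and screens the result for steric
#' clashes. A clashing model is flagged but still returned: scoring proceeds,
#' as clashes are themselves informative about the variant.
#'
#' @param seed The reference `rna_structure`.
#' @param variant A `variant_spec`.
#' @param clash_cutoff Clash distance cutoff (A).
#' @return list: `structure` (the model), `clashes` (a `clash_report`),
#'   `clashed` (logical).
#' @export
build_variant_model <- function(seed, variant, clash_cutoff = 2.0) {
  stopifnot(inherits(variant, "variant_spec"))
  m <- seed
  nt <- nucleotide_table(seed)
  for (rn in names(variant$substitutions)) {
    rni <- as.integer(rn)
    if (!rni %in% nt$resno)
      stop(sprintf("variant '%s': residue %s not in seed", variant$id, rn))
    m <- substitute_base(m, rni, variant$substitutions[[rn]])
  }
  m$id <- paste0(seed$id, "|", variant$id)
  m <- add_hydrogens(m)
  cl <- detect_clashes(m, cutoff = clash_cutoff)
  if (nrow(cl$pairs))
    warning(sprintf("variant '%s': %d atomic clash(es), worst %.2f A",
                    variant$id, nrow(cl$pairs), cl$worst_distance))
  list(structure = m, clashes = cl, clashed = nrow(cl$pairs) > 0L)
}

#' Read a variant table
#'
#' TSV with header columns `id`, `substitutions` (comma-separated
#' `<residue><base>` tokens, e.g. `2658U,2663C`; empty = seed sequence),
#' `label` (`active|inactive|unknown`) and optional `note`.
#'
#' @param path TSV file path.
#' @return list of `variant_spec`.
#' @export
read_variants <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "substitutions", "label")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(tb$note)) tb$note <- ""
  lapply(seq_len(nrow(tb)), function(i) {
    variant_spec(tb$id[i], parse_substitutions(tb$substitutions[i]),
                 label = tb$label[i], note = tb$note[i])
  })
}

#' Parse a substitution string
#'
#' @param txt Comma-separated `<residue><base>` tokens, e.g. `"2658U,2663C"`;
#'   empty or NA means no substitutions.
#' @return Named character vector residue -> base.
#' @export
parse_substitutions <- function(txt) {
  if (is.na(txt) || !nzchar(trimws(txt))) return(character(0))
  toks <- trimws(strsplit(txt, ",")[[1]])
  m <- regmatches(toks, regexec("^([0-9]+)([ACGU])$", toks))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed substitution token(s): ", paste(toks[bad], collapse = ", "))
  stats::setNames(vapply(m, `[`, character(1), 3), vapply(m, `[`, character(1), 2))
}
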