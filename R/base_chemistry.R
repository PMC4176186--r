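# Hydrogen placement and H-bond direction vectors.
#
# All in-plane constructions use the least-squares plane of the base ring.
# Direction conventions (standard H-bond stereochemistry): donors point along
# N->H; carbonyl acceptors carry two in-plane lone pairs at +/-60 degrees from
# the C->O extension; ring-N acceptors point along the external bisector of
# the two adjacent ring bonds; neutral C-H groups point along C->H; neutral
# carbons without hydrogens (guanine C2) point from the ring centroid through
# the atom. These live in one table (.role_table_data) so the convention can
# be revised without touching the scoring core.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("cannot normalize a near-zero vector")
  v / n
}

# least-squares plane of a point set: list(centroid, normal)
.ls_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

# ring geometry context for one residue: coordinates of ring atoms + plane
.ring_context <- function(s, chain, resno, base) {
  ring <- .base_ring[[base]]
  pos <- t(vapply(ring, function(a) {
    p <- .atom_pos(s, chain, resno, a)
    if (is.null(p)) stop(sprintf("residue %s%d missing ring atom %s", chain, resno, a))
    p
  }, numeric(3)))
  pl <- .ls_plane(pos)
  if (any(!is.finite(pl$normal))) stop(sprintf("degenerate ring geometry in residue %s%d", chain, resno))
  list(pos = pos, centroid = pl$centroid, normal = pl$normal)
}

# external bisector of atom `a`'s two bonded base neighbours, projected into
# the base plane
.bisector_dir <- function(s, chain, resno, base, a, ctx) {
  nb <- .base_neighbors[[base]][[a]]
  nb <- nb[vapply(nb, function(n) !is.null(.atom_pos(s, chain, resno, n)), logical(1))]
  p <- .atom_pos(s, chain, resno, a)
  if (length(nb) < 2)
    stop(sprintf("atom %s of residue %s%d has fewer than two placed neighbours", a, chain, resno))
  u1 <- .unit(p - .atom_pos(s, chain, resno, nb[1]))
  u2 <- .unit(p - .atom_pos(s, chain, resno, nb[2]))
  v <- u1 + u2
  v <- v - ctx$normal * sum(v * ctx$normal)   # keep strictly in-plane
  .unit(v)
}

# the two sp2 amino directions (N->H) for amino nitrogen `a` attached to
# carbon `cc`, in the base plane at +/-60 degrees from the C->N extension
.amino_dirs <- function(s, chain, resno, a, cc, ctx) {
  n <- .atom_pos(s, chain, resno, a)
  c0 <- .atom_pos(s, chain, resno, cc)
  v <- .unit(n - c0)
  v <- .unit(v - ctx$normal * sum(v * ctx$normal))
  p <- .unit(.cross3(ctx$normal, v))
  rbind(v * cos(pi / 3) + p * sin(pi / 3),
        v * cos(pi / 3) - p * sin(pi / 3))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# two carbonyl lone-pair directions for oxygen `a` attached to carbon `cc`
.carbonyl_dirs <- function(s, chain, resno, a, cc, ctx) {
  o <- .atom_pos(s, chain, resno, a)
  c0 <- .atom_pos(s, chain, resno, cc)
  v <- .unit(o - c0)
  v <- .unit(v - ctx$normal * sum(v * ctx$normal))
  p <- .unit(.cross3(ctx$normal, v))
  rbind(v * cos(pi / 3) + p * sin(pi / 3),
        v * cos(pi / 3) - p * sin(pi / 3))
}

#' Place base hydrogens at ideal positions
#'
#' Rebuilds all base hydrogens with ideal sp2 geometry (N-H 1.01 A, C-H
#' 1.08 A, in the base plane) plus the 2'-hydroxyl hydrogen (O-H 0.96 A).
#' Hydrogens already present are replaced, so the operation is idempotent and
#' every structure -- crystal fragment, substituted model or synthetic
#' fixture -- ends up protonated identically. Hydrogens whose parent heavy
#' atom is absent (e.g. a deleted exocyclic group in a fixture) are skipped.
#'
#' @param s An `rna_structure`.
#' @return The structure with hydrogens placed.
#' @export
add_hydrogens <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  a <- s$atoms[!(s$atoms$is_h), , drop = FALSE]
  s2 <- s
  s2$atoms <- a
  nt <- nucleotide_table(s2)
  hrows <- list()
  for (i in seq_len(nrow(nt))) {
    ch <- nt$chain[i]; rn <- nt$resno[i]; b <- nt$base[i]
    ctx <- .ring_context(s2, ch, rn, b)
    ht <- .base_hydrogens[[b]]
    for (j in seq_len(nrow(ht))) {
      parent <- ht$parent[j]
      pp <- .atom_pos(s2, ch, rn, parent)
      if (is.null(pp)) next
      if (ht$rule[j] == "ring") {
        d <- .bisector_dir(s2, ch, rn, b, parent, ctx)
        hpos <- pp + ht$len[j] * d
      } else {  # amino: H61/H21/H41 take the +60 branch, *2 the -60 branch
        cc <- .amino_carbon[[b]][[parent]]
        dirs <- .amino_dirs(s2, ch, rn, parent, cc, ctx)
        k <- if (grepl("1$", ht$h[j])) 1L else 2L
        hpos <- pp + ht$len[j] * dirs[k, ]
      }
      hrows[[length(hrows) + 1L]] <- data.frame(
        chain = ch, resno = rn, base = b, atom = ht$h[j],
        x = hpos[1], y = hpos[2], z = hpos[3], stringsAsFactors = FALSE)
    }
    # 2'-hydroxyl
    o2p <- .atom_pos(s2, ch, rn, "O2'")
    c2p <- .atom_pos(s2, ch, rn, "C2'")
    if (!is.null(o2p) && !is.null(c2p)) {
      hpos <- o2p + 0.96 * .unit(o2p - c2p)
      hrows[[length(hrows) + 1L]] <- data.frame(
        chain = ch, resno = rn, base = b, atom = "HO2'",
        x = hpos[1], y = hpos[2], z = hpos[3], stringsAsFactors = FALSE)
    }
  }
  if (length(hrows)) {
    h <- do.call(rbind, hrows)
    h$occluder <- FALSE
    h$element <- "H"
    h$is_h <- TRUE
    h$vdw <- .vdw_radii[["H"]]
    out <- rbind(a, h)
    # keep each residue's atoms contiguous, residue order unchanged
    keys <- unique(paste(a$chain, a$resno))
    out <- out[order(match(paste(out$chain, out$resno), keys)), , drop = FALSE]
    rownames(out) <- NULL
    s2$atoms <- out
  }
  s2
}

# names of the hydrogens attached to one heavy atom of a base
.attached_h <- function(base, heavy) {
  ht <- .base_hydrogens[[base]]
  hs <- ht$h[ht$parent == heavy]
  if (heavy == "O2'") hs <- c(hs, "HO2'")
  hs
}

#' H-bonding direction vectors for one base heavy atom
#'
#' @param s An `rna_structure`.
#' @param resno Residue number.
#' @param atom_name Base heavy-atom name (must carry a role, see
#'   [role_table()]).
#' @param chain Chain id; defaults to the first chain carrying `resno`.
#' @return Matrix (one unit vector per row) of potential H-bonding directions.
#' @export
hbond_directions <- function(s, resno, atom_name, chain = NULL) {
  if (is.null(chain)) {
    cand <- s$atoms$chain[!s$atoms$occluder & s$atoms$resno == resno]
    if (length(cand) == 0L) stop("no residue numbered ", resno)
    chain <- cand[1]
  }
  rows <- .res_rows(s, chain, resno)
  base <- s$atoms$base[rows[1]]
  rt <- .role_table_data[.role_table_data$base == base &
                           .role_table_data$atom == atom_name, ]
  if (nrow(rt) == 0L)
    stop(sprintf("atom %s carries no H-bonding role in base %s", atom_name, base))
  ctx <- .ring_context(s, chain, resno, base)
  dirs <- switch(rt$geometry,
    bisector = matrix(.bisector_dir(s, chain, resno, base, atom_name, ctx), nrow = 1),
    amino = .amino_dirs(s, chain, resno, atom_name,
                        .amino_carbon[[base]][[atom_name]], ctx),
    carbonyl = .carbonyl_dirs(s, chain, resno, atom_name,
                              .carbonyl_carbon[[base]][[atom_name]], ctx),
    centroid = {
      p <- .atom_pos(s, chain, resno, atom_name)
      matrix(.unit(p - ctx$centroid), nrow = 1)
    })
  dirs / sqrt(rowSums(dirs^2))
}

#' Annotate a structure with its chemical groups
#'
#' One group per role-bearing base heavy atom present in the structure:
#' position, donor/acceptor/neutral role and H-bonding direction vectors.
#' Solvent-exposed areas are left `NA` and filled by [group_areas()].
#' Groups are ordered by residue (structure order) then atom name, so the
#' annotation is deterministic.
#'
#' @param s An `rna_structure`.
#' @return A `chem_groups` data.frame with list-column `dirs`.
#' @export
annotate <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  nt <- nucleotide_table(s)
  recs <- list()
  for (i in seq_len(nrow(nt))) {
    ch <- nt$chain[i]; rn <- nt$resno[i]; b <- nt$base[i]
    rt <- .role_table_data[.role_table_data$base == b, ]
    rt <- rt[order(rt$atom), , drop = FALSE]
    for (j in seq_len(nrow(rt))) {
      p <- .atom_pos(s, ch, rn, rt$atom[j])
      if (is.null(p)) next  # exocyclic atom deleted
      d <- hbond_directions(s, rn, rt$atom[j], chain = ch)
      recs[[length(recs) + 1L]] <- list(
        chain = ch, resno = rn, base = b, atom = rt$atom[j], role = rt$role[j],
        x = p[1], y = p[2], z = p[3], dirs = d)
    }
  }
  g <- data.frame(
    chain = vapply(recs, `[[`, character(1), "chain"),
    resno = vapply(recs, `[[`, numeric(1), "resno"),
    base = vapply(recs, `[[`, character(1), "base"),
    atom = vapply(recs, `[[`, character(1), "atom"),
    role = vapply(recs, `[[`, character(1), "role"),
    x = vapply(recs, `[[`, numeric(1), "x"),
    y = vapply(recs, `[[`, numeric(1), "y"),
    z = vapply(recs, `[[`, numeric(1), "z"),
    area = NA_real_, stringsAsFactors = FALSE)
  g$dirs <- lapply(recs, `[[`, "dirs")
  class(g) <- c("chem_groups", "data.frame")
  g
}

# "resno:atom" identifiers used in profiles, reports and fixtures
.group_ids <- function(groups) paste0(groups$resno, ":", groups$atom)
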