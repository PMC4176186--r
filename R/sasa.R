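# Deterministic Shrake-Rupley solvent-accessible surface area.
#
# Each atom's accessible area is the fraction of a fixed quasi-uniform point
# lattice on its expanded sphere (r_vdw + probe) that falls outside every
# other atom's expanded sphere, times 4*pi*(r_vdw + probe)^2.
#
# The lattice is laid out in a molecule-local canonical frame (centroid +
# moment axes with third-moment sign fixing), so the computed areas are
# invariant under rigid-body motion of the whole structure, not merely
# approximately so.

# Fibonacci sphere lattice: n quasi-uniform unit vectors.
.fib_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

# Canonical molecule-local frame: rotate coordinates onto the principal axes
# of the atom cloud. Axis signs are fixed by the third central moment along
# each axis (rotation-equivariant), falling back to the first atom's
# projection when the cloud is symmetric; handedness is enforced last.
.canonical_frame <- function(xyz) {
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (nrow(xyz) < 3L) return(list(center = ctr, rot = diag(3)))
  cv <- crossprod(xc) / nrow(xc)
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors
  for (k in 1:2) {
    proj <- xc %*% v[, k]
    m3 <- sum(proj^3)
    sgn <- if (abs(m3) > 1e-8) sign(m3) else sign(proj[1] + (proj[1] == 0))
    v[, k] <- v[, k] * sgn
  }
  v[, 3] <- .cross3(v[, 1], v[, 2])
  list(center = ctr, rot = v)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA for all atoms (hydrogens and fixture occluders included) with
#' a water-sized probe. Deterministic: a fixed Fibonacci lattice evaluated in
#' a canonical molecule-local frame, so areas are reproducible and invariant
#' under rigid-body transformation of the structure.
#'
#' @param s An `rna_structure`, hydrogens already placed (see
#'   [add_hydrogens()]).
#' @param probe_radius Probe radius in Angstroms (default 1.4, water).
#' @param n_points Lattice points per atom (default 960; minimum 100).
#' @return A `sasa_result`: data.frame `per_atom` (chain, resno, atom, area
#'   in A^2) plus the parameters used.
#' @export
compute_sasa <- function(s, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(s, "rna_structure"))
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_points < 100) stop("n_points must be at least 100")
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  fr <- .canonical_frame(xyz)
  xyz <- sweep(xyz, 2, fr$center) %*% fr$rot
  rad <- a$vdw + probe_radius
  lat <- .fib_sphere(n_points)
  n <- nrow(a)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    pts <- sweep(lat * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dd <- sweep(pts[free, , drop = FALSE], 2, xyz[j, ])
      free[free] <- rowSums(dd^2) >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  res <- list(per_atom = data.frame(chain = a$chain, resno = a$resno,
                                    atom = a$atom, area = area,
                                    stringsAsFactors = FALSE),
              probe_radius = probe_radius, n_points = n_points,
              structure_id = s$id)
  class(res) <- "sasa_result"
  res
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result '%s': %d atoms, total %.1f A^2 (probe %.2f A, %d points)>\n",
              x$structure_id, nrow(x$per_atom), sum(x$per_atom$area),
              x$probe_radius, x$n_points))
  invisible(x)
}

#' Aggregate atom areas into chemical-group exposed areas
#'
#' A group's exposed area is its heavy atom's SASA plus the SASA of the
#' hydrogens covalently attached to it, implementing the rule that attached-H
#' surface counts toward the group.
#'
#' @param sasa A `sasa_result` computed on `s` (after [add_hydrogens()]).
#' @param groups `chem_groups` from [annotate()].
#' @param s The same `rna_structure` the SASA was computed on.
#' @return `groups` with the `area` column filled (A^2).
#' @export
group_areas <- function(sasa, groups, s) {
  stopifnot(inherits(sasa, "sasa_result"), inherits(groups, "chem_groups"))
  if (!identical(sasa$structure_id, s$id))
    stop("SASA was computed on '", sasa$structure_id, "', not on '", s$id, "'")
  pa <- sasa$per_atom
  akey <- paste(pa$chain, pa$resno, pa$atom)
  lookup <- function(ch, rn, at) {
    i <- match(paste(ch, rn, at), akey)
    if (is.na(i)) 0 else pa$area[i]
  }
  groups$area <- vapply(seq_len(nrow(groups)), function(i) {
    tot <- lookup(groups$chain[i], groups$resno[i], groups$atom[i])
    for (h in .attached_h(groups$base[i], groups$atom[i]))
      tot <- tot + lookup(groups$chain[i], groups$resno[i], h)
    tot
  }, numeric(1))
  groups
}
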