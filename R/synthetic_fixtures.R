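# Synthetic, download-free RNA-like fixtures with planted ground truth.
#
# Fixtures place idealized whole-nucleotide templates on a simple geometry
# (flat ladder or helical stack). Burial is produced by inert occluder
# pseudo-atoms (no roles, vdW 1.7 A) caged around a target group -- building
# realistic tertiary burial is out of scope, and occluders exist only in
# fixtures. Planted training sets delete or keep exocyclic groups so the
# profile-construction rules have an exactly known answer.

#' Specify a synthetic fixture
#'
#' @param sequence Base letters, e.g. `"GACU"`.
#' @param geometry `"ladder"` (nucleotides side by side, everything exposed)
#'   or `"helix"` (twisted stack).
#' @param buried Character vector of group ids `"<residue>:<atom>"` to force
#'   below the exposure threshold with occluder pseudo-atoms.
#' @param rng_seed Integer seed; fixed seed gives bit-identical output.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(sequence, geometry = c("ladder", "helix"),
                         buried = character(0), rng_seed = 1L) {
  geometry <- match.arg(geometry)
  letters_ <- strsplit(sequence, "")[[1]]
  bad <- !letters_ %in% c("A", "C", "G", "U")
  if (any(bad)) stop("invalid sequence letter(s): ",
                     paste(unique(letters_[bad]), collapse = ", "))
  structure(list(n_nucleotides = length(letters_), sequence = letters_,
                 geometry = geometry, buried = buried,
                 rng_seed = as.integer(rng_seed)), class = "fixture_spec")
}

.rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# Occluder cage for one atom: occluders on a sphere of `radius` around the
# atom, but only in directions more than 60 degrees away from every nearby
# (<= 3.2 A) heavy atom -- surface points facing a close atom are inside
# that atom's expanded sphere already, and skipping those directions spares
# the neighbours' own exposed area. With occluder vdW 1.7 A, probe 1.4 A and
# an 80-direction lattice, the angular coverage of each occluder (>= 74
# degrees for the largest target sphere) exceeds the lattice gaps, so the
# target's whole accessible surface ends up occluded.
.occluder_cage <- function(center, excluded_pos, radius = 2.0, n = 80) {
  u <- .fib_sphere(n)
  keep <- rep(TRUE, n)
  for (b in excluded_pos) {
    vb <- .unit(b - center)
    keep <- keep & (u %*% vb) < cos(pi / 3)
  }
  sweep(u[keep, , drop = FALSE] * radius, 2, center, "+")
}

#' Build a synthetic fixture structure
#'
#' Nucleotides are numbered from 1 on chain A. Ladder geometry spaces
#' template copies 9 A apart along x (every group solvent-exposed); helix
#' geometry applies a 33-degree twist and 2.81-A rise per residue to a
#' radially shifted template. Groups listed in `spec$buried` are caged in
#' occluder pseudo-atoms.
#'
#' @param spec A `fixture_spec`.
#' @return An `rna_structure`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rows <- list()
  for (i in seq_len(spec$n_nucleotides)) {
    b <- spec$sequence[i]
    tpl <- .nt_templates[.nt_templates$base == b, ]
    xyz <- as.matrix(tpl[, c("x", "y", "z")])
    if (spec$geometry == "ladder") {
      xyz <- sweep(xyz, 2, c(9 * (i - 1), 0, 0), "+")
    } else {
      xyz <- sweep(xyz, 2, c(9, 0, 0), "+") %*% t(.rot_z(33 * (i - 1)))
      xyz <- sweep(xyz, 2, c(0, 0, 2.81 * (i - 1)), "+")
    }
    rows[[i]] <- data.frame(chain = "A", resno = i, base = b, atom = tpl$atom,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  s <- rna_structure(sprintf("fixture-%s-%s", paste(spec$sequence, collapse = ""),
                             spec$geometry), atoms)
  for (gid in spec$buried) {
    parts <- strsplit(gid, ":")[[1]]
    rn <- as.integer(parts[1]); at <- parts[2]
    p <- .atom_pos(s, "A", rn, at)
    if (is.null(p)) stop("cannot bury absent atom ", gid)
    b <- s$atoms$base[.res_rows(s, "A", rn)][1]
    sh <- add_hydrogens(s)   # the group's future hydrogens carry area too
    hpos <- Filter(Negate(is.null), lapply(.attached_h(b, at), function(h)
      .atom_pos(sh, "A", rn, h)))
    heavy <- sh$atoms[!sh$atoms$is_h & !sh$atoms$occluder, , drop = FALSE]
    near <- function(center) {
      d <- sqrt((heavy$x - center[1])^2 + (heavy$y - center[2])^2 +
                  (heavy$z - center[3])^2)
      sel <- d > 1e-6 & d <= 3.2
      lapply(which(sel), function(r) c(heavy$x[r], heavy$y[r], heavy$z[r]))
    }
    cage <- .occluder_cage(p, near(p))
    for (hp in hpos) cage <- rbind(cage, .occluder_cage(hp, c(list(p), near(hp))))
    occ <- data.frame(chain = "A", resno = 9000L + nrow(s$atoms) + seq_len(nrow(cage)),
                      base = NA_character_, atom = "OCC",
                      x = cage[, 1], y = cage[, 2], z = cage[, 3],
                      element = "C", is_h = FALSE, vdw = 1.7, occluder = TRUE,
                      stringsAsFactors = FALSE)
    s$atoms <- rbind(s$atoms, occ[, names(s$atoms)])
  }
  s
}

# exocyclic atoms that can be deleted without breaking the base ring
.deletable <- list(A = "N6", G = c("O6", "N2"), C = c("O2", "N4"),
                   U = c("O2", "O4"))

# drop one named atom from one residue
.delete_atom <- function(s, resno, atom, chain = "A") {
  r <- which(!s$atoms$occluder & s$atoms$chain == chain &
               s$atoms$resno == resno & s$atoms$atom == atom)
  if (length(r) == 0L) stop(sprintf("no atom %s in residue %s%d", atom, chain, resno))
  s$atoms <- s$atoms[-r, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

# Small perturbation of each nucleotide: a rigid rotation of the base about
# its ring centroid (<= max_deg; rotates the H-bond directions by the same
# angle while moving ring atoms < 3 A * sin(max_deg)) plus a whole-residue
# translation (<= max_shift). At the documented caps (0.3 A, 15 degrees) a
# preserved group still matches its seed counterpart: the displacement stays
# under the 1-A distance floor and the direction cosine stays >= cos(15 deg),
# both clear of the 0.75 match threshold.
.jitter_structure <- function(s, max_shift, max_deg) {
  nt <- nucleotide_table(s)
  for (i in seq_len(nrow(nt))) {
    rows <- .res_rows(s, nt$chain[i], nt$resno[i])
    if (max_deg > 0) {
      base_rows <- rows[s$atoms$atom[rows] %in% .base_heavy[[nt$base[i]]]]
      ring_rows <- rows[s$atoms$atom[rows] %in% .base_ring[[nt$base[i]]]]
      ctr <- colMeans(.coords(s, ring_rows))
      ax <- .unit(stats::rnorm(3))
      ang <- stats::runif(1, 0, max_deg) * pi / 180
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      xyz <- sweep(sweep(.coords(s, base_rows), 2, ctr) %*% t(R), 2, ctr, "+")
      s$atoms$x[base_rows] <- xyz[, 1]
      s$atoms$y[base_rows] <- xyz[, 2]
      s$atoms$z[base_rows] <- xyz[, 3]
    }
    if (max_shift > 0) {
      shift <- .unit(stats::rnorm(3)) * stats::runif(1, 0, max_shift)
      xyz <- sweep(.coords(s, rows), 2, shift, "+")
      s$atoms$x[rows] <- xyz[, 1]; s$atoms$y[rows] <- xyz[, 2]; s$atoms$z[rows] <- xyz[, 3]
    }
  }
  s
}

#' Generate a training set with planted determinants
#'
#' Produces a seed structure, `n_pos` positive and `n_neg` negative copies
#' such that [build_profile()] must recover exactly the planted determinant
#' set: positives preserve every planted group (optionally under a small
#' rigid jitter); each planted group is deleted in at least one negative
#' (round-robin); one non-planted exocyclic control group is deleted in the
#' first positive so that it fails the present-in-all-positives rule; all
#' remaining groups are present everywhere and are filtered out as
#' uninformative.
#'
#' Planted determinants must be exocyclic groups (A:N6, G:O6/N2, C:O2/N4,
#' U:O2/O4): those can be removed without breaking the base ring, emulating
#' the loss of a group under base substitution.
#'
#' @param seed_spec A `fixture_spec` for the seed.
#' @param n_pos,n_neg Numbers of positive / negative structures.
#' @param planted Character vector of planted group ids `"<residue>:<atom>"`.
#' @param rng_seed Integer seed.
#' @param jitter Maximum rigid translation of each nucleotide in positives,
#'   A (default 0: positives reproduce the seed geometry exactly, as base
#'   substitution over a common reference does; at most 0.3).
#' @param dir_jitter_deg Maximum rigid rotation per nucleotide, degrees
#'   (default 0; at most 15).
#' @return list: `seed`, `positives`, `negatives`, `expected` (planted ids,
#'   empty if `n_neg == 0`), `control_positive_deleted`.
#' @export
make_planted_training_set <- function(seed_spec, n_pos, n_neg, planted,
                                      rng_seed = 1L, jitter = 0,
                                      dir_jitter_deg = 0) {
  stopifnot(n_pos >= 1, n_neg >= 0, length(planted) >= 1,
            jitter <= 0.3, dir_jitter_deg <= 15)
  seed <- make_fixture(seed_spec)
  nt <- nucleotide_table(seed)
  pl <- strsplit(planted, ":")
  for (k in seq_along(pl)) {
    rn <- as.integer(pl[[k]][1]); at <- pl[[k]][2]
    b <- nt$base[match(rn, nt$resno)]
    if (is.na(b)) stop("planted residue ", rn, " not in seed")
    if (!at %in% .deletable[[b]])
      stop(sprintf("planted group %s is not a deletable exocyclic group of %s",
                   planted[k], b))
  }
  # control: an exocyclic group not planted, deleted in the first positive
  all_exo <- unlist(lapply(seq_len(nrow(nt)), function(i)
    paste0(nt$resno[i], ":", .deletable[[nt$base[i]]])))
  control <- setdiff(all_exo, planted)
  if (length(control) == 0L) stop("no non-planted exocyclic group available as control")
  control <- control[1]
  set.seed(rng_seed)
  positives <- lapply(seq_len(n_pos), function(i) {
    p <- seed
    p$id <- sprintf("%s|pos%02d", seed$id, i)
    if (jitter > 0 || dir_jitter_deg > 0)
      p <- .jitter_structure(p, jitter, dir_jitter_deg)
    if (i == 1L) {
      cp <- strsplit(control, ":")[[1]]
      p <- .delete_atom(p, as.integer(cp[1]), cp[2])
    }
    p
  })
  negatives <- lapply(seq_len(n_neg), function(i) {
    n <- seed
    n$id <- sprintf("%s|neg%02d", seed$id, i)
    n
  })
  if (n_neg > 0) {
    for (k in seq_along(pl)) {
      tgt <- ((k - 1) %% n_neg) + 1
      negatives[[tgt]] <- .delete_atom(negatives[[tgt]],
                                       as.integer(pl[[k]][1]), pl[[k]][2])
    }
  }
  list(seed = seed, positives = positives, negatives = negatives,
       expected = if (n_neg > 0) sort(planted) else character(0),
       control_positive_deleted = control)
}

#' Monte-Carlo SASA oracle
#'
#' Independent check of [compute_sasa()]: for each atom, rejection sampling
#' of uniform random points on its expanded sphere, counting the fraction
#' outside every other atom's expanded sphere. Returns a binomial standard
#' error per atom. Slower and stochastic; intended for validation only.
#'
#' @param s An `rna_structure`.
#' @param probe_radius Probe radius, A.
#' @param n_samples Random points per atom (at least 1e4).
#' @param rng_seed Integer seed (same seed, identical output).
#' @return data.frame: chain, resno, atom, area, se.
#' @export
mc_sasa_oracle <- function(s, probe_radius = 1.4, n_samples = 1e5,
                           rng_seed = 1L) {
  stopifnot(inherits(s, "rna_structure"), n_samples >= 1e4)
  set.seed(rng_seed)
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$vdw + probe_radius
  n <- nrow(a)
  area <- se <- numeric(n)
  for (i in seq_len(n)) {
    g <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    pts <- sweep(g * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_samples)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 >= rad[j]^2
    }
    p <- mean(free)
    tot <- 4 * pi * rad[i]^2
    area[i] <- tot * p
    se[i] <- tot * sqrt(p * (1 - p) / n_samples)
  }
  data.frame(chain = a$chain, resno = a$resno, atom = a$atom,
             area = area, se = se, stringsAsFactors = FALSE)
}
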