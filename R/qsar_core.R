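# Activity-profile construction and variant scoring.
#
# Potential determinants are the seed's solvent-exposed base chemical groups.
# A group is kept as an activity determinant iff it is matched (score >= the
# match threshold) in every positive training structure AND fails to match
# (best score < the same threshold) in at least one negative structure.
# Predicted activity of a new variant is the mean over determinants of the
# best match score in its model, with no per-determinant thresholding.

#' Scoring and filtering parameters
#'
#' @param probe_radius Solvent probe radius, Angstroms (default 1.4, water).
#' @param area_min Minimum exposed area (heavy atom + attached hydrogens) for
#'   a group to count as solvent-accessible, A^2 (default 0.25; the threshold
#'   is inclusive).
#' @param match_threshold Minimum match score for a determinant to count as
#'   present in a structure, unitless in (0,1] (default 0.75).
#' @param distance_floor Distance under which no 1/d^2 penalty applies, A
#'   (default 1.0).
#' @param clash_cutoff Heavy-atom clash cutoff, A (default 2.0).
#' @param n_points Shrake-Rupley lattice points per atom (default 960).
#' @return A `qsar_params` list.
#' @export
qsar_params <- function(probe_radius = 1.4, area_min = 0.25,
                        match_threshold = 0.75, distance_floor = 1.0,
                        clash_cutoff = 2.0, n_points = 960) {
  stopifnot(probe_radius > 0, area_min >= 0, distance_floor > 0,
            clash_cutoff >= 0, n_points >= 100,
            match_threshold > 0, match_threshold <= 1)
  structure(list(probe_radius = probe_radius, area_min = area_min,
                 match_threshold = match_threshold,
                 distance_floor = distance_floor,
                 clash_cutoff = clash_cutoff, n_points = n_points),
            class = "qsar_params")
}

#' Solvent-exposed chemical groups of a structure
#'
#' Annotates the structure, places hydrogens, computes SASA and keeps the
#' groups whose exposed area (heavy atom + attached hydrogens) is at least
#' `params$area_min`. The same rule is applied to every structure: seed,
#' training models and scored variants alike.
#'
#' @param s An `rna_structure` (hydrogens optional; they are rebuilt).
#' @param params `qsar_params`.
#' @return `chem_groups` with areas filled, filtered to exposed groups.
#' @export
extract_exposed_groups <- function(s, params = qsar_params()) {
  sh <- add_hydrogens(s)
  groups <- annotate(sh)
  sasa <- compute_sasa(sh, probe_radius = params$probe_radius,
                       n_points = params$n_points)
  groups <- group_areas(sasa, groups, sh)
  out <- groups[groups$area >= params$area_min, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chem_groups", "data.frame")
  out
}

# score one determinant row against one candidate row (both chem_groups rows)
.match_score_rows <- function(dx, dy, dz, ddirs, drole, cx, cy, cz, cdirs, crole,
                              distance_floor) {
  if (drole != crole) return(0)
  s <- 1
  d <- sqrt((dx - cx)^2 + (dy - cy)^2 + (dz - cz)^2)
  if (d > distance_floor) s <- s / d^2
  dots <- ddirs %*% t(cdirs)
  s * max(pmin(pmax(dots, 0), 1))
}

#' Match score between a determinant and a candidate group
#'
#' 0 if the H-bonding roles differ. Otherwise the score starts at 1.0, is
#' divided by the squared inter-atomic distance when that distance exceeds
#' `distance_floor` (1.0 A by default; kept as is below), and is multiplied
#' by the scalar product of the H-bonding unit vectors, taking the best pair
#' when either group carries several directions. Anti-aligned directions
#' clamp to 0 so scores stay within [0,1].
#'
#' @param det,cand Single rows of a `chem_groups` table.
#' @param params `qsar_params`.
#' @return Score in [0,1].
#' @export
match_score <- function(det, cand, params = qsar_params()) {
  .match_score_rows(det$x, det$y, det$z, det$dirs[[1]], det$role,
                    cand$x, cand$y, cand$z, cand$dirs[[1]], cand$role,
                    params$distance_floor)
}

#' Best match of a determinant among a structure's exposed groups
#'
#' Maximum [match_score()] over the candidates of the same role; ties broken
#' by smaller inter-atomic distance, then by (residue, atom) order. Candidate
#' search spans the whole structure, so a group lost at one position can be
#' substituted by a different atom nearby.
#'
#' @param det One row of a `chem_groups` table (the determinant).
#' @param groups `chem_groups` of the candidate structure, superposed into
#'   the seed frame.
#' @param params `qsar_params`.
#' @return list: `score` (0 if no candidate) and `match` (candidate id or NA).
#' @export
best_match <- function(det, groups, params = qsar_params()) {
  cand <- which(groups$role == det$role)
  if (length(cand) == 0L) return(list(score = 0, match = NA_character_))
  sc <- vapply(cand, function(i) {
    .match_score_rows(det$x, det$y, det$z, det$dirs[[1]], det$role,
                      groups$x[i], groups$y[i], groups$z[i], groups$dirs[[i]],
                      groups$role[i], params$distance_floor)
  }, numeric(1))
  dist <- sqrt((groups$x[cand] - det$x)^2 + (groups$y[cand] - det$y)^2 +
                 (groups$z[cand] - det$z)^2)
  ord <- order(-sc, dist, groups$resno[cand], groups$atom[cand])
  best <- cand[ord[1]]
  list(score = sc[ord[1]],
       match = sprintf("%d:%s", groups$resno[best], groups$atom[best]))
}

#' Build an activity profile from a training set
#'
#' Potential determinants are the seed's exposed groups. Each is kept iff its
#' best match score is at least `params$match_threshold` in every positive
#' structure and below the threshold in at least one negative structure
#' ("absent in at least one negative"). With no negatives the determinant
#' list is empty (warning): nothing can be tied to loss of activity.
#'
#' All structures must be superposed into the seed frame; models built by
#' [substitute_base()] over the seed already are.
#'
#' @param seed The reference `rna_structure`.
#' @param positives,negatives Lists of `rna_structure` (active / inactive
#'   training models). The seed itself need not be repeated among positives.
#' @param params `qsar_params`.
#' @return An `activity_profile`.
#' @export
build_profile <- function(seed, positives, negatives, params = qsar_params()) {
  seed_groups <- extract_exposed_groups(seed, params)
  pos_groups <- lapply(positives, extract_exposed_groups, params = params)
  neg_groups <- lapply(negatives, extract_exposed_groups, params = params)
  keep <- logical(nrow(seed_groups))
  detail <- vector("list", nrow(seed_groups))
  for (i in seq_len(nrow(seed_groups))) {
    det <- seed_groups[i, , drop = FALSE]
    pos_sc <- vapply(pos_groups, function(g) best_match(det, g, params)$score,
                     numeric(1))
    neg_sc <- vapply(neg_groups, function(g) best_match(det, g, params)$score,
                     numeric(1))
    in_all_pos <- all(pos_sc >= params$match_threshold)
    absent_in_a_neg <- length(neg_sc) > 0 && any(neg_sc < params$match_threshold)
    keep[i] <- in_all_pos && absent_in_a_neg
    detail[[i]] <- list(pos_scores = pos_sc, neg_scores = neg_sc)
  }
  if (length(negatives) == 0L)
    warning("no negative examples: every determinant list is empty")
  dets <- seed_groups[keep, , drop = FALSE]
  rownames(dets) <- NULL
  class(dets) <- c("chem_groups", "data.frame")
  prof <- list(seed_id = seed$id, determinants = dets, parameters = params,
               training_summary = list(n_positives = length(positives),
                                       n_negatives = length(negatives)),
               candidate_ids = .group_ids(seed_groups),
               match_detail = stats::setNames(detail, .group_ids(seed_groups)),
               notes = paste("negative-side absence operationalized as best",
                             "match score <", params$match_threshold,
                             "; area filter applied to all structures"))
  class(prof) <- "activity_profile"
  prof
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile of '%s': %d determinant(s) from %d+/%d- training structures>\n",
              x$seed_id, nrow(x$determinants),
              x$training_summary$n_positives, x$training_summary$n_negatives))
  if (nrow(x$determinants))
    cat(paste0("  ", .group_ids(x$determinants), " (", x$determinants$role, ")",
               collapse = "\n"), "\n")
  invisible(x)
}

#' Determinant identifiers of a profile
#'
#' @param profile An `activity_profile`.
#' @return Character vector `"<residue>:<atom>"`.
#' @export
determinant_ids <- function(profile) .group_ids(profile$determinants)

#' Score a variant model against an activity profile
#'
#' Per-determinant score is the best match in the model's exposed groups (no
#' thresholding at prediction time); the aggregate activity score is their
#' arithmetic mean, in [0,1].
#'
#' @param profile An `activity_profile` with at least one determinant.
#' @param model `rna_structure` of the variant, superposed into the seed
#'   frame.
#' @param params `qsar_params`; defaults to the profile's.
#' @param clashed Optional clash flag carried into the result.
#' @return An `activity_score`: `variant_id`, `per_determinant` (named
#'   scores), `aggregate`, `clashed`.
#' @export
score_variant <- function(profile, model, params = profile$parameters,
                          clashed = NA) {
  stopifnot(inherits(profile, "activity_profile"))
  if (nrow(profile$determinants) == 0L)
    stop("activity profile has no determinants")
  groups <- extract_exposed_groups(model, params)
  dets <- profile$determinants
  per <- vapply(seq_len(nrow(dets)), function(i) {
    best_match(dets[i, , drop = FALSE], groups, params)$score
  }, numeric(1))
  names(per) <- .group_ids(dets)
  res <- list(variant_id = model$id, per_determinant = per,
              aggregate = mean(per), clashed = clashed)
  class(res) <- "activity_score"
  res
}

#' @export
print.activity_score <- function(x, ...) {
  cat(sprintf("<activity_score '%s': %.3f over %d determinant(s)%s>\n",
              x$variant_id, x$aggregate, length(x$per_determinant),
              if (isTRUE(x$clashed)) ", CLASHED" else ""))
  invisible(x)
}

#' Run the full pipeline on a seed and variant table
#'
#' Builds a model per variant, assembles the activity profile from the
#' labelled (active/inactive) variants plus the seed, then scores every
#' variant (and the seed) against it.
#'
#' @param seed The reference `rna_structure`.
#' @param variants list of `variant_spec`.
#' @param params `qsar_params`.
#' @return list: `profile`, `models`, and `scores` data.frame (variant id,
#'   label, aggregate score, clash flag).
#' @export
run_qsar <- function(seed, variants, params = qsar_params()) {
  models <- lapply(variants, function(v)
    build_variant_model(seed, v, clash_cutoff = params$clash_cutoff))
  labels <- vapply(variants, `[[`, character(1), "label")
  positives <- lapply(models[labels == "active"], `[[`, "structure")
  negatives <- lapply(models[labels == "inactive"], `[[`, "structure")
  profile <- build_profile(seed, c(list(seed), positives), negatives, params)
  scores <- lapply(seq_along(models), function(i)
    score_variant(profile, models[[i]]$structure, params,
                  clashed = models[[i]]$clashed))
  seed_score <- score_variant(profile, seed, params, clashed = FALSE)
  tab <- data.frame(
    id = c("seed", vapply(variants, `[[`, character(1), "id")),
    label = c("active", labels),
    score = c(seed_score$aggregate,
              vapply(scores, `[[`, numeric(1), "aggregate")),
    clashed = c(FALSE, vapply(models, `[[`, logical(1), "clashed")),
    stringsAsFactors = FALSE)
  list(profile = profile, models = models, scores = tab,
       score_objects = c(list(seed_score), scores))
}

#' Parameter sweep over area and match thresholds
#'
#' Rebuilds the profile and rescores the training set over a grid of exposed-
#' area and match-threshold values (defaults: areas 0 to 1.0 A^2 in steps of
#' 0.25; thresholds 0.05, 0.25, 0.50, 0.75, 0.95), reporting for each cell the
#' number of determinants and whether actives (score 1.0) separate from
#' inactives (score < 1.0).
#'
#' @param seed The reference `rna_structure`.
#' @param variants list of `variant_spec`.
#' @param areas,thresholds Grid values.
#' @param params Baseline `qsar_params` for the remaining parameters.
#' @return data.frame: area_min, match_threshold, n_determinants,
#'   min_active_score, max_inactive_score, separates.
#' @export
parameter_sweep <- function(seed, variants,
                            areas = seq(0, 1, by = 0.25),
                            thresholds = c(0.05, 0.25, 0.50, 0.75, 0.95),
                            params = qsar_params()) {
  grid <- expand.grid(area_min = areas, match_threshold = thresholds)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    p <- qsar_params(probe_radius = params$probe_radius,
                     area_min = grid$area_min[k],
                     match_threshold = grid$match_threshold[k],
                     distance_floor = params$distance_floor,
                     clash_cutoff = params$clash_cutoff,
                     n_points = params$n_points)
    res <- tryCatch(suppressWarnings(run_qsar(seed, variants, p)),
                    error = function(e) NULL)
    if (is.null(res) || nrow(res$profile$determinants) == 0L)
      return(data.frame(area_min = grid$area_min[k],
                        match_threshold = grid$match_threshold[k],
                        n_determinants = if (is.null(res)) NA_integer_ else 0L,
                        min_active_score = NA_real_,
                        max_inactive_score = NA_real_, separates = NA))
    act <- res$scores$score[res$scores$label == "active"]
    ina <- res$scores$score[res$scores$label == "inactive"]
    data.frame(area_min = grid$area_min[k],
               match_threshold = grid$match_threshold[k],
               n_determinants = nrow(res$profile$determinants),
               min_active_score = if (length(act)) min(act) else NA_real_,
               max_inactive_score = if (length(ina)) max(ina) else NA_real_,
               separates = length(act) > 0 && length(ina) > 0 &&
                 min(act) >= 1 - 1e-9 && max(ina) < 1 - 1e-9)
  })
  do.call(rbind, rows)
}
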