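# Serialized artifacts: activity profiles as versioned JSON, score reports
# and annotations as TSV. Every artifact embeds the full parameter set (and
# the van der Waals radius table) for provenance.

.PROFILE_SCHEMA <- "mc3dqsar-profile/1"

#' Write an activity profile to JSON
#'
#' @param profile An `activity_profile`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "activity_profile"))
  d <- profile$determinants
  dets <- lapply(seq_len(nrow(d)), function(i) list(
    residue = d$resno[i], atom = d$atom[i], base = d$base[i],
    chain = d$chain[i], role = d$role[i],
    position = c(d$x[i], d$y[i], d$z[i]),
    directions = unname(apply(d$dirs[[i]], 1, c, simplify = FALSE)),
    exposed_area = d$area[i]))
  obj <- list(schema = .PROFILE_SCHEMA, seed_id = profile$seed_id,
              parameters = unclass(profile$parameters),
              vdw_radii = as.list(vdw_radii()),
              training_summary = profile$training_summary,
              notes = profile$notes, determinants = dets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an activity profile from JSON
#'
#' @param path Path written by [write_profile()].
#' @return An `activity_profile` (without training match detail).
#' @export
read_profile <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, .PROFILE_SCHEMA))
    stop("unrecognized profile schema: ", obj$schema)
  dets <- obj$determinants
  g <- data.frame(
    chain = vapply(dets, function(d) d$chain, character(1)),
    resno = vapply(dets, function(d) as.numeric(d$residue), numeric(1)),
    base = vapply(dets, function(d) d$base, character(1)),
    atom = vapply(dets, function(d) d$atom, character(1)),
    role = vapply(dets, function(d) d$role, character(1)),
    x = vapply(dets, function(d) as.numeric(d$position[[1]]), numeric(1)),
    y = vapply(dets, function(d) as.numeric(d$position[[2]]), numeric(1)),
    z = vapply(dets, function(d) as.numeric(d$position[[3]]), numeric(1)),
    area = vapply(dets, function(d) as.numeric(d$exposed_area), numeric(1)),
    stringsAsFactors = FALSE)
  g$dirs <- lapply(dets, function(d)
    do.call(rbind, lapply(d$directions, function(v) as.numeric(unlist(v)))))
  class(g) <- c("chem_groups", "data.frame")
  p <- obj$parameters
  prof <- list(seed_id = obj$seed_id, determinants = g,
               parameters = qsar_params(p$probe_radius, p$area_min,
                                        p$match_threshold, p$distance_floor,
                                        p$clash_cutoff, p$n_points),
               training_summary = obj$training_summary, notes = obj$notes)
  class(prof) <- "activity_profile"
  prof
}

#' Write a score report as TSV
#'
#' One row per variant: id, label (if known), aggregate score, clash flag and
#' one column per determinant.
#'
#' @param scores list of `activity_score`.
#' @param path Output path.
#' @param labels Optional character vector of labels, recycled against
#'   `scores`.
#' @return Invisibly `path`.
#' @export
write_scores <- function(scores, path, labels = NULL) {
  ids <- vapply(scores, `[[`, character(1), "variant_id")
  agg <- vapply(scores, `[[`, numeric(1), "aggregate")
  clash <- vapply(scores, function(x) isTRUE(x$clashed), logical(1))
  per <- do.call(rbind, lapply(scores, `[[`, "per_determinant"))
  tab <- data.frame(id = ids,
                    label = if (is.null(labels)) "" else labels,
                    score = round(agg, 4), clashed = clash,
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab <- cbind(tab, round(as.data.frame(per, check.names = FALSE), 4))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a group annotation table as TSV
#'
#' @param groups A `chem_groups` table.
#' @param path Output path.
#' @param area_min Optional exposure threshold: groups within 0.05 A^2 of it
#'   get a `borderline` flag (sampling noise caveat).
#' @return Invisibly `path`.
#' @export
write_annotation <- function(groups, path, area_min = NULL) {
  tab <- data.frame(chain = groups$chain, residue = groups$resno,
                    base = groups$base, atom = groups$atom, role = groups$role,
                    n_directions = vapply(groups$dirs, nrow, integer(1)),
                    exposed_area = round(groups$area, 3),
                    stringsAsFactors = FALSE)
  if (!is.null(area_min))
    tab$borderline <- !is.na(groups$area) & abs(groups$area - area_min) <= 0.05
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
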