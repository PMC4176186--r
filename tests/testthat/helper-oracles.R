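# Independent brute-force oracles, deliberately written without reusing the
# package's scoring/filtering code paths.

# naive pharmacophore match: same arithmetic rules, separate implementation
oracle_match <- function(role1, pos1, dirs1, role2, pos2, dirs2, floor = 1.0) {
  if (role1 != role2) return(0)
  d <- sqrt(sum((pos1 - pos2)^2))
  s <- if (d > floor) 1 / d^2 else 1
  best <- 0
  for (i in seq_len(nrow(dirs1)))
    for (j in seq_len(nrow(dirs2))) {
      dp <- sum(dirs1[i, ] * dirs2[j, ])
      dp <- min(max(dp, 0), 1)
      if (dp > best) best <- dp
    }
  s * best
}

# chem_groups table -> plain list of records for the oracle
as_records <- function(groups) {
  lapply(seq_len(nrow(groups)), function(i) list(
    id = paste0(groups$resno[i], ":", groups$atom[i]),
    role = groups$role[i],
    pos = c(groups$x[i], groups$y[i], groups$z[i]),
    dirs = groups$dirs[[i]]))
}

oracle_best <- function(det, records, floor = 1.0) {
  best <- 0
  for (r in records) {
    sc <- oracle_match(det$role, det$pos, det$dirs, r$role, r$pos, r$dirs, floor)
    if (sc > best) best <- sc
  }
  best
}

# exhaustive evaluation of the two profile rules: present (>= thr) in every
# positive, absent (< thr) in at least one negative
oracle_profile <- function(seed_groups, pos_groups, neg_groups,
                           thr = 0.75, floor = 1.0) {
  seed_recs <- as_records(seed_groups)
  pos_recs <- lapply(pos_groups, as_records)
  neg_recs <- lapply(neg_groups, as_records)
  kept <- character(0)
  for (det in seed_recs) {
    in_all_pos <- TRUE
    for (p in pos_recs)
      if (oracle_best(det, p, floor) < thr) { in_all_pos <- FALSE; break }
    absent_in_neg <- FALSE
    for (n in neg_recs)
      if (oracle_best(det, n, floor) < thr) { absent_in_neg <- TRUE; break }
    if (in_all_pos && absent_in_neg) kept <- c(kept, det$id)
  }
  sort(kept)
}
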