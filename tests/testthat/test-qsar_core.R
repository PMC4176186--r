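test_that("match score reproduces the formula cases", {
  p <- qsar_params()
  u <- c(1, 0, 0)
  at <- function(pos, role = "acceptor", dirs = u) make_group(role, pos, dirs)
  # identical group: 1.0
  expect_equal(match_score(at(c(0, 0, 0)), at(c(0, 0, 0)), p), 1.0)
  # role mismatch: 0.0
  expect_equal(match_score(at(c(0, 0, 0), "donor"), at(c(0, 0, 0), "acceptor"), p), 0)
  # d = 2 A, parallel directions: 1/2^2
  expect_equal(match_score(at(c(0, 0, 0)), at(c(2, 0, 0)), p), 0.25)
  # d <= 1 A: no distance penalty, score = best dot
  expect_equal(match_score(at(c(0, 0, 0)), at(c(0.8, 0, 0), dirs = c(0.9, sqrt(1 - 0.81), 0)), p),
               0.9)
  # multiple directions: the best pair wins
  two <- make_group("acceptor", c(0, 0, 0), c(0, 1, 0, 1, 0, 0))
  expect_equal(match_score(two, at(c(0, 0, 0)), p), 1.0)
  # anti-aligned directions clamp to zero, never negative
  expect_equal(match_score(at(c(0, 0, 0)), at(c(0, 0, 0), dirs = c(-1, 0, 0)), p), 0)
  # agreement with the independent arithmetic oracle on random cases
  set.seed(42)
  for (k in 1:25) {
    r1 <- sample(c("donor", "acceptor", "neutral"), 1)
    r2 <- sample(c("donor", "acceptor", "neutral"), 1)
    p1 <- runif(3, -2, 2); p2 <- runif(3, -2, 2)
    d1 <- matrix(rnorm(6), 2); d1 <- d1 / sqrt(rowSums(d1^2))
    d2 <- matrix(rnorm(3), 1); d2 <- d2 / sqrt(rowSums(d2^2))
    g1 <- make_group(r1, p1, as.numeric(t(d1)))
    g2 <- make_group(r2, p2, as.numeric(t(d2)))
    expect_equal(match_score(g1, g2, p),
                 oracle_match(r1, p1, d1, r2, p2, d2), tolerance = 1e-12)
  }
})

test_that("best match maximizes over same-role candidates with stable ties", {
  p <- qsar_params()
  s <- ladder("GACU")
  groups <- extract_exposed_groups(s, p)
  # self-match: every group finds itself at score 1
  for (i in seq_len(nrow(groups))) {
    bm <- best_match(groups[i, , drop = FALSE], groups, p)
    expect_equal(bm$score, 1.0)
    expect_identical(bm$match, paste0(groups$resno[i], ":", groups$atom[i]))
  }
  # empty candidate list
  empty <- groups[0, , drop = FALSE]
  bm <- best_match(groups[1, , drop = FALSE], empty, p)
  expect_equal(bm$score, 0)
  expect_true(is.na(bm$match))
  # a lost group can be substituted by a nearby same-role atom elsewhere
  det <- groups[groups$resno == 1 & groups$atom == "O6", , drop = FALSE]
  without <- groups[!(groups$resno == 1 & groups$atom == "O6"), , drop = FALSE]
  bm <- best_match(det, without, p)
  expect_gt(bm$score, 0)
  expect_lt(bm$score, 0.75)
  expect_identical(bm$match, "1:N7")   # closest acceptor on the same base
})

test_that("the exposed-area filter is inclusive and removes buried groups", {
  s <- ladder("GAC")
  all_groups <- extract_exposed_groups(s, qsar_params(area_min = 0))
  # isolated ladder: every role-bearing group is exposed
  expect_equal(nrow(all_groups), 7 + 6 + 5)
  expect_true(all(all_groups$area >= 0.25))
  # inclusive threshold: area_min equal to an observed area keeps that group
  a0 <- min(all_groups$area)
  kept <- extract_exposed_groups(s, qsar_params(area_min = a0))
  expect_true(min(kept$area) == a0)
  expect_equal(nrow(kept), nrow(all_groups))
  # buried group excluded under the default threshold
  sb <- make_fixture(fixture_spec("GAC", buried = "1:N7"))
  gb <- extract_exposed_groups(sb, qsar_params())
  ids <- paste0(gb$resno, ":", gb$atom)
  expect_false("1:N7" %in% ids)
  expect_true(all(c("1:O6", "1:C8", "1:N3") %in% ids))
})

test_that("profile construction equals the brute-force rule oracle", {
  p <- qsar_params()
  ts <- make_planted_training_set(fixture_spec("GACU"), n_pos = 3, n_neg = 2,
                                  planted = c("1:O6", "4:O4"), rng_seed = 7)
  prof <- build_profile(ts$seed, ts$positives, ts$negatives, p)
  expect_identical(sort(determinant_ids(prof)), ts$expected)
  # the same decision from a fully independent rule evaluation
  oracle <- oracle_profile(extract_exposed_groups(ts$seed, p),
                           lapply(ts$positives, extract_exposed_groups, params = p),
                           lapply(ts$negatives, extract_exposed_groups, params = p))
  expect_identical(sort(determinant_ids(prof)), oracle)
  # determinants are a subset of the seed's exposed groups
  seed_ids <- mc3dqsar:::.group_ids(extract_exposed_groups(ts$seed, p))
  expect_true(all(determinant_ids(prof) %in% seed_ids))
})

test_that("no negatives means no determinants", {
  ts <- make_planted_training_set(fixture_spec("GAC"), n_pos = 2, n_neg = 0,
                                  planted = "1:O6", rng_seed = 3)
  expect_warning(prof <- build_profile(ts$seed, ts$positives, list()), "no negative")
  expect_equal(nrow(prof$determinants), 0L)
  expect_error(score_variant(prof, ts$seed), "no determinants")
})

test_that("profiles respond monotonically to added training examples", {
  p <- qsar_params()
  ts <- make_planted_training_set(fixture_spec("GACUG"), n_pos = 3, n_neg = 3,
                                  planted = c("1:O6", "3:N4", "5:N2"), rng_seed = 19)
  base_ids <- determinant_ids(build_profile(ts$seed, ts$positives, ts$negatives, p))
  # adding a negative never removes a determinant
  extra_neg <- ts$seed; extra_neg$id <- "extra-neg"
  grown <- determinant_ids(build_profile(ts$seed, ts$positives,
                                         c(ts$negatives, list(extra_neg)), p))
  expect_true(all(base_ids %in% grown))
  # adding a positive never adds a determinant
  extra_pos <- ts$negatives[[1]]; extra_pos$id <- "extra-pos"
  shrunk <- determinant_ids(build_profile(ts$seed,
                                          c(ts$positives, list(extra_pos)),
                                          ts$negatives, p))
  expect_true(all(shrunk %in% base_ids))
})

test_that("activity scores are means of per-determinant scores in [0,1]", {
  p <- qsar_params()
  ts <- make_planted_training_set(fixture_spec("GACU"), n_pos = 2, n_neg = 2,
                                  planted = c("1:O6", "4:O4"), rng_seed = 5)
  prof <- build_profile(ts$seed, ts$positives, ts$negatives, p)
  # seed scores exactly 1.0 against its own profile
  sc <- score_variant(prof, ts$seed, p)
  expect_equal(sc$aggregate, 1.0)
  expect_equal(unname(sc$per_determinant), rep(1, nrow(prof$determinants)))
  # every training structure: exact mean, bounded scores
  for (m in c(ts$positives, ts$negatives)) {
    sc <- score_variant(prof, m, p)
    expect_equal(sc$aggregate, mean(sc$per_determinant))
    expect_true(all(sc$per_determinant >= 0 & sc$per_determinant <= 1))
  }
  # deleting a determinant's group drops its score below the match threshold
  lost <- mc3dqsar:::.delete_atom(ts$seed, 1, "O6")
  sc <- score_variant(prof, lost, p)
  expect_lt(sc$per_determinant[["1:O6"]], p$match_threshold)
  expect_equal(sc$per_determinant[["4:O4"]], 1.0)
})

test_that("the full pipeline separates actives from inactives on planted data", {
  # substitution-driven scenario: activity hinges on G at position 1
  s <- ladder("GACU")
  vars <- list(variant_spec("a1", character(0), "active"),
               variant_spec("a2", c("2" = "G"), "active"),
               variant_spec("n1", c("1" = "A"), "inactive"),
               variant_spec("n2", c("1" = "A", "4" = "C"), "inactive"))
  res <- run_qsar(s, vars)
  expect_gt(nrow(res$profile$determinants), 0L)
  act <- res$scores$score[res$scores$label == "active"]
  ina <- res$scores$score[res$scores$label == "inactive"]
  expect_true(all(act == 1.0))
  expect_true(all(ina < 1.0))
  # determinants are the guanine-specific groups lost in the negatives
  expect_true(all(c("1:O6", "1:N1", "1:N2") %in% determinant_ids(res$profile)))
  # groups shared by G and A at position 1 are uninformative
  expect_false(any(c("1:N7", "1:C8", "1:N3") %in% determinant_ids(res$profile)))
})

test_that("the parameter sweep reports separation across the grid", {
  s <- ladder("GAC")
  vars <- list(variant_spec("a1", character(0), "active"),
               variant_spec("n1", c("1" = "A"), "inactive"))
  tab <- parameter_sweep(s, vars, areas = c(0.25, 0.5),
                         thresholds = c(0.25, 0.75))
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("area_min", "match_threshold", "n_determinants",
                    "separates") %in% names(tab)))
  strict <- tab[tab$match_threshold == 0.75, ]
  expect_true(all(strict$separates))
})
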