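test_that("component features equal the naive per-person double loop", {
  pipe <- medium_pipeline()
  feats <- component_features(pipe$filtered$associations, pipe$partition, pipe$S)
  memb <- pipe$partition$membership
  K <- max(memb)
  l1 <- dplyr::filter(pipe$filtered$associations, level == 1,
                      response %in% names(memb))
  set.seed(6)
  for (pid in sample(unique(l1$participant_id), 10)) {
    resp <- l1$response[l1$participant_id == pid]
    manual <- vapply(seq_len(K), function(k) {
      members <- names(memb)[memb == k]
      mean(vapply(resp, function(r) mean(pipe$S[r, members]), numeric(1)))
    }, numeric(1))
    row <- dplyr::filter(feats, participant_id == pid)
    expect_equal(unname(unlist(row[paste0("feature_", 1:K)])), manual,
                 tolerance = 1e-12)
  }
})

test_that("dominant within-component responders score highest on their component", {
  st <- simulate_study(small_config())
  f <- filter_associations(st$associations)
  S <- similarity_matrix(build_cooccurrence(f))
  part <- louvain(build_network(S), seed = 2)
  feats <- component_features(f$associations, part, S)
  shares <- component_shares(f$associations, part)
  # participants retrieving only component-1 words score feature_1 > feature_2
  pure1 <- rownames(shares)[shares[, 1] == 1]
  rows <- dplyr::filter(feats, participant_id %in% pure1)
  expect_true(all(rows$feature_1 > rows$feature_2))

  # duplicated participants give identical feature rows
  dup <- dplyr::mutate(f$associations, participant_id = paste0(participant_id, "_b"))
  feats2 <- component_features(dplyr::bind_rows(f$associations, dup), part, S)
  a <- dplyr::arrange(feats2[feats2$participant_id %in% feats$participant_id, ],
                      participant_id)
  b <- dplyr::arrange(
    dplyr::mutate(feats2[grepl("_b$", feats2$participant_id), ],
                  participant_id = sub("_b$", "", participant_id)),
    participant_id)
  expect_equal(a, b)
})

test_that("exact linear outcomes are recovered with unit standardized coefficients", {
  pipe <- medium_pipeline()
  feats <- component_features(pipe$filtered$associations, pipe$partition, pipe$S)
  st <- pipe$study
  survey <- st$survey[match(feats$participant_id, st$survey$participant_id), ]
  items <- c("general", "driving", "financial", "recreational",
             "occupational", "health", "social")
  survey[items] <- feats$feature_1  # outcome == feature_1 exactly
  reg <- fit_item_regressions(feats, st$participants, survey)
  g <- dplyr::filter(reg, item == "general")
  expect_equal(unname(g$estimate[g$term == "feature_1"]), 1, tolerance = 1e-8)
  expect_equal(max(abs(g$estimate[g$term != "feature_1"])), 0, tolerance = 1e-8)
})

test_that("rank-deficient designs are refused with the collinear columns named", {
  pipe <- medium_pipeline()
  feats <- component_features(pipe$filtered$associations, pipe$partition, pipe$S)
  feats$feature_2 <- feats$feature_1
  expect_error(fit_item_regressions(feats, pipe$study$participants,
                                    pipe$study$survey),
               "feature_1, feature_2|Rank-deficient")
})

test_that("corrected resampled t-test matches hand computation and edge cases", {
  # d = (0.1, 0.2, 0.3), J = 3, n_test/n_train = 1/9:
  # var = 0.01, se = sqrt(0.01 * (1/3 + 1/9)) = 0.0666..., t = 3
  res <- corrected_resampled_ttest(c(0.1, 0.2, 0.3), n_train = 90, n_test = 10)
  expect_equal(res$t, 3, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-3, df = 2), tolerance = 1e-12)

  zero <- corrected_resampled_ttest(rep(0, 5), 90, 10)
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)

  degen <- corrected_resampled_ttest(rep(0.2, 4), 90, 10)
  expect_true(degen$zero_variance)
  expect_lt(degen$p, 1e-300)
  expect_error(corrected_resampled_ttest(0.1, 90, 10), "at least 2")
})

test_that("cross-validation is seed-reproducible and self-comparison is null", {
  pipe <- medium_pipeline()
  feats <- component_features(pipe$filtered$associations, pipe$partition, pipe$S)
  cv1 <- cv_elastic_net(feats, pipe$study$participants, pipe$study$survey,
                        items = "general", folds = 4, repeats = 2, seed = 8)
  cv2 <- cv_elastic_net(feats, pipe$study$participants, pipe$study$survey,
                        items = "general", folds = 4, repeats = 2, seed = 8)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(nrow(cv1$folds), 3 * 4 * 2)

  self <- compare_cv_models(cv1, "combined", "combined")
  expect_equal(self$t, 0)
  expect_equal(self$p, 1)

  td <- tidy(cv1)
  expect_setequal(td$variant, c("components", "demographics", "combined"))
  expect_true(all(td$se >= 0))
})

test_that("word-level correlations respect the retrieval threshold and sign", {
  pipe <- medium_pipeline()
  st <- pipe$study
  wlc <- word_level_correlations(pipe$filtered$associations, st$survey,
                                 min_retrievals = 10)
  retr <- dplyr::distinct(dplyr::filter(pipe$filtered$associations, level == 1),
                          participant_id, response)
  counts <- table(retr$response)
  expect_true(all(wlc$n_retrievals >= 10))
  expect_false(any(names(counts)[counts < 10] %in% wlc$word))
  # ordering by mean correlation
  first_per_word <- wlc[!duplicated(wlc$word), ]
  expect_true(all(diff(first_per_word$mean_r) <= 1e-12))

  # outcome strictly higher for retrievers -> positive correlation
  w <- wlc$word[1]
  ids <- st$survey$participant_id
  ind <- ids %in% retr$participant_id[retr$response == w]
  forced <- st$survey
  forced$general <- as.integer(ifelse(ind, 9, 2))
  wlc2 <- word_level_correlations(pipe$filtered$associations, forced,
                                  min_retrievals = 10)
  expect_gt(wlc2$r[wlc2$word == w & wlc2$item == "general"], 0.9)

  # constant indicator (word retrieved by everyone) is reported missing
  allw <- dplyr::bind_rows(
    pipe$filtered$associations,
    toy_associations(lapply(ids, function(p) list(p, 1, "risk", 5, "ubiq"))))
  wlc3 <- word_level_correlations(allw, st$survey, min_retrievals = 10)
  expect_true(all(is.na(wlc3$r[wlc3$word == "ubiq"])))
})
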