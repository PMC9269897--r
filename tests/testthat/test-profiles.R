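test_that("retrieval proportions count level-1 tokens per component", {
  recs <- toy_associations(list(
    list("p1", 1, "risk", 1, "a"), list("p1", 1, "risk", 2, "b"),
    list("p2", 1, "risk", 1, "a"), list("p2", 1, "risk", 2, "a"),
    list("p2", 1, "risk", 3, "zzz")
  ))
  memb <- c(a = 1L, b = 2L)
  rp <- retrieval_proportions(recs, memb)
  expect_equal(rp$proportion[rp$component == 1], 0.75)
  expect_equal(rp$proportion[rp$component == 2], 0.25)
  expect_equal(attr(rp, "n_excluded"), 1L)  # "zzz" outside the network
  expect_equal(sum(rp$n) + attr(rp, "n_excluded"), 5L)

  # single component -> proportion 1 everywhere
  rp1 <- retrieval_proportions(recs, c(a = 1L, b = 1L), by = "position")
  expect_true(all(rp1$proportion == 1))
})

test_that("stratified retrieval proportions sum to one per stratum", {
  pipe <- medium_pipeline()
  for (by in c("position", "age", "gender")) {
    rp <- retrieval_proportions(pipe$filtered$associations, pipe$partition, by)
    stratum <- setdiff(names(rp), c("component", "n", "proportion"))
    sums <- tapply(rp$proportion, rp[[stratum]], sum)
    expect_equal(unname(as.vector(sums)), rep(1, length(sums)),
                 tolerance = 1e-12)
  }
  # conservation: denominators + excluded = total level-1 tokens
  rp <- retrieval_proportions(pipe$filtered$associations, pipe$partition)
  n_l1 <- sum(pipe$filtered$associations$level == 1)
  expect_equal(sum(rp$n) + attr(rp, "n_excluded"), n_l1)
})

test_that("sentiment propagation averages own and associate scores", {
  C <- matrix(c(2, 2, 0,
                0, 1, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("x", "y"), c("u", "v", "w")))
  lex <- tibble::tibble(word = c("x", "u", "v"), sentiment = c(0.4, 0.2, 0.2))
  s <- infer_sentiment(lex, C)
  expect_equal(s$inferred[s$word == "x"], 0.3)   # (0.4 + 0.2) / 2
  expect_equal(s$inferred[s$word == "y"], 0.2)   # associates only
  expect_true(all(abs(na.omit(s$inferred)) <= 1))

  # fixed point: own and all associates share the same score
  lex2 <- tibble::tibble(word = c("x", "y", "u", "v", "w"),
                         sentiment = rep(0.7, 5))
  s2 <- infer_sentiment(lex2, C)
  expect_equal(s2$inferred, rep(0.7, 2))

  # no coverage at all -> missing propagates
  s3 <- infer_sentiment(tibble::tibble(word = "q", sentiment = 0.5), C)
  expect_true(all(is.na(s3$inferred)))
})

test_that("inferred sentiment never leaves [-1, 1] on generated data", {
  pipe <- medium_pipeline()
  s <- infer_sentiment(pipe$study$lexicon, pipe$C)
  expect_true(all(abs(na.omit(s$inferred)) <= 1))
  expect_true(all(abs(na.omit(s$associates)) <= 1))
})

test_that("component sentiment bootstrap brackets the mean, degenerate CI collapses", {
  memb <- setNames(rep(1:2, each = 4), paste0("w", 1:8))
  sents <- setNames(c(rep(0.3, 4), c(-0.1, 0, 0.1, 0.4)), names(memb))
  cs <- component_sentiment(sents, memb, B = 200, seed = 1)
  expect_equal(cs$mean[1], 0.3)
  expect_equal(cs$lwr[1], 0.3)
  expect_equal(cs$upr[1], 0.3)
  expect_lte(cs$lwr[2], cs$mean[2])
  expect_gte(cs$upr[2], cs$mean[2])
  # missing component -> NA with warning
  expect_warning(
    component_sentiment(setNames(c(NA, NA, 0.5, 0.5), paste0("w", 1:4)),
                        setNames(c(1L, 1L, 2L, 2L), paste0("w", 1:4)),
                        B = 50, seed = 1),
    "no scored member")
})

test_that("planted component sentiment means are recovered with zero noise", {
  cfg <- small_config(sentiment_sd = 0)
  st <- simulate_study(cfg)
  f <- filter_associations(st$associations)
  C <- build_cooccurrence(f)
  s <- infer_sentiment(st$lexicon, C)
  planted <- planted_membership(st$lexicon, s$word)
  means <- tapply(s$inferred, planted, mean)
  expect_equal(as.vector(means), c(-0.5, 0.5))
})

test_that("risk similarity matches the brute-force Jaccard against the focal profile", {
  pipe <- medium_pipeline()
  focal <- focal_profile(pipe$filtered$associations, pipe$C)
  rs <- risk_similarity(pipe$C, pipe$partition, focal, B = 50, seed = 1)
  set.seed(10)
  for (w in sample(rownames(pipe$C), 5)) {
    expect_equal(rs$words$similarity[rs$words$word == w],
                 sum(pmin(focal, pipe$C[w, ])) / sum(pmax(focal, pipe$C[w, ])))
  }
  # identical profile -> similarity 1; disjoint -> 0
  C2 <- rbind(pipe$C, same = as.integer(focal))
  rs2 <- risk_similarity(C2, c(pipe$partition$membership, same = 1L), focal,
                         B = 10, seed = 1)
  expect_equal(rs2$words$similarity[rs2$words$word == "same"], 1)
  Ct <- matrix(c(1, 0, 0,
                 0, 2, 0), 2, 3, byrow = TRUE,
               dimnames = list(c("g", "h"), c("u", "v", "w")))
  rs3 <- risk_similarity(Ct, c(g = 1L, h = 1L), c(u = 3, v = 0, w = 1),
                         B = 5, seed = 1)
  expect_equal(rs3$words$similarity[rs3$words$word == "g"], 0.25)
  expect_equal(rs3$words$similarity[rs3$words$word == "h"], 0)
})

test_that("component profiles assemble sizes, proportions, sentiment and risk", {
  pipe <- medium_pipeline()
  prof <- component_profiles(pipe$filtered, pipe$partition, pipe$study$lexicon,
                             B = 50, seed = 2)
  d <- prof$components
  expect_equal(sum(d$size), length(pipe$partition$membership))
  expect_equal(sum(d$retrieval), 1, tolerance = 1e-12)
  expect_true(all(d$sentiment_lwr <= d$sentiment & d$sentiment <= d$sentiment_upr))
  expect_true(all(d$risk_lwr <= d$risk_similarity & d$risk_similarity <= d$risk_upr))
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
})

test_that("a similarity matrix compared with itself gives correlation 1 and equal blocks", {
  pipe <- medium_pipeline()
  cl <- crosslingual_compare(pipe$S, pipe$S, pipe$partition)
  expect_equal(cl$correlation, 1)
  expect_equal(cl$block_ref, cl$block_other)
  expect_equal(cl$n_terms, nrow(pipe$S))
})

test_that("cross-language comparison respects the term map and planted structure", {
  st <- simulate_study(small_config())
  f <- filter_associations(st$associations)
  C <- build_cooccurrence(f)
  S <- similarity_matrix(C)
  part <- louvain(build_network(S), seed = 2)

  # second "language": same planted structure, different seed
  cfg2 <- small_config(seed = 99L)
  st2 <- simulate_study(cfg2)
  f2 <- filter_associations(st2$associations)
  S2 <- similarity_matrix(build_cooccurrence(f2))
  cl <- crosslingual_compare(S, S2, part)
  # within-component mean similarity exceeds between-component means
  expect_true(all(diag(cl$block_other) >
                    cl$block_other[upper.tri(cl$block_other)]))
  expect_gt(cl$correlation, 0.5)

  # dropping half the terms shrinks the pair count accordingly
  half <- rownames(S)[seq_len(floor(nrow(S) / 2))]
  cl_half <- crosslingual_compare(S, S2, part,
                                  term_map = tibble::tibble(ref = half, other = half))
  nt <- cl_half$n_terms
  expect_lte(nt, length(half))
  expect_equal(cl_half$n_pairs, nt * (nt - 1) / 2)
  expect_error(
    crosslingual_compare(S, S2, part,
                         term_map = tibble::tibble(ref = "none", other = "none")),
    "shared")
})

test_that("swow tables convert to profile rows usable in the pipeline", {
  swow <- tibble::tibble(cue = c("a", "a", "b", "b", "b"),
                         response = c("x", "y", "x", "x", "z"),
                         count = c(2, 1, 1, 2, 4))
  M <- swow_to_profiles(swow)
  expect_equal(dim(M), c(2L, 3L))
  expect_equal(M["a", "x"], 2)
  expect_equal(M["b", "x"], 3)
  S <- similarity_matrix(M)
  expect_equal(S["a", "b"], sum(pmin(M["a", ], M["b", ])) / sum(pmax(M["a", ], M["b", ])))
})
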