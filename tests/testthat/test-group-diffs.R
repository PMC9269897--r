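# Build level-1 records with exact per-bin counts for one target word plus a
# filler word that tops the bin totals up to `totals`.
exact_age_data <- function(word_counts, totals) {
  recs <- list()
  pid <- 0L
  for (bin in 1:6) {
    for (i in seq_len(word_counts[bin])) {
      pid <- pid + 1L
      recs[[pid]] <- list(sprintf("p%04d", pid), 1, "risk", 1, "target", bin)
    }
    for (i in seq_len(totals[bin] - word_counts[bin])) {
      pid <- pid + 1L
      recs[[pid]] <- list(sprintf("p%04d", pid), 1, "risk", 1, "filler", bin)
    }
  }
  toy_associations(recs)
}

test_that("flat relative frequencies give a zero age slope", {
  totals <- c(100, 200, 100, 200, 100, 200)
  dat <- exact_age_data(totals / 10, totals)
  at <- age_trends(dat, words = "target")
  expect_true(at$eligible)
  expect_equal(at$beta, 0, tolerance = 1e-8)
  expect_gt(at$p, 0.99)
})

test_that("doubling relative frequency per bin gives a slope of log 2", {
  word <- 2^(1:6)                       # 2, 4, ..., 64
  totals <- rep(1000, 6)
  dat <- exact_age_data(word, totals)
  at <- age_trends(dat, words = "target")
  expect_equal(at$beta, log(2), tolerance = 1e-6)
  at_g <- age_trends(dat, words = "target", method = "gaussian")
  expect_equal(at_g$beta, log(2), tolerance = 1e-8)
})

test_that("words missing from any age bin are ineligible, not imputed", {
  dat <- exact_age_data(c(0, 2, 2, 2, 2, 2), rep(50, 6))
  at <- age_trends(dat, words = "target")
  expect_false(at$eligible)
  expect_true(is.na(at$beta))
})

test_that("age slopes are invariant to global rescaling of group totals", {
  word <- c(3, 5, 8, 12, 20, 30)
  d1 <- exact_age_data(word, rep(500, 6))
  d2 <- exact_age_data(word, rep(2000, 6))
  b1 <- age_trends(d1, words = "target")$beta
  b2 <- age_trends(d2, words = "target")$beta
  expect_equal(b1, b2, tolerance = 1e-6)
})

test_that("gender differences combine smoothed log ratios with the 2x2 chi-square", {
  gender_data <- function(cf, cm, Nf, Nm) {
    recs <- list()
    pid <- 0L
    add <- function(n, word, g) {
      for (i in seq_len(n)) {
        pid <<- pid + 1L
        recs[[pid]] <<- list(sprintf("p%04d", pid), 1, "risk", 1, word, 1, g)
      }
    }
    add(cf, "target", "f"); add(Nf - cf, "filler", "f")
    add(cm, "target", "m"); add(Nm - cm, "filler", "m")
    toy_associations(recs)
  }
  # identical relative frequencies -> delta 0, chisq 0, p 1
  eq <- gender_diffs(gender_data(10, 10, 100, 100), words = "target")
  expect_equal(eq$delta, 0)
  expect_equal(eq$chisq, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)

  # 2x2 table (10,0; 0,10): chi-square = n(ad-bc)^2 / row/col products = 20
  ex <- gender_diffs(gender_data(10, 0, 10, 10), words = "target")
  expect_equal(ex$chisq, 20)
  expect_equal(ex$delta, log(10.5 / 10) - log(0.5 / 10))

  # a word never retrieved yields no test
  none <- gender_diffs(gender_data(0, 0, 20, 20), words = "none")
  expect_true(is.na(none$chisq))
})

test_that("planted gender effects shift member-word log frequencies in sign", {
  cfg <- generator_config(n_participants = 600, words_per_component = 15,
                          age_effects = rep(0, 5),
                          gender_effects = c(0.8, -0.8, 0, 0, 0), seed = 17)
  st <- simulate_study(cfg)
  f <- filter_associations(st$associations)
  gd <- gender_diffs(f$associations, words = f$vocabulary)
  planted <- planted_membership(st$lexicon, gd$word)
  expect_gt(mean(gd$delta[planted == 1]), 0)
  expect_lt(mean(gd$delta[planted == 2]), 0)
  expect_gt(mean(gd$delta[planted == 1]), mean(gd$delta[planted == 3]))
})

test_that("component-by-group proportions are stratified and sum to one", {
  pipe <- medium_pipeline()
  byage <- component_by_group(pipe$filtered$associations, pipe$partition, "age")
  sums <- tapply(byage$proportion, byage$age_bin, sum)
  expect_equal(unname(as.vector(sums)), rep(1, 6), tolerance = 1e-12)
  bygender <- component_by_group(pipe$filtered$associations, pipe$partition,
                                 "gender")
  expect_equal(nrow(bygender), 2 * pipe$partition$n_communities)

  # planted age shift raises the first component's share across bins
  cfg <- generator_config(n_participants = 900, words_per_component = 15,
                          age_effects = c(0.4, rep(0, 4)),
                          gender_effects = rep(0, 5), seed = 23)
  st <- simulate_study(cfg)
  planted <- setNames(st$lexicon$component, st$lexicon$word)
  shares <- component_by_group(st$associations, planted, "age")
  c1 <- shares$proportion[shares$component == 1]
  expect_gt(cor(1:6, c1), 0.8)
})

test_that("benjamini-hochberg adjustment appends monotone adjusted p-values", {
  pipe <- medium_pipeline()
  at <- adjust_effects(age_trends(pipe$filtered$associations,
                                  words = pipe$filtered$vocabulary))
  ok <- !is.na(at$p)
  expect_true(all(at$p_adj[ok] >= at$p[ok]))
  expect_equal(at$p_adj[ok], stats::p.adjust(at$p[ok], "BH"))
})
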