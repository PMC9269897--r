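#' Component retrieval proportions
#'
#' Share of level-1 response tokens falling into each component, overall or
#' stratified by response position, age bin, or gender. Level-1 responses
#' outside the network vocabulary are excluded from the denominators; their
#' count is attached as attribute `"n_excluded"`.
#'
#' @param associations Association tibble (normalised responses).
#' @param partition `snowsem_partition` (or word -> component membership).
#' @param by `"overall"`, `"position"`, `"age"`, or `"gender"`.
#' @return Tibble with `component`, optional stratum column, `n`,
#'   `proportion`; proportions sum to 1 within each stratum.
#' @export
retrieval_proportions <- function(associations, partition,
                                  by = c("overall", "position", "age", "gender")) {
  by <- match.arg(by)
  memb <- as_membership(partition)
  K <- max(memb)
  l1 <- dplyr::filter(associations, .data$level == 1L)
  comp <- memb[l1$response]
  keep <- !is.na(comp)
  n_excluded <- sum(!keep)
  l1 <- l1[keep, , drop = FALSE]
  l1$component <- factor(comp[keep], levels = seq_len(K))

  strat <- switch(by,
                  overall = NULL,
                  position = rlang::sym("position"),
                  age = rlang::sym("age_bin"),
                  gender = rlang::sym("gender"))
  grouped <- if (is.null(strat)) {
    dplyr::count(l1, .data$component, .drop = FALSE)
  } else {
    dplyr::count(l1, !!strat, .data$component, .drop = FALSE)
  }
  out <- dplyr::mutate(
    if (is.null(strat)) grouped else dplyr::group_by(grouped, !!strat),
    proportion = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  out <- dplyr::mutate(out, component = as.integer(as.character(.data$component)))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Propagate sentiment from a lexicon over level-2 associates
#'
#' A word's associate sentiment is the count-weighted mean of the lexicon
#' scores of its level-2 responses (those present in the lexicon). The
#' inferred score is the average of the word's own lexicon score and its
#' associate sentiment when both exist, the associate sentiment when only
#' the word itself is missing from the lexicon, the own score when the
#' associates carry no coverage, and missing when neither is available.
#'
#' @param lexicon Tibble with `word` and `sentiment` (scores in `[-1, 1]`),
#'   or a named numeric vector.
#' @param C Co-occurrence matrix from [build_cooccurrence()].
#' @return Tibble `word`, `own`, `associates`, `inferred`.
#' @export
infer_sentiment <- function(lexicon, C) {
  s <- if (is.data.frame(lexicon)) {
    setNames(lexicon$sentiment, lexicon$word)
  } else {
    lexicon
  }
  if (any(abs(s) > 1, na.rm = TRUE)) stop_snowsem("Sentiment scores must lie in [-1, 1].")
  C <- as.matrix(C)
  covered <- intersect(colnames(C), names(s)[!is.na(s)])
  assoc <- rep(NA_real_, nrow(C))
  if (length(covered)) {
    Cc <- C[, covered, drop = FALSE]
    tot <- rowSums(Cc)
    num <- as.vector(Cc %*% s[covered])
    assoc[tot > 0] <- num[tot > 0] / tot[tot > 0]
  }
  own <- unname(s[rownames(C)])
  inferred <- dplyr::case_when(
    !is.na(own) & !is.na(assoc) ~ (own + assoc) / 2,
    is.na(own) & !is.na(assoc) ~ assoc,
    !is.na(own) & is.na(assoc) ~ own,
    TRUE ~ NA_real_
  )
  tibble(word = rownames(C), own = own, associates = assoc,
         inferred = inferred)
}

# Percentile bootstrap CI of a mean over component members.
bootstrap_component_mean <- function(values, component, B, seed, level = 0.95) {
  alpha <- (1 - level) / 2
  with_seed_opt(seed, {
    dplyr::bind_rows(lapply(sort(unique(component)), function(k) {
      x <- values[component == k & !is.na(values)]
      if (length(x) == 0L) {
        warn(sprintf("Component %d has no scored member; reporting NA.", k))
        return(tibble(component = k, n_scored = 0L, mean = NA_real_,
                      lwr = NA_real_, upr = NA_real_))
      }
      boots <- vapply(seq_len(B), function(b) mean(sample(x, replace = TRUE)),
                      numeric(1))
      tibble(component = k, n_scored = length(x), mean = mean(x),
             lwr = unname(quantile(boots, alpha)),
             upr = unname(quantile(boots, 1 - alpha)))
    }))
  })
}

#' Component sentiment with bootstrap confidence intervals
#'
#' Mean inferred sentiment per component with a percentile bootstrap CI
#' over member words.
#'
#' @param sentiments Tibble from [infer_sentiment()] (uses `inferred`), or a
#'   named numeric vector of word scores.
#' @param partition `snowsem_partition` or membership.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Tibble `component`, `n_scored`, `mean`, `lwr`, `upr`.
#' @export
component_sentiment <- function(sentiments, partition, B = 1000L, seed = 1L,
                                level = 0.95) {
  memb <- as_membership(partition)
  s <- if (is.data.frame(sentiments)) {
    setNames(sentiments$inferred, sentiments$word)
  } else {
    sentiments
  }
  s <- s[names(memb)]
  bootstrap_component_mean(unname(s), as.integer(memb), B, seed, level)
}

#' Frequency profile of the focal cue
#'
#' The focal concept is represented by the frequency vector of the level-1
#' responses it elicited, projected onto the level-2 column vocabulary of
#' the co-occurrence matrix. Out-of-vocabulary level-1 responses are dropped
#' and counted in attribute `"n_oov"`.
#'
#' @param associations Association tibble.
#' @param C Co-occurrence matrix.
#' @return Numeric vector over `colnames(C)`.
#' @export
focal_profile <- function(associations, C) {
  l1 <- dplyr::filter(associations, .data$level == 1L)
  counts <- table(l1$response)
  cols <- colnames(C)
  v <- setNames(numeric(length(cols)), cols)
  hit <- intersect(names(counts), cols)
  if (length(hit) == 0L) stop_snowsem("No level-1 response maps onto the level-2 vocabulary.")
  v[hit] <- as.numeric(counts[hit])
  attr(v, "n_oov") <- sum(counts) - sum(v)
  v
}

#' Similarity of words and components to the focal concept
#'
#' Per-word weighted Jaccard similarity between the focal profile and the
#' word's level-2 profile; components are summarised by the member mean with
#' a percentile bootstrap CI.
#'
#' @param C Co-occurrence matrix.
#' @param partition `snowsem_partition` or membership.
#' @param focal Focal profile vector over `colnames(C)` (see
#'   [focal_profile()]).
#' @param B,seed,level Bootstrap settings as in [component_sentiment()].
#' @return List with `words` (tibble `word`, `similarity`) and `components`
#'   (tibble `component`, `n_scored`, `mean`, `lwr`, `upr`).
#' @export
risk_similarity <- function(C, partition, focal, B = 1000L, seed = 1L,
                            level = 0.95) {
  C <- as.matrix(C)
  focal <- focal[colnames(C)]
  if (any(is.na(focal))) stop_snowsem("`focal` must cover the level-2 vocabulary.")
  if (sum(focal) == 0) stop_snowsem("Focal profile is empty after projection.")
  memb <- as_membership(partition)
  sim <- vapply(rownames(C), function(w) weighted_jaccard(focal, C[w, ]),
                numeric(1))
  comps <- bootstrap_component_mean(unname(sim[names(memb)]),
                                    as.integer(memb), B, seed, level)
  list(words = tibble(word = rownames(C), similarity = unname(sim)),
       components = comps)
}

#' Full component profile
#'
#' Assembles, per component: member count, overall and per-position
#' retrieval proportions, mean sentiment, and mean similarity to the focal
#' concept (both with bootstrap CIs).
#'
#' @param filtered `snowsem_filtered` object.
#' @param partition `snowsem_partition`.
#' @param lexicon Sentiment lexicon (tibble `word`, `sentiment`).
#' @param B,seed Bootstrap settings.
#' @return Object of class `snowsem_profile` (list of tibbles: `components`,
#'   `by_position`, plus `words`).
#' @export
component_profiles <- function(filtered, partition, lexicon, B = 1000L,
                               seed = 1L) {
  stopifnot(inherits(filtered, "snowsem_filtered"))
  C <- build_cooccurrence(filtered)
  overall <- retrieval_proportions(filtered$associations, partition, "overall")
  by_pos <- retrieval_proportions(filtered$associations, partition, "position")
  sent <- infer_sentiment(lexicon, C)
  sent_ci <- component_sentiment(sent, partition, B = B, seed = seed)
  focal <- focal_profile(filtered$associations, C)
  risk <- risk_similarity(C, partition, focal, B = B, seed = seed + 1L)
  memb <- as_membership(partition)
  sizes <- dplyr::count(tibble(component = as.integer(memb)), .data$component,
                        name = "size")
  components <- Reduce(function(x, y) dplyr::left_join(x, y, by = "component"), list(
    sizes,
    dplyr::select(overall, "component", retrieval = "proportion"),
    dplyr::rename(sent_ci, n_sentiment = "n_scored", sentiment = "mean",
                  sentiment_lwr = "lwr", sentiment_upr = "upr"),
    dplyr::rename(risk$components, n_risk = "n_scored", risk_similarity = "mean",
                  risk_lwr = "lwr", risk_upr = "upr")
  ))
  words <- dplyr::left_join(
    tibble(word = names(memb), component = as.integer(memb)),
    dplyr::select(sent, "word", sentiment = "inferred"), by = "word")
  words <- dplyr::left_join(words, risk$words, by = "word")
  structure(list(components = components, by_position = by_pos, words = words,
                 B = B),
            class = "snowsem_profile")
}

#' @export
print.snowsem_profile <- function(x, ...) {
  cat(sprintf("<snowsem_profile> (B = %d)\n", x$B))
  print(as.data.frame(x$components), row.names = FALSE, digits = 3)
  invisible(x)
}
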