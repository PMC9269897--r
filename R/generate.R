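#' Configuration for the synthetic mini-snowball study generator
#'
#' Bundles every parameter of the planted-component generative model used to
#' emulate a two-level (mini-snowball) word-association study. Participants
#' are quota-balanced over six age bins and two genders; each produces
#' `n_level1` associates to a focal cue and `n_level2` associates to each of
#' those, for `n_level1 * (1 + n_level2)` responses in total (30 under the
#' default 5 + 5x5 design). Responses are drawn from a lexicon of
#' `n_components * words_per_component` words partitioned into planted
#' components; retrieval within a component follows a Zipf-like rank
#' distribution so that response frequencies are realistically skewed.
#'
#' A participant's propensity to retrieve from component k at level 1 is
#' `softmax(age_effects[k] * age_bin + gender_effects[k] * is_female)`.
#' Level-2 responses come from the eliciting word's home component with
#' probability `1 - leakage`, otherwise from a uniformly chosen other
#' component. Survey ratings are linear in component propensities plus
#' Gaussian noise, rounded and clipped to the 0-10 integer scale.
#'
#' Defaults mirror the study design the generator emulates: 1205
#' participants, five components, and a 5 + 5x5 response scheme. The default
#' effect patterns plant one component with negative sentiment that rises
#' with age and female gender (a "threat"-like component, component 1), one
#' with positive sentiment and the opposite demographic pattern (a
#' "fortune"-like component, component 2), and weakly negative remaining
#' components, echoing the qualitative structure reported for risk
#' associations.
#'
#' @param n_participants Number of participants.
#' @param n_components Number K of planted components (>= 2).
#' @param words_per_component Distinct words per component.
#' @param n_level1 Associates given to the focal cue.
#' @param n_level2 Associates given to each level-1 associate.
#' @param leakage Probability in `[0, 1]` that a level-2 response is drawn
#'   from a component other than the eliciting word's home component.
#' @param zipf_exponent Exponent of the within-component rank distribution.
#' @param age_effects Length-K slopes of component retrieval propensity over
#'   the age-bin index 1..6 (log-odds per bin).
#' @param gender_effects Length-K log-odds shifts applied for female
#'   participants.
#' @param sentiment_means Length-K mean sentiment per component, in `[-1, 1]`.
#' @param sentiment_sd Sd of per-word sentiment around its component mean.
#' @param survey_loadings Length-K coefficients linking component propensity
#'   to survey ratings.
#' @param survey_intercepts Item-specific intercepts for the seven survey
#'   items (general + six domains), on the 0-10 scale.
#' @param noise_sd Sd of the Gaussian rating noise (> 0).
#' @param focal_cue Token used as the focal cue.
#' @param seed Integer base seed; all generator functions derive their
#'   streams from it.
#' @return A list of class `snowsem_config`.
#' @export
generator_config <- function(n_participants = 1205,
                             n_components = 5,
                             words_per_component = 40,
                             n_level1 = 5,
                             n_level2 = 5,
                             leakage = 0.05,
                             zipf_exponent = 1,
                             age_effects = NULL,
                             gender_effects = NULL,
                             sentiment_means = NULL,
                             sentiment_sd = 0.1,
                             survey_loadings = NULL,
                             survey_intercepts = NULL,
                             noise_sd = 1.5,
                             focal_cue = "risk",
                             seed = 1L) {
  for (nm in c("n_participants", "n_components", "words_per_component",
               "n_level1", "n_level2")) {
    if (!is_count(get(nm))) {
      stop_snowsem("`%s` must be a positive integer (got %s).", nm,
                   paste(get(nm), collapse = ","))
    }
  }
  K <- as.integer(n_components)
  if (K < 2) stop_snowsem("`n_components` must be at least 2.")
  if (!is.numeric(leakage) || leakage < 0 || leakage > 1) {
    stop_snowsem("`leakage` must lie in [0, 1].")
  }
  if (noise_sd < 0) stop_snowsem("`noise_sd` must be non-negative.")
  if (words_per_component < max(n_level2, ceiling(n_level1 / K))) {
    stop_snowsem(
      "`words_per_component` too small to draw distinct responses per cue.")
  }

  default_k <- function(x, five_default) {
    if (!is.null(x)) {
      if (length(x) != K) stop_snowsem("Per-component parameter of length %d; need K = %d.",
                                       length(x), K)
      return(as.numeric(x))
    }
    if (K == 5) five_default else rep(0, K)
  }
  age_effects <- default_k(age_effects, c(0.15, -0.15, 0.05, 0, 0))
  gender_effects <- default_k(gender_effects, c(0.2, -0.2, 0.05, 0, 0))
  sentiment_means <- default_k(sentiment_means, c(-0.8, 0.7, -0.2, -0.2, -0.2))
  survey_loadings <- default_k(survey_loadings, c(-1.5, 1.5, -1, 0, 1))
  if (any(abs(sentiment_means) > 1)) {
    stop_snowsem("`sentiment_means` must lie in [-1, 1].")
  }
  if (is.null(survey_intercepts)) {
    survey_intercepts <- c(general = 5, driving = 4.5, financial = 3.5,
                           recreational = 4.5, occupational = 4, health = 4,
                           social = 4.5)
  }
  if (length(survey_intercepts) != 7) {
    stop_snowsem("`survey_intercepts` must have length 7.")
  }
  survey_intercepts <- setNames(as.numeric(survey_intercepts), snowsem_items)

  structure(list(
    n_participants = as.integer(n_participants),
    n_components = K,
    words_per_component = as.integer(words_per_component),
    n_level1 = as.integer(n_level1),
    n_level2 = as.integer(n_level2),
    leakage = leakage,
    zipf_exponent = zipf_exponent,
    age_effects = age_effects,
    gender_effects = gender_effects,
    sentiment_means = sentiment_means,
    sentiment_sd = sentiment_sd,
    survey_loadings = survey_loadings,
    survey_intercepts = survey_intercepts,
    noise_sd = noise_sd,
    focal_cue = focal_cue,
    seed = as.integer(seed)
  ), class = "snowsem_config")
}

#' @export
print.snowsem_config <- function(x, ...) {
  cat("<snowsem_config>\n")
  cat(sprintf("  %d participants, %d components x %d words, %d + %dx%d design\n",
              x$n_participants, x$n_components, x$words_per_component,
              x$n_level1, x$n_level1, x$n_level2))
  cat(sprintf("  leakage %.2f, zipf %.2f, noise_sd %.2f, seed %d\n",
              x$leakage, x$zipf_exponent, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate the planted lexicon
#'
#' Creates `n_components * words_per_component` distinct word tokens, each
#' assigned to a home component and given a sentiment score drawn around its
#' component's planted mean, clipped to `[-1, 1]`. The within-component index
#' doubles as the word's frequency rank under the Zipf-like retrieval model.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `word`, `component`, `rank`, `sentiment`.
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "snowsem_config"))
  K <- config$n_components
  W <- config$words_per_component
  with_seed_opt(config$seed + 1L, {
    tibble(
      word = sprintf("c%d_w%02d", rep(seq_len(K), each = W),
                     rep(seq_len(W), times = K)),
      component = rep(seq_len(K), each = W),
      rank = rep(seq_len(W), times = K),
      sentiment = clip(
        rnorm(K * W, mean = rep(config$sentiment_means, each = W),
              sd = config$sentiment_sd), -1, 1)
    )
  })
}

#' Generate quota-balanced participants
#'
#' Allocates participants over the 6 age bins x 2 genders grid so that cell
#' sizes differ by at most one; the cells receiving the remainder are chosen
#' at random under the config seed.
#'
#' @param config A [generator_config()].
#' @return A tibble with `participant_id`, `age_bin` (1..6), `gender`
#'   (`"f"`/`"m"`).
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "snowsem_config"))
  n <- config$n_participants
  if (n < 12) warn("Fewer than 12 participants: age x gender quotas are degenerate.")
  cells <- tidyr::expand_grid(age_bin = 1:6, gender = c("f", "m"))
  base <- n %/% 12L
  rem <- n - 12L * base
  with_seed_opt(config$seed + 2L, {
    sizes <- rep(base, 12L)
    if (rem > 0) {
      extra <- sample.int(12L, rem)
      sizes[extra] <- sizes[extra] + 1L
    }
    out <- cells[rep(seq_len(12L), sizes), ]
    out$participant_id <- sprintf("p%04d", seq_len(n))
    dplyr::select(out, "participant_id", "age_bin", "gender")
  })
}

#' Latent component-retrieval propensities
#'
#' Deterministic softmax propensities per participant implied by the
#' config's demographic effects:
#' `softmax(age_effects * age_bin + gender_effects * is_female)`.
#'
#' @param participants Tibble from [generate_participants()].
#' @param config A [generator_config()].
#' @return Matrix (participants x K) of propensities, rows summing to 1.
#' @export
participant_propensities <- function(participants, config) {
  stopifnot(inherits(config, "snowsem_config"))
  eta <- outer(participants$age_bin, config$age_effects) +
    outer(as.numeric(participants$gender == "f"), config$gender_effects)
  P <- t(apply(eta, 1, softmax))
  rownames(P) <- participants$participant_id
  colnames(P) <- paste0("component_", seq_len(config$n_components))
  P
}

#' Generate mini-snowball association records
#'
#' For each participant, draws `n_level1` distinct level-1 responses to the
#' focal cue (component chosen by the participant's propensity, word within
#' component by the Zipf rank distribution), then `n_level2` distinct level-2
#' responses per level-1 word (home component with probability
#' `1 - leakage`). Repeats within the same cue page are impossible by
#' construction: responses are drawn sequentially without replacement, which
#' is equivalent to rejection-resampling duplicates.
#'
#' @param lexicon Tibble from [generate_lexicon()].
#' @param participants Tibble from [generate_participants()].
#' @param config A [generator_config()].
#' @return Long tibble with columns `participant_id`, `age_bin`, `gender`,
#'   `level`, `cue`, `cue_position`, `position`, `response`. The latent
#'   propensity matrix is attached as attribute `"propensities"`.
#' @export
generate_associations <- function(lexicon, participants, config) {
  stopifnot(inherits(config, "snowsem_config"))
  if (nrow(lexicon) == 0) stop_snowsem("`lexicon` is empty.")
  K <- config$n_components
  n1 <- config$n_level1
  n2 <- config$n_level2
  words <- lexicon$word
  comp <- lexicon$component
  zw <- zipf_weights(config$words_per_component, config$zipf_exponent)
  word_w <- zw[lexicon$rank]  # within-component weight of each word
  home <- setNames(comp, words)

  props <- participant_propensities(participants, config)
  n <- nrow(participants)
  per <- n1 * (1L + n2)

  # level-2 component mixture given a home component h
  leak <- config$leakage
  comp_mix <- matrix(leak / (K - 1), K, K)
  diag(comp_mix) <- 1 - leak

  pid <- rep(participants$participant_id, each = per)
  abin <- rep(participants$age_bin, each = per)
  gen <- rep(participants$gender, each = per)
  level <- integer(n * per)
  cue <- character(n * per)
  cue_pos <- rep(NA_integer_, n * per)
  pos <- integer(n * per)
  resp <- character(n * per)

  with_seed_opt(config$seed + 3L, {
    for (i in seq_len(n)) {
      off <- (i - 1L) * per
      q1 <- props[i, comp] * word_w
      l1 <- sample(words, n1, prob = q1)
      idx1 <- off + seq_len(n1)
      level[idx1] <- 1L
      cue[idx1] <- config$focal_cue
      pos[idx1] <- seq_len(n1)
      resp[idx1] <- l1
      for (j in seq_len(n1)) {
        h <- home[[l1[j]]]
        q2 <- comp_mix[comp, h] * word_w
        l2 <- sample(words, n2, prob = q2)
        idx2 <- off + n1 + (j - 1L) * n2 + seq_len(n2)
        level[idx2] <- 2L
        cue[idx2] <- l1[j]
        cue_pos[idx2] <- j
        pos[idx2] <- seq_len(n2)
        resp[idx2] <- l2
      }
    }
  })

  out <- tibble(participant_id = pid, age_bin = abin, gender = gen,
                level = level, cue = cue, cue_position = cue_pos,
                position = pos, response = resp)
  attr(out, "propensities") <- props
  out
}

#' Generate seven-item risk-propensity survey outcomes
#'
#' Each item rating is `round(clip(intercept_j + propensities %*% loadings +
#' N(0, noise_sd), 0, 10))`, with item-specific intercepts and loadings
#' shared across items.
#'
#' @param participants Tibble from [generate_participants()].
#' @param propensities Participants x K matrix of component propensities
#'   (latent, from [participant_propensities()], or realised, from
#'   [component_shares()]).
#' @param config A [generator_config()].
#' @param loadings,noise_sd Optional overrides of the config values.
#' @return Tibble `participant_id` + the seven integer items.
#' @export
generate_survey <- function(participants, propensities, config,
                            loadings = NULL, noise_sd = NULL) {
  stopifnot(inherits(config, "snowsem_config"))
  loadings <- loadings %||% config$survey_loadings
  noise_sd <- noise_sd %||% config$noise_sd
  P <- as.matrix(propensities[participants$participant_id, , drop = FALSE])
  if (ncol(P) != length(loadings)) {
    stop_snowsem("Propensity matrix has %d columns; need %d.", ncol(P),
                 length(loadings))
  }
  lin <- as.vector(P %*% loadings)
  n <- nrow(P)
  with_seed_opt(config$seed + 4L, {
    ratings <- lapply(config$survey_intercepts, function(a) {
      as.integer(round(clip(a + lin + rnorm(n, 0, noise_sd), 0, 10)))
    })
    dplyr::bind_cols(tibble(participant_id = participants$participant_id),
                     as_tibble(ratings))
  })
}

#' Realised per-participant component shares
#'
#' Share of a participant's level-1 responses whose word belongs to each
#' component, under a word -> component assignment (planted lexicon or an
#' inferred partition). Responses not covered by the assignment are dropped
#' from the denominator.
#'
#' @param associations Association tibble.
#' @param membership Named integer vector `word -> component`, a lexicon
#'   tibble, or a partition object.
#' @return Matrix (participants x K) of shares, rows summing to 1 (or NA for
#'   participants with no covered response).
#' @export
component_shares <- function(associations, membership) {
  memb <- as_membership(membership)
  K <- max(memb)
  l1 <- dplyr::filter(associations, .data$level == 1L)
  ids <- unique(l1$participant_id)
  comp <- memb[l1$response]
  keep <- !is.na(comp)
  tab <- table(factor(l1$participant_id[keep], levels = ids),
               factor(comp[keep], levels = seq_len(K)))
  M <- unclass(tab)
  M / pmax(rowSums(M), 1e-300)
}

#' Simulate a complete mini-snowball study
#'
#' Convenience wrapper chaining lexicon, participants, associations, and
#' survey generation (survey driven by the latent propensities).
#'
#' @param config A [generator_config()].
#' @return List of class `snowsem_study` with elements `config`, `lexicon`,
#'   `participants`, `associations`, `survey`, `propensities`.
#' @export
simulate_study <- function(config = generator_config()) {
  lexicon <- generate_lexicon(config)
  participants <- generate_participants(config)
  associations <- generate_associations(lexicon, participants, config)
  propensities <- attr(associations, "propensities")
  survey <- generate_survey(participants, propensities, config)
  structure(list(config = config, lexicon = lexicon,
                 participants = participants, associations = associations,
                 survey = survey, propensities = propensities),
            class = "snowsem_study")
}

#' @export
print.snowsem_study <- function(x, ...) {
  cat("<snowsem_study>\n")
  cat(sprintf("  %d participants, %d association records, %d lexicon words\n",
              nrow(x$participants), nrow(x$associations), nrow(x$lexicon)))
  invisible(x)
}

# Coerce the various word -> component representations to a named integer
# vector.
as_membership <- function(x) {
  if (inherits(x, "snowsem_partition")) return(x$membership)
  if (is.data.frame(x)) {
    if (all(c("word", "component") %in% names(x))) {
      return(setNames(as.integer(x$component), x$word))
    }
    stop_snowsem("Data frame membership needs `word` and `component` columns.")
  }
  if (!is.null(names(x))) return(setNames(as.integer(x), names(x)))
  stop_snowsem("Cannot interpret membership object of class %s.",
               paste(class(x), collapse = "/"))
}
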