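#' Word-level age trends in retrieval frequency
#'
#' For each word, models the level-1 retrieval counts across the six age
#' bins. The default is a Poisson log-linear model with the log of the total
#' level-1 tokens per bin as exposure offset and a linear predictor on the
#' age-bin index; `beta` is the unstandardised slope (log relative-frequency
#' change per bin) and `p` its Wald test. The Gaussian alternative regresses
#' the log relative frequency on the bin index by least squares. Only words
#' retrieved at least once in every age bin are eligible; others are
#' reported with `eligible = FALSE` and NA estimates.
#'
#' @param associations Association tibble with `age_bin`.
#' @param words Words to analyse (default: all distinct level-1 responses).
#' @param method `"poisson"` (log-linear with offset) or `"gaussian"`.
#' @return Tibble `word`, `n_total`, `eligible`, `beta`, `p`.
#' @export
age_trends <- function(associations, words = NULL,
                       method = c("poisson", "gaussian")) {
  method <- match.arg(method)
  l1 <- dplyr::filter(associations, .data$level == 1L)
  totals <- table(factor(l1$age_bin, levels = 1:6))
  if (any(totals == 0)) stop_snowsem("Some age bins contain no level-1 tokens.")
  words <- words %||% sort(unique(l1$response))
  counts <- unclass(table(factor(l1$response, levels = words),
                          factor(l1$age_bin, levels = 1:6)))
  bin <- 1:6
  off <- log(as.numeric(totals))
  res <- lapply(seq_along(words), function(i) {
    y <- counts[i, ]
    if (any(y == 0)) {
      return(tibble(word = words[i], n_total = sum(y), eligible = FALSE,
                    beta = NA_real_, p = NA_real_))
    }
    if (method == "poisson") {
      fit <- suppressWarnings(glm(y ~ bin, family = poisson(),
                                  offset = off))
      sm <- summary(fit)$coefficients
      tibble(word = words[i], n_total = sum(y), eligible = TRUE,
             beta = sm["bin", "Estimate"], p = sm["bin", "Pr(>|z|)"])
    } else {
      fit <- lm(log(y / as.numeric(totals)) ~ bin)
      sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
      tibble(word = words[i], n_total = sum(y), eligible = TRUE,
             beta = sm["bin", "Estimate"], p = sm["bin", "Pr(>|t|)"])
    }
  })
  dplyr::bind_rows(res)
}

#' Word-level gender differences in retrieval frequency
#'
#' For each word, `delta` is the difference in log relative retrieval
#' frequency between female and male participants, with additive smoothing
#' of 0.5 on the counts (display only); the p-value comes from the 2 x 2
#' chi-square test for stochastic independence (word vs all other level-1
#' tokens by gender) on the raw counts, without continuity correction.
#'
#' @param associations Association tibble with `gender` (`"f"`/`"m"`).
#' @param words Words to analyse (default: all distinct level-1 responses).
#' @return Tibble `word`, `n_f`, `n_m`, `delta`, `chisq`, `p`.
#' @export
gender_diffs <- function(associations, words = NULL) {
  l1 <- dplyr::filter(associations, .data$level == 1L)
  if (nrow(l1) == 0L) stop_snowsem("No level-1 tokens.")
  N <- table(factor(l1$gender, levels = c("f", "m")))
  words <- words %||% sort(unique(l1$response))
  counts <- unclass(table(factor(l1$response, levels = words),
                          factor(l1$gender, levels = c("f", "m"))))
  Nf <- as.numeric(N["f"]); Nm <- as.numeric(N["m"])
  res <- lapply(seq_along(words), function(i) {
    cf <- counts[i, "f"]; cm <- counts[i, "m"]
    delta <- log((cf + 0.5) / Nf) - log((cm + 0.5) / Nm)
    tab <- matrix(c(cf, Nf - cf, cm, Nm - cm), nrow = 2)
    if (cf + cm == 0) {
      return(tibble(word = words[i], n_f = cf, n_m = cm, delta = delta,
                    chisq = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble(word = words[i], n_f = cf, n_m = cm, delta = delta,
           chisq = unname(ct$statistic), p = unname(ct$p.value))
  })
  out <- dplyr::bind_rows(res)
  # Degenerate identical relative frequencies give chisq = 0, p = 1.
  out$p[!is.na(out$chisq) & out$chisq == 0] <- 1
  out
}

#' Component retrieval proportions by demographic group
#'
#' Stratified retrieval proportions of the components across age bins or
#' genders (thin wrapper over [retrieval_proportions()]).
#'
#' @param associations Association tibble.
#' @param partition `snowsem_partition` or membership.
#' @param by `"age"` or `"gender"`.
#' @return Tibble with stratum column, `component`, `n`, `proportion`.
#' @export
component_by_group <- function(associations, partition, by = c("age", "gender")) {
  by <- match.arg(by)
  retrieval_proportions(associations, partition, by = by)
}

#' Benjamini-Hochberg adjustment helper
#'
#' Adds a `p_adj` column (BH-adjusted across the non-missing p-values) to an
#' effect table; adjusted values are supplementary to the per-word 0.05
#' flags.
#'
#' @param effects Tibble with a `p` column.
#' @return The tibble with `p_adj` appended.
#' @export
adjust_effects <- function(effects) {
  dplyr::mutate(effects, p_adj = stats::p.adjust(.data$p, method = "BH"))
}
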