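#' Per-participant component similarity features
#'
#' The default feature of participant p for component k is the mean, over
#' p's in-network level-1 responses r, of the mean weighted Jaccard
#' similarity of r to the members of k. The `"share"` variant instead uses
#' the fraction of p's in-network responses assigned to k. Participants with
#' no in-network level-1 response are excluded; their ids are attached as
#' attribute `"excluded"`.
#'
#' @param associations Association tibble.
#' @param partition `snowsem_partition` or membership.
#' @param S Similarity matrix over the partition vocabulary (required for
#'   the `"similarity"` method).
#' @param method `"similarity"` (mean Jaccard to component members) or
#'   `"share"` (assignment proportions).
#' @return Tibble `participant_id`, `feature_1` .. `feature_K`.
#' @export
component_features <- function(associations, partition, S = NULL,
                               method = c("similarity", "share")) {
  method <- match.arg(method)
  memb <- as_membership(partition)
  K <- max(memb)
  l1 <- dplyr::filter(associations, .data$level == 1L,
                      .data$response %in% names(memb))
  all_ids <- unique(associations$participant_id)
  if (nrow(l1) == 0L) stop_snowsem("All participants lack in-network responses.")
  if (method == "similarity") {
    if (is.null(S)) stop_snowsem("`S` is required for method = \"similarity\".")
    S <- as.matrix(S)[names(memb), names(memb)]
    Mk <- outer(memb, seq_len(K), "==") * 1
    compsim <- S %*% Mk %*% diag(1 / colSums(Mk), K)  # word x K mean similarity
    F0 <- compsim[l1$response, , drop = FALSE]
    num <- rowsum(F0, l1$participant_id)
    cnt <- as.vector(table(l1$participant_id)[rownames(num)])
    feats <- num / cnt
  } else {
    feats <- component_shares(l1, memb)
    feats <- feats[rowSums(is.na(feats)) == 0, , drop = FALSE]
  }
  out <- dplyr::bind_cols(
    tibble(participant_id = rownames(feats)),
    as_tibble(`dimnames<-`(as.matrix(feats),
                           list(NULL, paste0("feature_", seq_len(K))))))
  excluded <- setdiff(all_ids, out$participant_id)
  if (length(excluded) == length(all_ids)) {
    stop_snowsem("All participants lack in-network responses.")
  }
  attr(out, "excluded") <- excluded
  out
}

# Assemble the z-scored design for one model variant.
prediction_design <- function(features, participants, survey,
                              variant = c("combined", "components", "demographics")) {
  variant <- match.arg(variant)
  dat <- dplyr::inner_join(features, participants, by = "participant_id")
  dat <- dplyr::inner_join(dat, survey, by = "participant_id")
  if (nrow(dat) < 20L) stop_snowsem("Fewer than 20 complete cases.")
  demo <- cbind(age = dat$age_bin, gender = as.numeric(dat$gender == "f"))
  feat <- as.matrix(dplyr::select(dat, dplyr::starts_with("feature_")))
  X <- switch(variant,
              combined = cbind(demo, feat),
              components = feat,
              demographics = demo)
  list(X = X, items = as.matrix(dat[, snowsem_items]), data = dat)
}

#' Standardised per-item regressions
#'
#' Ordinary least squares of each z-scored survey item on z-scored
#' predictors (age-bin index, female indicator, and the K component
#' features), with two-sided t-tests on the coefficients.
#'
#' @param features Tibble from [component_features()].
#' @param participants Participant tibble (`participant_id`, `age_bin`,
#'   `gender`).
#' @param survey Survey tibble.
#' @return Tibble `item`, `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
fit_item_regressions <- function(features, participants, survey) {
  d <- prediction_design(features, participants, survey, "combined")
  Xz <- scale(d$X)
  bad <- colnames(d$X)[attr(Xz, "scaled:scale") == 0 | is.na(attr(Xz, "scaled:scale"))]
  if (length(bad)) stop_snowsem("Constant predictor column(s): %s.",
                                paste(bad, collapse = ", "))
  qr_rank <- qr(cbind(1, Xz))$rank
  if (qr_rank < ncol(Xz) + 1L) {
    cmat <- abs(cor(Xz))
    diag(cmat) <- 0
    pair <- which(cmat == max(cmat), arr.ind = TRUE)[1, ]
    stop_snowsem("Rank-deficient design; most collinear columns: %s, %s.",
                 colnames(Xz)[pair[1]], colnames(Xz)[pair[2]])
  }
  dplyr::bind_rows(lapply(snowsem_items, function(item) {
    y <- as.numeric(scale(d$items[, item]))
    fit <- lm(y ~ Xz)
    sm <- suppressWarnings(summary(fit))$coefficients[-1, , drop = FALSE]
    tibble(item = item, term = colnames(Xz),
           estimate = sm[, "Estimate"], std_error = sm[, "Std. Error"],
           statistic = sm[, "t value"], p_value = sm[, "Pr(>|t|)"])
  }))
}

#' Repeated cross-validated elastic-net prediction
#'
#' Repeated k-fold cross-validation of elastic-net models (fixed mixing
#' `alpha`, penalty chosen by inner cross-validation on each training fold)
#' for three predictor sets: components only, demographics only, and
#' combined. Held-out performance is `R^2 = 1 - SSE/SST` computed on each
#' test fold. Fold assignments and inner fold splits are fully determined by
#' `seed`.
#'
#' @param features,participants,survey As in [fit_item_regressions()].
#' @param items Survey items to model (default all seven).
#' @param folds,repeats Outer k-fold settings.
#' @param seed Integer seed.
#' @param alpha Elastic-net mixing parameter.
#' @param variants Model variants to fit.
#' @return Object of class `snowsem_cv`: `folds` tibble (`item`, `variant`,
#'   `rep`, `fold`, `r2`, `n_train`, `n_test`), plus settings. Summaries via
#'   [tidy()] (mean R^2 with corrected resampled SE).
#' @export
cv_elastic_net <- function(features, participants, survey,
                           items = snowsem_items,
                           folds = 10L, repeats = 10L, seed = 1L,
                           alpha = 0.5,
                           variants = c("components", "demographics", "combined")) {
  variants <- match.arg(variants, several.ok = TRUE)
  designs <- lapply(setNames(variants, variants), function(v) {
    prediction_design(features, participants, survey, v)
  })
  n <- nrow(designs[[1]]$X)
  rows <- list()
  with_seed_opt(seed, {
    for (rep_i in seq_len(repeats)) {
      fold_id <- sample(rep_len(seq_len(folds), n))
      for (item in items) {
        for (v in variants) {
          X <- designs[[v]]$X
          y <- as.numeric(designs[[v]]$items[, item])
          for (f in seq_len(folds)) {
            test <- fold_id == f
            ytr <- y[!test]
            if (var(ytr) == 0 || var(y[test]) == 0) next  # degenerate fold
            cvfit <- glmnet::cv.glmnet(X[!test, , drop = FALSE], ytr,
                                       alpha = alpha, nfolds = 5)
            pred <- as.numeric(predict(cvfit, X[test, , drop = FALSE],
                                       s = "lambda.min"))
            sse <- sum((y[test] - pred)^2)
            sst <- sum((y[test] - mean(y[test]))^2)
            rows[[length(rows) + 1L]] <- tibble(
              item = item, variant = v, rep = rep_i, fold = f,
              r2 = 1 - sse / sst, n_train = sum(!test), n_test = sum(test))
          }
        }
      }
    }
  })
  structure(list(folds = dplyr::bind_rows(rows),
                 settings = list(folds = folds, repeats = repeats,
                                 seed = seed, alpha = alpha)),
            class = "snowsem_cv")
}

#' Corrected resampled t-test on paired fold results
#'
#' Paired t-test on per-fold performance differences with the variance
#' inflated by `1/J + n_test/n_train` to account for the overlap of
#' cross-validation training sets; two-sided p on J - 1 degrees of freedom.
#'
#' @param d Numeric vector of paired per-fold differences (J >= 2).
#' @param n_train,n_test Training and test sizes per fold.
#' @return Tibble `t`, `p`, `df`, `mean_diff`, `se`, with a
#'   `zero_variance` flag when all differences are identical.
#' @export
corrected_resampled_ttest <- function(d, n_train, n_test) {
  J <- length(d)
  if (J < 2L) stop_snowsem("Need at least 2 paired fold results.")
  v <- var(d)
  se <- sqrt(v * (1 / J + n_test / n_train))
  zero_var <- v == 0
  if (zero_var) {
    if (mean(d) == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(d)) * Inf
      p <- .Machine$double.xmin
    }
  } else {
    t <- mean(d) / se
    p <- 2 * pt(-abs(t), df = J - 1)
  }
  tibble(t = t, p = p, df = J - 1L, mean_diff = mean(d), se = se,
         zero_variance = zero_var)
}

#' Compare two cross-validated model variants
#'
#' Applies the corrected resampled t-test to the per-fold R^2 differences of
#' two variants, per item.
#'
#' @param cv A `snowsem_cv` object.
#' @param variant_a,variant_b Variant names (difference is a - b).
#' @return Tibble with one row per item.
#' @export
compare_cv_models <- function(cv, variant_a, variant_b) {
  stopifnot(inherits(cv, "snowsem_cv"))
  wide <- tidyr::pivot_wider(cv$folds, names_from = "variant",
                             values_from = "r2",
                             id_cols = c("item", "rep", "fold", "n_train", "n_test"))
  dplyr::bind_rows(lapply(unique(wide$item), function(it) {
    w <- dplyr::filter(wide, .data$item == it)
    d <- w[[variant_a]] - w[[variant_b]]
    keep <- !is.na(d)
    res <- corrected_resampled_ttest(d[keep], mean(w$n_train[keep]),
                                     mean(w$n_test[keep]))
    dplyr::bind_cols(tibble(item = it), res)
  }))
}

#' Word-level correlations with risk-taking items
#'
#' For every word retrieved at level 1 by at least `min_retrievals`
#' participants, the Pearson correlation between the binary
#' retrieved-indicator and each survey item. Rows are ordered by the mean
#' correlation across items; correlations with `|r| > flag_threshold` are
#' flagged.
#'
#' @param associations Association tibble.
#' @param survey Survey tibble.
#' @param min_retrievals Minimum number of distinct retrieving participants.
#' @param flag_threshold Absolute correlation flagging threshold.
#' @return Long tibble `word`, `n_retrievals`, `item`, `r`, `flagged`,
#'   `mean_r`, ordered by decreasing `mean_r`.
#' @export
word_level_correlations <- function(associations, survey, min_retrievals = 10L,
                                    flag_threshold = 0.05) {
  l1 <- dplyr::filter(associations, .data$level == 1L,
                      .data$participant_id %in% survey$participant_id)
  ids <- survey$participant_id
  retr <- dplyr::distinct(l1, .data$participant_id, .data$response)
  n_by_word <- dplyr::count(retr, .data$response, name = "n_retrievals")
  keep <- dplyr::filter(n_by_word, .data$n_retrievals >= min_retrievals)
  if (nrow(keep) == 0L) {
    return(tibble(word = character(), n_retrievals = integer(),
                  item = character(), r = double(), flagged = logical(),
                  mean_r = double()))
  }
  Y <- as.matrix(survey[match(ids, survey$participant_id), snowsem_items])
  out <- dplyr::bind_rows(lapply(seq_len(nrow(keep)), function(i) {
    w <- keep$response[i]
    ind <- as.numeric(ids %in% retr$participant_id[retr$response == w])
    r <- if (sd(ind) == 0) rep(NA_real_, length(snowsem_items)) else {
      as.numeric(cor(ind, Y))
    }
    tibble(word = w, n_retrievals = keep$n_retrievals[i],
           item = snowsem_items, r = r,
           flagged = !is.na(r) & abs(r) > flag_threshold)
  }))
  means <- dplyr::summarise(dplyr::group_by(out, .data$word),
                            mean_r = mean(.data$r, na.rm = TRUE),
                            .groups = "drop")
  out <- dplyr::left_join(out, means, by = "word")
  dplyr::arrange(out, dplyr::desc(.data$mean_r), .data$word)
}
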