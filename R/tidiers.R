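#' Tidy a Louvain partition
#'
#' @param x A `snowsem_partition`.
#' @param ... Unused.
#' @return Tibble `word`, `component`.
#' @method tidy snowsem_partition
#' @export
tidy.snowsem_partition <- function(x, ...) {
  tibble(word = names(x$membership), component = as.integer(x$membership))
}

#' @rdname tidy.snowsem_partition
#' @method glance snowsem_partition
#' @export
glance.snowsem_partition <- function(x, ...) {
  tibble(n_nodes = length(x$membership), n_communities = x$n_communities,
         modularity = x$modularity, seed = x$seed, restarts = x$restarts,
         resolution = x$resolution)
}

#' Tidy a stability analysis
#'
#' @param x A `snowsem_stability`.
#' @param ... Unused.
#' @return Word-level tibble with per-component co-stability proportions.
#' @method tidy snowsem_stability
#' @export
tidy.snowsem_stability <- function(x, ...) x$words

#' @rdname tidy.snowsem_stability
#' @method glance snowsem_stability
#' @export
glance.snowsem_stability <- function(x, ...) {
  dplyr::bind_cols(
    tibble(B = x$B, mean_stability = mean(x$summary$stability)),
    tidyr::pivot_wider(x$summary, names_from = "component",
                       values_from = "stability", names_prefix = "stability_",
                       id_cols = character()))
}

#' Tidy cross-validated elastic-net results
#'
#' Per item and variant: mean held-out R^2 and its corrected resampled
#' standard error.
#'
#' @param x A `snowsem_cv`.
#' @param ... Unused.
#' @return Tibble `item`, `variant`, `mean_r2`, `se`, `n_folds`.
#' @method tidy snowsem_cv
#' @export
tidy.snowsem_cv <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$folds, .data$item, .data$variant),
    mean_r2 = mean(.data$r2),
    se = sqrt(var(.data$r2) * (1 / dplyr::n() +
                                 mean(.data$n_test) / mean(.data$n_train))),
    n_folds = dplyr::n(),
    .groups = "drop")
}

#' @rdname tidy.snowsem_cv
#' @method glance snowsem_cv
#' @export
glance.snowsem_cv <- function(x, ...) {
  tibble(folds = x$settings$folds, repeats = x$settings$repeats,
         alpha = x$settings$alpha, seed = x$settings$seed,
         n_results = nrow(x$folds))
}

#' Tidy a cross-language comparison
#'
#' @param x A `snowsem_crosslingual`.
#' @param ... Unused.
#' @return Long tibble of within/between block mean similarities per
#'   language.
#' @method tidy snowsem_crosslingual
#' @export
tidy.snowsem_crosslingual <- function(x, ...) {
  one <- function(M, language) {
    df <- as_tibble(as.data.frame(as.table(M), stringsAsFactors = FALSE))
    names(df) <- c("component_a", "component_b", "mean_similarity")
    dplyr::mutate(df, language = language,
                  within = .data$component_a == .data$component_b)
  }
  dplyr::bind_rows(one(x$block_ref, "reference"), one(x$block_other, "other"))
}

#' @rdname tidy.snowsem_crosslingual
#' @method glance snowsem_crosslingual
#' @export
glance.snowsem_crosslingual <- function(x, ...) {
  tibble(correlation = x$correlation, n_terms = x$n_terms,
         n_pairs = x$n_pairs,
         retrieval_correlation = x$retrieval_correlation)
}
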