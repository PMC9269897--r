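#' Build the level-1 x level-2 co-occurrence matrix
#'
#' Cell (w, v) counts, pooled over participants, the level-2 records whose
#' cue is the eligible level-1 word w and whose response is v. Level-2
#' records whose cue is not in the eligible vocabulary are dropped silently;
#' their number is attached as attribute `"n_dropped_level2"`.
#'
#' @param filtered A `snowsem_filtered` object from [filter_associations()],
#'   or an association tibble together with `vocabulary`.
#' @param vocabulary Eligible level-1 words (taken from `filtered` when
#'   omitted).
#' @return Integer count matrix (vocabulary x level-2 vocabulary).
#' @export
build_cooccurrence <- function(filtered, vocabulary = NULL) {
  if (inherits(filtered, "snowsem_filtered")) {
    associations <- filtered$associations
    vocabulary <- vocabulary %||% filtered$vocabulary
  } else {
    associations <- filtered
    if (is.null(vocabulary)) stop_snowsem("`vocabulary` is required.")
  }
  if (length(vocabulary) == 0L) stop_snowsem("Eligible vocabulary is empty.")
  l2 <- dplyr::filter(associations, .data$level == 2L)
  keep <- l2$cue %in% vocabulary
  dropped <- sum(!keep)
  l2 <- l2[keep, , drop = FALSE]
  cols <- sort(unique(l2$response))
  C <- unclass(table(factor(l2$cue, levels = vocabulary),
                     factor(l2$response, levels = cols)))
  dimnames(C) <- list(vocabulary, cols)
  storage.mode(C) <- "integer"
  attr(C, "n_dropped_level2") <- dropped
  C
}

#' Weighted Jaccard (Ruzicka) similarity between count vectors
#'
#' `J(x, y) = sum(min(x, y)) / sum(max(x, y))` over two non-negative vectors
#' of equal length; defined as 0 when both vectors are all-zero.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
weighted_jaccard <- function(x, y) {
  if (length(x) != length(y)) stop_snowsem("`x` and `y` differ in length.")
  if (any(x < 0) || any(y < 0)) stop_snowsem("Count vectors must be non-negative.")
  denom <- sum(pmax(x, y))
  if (denom == 0) return(0)
  sum(pmin(x, y)) / denom
}

#' Pairwise weighted Jaccard similarity over profile rows
#'
#' Computes the symmetric similarity matrix over all row pairs of a
#' co-occurrence (profile) matrix. Uses the identity
#' `sum(max) = sum(x) + sum(y) - sum(min)` so only the min-sums are
#' accumulated.
#'
#' @param C Non-negative numeric matrix with row names.
#' @return Symmetric similarity matrix with unit diagonal (for non-empty
#'   rows) and entries in `[0, 1]`.
#' @export
similarity_matrix <- function(C) {
  C <- as.matrix(C)
  if (any(C < 0)) stop_snowsem("Profile matrix must be non-negative.")
  n <- nrow(C)
  rs <- rowSums(C)
  if (any(rs == 0)) {
    warn(sprintf("%d all-zero profile row(s); their similarities are 0.",
                 sum(rs == 0)))
  }
  S <- diag(as.numeric(rs > 0), n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      block <- C[(i + 1L):n, , drop = FALSE]
      mins <- rowSums(pmin(block, rep(C[i, ], each = n - i)))
      denom <- rs[i] + rs[(i + 1L):n] - mins
      val <- ifelse(denom > 0, mins / denom, 0)
      S[i, (i + 1L):n] <- val
      S[(i + 1L):n, i] <- val
    }
  }
  dimnames(S) <- list(rownames(C), rownames(C))
  S
}
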