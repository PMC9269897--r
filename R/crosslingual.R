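#' Compare the semantic network across languages
#'
#' Aligns the reference similarity matrix with one estimated from another
#' language (e.g. a SWOW-derived matrix) via a translation table, then
#' computes (i) the Pearson correlation over all upper-triangle word pairs
#' present in both matrices, (ii) K x K within/between-component mean
#' similarity tables for each language (blocks defined by the reference
#' partition, restricted to the shared terms), and optionally (iii) the
#' correlation between per-component retrieval proportions.
#'
#' @param S_ref Reference similarity matrix (dimnames = reference terms).
#' @param S_other Similarity matrix for the comparison language.
#' @param partition Reference `snowsem_partition` (or membership).
#' @param term_map Two-column tibble `ref`, `other` translating reference
#'   terms; `NULL` uses the identity mapping on shared rownames.
#' @param props_ref,props_other Optional per-component retrieval-proportion
#'   vectors (aligned by component) for the retrieval correlation.
#' @return Object of class `snowsem_crosslingual`: `correlation`, `n_terms`,
#'   `n_pairs`, `block_ref`, `block_other` (K x K matrices),
#'   `retrieval_correlation` (or NA).
#' @export
crosslingual_compare <- function(S_ref, S_other, partition, term_map = NULL,
                                 props_ref = NULL, props_other = NULL) {
  S_ref <- as.matrix(S_ref)
  S_other <- as.matrix(S_other)
  memb <- as_membership(partition)
  if (is.null(term_map)) {
    shared <- intersect(rownames(S_ref), rownames(S_other))
    term_map <- tibble(ref = shared, other = shared)
  }
  term_map <- dplyr::filter(term_map,
                            .data$ref %in% rownames(S_ref),
                            .data$other %in% rownames(S_other),
                            .data$ref %in% names(memb))
  term_map <- dplyr::distinct(term_map, .data$ref, .keep_all = TRUE)
  nt <- nrow(term_map)
  if (nt < 3L) stop_snowsem("Fewer than 3 shared terms after mapping.")
  A <- S_ref[term_map$ref, term_map$ref]
  Bm <- S_other[term_map$other, term_map$other]
  ut <- upper.tri(A)
  if (sum(ut) < 3L) stop_snowsem("Fewer than 3 shared pairs after mapping.")
  correlation <- cor(A[ut], Bm[ut])

  labs <- factor(memb[term_map$ref])
  block_ref <- block_means(A, labs)
  block_other <- block_means(Bm, labs)

  retrieval_correlation <- if (!is.null(props_ref) && !is.null(props_other)) {
    cor(as.numeric(props_ref), as.numeric(props_other))
  } else {
    NA_real_
  }
  structure(list(correlation = correlation, n_terms = nt, n_pairs = sum(ut),
                 block_ref = block_ref, block_other = block_other,
                 retrieval_correlation = retrieval_correlation),
            class = "snowsem_crosslingual")
}

# Mean similarity within/between partition blocks (diagonal of S excluded).
block_means <- function(S, labs) {
  ks <- levels(labs)
  K <- length(ks)
  M <- matrix(NA_real_, K, K, dimnames = list(ks, ks))
  for (i in seq_len(K)) {
    for (j in i:K) {
      ii <- which(labs == ks[i])
      jj <- which(labs == ks[j])
      block <- S[ii, jj, drop = FALSE]
      vals <- if (i == j) block[upper.tri(block)] else as.vector(block)
      M[i, j] <- M[j, i] <- if (length(vals)) mean(vals) else NA_real_
    }
  }
  M
}

#' @export
print.snowsem_crosslingual <- function(x, ...) {
  cat("<snowsem_crosslingual>\n")
  cat(sprintf("  %d shared terms, %d pairs, similarity correlation r = %.3f\n",
              x$n_terms, x$n_pairs, x$correlation))
  if (!is.na(x$retrieval_correlation)) {
    cat(sprintf("  retrieval-proportion correlation r = %.3f\n",
                x$retrieval_correlation))
  }
  invisible(x)
}
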