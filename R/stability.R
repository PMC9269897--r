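#' Bootstrap partitions by resampling level-2 responses
#'
#' For each replicate, the level-2 response tokens are resampled with
#' replacement within each level-1 cue row (a row-wise multinomial with the
#' original row total), the weighted Jaccard similarity matrix and network
#' are rebuilt, and the Louvain partition re-run with a replicate-specific
#' seed drawn from `seed`.
#'
#' @param C Co-occurrence matrix from [build_cooccurrence()] (the resampling
#'   unit is its rows), or a `snowsem_filtered` object.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the replicate stream.
#' @param restarts Louvain restarts per replicate.
#' @param min_weight Edge threshold passed to [build_network()].
#' @return Object of class `snowsem_bootstrap`: list with `partitions`
#'   (list of named membership vectors), `B`, `seed`, `nodes`.
#' @export
bootstrap_partitions <- function(C, B = 1000L, seed = 1L, restarts = 5L,
                                 min_weight = 0) {
  if (inherits(C, "snowsem_filtered")) C <- build_cooccurrence(C)
  if (!is_count(B)) stop_snowsem("`B` must be a positive integer.")
  C <- as.matrix(C)
  n <- nrow(C)
  rs <- rowSums(C)
  parts <- vector("list", B)
  with_seed_opt(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  })
  for (b in seq_len(B)) {
    Cb <- with_seed_opt(rep_seeds[b], {
      t(vapply(seq_len(n), function(i) {
        if (rs[i] == 0) return(C[i, ] * 0)
        as.numeric(rmultinom(1, rs[i], C[i, ] / rs[i]))
      }, numeric(ncol(C))))
    })
    dimnames(Cb) <- dimnames(C)
    Sb <- similarity_matrix(Cb)
    net <- build_network(Sb, min_weight = min_weight)
    parts[[b]] <- louvain(net, seed = rep_seeds[b], restarts = restarts)$membership
  }
  structure(list(partitions = parts, B = B, seed = seed,
                 nodes = rownames(C)),
            class = "snowsem_bootstrap")
}

#' Size-normalised bootstrap co-stability of a reference partition
#'
#' For each word w and each original component k, the raw score is the mean
#' over replicates of the fraction of k's other members found in w's
#' replicate cluster (`|cluster_b(w) intersect k \\ {w}| / |k \\ {w}|`).
#' Dividing by component size prevents large components from dominating
#' modal assignments mechanically. Per-word scores are renormalised to sum
#' to one over components; the modal component is the argmax (ties resolved
#' toward the original component, then the lowest index). Each component is
#' summarised by the fraction of its members whose modal component is the
#' original one.
#'
#' @param bootstrap A `snowsem_bootstrap` (or plain list of named
#'   memberships over a common node set).
#' @param reference The original `snowsem_partition` (or named membership).
#' @return Object of class `snowsem_stability`: `words` (tibble with word,
#'   original component, per-component proportions, modal component,
#'   `stable` flag), `summary` (tibble component, size, stability), `B`.
#' @export
costability <- function(bootstrap, reference) {
  parts <- if (inherits(bootstrap, "snowsem_bootstrap")) bootstrap$partitions else bootstrap
  ref <- as_membership(reference)
  nodes <- names(ref)
  K <- max(ref)
  for (p in parts) {
    if (!setequal(names(p), nodes)) {
      stop_snowsem("Bootstrap partitions and reference cover different node sets.")
    }
  }
  n <- length(nodes)
  Mk <- outer(ref, seq_len(K), "==") * 1   # n x K reference indicator
  sizes <- colSums(Mk)
  denom <- matrix(rep(sizes, each = n), n, K) - Mk  # |k \ {w}| per word
  raw <- matrix(0, n, K)
  for (p in parts) {
    pm <- p[nodes]
    same <- outer(pm, pm, "==") * 1
    diag(same) <- 0
    raw <- raw + (same %*% Mk) / pmax(denom, 1)
  }
  raw <- raw / length(parts)
  tot <- rowSums(raw)
  norm <- raw / ifelse(tot > 0, tot, 1)
  modal <- vapply(seq_len(n), function(i) {
    x <- norm[i, ]
    top <- which(x >= max(x) - 1e-12)
    if (ref[i] %in% top) ref[[i]] else min(top)
  }, integer(1))
  words <- tibble(word = nodes, component = as.integer(ref),
                  modal_component = modal, stable = modal == ref)
  props <- as_tibble(norm, .name_repair = ~ paste0("prop_component_", seq_len(K)))
  words <- dplyr::bind_cols(words, props)
  summary <- dplyr::summarise(dplyr::group_by(words, .data$component),
                              size = dplyr::n(),
                              stability = mean(.data$stable),
                              .groups = "drop")
  structure(list(words = words, summary = summary, B = length(parts)),
            class = "snowsem_stability")
}

#' @export
print.snowsem_stability <- function(x, ...) {
  cat(sprintf("<snowsem_stability> (B = %d)\n", x$B))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
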