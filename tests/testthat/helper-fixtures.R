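# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

# Small end-to-end study: 2 components, disjoint vocabularies, no leakage.
small_config <- function(...) {
  defaults <- list(n_participants = 60, n_components = 2,
                   words_per_component = 12, leakage = 0,
                   age_effects = c(0, 0), gender_effects = c(0, 0),
                   sentiment_means = c(-0.5, 0.5), survey_loadings = c(-2, 2),
                   seed = 42L)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Medium study with 5 planted components, mild leakage; reused across tests.
medium_study <- function() {
  if (is.null(fixture_env$medium)) {
    cfg <- generator_config(n_participants = 300, words_per_component = 20,
                            leakage = 0.05, seed = 11L)
    fixture_env$medium <- simulate_study(cfg)
  }
  fixture_env$medium
}

medium_pipeline <- function() {
  if (is.null(fixture_env$medium_pipe)) {
    st <- medium_study()
    f <- filter_associations(st$associations)
    C <- build_cooccurrence(f)
    S <- similarity_matrix(C)
    net <- build_network(S)
    part <- louvain(net, seed = 5L)
    fixture_env$medium_pipe <- list(study = st, filtered = f, C = C, S = S,
                                    net = net, partition = part)
  }
  fixture_env$medium_pipe
}

# Hand-built association tibble: helper for toy examples.
toy_associations <- function(records) {
  # records: list of c(pid, level, cue, position, response[, age_bin, gender])
  dplyr::bind_rows(lapply(records, function(r) {
    tibble::tibble(participant_id = r[[1]],
                   age_bin = if (length(r) >= 6) as.integer(r[[6]]) else 1L,
                   gender = if (length(r) >= 7) r[[7]] else "f",
                   level = as.integer(r[[2]]), cue = r[[3]],
                   cue_position = NA_integer_,
                   position = as.integer(r[[4]]), response = r[[5]])
  }))
}

# Naive O(n^2 d) pairwise weighted-Jaccard oracle.
naive_similarity <- function(C) {
  n <- nrow(C)
  S <- matrix(0, n, n, dimnames = list(rownames(C), rownames(C)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      mx <- sum(pmax(C[i, ], C[j, ]))
      S[i, j] <- if (mx == 0) 0 else sum(pmin(C[i, ], C[j, ])) / mx
    }
  }
  S
}

# Enumerate all set partitions of n elements as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum-modularity search over all partitions of a small graph.
max_modularity <- function(A) {
  parts <- all_partitions(nrow(A))
  qs <- vapply(parts, function(m) modularity_q(A, setNames(m, rownames(A))),
               numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# Dense linear-system PageRank oracle (dangling nodes teleport uniformly).
solve_pagerank <- function(A, damping = 0.85) {
  n <- nrow(A)
  k <- rowSums(A)
  W <- A / ifelse(k > 0, k, 1)
  W[k == 0, ] <- 1 / n
  x <- solve(diag(n) - damping * t(W), rep((1 - damping) / n, n))
  x / sum(x)
}

random_weighted_graph <- function(n, p = 0.5) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) A[i, j] <- A[j, i] <- runif(1, 0.1, 1)
    }
  }
  rownames(A) <- colnames(A) <- paste0("n", seq_len(n))
  A
}

planted_membership <- function(lexicon, nodes) {
  setNames(lexicon$component, lexicon$word)[nodes]
}
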