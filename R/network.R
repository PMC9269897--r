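#' Represent a similarity matrix as a weighted network
#'
#' Nodes are the level-1 words; undirected edges connect pairs whose
#' similarity strictly exceeds `min_weight`. Self-loops are never created.
#' By default every strictly positive similarity becomes an edge.
#'
#' @param S Symmetric similarity matrix with dimnames.
#' @param min_weight Edges require similarity > `min_weight`.
#' @return An undirected weighted [igraph::graph] (isolated nodes retained).
#' @export
build_network <- function(S, min_weight = 0) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop_snowsem("Similarity matrix must be square.")
  A <- S
  diag(A) <- 0
  A[A <= min_weight] <- 0
  if (all(A == 0)) stop_snowsem("Resulting network has no edges (min_weight = %g).",
                                min_weight)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
}

net_adjacency <- function(net) {
  if (igraph::is_igraph(net)) {
    return(igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE))
  }
  as.matrix(net)
}

#' Newman-Girvan weighted modularity of a labelled partition
#'
#' `Q = sum_c (e_c - a_c^2)` with `e_c` the fraction of total edge weight
#' inside community c and `a_c` the fraction of total weighted degree in c.
#'
#' @param net Weighted undirected igraph network (or adjacency matrix).
#' @param membership Named (or node-ordered) community labels covering all
#'   nodes.
#' @return Modularity Q in `[-1, 1]`.
#' @export
modularity_q <- function(net, membership) {
  A <- net_adjacency(net)
  m <- align_membership(membership, rownames(A))
  modularity_dense(A, m)
}

align_membership <- function(membership, nodes) {
  membership <- as_membership(membership)
  if (!is.null(nodes) && !is.null(names(membership))) {
    if (!all(nodes %in% names(membership))) {
      stop_snowsem("Membership does not label all nodes.")
    }
    membership <- membership[nodes]
  }
  if (any(is.na(membership))) stop_snowsem("Membership contains NA labels.")
  membership
}

# Q from a dense symmetric adjacency (zero diagonal) and integer labels.
modularity_dense <- function(A, memb) {
  m2 <- sum(A)
  if (m2 <= 0) stop_snowsem("Network has no edge weight.")
  k <- rowSums(A)
  memb <- match(memb, unique(memb))
  e <- vapply(split(seq_along(memb), memb),
              function(idx) sum(A[idx, idx, drop = FALSE]), numeric(1)) / m2
  a <- vapply(split(k, memb), sum, numeric(1)) / m2
  sum(e - a^2)
}

#' Louvain community detection with seeded restarts
#'
#' Two-phase Louvain modularity maximisation: nodes are repeatedly moved to
#' the neighbouring community with the largest strictly positive modularity
#' gain (ties broken toward the lowest community index), then communities
#' are aggregated into super-nodes; the two phases iterate until no gain
#' remains. The node visit order is shuffled independently in each of
#' `restarts` runs under `seed`, and the best partition by modularity is
#' kept. To diversify the search beyond visit order (greedy max-gain moving
#' can be trapped in the same local optimum for every order), all restarts
#' after the first accept a uniformly chosen strictly improving move instead
#' of the maximal one; the first restart is the classical deterministic
#' sweep. Components of a disconnected network are handled naturally.
#' Community labels of the result are renumbered by decreasing component
#' size (ties by first node name).
#'
#' @param net Weighted undirected igraph network or adjacency matrix.
#' @param seed Integer seed governing the restart shuffles.
#' @param restarts Number of seeded restarts.
#' @param resolution Resolution parameter gamma of the modularity gain
#'   (1 = standard modularity).
#' @return Object of class `snowsem_partition`: `membership` (named integer
#'   vector), `modularity` (Q at resolution 1), `n_communities`, `seed`,
#'   `restarts`, `resolution`.
#' @export
louvain <- function(net, seed = 1L, restarts = 10L, resolution = 1) {
  A <- net_adjacency(net)
  if (nrow(A) == 0L) stop_snowsem("Empty network.")
  if (sum(A) <= 0) stop_snowsem("Network has no edge weight.")
  nodes <- rownames(A) %||% as.character(seq_len(nrow(A)))
  best_m <- NULL
  best_q <- -Inf
  with_seed_opt(seed, {
    for (r in seq_len(restarts)) {
      m <- louvain_run(A, resolution, stochastic = r > 1L)
      q <- modularity_dense(A, m)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_m <- m
      }
    }
  })
  memb <- renumber_by_size(setNames(best_m, nodes))
  structure(list(membership = memb,
                 modularity = best_q,
                 n_communities = max(memb),
                 seed = seed, restarts = restarts, resolution = resolution),
            class = "snowsem_partition")
}

renumber_by_size <- function(memb) {
  sizes <- table(memb)
  ord <- order(-as.vector(sizes), vapply(names(sizes), function(l) {
    min(which(memb == as.integer(l)))
  }, numeric(1)))
  new <- setNames(seq_along(ord), names(sizes)[ord])
  setNames(as.integer(new[as.character(memb)]), names(memb))
}

# One full Louvain run (local moving + aggregation until convergence),
# returning original-node community labels. Uses the running RNG stream for
# the node visit order.
louvain_run <- function(A, resolution = 1, stochastic = FALSE) {
  n0 <- nrow(A)
  map <- seq_len(n0)       # original node -> current super-node
  cur <- A
  m2 <- sum(A)             # total weight x2; invariant across levels
  repeat {
    lm <- local_move(cur, m2, resolution, stochastic)
    if (!lm$improved) break
    relab <- match(lm$comm, sort(unique(lm$comm)))
    map <- relab[map]
    if (max(relab) == nrow(cur)) break  # no merge happened
    # aggregate: diagonal accumulates 2x internal weight, consistent with
    # rowSums() as weighted degree and sum() as 2m.
    cur <- rowsum(t(rowsum(cur, relab)), relab)
  }
  map
}

# Phase 1: greedy local moving on adjacency `cur` (diag may carry self-loop
# weight from aggregation). Returns community labels and whether any move
# improved modularity.
local_move <- function(cur, m2, resolution, stochastic = FALSE) {
  n <- nrow(cur)
  k <- rowSums(cur)
  comm <- seq_len(n)
  tot <- k
  improved <- FALSE
  order <- sample.int(n)
  repeat {
    moved <- FALSE
    for (i in order) {
      ci <- comm[i]
      li <- cur[i, ]
      tot[ci] <- tot[ci] - k[i]
      w <- numeric(n)
      s <- rowsum(li, comm)
      w[as.integer(rownames(s))] <- s
      w[ci] <- w[ci] - li[i]   # exclude i's self-loop from its own community
      cand <- which(w > 0 | seq_len(n) == ci)
      gain <- w[cand] - resolution * k[i] * tot[cand] / m2
      cur_gain <- gain[match(ci, cand)]
      improving <- cand[gain > cur_gain + 1e-12]
      best <- if (length(improving) == 0L) {
        ci
      } else if (stochastic && length(improving) > 1L) {
        sample(improving, 1L)           # uniform among improving moves
      } else {
        cand[which.max(gain)]           # ties -> lowest community index
      }
      if (best != ci) {
        comm[i] <- best
        tot[best] <- tot[best] + k[i]
        moved <- TRUE
        improved <- TRUE
      } else {
        tot[ci] <- tot[ci] + k[i]
      }
    }
    if (!moved) break
  }
  list(comm = comm, improved = improved)
}

#' @export
print.snowsem_partition <- function(x, ...) {
  cat("<snowsem_partition>\n")
  cat(sprintf("  %d nodes in %d communities, Q = %.4f (seed %d, %d restarts)\n",
              length(x$membership), x$n_communities, x$modularity,
              x$seed, x$restarts))
  print(table(component = x$membership))
  invisible(x)
}

#' Weighted PageRank by power iteration
#'
#' Stationary distribution of the damped random walk with transition
#' probabilities proportional to edge weight; dangling (isolated) nodes
#' teleport uniformly. Iterates until the L1 change drops below `tol`.
#'
#' @param net Weighted undirected igraph network or adjacency matrix with at
#'   least one edge.
#' @param damping Damping factor d.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   last L1 change.
#' @return Named numeric vector of scores summing to 1.
#' @export
pagerank <- function(net, damping = 0.85, tol = 1e-10, max_iter = 10000L) {
  A <- net_adjacency(net)
  n <- nrow(A)
  if (sum(A) <= 0) stop_snowsem("Network has no edge weight.")
  k <- rowSums(A)
  dangling <- k == 0
  W <- A / ifelse(k > 0, k, 1)
  W[dangling, ] <- 0
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    xn <- damping * (as.vector(crossprod(W, x)) + sum(x[dangling]) / n) +
      (1 - damping) / n
    delta <- sum(abs(xn - x))
    x <- xn
    if (delta < tol) {
      return(setNames(x / sum(x), rownames(A)))
    }
  }
  stop_snowsem("PageRank did not converge in %d iterations (last L1 change %.3g).",
               max_iter, delta)
}
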