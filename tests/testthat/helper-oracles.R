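# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: likelihoods are full enumerations over
# internal-node state assignments, components come from transitive closure of
# the adjacency matrix, and overlap resolution is exhaustive subset search.

# enumerate all internal-node state assignments of a binary character:
# returns the exact log-likelihood and per-internal-node marginals
enum_er_oracle <- function(tree, states, q, prior = c(0.5, 0.5)) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  E <- tree$edge
  el <- tree$edge.length
  internal <- (nt + 1):(nt + nn)
  grid <- as.matrix(expand.grid(rep(list(0:1), nn)))
  st <- states[tree$tip.label]
  total <- 0
  marg <- matrix(0, nn, 2)
  for (r in seq_len(nrow(grid))) {
    s <- integer(nt + nn)
    s[seq_len(nt)] <- st
    s[internal] <- grid[r, ]
    p <- prior[s[nt + 1] + 1]
    for (i in seq_len(nrow(E))) {
      P <- er_transition(q, el[i])
      p <- p * P[s[E[i, 1]] + 1, s[E[i, 2]] + 1]
    }
    total <- total + p
    for (k in seq_len(nn)) {
      marg[k, grid[r, k] + 1] <- marg[k, grid[r, k] + 1] + p
    }
  }
  list(loglik = log(total), marginals = marg / total)
}

# connected components by boolean transitive closure (Warshall)
closure_components <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    A[edges$id_a[i], edges$id_b[i]] <- TRUE
    A[edges$id_b[i], edges$id_a[i]] <- TRUE
  }
  for (k in seq_len(n)) {
    A <- A | (A[, k] %o% A[k, ])
  }
  comp <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[A[i, ]] <- next_id
    }
  }
  split(nodes, comp)
}

# exhaustive maximum non-overlapping subset (largest count, ties by lowest
# total E-value) — the true optimum, attained by the greedy rule whenever
# overlapping hits are mutually overlapping
max_subset_oracle <- function(hits) {
  n <- nrow(hits)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2 || !any(outer(hits$start[idx], hits$end[idx], "<=") &
                                outer(hits$end[idx], hits$start[idx], ">=") &
                                !diag(TRUE, length(idx)))) {
      cand <- list(idx = idx, k = length(idx), ev = sum(hits$evalue[idx]))
      if (is.null(best) || cand$k > best$k ||
          (cand$k == best$k && cand$ev < best$ev)) {
        best <- cand
      }
    }
  }
  sort(best$idx)
}

# the greedy retention rule restated as a recursion on index sets — an
# implementation-independent rendering of "best first, drop what overlaps"
greedy_rule_oracle <- function(hits) {
  pick <- function(idx) {
    if (length(idx) == 0L) return(integer(0))
    ord <- idx[order(hits$evalue[idx], -hits$score[idx], hits$start[idx])]
    h <- ord[1L]
    keep <- idx[!(hits$start[idx] <= hits$end[h] &
                    hits$end[idx] >= hits$start[h])]
    c(h, pick(keep))
  }
  sort(pick(seq_len(nrow(hits))))
}

# random rooted tree with mixed tip states (both states present)
random_tree_with_states <- function(n_tips, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_tips)
    st <- sample(0:1, n_tips, replace = TRUE)
    if (length(unique(st)) == 1L) st[1] <- 1L - st[1]
    list(tree = tr, states = stats::setNames(st, tr$tip.label))
  })
}
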