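# Shared oracles and fixtures, all generated in code under fixed seeds.

# plain (element, count) table for comparing profile implementations
vcp_table <- function(v) {
  d <- as.data.frame(v)[c("element", "count")]
  rownames(d) <- NULL
  d
}

# breadth-first-search geodesic distances from one source over the
# undirected projection; independent of the package's adjacency tricks
bfs_distances <- function(graph, source) {
  nv <- graph$n_vertices
  dist <- rep(NA_integer_, nv)
  dist[source + 1L] <- 0L
  frontier <- source
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer(0)
    for (v in frontier) {
      nb <- graph$adj[[v + 1L]]$nbr
      new <- nb[is.na(dist[nb + 1L])]
      dist[new + 1L] <- d
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  dist
}

# all pairs at geodesic distance exactly two, by running BFS from every vertex
ell2_oracle <- function(graph) {
  nv <- graph$n_vertices
  out <- list()
  for (s in 0:(nv - 1L)) {
    dist <- bfs_distances(graph, s)
    at2 <- which(dist == 2L) - 1L
    at2 <- at2[at2 > s]
    if (length(at2)) out[[s + 1L]] <- cbind(s, at2)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) return(data.frame(s = integer(), t = integer()))
  data.frame(s = m[, 1L], t = m[, 2L])
}

# pairs at geodesic distance one or two (the oracle-equivalence pair set)
near_pairs <- function(graph) {
  e <- graph$edges[, c("u", "v")]
  names(e) <- c("s", "t")
  rbind(as.data.frame(e), ell2_oracle(graph))
}

# exhaustive threshold-sweep evaluation oracle: recompute precision/recall
# and TPR/FPR at every distinct score from scratch
eval_sweep_oracle <- function(scores, labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- fp <- numeric(length(th))
  for (i in seq_along(th)) {
    sel <- scores >= th[i]
    tp[i] <- sum(labels[sel] == 1)
    fp[i] <- sum(labels[sel] == 0)
  }
  recall <- tp / np
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  # trapezoid-free AUROC via pairwise comparisons (ties count half)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auroc = mean(cmp), aupr = aupr)
}

# direct entropy-based information gain for one feature vector (value per
# row) against binary labels
info_gain_oracle <- function(values, labels) {
  H <- function(y) {
    p <- table(y) / length(y)
    -sum(p * log2(p))
  }
  h0 <- H(labels)
  cond <- 0
  for (v in unique(values)) {
    sel <- values == v
    cond <- cond + mean(sel) * H(labels[sel])
  }
  h0 - cond
}
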