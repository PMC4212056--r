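# Synthetic generators: the adversarial multirelational Erdos-Renyi model
# used to stress element population, generic seeded random graphs for the
# oracle suites, and a longitudinal event-stream generator with a
# recency-biased link-formation mechanism for end-to-end pipeline tests.

#' Adversarial multirelational Erdos-Renyi graph
#'
#' For each unordered vertex pair a uniform draw below `p_edge` makes the
#' pair a candidate; each of the r relations is then included independently
#' when its own uniform draw falls below `p_rel`. A candidate can end up with
#' no relations at all (`p_edge = 1` does not imply a link). This model is
#' adversarial for profile analysis: moderate densities and moderate `p_rel`
#' maximize the diversity of observed isomorphism classes.
#'
#' @param n_vertices Number of vertices.
#' @param r Number of relations.
#' @param p_edge Probability a pair is a candidate edge.
#' @param p_rel Per-relation inclusion probability on candidates.
#' @param seed RNG seed; identical parameters and seed give byte-identical
#'   graphs.
#' @return An undirected `multigraph`.
#' @export
adversarial_er <- function(n_vertices, r, p_edge, p_rel, seed) {
  stopifnot(p_edge >= 0, p_edge <= 1, p_rel >= 0, p_rel <= 1)
  withr::with_seed(as.integer(seed), {
    pr <- utils::combn(0:(n_vertices - 1L), 2L)
    cand <- stats::runif(ncol(pr)) < p_edge
    u <- pr[1L, cand]; v <- pr[2L, cand]
    nc <- length(u)
    rows <- list()
    if (nc) {
      hits <- matrix(stats::runif(nc * r) < p_rel, nrow = nc)
      for (k in seq_len(r)) {
        on <- hits[, k]
        if (any(on)) rows[[k]] <- tibble::tibble(src = u[on], dst = v[on],
                                                 rel = k)
      }
    }
    edges <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(src = integer(), dst = integer(), rel = integer())
    multigraph(edges, n_vertices = n_vertices, r = r, directed = FALSE)
  })
}

#' Seeded uniform random multigraph
#'
#' Plain Erdos-Renyi generator for oracle and property suites: every
#' (ordered, when directed) vertex pair carries each relation independently
#' with probability `p`.
#'
#' @param n_vertices Number of vertices.
#' @param p Per-relation edge probability.
#' @param r Number of relations.
#' @param directed Logical.
#' @param seed RNG seed.
#' @return A `multigraph`.
#' @export
rand_multigraph <- function(n_vertices, p, r = 1, directed = FALSE, seed = 1) {
  withr::with_seed(as.integer(seed), {
    pr <- utils::combn(0:(n_vertices - 1L), 2L)
    if (directed) pr <- cbind(pr, pr[2:1, ])
    np <- ncol(pr)
    rows <- list()
    for (k in seq_len(r)) {
      on <- stats::runif(np) < p
      if (any(on)) rows[[k]] <- tibble::tibble(src = pr[1L, on],
                                               dst = pr[2L, on], rel = k)
    }
    edges <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(src = integer(), dst = integer(), rel = integer())
    multigraph(edges, n_vertices = n_vertices, r = r, directed = directed)
  })
}

#' Number of distinct populated VCP elements over all vertex pairs
#'
#' Runs the profile computation for every unordered vertex pair of the graph
#' and returns the size of the union of populated element ids — the quantity
#' that measures how much of the element universe a graph actually exercises.
#'
#' @param graph A `multigraph`.
#' @param spec A [universe_spec()] with n = 3 or 4 matching the graph.
#' @param mapping Optional `element_mapping`.
#' @return Count of distinct populated elements.
#' @export
element_population <- function(graph, spec, mapping = NULL) {
  stopifnot(inherits(spec, "universe_spec"), spec$n %in% c(3L, 4L))
  nv <- graph$n_vertices
  pr <- utils::combn(0:(nv - 1L), 2L)
  pairs <- tibble::tibble(s = pr[1L, ], t = pr[2L, ])
  prof <- profile_pairs(graph, pairs, n = spec$n, mapping = mapping)
  length(unique(prof$element))
}

#' Longitudinal event stream with recency-biased closure
#'
#' Generates a timestamped stream in which part of the events close open
#' wedges: an earlier event is sampled, a second event incident to one of
#' its endpoints is sampled, and the new event joins the two outer
#' endpoints. Wedge edges become eligible after a formation latency of
#' `lag` chunks (new links follow earlier interactions with a delay, as in
#' collaboration and communication networks) and their sampling weight then
#' decays as exp(-recency_bias * (age - lag)), so the probability that a
#' pair at distance two is closed rises sharply with the recency of its
#' wedge. The remaining events are uniform random pairs. With
#' `recency_bias = 0` the latency is dropped and wedge closure ignores
#' history timing entirely (the null model), so temporally resolved
#' features carry signal only when the bias is positive — and only under
#' the true event ordering.
#'
#' This generator is package test machinery: it emulates the time-dependent
#' link formation that longitudinal social and collaboration data exhibit,
#' not any specific published data set.
#'
#' @param n_vertices Number of vertices.
#' @param chunks Number of equal-duration chunks; chunk c spans `[c-1, c)`.
#' @param events_per_chunk Events generated in each chunk (exact).
#' @param recency_bias Exponential decay rate (per chunk of age beyond the
#'   latency) of the wedge-edge sampling weight; 0 disables both the bias
#'   and the latency.
#' @param seed RNG seed.
#' @param p_close Fraction of events that attempt wedge closure.
#' @param lag Formation latency in chunks: wedge edges younger than this are
#'   not yet citable by a closure.
#' @return A tibble with columns `src`, `dst`, `time`, sorted by time.
#' @export
longitudinal_synth <- function(n_vertices, chunks = 6, events_per_chunk = 120,
                               recency_bias = 3, seed = 1, p_close = 0.8,
                               lag = 1) {
  stopifnot(n_vertices >= 4, chunks >= 1, events_per_chunk >= 1,
            recency_bias >= 0, lag >= 0)
  withr::with_seed(as.integer(seed), {
    ne <- chunks * events_per_chunk
    src <- integer(ne); dst <- integer(ne)
    tms <- rep(seq_len(chunks) - 1L, each = events_per_chunk) +
      (seq_len(events_per_chunk) - 0.5) / events_per_chunk
    inc <- vector("list", n_vertices)   # event ids incident to each vertex
    if (recency_bias == 0) lag <- 0
    wt <- function(ids, now) {
      age <- now - tms[ids]
      exp(-recency_bias * pmax(age - lag, 0)) * (age >= lag)
    }
    rnd_pair <- function() sample.int(n_vertices, 2L) - 1L
    for (i in seq_len(ne)) {
      now <- tms[i]
      pair <- NULL
      if (i > 2L && stats::runif(1) < p_close) {
        w1 <- wt(seq_len(i - 1L), now)
        if (any(w1 > 0)) {
          e1 <- sample.int(i - 1L, 1L, prob = w1)
          wshared <- if (stats::runif(1) < 0.5) src[e1] else dst[e1]
          u <- if (wshared == src[e1]) dst[e1] else src[e1]
          cand <- inc[[wshared + 1L]]
          cand <- cand[cand != e1]
          if (length(cand)) {
            w2 <- wt(cand, now)
            if (any(w2 > 0)) {
              e2 <- if (length(cand) == 1L) cand else
                sample(cand, 1L, prob = w2)
              v <- if (src[e2] == wshared) dst[e2] else src[e2]
              if (u != v) pair <- c(u, v)
            }
          }
        }
      }
      if (is.null(pair)) pair <- rnd_pair()
      src[i] <- pair[1L]; dst[i] <- pair[2L]
      inc[[pair[1L] + 1L]] <- c(inc[[pair[1L] + 1L]], i)
      inc[[pair[2L] + 1L]] <- c(inc[[pair[2L] + 1L]], i)
    }
    tibble::tibble(src = src, dst = dst, time = tms)
  })
}
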