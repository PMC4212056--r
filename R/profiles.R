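`%||%` <- function(a, b) if (is.null(a)) b else a

# Vertex collocation profile counting.
#
# A profile for a pair (s, t) counts, for every selection of n - 2 free
# vertices from V \ {s, t}, which isomorphism class (VCP element) the induced
# subgraph on {s, t, free...} falls into. The naive counters enumerate every
# selection and serve as oracles; the optimized counters touch only the
# neighborhoods of s, t and their neighbors and recover everything else with
# closed-form corrections, so per-pair work is bound by neighborhood sizes
# rather than |V|.

spec_for_graph <- function(graph, n, mapping = NULL) {
  if (!is.null(mapping)) {
    spec <- mapping$spec
    if (spec$n != n) stop("mapping is for n = ", spec$n, call. = FALSE)
    if (spec$r != graph$r || spec$d != as.integer(graph$directed))
      stop("mapping universe does not match graph (r, directedness)",
           call. = FALSE)
    return(spec)
  }
  universe_spec(n, graph$r, directed = graph$directed)
}

default_mapping <- function(spec) {
  if (spec$n == 3L) return(identity_mapping(spec))
  if (spec$address_bits <= 20L) build_static_mapping(spec)
  else dynamic_mapping(spec)
}

# combined cell value of masks on an ordered pair (lower label first)
cellv <- function(fwd, bwd, spec) {
  if (spec$d == 1L) fwd + 2^spec$r * bwd else fwd
}

# dense mask matrix M[i+1, j+1] = mask of i -> j; oracle-side helper
mask_matrix <- function(graph) {
  nv <- graph$n_vertices
  M <- matrix(0L, nv, nv)
  e <- graph$edges
  M[cbind(e$u + 1L, e$v + 1L)] <- e$fwd
  M[cbind(e$v + 1L, e$u + 1L)] <- e$bwd
  M
}

dense_cell <- function(M, a, b, spec) {
  f <- M[cbind(a + 1L, b + 1L)]
  if (spec$d == 1L) f + 2^spec$r * M[cbind(b + 1L, a + 1L)] else f
}

vcp_result <- function(elements, counts, s, t, spec, ops = NA_real_) {
  keep <- counts > 0
  elements <- elements[keep]; counts <- counts[keep]
  if (length(elements)) {
    # group by position, not by stringified value: element ids can be large
    ue <- unique(elements)
    agg <- rowsum(as.numeric(counts), group = match(elements, ue))
    o <- order(ue)
    out <- tibble::new_tibble(list(element = ue[o],
                                   count = as.numeric(agg[o, 1L])),
                              nrow = length(ue))
  } else {
    out <- tibble::new_tibble(list(element = numeric(), count = numeric()),
                              nrow = 0L)
  }
  attr(out, "pair") <- c(s = s, t = t)
  attr(out, "spec") <- spec
  attr(out, "ops") <- ops
  class(out) <- c("vcp_vector", class(out))
  out
}

check_pair <- function(graph, s, t) {
  if (s == t) stop("s and t must differ", call. = FALSE)
  if (min(s, t) < 0 || max(s, t) >= graph$n_vertices)
    stop("vertex id out of range", call. = FALSE)
}

st_cell <- function(graph, s, t, spec) {
  m <- relation_mask(graph, s, t)
  cellv(m[["forward"]], m[["backward"]], spec)
}

#' Naive 3-vertex profile (enumeration oracle)
#'
#' Builds the induced 3-vertex subgraph on (s, t, k) for every other vertex k
#' and increments the corresponding element. O(|V|) edge lookups; intended as
#' a transparent oracle for [vcp3()].
#'
#' @param graph A `multigraph`.
#' @param s,t Vertex ids (0-based), distinct.
#' @param mapping Optional `element_mapping` for the (3, r, d) universe;
#'   defaults to the identity mapping (with one free vertex every address is
#'   its own canonical representative).
#' @return A `vcp_vector` tibble with columns `element`, `count`.
#' @export
vcp3_naive <- function(graph, s, t, mapping = NULL) {
  check_pair(graph, s, t)
  spec <- spec_for_graph(graph, 3L, mapping)
  if (is.null(mapping)) mapping <- identity_mapping(spec)
  nv <- graph$n_vertices
  ks <- setdiff(0:(nv - 1L), c(s, t))
  c12 <- st_cell(graph, s, t, spec)
  w <- spec$weights
  if (length(ks)) {
    M <- mask_matrix(graph)
    cS <- dense_cell(M, rep(s, length(ks)), ks, spec)
    cT <- dense_cell(M, rep(t, length(ks)), ks, spec)
    addr <- c12 * w[1L] + cS * w[2L] + cT * w[3L]
  } else addr <- numeric()
  vcp_result(element_of(addr, mapping), rep(1, length(addr)), s, t, spec)
}

#' Optimized 3-vertex profile
#'
#' Identical output to [vcp3_naive()], computed from a single merged scan of
#' the sorted adjacencies of s and t; the count of the fully disconnected
#' element is |V| - 2 - |neighborhood union| and never requires touching the
#' rest of the graph. Handles any r and both directednesses.
#'
#' @inheritParams vcp3_naive
#' @param omit_detached Suppress the element whose free vertex is adjacent to
#'   neither s nor t.
#' @return A `vcp_vector`; attribute `"ops"` counts adjacency entries touched.
#' @export
vcp3 <- function(graph, s, t, mapping = NULL, omit_detached = FALSE) {
  check_pair(graph, s, t)
  spec <- spec_for_graph(graph, 3L, mapping)
  if (is.null(mapping)) mapping <- identity_mapping(spec)
  as_ <- graph$adj[[s + 1L]]; at_ <- graph$adj[[t + 1L]]
  N <- setdiff(sort(unique(c(as_$nbr, at_$nbr))), c(s, t))
  is_ <- match(N, as_$nbr); it_ <- match(N, at_$nbr)
  sf <- ifelse(is.na(is_), 0L, as_$fwd[is_])
  sb <- ifelse(is.na(is_), 0L, as_$bwd[is_])
  tf <- ifelse(is.na(it_), 0L, at_$fwd[it_])
  tb <- ifelse(is.na(it_), 0L, at_$bwd[it_])
  c12 <- st_cell(graph, s, t, spec)
  w <- spec$weights
  addr <- c12 * w[1L] + cellv(sf, sb, spec) * w[2L] + cellv(tf, tb, spec) * w[3L]
  cnt <- rep(1, length(addr))
  nd <- graph$n_vertices - 2L - length(N)
  if (!omit_detached && nd > 0L) {
    addr <- c(addr, c12 * w[1L]); cnt <- c(cnt, nd)
  }
  vcp_result(element_of(addr, mapping), cnt, s, t, spec,
             ops = length(as_$nbr) + length(at_$nbr))
}

#' Naive 4-vertex profile (enumeration oracle)
#'
#' Iterates over every unordered pair of free vertices, builds the induced
#' 4-vertex subgraph, and increments its element — each selection counted
#' exactly once. Intended for graphs of at most a few hundred vertices as the
#' correctness oracle for [vcp4()].
#'
#' @inheritParams vcp3_naive
#' @param mapping `element_mapping` for the (4, r, d) universe; defaults to a
#'   static mapping (dynamic when the universe exceeds 2^20 addresses).
#' @return A `vcp_vector`.
#' @export
vcp4_naive <- function(graph, s, t, mapping = NULL) {
  check_pair(graph, s, t)
  spec <- spec_for_graph(graph, 4L, mapping)
  if (is.null(mapping)) mapping <- default_mapping(spec)
  nv <- graph$n_vertices
  free <- setdiff(0:(nv - 1L), c(s, t))
  c12 <- st_cell(graph, s, t, spec)
  w <- spec$weights
  if (length(free) >= 2L) {
    cmb <- utils::combn(free, 2L)
    k <- cmb[1L, ]; l <- cmb[2L, ]
    M <- mask_matrix(graph)
    addr <- c12 * w[1L] +
      dense_cell(M, rep(s, length(k)), k, spec) * w[2L] +
      dense_cell(M, rep(s, length(l)), l, spec) * w[3L] +
      dense_cell(M, rep(t, length(k)), k, spec) * w[4L] +
      dense_cell(M, rep(t, length(l)), l, spec) * w[5L] +
      dense_cell(M, k, l, spec) * w[6L]
  } else addr <- numeric()
  vcp_result(element_of(addr, mapping), rep(1, length(addr)), s, t, spec)
}

# per-graph table of edge cell values in lower-id -> higher-id orientation,
# used to resolve relation combinations of fully detached free pairs
edge_combo_table <- function(graph, spec) {
  cells <- cellv(graph$edges$fwd, graph$edges$bwd, spec)
  if (!length(cells)) return(numeric())
  tab <- table(cells)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

#' Optimized 4-vertex profile
#'
#' Identical output to [vcp4_naive()]. Only the neighborhoods of s, t and of
#' their neighbors are scanned; everything the scan cannot see is recovered
#' with closed-form corrections: structures whose fourth vertex is isolated
#' are counted as |V| minus the three neighborhoods, unobserved connected
#' free pairs as the global edge count minus the edges met directly, and
#' unobserved disconnected free pairs as the global gap count minus observed
#' and implied gaps. For r > 1 the relation combinations of fully detached
#' free pairs are resolved by decrementing a per-graph table of edge
#' combination frequencies for every directly encountered edge.
#'
#' @inheritParams vcp4_naive
#' @param omit_detached Suppress elements in which neither free vertex is
#'   adjacent to s or t (the detached substructures); counts of the remaining
#'   elements are unchanged.
#' @param combo_table Precomputed [edge combination table][vcp4] for batch
#'   drivers; computed from the graph when `NULL`.
#' @param detach_threshold Beyond this many relations the detached-combination
#'   table is not maintained and `omit_detached` is forced on (with a notice).
#' @return A `vcp_vector`; attribute `"ops"` counts adjacency entries touched.
#' @export
vcp4 <- function(graph, s, t, mapping = NULL, omit_detached = FALSE,
                 combo_table = NULL, detach_threshold = 16L) {
  check_pair(graph, s, t)
  spec <- spec_for_graph(graph, 4L, mapping)
  if (is.null(mapping)) mapping <- default_mapping(spec)
  if (graph$r > detach_threshold && !omit_detached) {
    message("r = ", graph$r, " exceeds the detached-substructure threshold; ",
            "omitting detached elements")
    omit_detached <- TRUE
  }
  nv <- graph$n_vertices
  w <- spec$weights
  as_ <- graph$adj[[s + 1L]]; at_ <- graph$adj[[t + 1L]]
  N <- setdiff(sort(unique(c(as_$nbr, at_$nbr))), c(s, t))
  nn <- length(N)
  is_ <- match(N, as_$nbr); it_ <- match(N, at_$nbr)
  cS <- cellv(ifelse(is.na(is_), 0L, as_$fwd[is_]),
              ifelse(is.na(is_), 0L, as_$bwd[is_]), spec)
  cT <- cellv(ifelse(is.na(it_), 0L, at_$fwd[it_]),
              ifelse(is.na(it_), 0L, at_$bwd[it_]), spec)
  c12 <- st_cell(graph, s, t, spec)
  w_size <- nv - 2L - nn
  Nst <- c(N, s, t)
  ops <- length(as_$nbr) + length(at_$nbr)

  addrs <- vector("list", 2L * nn + 4L)
  cnts <- vector("list", 2L * nn + 4L)
  ai <- 0L
  push <- function(a, c) {
    ai <<- ai + 1L
    addrs[[ai]] <<- a; cnts[[ai]] <<- c
  }

  for (ki in seq_len(nn)) {
    k <- N[ki]
    ak <- graph$adj[[k + 1L]]
    ops <- ops + length(ak$nbr)
    # free pairs with both vertices attached: k with every later neighbor of
    # the pair; masks between them read from k's adjacency
    if (ki < nn) {
      lv <- N[(ki + 1L):nn]
      mk <- match(lv, ak$nbr)
      ckl <- cellv(ifelse(is.na(mk), 0L, ak$fwd[mk]),
                   ifelse(is.na(mk), 0L, ak$bwd[mk]), spec)
      li <- (ki + 1L):nn
      push(c12 * w[1L] + cS[ki] * w[2L] + cS[li] * w[3L] +
             cT[ki] * w[4L] + cT[li] * w[5L] + ckl * w[6L],
           rep(1, length(li)))
    }
    # two-hop vertices: attached k plus a neighbor of k outside the pair's
    # neighborhood
    two_hop <- !(ak$nbr %in% Nst)
    n2 <- sum(two_hop)
    if (n2) {
      ckl <- cellv(ak$fwd[two_hop], ak$bwd[two_hop], spec)
      push(c12 * w[1L] + cS[ki] * w[2L] + cT[ki] * w[4L] + ckl * w[6L],
           rep(1, n2))
    }
    # correction: attached k with an isolated fourth vertex
    iso <- w_size - n2
    if (iso > 0L)
      push(c12 * w[1L] + cS[ki] * w[2L] + cT[ki] * w[4L], iso)
  }
  ops <- ops + nn * (nn - 1) / 2

  if (!omit_detached && w_size >= 2L) {
    # detached free pairs: global edge-combination counts minus every edge
    # encountered with an endpoint in {s, t} or the neighborhood
    if (is.null(combo_table)) combo_table <- edge_combo_table(graph, spec)
    obs <- vector("list", nn + 2L)
    for (ui in seq_along(Nst)) {
      u <- Nst[ui]
      au <- graph$adj[[u + 1L]]
      ops <- ops + length(au$nbr)
      vv <- au$nbr
      count_here <- !(vv %in% Nst) | (u < vv)
      if (any(count_here)) {
        lower <- u < vv[count_here]
        f <- au$fwd[count_here]; b <- au$bwd[count_here]
        obs[[ui]] <- ifelse(lower, cellv(f, b, spec), cellv(b, f, spec))
      }
    }
    obs <- unlist(obs, use.names = FALSE)
    rem <- combo_table
    if (length(obs)) {
      ot <- table(obs)
      hit <- match(names(ot), names(rem))
      rem[hit] <- rem[hit] - as.numeric(ot)
    }
    rem <- rem[rem > 0]
    if (length(rem))
      push(c12 * w[1L] + as.numeric(names(rem)) * w[6L], as.numeric(rem))
    gap <- w_size * (w_size - 1) / 2 - sum(rem)
    if (gap > 0) push(c12 * w[1L], gap)
  }

  addr <- unlist(addrs[seq_len(ai)], use.names = FALSE)
  cnt <- unlist(cnts[seq_len(ai)], use.names = FALSE)
  if (is.null(addr)) { addr <- numeric(); cnt <- numeric() }
  vcp_result(element_of(addr, mapping), cnt, s, t, spec, ops = ops)
}

#' Batch profile computation for a list of pairs
#'
#' Shares per-graph precomputation (element mapping, edge combination table)
#' across pairs and returns one long tibble in input pair order with sparse
#' (element, count) rows, elements ascending within each pair.
#'
#' @param graph A `multigraph`.
#' @param pairs Data frame (or 2-column matrix) of vertex pairs `s`, `t`.
#' @param n Subgraph order: 3 or 4.
#' @param mapping Optional `element_mapping`; defaults as in the per-pair
#'   functions.
#' @param omit_detached Suppress elements with no free vertex adjacent to the
#'   pair (counts of other elements unchanged).
#' @param method `"fast"` for the neighborhood-bound algorithms, `"naive"`
#'   for the enumeration oracles.
#' @return A tibble with columns `s`, `t`, `element`, `count`; attribute
#'   `"spec"` carries the universe.
#' @export
profile_pairs <- function(graph, pairs, n = 4, mapping = NULL,
                          omit_detached = FALSE,
                          method = c("fast", "naive")) {
  method <- match.arg(method)
  stopifnot(n %in% c(3L, 4L))
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  if (!all(c("s", "t") %in% names(pairs)))
    names(pairs)[1:2] <- c("s", "t")
  spec <- spec_for_graph(graph, as.integer(n), mapping)
  if (is.null(mapping)) mapping <- default_mapping(spec)
  combo <- if (n == 4L && method == "fast") edge_combo_table(graph, spec)
  np <- nrow(pairs)
  sv <- tv <- ev <- cv <- vector("list", np)
  for (i in seq_len(np)) {
    s <- pairs$s[i]; t <- pairs$t[i]
    v <- if (n == 3L) {
      if (method == "fast") vcp3(graph, s, t, mapping, omit_detached)
      else vcp3_naive(graph, s, t, mapping)
    } else {
      if (method == "fast") vcp4(graph, s, t, mapping, omit_detached,
                                 combo_table = combo)
      else vcp4_naive(graph, s, t, mapping)
    }
    k <- nrow(v)
    sv[[i]] <- rep(s, k); tv[[i]] <- rep(t, k)
    ev[[i]] <- v$element; cv[[i]] <- v$count
  }
  res <- tibble::new_tibble(list(
    s = unlist(sv, use.names = FALSE) %||% numeric(),
    t = unlist(tv, use.names = FALSE) %||% numeric(),
    element = unlist(ev, use.names = FALSE) %||% numeric(),
    count = unlist(cv, use.names = FALSE) %||% numeric()))
  attr(res, "spec") <- spec
  attr(res, "mapping") <- mapping
  res
}

#' Write profiles in the sparse (index, count) line format
#'
#' One line per pair: `src<TAB>dst<TAB>e1:c1 e2:c2 ...` with element ids
#' ascending; a header comment records the universe and layout version so the
#' output is bit-exact reproducible.
#'
#' @param profiles Long tibble from [profile_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  spec <- attr(profiles, "spec")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(spec))
    writeLines(sprintf("# vcp-profile\tn=%d\tr=%d\td=%d\tshift_st=%d\tlayout=1",
                       spec$n, spec$r, spec$d, as.integer(spec$shift_st)), con)
  key <- paste(profiles$s, profiles$t)
  for (k in unique(key)) {
    rows <- profiles[key == k, ]
    rows <- rows[order(rows$element), ]
    writeLines(sprintf("%s\t%s\t%s", format(rows$s[1L], scientific = FALSE),
                       format(rows$t[1L], scientific = FALSE),
                       paste(sprintf("%.0f:%.0f", rows$element, rows$count),
                             collapse = " ")), con)
  }
  invisible(path)
}
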