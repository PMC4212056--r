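#' Describe a subgraph universe
#'
#' A subgraph universe G^(n,r,d) is the set of all labeled subgraphs on `n`
#' vertices over `r` relations, undirected (`directed = FALSE`) or directed.
#' Vertex labels 1 and 2 are reserved for the profiled pair (v_s, v_t); labels
#' 3..n are the free vertices. Every subgraph in the universe is identified by
#' an integer address obtained by packing one relation bitmask per unordered
#' vertex pair into a significance-ordered bit field.
#'
#' The cell for pair (1,2) occupies the least significant bits and significance
#' increases in lexicographic pair order up to (n-1,n). In directed universes
#' each cell holds 2r bits: the forward block (edge from the lower to the
#' higher label) in the low r bits, then the backward block. With
#' `shift_st = TRUE` the (1,2) cell is moved to the most significant position
#' instead, so that for non-adjacent prediction pairs the populated part of
#' the vector clusters in the low half of the address space.
#'
#' @param n Number of subgraph vertices (>= 3).
#' @param r Number of relations (>= 1).
#' @param directed Logical; treat edges as directed?
#' @param shift_st Logical; give the (v_s, v_t) cell highest significance.
#' @return An object of class `universe_spec`.
#' @examples
#' universe_spec(4, 1)
#' universe_size(universe_spec(3, 1))  # 8
#' @export
universe_spec <- function(n, r, directed = FALSE, shift_st = FALSE) {
  stopifnot(length(n) == 1, length(r) == 1, n >= 3, r >= 1,
            n == as.integer(n), r == as.integer(r))
  d <- as.integer(isTRUE(directed))
  bpc <- (d + 1L) * as.integer(r)
  pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  np <- nrow(pairs)
  # significance rank per pair: default lexicographic; shift_st moves (1,2) last
  rank <- seq_len(np)
  if (isTRUE(shift_st)) rank <- c(np, seq_len(np - 1L))
  bits <- bpc * np
  spec <- structure(list(
    n = as.integer(n), r = as.integer(r), d = d,
    bits_per_cell = bpc, n_pairs = np, address_bits = bits,
    pairs = pairs, rank = rank,
    weights = 2^((rank - 1L) * bpc),
    shift_st = isTRUE(shift_st)
  ), class = "universe_spec")
  spec
}

#' @export
print.universe_spec <- function(x, ...) {
  cat(sprintf("<universe G^(%d,%d,%d)>  %d cells x %d bits = %d address bits%s\n",
              x$n, x$r, x$d, x$n_pairs, x$bits_per_cell, x$address_bits,
              if (x$shift_st) "  [s-t cell shifted to top]" else ""))
  invisible(x)
}

#' Size of a subgraph universe
#'
#' Returns 2^((d+1) r n(n-1)/2), the number of labeled subgraphs in the
#' universe. Powers of two are exactly representable as doubles well beyond
#' 2^53, so the value is exact even for universes such as G^(6,4,0) = 2^60.
#'
#' @param spec A [universe_spec()].
#' @return The exact universe size as a double.
#' @export
universe_size <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  2^spec$address_bits
}

#' Per-pair bit weights of the addressing scheme
#'
#' The weight of a cell is 2^offset where the offset increases by
#' `bits_per_cell` per lexicographic pair rank, e.g. (1,2,4,8,16,32) for the
#' six cells of G^(4,1,0).
#'
#' @param spec A [universe_spec()].
#' @return Named numeric vector of cell weights in pair order (1,2), (1,3), ...
#' @export
cell_weights <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  w <- spec$weights
  names(w) <- paste0("e", spec$pairs[, 1L], ",", spec$pairs[, 2L])
  w
}

check_addressable <- function(spec) {
  if (spec$address_bits > 52)
    stop("universe has ", spec$address_bits,
         " address bits; integer addresses are exact only up to 52 bits. ",
         "Use cell vectors and dynamic mode for larger universes.",
         call. = FALSE)
}

#' Encode per-pair cell values into a subgraph address
#'
#' @param cells Numeric vector of one relation-bitmask value per unordered
#'   vertex pair, in lexicographic pair order (1,2), (1,3), ..., (n-1,n).
#'   Directed cells hold forward + 2^r * backward.
#' @param spec A [universe_spec()] with at most 52 address bits.
#' @return The subgraph address (double).
#' @seealso [decode_address()], [canonical_address()]
#' @export
subgraph_address <- function(cells, spec) {
  stopifnot(inherits(spec, "universe_spec"), length(cells) == spec$n_pairs)
  check_addressable(spec)
  if (any(cells < 0) || any(cells >= 2^spec$bits_per_cell))
    stop("cell value out of range for ", spec$bits_per_cell, "-bit cells")
  sum(cells * spec$weights)
}

#' Decode a subgraph address into per-pair cell values
#'
#' @param addr Subgraph address (scalar).
#' @inheritParams subgraph_address
#' @return Numeric vector of cell values in pair order.
#' @export
decode_address <- function(addr, spec) {
  stopifnot(inherits(spec, "universe_spec"))
  check_addressable(spec)
  (addr %/% spec$weights) %% 2^spec$bits_per_cell
}

# All permutations of the free labels 3..n, each returned as the full label
# vector c(1, 2, image of 3, ..., image of n). (n-2)! entries; identity first.
free_permutations <- function(n) {
  free <- if (n > 2) 3:n else integer(0)
  perm_rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  ps <- perm_rec(free)
  ps <- lapply(ps, function(p) c(1L, 2L, p))
  # identity first for convenience
  idx <- which(vapply(ps, function(p) all(p == seq_len(n)), logical(1)))
  c(ps[idx], ps[-idx])
}

# For a full label mapping `lab` (lab[i] = new label of vertex i), derive how
# cells move: source pair rank k goes to target rank tgt[k]; swap[k] is TRUE
# when the endpoints change order (directed cells then exchange their forward
# and backward blocks).
perm_cell_map <- function(spec, lab) {
  p <- spec$pairs
  a <- lab[p[, 1L]]
  b <- lab[p[, 2L]]
  swap <- a > b
  lo <- pmin(a, b); hi <- pmax(a, b)
  # rank of pair (lo,hi) in lexicographic order among upper-triangle pairs
  key <- function(i, j) match(paste(i, j), paste(p[, 1L], p[, 2L]))
  list(target = key(lo, hi), swap = swap)
}

# Apply one cell map to a vector of addresses (vectorized core shared by
# permuted_address() and the whole-universe canonicalization).
apply_cell_map <- function(addrs, map, spec) {
  bpc <- spec$bits_per_cell
  r <- spec$r
  base <- 2^bpc
  out <- numeric(length(addrs))
  for (k in seq_len(spec$n_pairs)) {
    cv <- (addrs %/% spec$weights[k]) %% base
    if (spec$d == 1L && map$swap[k])
      cv <- (cv %% 2^r) * 2^r + cv %/% 2^r
    out <- out + cv * spec$weights[map$target[k]]
  }
  out
}

#' Address of a subgraph after permuting its free vertices
#'
#' Relabels the free vertices of the subgraph at `addr` according to `perm`
#' and returns the address of the resulting subgraph. Cells whose endpoints
#' change order under the relabeling exchange their forward and backward
#' blocks in directed universes.
#'
#' @param addr Vector of subgraph addresses.
#' @param perm Integer vector: a permutation of the labels `3:n` (the image of
#'   label i+2 at position i). Labels 1 and 2 are always fixed.
#' @inheritParams subgraph_address
#' @return Vector of permuted addresses.
#' @export
permuted_address <- function(addr, perm, spec) {
  stopifnot(inherits(spec, "universe_spec"))
  check_addressable(spec)
  nfree <- spec$n - 2L
  stopifnot(length(perm) == nfree, setequal(perm, seq_len(nfree) + 2L))
  lab <- c(1L, 2L, as.integer(perm))
  apply_cell_map(addr, perm_cell_map(spec, lab), spec)
}

#' Canonical representative of a subgraph's isomorphism class
#'
#' The canonical address is the minimum address over all (n-2)! permutations
#' of the free vertices. Two subgraphs receive the same canonical address
#' exactly when they are isomorphic under a mapping that fixes v_s and v_t,
#' i.e. when they belong to the same VCP element.
#'
#' @param addr Vector of subgraph addresses.
#' @inheritParams subgraph_address
#' @return Vector of canonical addresses (idempotent: canonical of canonical
#'   is itself).
#' @export
canonical_address <- function(addr, spec) {
  stopifnot(inherits(spec, "universe_spec"))
  check_addressable(spec)
  best <- as.numeric(addr)
  for (lab in free_permutations(spec$n)[-1L]) {
    best <- pmin(best, apply_cell_map(addr, perm_cell_map(spec, lab), spec))
  }
  best
}

# Every free-vertex permutation acts on an address as a pure bit
# permutation: cells move to their relabeled pair's offset, and a directed
# cell whose endpoints swap order exchanges its forward and backward blocks
# — both are bit moves. Returns the target offset of every source bit.
perm_bit_map <- function(spec, lab) {
  m <- perm_cell_map(spec, lab)
  bpc <- spec$bits_per_cell
  r <- spec$r
  sigma <- integer(spec$address_bits)
  for (k in seq_len(spec$n_pairs)) {
    src_off <- (spec$rank[k] - 1L) * bpc
    tgt_off <- (spec$rank[m$target[k]] - 1L) * bpc
    for (j in 0:(bpc - 1L)) {
      jj <- if (spec$d == 1L && m$swap[k]) (j + r) %% bpc else j
      sigma[src_off + j + 1L] <- tgt_off + jj
    }
  }
  sigma
}

# Canonicalize the full universe in one vectorized sweep: the address vector
# 0:(2^bits - 1) is pushed through every non-identity free-vertex permutation
# and the running minimum kept. Each permutation is a bit permutation, so it
# is applied with two precomputed half-word lookup tables rather than
# per-cell arithmetic. Returns the canonical address of every subgraph,
# indexed by address + 1.
canon_universe <- function(spec) {
  check_addressable(spec)
  bits <- spec$address_bits
  n_addr <- 2^bits
  addrs <- seq.int(0, n_addr - 1)
  lo_bits <- ceiling(bits / 2)
  lo_size <- 2^lo_bits
  lo <- addrs %% lo_size
  hi <- addrs %/% lo_size
  apply_sigma <- function(x, sigma_sub) {
    out <- numeric(length(x))
    for (b in seq_along(sigma_sub))
      out <- out + ((x %/% 2^(b - 1)) %% 2) * 2^sigma_sub[b]
    out
  }
  best <- addrs
  for (lab in free_permutations(spec$n)[-1L]) {
    sigma <- perm_bit_map(spec, lab)
    t_lo <- apply_sigma(seq.int(0, lo_size - 1), sigma[seq_len(lo_bits)])
    t_hi <- apply_sigma(seq.int(0, 2^(bits - lo_bits) - 1),
                        sigma[(lo_bits + 1L):bits])
    best <- pmin(best, t_lo[lo + 1L] + t_hi[hi + 1L])
  }
  best
}
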