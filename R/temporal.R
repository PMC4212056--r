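# Temporal snapshot encoding: longitudinal event streams become
# multirelational graphs by using the snapshot an event falls in as its
# relation type. Relation 1 is the OLDEST snapshot; the highest relation is
# the most recent, so recency occupies the high bits of each cell.

#' Chunk boundaries for an event stream
#'
#' Divides the stream's time span into `k` chunks, either of equal duration
#' (`by-time`) or of near-equal event counts with ties broken at timestamp
#' boundaries (`by-count`). Boundaries are half-open: chunk j is
#' `[b[j], b[j+1])`; the final boundary sits just above the last event so
#' every event is covered.
#'
#' @param stream Data frame with a `time` column.
#' @param k Number of chunks (>= 1).
#' @param mode `"by-time"` or `"by-count"`.
#' @return Numeric vector of `k + 1` boundaries.
#' @export
chunk_boundaries <- function(stream, k, mode = c("by-time", "by-count")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, nrow(stream) > 0)
  ts <- stream$time
  lo <- min(ts); hi <- max(ts)
  eps <- max((hi - lo) * 1e-9, abs(hi) * 1e-12, 1e-12)
  if (mode == "by-time") {
    b <- lo + (0:k) * (hi - lo) / k
    b[k + 1L] <- hi + eps
    return(b)
  }
  st <- sort(ts)
  distinct <- unique(st)
  if (k > length(distinct))
    stop("by-count chunking needs at least k distinct timestamps",
         call. = FALSE)
  n <- length(st)
  b <- numeric(k + 1L)
  b[1L] <- lo; b[k + 1L] <- hi + eps
  for (j in seq_len(k - 1L)) {
    target <- j * n / k
    # nearest index where the timestamp changes (ties are never split)
    breaks <- which(diff(st) > 0)          # split allowed after these indices
    i <- breaks[which.min(abs(breaks - target))]
    b[j + 1L] <- (st[i] + st[i + 1L]) / 2
  }
  if (any(diff(b) <= 0))
    stop("could not place ", k, " non-empty chunks at timestamp boundaries",
         call. = FALSE)
  b
}

#' Group chunks into temporal snapshots
#'
#' Produces the snapshot partition that becomes the relation structure of a
#' temporally encoded graph. With the `"equal"` scheme the chunks are split
#' as evenly as possible and the oldest snapshot absorbs the remainder. With
#' the `"exponential"` scheme the newest snapshot spans `newest_chunks`
#' chunks (default 2, which buffers short-period periodicity), each older
#' snapshot doubles, and the oldest absorbs any deficit or surplus —
#' emphasizing recent events by making recent snapshots short.
#'
#' @param chunks Numeric vector of chunk boundaries (length = chunks + 1),
#'   e.g. from [chunk_boundaries()].
#' @param periods Number of snapshots (= relations of the encoded graph).
#' @param scheme `"equal"` or `"exponential"`.
#' @param newest_chunks Chunks in the newest snapshot under the exponential
#'   scheme.
#' @return A `snapshot_spec`: snapshot boundaries `t_0 < ... < t_p`, sizes in
#'   chunks (oldest first), and the scheme.
#' @examples
#' snapshot_spec(0:13, 3, "exponential")$sizes  # 7 4 2, oldest first
#' @export
snapshot_spec <- function(chunks, periods, scheme = c("equal", "exponential"),
                          newest_chunks = 2L) {
  scheme <- match.arg(scheme)
  nc <- length(chunks) - 1L
  stopifnot(nc >= 1, periods >= 1)
  if (periods > nc)
    stop("periods (", periods, ") exceeds chunk count (", nc, ")",
         call. = FALSE)
  if (scheme == "equal") {
    q <- nc %/% periods
    sizes <- c(nc - (periods - 1L) * q, rep(q, periods - 1L))
  } else {
    ideal <- newest_chunks * 2^((periods - 1L):0L)   # oldest first
    oldest <- nc - sum(ideal[-1L])
    if (oldest < 1L)
      stop("too few chunks for ", periods, " exponential snapshots",
           call. = FALSE)
    sizes <- c(oldest, ideal[-1L])
  }
  cuts <- cumsum(c(0L, sizes))
  structure(list(boundaries = chunks[cuts + 1L], sizes = sizes,
                 scheme = scheme, chunks = chunks),
            class = "snapshot_spec")
}

#' @export
print.snapshot_spec <- function(x, ...) {
  cat(sprintf("<snapshot spec> %d snapshots (%s), sizes oldest-first: %s\n",
              length(x$sizes), x$scheme, paste(x$sizes, collapse = " ")))
  invisible(x)
}

#' Encode an event stream as a multirelational snapshot graph
#'
#' An event in snapshot j (1 = oldest) sets relation j on its edge; events
#' outside all snapshots are ignored and repeated in-snapshot events
#' collapse. Collapsing all relations (OR of masks) recovers the
#' unirelational union graph over the same window.
#'
#' @param stream Data frame with columns `src`, `dst`, `time`.
#' @param spec A [snapshot_spec()].
#' @param n_vertices Vertex count; inferred as max id + 1 when omitted.
#' @param directed Logical.
#' @return A `multigraph` with `r` = number of snapshots; attribute
#'   `"window"` records the covered interval.
#' @export
snapshot_encode <- function(stream, spec, n_vertices = NULL,
                            directed = FALSE) {
  stopifnot(inherits(spec, "snapshot_spec"))
  b <- spec$boundaries
  p <- length(b) - 1L
  if (is.null(n_vertices)) {
    if (!nrow(stream))
      stop("empty vertex universe: supply n_vertices", call. = FALSE)
    n_vertices <- max(stream$src, stream$dst) + 1L
  }
  snap <- findInterval(stream$time, b, rightmost.closed = FALSE)
  keep <- snap >= 1L & snap <= p & stream$time < b[p + 1L]
  g <- multigraph(
    tibble::tibble(src = stream$src[keep], dst = stream$dst[keep],
                   rel = snap[keep]),
    n_vertices = n_vertices, r = p, directed = directed)
  attr(g, "window") <- c(b[1L], b[p + 1L])
  g
}

#' Randomly reorder an event stream (surrogate-for-weight control)
#'
#' Permutes the assignment of timestamps to vertex pairs uniformly at random:
#' the multiset of timestamps and the multiset of pairs are each preserved,
#' so the union graph over any window covering the stream is unchanged, but
#' any genuinely temporal signal is destroyed. Used to test whether temporal
#' relations carry information beyond edge-weight surrogacy.
#'
#' @param stream Data frame with columns `src`, `dst`, `time`.
#' @param seed RNG seed; the same seed gives the same reordering.
#' @return A tibble with the same columns, times in the original order.
#' @export
reorder_events <- function(stream, seed) {
  n <- nrow(stream)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  out <- tibble::as_tibble(stream)
  pair_cols <- intersect(c("src", "dst"), names(out))
  out[pair_cols] <- out[perm, pair_cols]
  out
}
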