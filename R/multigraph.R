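#' Construct a multirelational graph from an edge table
#'
#' Builds the sorted-adjacency representation all profile counting runs on.
#' Vertices are 0-based contiguous integers; character ids are mapped through
#' a label table. Each unordered pair stores a forward and a backward
#' relation bitmask (bit k-1 set when relation k is present); undirected
#' graphs store the same mask in both directions. Duplicate rows and multiple
#' relation rows for one pair merge by OR-ing masks. Self-loops are dropped
#' with a warning.
#'
#' @param edges Data frame with columns `src`, `dst` and optionally `rel`
#'   (1-based relation index, defaults to 1).
#' @param n_vertices Vertex count; inferred as max id + 1 when omitted.
#' @param r Number of relations (>= 1, <= 30).
#' @param directed Logical.
#' @param max_degree Optional cap: edges incident to vertices whose total
#'   degree exceeds the cap are removed (default off).
#' @return An object of class `multigraph`.
#' @examples
#' g <- multigraph(tibble::tibble(src = c(0, 1), dst = c(1, 2)))
#' relation_mask(g, 0, 1)
#' @export
multigraph <- function(edges, n_vertices = NULL, r = 1, directed = FALSE,
                       max_degree = Inf) {
  stopifnot(is.data.frame(edges), r >= 1, r <= 30)
  r <- as.integer(r)
  src <- edges$src
  dst <- edges$dst
  if (is.null(src) || is.null(dst))
    stop("edge table must have columns `src` and `dst`", call. = FALSE)
  labels <- NULL
  if (is.character(src) || is.character(dst) || is.factor(src)) {
    labels <- sort(unique(c(as.character(src), as.character(dst))))
    src <- match(as.character(src), labels) - 1L
    dst <- match(as.character(dst), labels) - 1L
  }
  src <- as.integer(src)
  dst <- as.integer(dst)
  rel <- if (is.null(edges[["rel"]])) rep(1L, length(src)) else
    as.integer(edges[["rel"]])
  if (length(rel) && (any(rel < 1L) || any(rel > r)))
    stop("relation index out of range [1, ", r, "]", call. = FALSE)
  loop <- src == dst
  if (any(loop)) {
    warning("dropped ", sum(loop), " self-loop line(s)", call. = FALSE)
    src <- src[!loop]; dst <- dst[!loop]; rel <- rel[!loop]
  }
  if (is.null(n_vertices))
    n_vertices <- if (!is.null(labels)) length(labels) else
      if (length(src)) max(src, dst) + 1L else
        stop("empty vertex universe: supply n_vertices", call. = FALSE)
  n_vertices <- as.integer(n_vertices)
  if (length(src) && (min(src, dst) < 0L || max(src, dst) >= n_vertices))
    stop("vertex id out of range [0, ", n_vertices - 1L, "]", call. = FALSE)

  g <- build_multigraph(src, dst, rel, n_vertices, r, isTRUE(directed), labels)
  if (is.finite(max_degree)) {
    deg <- vapply(g$adj, function(a) length(a$nbr), integer(1))
    hot <- which(deg > max_degree) - 1L
    if (length(hot)) {
      keep <- !(src %in% hot | dst %in% hot)
      g <- build_multigraph(src[keep], dst[keep], rel[keep],
                            n_vertices, r, isTRUE(directed), labels)
    }
  }
  g
}

# core assembly from clean 0-based vectors; bitmask OR through deduplicated
# (pair, relation, direction) rows summed per pair
build_multigraph <- function(src, dst, rel, nv, r, directed, labels) {
  u <- pmin(src, dst); v <- pmax(src, dst)
  fb <- if (directed) ifelse(src < dst, 1L, 2L) else rep(1L, length(src))
  key <- paste(u, v, rel, fb)
  keep <- !duplicated(key)
  u <- u[keep]; v <- v[keep]; rel <- rel[keep]
  fb <- if (directed) fb[keep] else rep(1L, sum(keep))
  bit <- as.integer(2^(rel - 1L))
  pk <- as.numeric(u) * nv + v
  upk <- sort(unique(pk))
  i <- match(pk, upk)
  # every upk value occurs in i, so rowsum rows align with upk; summing
  # deduplicated relation bits per pair is exactly the bitmask OR
  fwd <- bwd <- integer(length(upk))
  if (length(i)) {
    if (directed) {
      f <- fb == 1L
      fwd <- as.integer(rowsum(bit * f, i))
      bwd <- as.integer(rowsum(bit * (!f), i))
    } else {
      fwd <- bwd <- as.integer(rowsum(bit, i))
    }
  }
  eu <- upk %/% nv; ev <- upk %% nv
  # adjacency: each pair contributes both directions of lookup
  from <- c(eu, ev); to <- c(ev, eu)
  f2 <- c(fwd, bwd); b2 <- c(bwd, fwd)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; f2 <- f2[o]; b2 <- b2[o]
  idx <- split(seq_along(from), factor(from, levels = 0:(nv - 1L)))
  adj <- lapply(idx, function(ii)
    list(nbr = to[ii], fwd = f2[ii], bwd = b2[ii]))
  structure(list(
    n_vertices = nv, r = r, directed = directed,
    adj = adj,
    edges = tibble::tibble(u = as.integer(eu), v = as.integer(ev),
                           fwd = fwd, bwd = bwd),
    n_edges = length(upk),
    labels = labels
  ), class = "multigraph")
}

#' @export
print.multigraph <- function(x, ...) {
  cat(sprintf("<multigraph> %d vertices, %d edges, r = %d, %s\n",
              x$n_vertices, x$n_edges, x$r,
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Edge table of a multigraph
#'
#' One row per (pair, relation, direction), sorted — the same records the
#' edge-list writer emits.
#'
#' @param x A `multigraph`.
#' @param ... Unused.
#' @return A tibble with columns `src`, `dst`, `rel`.
#' @method as_tibble multigraph
#' @export
as_tibble.multigraph <- function(x, ...) {
  e <- x$edges
  rows <- list()
  for (k in seq_len(x$r)) {
    bit <- 2^(k - 1L)
    fi <- bitwAnd(e$fwd, bit) != 0L
    if (any(fi)) rows[[length(rows) + 1L]] <-
        tibble::tibble(src = e$u[fi], dst = e$v[fi], rel = k)
    if (x$directed) {
      bi <- bitwAnd(e$bwd, bit) != 0L
      if (any(bi)) rows[[length(rows) + 1L]] <-
          tibble::tibble(src = e$v[bi], dst = e$u[bi], rel = k)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(src = integer(), dst = integer(), rel = integer())
  dplyr::arrange(out, .data$src, .data$dst, .data$rel)
}

#' Relation bitmasks between two vertices
#'
#' Looks the pair up by binary search in the adjacency list of the
#' lower-degree endpoint. Returns `(0, 0)` when no edge exists in either
#' direction; for undirected graphs forward and backward are equal.
#'
#' @param graph A `multigraph`.
#' @param i,j Vertex ids (0-based), `i != j`.
#' @return Named integer vector `c(forward, backward)` where forward is the
#'   mask of relations on the edge i -> j.
#' @export
relation_mask <- function(graph, i, j) {
  nv <- graph$n_vertices
  if (i == j) stop("self-pair has no relation mask", call. = FALSE)
  if (i < 0 || j < 0 || i >= nv || j >= nv)
    stop("vertex id out of range", call. = FALSE)
  ai <- graph$adj[[i + 1L]]; aj <- graph$adj[[j + 1L]]
  if (length(ai$nbr) <= length(aj$nbr)) {
    p <- bin_find(ai$nbr, j)
    if (is.na(p)) return(c(forward = 0L, backward = 0L))
    c(forward = ai$fwd[p], backward = ai$bwd[p])
  } else {
    p <- bin_find(aj$nbr, i)
    if (is.na(p)) return(c(forward = 0L, backward = 0L))
    c(forward = aj$bwd[p], backward = aj$fwd[p])
  }
}

# position of x in sorted integer vector v, NA if absent
bin_find <- function(v, x) {
  if (!length(v)) return(NA_integer_)
  p <- findInterval(x, v)
  if (p >= 1L && v[p] == x) p else NA_integer_
}

#' Build a unirelational union graph from timestamped events
#'
#' Collapses every event with both endpoints inside the half-open window
#' `[start, end)` onto a single-relation edge. The window is recorded on the
#' result (attribute `"window"`) so downstream dataset assembly can enforce
#' that label windows strictly follow feature windows.
#'
#' @param stream Data frame with columns `src`, `dst`, `time`.
#' @param window Numeric `c(start, end)`, half-open.
#' @param n_vertices Vertex count; inferred as max id + 1 over the whole
#'   stream when omitted (error on an empty stream).
#' @param directed Logical.
#' @return A `multigraph` with `r = 1`.
#' @export
from_events <- function(stream, window = range(stream$time) + c(0, 1),
                        n_vertices = NULL, directed = FALSE) {
  stopifnot(is.data.frame(stream), all(c("src", "dst", "time") %in% names(stream)))
  if (is.null(n_vertices)) {
    if (!nrow(stream))
      stop("empty vertex universe: supply n_vertices", call. = FALSE)
    n_vertices <- max(stream$src, stream$dst) + 1L
  }
  keep <- stream$time >= window[1] & stream$time < window[2]
  g <- multigraph(stream[keep, c("src", "dst")], n_vertices = n_vertices,
                  r = 1, directed = directed)
  attr(g, "window") <- as.numeric(window)
  g
}

#' Read a whitespace-delimited edge list
#'
#' Lines starting with `#` are skipped. Columns are interpreted according to
#' `columns` (names from `src`, `dst`, `rel`, `time`, `weight`, `ignore`);
#' by default the first two columns are `src dst` and a third column is taken
#' as the relation index when `num_relations > 1`. Weight columns are
#' accepted and ignored. Self-loop lines are dropped with a warning;
#' malformed lines raise an error naming the line number.
#'
#' @param path File path.
#' @param directed Logical.
#' @param num_relations Number of relations r.
#' @param columns Optional character vector naming the file columns.
#' @param n_vertices Optional vertex count.
#' @param max_degree Optional degree cap (see [multigraph()]).
#' @return A `multigraph`.
#' @export
read_edgelist <- function(path, directed = FALSE, num_relations = 1,
                          columns = NULL, n_vertices = NULL,
                          max_degree = Inf) {
  tab <- parse_delim(path)
  nc <- length(tab$fields[[1L]])
  if (is.null(columns)) {
    columns <- c("src", "dst")
    if (nc >= 3L)
      columns <- c(columns, if (num_relations > 1) "rel" else "ignore")
    if (nc >= 4L) columns <- c(columns, rep("ignore", nc - 3L))
  }
  df <- fields_to_frame(tab, columns, path)
  multigraph(df, n_vertices = n_vertices, r = num_relations,
             directed = directed, max_degree = max_degree)
}

#' Read a timestamped event stream
#'
#' Same format as [read_edgelist()] with a mandatory `time` column
#' (default column order `src dst time [rel]`).
#'
#' @inheritParams read_edgelist
#' @return A tibble with columns `src`, `dst`, `time` (and `rel` if present),
#'   sorted by time.
#' @export
read_events <- function(path, columns = NULL) {
  tab <- parse_delim(path)
  nc <- length(tab$fields[[1L]])
  if (is.null(columns)) {
    if (nc < 3L) stop("event stream needs a timestamp column", call. = FALSE)
    columns <- c("src", "dst", "time", rep("ignore", nc - 3L))
    if (nc >= 4L) columns[4L] <- "rel"
  }
  df <- fields_to_frame(tab, columns, path)
  if (is.null(df$time)) stop("no `time` column mapped", call. = FALSE)
  if (any(df$src == df$dst))
    stop("event stream contains self-loop events", call. = FALSE)
  dplyr::arrange(tibble::as_tibble(df), .data$time)
}

parse_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ln <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", ln)
  fields <- strsplit(trimws(ln[keep]), "\\s+")
  nfield <- lengths(fields)
  if (length(fields) && any(nfield != nfield[1L]))
    stop("malformed line ", which(keep)[which(nfield != nfield[1L])[1L]],
         " in ", path, ": inconsistent field count", call. = FALSE)
  list(fields = fields, lineno = which(keep))
}

fields_to_frame <- function(tab, columns, path) {
  out <- list()
  for (ci in seq_along(columns)) {
    nm <- columns[ci]
    if (nm == "ignore" || nm == "weight") next
    vals <- vapply(tab$fields, `[`, character(1), ci)
    if (nm %in% c("src", "dst") && any(grepl("[^0-9]", vals))) {
      out[[nm]] <- vals  # label-mapped downstream
    } else {
      num <- suppressWarnings(as.numeric(vals))
      if (anyNA(num))
        stop("malformed line ", tab$lineno[which(is.na(num))[1L]], " in ",
             path, ": cannot parse `", vals[which(is.na(num))[1L]],
             "` as ", nm, call. = FALSE)
      out[[nm]] <- num
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write a multigraph as a sorted, deduplicated edge list
#'
#' One line per (pair, relation); directed masks emit one line per direction.
#' Reading the file back with the same `directed`/`num_relations` reproduces
#' the adjacency and masks exactly.
#'
#' @param graph A `multigraph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  tab <- as_tibble(graph)
  if (!is.null(graph$labels)) {
    tab$src <- graph$labels[tab$src + 1L]
    tab$dst <- graph$labels[tab$dst + 1L]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
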