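#' Build the static subgraph-to-element mapping for a universe
#'
#' Enumerates every subgraph address in the universe, canonicalizes it over
#' the free-vertex permutations, and assigns 0-based contiguous element
#' indices in increasing canonical-address order. Lookup is then a constant
#' time vector dereference.
#'
#' @param spec A [universe_spec()].
#' @param cap Refuse to enumerate universes larger than this (default 2^24
#'   addresses); larger universes should use [dynamic_mapping()].
#' @return An `element_mapping` of mode `"static"`.
#' @examples
#' m <- build_static_mapping(universe_spec(4, 1))
#' element_count(m)          # 40 elements
#' element_of(c(2, 4), m)    # the isomorphic pair of single-edge subgraphs
#' @export
build_static_mapping <- function(spec, cap = 2^24) {
  stopifnot(inherits(spec, "universe_spec"))
  if (universe_size(spec) > cap)
    stop("universe size ", format(universe_size(spec)),
         " exceeds the static cap (", format(cap),
         "); use dynamic_mapping() instead.", call. = FALSE)
  canon <- canon_universe(spec)
  elements <- sort(unique(canon))
  structure(list(spec = spec, mode = "static",
                 elements = elements,
                 index = match(canon, elements) - 1L),
            class = "element_mapping")
}

#' Identity mapping for universes without free-vertex collapsing
#'
#' With a single free vertex (n = 3) every subgraph address is its own
#' canonical representative, so the element id of an address is the address
#' itself.
#'
#' @inheritParams build_static_mapping
#' @return An `element_mapping` of mode `"identity"`.
#' @export
identity_mapping <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  structure(list(spec = spec, mode = "identity"), class = "element_mapping")
}

#' Memoized dynamic subgraph-to-element mapping
#'
#' Instead of enumerating the universe, canonical representatives are computed
#' on first observation of a subgraph and the whole (n-2)! orbit is memoized,
#' so subsequent lookups of any orbit member are pure map reads. Element ids
#' are the (non-contiguous) canonical addresses.
#'
#' @inheritParams build_static_mapping
#' @return An `element_mapping` of mode `"dynamic"`.
#' @export
dynamic_mapping <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  structure(list(spec = spec, mode = "dynamic",
                 memo = new.env(hash = TRUE, parent = emptyenv())),
            class = "element_mapping")
}

#' @export
print.element_mapping <- function(x, ...) {
  cat(sprintf("<element mapping (%s) for G^(%d,%d,%d)>", x$mode,
              x$spec$n, x$spec$r, x$spec$d))
  if (x$mode == "static") cat(" ", length(x$elements), "elements")
  if (x$mode == "dynamic")
    cat(" ", length(ls(x$memo)), "memoized addresses")
  cat("\n")
  invisible(x)
}

#' Number of distinct elements known to a mapping
#' @param mapping An `element_mapping`.
#' @return Element count (for dynamic mappings, the number observed so far).
#' @export
element_count <- function(mapping) {
  switch(mapping$mode,
         static = length(mapping$elements),
         identity = universe_size(mapping$spec),
         dynamic = length(unique(unlist(as.list(mapping$memo), use.names = FALSE))))
}

#' Element id of one or more subgraph addresses
#'
#' Static mappings return 0-based contiguous element indices; identity
#' mappings return the address unchanged; dynamic mappings return the
#' canonical address, memoizing the full permutation orbit on first sight.
#'
#' @param addr Vector of subgraph addresses.
#' @param mapping An `element_mapping`.
#' @return Numeric vector of element ids.
#' @export
element_of <- function(addr, mapping) {
  switch(mapping$mode,
    identity = as.numeric(addr),
    static = mapping$index[addr + 1],
    dynamic = {
      spec <- mapping$spec
      memo <- mapping$memo
      perms <- free_permutations(spec$n)[-1L]
      maps <- lapply(perms, function(lab) perm_cell_map(spec, lab))
      vapply(as.numeric(addr), function(a) {
        key <- sprintf("%.0f", a)
        hit <- memo[[key]]
        if (!is.null(hit)) return(hit)
        orbit <- a
        for (m in maps) orbit <- c(orbit, apply_cell_map(a, m, spec))
        canon <- min(orbit)
        for (o in unique(orbit)) memo[[sprintf("%.0f", o)]] <- canon
        canon
      }, numeric(1))
    })
}

#' Dynamic element id for arbitrarily large universes
#'
#' Works on the per-pair cell representation so that universes beyond 52
#' address bits never overflow: cell vectors are exact integers and the
#' canonical representative is selected by comparing cells from the most
#' significant pair downwards (equivalent to the minimum address). The memo
#' key of the canonical orbit member is returned as the element id.
#'
#' @param cells Numeric vector of per-pair cell values (see
#'   [subgraph_address()]), or a subgraph address when the universe is small
#'   enough to address directly.
#' @param mapping A dynamic `element_mapping`.
#' @return The canonical cell key (character), and attribute `"address"` with
#'   the numeric canonical address when representable (<= 52 bits).
#' @export
dynamic_element <- function(cells, mapping) {
  stopifnot(inherits(mapping, "element_mapping"), mapping$mode == "dynamic")
  spec <- mapping$spec
  if (length(cells) == 1L && spec$address_bits <= 52)
    cells <- decode_address(cells, spec)
  stopifnot(length(cells) == spec$n_pairs)
  memo <- mapping$memo
  key <- paste(cells, collapse = ",")
  hit <- memo[[key]]
  if (is.null(hit)) {
    orbit <- lapply(free_permutations(spec$n), function(lab) {
      m <- perm_cell_map(spec, lab)
      cv <- cells
      if (spec$d == 1L) {
        sw <- m$swap
        cv[sw] <- (cv[sw] %% 2^spec$r) * 2^spec$r + cv[sw] %/% 2^spec$r
      }
      out <- numeric(spec$n_pairs)
      out[m$target] <- cv
      out
    })
    # minimum address == lexicographic minimum over cells read from the most
    # significant rank downwards
    ord <- order(spec$rank, decreasing = TRUE)
    keys <- vapply(orbit, function(cv) paste(cv, collapse = ","), character(1))
    cmp <- vapply(orbit, function(cv)
      paste(sprintf("%020.0f", cv[ord]), collapse = ""), character(1))
    hit <- keys[which.min(cmp)]
    for (k in unique(keys)) memo[[k]] <- hit
  }
  canon_cells <- as.numeric(strsplit(hit, ",", fixed = TRUE)[[1L]])
  if (spec$address_bits <= 52)
    attr(hit, "address") <- sum(canon_cells * spec$weights)
  hit
}

#' Number of VCP elements in a universe
#'
#' Counts distinct canonical representatives by full enumeration of the
#' universe. See [vcp_cardinality_burnside()] for the group-theoretic count
#' that does not enumerate.
#'
#' @inheritParams build_static_mapping
#' @return Element count (double).
#' @examples
#' vcp_cardinality(universe_spec(4, 2))  # 2176
#' @export
vcp_cardinality <- function(spec, cap = 2^24) {
  stopifnot(inherits(spec, "universe_spec"))
  if (universe_size(spec) > cap)
    stop("universe size exceeds the static cap; enumeration refused.",
         call. = FALSE)
  length(unique(canon_universe(spec)))
}

#' Burnside orbit count of VCP elements
#'
#' Computes the number of isomorphism classes as the average, over the
#' free-vertex permutation group, of the number of addresses each permutation
#' fixes. A permutation acts on the r-bit blocks of the address (one block
#' per pair, two per pair when directed); an address is fixed exactly when
#' its block values are constant on the cycles of that block permutation, so
#' the fixed-point count is (2^r)^cycles. No subgraph is ever enumerated,
#' which makes this an independent check on [vcp_cardinality()].
#'
#' @param spec A [universe_spec()].
#' @return Element count (double).
#' @export
vcp_cardinality_burnside <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  p <- spec$pairs
  np <- spec$n_pairs
  perms <- free_permutations(spec$n)
  total <- 0
  for (lab in perms) {
    m <- perm_cell_map(spec, lab)
    if (spec$d == 0L) {
      blocks <- m$target                  # block k -> block target[k]
    } else {
      # forward block of pair k is 2k-1, backward is 2k; a swapped pair sends
      # forward to backward and vice versa
      blocks <- integer(2L * np)
      for (k in seq_len(np)) {
        tk <- m$target[k]
        if (m$swap[k]) {
          blocks[2L * k - 1L] <- 2L * tk
          blocks[2L * k] <- 2L * tk - 1L
        } else {
          blocks[2L * k - 1L] <- 2L * tk - 1L
          blocks[2L * k] <- 2L * tk
        }
      }
    }
    # count cycles of the block permutation
    seen <- logical(length(blocks))
    ncyc <- 0L
    for (i in seq_along(blocks)) {
      if (!seen[i]) {
        ncyc <- ncyc + 1L
        j <- i
        while (!seen[j]) { seen[j] <- TRUE; j <- blocks[j] }
      }
    }
    total <- total + (2^spec$r)^ncyc
  }
  total / length(perms)
}

#' Write a subgraph-to-element mapping table
#'
#' Emits a TSV with columns address, canonical address and contiguous element
#' index, preceded by a header comment recording the universe parameters so
#' the table can be reloaded without recomputation.
#'
#' @param mapping A static `element_mapping`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "element_mapping"), mapping$mode == "static")
  spec <- mapping$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vcp-mapping\tn=%d\tr=%d\td=%d\tshift_st=%d\tlayout=1",
                     spec$n, spec$r, spec$d, as.integer(spec$shift_st)), con)
  addr <- seq_along(mapping$index) - 1
  canon <- mapping$elements[mapping$index + 1L]
  utils::write.table(
    data.frame(address = addr, canonical = canon, element = mapping$index),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Reload a mapping written by [write_mapping()]
#' @param path File path.
#' @return A static `element_mapping`.
#' @export
read_mapping <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# vcp-mapping"))
    stop("not a vcp mapping file: ", path, call. = FALSE)
  f <- function(k) as.integer(sub(sprintf(".*\\b%s=(\\d+).*", k), "\\1", hdr))
  spec <- universe_spec(f("n"), f("r"), directed = f("d") == 1L,
                        shift_st = f("shift_st") == 1L)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  elements <- sort(unique(tab$canonical[order(tab$address)]))
  structure(list(spec = spec, mode = "static", elements = elements,
                 index = as.integer(tab$element[order(tab$address)])),
            class = "element_mapping")
}
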