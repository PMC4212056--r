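# Supervised link prediction on VCP features: candidate enumeration at
# geodesic distance 2, labeled dataset assembly with a hard leakage guard,
# class rebalancing, information-gain feature ranking on ordered
# value-frequency maps, and a bagged random-subspace classifier.

#' Unordered vertex pairs at geodesic distance exactly two
#'
#' The standard high-prior candidate set for link prediction: pairs reachable
#' through at least one common neighbor but not directly linked by any
#' relation in any direction. Directed graphs are projected to their
#' undirected union for candidate enumeration (features stay fully directed).
#' Output is deterministic, ascending by (s, t).
#'
#' @param graph A `multigraph`.
#' @return A tibble with columns `s`, `t` (s < t).
#' @export
ell2_pairs <- function(graph) {
  nv <- graph$n_vertices
  keys <- vector("list", nv)
  for (v in seq_len(nv)) {
    nb <- graph$adj[[v]]$nbr
    m <- length(nb)
    if (m >= 2L) {
      a <- rep(nb[-m], times = (m - 1L):1L)
      b <- nb[sequence((m - 1L):1L, from = 2:m)]
      keys[[v]] <- as.numeric(a) * nv + b
    }
  }
  keys <- unique(unlist(keys, use.names = FALSE))
  if (is.null(keys)) return(tibble::tibble(s = integer(), t = integer()))
  e <- graph$edges
  keys <- setdiff(keys, as.numeric(e$u) * nv + e$v)
  keys <- sort(keys)
  tibble::tibble(s = as.integer(keys %/% nv), t = as.integer(keys %% nv))
}

edge_present <- function(graph, s, t) {
  vapply(seq_along(s), function(i) {
    m <- relation_mask(graph, s[i], t[i])
    (m[["forward"]] + m[["backward"]]) > 0
  }, logical(1))
}

#' Assemble a labeled pair dataset for supervised link prediction
#'
#' One row per candidate pair: its sparse VCP feature vector computed on the
#' feature graph and a binary label, positive exactly when the pair is
#' linked in the label graph and not in the feature graph. When both graphs
#' carry window attributes (see [from_events()], [snapshot_encode()]) the
#' label window must start at or after the feature window's end — any
#' overlap is a hard leakage failure.
#'
#' @param feature_graph `multigraph` the features are computed on.
#' @param label_graph `multigraph` supplying the labels (a strictly later
#'   window of the same network).
#' @param pairs Data frame of candidate pairs `s`, `t` (no duplicates).
#' @param n Subgraph order (3 or 4).
#' @param mapping Optional `element_mapping`.
#' @param omit_detached Passed to [profile_pairs()].
#' @return A `pair_dataset`: tibble with columns `s`, `t`, `label` and a
#'   `features` list-column of (element, count) tibbles; attributes `spec`
#'   and `provenance`.
#' @export
build_dataset <- function(feature_graph, label_graph, pairs, n = 4,
                          mapping = NULL, omit_detached = FALSE) {
  fw <- attr(feature_graph, "window")
  lw <- attr(label_graph, "window")
  if (!is.null(fw) && !is.null(lw) && lw[1] < fw[2])
    stop("label window [", lw[1], ", ", lw[2], ") overlaps feature window [",
         fw[1], ", ", fw[2], "): leakage", call. = FALSE)
  if (anyDuplicated(paste(pairs$s, pairs$t)))
    stop("duplicate pairs in candidate set", call. = FALSE)
  prof <- profile_pairs(feature_graph, pairs, n = n, mapping = mapping,
                        omit_detached = omit_detached)
  key <- paste(prof$s, prof$t)
  feats <- split(prof[c("element", "count")],
                 factor(key, levels = unique(paste(pairs$s, pairs$t))))
  label <- edge_present(label_graph, pairs$s, pairs$t) &
    !edge_present(feature_graph, pairs$s, pairs$t)
  out <- tibble::tibble(s = pairs$s, t = pairs$t,
                        label = as.integer(label),
                        features = unname(feats))
  attr(out, "spec") <- attr(prof, "spec")
  attr(out, "mapping") <- attr(prof, "mapping")
  attr(out, "provenance") <- list(feature_window = fw, label_window = lw)
  class(out) <- c("pair_dataset", class(out))
  out
}

#' Undersample negatives to a target positive prevalence
#'
#' Keeps every positive row and uniformly subsamples negatives so positives
#' make up `positive_prevalence` of the result (rounding the negative count
#' to the nearest integer). Datasets already at or above the target are
#' returned unchanged. Test sets are never undersampled.
#'
#' @param ds A `pair_dataset`.
#' @param positive_prevalence Target fraction of positives (0, 1].
#' @param seed RNG seed for the negative subsample.
#' @return A `pair_dataset` with rows in their original order.
#' @export
undersample <- function(ds, positive_prevalence = 0.25, seed = 1) {
  stopifnot(positive_prevalence > 0, positive_prevalence <= 1)
  pos <- which(ds$label == 1L)
  neg <- which(ds$label == 0L)
  if (!length(pos)) stop("no positive rows to balance around", call. = FALSE)
  target <- round(length(pos) * (1 - positive_prevalence) /
                    positive_prevalence)
  if (length(neg) <= target) return(ds)
  keep_neg <- withr::with_seed(as.integer(seed), sample(neg, target))
  ds[sort(c(pos, keep_neg)), ]
}

#' Ordered value-frequency maps of every feature, split by class
#'
#' A single pass over the sparse rows builds, for each element, the ordered
#' map from observed count value to its frequency in each class — rows in
#' which the element is absent contribute to value 0, so per-element
#' frequency totals equal the dataset size. This non-contiguous counting
#' sort is the substrate for near-instant information-gain ranking.
#'
#' @param ds A `pair_dataset`.
#' @return A `feature_stats` tibble with columns `element`, `value`,
#'   `n_pos`, `n_neg`; attributes record class totals.
#' @export
feature_stats <- function(ds) {
  tot_pos <- sum(ds$label == 1L)
  tot_neg <- sum(ds$label == 0L)
  long <- tidyr::unnest(ds[c("label", "features")], "features")
  tab <- dplyr::summarise(
    dplyr::group_by(long, .data$element, value = .data$count),
    n_pos = sum(.data$label == 1L), n_neg = sum(.data$label == 0L),
    .groups = "drop")
  # implicit zeros: the remainder of each class per element
  zero <- dplyr::summarise(
    dplyr::group_by(tab, .data$element),
    value = 0, n_pos = !!tot_pos - sum(.data$n_pos),
    n_neg = !!tot_neg - sum(.data$n_neg), .groups = "drop")
  zero <- zero[zero$n_pos + zero$n_neg > 0, ]
  out <- dplyr::arrange(dplyr::bind_rows(tab, zero),
                        .data$element, .data$value)
  attr(out, "n_pos") <- tot_pos
  attr(out, "n_neg") <- tot_neg
  class(out) <- c("feature_stats", class(out))
  out
}

entropy2 <- function(a, b) {
  n <- a + b
  p <- c(a, b) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rank elements by information gain
#'
#' The gain of an element is the reduction in class entropy from
#' conditioning on its exact count value (each distinct value is one
#' category, computed directly from the ordered value-frequency maps).
#' Elements with identical value distributions in both classes get gain 0; a
#' perfectly separating element attains the full class entropy. Descending
#' by gain, ties broken by element id.
#'
#' @param stats A [feature_stats()] table.
#' @return A tibble with columns `element`, `gain`, ranked.
#' @export
info_gain_rank <- function(stats) {
  n_pos <- attr(stats, "n_pos")
  n_neg <- attr(stats, "n_neg")
  if (n_pos == 0 || n_neg == 0)
    stop("information gain needs both classes present", call. = FALSE)
  n <- n_pos + n_neg
  h0 <- entropy2(n_pos, n_neg)
  gain <- dplyr::summarise(
    dplyr::group_by(stats, .data$element),
    gain = h0 - sum((.data$n_pos + .data$n_neg) / n *
                      mapply(entropy2, .data$n_pos, .data$n_neg)),
    .groups = "drop")
  dplyr::arrange(gain, dplyr::desc(.data$gain), .data$element)
}

#' Keep only the k strongest elements of a dataset
#'
#' @param ds A `pair_dataset`.
#' @param k Number of elements to retain.
#' @param ranking Optional precomputed [info_gain_rank()] table; computed
#'   from `ds` when missing.
#' @return `ds` with features restricted to the top-k elements.
#' @export
filter_top_k <- function(ds, k = 1000, ranking = NULL) {
  if (is.null(ranking)) ranking <- info_gain_rank(feature_stats(ds))
  keep <- utils::head(ranking$element, k)
  ds$features <- lapply(ds$features, function(f)
    f[f$element %in% keep, , drop = FALSE])
  ds
}

# dense feature matrix over a fixed element vocabulary
dataset_matrix <- function(ds, elements = NULL) {
  if (is.null(elements))
    elements <- sort(unique(unlist(lapply(ds$features, `[[`, "element"))))
  X <- matrix(0, nrow = nrow(ds), ncol = length(elements))
  for (i in seq_len(nrow(ds))) {
    f <- ds$features[[i]]
    j <- match(f$element, elements)
    ok <- !is.na(j)
    X[i, j[ok]] <- f$count[ok]
  }
  colnames(X) <- paste0("e", seq_along(elements))
  list(X = X, elements = elements)
}

#' Bagged random-subspace classification scores
#'
#' Fits an ensemble of `bags` bootstrap replicates, each holding
#' `subspaces` decision trees grown on a random half of the feature space
#' (classification trees are delegated to rpart), and returns the mean
#' positive-class probability for each test row — a score in [0, 1].
#' Feature vocabulary is fixed by the training set; unseen test elements are
#' ignored.
#'
#' @param train,test `pair_dataset`s sharing a universe spec.
#' @param bags Number of bootstrap bags.
#' @param subspaces Trees per bag, each on its own feature subspace.
#' @param subspace_frac Fraction of features sampled per tree.
#' @param seed RNG seed; scores are reproducible per seed.
#' @return Numeric scores, one per test row.
#' @export
train_predict <- function(train, test, bags = 10, subspaces = 10,
                          subspace_frac = 0.5, seed = 1) {
  spec_tr <- attr(train, "spec"); spec_te <- attr(test, "spec")
  if (!is.null(spec_tr) && !is.null(spec_te) &&
      !identical(spec_tr[c("n", "r", "d")], spec_te[c("n", "r", "d")]))
    stop("train and test datasets use different universes", call. = FALSE)
  if (length(unique(train$label)) < 2L)
    stop("degenerate training set: a single class", call. = FALSE)
  tr <- dataset_matrix(train)
  te <- dataset_matrix(test, elements = tr$elements)
  p <- ncol(tr$X)
  if (p == 0L) stop("no populated features in the training set", call. = FALSE)
  y <- factor(train$label, levels = c(0L, 1L))
  ntr <- nrow(tr$X)
  scores <- numeric(nrow(te$X))
  nmodels <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(bags)) {
      rows <- sample.int(ntr, replace = TRUE)
      for (m in seq_len(subspaces)) {
        cols <- sample.int(p, max(1L, ceiling(subspace_frac * p)))
        df <- as.data.frame(tr$X[rows, cols, drop = FALSE])
        df$.y <- y[rows]
        if (length(unique(df$.y)) < 2L) next
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(
                              xval = 0, maxcompete = 0, maxsurrogate = 0))
        pr <- stats::predict(
          fit, newdata = as.data.frame(te$X[, cols, drop = FALSE]),
          type = "prob")
        scores <- scores + if ("1" %in% colnames(pr)) pr[, "1"] else 0
        nmodels <- nmodels + 1L
      }
    }
  })
  if (nmodels == 0L) stop("no model could be fit", call. = FALSE)
  scores / nmodels
}

#' Average a pair's two directional scores
#'
#' Undirected prediction targets get one score per orientation of the pair;
#' the final prediction is their arithmetic mean.
#'
#' @param score_st,score_ts Finite numeric scores (vectorized).
#' @return Elementwise mean.
#' @export
symmetrize_scores <- function(score_st, score_ts) {
  stopifnot(all(is.finite(score_st)), all(is.finite(score_ts)))
  (score_st + score_ts) / 2
}
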