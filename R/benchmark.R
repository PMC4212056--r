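#' End-to-end temporal link-prediction benchmark on synthetic streams
#'
#' Runs the full pipeline on one [longitudinal_synth()] stream three ways and
#' returns held-out performance for each: unirelational features (the union
#' graph of the feature window), temporally resolved multirelational
#' features (the feature window split into `periods` snapshots encoded as
#' relations), and the same temporal features after randomly reordering the
#' feature-window events (the surrogate-for-weight control; the union graph
#' and the labels are untouched by the reorder).
#'
#' The temporal split follows the standard longitudinal protocol: with C
#' chunks, training features span chunks 1..C-2 and training labels chunk
#' C-1; testing features span chunks 2..C-1 and testing labels chunk C, so
#' training labels always precede the testing label period. Training sets
#' are undersampled to 25% positive prevalence; test sets are untouched.
#'
#' @param seed Seed driving the stream, the undersampling, the classifier
#'   and the reorder control.
#' @param n_vertices,chunks,events_per_chunk,recency_bias Passed to
#'   [longitudinal_synth()].
#' @param periods Temporal snapshots in the feature window.
#' @param n Subgraph order of the profiles (3 or 4).
#' @param n_reorder Reorderings averaged for the control.
#' @param bags,subspaces Classifier ensemble shape.
#' @return A one-row tibble with AUROC and AUPR for the unirelational,
#'   temporal and reordered pipelines, plus candidate/positive counts.
#' @export
recency_benchmark <- function(seed, n_vertices = 100, chunks = 6,
                              events_per_chunk = 120, recency_bias = 3,
                              periods = 2, n = 4, n_reorder = 1,
                              bags = 10, subspaces = 10) {
  stopifnot(chunks >= 4)
  stream <- longitudinal_synth(n_vertices, chunks, events_per_chunk,
                               recency_bias, seed = seed)
  # one train/test side: features in [f_lo, f_hi), labels in [f_hi, l_hi).
  # The reorder control scrambles timestamps only inside the side's feature
  # window, so the union graph, the candidate set and the labels are
  # identical to the ordered run; only snapshot membership changes.
  one_side <- function(f_lo, f_hi, l_hi, scramble_seed = NULL,
                       temporal_only = FALSE) {
    fstr <- stream
    if (!is.null(scramble_seed)) {
      idx <- stream$time >= f_lo & stream$time < f_hi
      fstr[idx, ] <- reorder_events(stream[idx, ], seed = scramble_seed)
    }
    uni <- from_events(fstr, c(f_lo, f_hi), n_vertices = n_vertices)
    lab <- from_events(stream, c(f_hi, l_hi), n_vertices = n_vertices)
    cand <- ell2_pairs(uni)
    sspec <- snapshot_spec(seq(f_lo, f_hi), periods, "equal")
    tmp <- snapshot_encode(fstr, sspec, n_vertices = n_vertices)
    list(uni = if (!temporal_only) build_dataset(uni, lab, cand, n = n),
         tmp = build_dataset(tmp, lab, cand, n = n))
  }
  score <- function(tr, te) {
    tr <- undersample(tr, 0.25, seed = seed)
    evaluate_scores(train_predict(tr, te, bags = bags,
                                  subspaces = subspaces, seed = seed),
                    te$label)
  }
  train <- one_side(0, chunks - 2, chunks - 1)
  test <- one_side(1, chunks - 1, chunks)
  ev_uni <- score(train$uni, test$uni)
  ev_tmp <- score(train$tmp, test$tmp)
  reord <- vapply(seq_len(n_reorder), function(i) {
    rtrain <- one_side(0, chunks - 2, chunks - 1,
                       scramble_seed = seed * 1000L + 2L * i,
                       temporal_only = TRUE)
    rtest <- one_side(1, chunks - 1, chunks,
                      scramble_seed = seed * 1000L + 2L * i + 1L,
                      temporal_only = TRUE)
    ev <- score(rtrain$tmp, rtest$tmp)
    c(ev$auroc, ev$aupr)
  }, numeric(2))
  tibble::tibble(
    seed = seed,
    auroc_uni = ev_uni$auroc, aupr_uni = ev_uni$aupr,
    auroc_temporal = ev_tmp$auroc, aupr_temporal = ev_tmp$aupr,
    auroc_reordered = mean(reord[1, ]), aupr_reordered = mean(reord[2, ]),
    n_candidates = nrow(test$uni), n_positives = sum(test$uni$label))
}
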