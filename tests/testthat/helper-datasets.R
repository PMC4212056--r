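# Synthetic pair datasets built directly (no graph), for classifier and
# sampling tests.

edge_present_oracle <- function(graph, pairs) {
  vapply(seq_len(nrow(pairs)), function(i)
    sum(relation_mask(graph, pairs$s[i], pairs$t[i])) > 0, logical(1))
}

fake_dataset <- function(n_pos, n_neg, seed) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    lab <- c(rep(1L, n_pos), rep(0L, n_neg))
    ds <- tibble::tibble(
      s = seq_len(n) - 1, t = seq_len(n) + 1000, label = lab,
      features = lapply(seq_len(n), function(i)
        tibble::tibble(element = sort(sample(1:20, 3)),
                       count = sample(1:5, 3, TRUE))))
    class(ds) <- c("pair_dataset", class(ds))
    ds
  })
}

# linearly separable: element 1's count determines the class, plus noise
# elements shared by both classes
separable_dataset <- function(n, seed) {
  withr::with_seed(seed, {
    lab <- rbinom(n, 1, 0.5)
    ds <- tibble::tibble(
      s = seq_len(n) - 1, t = seq_len(n) + 1000, label = lab,
      features = lapply(seq_len(n), function(i)
        tibble::tibble(element = c(1, sample(5:30, 2)),
                       count = c(if (lab[i] == 1) 8 + rpois(1, 2) else
                                   1 + rpois(1, 2),
                                 sample(1:4, 2, TRUE)))))
    class(ds) <- c("pair_dataset", class(ds))
    ds
  })
}
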