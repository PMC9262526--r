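# Shared fixtures, all built in code.

els6 <- syndrome_elements()

# Small bank with fully controlled parameters. thresholds: list of numeric
# vectors (one per item) or a single vector recycled.
make_bank <- function(a, elements, thresholds, elements_universe = els6) {
  n <- length(a)
  if (!is.list(thresholds)) thresholds <- rep(list(thresholds), n)
  K1 <- max(lengths(thresholds))
  b <- t(vapply(thresholds, function(x) c(x, rep(NA, K1 - length(x))),
                numeric(K1)))
  colnames(b) <- paste0("b", seq_len(K1))
  items <- data.frame(item_id = seq_len(n), element = elements, a = a, b,
                      stringsAsFactors = FALSE)
  catmcid:::new_item_bank(items, elements_universe)
}

# Brute-force D-optimal selection: literal determinant maximization.
select_bruteforce <- function(bank, administered_ids, theta, prior) {
  ids <- bank$items$item_id
  cand <- setdiff(ids, administered_ids)
  A <- prior$precision
  for (id in administered_ids) {
    row <- bank$items[match(id, ids), , drop = FALSE]
    A <- A + item_information(row, theta, bank$elements)
  }
  dets <- vapply(cand, function(id) {
    row <- bank$items[match(id, ids), , drop = FALSE]
    det(A + item_information(row, theta, bank$elements))
  }, numeric(1))
  best <- cand[dets == max(dets)]
  min(best)
}

# Mann-Whitney pair statistic: P(score+ > score-) + 0.5 P(tie), all pairs.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A tiny but structurally complete cohort for plumbing tests.
tiny_cohort <- function(n = 40, seed = 7, ...) {
  suppressMessages(generate_cohort(
    cohort_config(n_baseline = n, n_dropout = 3, seed = seed, ...)))
}
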