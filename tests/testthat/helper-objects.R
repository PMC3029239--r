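# Shared objects built once per test run: the default synthetic benchmark,
# a train/test split, and a small trained model for tests that only need
# some fitted embedding (not a converged one).

fx_default <- generate_fixture(fixture_config(seed = 1))

split_default <- holdout_split(fx_default, n_test = 20, seed = 2)

train_hits <- function(fx, train_ids) {
  fx$hits[fx$hits$query_id %in% train_ids &
            fx$hits$target_id %in% train_ids, ]
}

query_hits <- function(fx, test_ids, train_ids) {
  fx$hits[fx$hits$query_id %in% test_ids &
            fx$hits$target_id %in% train_ids, ]
}

fm_default <- build_feature_matrix(fx_default$hits, fx_default$sequences$id)

fit_small <- seqembed(
  fm_default, fx_default$hits,
  config = seqembed_control(
    d = 6, lr = 0.05, epochs = 4, tuples_per_epoch = 500, seed = 3
  )
)

# random labeled ranking for ROC oracle tests
random_classes <- function(n, p_pos = 0.3, p_ign = 0.1) {
  sample(
    c("positive", "negative", "ignore"), n,
    replace = TRUE, prob = c(p_pos, 1 - p_pos - p_ign, p_ign)
  )
}

# exhaustive pair-counting oracle for the truncated ROC score
roc_n_oracle <- function(classes, n_cap) {
  cls <- classes[classes != "ignore"]
  pos <- which(cls == "positive")
  neg <- which(cls == "negative")
  if (length(pos) == 0L) {
    return(NA_real_)
  }
  counted_neg <- utils::head(neg, n_cap)
  hits <- 0L
  for (i in pos) {
    for (j in counted_neg) {
      if (i < j) hits <- hits + 1L
    }
  }
  hits / (n_cap * length(pos))
}
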