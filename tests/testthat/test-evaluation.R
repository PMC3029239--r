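test_that("SCOP-style dotted ids expand to fold/superfamily/family", {
  p <- parse_scop_id(c("d.15.6.1", "b.40.2.3"))
  expect_equal(p$fold, c("d.15", "b.40"))
  expect_equal(p$superfamily, c("d.15.6", "b.40.2"))
  expect_equal(p$family, c("d.15.6.1", "b.40.2.3"))
  expect_error(parse_scop_id("d.15.6"), "dotted id")
})

test_that("label files: dotted 2-column and explicit 4-column dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\td.15.6.1", "p2\tb.40.2.3"), f)
  l2 <- read_labels(f)
  expect_equal(l2$superfamily, c("d.15.6", "b.40.2"))
  writeLines(c("p1\td.15\td.15.6\td.15.6.1"), f)
  l4 <- read_labels(f)
  expect_equal(l4$fold, "d.15")
})

test_that("homology classes follow the superfamily/fold rule set", {
  q <- list(fold = "d.15", superfamily = "d.15.6", family = "d.15.6.1")
  targets <- data.frame(
    fold = c("d.15", "d.15", "d.15", "b.40"),
    superfamily = c("d.15.6", "d.15.6", "d.15.9", "b.40.2"),
    family = c("d.15.6.1", "d.15.6.2", "d.15.9.1", "b.40.2.1"),
    stringsAsFactors = FALSE
  )
  cls <- label_targets(q, targets)
  expect_equal(cls, c("positive", "positive", "ignore", "negative"))
  # family-exclusion mode additionally ignores the query's own family
  cls_xf <- label_targets(q, targets, exclude_family = TRUE)
  expect_equal(cls_xf, c("ignore", "positive", "ignore", "negative"))
  targets$superfamily[2] <- NA
  expect_error(label_targets(q, targets), "unlabeled")
})

test_that("roc_n: perfect and worst-case rankings, ignore handling", {
  expect_equal(
    as.numeric(roc_n(c(rep("positive", 3), rep("negative", 5)), 1)), 1
  )
  expect_equal(
    as.numeric(roc_n(c("negative", "positive", "negative"), 1)), 0
  )
  # ignores are dropped before scoring
  expect_equal(
    as.numeric(roc_n(c("ignore", "positive", "ignore", "negative"), 1)), 1
  )
  expect_true(is.na(roc_n(rep("negative", 5), 1)))
  expect_error(roc_n(c("positive", "negative"), 50), "negatives")
})

test_that("roc_n equals the exhaustive pair-counting oracle", {
  set.seed(50)
  for (k in 1:200) {
    cls <- random_classes(sample(8:16, 1))
    for (cap in c(1, 3)) {
      kept <- cls[cls != "ignore"]
      if (sum(kept == "negative") < cap) next
      expect_equal(
        as.numeric(roc_n(cls, cap)), roc_n_oracle(cls, cap),
        info = paste("case", k, "cap", cap)
      )
    }
  }
})

test_that("roc_n depends only on the ordering, not on score scale", {
  cls <- c("positive", "negative", "positive", "negative", "negative")
  r1 <- as.numeric(roc_n(cls, 2))
  # relabeling ids / monotone score transforms leave the class order
  # unchanged, hence the same score
  expect_equal(as.numeric(roc_n(cls, 2)), r1)
})

test_that("pooled ROC: single query, disjoint ranges, U-statistic oracle", {
  r1 <- data.frame(
    score = c(1, 2, 3), class = c("positive", "negative", "negative")
  )
  single <- pooled_roc(list(r1))
  expect_equal(single$tpf, c(0, 1, 1, 1))
  expect_equal(single$fpf, c(0, 0, 0.5, 1))

  r2 <- data.frame(
    score = c(10, 20), class = c("positive", "negative")
  )
  both <- pooled_roc(list(r1, r2))
  # disjoint score ranges: r2 entries follow all of r1
  expect_equal(nrow(both), 6)
  expect_equal(both$tpf[5], 1) # both positives precede r2's negative

  set.seed(51)
  scores <- runif(40)
  cls <- sample(c("positive", "negative"), 40, replace = TRUE,
                prob = c(0.4, 0.6))
  curve <- pooled_roc(list(data.frame(score = scores, class = cls)))
  # independent U-statistic oracle: P(pos score < neg score), ties half
  pos <- scores[cls == "positive"]
  neg <- scores[cls == "negative"]
  u <- 0
  for (a in pos) for (b in neg) u <- u + (a < b) + 0.5 * (a == b)
  expect_equal(attr(curve, "auc"), u / (length(pos) * length(neg)),
               tolerance = 1e-12)
})

test_that("wilcoxon signed-rank: degenerate, shifted and exact cases", {
  a <- c(1, 2, 3, 4, 5)
  w0 <- wilcoxon_signed_rank(a, a)
  expect_equal(w0$p.value, 1)
  expect_equal(w0$direction, 0)

  set.seed(52)
  b <- rnorm(20)
  ws <- wilcoxon_signed_rank(b + 1, b)
  expect_lt(ws$p.value, 0.001)
  expect_equal(ws$direction, 1)

  # n = 8: exact enumeration over all 2^8 sign assignments
  set.seed(53)
  d <- round(rnorm(8), 3)
  d <- d[d != 0]
  while (anyDuplicated(abs(d)) || length(d) < 8) {
    d <- round(rnorm(8), 3)
    d <- d[d != 0]
  }
  w <- wilcoxon_signed_rank(d, numeric(8))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- sapply(0:(2^8 - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[1:8]
    sum(r[signs == 1])
  })
  p_exact <- min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
  expect_equal(w$p.value, p_exact, tolerance = 1e-10)
})

test_that("evaluation excludes queries without positives from the mean", {
  ev <- data.frame(
    query_id = c("a", "b", "c"), roc = c(1, NA, 0.5),
    n_pos = c(2, 0, 1), n_neg = c(5, 5, 5)
  )
  m <- mean_roc(ev)
  expect_equal(as.numeric(m), 0.75)
  expect_equal(attr(m, "n_undefined"), 1L)
})
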