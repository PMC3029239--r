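test_that("Markov null: conditionals normalize; single-symbol corpus", {
  m <- fit_markov_null(strrep("A", 300), order = 3, pseudocount = 0.01)
  expect_true(all(abs(rowSums(m$trans) - 1) < 1e-9))
  expect_gt(m$trans[1, 1], 0.99) # P(A | AAA) up to pseudocount mass
  expect_true(all(m$trans > 0)) # pseudocount keeps support full
  expect_error(fit_markov_null(character(0)), "no training sequences")
})

test_that("Markov null on uniform corpus: conditionals near 1/20", {
  set.seed(40)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- replicate(
    60, paste0(sample(aa, 500, replace = TRUE), collapse = "")
  )
  m <- fit_markov_null(seqs, order = 1, pseudocount = 1)
  counts_per_ctx <- (60 * 499) / 20
  band <- 3 * sqrt((1 / 20) * (19 / 20) / counts_per_ctx)
  expect_true(all(abs(m$trans - 1 / 20) < band + 0.01))
})

test_that("decoy generation: deterministic chain, seeding, empty call", {
  expect_equal(nrow(generate_decoys(
    fit_markov_null("AAAA", order = 2), 10, 0
  )), 0L)

  # hand-built chain that always emits A
  m <- structure(
    list(
      order = 2L,
      trans = matrix(rep(c(1, rep(0, 19)), each = 400), 400, 20),
      init = replace(numeric(400), 1, 1),
      alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
      pseudocount = 0
    ),
    class = "markov_null"
  )
  d <- generate_decoys(m, 8, 3, seed = 1)
  expect_equal(d$sequence, rep("AAAAAAAA", 3))

  mk <- fit_markov_null(fx_default$sequences, order = 3)
  d1 <- generate_decoys(mk, 50, 20, seed = 7)
  d2 <- generate_decoys(mk, 50, 20, seed = 7)
  expect_identical(d1, d2)
})

test_that("decoys reproduce the residue statistics of the fitted model", {
  set.seed(41)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # biased corpus: A-rich
  seqs <- replicate(40, paste0(
    sample(aa, 400, replace = TRUE, prob = c(8, rep(1, 19))),
    collapse = ""
  ))
  mk <- fit_markov_null(seqs, order = 1, pseudocount = 0.01)
  dec <- generate_decoys(mk, 200, 300, seed = 8)
  chars <- unlist(strsplit(dec$sequence, ""))
  pA <- mean(chars == "A")
  p_true <- 8 / 27
  band <- 3 * sqrt(p_true * (1 - p_true) / length(chars)) + 0.02
  expect_lt(abs(pA - p_true), band)
})

test_that("decoy scores are best-hit distances (scan oracle, zero rows)", {
  dfeat <- Matrix::sparseMatrix(
    i = c(1, 1), j = c(2, 5), x = c(0.4, 0.6),
    dims = c(3, length(fit_small$ids)),
    dimnames = list(c("d1", "d2", "d3"), fit_small$ids)
  )
  # d2 duplicates a database feature row: its embedding coincides
  dfeat[2, ] <- fm_default$matrix[4, ]
  sc <- decoy_scores(fit_small, dfeat)
  expect_equal(sc[2], 0, tolerance = 1e-9)
  expect_true(attr(sc, "no_hits")[3])
  # brute-force scan oracle
  pts <- embed_features(fit_small, dfeat)
  for (k in 1:3) {
    brute <- min(colSums(abs(fit_small$db_points - pts[, k])))
    expect_equal(unname(sc[k]), brute, tolerance = 1e-9)
  }
  # all-zero decoy: distance is the smallest database point norm
  expect_equal(
    unname(sc[3]), min(colSums(abs(fit_small$db_points))),
    tolerance = 1e-9
  )
})

test_that("Weibull left-tail fit recovers simulated parameters", {
  set.seed(42)
  samp <- rweibull(5000, 1.5, 2.0)
  f <- fit_weibull_left_tail(samp, tail_fraction = 1.0)
  expect_lt(abs(f$shape - 1.5) / 1.5, 0.1)
  expect_lt(abs(f$scale - 2.0) / 2.0, 0.1)

  set.seed(43)
  fe <- fit_weibull_left_tail(rexp(3000), tail_fraction = 1.0)
  expect_lt(abs(fe$shape - 1), 0.1) # exponential is Weibull shape 1

  expect_error(fit_weibull_left_tail(rep(1, 500)), "degenerate")
  expect_error(fit_weibull_left_tail(rweibull(100, 1, 1)), "at least 200")
})

test_that("tail-restricted and full fits agree in the extreme left tail", {
  set.seed(44)
  samp <- rweibull(5000, 1.3, 3.0)
  fa <- fit_weibull_left_tail(samp, tail_fraction = 1.0)
  fb <- fit_weibull_left_tail(samp, tail_fraction = 0.25)
  q1 <- quantile(samp, 0.01)
  ca <- pweibull(max(q1 - fa$location, 0), fa$shape, fa$scale)
  cb <- pweibull(max(q1 - fb$location, 0), fb$shape, fb$scale)
  expect_lt(max(ca, cb) / min(ca, cb), 2)
})

test_that("p-values: boundary values and monotonicity", {
  mk <- fit_markov_null(fx_default$sequences, order = 3)
  teacher <- make_decoy_teacher(fit_small$ids, fx_default$config$teacher)
  cal <- calibrate_null(
    fit_small, mk, teacher,
    length_range = c(80, 84), n_decoys = 300, seed = 6
  )
  expect_equal(distance_pvalue(0, cal, 82), 0)
  big <- max(cal$samples[[1]]) * 10
  expect_equal(distance_pvalue(big, cal, 82), 1)
  ds <- seq(0, big, length.out = 50)
  ps <- distance_pvalue(ds, cal, 82)
  expect_true(all(diff(ps) >= -1e-12))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_warning(distance_pvalue(1, cal, 500), "nearest bin")
})

test_that("Storey pi0: uniform, clamped and mixture cases", {
  set.seed(45)
  expect_lt(abs(estimate_pi0(runif(10000)) - 1), 0.05)
  expect_equal(estimate_pi0(rep(0.01, 50)), 1 / 50) # clamp branch
  mix <- c(runif(5000), rbeta(5000, 0.05, 20))
  expect_lt(abs(estimate_pi0(mix) - 0.5), 0.1)
})

test_that("q-values reproduce the pi0-adjusted BH step-up", {
  expect_equal(qvalues(0.01, pi0 = 1), 0.01)
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # exhaustive definition oracle: q_i = min over p_j >= p_i of pi0*m*p_j/r_j
  set.seed(46)
  for (k in 1:10) {
    p <- runif(12)
    pi0 <- runif(1, 0.2, 1)
    q <- qvalues(p, pi0)
    m <- length(p)
    r <- rank(p, ties.method = "first")
    oracle <- sapply(seq_len(m), function(i) {
      min(1, min(pi0 * m * p[p >= p[i]] / r[p >= p[i]]))
    })
    expect_equal(q, oracle, tolerance = 1e-12)
    expect_true(all(q >= pi0 * p - 1e-12))
    # monotone along sorted p, invariant to input order
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    perm <- sample(m)
    expect_equal(qvalues(p[perm], pi0), q[perm])
  }
  # when pi0 = 1 the step-up equals the standard BH adjustment
  set.seed(47)
  p <- runif(30)
  expect_equal(qvalues(p, 1), p.adjust(p, "BH"))
})

test_that("significance columns join the ranking and keep its order", {
  mk <- fit_markov_null(fx_default$sequences, order = 3)
  teacher <- make_decoy_teacher(fit_small$ids, fx_default$config$teacher)
  cal <- calibrate_null(
    fit_small, mk, teacher,
    length_range = c(80, 84), n_decoys = 300, seed = 6
  )
  qf <- fm_default$matrix[5, , drop = FALSE]
  rk <- predict(fit_small, qf, type = "ranking")
  rk2 <- add_significance(rk, cal, query_length = 82)
  expect_equal(rk2$target_id, rk$target_id)
  expect_true(all(diff(rk2$p) >= -1e-12)) # p monotone in distance
  expect_true(all(rk2$q >= rk2$p * attr(rk2, "pi0") - 1e-12))
})
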