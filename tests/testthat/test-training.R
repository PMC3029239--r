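test_that("positive sets use a strict E-value threshold and exclude self", {
  hits <- data.frame(
    query_id = c("a", "a", "a", "b"),
    target_id = c("b", "c", "a", "a"),
    evalue = c(0.01, 0.1, 0, 0.09),
    stringsAsFactors = FALSE
  )
  ps <- positive_sets(hits, c("a", "b", "c"), threshold = 0.1)
  expect_equal(ps$pos[[1]], 2L) # E = 0.1 exactly is NOT a positive
  expect_equal(ps$pos[[2]], 1L)
  expect_equal(ps$queries, c(1L, 2L))
})

test_that("sample_tuple: forced choice and uniform positive frequencies", {
  hits <- data.frame(
    query_id = "a", target_id = "b", evalue = 0.01,
    stringsAsFactors = FALSE
  )
  ps <- positive_sets(hits, c("a", "b", "c"))
  set.seed(30)
  for (k in 1:50) {
    t <- sample_tuple(ps)
    expect_equal(unname(t[1:2]), c(1L, 2L))
    expect_true(t[3] == 3L) # only non-degenerate negative available
  }

  hits3 <- data.frame(
    query_id = rep("a", 3), target_id = c("b", "c", "d"),
    evalue = rep(0.001, 3), stringsAsFactors = FALSE
  )
  ps3 <- positive_sets(hits3, c("a", "b", "c", "d", "e"))
  set.seed(31)
  draws <- replicate(9000, sample_tuple(ps3)[2])
  freq <- table(draws) / 9000
  # binomial 3-sigma band around 1/3
  band <- 3 * sqrt((1 / 3) * (2 / 3) / 9000)
  expect_true(all(abs(freq - 1 / 3) < band))

  none <- positive_sets(hits[0, ], c("a", "b"))
  expect_error(sample_tuple(none), "no training signal")
})

test_that("tuple margin loss is the hinge of the two distances", {
  # geometry engineered so D(q,pos) = 0 and D(q,neg) = 2
  W <- rbind(c(1, 1, 0), c(0, 0, 2))
  F <- diag(3)
  expect_equal(tuple_margin_loss(W, c(1, 2, 3), F, margin = 1), 0)
  # equal distances: loss = margin
  expect_equal(
    tuple_margin_loss(diag(2), c(1, 2, 2), diag(2), margin = 0.7), 0.7
  )
  # two-path check against an independent hinge computation
  set.seed(32)
  for (k in 1:20) {
    n <- 8
    d <- 3
    W <- matrix(rnorm(d * n), d, n)
    F <- matrix(rexp(3 * n) * rbinom(3 * n, 1, 0.5), 3, n)
    phi <- W %*% t(F)
    expected <- max(
      0, 1 + sum(abs(phi[, 1] - phi[, 2])) - sum(abs(phi[, 1] - phi[, 3]))
    )
    expect_equal(
      tuple_margin_loss(W, c(1, 2, 3), F, margin = 1), expected,
      tolerance = 1e-12
    )
  }
})

test_that("sgd_step: no-op at zero loss, strict descent at small lr", {
  W <- rbind(c(1, 1, 0), c(0, 0, 2))
  F <- diag(3)
  W2 <- sgd_step(W, c(1, 2, 3), F, lr = 0.1, margin = 1)
  expect_identical(unclass(W2)[, ], W[, ]) # bitwise unchanged

  set.seed(33)
  for (k in 1:10) {
    n <- 10
    W <- matrix(rnorm(3 * n), 3, n)
    F <- matrix(rexp(3 * n) * rbinom(3 * n, 1, 0.6), 3, n)
    l0 <- tuple_margin_loss(W, c(1, 2, 3), F)
    if (l0 <= 0) next
    Wn <- sgd_step(W, c(1, 2, 3), F, lr = 1e-3)
    expect_lt(tuple_margin_loss(Wn, c(1, 2, 3), F), l0)
  }
})

test_that("class task is a no-op when the pair shares fold and superfamily", {
  set.seed(34)
  n <- 8
  d <- 3
  W <- matrix(rnorm(d * n), d, n)
  C <- matrix(rnorm(d * 5), d, 5)
  f <- rexp(n)
  st <- class_task_step(W, C, f, bits = c(1, 3), bits_other = c(1, 3),
                        lr = 0.5)
  expect_equal(st$loss, 1) # margin slack remains
  expect_equal(st$W, W, tolerance = 1e-14) # gradients cancel
  expect_equal(st$C, C, tolerance = 1e-14)
})

test_that("class-centroid training separates two synthetic classes", {
  set.seed(35)
  n <- 20
  d <- 4
  # two blocks of proteins with block-structured features
  F <- matrix(0, n, n)
  for (i in 1:10) F[i, 1:10] <- rexp(10)
  for (i in 11:20) F[i, 11:20] <- rexp(10)
  F <- F / rowSums(F)
  W <- matrix(rnorm(d * n), d, n)
  C <- matrix(rnorm(d * 4), d, 4) # folds 1,2 then superfamilies 3,4
  bits <- function(i) if (i <= 10) c(1, 3) else c(2, 4)
  for (step in 1:200) {
    i <- sample.int(n, 1)
    j <- sample.int(n, 1)
    st <- class_task_step(W, C, F[i, ], bits(i), bits(j), lr = 0.05)
    W <- st$W
    C <- st$C
  }
  emb <- W %*% t(F)
  own <- sapply(1:n, function(i) {
    sum(abs(emb[, i] - rowSums(C[, bits(i)])))
  })
  other <- sapply(1:n, function(i) {
    sum(abs(emb[, i] - rowSums(C[, bits(if (i <= 10) 11 else 1)])))
  })
  expect_lt(mean(own), mean(other))
})

test_that("auxiliary pairs: strict structural cutoff and label symmetry", {
  ids <- c("a", "b", "c", "d")
  labels <- data.frame(
    id = ids, fold = c("x.1", "x.1", "x.1", "y.2"),
    superfamily = c("x.1.1", "x.1.1", "x.1.2", "y.2.1"),
    family = paste0(ids, ".f"), stringsAsFactors = FALSE
  )
  struct <- data.frame(
    id_a = c("a", "a", "a"), id_b = c("b", "c", "d"),
    score = c(2.5, 1.0, 2.0), stringsAsFactors = FALSE
  )
  aux <- auxiliary_pairs(ids, labels, struct, cutoff = 2.0, mode = "struct")
  # only (a,b) is above the cutoff; score exactly 2.0 is excluded
  expect_equal(nrow(aux$pairs), 2L)
  expect_setequal(aux$pairs[, 1], c(1L, 2L))

  auxl <- auxiliary_pairs(ids, labels, mode = "label")
  expect_true(any(auxl$pairs[, 1] == 1 & auxl$pairs[, 2] == 2))
  expect_true(any(auxl$pairs[, 1] == 2 & auxl$pairs[, 2] == 1))

  lone <- labels[4, , drop = FALSE]
  expect_error(
    auxiliary_pairs("d", lone, mode = "label"),
    "no qualifying"
  )
})

test_that("epochs = 0 returns the seeded random initialization", {
  cfg <- seqembed_control(d = 5, epochs = 0, seed = 99)
  fit <- seqembed(fm_default, fx_default$hits, config = cfg)
  set.seed(99)
  expected <- matrix(rnorm(5 * length(fit$ids)), 5)
  expect_equal(unname(fit$W), expected)
  expect_equal(nrow(fit$trace), 0L)
})

test_that("identical seed and config give bitwise-identical models", {
  cfg <- seqembed_control(d = 4, epochs = 2, tuples_per_epoch = 300,
                          seed = 17)
  f1 <- seqembed(fm_default, fx_default$hits, config = cfg)
  f2 <- seqembed(fm_default, fx_default$hits, config = cfg)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$db_points, f2$db_points)
})

test_that("epoch-averaged training loss decreases (smoothed trend)", {
  cfg <- seqembed_control(d = 8, epochs = 15, tuples_per_epoch = 1000,
                          seed = 5)
  fit <- seqembed(fm_default, fx_default$hits, config = cfg)
  tr <- fit$trace$mean_loss
  smooth <- stats::filter(tr, rep(1 / 5, 5), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  # non-increasing after window-5 smoothing, allowing 5% stochastic upticks
  expect_true(all(diff(smooth) <= 0.05 * smooth[-length(smooth)]))
  expect_lt(tail(smooth, 1), smooth[1])
})

test_that("fit object methods: print, summary, coef, predict, save/load", {
  expect_output(print(fit_small), "Semantic embedding")
  expect_output(print(summary(fit_small)), "loss trace")
  expect_equal(dim(coef(fit_small)), c(6L, 96L))

  qf <- fm_default$matrix[1:2, , drop = FALSE]
  pts <- predict(fit_small, qf, type = "embedding")
  expect_equal(dim(pts), c(6L, 2L))
  rk <- predict(fit_small, qf[1, , drop = FALSE], type = "ranking")
  expect_s3_class(rk, "ranked_result")
  expect_equal(rk$target_id[1], rownames(qf)[1]) # self-retrieval

  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fit_small, f)
  back <- load_model(f)
  expect_identical(back$W, fit_small$W)
  expect_identical(back$config, fit_small$config)
})
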