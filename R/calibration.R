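# Statistical calibration of embedding distances: an empirical null from
# third-order Markov decoy sequences, a Weibull fit to its left tail, and
# pi0-adjusted Benjamini-Hochberg q-values.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# Non-standard residue codes mapped to a uniform draw among their standard
# expansions (keeps the alphabet at the 20 standard residues).
.ambiguity_map <- list(
  B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"),
  U = "C", O = "K", X = NULL # X -> uniform over all 20
)

# Replace non-standard residues; uses the current RNG state.
.map_nonstandard <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  bad <- which(!(chars %in% .aa_alphabet))
  for (k in bad) {
    exp <- .ambiguity_map[[chars[[k]]]]
    if (is.null(exp)) exp <- .aa_alphabet
    chars[[k]] <- exp[[sample.int(length(exp), 1L)]]
  }
  paste0(chars, collapse = "")
}

#' Fit a k-th order Markov null model of protein sequences
#'
#' Estimates transition probabilities over amino-acid (k+1)-mers by maximum
#' likelihood with an additive pseudocount, together with an initial
#' distribution over k-mers (all observed k-mer windows). Non-standard
#' residue codes (B, Z, J, U, O, X) are mapped to a uniform choice among
#' their standard expansions before counting.
#'
#' @param sequences Character vector of amino-acid sequences, or a sequence
#'   data frame with a `sequence` column.
#' @param order Markov order (default 3: the next residue depends on the
#'   previous three).
#' @param pseudocount Additive smoothing count (> 0 keeps every transition
#'   probability positive).
#' @param seed Optional seed for the ambiguity-code mapping.
#' @return Object of class `"markov_null"`: transition matrix
#'   (20^order x 20), initial k-mer distribution, order and alphabet.
#' @export
fit_markov_null <- function(sequences, order = 3L, pseudocount = 1,
                            seed = NULL) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (length(sequences) == 0L) stop("no training sequences")
  stopifnot(order >= 1L, pseudocount >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_ctx <- 20L^order
  trans_counts <- numeric(n_ctx * 20L)
  init_counts <- numeric(n_ctx)
  pow <- 20L^((order - 1L):0L)
  for (s in sequences) {
    if (any(!(strsplit(s, "")[[1L]] %in% .aa_alphabet))) {
      s <- .map_nonstandard(s)
    }
    v <- match(strsplit(s, "")[[1L]], .aa_alphabet)
    L <- length(v)
    if (L < order) next
    # context code in 0 .. 20^order - 1 for every k-mer window
    nwin <- L - order + 1L
    ctx <- numeric(nwin)
    for (k in seq_len(order)) {
      ctx <- ctx + (v[k:(k + nwin - 1L)] - 1) * pow[[k]]
    }
    init_counts <- init_counts + tabulate(ctx + 1, nbins = n_ctx)
    if (L > order) {
      tctx <- ctx[seq_len(L - order)]
      nxt <- v[(order + 1L):L]
      code <- tctx * 20 + (nxt - 1) + 1
      trans_counts <- trans_counts + tabulate(code, nbins = n_ctx * 20L)
    }
  }
  tc <- matrix(trans_counts, nrow = n_ctx, ncol = 20L, byrow = TRUE) +
    pseudocount
  trans <- tc / rowSums(tc)
  init <- (init_counts + pseudocount) / sum(init_counts + pseudocount)
  structure(
    list(order = as.integer(order), trans = trans, init = init,
         alphabet = .aa_alphabet, pseudocount = pseudocount),
    class = "markov_null"
  )
}

#' @export
print.markov_null <- function(x, ...) {
  cat(
    "Markov null model of order ", x$order, " over ", length(x$alphabet),
    " residues (pseudocount ", x$pseudocount, ")\n",
    sep = ""
  )
  invisible(x)
}

# decode a context code into residue indices (most significant first)
.decode_ctx <- function(code, order) {
  out <- integer(order)
  for (k in order:1) {
    out[[k]] <- code %% 20L + 1L
    code <- code %/% 20L
  }
  out
}

#' Generate decoy sequences from a Markov null model
#'
#' Samples `n` sequences of exactly `length` residues: an initial k-mer from
#' the model's k-mer distribution, then one residue at a time from the
#' transition distribution. Deterministic under `seed`.
#'
#' @param model A `"markov_null"` model.
#' @param length Sequence length (>= model order).
#' @param n Number of decoys.
#' @param seed Optional seed.
#' @param prefix Identifier prefix for the generated records.
#' @return Sequence data frame (`id`, `sequence`, `length`).
#' @export
generate_decoys <- function(model, length, n, seed = NULL,
                            prefix = "decoy") {
  stopifnot(inherits(model, "markov_null"))
  if (n == 0L) {
    return(data.frame(
      id = character(0), sequence = character(0), length = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  if (length < model$order) stop("length must be >= the model order")
  if (!is.null(seed)) set.seed(seed)
  order <- model$order
  cum_init <- cumsum(model$init)
  cum_trans <- t(apply(model$trans, 1L, cumsum))
  base <- 20L^(order - 1L)
  seqs <- vapply(seq_len(n), function(k) {
    ctx_code <- findInterval(stats::runif(1L), cum_init,
                             rightmost.closed = TRUE)
    v <- integer(length)
    v[seq_len(order)] <- .decode_ctx(ctx_code, order)
    if (length > order) {
      for (pos in (order + 1L):length) {
        nxt <- findInterval(stats::runif(1L), cum_trans[ctx_code + 1L, ]) + 1L
        if (nxt > 20L) nxt <- 20L
        v[[pos]] <- nxt
        ctx_code <- (ctx_code %% base) * 20L + (nxt - 1L)
      }
    }
    paste0(model$alphabet[v], collapse = "")
  }, character(1))
  data.frame(
    id = sprintf("%s%05d", prefix, seq_len(n)),
    sequence = seqs, length = nchar(seqs),
    stringsAsFactors = FALSE
  )
}

#' Null retrieval scores of decoy queries
#'
#' Embeds each decoy's feature vector and returns its distance to the
#' nearest database point — the best-hit score that retrieval thresholds.
#' Decoys with no teacher hits have an all-zero feature vector; their
#' distance is still computed and the rows are flagged in the
#' `"no_hits"` attribute.
#'
#' @param model A `"seqembed"` fit.
#' @param decoy_features Sparse matrix of decoy feature rows (see
#'   [query_features()]).
#' @return Numeric vector of best-hit distances, one per decoy, with
#'   attribute `"no_hits"` (logical).
#' @export
decoy_scores <- function(model, decoy_features) {
  pts <- embed_features(model, decoy_features)
  no_hits <- Matrix::rowSums(decoy_features != 0) == 0
  p <- model$config$p
  d <- vapply(seq_len(ncol(pts)), function(k) {
    min(.distances_to_db(pts[, k], model$db_points, p))
  }, numeric(1))
  attr(d, "no_hits") <- as.logical(no_hits)
  d
}

#' Fit a Weibull distribution to the left tail of null scores
#'
#' Maximum-likelihood Weibull fit to the lowest `tail_fraction` of the
#' samples, treating the remaining samples as right-censored at the tail
#' threshold, so the fitted distribution approximates the left tail of the
#' null score distribution (the region where small distances are called
#' significant). Null retrieval scores are minima over the database, so
#' their support is bounded away from zero; an optional location
#' parameter, profiled by maximum likelihood over `[0, min(samples))`,
#' accounts for that shift. With `tail_fraction = 1` this is a plain
#' (uncensored) MLE on the full sample.
#'
#' @param samples Numeric null scores (>= 200 values).
#' @param tail_fraction Fraction of the smallest samples observed
#'   uncensored (in (0, 1]).
#' @param location Profile a location (shift) parameter; `FALSE` fixes it
#'   at 0.
#' @return List with `shape`, `scale`, `location`, `threshold` (censoring
#'   point), `n`, `n_tail` and `tail_fraction`.
#' @export
fit_weibull_left_tail <- function(samples, tail_fraction = 0.25,
                                  location = TRUE) {
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 200L) {
    stop("need at least 200 null samples, got ", n)
  }
  if (max(samples) - min(samples) < .Machine$double.eps) {
    stop("degenerate null samples: all values equal")
  }
  xs <- sort(samples)
  k <- ceiling(tail_fraction * n)
  thr <- xs[[k]]
  if (thr <= min(xs)) stop("tail threshold collapses onto the minimum")

  fit_at <- function(loc) {
    if (tail_fraction >= 1) {
      y <- samples - loc
      y <- y[y > 0]
      tryCatch(fitdistrplus::fitdist(y, "weibull"), error = function(e) NULL)
    } else {
      d <- data.frame(
        left = pmin(samples, thr) - loc,
        right = ifelse(samples <= thr, samples - loc, NA_real_)
      )
      d <- d[d$left > 0, , drop = FALSE]
      # moment start from the observed (uncensored) tail
      obs <- samples[samples <= thr] - loc
      start <- list(
        shape = 1.2,
        scale = max(mean(obs), .Machine$double.eps)
      )
      tryCatch(
        suppressWarnings(
          fitdistrplus::fitdistcens(d, "weibull", start = start)
        ),
        error = function(e) NULL
      )
    }
  }
  loc <- 0
  if (location && min(xs) > 0) {
    obj <- function(l) {
      f <- fit_at(l)
      if (is.null(f) || !is.finite(f$loglik)) 1e300 else -f$loglik
    }
    loc <- stats::optimize(obj, c(0, min(xs) * 0.999))$minimum
  }
  fit <- fit_at(loc)
  if (is.null(fit)) {
    loc <- 0
    fit <- fit_at(0)
  }
  if (is.null(fit)) stop("Weibull fit failed")
  est <- fit$estimate
  if (est[["shape"]] <= 0 || est[["scale"]] <= 0) {
    stop("Weibull fit returned non-positive parameters")
  }
  list(
    shape = unname(est[["shape"]]), scale = unname(est[["scale"]]),
    location = loc, threshold = thr,
    n = n, n_tail = k, tail_fraction = tail_fraction
  )
}

# geometric length-bin edges: 25, 25*1.5, 25*1.5^2, ... covering `range`
.length_bins <- function(range, start = 25, factor = 1.5) {
  edges <- start
  while (utils::tail(edges, 1) < range[[2L]]) {
    edges <- c(edges, utils::tail(edges, 1) * factor)
  }
  lo <- utils::head(edges, -1L)
  hi <- utils::tail(edges, -1L)
  keep <- hi > range[[1L]] & lo < range[[2L]]
  data.frame(min_len = lo[keep], max_len = hi[keep])
}

#' Calibrate the retrieval null for a fitted embedding
#'
#' Builds a length-conditioned empirical null: for each geometric length
#' bin, decoy sequences are generated from the Markov null model, scored
#' against the database through the teacher, embedded, and their best-hit
#' distances fitted with a left-tail Weibull. P-values of real queries are
#' later read from the bin covering the query length.
#'
#' @param model A `"seqembed"` fit.
#' @param markov A `"markov_null"` model (see [fit_markov_null()]).
#' @param teacher A function taking a decoy sequence data frame and
#'   returning a teacher hits data frame (query_id, target_id, evalue)
#'   against the model's database.
#' @param length_range Query-length range to cover, `c(min, max)`.
#' @param n_decoys Decoys generated per length bin.
#' @param tail_fraction Passed to [fit_weibull_left_tail()].
#' @param bin_start,bin_factor Geometric binning: edges
#'   `bin_start * bin_factor^k`.
#' @param seed Seed for decoy generation and teacher noise.
#' @return Object of class `"null_calibration"`: per-bin decoy scores and
#'   Weibull parameters, plus the configuration used.
#' @export
calibrate_null <- function(model, markov, teacher,
                           length_range = c(25, 200), n_decoys = 1000L,
                           tail_fraction = 0.25, bin_start = 25,
                           bin_factor = 1.5, seed = 1L) {
  stopifnot(inherits(model, "seqembed"), inherits(markov, "markov_null"))
  set.seed(seed)
  bins <- .length_bins(length_range, bin_start, bin_factor)
  samples <- vector("list", nrow(bins))
  fits <- vector("list", nrow(bins))
  for (b in seq_len(nrow(bins))) {
    lo <- max(ceiling(bins$min_len[[b]]), markov$order + 1L)
    hi <- max(lo, floor(bins$max_len[[b]] - 1e-9))
    lens <- lo + sample.int(hi - lo + 1L, n_decoys, replace = TRUE) - 1L
    tab <- table(lens)
    decoys <- do.call(rbind, lapply(seq_along(tab), function(k) {
      generate_decoys(
        markov, as.integer(names(tab)[[k]]), as.integer(tab[[k]]),
        prefix = sprintf("decoy_b%d_l%s_", b, names(tab)[[k]])
      )
    }))
    hits <- teacher(decoys)
    feats <- query_features(
      hits, decoys$id, model$ids,
      sigma = model$sigma, normalize = model$normalized
    )
    sc <- decoy_scores(model, feats)
    samples[[b]] <- sort(as.numeric(sc))
    fits[[b]] <- fit_weibull_left_tail(sc, tail_fraction)
  }
  bins$shape <- vapply(fits, `[[`, numeric(1), "shape")
  bins$scale <- vapply(fits, `[[`, numeric(1), "scale")
  bins$location <- vapply(fits, `[[`, numeric(1), "location")
  bins$threshold <- vapply(fits, `[[`, numeric(1), "threshold")
  bins$n <- vapply(samples, length, integer(1))
  structure(
    list(
      bins = bins, samples = samples, tail_fraction = tail_fraction,
      n_decoys = n_decoys, seed = seed
    ),
    class = "null_calibration"
  )
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(
    "Length-binned null calibration: ", nrow(x$bins), " bins, ",
    x$n_decoys, " decoys/bin, Weibull left-tail fraction ",
    x$tail_fraction, "\n",
    sep = ""
  )
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' P-value of an embedding distance
#'
#' The probability that a null (decoy) best-hit score is at most the
#' observed distance, read from the length bin covering the query (the
#' nearest bin is used, with a warning, for lengths outside all bins).
#' Below the tail threshold — the significant region — the p-value comes
#' from the fitted Weibull left tail; above it, from the linearly
#' interpolated empirical null distribution, which the Weibull tail
#' continues smoothly. P-values are 0 at distance 0 and approach 1 for
#' distances beyond every null sample.
#'
#' @param distance Observed distance(s).
#' @param calibration A `"null_calibration"`.
#' @param query_length Residue length of the query sequence.
#' @return P-value(s) in `[0, 1]`.
#' @export
distance_pvalue <- function(distance, calibration, query_length) {
  bins <- calibration$bins
  b <- which(query_length >= bins$min_len & query_length < bins$max_len)
  if (length(b) == 0L) {
    mid <- (bins$min_len + bins$max_len) / 2
    b <- which.min(abs(mid - query_length))
    warning(
      "query length ", query_length,
      " outside calibrated bins; using nearest bin"
    )
  }
  b <- b[[1L]]
  shape <- bins$shape[[b]]
  scale <- bins$scale[[b]]
  loc <- bins$location[[b]]
  thr <- bins$threshold[[b]]
  xs <- calibration$samples[[b]]
  n <- length(xs)
  f_thr <- stats::pweibull(max(thr - loc, 0), shape, scale)

  p <- stats::pweibull(pmax(distance - loc, 0), shape, scale)
  above <- which(distance > thr)
  if (length(above)) {
    # conditional empirical CDF above the censoring point, linearly
    # interpolated between order statistics; 1 beyond the largest sample
    xa <- xs[xs > thr]
    grid_x <- c(thr, xa)
    grid_p <- c(f_thr, f_thr + (1 - f_thr) * seq_along(xa) / length(xa))
    p[above] <- stats::approx(
      grid_x, grid_p,
      xout = distance[above], rule = 2L, ties = "ordered"
    )$y
  }
  pmin(pmax(p, 0), 1)
}

#' Storey estimate of the null proportion
#'
#' `pi0 = #{p > lambda} / ((1 - lambda) m)`, the single-lambda Storey
#' estimator, clamped to `(1/m, 1]`.
#'
#' @param pvalues Numeric p-values.
#' @param lambda Tuning threshold (default 0.5).
#' @return Estimated proportion of null tests.
#' @export
estimate_pi0 <- function(pvalues, lambda = 0.5) {
  m <- length(pvalues)
  if (m == 0L) stop("no p-values")
  pi0 <- sum(pvalues > lambda) / ((1 - lambda) * m)
  min(1, max(1 / m, pi0))
}

#' Q-values by pi0-adjusted Benjamini-Hochberg
#'
#' `q_i = min over {j : p_j >= p_i} of (pi0 * m * p_j / rank_j)`, clamped to
#' at most 1: the minimum FDR threshold at which test i is called
#' significant, including the pi0 multiplicative factor.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param pi0 Null proportion multiplier (see [estimate_pi0()]).
#' @return Q-values in the input order.
#' @export
qvalues <- function(pvalues, pi0 = 1) {
  m <- length(pvalues)
  if (m == 0L) {
    return(numeric(0))
  }
  stopifnot(all(pvalues >= 0 & pvalues <= 1), pi0 > 0, pi0 <= 1)
  o <- order(pvalues)
  q <- pi0 * m * pvalues[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Attach significance estimates to a ranked result
#'
#' Adds per-target p-values (length-binned Weibull null) and q-values
#' (pi0-adjusted Benjamini-Hochberg) to a ranking.
#'
#' @param ranking A `"ranked_result"` data frame.
#' @param calibration A `"null_calibration"`.
#' @param query_length Residue length of the query.
#' @param lambda Storey lambda for [estimate_pi0()].
#' @return The ranking with `p` and `q` columns; the pi0 estimate is
#'   attached as attribute `"pi0"`.
#' @export
add_significance <- function(ranking, calibration, query_length,
                             lambda = 0.5) {
  p <- distance_pvalue(ranking$distance, calibration, query_length)
  pi0 <- estimate_pi0(p, lambda)
  ranking$p <- p
  ranking$q <- qvalues(p, pi0)
  attr(ranking, "pi0") <- pi0
  ranking
}

#' Save / load a null calibration
#'
#' @param calibration A `"null_calibration"`.
#' @param path File path.
#' @export
save_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "null_calibration"))
  saveRDS(calibration, path)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  cal <- readRDS(path)
  if (!inherits(cal, "null_calibration")) stop("not a calibration file")
  cal
}
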