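# Ranking evaluation against structural category labels: truncated ROC
# scores per query, pooled ROC curves across queries, and paired Wilcoxon
# comparison of methods.

#' Parse SCOP-style dotted identifiers
#'
#' A dotted identifier `class.fold.superfamily.family` (e.g. `d.15.6.1`)
#' expands to fold `d.15`, superfamily `d.15.6` and family `d.15.6.1`.
#'
#' @param x Character vector of 4-part dotted identifiers.
#' @return Data frame with columns `fold`, `superfamily`, `family`.
#' @export
parse_scop_id <- function(x) {
  parts <- strsplit(x, ".", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop(
      "expected class.fold.superfamily.family dotted id, got '",
      x[bad[[1L]]], "'"
    )
  }
  join <- function(k) vapply(parts, function(p) {
    paste(p[seq_len(k)], collapse = ".")
  }, character(1))
  data.frame(
    fold = join(2L), superfamily = join(3L), family = join(4L),
    stringsAsFactors = FALSE
  )
}

#' Read a category label table
#'
#' Tab-separated, no header. Either two columns (`id`, dotted SCOP-style
#' identifier) or four columns (`id`, `fold`, `superfamily`, `family`).
#'
#' @param path Path to the labels file.
#' @return Data frame with columns `id`, `fold`, `superfamily`, `family`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(
    path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  if (ncol(tab) == 2L) {
    cbind(data.frame(id = tab[[1L]], stringsAsFactors = FALSE),
          parse_scop_id(tab[[2L]]))
  } else if (ncol(tab) == 4L) {
    names(tab) <- c("id", "fold", "superfamily", "family")
    tab
  } else {
    stop("labels file must have 2 or 4 tab-separated columns")
  }
}

#' Read a structural similarity score table
#'
#' Tab-separated, no header: `id_a`, `id_b`, `score`.
#'
#' @param path Path to the scores file.
#' @return Data frame with columns `id_a`, `id_b`, `score`.
#' @export
read_struct_scores <- function(path) {
  tab <- utils::read.table(
    path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE
  )
  if (ncol(tab) != 3L) stop("structural scores must have 3 columns")
  data.frame(
    id_a = as.character(tab[[1L]]), id_b = as.character(tab[[2L]]),
    score = as.numeric(tab[[3L]]), stringsAsFactors = FALSE
  )
}

#' Homology classes of ranked targets
#'
#' Targets in the query's superfamily are positive; targets in a different
#' fold are negative; targets in the same fold but a different superfamily
#' are ignored, because their homology to the query is uncertain. With
#' `exclude_family = TRUE`, members of the query's own family are also
#' ignored, so that performance does not rest on easy family-level matches.
#'
#' @param query_label One-row data frame or list with `fold`,
#'   `superfamily`, `family`.
#' @param target_labels Data frame with columns `fold`, `superfamily`,
#'   `family` (one row per target, in ranking order).
#' @param exclude_family Ignore same-family targets.
#' @return Character vector in `{"positive", "negative", "ignore"}`.
#' @export
label_targets <- function(query_label, target_labels,
                          exclude_family = FALSE) {
  need <- c("fold", "superfamily", "family")
  stopifnot(all(need %in% names(target_labels)))
  if (anyNA(target_labels$superfamily) || anyNA(target_labels$fold)) {
    stop("unlabeled target")
  }
  cls <- ifelse(
    target_labels$superfamily == query_label$superfamily, "positive",
    ifelse(target_labels$fold == query_label$fold, "ignore", "negative")
  )
  if (exclude_family) {
    cls[target_labels$family == query_label$family] <- "ignore"
  }
  cls
}

#' Truncated ROC score of a labeled ranking
#'
#' Area under the ROC curve up to the `n_cap`-th false positive, normalized
#' by `n_cap * #positives` so that a ranking placing every positive before
#' the first `n_cap` negatives scores 1.0. Ignored targets are removed
#' before scoring. Equivalent to counting the (positive, negative) pairs in
#' which the positive precedes a negative that is among the first `n_cap`
#' negatives.
#'
#' @param classes Character vector of target classes in rank order
#'   (`"positive"`, `"negative"`, `"ignore"`).
#' @param n_cap False-positive truncation (1 and 50 are conventional).
#' @return The score in `[0, 1]`, with attributes `n_cap`, `n_pos`,
#'   `n_neg`; `NA` when the ranking contains no positives.
#' @export
roc_n <- function(classes, n_cap = 1L) {
  cls <- classes[classes != "ignore"]
  n_pos <- sum(cls == "positive")
  n_neg <- sum(cls == "negative")
  if (n_pos == 0L) {
    return(structure(NA_real_, n_cap = n_cap, n_pos = 0L, n_neg = n_neg))
  }
  if (n_neg < n_cap) {
    stop("need at least n_cap = ", n_cap, " negatives, got ", n_neg)
  }
  neg_before <- cumsum(cls == "negative")[cls == "positive"]
  value <- sum(pmax(0L, n_cap - neg_before)) / (n_cap * n_pos)
  structure(value, n_cap = n_cap, n_pos = n_pos, n_neg = n_neg)
}

#' Pooled ROC curve across queries
#'
#' Sorts the labeled scores of all queries into one list (ascending score:
#' smaller distance or p-value is better) and traces the pooled ROC curve,
#' measuring how comparable scores are between queries. Ignored targets are
#' dropped.
#'
#' @param rankings List of data frames, each with columns `score` and
#'   `class` (`"positive"`/`"negative"`/`"ignore"`).
#' @return Data frame of curve points (`fpf`, `tpf`) starting at (0, 0),
#'   with the full pooled AUC as attribute `"auc"`.
#' @export
pooled_roc <- function(rankings) {
  pool <- do.call(rbind, lapply(rankings, function(r) {
    r[r$class != "ignore", c("score", "class"), drop = FALSE]
  }))
  pool <- pool[order(pool$score), , drop = FALSE]
  n_pos <- sum(pool$class == "positive")
  n_neg <- sum(pool$class == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    stop("pooled ranking needs both positives and negatives")
  }
  tp <- cumsum(pool$class == "positive")
  fp <- cumsum(pool$class == "negative")
  curve <- data.frame(fpf = c(0, fp / n_neg), tpf = c(0, tp / n_pos))
  # pooled AUC via the rank formula: P(positive scores below negative),
  # ties counted half (the Mann-Whitney U-statistic)
  pos_rank <- rank(pool$score)[pool$class == "positive"]
  auc <- (sum(pos_rank) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  attr(curve, "auc") <- 1 - auc # smaller score = better: positives low
  curve
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided test on paired per-query scores. Zero differences are dropped;
#' the exact distribution is used for fewer than 15 non-zero untied
#' differences and the tie-corrected normal approximation otherwise. The
#' direction reports which method scores higher.
#'
#' @param scores_a,scores_b Paired numeric vectors (e.g. per-query ROC
#'   scores of two methods).
#' @return List with `statistic` (V), `p.value` and `direction` (sign of
#'   the median difference a - b).
#' @export
wilcoxon_signed_rank <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b))
  d <- scores_a - scores_b
  direction <- sign(stats::median(d))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p.value = 1, direction = 0))
  }
  use_exact <- n < 15L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = use_exact, correct = TRUE)
  )
  list(
    statistic = unname(wt$statistic), p.value = wt$p.value,
    direction = direction
  )
}

#' Evaluate held-out queries against a fitted embedding
#'
#' Ranks the training database for each query, labels the targets from the
#' category table, and reports the truncated ROC score per query. Queries
#' without positives are returned with `NA` scores (and are excluded from
#' means by [mean_roc()]).
#'
#' @param model A `"seqembed"` fit.
#' @param qfeats Query feature rows (see [query_features()]), one per
#'   query, rownames = query ids.
#' @param labels Label data frame covering queries and database targets.
#' @param n_cap ROC truncation.
#' @param exclude_family Passed to [label_targets()].
#' @return Data frame (`query_id`, `roc`, `n_pos`, `n_neg`) of class
#'   `"seqembed_eval"`.
#' @export
evaluate_queries <- function(model, qfeats, labels, n_cap = 1L,
                             exclude_family = FALSE) {
  lab <- labels
  rownames(lab) <- lab$id
  rankings <- predict(model, qfeats, type = "ranking")
  if (inherits(rankings, "ranked_result")) rankings <- list(rankings)
  qids <- rownames(qfeats)
  out <- do.call(rbind, lapply(seq_along(qids), function(k) {
    r <- rankings[[k]]
    cls <- label_targets(
      lab[qids[[k]], ], lab[r$target_id, ],
      exclude_family = exclude_family
    )
    sc <- roc_n(cls, n_cap)
    data.frame(
      query_id = qids[[k]], roc = as.numeric(sc),
      n_pos = attr(sc, "n_pos"), n_neg = attr(sc, "n_neg"),
      stringsAsFactors = FALSE
    )
  }))
  class(out) <- c("seqembed_eval", "data.frame")
  out
}

#' Mean ROC over evaluated queries
#'
#' Queries with no positives (undefined ROC) are excluded; their count is
#' reported in the `"n_undefined"` attribute.
#'
#' @param eval_result Data frame from [evaluate_queries()].
#' @return Mean ROC score.
#' @export
mean_roc <- function(eval_result) {
  ok <- !is.na(eval_result$roc)
  structure(mean(eval_result$roc[ok]), n_undefined = sum(!ok))
}

#' Write a per-query evaluation report as TSV
#'
#' @param eval_result Data frame from [evaluate_queries()].
#' @param path Output path.
#' @export
write_eval_report <- function(eval_result, path) {
  utils::write.table(
    as.data.frame(eval_result), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
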