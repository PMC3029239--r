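#' Training hyperparameters
#'
#' Collects all tunable parameters of the embedding fit. Defaults follow the
#' settings selected by cross-validation for a PSI-BLAST-style teacher:
#' embedding dimension 250, learning rate 0.05, 150 epochs of 20,000 tuples.
#' For an HMM-HMM-comparison-style teacher, `d = 100` and `lr = 0.02` are the
#' recommended settings. The margin is conventionally 1; loss scale and
#' learning rate are coupled, so only their ratio matters.
#'
#' @param d Embedding dimension (rows of the projection matrix).
#' @param lr Fixed SGD learning rate.
#' @param margin Ranking margin of the hinge loss.
#' @param p Norm order of the embedding distance. The default 1-norm has the
#'   componentwise-sign subgradient used by the updates; other `p >= 1` use
#'   the corresponding p-norm subgradient.
#' @param epochs Number of epochs; 0 returns the random initialization.
#' @param tuples_per_epoch Main-task tuples drawn per epoch.
#' @param pos_evalue_threshold A target with teacher E-value strictly below
#'   this is a positive for its query (default 0.1).
#' @param struct_cutoff Structural-similarity score strictly above which a
#'   pair yields auxiliary ranking positives (default 2.0).
#' @param aux_mode Auxiliary task: `"none"`, `"class"` (fold/superfamily
#'   centroids), `"rank_label"` (same-superfamily ranking tuples) or
#'   `"rank_struct"` (structural-score ranking tuples).
#' @param aux_ratio Auxiliary steps interleaved per main-task step.
#' @param seed Integer seed; fixes initialization and all tuple draws.
#' @return A list of class `"seqembed_control"`.
#' @export
seqembed_control <- function(d = 250L, lr = 0.05, margin = 1, p = 1,
                             epochs = 150L, tuples_per_epoch = 20000L,
                             pos_evalue_threshold = 0.1, struct_cutoff = 2.0,
                             aux_mode = c("none", "class", "rank_label",
                                          "rank_struct"),
                             aux_ratio = 1L, seed = 1L) {
  aux_mode <- match.arg(aux_mode)
  stopifnot(
    d >= 1, lr > 0, margin > 0, p >= 1, epochs >= 0,
    tuples_per_epoch >= 1, pos_evalue_threshold > 0, aux_ratio >= 1
  )
  structure(
    list(
      d = as.integer(d), lr = lr, margin = margin, p = p,
      epochs = as.integer(epochs),
      tuples_per_epoch = as.integer(tuples_per_epoch),
      pos_evalue_threshold = pos_evalue_threshold,
      struct_cutoff = struct_cutoff, aux_mode = aux_mode,
      aux_ratio = as.integer(aux_ratio), seed = as.integer(seed)
    ),
    class = "seqembed_control"
  )
}

# ---- sparse row helpers -----------------------------------------------------

# List of per-row supports (i = column indices, x = values) of a sparse or
# dense matrix; the training loop touches only these columns per step.
.row_supports <- function(m) {
  if (inherits(m, "feature_matrix")) m <- m$matrix
  # route through generalMatrix: diagonal/triangular classes store unit
  # diagonals implicitly, which would hide entries from @i/@x
  tm <- methods::as(
    methods::as(Matrix::t(m), "generalMatrix"), "CsparseMatrix"
  )
  p <- tm@p
  lapply(seq_len(ncol(tm)), function(j) {
    if (p[j + 1L] == p[j]) {
      list(i = integer(0), x = numeric(0))
    } else {
      idx <- (p[j] + 1L):p[j + 1L]
      list(i = tm@i[idx] + 1L, x = tm@x[idx])
    }
  })
}

# W f for a support-list feature vector
.phi <- function(W, f) {
  if (length(f$i) == 0L) {
    return(numeric(nrow(W)))
  }
  as.vector(W[, f$i, drop = FALSE] %*% f$x)
}

# sparse difference a - b as a support list
.support_diff <- function(a, b) {
  u <- unique(c(a$i, b$i))
  x <- numeric(length(u))
  if (length(a$i)) x[match(a$i, u)] <- a$x
  if (length(b$i)) {
    mb <- match(b$i, u)
    x[mb] <- x[mb] - b$x
  }
  list(i = u, x = x)
}

# subgradient of ||v||_p at v (componentwise sign for p = 1)
.pnorm_subgrad <- function(v, p) {
  if (p == 1) {
    return(sign(v))
  }
  nv <- sum(abs(v)^p)^(1 / p)
  if (nv == 0) {
    return(numeric(length(v)))
  }
  sign(v) * (abs(v) / nv)^(p - 1)
}

.pnorm <- function(v, p) {
  if (p == 1) sum(abs(v)) else sum(abs(v)^p)^(1 / p)
}

# coerce features argument (feature_matrix | matrix | support list) to supports
.as_supports <- function(features) {
  if (is.list(features) && !inherits(features, "feature_matrix") &&
      !is.data.frame(features)) {
    return(features)
  }
  .row_supports(if (inherits(features, "feature_matrix")) features$matrix
                else Matrix::Matrix(as.matrix(features), sparse = TRUE))
}

# ---- tuple construction -----------------------------------------------------

#' Positive sets from teacher hits
#'
#' For each database protein, the set of targets whose teacher E-value is
#' strictly below the positive threshold (the "similar" proteins). Self-hits
#' never count as positives. Duplicate pairs keep the smallest E-value.
#'
#' @param hits Teacher hits data frame (see [read_hits()]).
#' @param ids Database identifiers.
#' @param threshold Strict upper bound on the E-value of a positive.
#' @return A list with `pos` (per-protein integer index vectors) and
#'   `queries` (indices of proteins with at least one positive).
#' @export
positive_sets <- function(hits, ids, threshold = 0.1) {
  n <- length(ids)
  i <- match(hits$query_id, ids)
  j <- match(hits$target_id, ids)
  if (anyNA(i) || anyNA(j)) stop("hit refers to an id not in `ids`")
  keep <- hits$evalue < threshold & i != j
  pos <- split(j[keep], factor(i[keep], levels = seq_len(n)))
  pos <- lapply(pos, function(v) sort(unique(v)))
  queries <- unname(which(lengths(pos) > 0L))
  list(pos = pos, queries = queries, n = n)
}

#' Draw one training tuple
#'
#' Draws a query uniformly among proteins with at least one positive, a
#' positive uniformly among that query's positives, and a negative uniformly
#' from the whole database. Negatives equal to the query or the positive are
#' rejected and redrawn; other accidental homologs are kept, as the training
#' signal tolerates that noise. Uses the current RNG state.
#'
#' @param psets Positive sets from [positive_sets()].
#' @return Named integer vector `c(q, pos, neg)`.
#' @export
sample_tuple <- function(psets) {
  if (length(psets$queries) == 0L) stop("no training signal: no positives")
  q <- psets$queries[[sample.int(length(psets$queries), 1L)]]
  pq <- psets$pos[[q]]
  pos <- pq[[sample.int(length(pq), 1L)]]
  repeat {
    neg <- sample.int(psets$n, 1L)
    if (neg != q && neg != pos) break
  }
  c(q = q, pos = pos, neg = neg)
}

#' Auxiliary ranking pairs from structural information
#'
#' Builds the positive pairs of the auxiliary ranking task. In `"label"`
#' mode, two labeled proteins are similar when they share a superfamily. In
#' `"struct"` mode, a pair is similar when its structural-alignment score is
#' strictly above `cutoff` (default 2.0). Pairs are symmetric: both
#' orientations can seed a tuple. Negatives are later drawn uniformly from
#' the labeled set.
#'
#' @param ids Database identifiers.
#' @param labels Label data frame (`id`, `fold`, `superfamily`, `family`),
#'   required for `"label"` mode and to define the labeled universe.
#' @param struct_scores Data frame (`id_a`, `id_b`, `score`) for `"struct"`
#'   mode.
#' @param cutoff Strict lower bound on a similar structural score.
#' @param mode `"label"` or `"struct"`.
#' @return List with `pairs` (two-column integer matrix, both orientations)
#'   and `universe` (labeled indices for negative draws).
#' @export
auxiliary_pairs <- function(ids, labels = NULL, struct_scores = NULL,
                            cutoff = 2.0, mode = c("label", "struct")) {
  mode <- match.arg(mode)
  if (is.null(labels)) stop("auxiliary tasks require labels")
  li <- match(labels$id, ids)
  if (anyNA(li)) stop("label refers to an id not in `ids`")
  universe <- sort(li)
  if (mode == "label") {
    sf <- split(li, labels$superfamily)
    pairs <- do.call(rbind, lapply(sf, function(v) {
      if (length(v) < 2L) {
        return(NULL)
      }
      g <- expand.grid(a = v, b = v)
      as.matrix(g[g$a != g$b, , drop = FALSE])
    }))
  } else {
    if (is.null(struct_scores)) stop("struct mode requires struct_scores")
    a <- match(struct_scores$id_a, ids)
    b <- match(struct_scores$id_b, ids)
    if (anyNA(a) || anyNA(b)) stop("structural score refers to unknown id")
    keep <- struct_scores$score > cutoff & a != b
    pairs <- cbind(a = c(a[keep], b[keep]), b = c(b[keep], a[keep]))
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("no qualifying auxiliary pairs")
  }
  dimnames(pairs) <- list(NULL, c("a", "b"))
  list(pairs = pairs, universe = universe)
}

# one auxiliary ranking tuple (q, pos) from the pair list, neg from universe
.sample_aux_tuple <- function(aux) {
  k <- sample.int(nrow(aux$pairs), 1L)
  q <- aux$pairs[k, 1L]
  pos <- aux$pairs[k, 2L]
  repeat {
    neg <- aux$universe[[sample.int(length(aux$universe), 1L)]]
    if (neg != q && neg != pos) break
  }
  c(q = q, pos = pos, neg = neg)
}

# ---- losses and SGD steps ---------------------------------------------------

#' Margin ranking loss of one tuple
#'
#' The hinge `max(0, margin + D(q, pos) - D(q, neg))` where `D` is the
#' embedding p-norm distance. Zero when the positive is already closer to
#' the query than the negative by at least the margin.
#'
#' @param W d x n projection matrix.
#' @param tuple Integer vector `(q, pos, neg)` of database indices.
#' @param features Feature matrix (rows are feature vectors) or a
#'   `"feature_matrix"` object.
#' @param margin,p Hinge margin and norm order.
#' @return Non-negative scalar.
#' @export
tuple_margin_loss <- function(W, tuple, features, margin = 1, p = 1) {
  rows <- .as_supports(features)
  .tuple_loss(W, tuple, rows, margin, p)
}

.tuple_loss <- function(W, tuple, rows, margin, p) {
  phi_q <- .phi(W, rows[[tuple[[1L]]]])
  dqp <- phi_q - .phi(W, rows[[tuple[[2L]]]])
  dqn <- phi_q - .phi(W, rows[[tuple[[3L]]]])
  max(0, margin + .pnorm(dqp, p) - .pnorm(dqn, p))
}

#' One stochastic gradient step on a ranking tuple
#'
#' If the tuple violates the margin constraint, takes a subgradient step on
#' the projection matrix; for the default 1-norm the subgradient applies the
#' sign function componentwise. Only the columns in the tuple's feature
#' supports are touched. Tuples with zero loss leave `W` unchanged.
#'
#' @inheritParams tuple_margin_loss
#' @param lr Learning rate.
#' @return The updated projection matrix, with the pre-update loss attached
#'   as attribute `"loss"`.
#' @export
sgd_step <- function(W, tuple, features, lr = 0.05, margin = 1, p = 1) {
  rows <- .as_supports(features)
  res <- .sgd_step(W, tuple, rows, lr, margin, p)
  structure(res$W, loss = res$loss)
}

.sgd_step <- function(W, tuple, rows, lr, margin, p) {
  fq <- rows[[tuple[[1L]]]]
  fp <- rows[[tuple[[2L]]]]
  fn <- rows[[tuple[[3L]]]]
  phi_q <- .phi(W, fq)
  dqp <- phi_q - .phi(W, fp)
  dqn <- phi_q - .phi(W, fn)
  loss <- margin + .pnorm(dqp, p) - .pnorm(dqn, p)
  if (loss <= 0) {
    return(list(W = W, loss = 0))
  }
  gp <- .pnorm_subgrad(dqp, p)
  gn <- .pnorm_subgrad(dqn, p)
  up <- .support_diff(fq, fp)
  if (length(up$i)) {
    W[, up$i] <- W[, up$i, drop = FALSE] - lr * tcrossprod(gp, up$x)
  }
  un <- .support_diff(fq, fn)
  if (length(un$i)) {
    W[, un$i] <- W[, un$i, drop = FALSE] + lr * tcrossprod(gn, un$x)
  }
  list(W = W, loss = loss)
}

#' Margin loss of the class-centroid auxiliary task
#'
#' The class task keeps each labeled protein closer to its own fold and
#' superfamily centroids than to the centroids of another labeled protein:
#' `max(0, margin + D(W f, C b) - D(W f, C b'))`, where `b` and `b'` are
#' two-hot indicator vectors over centroid columns.
#'
#' @param W d x n projection matrix.
#' @param C d x K centroid matrix (one column per fold and per superfamily).
#' @param f Feature vector of the labeled protein (length n, dense or
#'   sparse).
#' @param bits,bits_other Integer vectors of centroid column indices (fold
#'   and superfamily) of the protein and of the contrasted protein.
#' @param margin,p Hinge margin and norm order.
#' @return Non-negative scalar.
#' @export
class_margin_loss <- function(W, C, f, bits, bits_other, margin = 1, p = 1) {
  f <- as.numeric(f)
  phi <- as.vector(W %*% f)
  e1 <- phi - rowSums(C[, bits, drop = FALSE])
  e2 <- phi - rowSums(C[, bits_other, drop = FALSE])
  max(0, margin + .pnorm(e1, p) - .pnorm(e2, p))
}

#' One stochastic gradient step on the class-centroid task
#'
#' Hinge step pushing the embedded protein toward its own fold/superfamily
#' centroids and away from the other protein's centroids, updating both the
#' projection matrix and the centroid matrix. When the two proteins share
#' fold and superfamily the two gradient terms cancel and the step is a
#' no-op.
#'
#' @inheritParams class_margin_loss
#' @param lr Learning rate.
#' @return List with updated `W` and `C` and the pre-update `loss`.
#' @export
class_task_step <- function(W, C, f, bits, bits_other, lr = 0.05,
                            margin = 1, p = 1) {
  if (is.numeric(f) && is.null(dim(f))) {
    fs <- list(i = which(f != 0), x = f[f != 0])
  } else {
    fs <- .as_supports(Matrix::Matrix(matrix(as.numeric(f), nrow = 1),
                                      sparse = TRUE))[[1L]]
  }
  .class_step(W, C, fs, bits, bits_other, lr, margin, p)
}

.class_step <- function(W, C, fs, bits, bits_other, lr, margin, p) {
  phi <- .phi(W, fs)
  e1 <- phi - rowSums(C[, bits, drop = FALSE])
  e2 <- phi - rowSums(C[, bits_other, drop = FALSE])
  loss <- margin + .pnorm(e1, p) - .pnorm(e2, p)
  if (loss <= 0) {
    return(list(W = W, C = C, loss = 0))
  }
  g1 <- .pnorm_subgrad(e1, p)
  g2 <- .pnorm_subgrad(e2, p)
  if (length(fs$i)) {
    W[, fs$i] <- W[, fs$i, drop = FALSE] - lr * tcrossprod(g1 - g2, fs$x)
  }
  # d loss / d C = -g1 b^T + g2 b'^T on violating tuples
  for (k in bits) C[, k] <- C[, k] + lr * g1
  for (k in bits_other) C[, k] <- C[, k] - lr * g2
  list(W = W, C = C, loss = loss)
}

# centroid column index for a label row: c(fold column, superfamily column)
.centroid_index <- function(labels) {
  folds <- sort(unique(labels$fold))
  sfs <- sort(unique(labels$superfamily))
  list(
    levels = c(paste0("fold:", folds), paste0("sf:", sfs)),
    fold = match(labels$fold, folds),
    superfamily = length(folds) + match(labels$superfamily, sfs),
    n_fold = length(folds), n_sf = length(sfs)
  )
}

# ---- the fitting function ---------------------------------------------------

#' Fit a semantic embedding of a protein database
#'
#' Learns the d x n projection matrix that maps each protein's sparse
#' teacher-similarity profile to a point in a d-dimensional semantic space
#' in which the p-norm distance reflects homology. Training minimizes the
#' margin ranking loss over (query, similar, dissimilar) tuples by
#' stochastic gradient descent: similar pairs (teacher E-value strictly
#' below the positive threshold) are pulled together and random negatives
#' pushed apart until the margin holds. With `aux_mode` other than
#' `"none"`, an auxiliary structural task is multitasked with the main
#' objective by interleaving its stochastic steps with the main steps
#' (`aux_ratio` auxiliary draws per main draw); per-tuple SGD on the summed
#' objective is equivalent in expectation to this proportional interleaving.
#'
#' The projection matrix (and centroid matrix, for the class task) is
#' initialized with i.i.d. standard normal entries from `config$seed`;
#' `epochs = 0` returns that initialization. The whole fit is a
#' deterministic function of (features, hits, auxiliary data, config).
#'
#' @param features `"feature_matrix"` of the training database (see
#'   [build_feature_matrix()]).
#' @param hits Teacher hits data frame; defines the positive pairs.
#' @param config A [seqembed_control()] list.
#' @param labels Optional label data frame (`id`, `fold`, `superfamily`,
#'   `family`) for the `"class"` and `"rank_label"` auxiliary modes.
#' @param struct_scores Optional structural score data frame (`id_a`,
#'   `id_b`, `score`) for the `"rank_struct"` mode.
#' @return An object of class `"seqembed"`: a list with the projection
#'   matrix `W`, optional centroid matrix `C` and `centroid_levels`,
#'   database `ids`, precomputed embedded database points `db_points`
#'   (d x n), the `config`, and a per-epoch training `trace` (epoch, mean
#'   loss, violation count).
#' @examples
#' fx <- generate_fixture(fixture_config(seed = 1))
#' fm <- build_feature_matrix(fx$hits, fx$sequences$id)
#' fit <- seqembed(fm, fx$hits,
#'   config = seqembed_control(d = 5, epochs = 2, tuples_per_epoch = 200)
#' )
#' fit
#' @export
seqembed <- function(features, hits, config = seqembed_control(),
                     labels = NULL, struct_scores = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  cl <- match.call()
  ids <- features$ids
  n <- length(ids)
  rows <- .row_supports(features$matrix)
  psets <- positive_sets(hits, ids, config$pos_evalue_threshold)
  if (length(psets$queries) == 0L) stop("no training signal: no positives")

  aux <- NULL
  cindex <- NULL
  lab_rows <- NULL
  if (config$aux_mode != "none") {
    if (is.null(labels)) stop("aux_mode != 'none' requires labels")
    if (config$aux_mode == "class") {
      cindex <- .centroid_index(labels)
      lab_rows <- match(labels$id, ids)
      if (anyNA(lab_rows)) stop("label refers to an id not in the database")
    } else {
      aux <- auxiliary_pairs(
        ids,
        labels = labels, struct_scores = struct_scores,
        cutoff = config$struct_cutoff,
        mode = if (config$aux_mode == "rank_struct") "struct" else "label"
      )
    }
  }

  set.seed(config$seed)
  W <- matrix(stats::rnorm(config$d * n), config$d, n)
  C <- NULL
  if (!is.null(cindex)) {
    K <- cindex$n_fold + cindex$n_sf
    C <- matrix(stats::rnorm(config$d * K), config$d, K)
    colnames(C) <- cindex$levels
  }

  trace <- data.frame(
    epoch = integer(0), mean_loss = numeric(0), violations = integer(0)
  )
  if (config$epochs > 0L) {
    for (ep in seq_len(config$epochs)) {
      loss_sum <- 0
      viol <- 0L
      for (t in seq_len(config$tuples_per_epoch)) {
        tup <- sample_tuple(psets)
        res <- .sgd_step(W, tup, rows, config$lr, config$margin, config$p)
        W <- res$W
        loss_sum <- loss_sum + res$loss
        if (res$loss > 0) viol <- viol + 1L
        if (config$aux_mode == "class") {
          for (r in seq_len(config$aux_ratio)) {
            k1 <- sample.int(length(lab_rows), 1L)
            k2 <- sample.int(length(lab_rows), 1L)
            cres <- .class_step(
              W, C, rows[[lab_rows[[k1]]]],
              c(cindex$fold[[k1]], cindex$superfamily[[k1]]),
              c(cindex$fold[[k2]], cindex$superfamily[[k2]]),
              config$lr, config$margin, config$p
            )
            W <- cres$W
            C <- cres$C
          }
        } else if (config$aux_mode %in% c("rank_label", "rank_struct")) {
          for (r in seq_len(config$aux_ratio)) {
            atup <- .sample_aux_tuple(aux)
            ares <- .sgd_step(W, atup, rows, config$lr, config$margin,
                              config$p)
            W <- ares$W
          }
        }
      }
      mean_loss <- loss_sum / config$tuples_per_epoch
      if (!is.finite(mean_loss)) {
        stop(
          "non-finite training loss at epoch ", ep,
          "; check learning rate and feature scaling"
        )
      }
      trace <- rbind(trace, data.frame(
        epoch = ep, mean_loss = mean_loss, violations = viol
      ))
    }
  }

  colnames(W) <- ids
  db_points <- as.matrix(W %*% Matrix::t(features$matrix))
  colnames(db_points) <- ids
  structure(
    list(
      W = W, C = C,
      centroid_levels = if (is.null(cindex)) NULL else cindex$levels,
      ids = ids, sigma = features$sigma, normalized = features$normalized,
      db_points = db_points, config = config, trace = trace, call = cl
    ),
    class = "seqembed"
  )
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.seqembed <- function(x, ...) {
  cat("Semantic embedding of a protein database\n")
  cat(
    "  ", length(x$ids), " proteins embedded in ", x$config$d,
    " dimensions (", x$config$p, "-norm distance)\n",
    sep = ""
  )
  cat(
    "  trained ", x$config$epochs, " epochs x ", x$config$tuples_per_epoch,
    " tuples, lr = ", x$config$lr, ", margin = ", x$config$margin,
    ", aux = ", x$config$aux_mode, ", seed = ", x$config$seed, "\n",
    sep = ""
  )
  if (nrow(x$trace)) {
    cat(
      "  final epoch mean ranking loss: ",
      signif(utils::tail(x$trace$mean_loss, 1), 4), "\n",
      sep = ""
    )
  } else {
    cat("  untrained (random initialization)\n")
  }
  invisible(x)
}

#' @export
summary.seqembed <- function(object, ...) {
  out <- list(
    n = length(object$ids), config = object$config, trace = object$trace,
    has_centroids = !is.null(object$C)
  )
  class(out) <- "summary.seqembed"
  out
}

#' @export
print.summary.seqembed <- function(x, ...) {
  cat(
    "seqembed model: n = ", x$n, ", d = ", x$config$d,
    ", aux = ", x$config$aux_mode, "\n",
    sep = ""
  )
  if (nrow(x$trace)) {
    cat("Training loss trace (per epoch):\n")
    print(utils::head(x$trace, 5))
    if (nrow(x$trace) > 5) {
      cat("  ...\n")
      print(utils::tail(x$trace, 1))
    }
  } else {
    cat("No training epochs run.\n")
  }
  invisible(x)
}

#' Extract the learned projection matrix
#'
#' @param object A `"seqembed"` fit.
#' @param ... Unused.
#' @return The d x n projection matrix; the centroid matrix, when present,
#'   is attached as attribute `"centroids"`.
#' @export
coef.seqembed <- function(object, ...) {
  W <- object$W
  if (!is.null(object$C)) attr(W, "centroids") <- object$C
  W
}

#' Embed or rank with a fitted model
#'
#' @param object A `"seqembed"` fit.
#' @param features Query feature vectors as rows (see [query_features()] for
#'   queries outside the training database).
#' @param type `"embedding"` returns embedded coordinates (d rows, one
#'   column per query); `"ranking"` ranks the training database for each
#'   query.
#' @param ... Unused.
#' @return A coordinate matrix, or a list of `"ranked_result"` data frames
#'   (a single data frame for a single query).
#' @export
predict.seqembed <- function(object, features,
                             type = c("embedding", "ranking"), ...) {
  type <- match.arg(type)
  pts <- embed_features(object, features)
  if (type == "embedding") {
    return(pts)
  }
  res <- lapply(seq_len(ncol(pts)), function(k) {
    rank_database(object, pts[, k], object$db_points)
  })
  names(res) <- colnames(pts)
  if (length(res) == 1L) res[[1L]] else res
}

#' Plot the training loss trace
#'
#' @param x A `"seqembed"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.seqembed <- function(x, ...) {
  if (!nrow(x$trace)) {
    stop("model has no training trace (epochs = 0)")
  }
  graphics::plot(
    x$trace$epoch, x$trace$mean_loss,
    type = "l",
    xlab = "epoch", ylab = "mean ranking loss", ...
  )
  invisible(x)
}

#' Save / load a fitted model
#'
#' The serialized model is self-describing: it carries the database ids,
#' the transfer width, and every training hyperparameter.
#'
#' @param model A `"seqembed"` fit.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seqembed"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "seqembed")) stop("not a seqembed model file")
  model
}

#' Write the per-epoch training log as TSV
#'
#' @param model A `"seqembed"` fit.
#' @param path Output path.
#' @export
write_training_log <- function(model, path) {
  utils::write.table(
    model$trace, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
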