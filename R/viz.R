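# 2D neighborhood maps: classical multidimensional scaling of the query
# and its significant hits, in either the raw teacher-feature space or the
# learned embedding space.

#' Classical multidimensional scaling to two dimensions
#'
#' Double-centering (Torgerson) MDS via [stats::cmdscale()], keeping the
#' top two eigendirections. Deterministic up to sign and rotation, so
#' downstream checks compare preserved distances, not raw coordinates.
#'
#' @param distance_matrix Symmetric non-negative matrix with zero diagonal.
#' @return An n x 2 coordinate matrix (rownames preserved).
#' @export
mds_project <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  n <- nrow(d)
  if (n == 1L) {
    out <- matrix(0, 1L, 2L)
    rownames(out) <- rownames(d)
    return(out)
  }
  if (all(d == 0)) {
    out <- matrix(0, n, 2L, dimnames = list(rownames(d), c("x", "y")))
    return(out)
  }
  k <- min(2L, n - 1L)
  coords <- stats::cmdscale(d, k = k)
  if (ncol(coords) < 2L) {
    coords <- cbind(coords, matrix(0, n, 2L - ncol(coords)))
  }
  colnames(coords) <- c("x", "y")
  coords
}

# L1 (or general p) pairwise distance matrix between columns of a point set
.pairwise_dist <- function(pts, p = 1) {
  n <- ncol(pts)
  d <- matrix(0, n, n, dimnames = list(colnames(pts), colnames(pts)))
  for (i in seq_len(n)) {
    d[i, ] <- .distances_to_db(pts[, i], pts, p)
  }
  (d + t(d)) / 2 # exact symmetry despite floating-point order
}

#' Neighborhood map of a query
#'
#' Ranks the database for the query, keeps the targets passing the q-value
#' threshold (or the top `rank_cap` targets when no calibration is given),
#' and projects the query plus its hits to 2D by classical MDS of their
#' pairwise distances. The distances can be measured in the learned
#' embedding (`space = "embedded"`) or in the raw teacher feature space
#' (`space = "initial"`, the initialization-time geometry), which makes
#' the effect of training visible.
#'
#' @param model A `"seqembed"` fit.
#' @param qfeat One query feature row (see [query_features()]).
#' @param query_id Identifier used for the query point.
#' @param calibration Optional `"null_calibration"` for q-value inclusion.
#' @param query_length Query residue length (required with `calibration`).
#' @param q_threshold Include targets with q-value at most this (default
#'   0.01).
#' @param space `"embedded"` or `"initial"`.
#' @param db_features The database `"feature_matrix"` (required for
#'   `space = "initial"`).
#' @param labels Optional label data frame; point classes are the
#'   relationship of each hit to the query (same family / superfamily /
#'   fold / other).
#' @param rank_cap Fallback inclusion rule without calibration.
#' @return Object of class `"neighborhood_map"`: a data frame with
#'   columns `id`, `x`, `y`, `class`, `is_query` and attributes `space`
#'   and `q_threshold`.
#' @export
neighborhood <- function(model, qfeat, query_id = "query",
                         calibration = NULL, query_length = NULL,
                         q_threshold = 0.01,
                         space = c("embedded", "initial"),
                         db_features = NULL, labels = NULL,
                         rank_cap = 25L) {
  space <- match.arg(space)
  ranking <- predict(model, qfeat, type = "ranking")
  if (!is.null(calibration)) {
    if (is.null(query_length)) {
      stop("query_length is required to use the calibration")
    }
    ranking <- add_significance(ranking, calibration, query_length)
    hits <- ranking$target_id[ranking$q <= q_threshold]
  } else {
    hits <- utils::head(ranking$target_id, rank_cap)
  }
  if (length(hits) == 0L) {
    warning("no hits pass the inclusion rule; map contains the query alone")
  }
  hits <- setdiff(hits, query_id)

  if (space == "embedded") {
    qpt <- embed_features(model, qfeat)
    pts <- cbind(qpt, model$db_points[, hits, drop = FALSE])
    colnames(pts) <- c(query_id, hits)
  } else {
    if (is.null(db_features)) {
      stop("space = 'initial' requires the database feature matrix")
    }
    qv <- if (is.null(dim(qfeat))) matrix(qfeat, nrow = 1) else qfeat
    fv <- rbind(
      Matrix::Matrix(qv, sparse = TRUE),
      db_features$matrix[hits, , drop = FALSE]
    )
    pts <- Matrix::t(fv)
    pts <- as.matrix(pts)
    colnames(pts) <- c(query_id, hits)
  }
  dmat <- .pairwise_dist(pts, model$config$p)
  coords <- mds_project(dmat)

  cls <- rep("hit", length(hits))
  if (!is.null(labels)) {
    lab <- labels
    rownames(lab) <- lab$id
    ql <- lab[query_id, ]
    tl <- lab[hits, ]
    cls <- ifelse(
      !is.na(tl$family) & tl$family == ql$family, "same family",
      ifelse(!is.na(tl$superfamily) & tl$superfamily == ql$superfamily,
             "same superfamily",
             ifelse(!is.na(tl$fold) & tl$fold == ql$fold, "same fold",
                    "other"))
    )
  }
  out <- data.frame(
    id = c(query_id, hits),
    x = coords[, 1L], y = coords[, 2L],
    class = c("query", cls),
    is_query = c(TRUE, rep(FALSE, length(hits))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "space") <- space
  attr(out, "q_threshold") <- if (is.null(calibration)) NA_real_
                              else q_threshold
  class(out) <- c("neighborhood_map", "data.frame")
  out
}

#' Plot a neighborhood map
#'
#' Base-graphics scatter of the 2D MDS coordinates; the query is drawn as
#' a filled black circle, hits are colored by class.
#'
#' @param x A `"neighborhood_map"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.neighborhood_map <- function(x, ...) {
  classes <- unique(x$class[!x$is_query])
  pal <- grDevices::hcl.colors(max(1L, length(classes)), "Dark 3")
  col <- rep("grey40", nrow(x))
  for (k in seq_along(classes)) col[x$class == classes[[k]]] <- pal[[k]]
  col[x$is_query] <- "black"
  graphics::plot(
    x$x, x$y,
    col = col, pch = ifelse(x$is_query, 19, 17),
    xlab = "MDS 1", ylab = "MDS 2", asp = 1, ...
  )
  if (length(classes)) {
    graphics::legend(
      "topright",
      legend = c("query", classes), pch = c(19, rep(17, length(classes))),
      col = c("black", pal[seq_along(classes)]), cex = 0.8, bty = "n"
    )
  }
  invisible(x)
}

#' Write neighborhood map coordinates as TSV
#'
#' @param map A `"neighborhood_map"`.
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  utils::write.table(
    as.data.frame(map), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
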