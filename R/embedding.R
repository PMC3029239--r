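#' Embed feature vectors into the learned semantic space
#'
#' Applies the learned linear map: a feature vector (a protein's transformed
#' similarity profile over the n database proteins) is projected to a
#' d-dimensional point `W f`. The multiplication exploits sparsity of `f`.
#'
#' @param model A fitted `"seqembed"` model (see [seqembed()]), or a bare
#'   projection matrix with d rows and n columns.
#' @param features A length-n feature vector, or a matrix with one feature
#'   vector per row (dense or [Matrix::sparseMatrix()]).
#' @return A d-row matrix with one embedded point per column; column names
#'   are taken from the feature row names when present.
#' @export
embed_features <- function(model, features) {
  W <- if (inherits(model, "seqembed")) model$W else model
  stopifnot(is.matrix(W))
  if (is.null(dim(features))) {
    if (length(features) != ncol(W)) {
      stop(
        "feature vector has length ", length(features),
        " but the model expects ", ncol(W)
      )
    }
    out <- matrix(as.vector(W %*% features), nrow = nrow(W))
    return(out)
  }
  if (ncol(features) != ncol(W)) {
    stop(
      "feature matrix has ", ncol(features),
      " columns but the model expects ", ncol(W)
    )
  }
  out <- as.matrix(W %*% Matrix::t(features))
  colnames(out) <- rownames(features)
  out
}

#' Distance between embedded points
#'
#' The p-norm of the coordinate difference. The default `p = 1` is the
#' distance the training updates descend on (its subgradient is the
#' componentwise sign).
#'
#' @param a,b Numeric vectors of equal length (embedded coordinates).
#' @param p Norm order, `p >= 1`.
#' @return A non-negative scalar.
#' @export
embedding_distance <- function(a, b, p = 1) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("points differ in dimension")
  if (p < 1) stop("p must be >= 1")
  d <- abs(a - b)
  if (p == 1) {
    sum(d)
  } else if (is.infinite(p)) {
    max(d)
  } else {
    sum(d^p)^(1 / p)
  }
}

# L_p distances from one query point to every column of a d x n point matrix.
.distances_to_db <- function(query_point, db_points, p = 1) {
  diff <- abs(db_points - as.numeric(query_point))
  if (p == 1) {
    colSums(diff)
  } else if (is.infinite(p)) {
    apply(diff, 2L, max)
  } else {
    colSums(diff^p)^(1 / p)
  }
}

#' Rank a database of embedded points by distance to a query
#'
#' Linear scan retrieval: every database point is scored by its embedding
#' distance to the query and the database is sorted by ascending distance.
#' Ties are broken by ascending target id so that rankings (and the ROC
#' scores computed from them) are identical run to run.
#'
#' @param model A `"seqembed"` model or projection matrix (used for its
#'   p-norm order when it is a model; otherwise `p` applies).
#' @param query_point Length-d coordinates of the embedded query.
#' @param db_points d x n matrix of embedded database points, with ids as
#'   column names.
#' @param p Norm order used when `model` carries no configuration.
#' @return A data frame of class `"ranked_result"` with columns `rank`,
#'   `target_id`, `distance`, sorted by ascending distance.
#' @export
rank_database <- function(model, query_point, db_points, p = 1) {
  if (inherits(model, "seqembed")) p <- model$config$p
  if (length(db_points) == 0L || ncol(db_points) == 0L) {
    out <- data.frame(
      rank = integer(0), target_id = character(0), distance = numeric(0),
      stringsAsFactors = FALSE
    )
    class(out) <- c("ranked_result", "data.frame")
    return(out)
  }
  if (nrow(db_points) != length(as.numeric(query_point))) {
    stop("query and database points differ in dimension")
  }
  ids <- colnames(db_points)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(db_points)))
  dist <- .distances_to_db(query_point, db_points, p)
  o <- order(dist, ids, method = "radix")
  out <- data.frame(
    rank = seq_along(o),
    target_id = ids[o],
    distance = unname(dist[o]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ranked_result", "data.frame")
  out
}

#' Write a ranked result as TSV
#'
#' Columns: rank, target_id, distance, and p/q-values when present.
#'
#' @param ranking A `"ranked_result"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(
    as.data.frame(ranking),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
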