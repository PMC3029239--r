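#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that enforces the
#' contract required downstream: unique identifiers and non-empty sequences.
#' Identifiers are taken as the first whitespace-delimited token of each
#' header line. No length filtering is applied here; see
#' [filter_sequences()].
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `sequence` and `length`, in file
#'   order.
#' @seealso [write_fasta()], [filter_sequences()]
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA record with empty or missing header in ", path)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate id ", dup[[1L]], " in ", path)
  }
  seqs <- as.character(aa)
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop("empty sequence for record ", ids[empty[[1L]]], " in ", path)
  }
  data.frame(
    id = ids, sequence = unname(seqs), length = nchar(seqs),
    stringsAsFactors = FALSE
  )
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with columns `id` and `sequence`, as returned by
#'   [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Filter sequences by length and ambiguity content
#'
#' Removes sequences shorter than `min_len` residues, longer than `max_len`
#' residues, or composed entirely of the ambiguity code `"X"`. Input order is
#' preserved. Defaults follow the standard domain-database cleanup: drop
#' sequences below 6 or above 10,000 residues.
#'
#' @param records Sequence data frame (see [read_fasta()]).
#' @param min_len Minimum length kept (inclusive).
#' @param max_len Maximum length kept (inclusive).
#' @return The filtered data frame.
#' @export
filter_sequences <- function(records, min_len = 6L, max_len = 10000L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(records)
  }
  len <- nchar(records$sequence)
  all_x <- grepl("^X+$", records$sequence)
  keep <- len >= min_len & len <= max_len & !all_x
  records[keep, , drop = FALSE]
}

#' Read pairwise teacher hits
#'
#' Reads all-vs-all E-values from a pairwise search program ("teacher").
#' Two dialects are accepted: the canonical 3-column tab-separated form
#' (`query_id`, `target_id`, `evalue`) and 12-column BLAST tabular output
#' (outfmt 6), from which columns 1, 2 and 11 are used.
#'
#' @param path Path to a tab-separated hits file (no header).
#' @return A data frame with columns `query_id`, `target_id`, `evalue`.
#' @export
read_hits <- function(path) {
  tab <- utils::read.table(
    path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    colClasses = "character", quote = "", comment.char = ""
  )
  if (ncol(tab) == 3L) {
    hits <- data.frame(
      query_id = tab[[1L]], target_id = tab[[2L]],
      evalue = as.numeric(tab[[3L]]), stringsAsFactors = FALSE
    )
  } else if (ncol(tab) == 12L) {
    hits <- data.frame(
      query_id = tab[[1L]], target_id = tab[[2L]],
      evalue = as.numeric(tab[[11L]]), stringsAsFactors = FALSE
    )
  } else {
    stop(
      "expected 3-column (query, target, evalue) or 12-column BLAST ",
      "tabular hits, got ", ncol(tab), " columns in ", path
    )
  }
  if (anyNA(hits$evalue)) stop("non-numeric E-value in ", path)
  if (any(hits$evalue < 0)) stop("negative E-value in ", path)
  hits
}

#' Write pairwise hits in the canonical 3-column form
#'
#' @param hits Data frame with columns `query_id`, `target_id`, `evalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  stopifnot(all(c("query_id", "target_id", "evalue") %in% names(hits)))
  utils::write.table(
    hits[, c("query_id", "target_id", "evalue")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Weights below this are stored as exact zeros: the teacher's "no detectable
# similarity" sentinel E-values must not create dense rows.
.transfer_floor <- 1e-12

#' Exponential transfer from E-values to similarity weights
#'
#' Converts a teacher E-value to a connectivity weight `exp(-evalue / sigma)`.
#' Large E-values (including "no hit" sentinels) decay to zero; weights below
#' `1e-12` are treated as exactly zero by the sparse feature matrix.
#'
#' @param evalue Non-negative E-value(s).
#' @param sigma Positive transfer width; larger values keep weaker hits.
#' @return Weights in `[0, 1]`, vectorised over `evalue`.
#' @export
transfer_evalue <- function(evalue, sigma = 100) {
  if (!is.numeric(evalue) || any(evalue < 0)) {
    stop("evalue must be non-negative")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  exp(-evalue / sigma)
}

#' Build the sparse feature matrix from teacher hits
#'
#' Row `i` of the result is the feature vector of database protein `i`: its
#' transformed similarity profile against every database protein. Entry
#' `(i, j)` is `exp(-E(i, j) / sigma)` for reported hits and exactly zero
#' otherwise. With `normalize = TRUE` (default) every non-empty row is scaled
#' to sum to one, so the matrix is the transition matrix of a random walk on
#' the protein similarity network. Duplicate `(query, target)` hits keep the
#' smallest E-value.
#'
#' @param hits Hits data frame (see [read_hits()]).
#' @param ids Character vector of database identifiers fixing row/column order.
#' @param sigma Transfer width passed to [transfer_evalue()].
#' @param normalize Row-stochastic normalization flag.
#' @return An object of class `"feature_matrix"`: a list with elements
#'   `matrix` (a [Matrix::sparseMatrix()] with `ids` as dimnames), `ids`,
#'   `sigma` and `normalized`.
#' @export
build_feature_matrix <- function(hits, ids, sigma = 100, normalize = TRUE) {
  stopifnot(is.character(ids), !anyDuplicated(ids))
  n <- length(ids)
  i <- match(hits$query_id, ids)
  j <- match(hits$target_id, ids)
  if (anyNA(i)) stop("unknown query id: ", hits$query_id[which(is.na(i))[1L]])
  if (anyNA(j)) stop("unknown target id: ", hits$target_id[which(is.na(j))[1L]])
  if (nrow(hits)) {
    # best (smallest) E-value wins on duplicate pairs
    key <- (i - 1) * as.double(n) + j
    o <- order(key, hits$evalue)
    keep <- o[!duplicated(key[o])]
    i <- i[keep]
    j <- j[keep]
    w <- transfer_evalue(hits$evalue[keep], sigma)
    nz <- w >= .transfer_floor
    i <- i[nz]
    j <- j[nz]
    w <- w[nz]
  } else {
    w <- numeric(0)
  }
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = w, dims = c(n, n), dimnames = list(ids, ids)
  )
  if (normalize) {
    rs <- Matrix::rowSums(m)
    scale <- ifelse(rs > 0, 1 / rs, 0)
    m <- Matrix::Diagonal(n, scale) %*% m
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(ids, ids)
  }
  structure(
    list(matrix = m, ids = ids, sigma = sigma, normalized = normalize),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  nnz <- length(x$matrix@x)
  n <- length(x$ids)
  cat(
    "Sparse teacher feature matrix: ", n, " x ", n, " proteins, ",
    nnz, " stored weights (density ",
    signif(nnz / max(1, n)^2, 3), ")\n",
    "  sigma = ", x$sigma, ", row-stochastic = ", x$normalized, "\n",
    sep = ""
  )
  invisible(x)
}

#' Feature vectors for query proteins absent from the database
#'
#' Builds sparse query-by-database feature rows from the queries' teacher
#' hits against the database, using the same transfer and normalization as
#' the database feature matrix. The database axis (`db_ids`) never changes:
#' unseen queries are represented in the same n-dimensional feature space.
#'
#' @param hits Hits of the queries against the database.
#' @param query_ids Identifiers of the query proteins (row order).
#' @param db_ids Database identifiers (column order; the feature axes).
#' @param sigma,normalize As in [build_feature_matrix()].
#' @return A sparse matrix with one row per query.
#' @export
query_features <- function(hits, query_ids, db_ids, sigma = 100,
                           normalize = TRUE) {
  stopifnot(!anyDuplicated(query_ids), !anyDuplicated(db_ids))
  i <- match(hits$query_id, query_ids)
  j <- match(hits$target_id, db_ids)
  if (anyNA(i)) stop("unknown query id: ", hits$query_id[which(is.na(i))[1L]])
  if (anyNA(j)) stop("unknown target id: ", hits$target_id[which(is.na(j))[1L]])
  nq <- length(query_ids)
  n <- length(db_ids)
  if (nrow(hits)) {
    key <- (i - 1) * as.double(n) + j
    o <- order(key, hits$evalue)
    keep <- o[!duplicated(key[o])]
    i <- i[keep]
    j <- j[keep]
    w <- transfer_evalue(hits$evalue[keep], sigma)
    nz <- w >= .transfer_floor
    i <- i[nz]
    j <- j[nz]
    w <- w[nz]
  } else {
    w <- numeric(0)
  }
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = w, dims = c(nq, n), dimnames = list(query_ids, db_ids)
  )
  if (normalize) {
    rs <- Matrix::rowSums(m)
    scale <- ifelse(rs > 0, 1 / rs, 0)
    m <- methods::as(Matrix::Diagonal(nq, scale) %*% m, "CsparseMatrix")
    dimnames(m) <- list(query_ids, db_ids)
  }
  m
}
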