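# Self-contained synthetic benchmark: a SCOP-like hierarchy of sequence
# families, a simulated pairwise-search teacher, and structural labels and
# scores, so the whole method is testable without external databases.

#' Configuration of the synthetic benchmark
#'
#' The generator emulates the statistical structure the method assumes:
#' a fold/superfamily/family hierarchy of substitution-mutated sequences,
#' and a noisy teacher whose log E-values are tiered by relationship
#' (family pairs strongest, superfamily pairs weaker, unrelated pairs
#' mostly undetected — the sparsity real search programs produce).
#' Structural scores are high within superfamilies and low across folds,
#' mirroring structure-alignment score behaviour around the conventional
#' 2.0 similarity cutoff.
#'
#' @param n_folds,superfamilies_per_fold,families_per_superfamily,members_per_family
#'   Hierarchy shape; defaults give 4 x 2 x 2 x 6 = 96 sequences.
#' @param seq_length Ancestral length range (uniform integer draw).
#' @param family_mutation Per-residue substitution rate from the
#'   superfamily ancestor to each family ancestor.
#' @param member_mutation Per-residue substitution rate from the family
#'   ancestor to each member.
#' @param teacher Per-tier teacher noise: `detect` (probability a hit is
#'   reported), `mu` and `sd` of log10 E-value, for tiers `family`,
#'   `superfamily` (same superfamily, different family) and `unrelated`
#'   (different superfamily, including same fold).
#' @param struct Per-tier mean/sd of the structural similarity score, for
#'   tiers `superfamily`, `fold` (same fold, different superfamily) and
#'   `unrelated`.
#' @param seed Seed making the whole fixture deterministic.
#' @return A list of class `"fixture_config"`.
#' @export
fixture_config <- function(n_folds = 4L, superfamilies_per_fold = 2L,
                           families_per_superfamily = 2L,
                           members_per_family = 6L,
                           seq_length = c(80L, 120L),
                           family_mutation = 0.30,
                           member_mutation = 0.10,
                           teacher = list(
                             family = list(detect = 0.95, mu = -20, sd = 3),
                             superfamily = list(detect = 0.85, mu = -8,
                                                sd = 3),
                             unrelated = list(detect = 0.04, mu = 1,
                                              sd = 0.8)
                           ),
                           struct = list(
                             superfamily = c(mean = 4.0, sd = 1.0),
                             fold = c(mean = 1.5, sd = 0.7),
                             unrelated = c(mean = 0.4, sd = 0.4)
                           ),
                           seed = 1L) {
  stopifnot(
    n_folds >= 1, superfamilies_per_fold >= 1,
    families_per_superfamily >= 1, members_per_family >= 1,
    length(seq_length) == 2L, seq_length[[1L]] <= seq_length[[2L]],
    teacher$family$mu < teacher$unrelated$mu
  )
  structure(
    list(
      n_folds = as.integer(n_folds),
      superfamilies_per_fold = as.integer(superfamilies_per_fold),
      families_per_superfamily = as.integer(families_per_superfamily),
      members_per_family = as.integer(members_per_family),
      seq_length = as.integer(seq_length),
      family_mutation = family_mutation,
      member_mutation = member_mutation,
      teacher = teacher, struct = struct, seed = as.integer(seed)
    ),
    class = "fixture_config"
  )
}

# substitution-only mutation with uniform replacement
.mutate_seq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- .aa_alphabet[sample.int(20L, sum(hit), replace = TRUE)]
  chars
}

#' Generate the synthetic benchmark
#'
#' Deterministically (from `config$seed`) generates sequences, category
#' labels, all-vs-all teacher hits, and structural similarity scores.
#' Each superfamily gets an independent random ancestral sequence; family
#' ancestors are mutated copies and members mutated copies of those — so
#' sequence similarity tracks the hierarchy. Teacher E-values are sampled
#' log-normally per relationship tier, with unrelated pairs reported only
#' with small probability; self-hits are reported at E = 0. Structural
#' scores are emitted for every unordered pair.
#'
#' @param config A [fixture_config()].
#' @return List with `sequences` (data frame), `labels`, `hits`,
#'   `struct_scores` and the `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  cls_letters <- rep(letters, length.out = config$n_folds)

  ids <- character(0)
  fold <- character(0)
  sf <- character(0)
  fam <- character(0)
  seqs <- character(0)
  idx <- 0L
  for (f in seq_len(config$n_folds)) {
    fold_id <- sprintf("%s.%d", cls_letters[[f]], f)
    for (s in seq_len(config$superfamilies_per_fold)) {
      sf_id <- sprintf("%s.%d", fold_id, s)
      len <- config$seq_length[[1L]] +
        sample.int(diff(config$seq_length) + 1L, 1L) - 1L
      ancestor <- .aa_alphabet[sample.int(20L, len, replace = TRUE)]
      for (m in seq_len(config$families_per_superfamily)) {
        fam_id <- sprintf("%s.%d", sf_id, m)
        fam_anc <- .mutate_seq(ancestor, config$family_mutation)
        for (k in seq_len(config$members_per_family)) {
          idx <- idx + 1L
          ids <- c(ids, sprintf("p%03d", idx))
          fold <- c(fold, fold_id)
          sf <- c(sf, sf_id)
          fam <- c(fam, fam_id)
          seqs <- c(seqs, paste0(
            .mutate_seq(fam_anc, config$member_mutation),
            collapse = ""
          ))
        }
      }
    }
  }
  sequences <- data.frame(
    id = ids, sequence = seqs, length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  labels <- data.frame(
    id = ids, fold = fold, superfamily = sf, family = fam,
    stringsAsFactors = FALSE
  )

  n <- length(ids)
  pair <- expand.grid(i = seq_len(n), j = seq_len(n))
  pair <- pair[pair$i != pair$j, , drop = FALSE]
  tier <- ifelse(
    fam[pair$i] == fam[pair$j], "family",
    ifelse(sf[pair$i] == sf[pair$j], "superfamily", "unrelated")
  )
  tp <- config$teacher
  detect <- c(
    family = tp$family$detect, superfamily = tp$superfamily$detect,
    unrelated = tp$unrelated$detect
  )[tier]
  mu <- c(
    family = tp$family$mu, superfamily = tp$superfamily$mu,
    unrelated = tp$unrelated$mu
  )[tier]
  sd <- c(
    family = tp$family$sd, superfamily = tp$superfamily$sd,
    unrelated = tp$unrelated$sd
  )[tier]
  reported <- stats::runif(nrow(pair)) < detect
  evalue <- 10^stats::rnorm(nrow(pair), mu, sd)
  hits <- data.frame(
    query_id = ids[pair$i[reported]],
    target_id = ids[pair$j[reported]],
    evalue = evalue[reported],
    stringsAsFactors = FALSE
  )
  hits <- rbind(
    data.frame(
      query_id = ids, target_id = ids, evalue = 0,
      stringsAsFactors = FALSE
    ),
    hits
  )

  up <- expand.grid(i = seq_len(n), j = seq_len(n))
  up <- up[up$i < up$j, , drop = FALSE]
  stier <- ifelse(
    sf[up$i] == sf[up$j], "superfamily",
    ifelse(fold[up$i] == fold[up$j], "fold", "unrelated")
  )
  sp <- config$struct
  smean <- c(
    superfamily = sp$superfamily[["mean"]], fold = sp$fold[["mean"]],
    unrelated = sp$unrelated[["mean"]]
  )[stier]
  ssd <- c(
    superfamily = sp$superfamily[["sd"]], fold = sp$fold[["sd"]],
    unrelated = sp$unrelated[["sd"]]
  )[stier]
  struct_scores <- data.frame(
    id_a = ids[up$i], id_b = ids[up$j],
    score = pmax(0, stats::rnorm(nrow(up), smean, ssd)),
    stringsAsFactors = FALSE
  )

  list(
    sequences = sequences, labels = labels, hits = hits,
    struct_scores = struct_scores, config = config
  )
}

#' Write a fixture to disk in the package's canonical formats
#'
#' FASTA sequences, 3-column teacher hits TSV, 4-column labels TSV and
#' 3-column structural scores TSV.
#'
#' @param fixture Result of [generate_fixture()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fixture$sequences, file.path(dir, "sequences.fasta"))
  write_hits(fixture$hits, file.path(dir, "hits.tsv"))
  utils::write.table(
    fixture$labels, file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  utils::write.table(
    fixture$struct_scores, file.path(dir, "struct.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(dir)
}

#' Split a fixture into training database and held-out test queries
#'
#' Test queries are sampled at random, subject to every test query keeping
#' at least one same-superfamily target in the training set (otherwise its
#' retrieval score would be undefined). Test sequences are excluded
#' entirely from the training database.
#'
#' @param fixture Result of [generate_fixture()].
#' @param n_test Number of held-out queries.
#' @param seed Seed for the split.
#' @return List with character vectors `train` and `test`.
#' @export
holdout_split <- function(fixture, n_test = 20L, seed = 1L) {
  ids <- fixture$sequences$id
  sf <- fixture$labels$superfamily[match(ids, fixture$labels$id)]
  if (n_test >= length(ids)) stop("n_test must be smaller than the database")
  set.seed(seed)
  if (n_test == 0L) {
    return(list(train = ids, test = character(0)))
  }
  for (attempt in seq_len(1000L)) {
    test <- sample(ids, n_test)
    train <- setdiff(ids, test)
    ok <- vapply(test, function(q) {
      any(sf[match(train, ids)] == sf[match(q, ids)])
    }, logical(1))
    if (all(ok)) {
      return(list(train = train, test = test))
    }
  }
  stop("could not stratify the split: a test query would lose all ",
       "same-superfamily training targets")
}

#' Synthetic teacher for decoy queries
#'
#' Returns a function that scores decoy sequences against the database the
#' way the fixture's teacher scores unrelated pairs: each (decoy, target)
#' pair is reported with the unrelated-tier detection probability and a
#' log-normal E-value. Used to calibrate the null (see
#' [calibrate_null()]); uses the caller's RNG state.
#'
#' @param db_ids Database identifiers.
#' @param teacher Teacher noise parameters (the `teacher` element of a
#'   [fixture_config()]).
#' @return A function mapping a decoy sequence data frame to a hits data
#'   frame.
#' @export
make_decoy_teacher <- function(db_ids, teacher = fixture_config()$teacher) {
  force(db_ids)
  un <- teacher$unrelated
  function(decoys) {
    m <- nrow(decoys)
    n <- length(db_ids)
    reported <- stats::runif(m * n) < un$detect
    evalue <- 10^stats::rnorm(m * n, un$mu, un$sd)
    pair_q <- rep(decoys$id, each = n)
    pair_t <- rep(db_ids, times = m)
    data.frame(
      query_id = pair_q[reported], target_id = pair_t[reported],
      evalue = evalue[reported], stringsAsFactors = FALSE
    )
  }
}
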