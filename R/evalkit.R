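#' Cosine similarity between two vectors
#'
#' `dot(a, b) / (||a|| * ||b||)`, in `[-1, 1]` up to rounding.
#'
#' @param a,b Numeric vectors of equal length; neither all-zero.
#' @return Numeric scalar.
#' @examples
#' cosine_similarity(c(1, 0), c(1, 0))  # 1
#' cosine_similarity(c(1, 1), c(1, 0))  # 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("cosine_similarity: dimension mismatch (", length(a), " vs ",
         length(b), ")")
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop("cosine_similarity: undefined for zero-norm input")
  sum(a * b) / (na * nb)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive their mean
#' rank).
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Numeric scalar in `[-1, 1]`.
#' @examples
#' spearman_correlation(1:3, c(10, 20, 30))  #  1
#' spearman_correlation(1:3, c(30, 20, 10))  # -1
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_correlation: unequal lengths")
  if (length(x) < 3L) stop("spearman_correlation: need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("spearman_correlation: NA input")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("spearman_correlation: undefined for constant input")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2 * precision * recall / (precision + recall)`. A metric whose
#' denominator is zero is `NA` and propagates to `f1`.
#'
#' @param tp,fp,fn Non-negative integer counts of true positives, false
#'   positives and false negatives.
#' @return List with `precision`, `recall`, `f1` (each numeric or `NA`).
#' @examples
#' precision_recall_f1(3, 1, 2)  # 0.75, 0.6, 2/3
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("confusion counts must be non-negative")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' Read a term-pair similarity dataset
#'
#' Delimited text with two term columns and a numeric human score column.
#' The delimiter defaults to tab when the first line contains one, comma
#' otherwise. A header row is skipped automatically when its score cell is
#' non-numeric. Malformed rows are skipped with a message giving the count.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects.
#' @param columns Integer positions of term1, term2 and score; default
#'   `c(1, 2, 3)`.
#' @return Data frame with columns `term1`, `term2`, `human_score`.
#' @export
read_term_pairs <- function(path, sep = NULL, columns = c(1L, 2L, 3L)) {
  stopifnot(length(columns) == 3L)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no parsable rows in ", path)
  if (is.null(sep)) sep <- if (grepl("\t", lines[1L])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  parse_row <- function(p) {
    if (length(p) < max(columns)) return(NULL)
    score <- suppressWarnings(as.numeric(trimws(p[columns[3L]])))
    t1 <- trimws(p[columns[1L]]); t2 <- trimws(p[columns[2L]])
    if (is.na(score) || !nzchar(t1) || !nzchar(t2)) return(NULL)
    data.frame(term1 = t1, term2 = t2, human_score = score,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(parts, parse_row)
  header_skipped <- FALSE
  if (is.null(rows[[1L]]) && length(parts[[1L]]) >= max(columns)) {
    rows <- rows[-1L]  # header row: score cell non-numeric
    header_skipped <- TRUE
  }
  bad <- sum(vapply(rows, is.null, TRUE))
  if (bad > 0L)
    message("read_term_pairs: skipped ", bad, " malformed row(s) in ", path)
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no parsable rows in ", path)
  do.call(rbind, rows)
}

#' Evaluate an embedding on a term-pair benchmark
#'
#' Encodes both terms of every pair with [encode_term()]; a pair is covered
#' iff both terms resolve to a vector. Model similarity is the cosine between
#' the two vectors; the Spearman correlation is computed between human scores
#' and model similarities over covered pairs only (unresolved pairs are
#' excluded rather than zero-filled, since zero vectors would corrupt the
#' cosine).
#'
#' @param pairs Data frame with columns `term1`, `term2`, `human_score`
#'   (see [read_term_pairs()]).
#' @inheritParams encode_token
#' @return An `eval_report`: `n_total`, `n_covered`, `coverage_pct`,
#'   `spearman` (`NA` when fewer than 3 covered pairs or constant input), and
#'   `per_pair` (the input plus `model_similarity` and `covered` columns).
#' @export
evaluate_pairs <- function(pairs, emb, lexicon = NULL, seg = NULL,
                           stages = stage_order) {
  stopifnot(is.data.frame(pairs),
            all(c("term1", "term2", "human_score") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("evaluate_pairs: empty pair list")
  sim <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    e1 <- encode_term(pairs$term1[i], emb, lexicon, seg, stages)
    e2 <- encode_term(pairs$term2[i], emb, lexicon, seg, stages)
    if (!is.null(e1$vector) && !is.null(e2$vector))
      sim[i] <- cosine_similarity(e1$vector, e2$vector)
  }
  covered <- !is.na(sim)
  n_total <- nrow(pairs)
  n_covered <- sum(covered)
  sp <- NA_real_
  if (n_covered >= 3L &&
      stats::var(pairs$human_score[covered]) > 0 && stats::var(sim[covered]) > 0)
    sp <- spearman_correlation(pairs$human_score[covered], sim[covered])
  per_pair <- pairs
  per_pair$model_similarity <- sim
  per_pair$covered <- covered
  structure(list(n_total = n_total, n_covered = n_covered,
                 coverage_pct = 100 * n_covered / n_total,
                 spearman = sp, per_pair = per_pair),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("pairs: %d covered of %d (%.1f%%); Spearman: %s\n",
              x$n_covered, x$n_total, x$coverage_pct,
              if (is.na(x$spearman)) "NA" else sprintf("%.3f", x$spearman)))
  invisible(x)
}

#' Token-level coverage and provenance histogram
#'
#' Encodes each token with [encode_token()] and tabulates the stage that
#' resolved it.
#'
#' @param tokens Character vector of tokens.
#' @inheritParams encode_token
#' @return List with `n_total`, `n_covered`, `coverage_pct` and `provenance`
#'   (named integer vector over direct/inflection/parser/segmenter/
#'   unresolved).
#' @export
token_coverage <- function(tokens, emb, lexicon = NULL, seg = NULL,
                           stages = stage_order) {
  if (length(tokens) == 0L) stop("token_coverage: empty token list")
  provs <- vapply(tokens, function(tok)
    encode_token(tok, emb, lexicon, seg, stages)$provenance, "")
  levels <- c(stage_order, "unresolved")
  counts <- vapply(levels, function(l) sum(provs == l), 0L)
  n_covered <- sum(counts[stage_order])
  list(n_total = length(tokens), n_covered = n_covered,
       coverage_pct = 100 * n_covered / length(tokens),
       provenance = counts)
}
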