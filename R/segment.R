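affix_units <- c("ness", "less", "ful", "ing", "ed", "er", "s")

#' Construct a unigram segmenter model
#'
#' Low-level constructor taking a ready-made unit log-probability table; use
#' [train_segmenter()] to build one from a word list. Accepting an external
#' table makes the model an adapter point for any pre-trained unigram
#' segmenter with the same contract.
#'
#' @param unit_log_prob Named numeric vector: unit string -> non-positive log
#'   probability.
#' @param min_unit_len Minimum unit length considered by [segment_term()];
#'   default 1.
#' @param unknown_penalty Positive per-character score penalty for units not
#'   in the table; default 10.
#' @return An object of class `segmenter_model`.
#' @export
segmenter_model <- function(unit_log_prob, min_unit_len = 1L,
                            unknown_penalty = 10) {
  if (length(unit_log_prob) == 0L || is.null(names(unit_log_prob)) ||
      any(!nzchar(names(unit_log_prob))))
    stop("unit_log_prob must be a non-empty named numeric vector")
  if (any(unit_log_prob > 0))
    stop("unit log probabilities must be non-positive")
  if (min_unit_len < 1L) stop("min_unit_len must be >= 1")
  if (unknown_penalty <= 0) stop("unknown_penalty must be positive")
  structure(list(unit_log_prob = unit_log_prob,
                 min_unit_len = as.integer(min_unit_len),
                 unknown_penalty = unknown_penalty),
            class = "segmenter_model")
}

#' Train the unigram subword segmenter
#'
#' Builds unit log probabilities from the relative frequencies of the words in
#' a training list, plus a closed set of English affix units
#' (`ness, less, ful, ing, ed, er, s`) with pseudo-count 1 each. Duplicate
#' words are aggregated by summing counts; the result is independent of input
#' order.
#'
#' @param words Character vector of training words, or a data frame with
#'   columns `word` and `count`.
#' @param counts Optional numeric vector of counts matching `words`; default
#'   all 1.
#' @inheritParams segmenter_model
#' @return A `segmenter_model`.
#' @examples
#' m <- train_segmenter(c("sea", "sick"), counts = c(5, 5))
#' segment_term("seasickness", m)  # "sea" "sick" "ness"
#' @export
train_segmenter <- function(words, counts = NULL, min_unit_len = 1L,
                            unknown_penalty = 10) {
  if (is.data.frame(words)) {
    if (!all(c("word", "count") %in% names(words)))
      stop("data-frame input needs columns 'word' and 'count'")
    counts <- words$count
    words <- words$word
  }
  if (length(words) == 0L) stop("empty training word list")
  if (is.null(counts)) counts <- rep(1, length(words))
  if (length(counts) != length(words) || any(counts < 1))
    stop("counts must match words and be >= 1")
  words <- tolower(trimws(words))
  tab <- tapply(counts, words, sum)
  units <- stats::setNames(as.numeric(tab), names(tab))
  for (af in affix_units)
    units[af] <- if (is.na(units[af])) 1 else units[af] + 1
  segmenter_model(log(units / sum(units)), min_unit_len, unknown_penalty)
}

#' Read a segmenter training word list from a file
#'
#' Two-column TSV (`word`, `count`) with or without header; a plain
#' word-per-line file is accepted with every count 1.
#'
#' @param path File path.
#' @return Data frame with columns `word` and `count`.
#' @export
read_word_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty word list file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  word <- vapply(parts, `[[`, "", 1L)
  count <- vapply(parts, function(p)
    if (length(p) >= 2L) suppressWarnings(as.numeric(p[2L])) else 1, 0)
  header <- tolower(word[1L]) == "word" && is.na(count[1L])
  if (header) { word <- word[-1L]; count <- count[-1L] }
  count[is.na(count)] <- 1
  data.frame(word = tolower(trimws(word)), count = count,
             stringsAsFactors = FALSE)
}

unit_score <- function(unit, model) {
  lp <- model$unit_log_prob[unit]
  if (is.na(lp)) -model$unknown_penalty * nchar(unit) else as.numeric(lp)
}

#' Segment a term into subword units
#'
#' Maximum-log-probability segmentation of `term` into units (Viterbi over cut
#' positions). A known unit scores its log probability; an unknown unit scores
#' `-unknown_penalty * nchar(unit)`. Ties are broken by fewer units, then by
#' the leftmost-longest unit. Always returns a non-empty unit list whose
#' concatenation is the input (worst case the whole term as one unknown unit).
#'
#' @param term Lowercase alphabetic string, length >= 1.
#' @param model A `segmenter_model`.
#' @return Character vector of units.
#' @examples
#' m <- train_segmenter(c("sea", "sick"), counts = c(5, 5))
#' segment_term("seasickness", m)  # "sea" "sick" "ness"
#' segment_term("qqqq", m)         # "qqqq"
#' @export
segment_term <- function(term, model) {
  stopifnot(inherits(model, "segmenter_model"))
  if (length(term) != 1L || is.na(term) || !grepl("^[a-z]+$", term))
    stop("segment_term expects a lowercase alphabetic term, got: ",
         deparse(term))
  n <- nchar(term)
  # best[i]: optimal segmentation of term[i..n]; filled right to left
  best <- vector("list", n + 1L)
  best[[n + 1L]] <- list(score = 0, n_units = 0L, units = character())
  for (i in n:1) {
    chosen <- NULL
    max_len <- n - i + 1L
    lengths_desc <- if (max_len >= model$min_unit_len)
      seq(max_len, model$min_unit_len) else integer()
    for (L in lengths_desc) {
      unit <- substr(term, i, i + L - 1L)
      tail <- best[[i + L]]
      if (is.null(tail)) next
      cand <- list(score = unit_score(unit, model) + tail$score,
                   n_units = 1L + tail$n_units,
                   units = c(unit, tail$units))
      if (is.null(chosen) ||
          cand$score > chosen$score + 1e-12 ||
          (abs(cand$score - chosen$score) <= 1e-12 &&
           (cand$n_units < chosen$n_units ||
            (cand$n_units == chosen$n_units &&
             nchar(cand$units[1L]) > nchar(chosen$units[1L])))))
        chosen <- cand
    }
    if (is.null(chosen))  # term shorter than min_unit_len: one unknown unit
      chosen <- list(score = unit_score(substr(term, i, n), model),
                     n_units = 1L, units = substr(term, i, n))
    best[[i]] <- chosen
  }
  best[[1L]]$units
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf("<segmenter_model: %d units, unknown penalty %g/char>\n",
              length(x$unit_log_prob), x$unknown_penalty))
  invisible(x)
}
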