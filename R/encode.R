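#' Construct an embedding source from a word-by-dimension matrix
#'
#' An `embedding_source` wraps a numeric matrix whose rownames are the
#' vocabulary; lookups are deterministic and every vector shares one
#' dimension.
#'
#' @param vectors Numeric matrix, one row per word, rownames = words.
#' @return An object of class `embedding_source`.
#' @seealso [read_word2vec_text()], [emb_lookup()]
#' @export
embedding_source <- function(vectors) {
  if (!is.matrix(vectors) || !is.numeric(vectors) || nrow(vectors) == 0L)
    stop("vectors must be a non-empty numeric matrix")
  if (is.null(rownames(vectors)) || any(!nzchar(rownames(vectors))))
    stop("vectors must have non-empty rownames (the vocabulary)")
  if (any(!is.finite(vectors)))
    stop("embedding vectors must be finite")
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "embedding_source")
}

#' @rdname embedding_source
#' @param emb An `embedding_source`.
#' @export
emb_vocab <- function(emb) rownames(emb$vectors)

#' @rdname embedding_source
#' @export
emb_dim <- function(emb) emb$dim

#' @rdname embedding_source
#' @param word Single word to look up (exact surface form).
#' @return `emb_lookup` returns the word's numeric vector, or `NULL` on a
#'   miss.
#' @export
emb_lookup <- function(emb, word) {
  i <- match(word, rownames(emb$vectors))
  if (is.na(i)) NULL else emb$vectors[i, ]
}

#' @export
print.embedding_source <- function(x, ...) {
  cat(sprintf("<embedding_source: %d words, dimension %d>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Read a word2vec text-format embedding file
#'
#' One token plus `dim` whitespace-separated floats per line, with or without
#' the optional `count dim` header line. The dimension is inferred from the
#' first data row and enforced on every other row.
#'
#' @param path File path.
#' @return An `embedding_source`.
#' @export
read_word2vec_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty embedding file: ", path)
  first <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  offset <- 0L
  if (length(first) == 2L &&
      !any(is.na(suppressWarnings(as.numeric(first))))) {
    offset <- 1L
    lines <- lines[-1L]
    if (length(lines) == 0L) stop("embedding file has header but no rows: ",
                                  path)
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  dim <- length(parts[[1L]]) - 1L
  if (dim < 1L) stop("embedding file '", path, "': line ", offset + 1L,
                     " has no vector values")
  words <- character(length(parts))
  mat <- matrix(NA_real_, nrow = length(parts), ncol = dim)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) - 1L != dim)
      stop("embedding file '", path, "': line ", offset + i, " has ",
           length(p) - 1L, " values, expected ", dim)
    vals <- suppressWarnings(as.numeric(p[-1L]))
    if (any(is.na(vals)))
      stop("embedding file '", path, "': line ", offset + i,
           " has non-numeric values")
    words[i] <- p[1L]
    mat[i, ] <- vals
  }
  keep <- !duplicated(words)
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- words[keep]
  embedding_source(mat)
}

#' Write an embedding source in word2vec text format
#'
#' @param emb An `embedding_source`.
#' @param path Output file path.
#' @param header Write the `count dim` header line; default `TRUE`.
#' @return Invisibly, `path`.
#' @export
write_word2vec_text <- function(emb, path, header = TRUE) {
  stopifnot(inherits(emb, "embedding_source"))
  rows <- apply(emb$vectors, 1L, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = " "))
  out <- paste(rownames(emb$vectors), rows)
  if (header) out <- c(paste(nrow(emb$vectors), emb$dim), out)
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Mean vector of a word list under an embedding
#'
#' Element-wise arithmetic mean of the vectors of those words found in the
#' embedding (each word is tried as-is, then normalized with
#' [normalize_token()]). Words missing from the embedding are skipped; `NULL`
#' is returned when no word is found.
#'
#' @param words Non-empty character vector.
#' @param emb An `embedding_source`.
#' @return List with `vector` (numeric vector or `NULL`) and `contributing`
#'   (data frame of `word`, `found`).
#' @examples
#' emb <- embedding_source(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
#'                                dimnames = list(c("a", "b"), NULL)))
#' mean_vector(c("a", "b"), emb)$vector  # 0.5 0.5
#' @export
mean_vector <- function(words, emb) {
  stopifnot(inherits(emb, "embedding_source"))
  if (length(words) == 0L) stop("mean_vector: empty word list")
  vocab <- emb_vocab(emb)
  hits <- lapply(words, function(w) {
    k <- is_known(w, vocab)
    if (k$known) emb_lookup(emb, k$match) else NULL
  })
  found <- !vapply(hits, is.null, TRUE)
  contributing <- data.frame(word = as.character(words), found = found,
                             stringsAsFactors = FALSE)
  if (!any(found)) return(list(vector = NULL, contributing = contributing))
  list(vector = colMeans(do.call(rbind, hits[found])),
       contributing = contributing)
}

stage_order <- c("direct", "inflection", "parser", "segmenter")

check_stages <- function(stages) {
  if (!all(stages %in% stage_order))
    stop("unknown stage(s): ",
         paste(setdiff(stages, stage_order), collapse = ", "))
  if (!"direct" %in% stages) stop("stages must contain 'direct'")
  stage_order[stage_order %in% stages]
}

new_encoded_token <- function(token, vector, provenance, trace,
                              contributing_words = NULL) {
  structure(list(token = token, vector = vector, provenance = provenance,
                 trace = trace, contributing_words = contributing_words),
            class = "encoded_token")
}

#' Encode a single token through the fallback chain
#'
#' Runs the enabled stages in the fixed order direct -> inflection -> parser
#' -> segmenter; the first stage producing a vector sets the provenance and
#' stops. `direct` looks the token up after normalization; `inflection` looks
#' up each singular/plural candidate; `parser` decomposes the term and
#' mean-encodes its meaning words; `segmenter` mean-encodes its subword units.
#' If all enabled stages fail, provenance is `"unresolved"` and the vector is
#' `NULL` (never a random vector).
#'
#' @param token Non-empty string.
#' @param emb An `embedding_source`.
#' @param lexicon A `med_lexicon` (needed for the inflection and parser
#'   stages).
#' @param seg A `segmenter_model`, or `NULL` to leave the segmenter stage with
#'   nothing to run.
#' @param stages Subset of `c("direct", "inflection", "parser", "segmenter")`;
#'   must contain `"direct"`.
#' @return An `encoded_token`: `token`, `vector` (or `NULL`), `provenance`
#'   (one of the stage names or `"unresolved"`), `trace` (stage-by-stage log),
#'   and `contributing_words` (data frame, for parser/segmenter provenance).
#' @examples
#' emb <- embedding_source(matrix(rnorm(4), 2,
#'          dimnames = list(c("painful", "breathing"), NULL)))
#' enc <- encode_token("dyspnea", emb, fixture_lexicon())
#' enc$provenance  # "parser"
#' @export
encode_token <- function(token, emb, lexicon = NULL, seg = NULL,
                         stages = stage_order) {
  stopifnot(inherits(emb, "embedding_source"))
  stages <- check_stages(stages)
  if (length(token) != 1L || is.na(token) || !nzchar(trimws(token)))
    stop("encode_token: empty token")
  trace <- character()
  vocab <- emb_vocab(emb)
  norm <- normalize_token(token)$normalized
  alphabetic <- grepl("^[a-z]+$", norm)

  for (stage in stages) {
    if (stage == "direct") {
      k <- is_known(token, vocab)
      if (k$known) {
        trace <- c(trace, sprintf("direct: hit '%s'", k$match))
        return(new_encoded_token(token, emb_lookup(emb, k$match), "direct",
                                 trace))
      }
      trace <- c(trace, "direct: miss")
    } else if (stage == "inflection") {
      if (is.null(lexicon) || !alphabetic) {
        trace <- c(trace, "inflection: skipped")
        next
      }
      cands <- inflection_candidates(norm, lexicon$inflection_rules)
      hit <- cands[cands %in% vocab]
      if (length(hit) > 0L) {
        trace <- c(trace, sprintf("inflection: hit '%s'", hit[1L]))
        return(new_encoded_token(token, emb_lookup(emb, hit[1L]),
                                 "inflection", trace))
      }
      trace <- c(trace, sprintf("inflection: miss (%d candidate(s))",
                                length(cands)))
    } else if (stage == "parser") {
      if (is.null(lexicon) || !alphabetic) {
        trace <- c(trace, "parser: skipped")
        next
      }
      mw <- term_meanings(norm, lexicon)
      if (is.null(mw)) {
        trace <- c(trace, "parser: no decomposition")
        next
      }
      mv <- mean_vector(mw, emb)
      if (is.null(mv$vector)) {
        trace <- c(trace, "parser: decomposed but no meaning word in embedding")
        next
      }
      trace <- c(trace, sprintf("parser: mean over {%s}",
                                paste(mw, collapse = " ")))
      return(new_encoded_token(token, mv$vector, "parser", trace,
                               mv$contributing))
    } else if (stage == "segmenter") {
      if (is.null(seg) || !alphabetic) {
        trace <- c(trace, "segmenter: skipped")
        next
      }
      units <- segment_term(norm, seg)
      mv <- mean_vector(units, emb)
      if (is.null(mv$vector)) {
        trace <- c(trace, "segmenter: no unit in embedding")
        next
      }
      trace <- c(trace, sprintf("segmenter: mean over {%s}",
                                paste(units, collapse = " ")))
      return(new_encoded_token(token, mv$vector, "segmenter", trace,
                               mv$contributing))
    }
  }
  new_encoded_token(token, NULL, "unresolved", trace)
}

#' Encode a (possibly multi-word) term
#'
#' Single-word terms delegate to [encode_token()]; multi-word terms (split on
#' whitespace) are the element-wise mean of the per-word vectors, excluding
#' words that resolve to nothing. The provenance of a multi-word term is the
#' worst stage used among its resolved words
#' (direct < inflection < parser < segmenter); if no word resolves the term is
#' `"unresolved"`.
#'
#' @inheritParams encode_token
#' @param term Non-empty string; words split on whitespace.
#' @param unresolved_zero When `TRUE`, an unresolved term gets a zero vector
#'   of the embedding's dimension instead of `NULL` (for pipelines that
#'   require a vector for every token); provenance stays `"unresolved"`.
#' @return An `encoded_token`.
#' @examples
#' emb <- embedding_source(matrix(rnorm(4), 2,
#'          dimnames = list(c("painful", "breathing"), NULL)))
#' encode_term("dyspnea", emb, fixture_lexicon())$provenance  # "parser"
#' @export
encode_term <- function(term, emb, lexicon = NULL, seg = NULL,
                        stages = stage_order, unresolved_zero = FALSE) {
  if (length(term) != 1L || is.na(term) || !nzchar(trimws(term)))
    stop("encode_term: empty term")
  words <- strsplit(trimws(term), "[ \t]+")[[1L]]
  toks <- lapply(words, encode_token, emb = emb, lexicon = lexicon,
                 seg = seg, stages = stages)
  if (length(toks) == 1L) {
    out <- toks[[1L]]
  } else {
    vecs <- Filter(Negate(is.null), lapply(toks, `[[`, "vector"))
    trace <- unlist(lapply(seq_along(toks), function(i)
      paste0("[", words[i], "] ", toks[[i]]$trace)), use.names = FALSE)
    provs <- vapply(toks, `[[`, "", "provenance")
    used <- provs[provs != "unresolved"]
    if (length(vecs) == 0L) {
      out <- new_encoded_token(term, NULL, "unresolved", trace)
    } else {
      worst <- stage_order[max(match(used, stage_order))]
      out <- new_encoded_token(term, colMeans(do.call(rbind, vecs)), worst,
                               trace)
    }
  }
  if (unresolved_zero && is.null(out$vector))
    out$vector <- numeric(emb_dim(emb))
  out
}

#' @export
print.encoded_token <- function(x, ...) {
  cat(sprintf("<encoded_token '%s': %s%s>\n", x$token, x$provenance,
              if (is.null(x$vector)) ", no vector"
              else sprintf(", dim %d", length(x$vector))))
  invisible(x)
}
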