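#' Decompose a medical term into prefix/root/suffix components
#'
#' Searches all segmentations of `term` into an optional prefix, zero or more
#' roots (each optionally followed by a combining vowel), and an optional
#' terminal suffix, where every non-vowel segment must be a lexicon form or
#' one of its combining forms. The best complete segmentation is returned:
#' fewest meaning-bearing components first, then longest terminal suffix, then
#' lexicographically earliest component surface tuple. The search is exact
#' (memoized dynamic programming over cut positions), not greedy.
#'
#' A surface present as both prefix and root is labeled prefix when
#' term-initial, root otherwise. Combining vowels carry no meaning words.
#' Non-vowel component surfaces must be at least `min_len` characters long.
#'
#' @param term Lowercase alphabetic string (already normalized).
#' @param lexicon A `med_lexicon`, e.g. [fixture_lexicon()].
#' @param min_len Minimum surface length for non-vowel components; default 2
#'   suppresses spurious single-letter matches.
#' @return An object of class `decomposition` (list with `term`, `components`
#'   data frame of `surface`/`role`/`form`, `meaning_words`, `score`), or
#'   `NULL` when no complete segmentation exists.
#' @examples
#' lex <- fixture_lexicon()
#' decompose_term("dyspnea", lex)$meaning_words      # painful breathing
#' decompose_term("choledocholithiasis", lex)        # choledoch + o + lithiasis
#' decompose_term("zzzz", lex)                       # NULL
#' @export
decompose_term <- function(term, lexicon, min_len = 2L) {
  stopifnot(inherits(lexicon, "med_lexicon"))
  if (length(term) != 1L || is.na(term) || !grepl("^[a-z]+$", term))
    stop("decompose_term expects a lowercase alphabetic term, got: ",
         deparse(term))
  n <- nchar(term)

  # Surface index: surface string -> list of records
  # (kind, entry, split = nchar(form) when the surface is form + vowel tail).
  idx <- new.env(parent = emptyenv())
  add_surface <- function(surface, kind, entry) {
    if (nchar(surface) < min_len) return(invisible())
    split <- if (kind != "suffix" && surface != entry$form &&
                 startsWith(surface, entry$form)) nchar(entry$form) else NA_integer_
    rec <- list(kind = kind, entry = entry, split = split)
    idx[[surface]] <- c(idx[[surface]], list(rec))
    invisible()
  }
  slot_of <- c(prefix = "prefixes", root = "roots", suffix = "suffixes")
  for (kind in names(slot_of))
    for (entry in lexicon[[slot_of[[kind]]]])
      for (surface in unique(c(entry$form, entry$combining_forms)))
        add_surface(surface, kind, entry)
  lens <- sort(unique(nchar(ls(idx))))

  empty_parse <- list(comps = list(), n_comp = 0L, suffix_len = 0L,
                      surfaces = character())
  better <- function(a, b) {
    # TRUE when parse `a` is preferred over `b`
    if (a$n_comp != b$n_comp) return(a$n_comp < b$n_comp)
    if (a$suffix_len != b$suffix_len) return(a$suffix_len > b$suffix_len)
    k <- min(length(a$surfaces), length(b$surfaces))
    for (j in seq_len(k)) {
      if (a$surfaces[j] != b$surfaces[j]) return(a$surfaces[j] < b$surfaces[j])
    }
    length(a$surfaces) < length(b$surfaces)
  }
  prepend <- function(comps, n_comp, suffix_len, tail) {
    list(comps = c(comps, tail$comps),
         n_comp = n_comp + tail$n_comp,
         suffix_len = max(suffix_len, tail$suffix_len),
         surfaces = c(vapply(comps, `[[`, "", "surface"), tail$surfaces))
  }
  comp <- function(surface, role, entry = NULL)
    list(surface = surface, role = role, entry = entry)

  memo <- new.env(parent = emptyenv())
  best <- function(i, ctx) {
    if (i > n) {
      return(if (ctx == "after_comp") empty_parse else NULL)
    }
    key <- paste0(i, ":", ctx)
    if (!is.null(memo[[key]])) {
      cached <- memo[[key]]
      return(if (identical(cached, "none")) NULL else cached)
    }
    found <- NULL
    # explicit combining vowel between components
    ch <- substr(term, i, i)
    if (ctx == "after_comp" && ch %in% lexicon$combining_vowels && i < n) {
      tail <- best(i + 1L, "after_vowel")
      if (!is.null(tail)) {
        cand <- prepend(list(comp(ch, "combining_vowel")), 0L, 0L, tail)
        if (is.null(found) || better(cand, found)) found <- cand
      }
    }
    # prefixes forms claimed at term start, so the same surface is not also
    # tried as a root there (role labeling rule)
    start_prefix_forms <- character()
    for (L in lens) {
      if (i + L - 1L > n) break
      s <- substr(term, i, i + L - 1L)
      recs <- idx[[s]]
      if (is.null(recs)) next
      if (ctx == "start")
        start_prefix_forms <- c(start_prefix_forms,
          vapply(Filter(function(r) r$kind == "prefix", recs),
                 function(r) r$entry$form, ""))
      for (rec in recs) {
        if (rec$kind == "prefix" && ctx != "start") next
        if (rec$kind == "root" && ctx == "start" &&
            rec$entry$form %in% start_prefix_forms) next
        if (rec$kind == "suffix" && i + L - 1L != n) next
        if (!is.na(rec$split)) {
          comps <- list(comp(substr(s, 1L, rec$split), rec$kind, rec$entry),
                        comp(substr(s, rec$split + 1L, L), "combining_vowel"))
          next_ctx <- "after_vowel"
        } else {
          comps <- list(comp(s, rec$kind, rec$entry))
          next_ctx <- "after_comp"
        }
        tail <- best(i + L, next_ctx)
        if (is.null(tail)) next
        suffix_len <- if (rec$kind == "suffix") L else 0L
        cand <- prepend(comps, 1L, suffix_len, tail)
        if (is.null(found) || better(cand, found)) found <- cand
      }
    }
    memo[[key]] <- if (is.null(found)) "none" else found
    found
  }

  res <- best(1L, "start")
  if (is.null(res)) return(NULL)
  surfaces <- vapply(res$comps, `[[`, "", "surface")
  stopifnot(identical(paste(surfaces, collapse = ""), term))
  roles <- vapply(res$comps, `[[`, "", "role")
  forms <- vapply(res$comps, function(cp)
    if (is.null(cp$entry)) cp$surface else cp$entry$form, "")
  meaning_words <- unlist(lapply(res$comps, function(cp)
    if (is.null(cp$entry)) character() else cp$entry$meaning_words),
    use.names = FALSE)
  structure(list(term = term,
                 components = data.frame(surface = surfaces, role = roles,
                                         form = forms,
                                         stringsAsFactors = FALSE),
                 meaning_words = meaning_words,
                 score = res$n_comp),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  parts <- sprintf("%s(%s)", x$components$surface,
                   ifelse(x$components$role == "combining_vowel", "o",
                          x$components$role))
  cat(sprintf("%s = %s -> %s\n", x$term, paste(parts, collapse = " + "),
              paste(x$meaning_words, collapse = " ")))
  invisible(x)
}

#' Meaning words of a term via decomposition
#'
#' Convenience wrapper: [decompose_term()] then the flattened meaning-word
#' list; `NULL` propagates when the term has no complete decomposition.
#'
#' @inheritParams decompose_term
#' @param drop_stopwords Drop the function words `of`, `or`, `a`, `the` from
#'   the meaning list before returning; off by default (the flattened meaning
#'   phrases keep their function words).
#' @return Character vector of meaning words, or `NULL`.
#' @examples
#' lex <- fixture_lexicon()
#' term_meanings("mastodynia", lex)       # breast pain discomfort
#' term_meanings("arteriosclerosis", lex) # artery hardening
#' @export
term_meanings <- function(term, lexicon, min_len = 2L,
                          drop_stopwords = FALSE) {
  d <- decompose_term(term, lexicon, min_len = min_len)
  if (is.null(d)) return(NULL)
  mw <- d$meaning_words
  if (drop_stopwords) mw <- mw[!mw %in% c("of", "or", "a", "the")]
  mw
}
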