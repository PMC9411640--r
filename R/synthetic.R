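# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for the synthetic-data generators
#'
#' @param n_terms Number of terms (or pairs) to generate; > 0.
#' @param max_components Maximum number of meaning-bearing components per
#'   term, in `[1, 3]`; at least 2 components are needed for a term that is
#'   not itself a lexicon form, so `max_components = 1` is rejected by the
#'   generators.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, lexicon).
#' @param embedding_dim Dimension of toy embedding vectors; default 50.
#' @param noise_sd Standard deviation of Gaussian noise added to synthetic
#'   human scores; 0 gives scores identical to the ground-truth cosines.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_terms, max_components = 3L, seed = 1L,
                         embedding_dim = 50L, noise_sd = 0) {
  if (n_terms < 1L) stop("n_terms must be > 0")
  if (max_components < 1L || max_components > 3L)
    stop("max_components must be in [1, 3]")
  if (embedding_dim < 1L) stop("embedding_dim must be > 0")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_terms = as.integer(n_terms),
                 max_components = as.integer(max_components),
                 seed = as.integer(seed),
                 embedding_dim = as.integer(embedding_dim),
                 noise_sd = noise_sd),
            class = "synth_config")
}

# Join components into a surface term: a combining vowel "o" goes after a
# root when the next component starts with a consonant; prefixes attach bare.
join_components <- function(forms, roles, vowel = "o") {
  out <- character()
  for (i in seq_along(forms)) {
    out <- c(out, forms[i])
    if (i < length(forms) && roles[i] == "root" &&
        !substr(forms[i + 1L], 1L, 1L) %in% c("a", "e", "i", "o", "u"))
      out <- c(out, vowel)
  }
  paste(out, collapse = "")
}

#' Generate synthetic compound medical terms
#'
#' Seeded pseudo-random sampling of component tuples (optional prefix, roots
#' with combining vowels, optional terminal suffix; 2 to `max_components`
#' meaning-bearing components), concatenated into terms and paired with the
#' concatenated meaning-word lists. Generated terms never collide with a
#' lexicon form or a meaning word (they are genuinely out of vocabulary for a
#' meaning-word embedding), and only terms whose canonical
#' [decompose_term()] meaning list equals the generating components' list are
#' kept, so the expected meanings are a well-defined ground truth.
#' Deterministic per seed.
#'
#' @param cfg A [synth_config()].
#' @param lexicon A `med_lexicon` non-empty in all three kinds.
#' @return A list of class `synth_terms` with `term` (character vector) and
#'   `meaning_words` (list of character vectors, parallel to `term`).
#' @examples
#' terms <- generate_terms(synth_config(5, seed = 42), fixture_lexicon())
#' terms$term
#' @export
generate_terms <- function(cfg, lexicon) {
  stopifnot(inherits(cfg, "synth_config"), inherits(lexicon, "med_lexicon"))
  if (length(lexicon$prefixes) == 0L || length(lexicon$roots) == 0L ||
      length(lexicon$suffixes) == 0L)
    stop("generate_terms needs prefixes, roots and suffixes in the lexicon")
  if (cfg$max_components < 2L)
    stop("impossible config: single-component terms are lexicon forms, ",
         "max_components must be >= 2")
  all_forms <- unlist(lapply(c(lexicon$prefixes, lexicon$roots,
                               lexicon$suffixes),
                             function(e) c(e$form, e$combining_forms)),
                      use.names = FALSE)
  all_meanings <- unlist(lapply(c(lexicon$prefixes, lexicon$roots,
                                  lexicon$suffixes),
                                function(e) e$meaning_words),
                         use.names = FALSE)
  forbidden <- unique(c(all_forms, all_meanings))
  vowel <- lexicon$combining_vowels[1L]

  with_local_seed(cfg$seed, {
    terms <- character()
    meanings <- list()
    attempts <- 0L
    max_attempts <- cfg$n_terms * 500L
    while (length(terms) < cfg$n_terms && attempts < max_attempts) {
      attempts <- attempts + 1L
      k <- if (cfg$max_components == 2L) 2L else sample(2:cfg$max_components, 1L)
      has_prefix <- stats::runif(1) < 0.4
      has_suffix <- stats::runif(1) < 0.8
      n_roots <- k - has_prefix - has_suffix
      if (n_roots < 0L) next
      entries <- list()
      if (has_prefix)
        entries <- c(entries, lexicon$prefixes[sample(length(lexicon$prefixes), 1L)])
      if (n_roots > 0L)
        entries <- c(entries,
                     lexicon$roots[sample(length(lexicon$roots), n_roots,
                                          replace = TRUE)])
      if (has_suffix)
        entries <- c(entries, lexicon$suffixes[sample(length(lexicon$suffixes), 1L)])
      forms <- vapply(entries, `[[`, "", "form")
      roles <- vapply(entries, `[[`, "", "kind")
      term <- join_components(forms, roles, vowel)
      if (term %in% forbidden || term %in% terms) next
      expected <- unlist(lapply(entries, `[[`, "meaning_words"),
                         use.names = FALSE)
      d <- decompose_term(term, lexicon)
      if (is.null(d) || !identical(d$meaning_words, expected)) next
      terms <- c(terms, term)
      meanings[[length(terms)]] <- expected
    }
    if (length(terms) < cfg$n_terms)
      stop("could not generate ", cfg$n_terms, " unambiguous terms from this ",
           "lexicon (got ", length(terms), ")")
    structure(list(term = terms, meaning_words = meanings),
              class = "synth_terms")
  })
}

#' Generate a toy embedding with unit-norm random vectors
#'
#' Deterministic per seed: each word receives an independent random direction
#' on the unit sphere of dimension `cfg$embedding_dim`. The vocabulary is the
#' sorted unique input word set.
#'
#' @param words Non-empty character vector.
#' @param cfg A [synth_config()].
#' @return An `embedding_source`.
#' @export
generate_embedding <- function(words, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(words) == 0L) stop("generate_embedding: empty word list")
  words <- sort(unique(as.character(words)))
  with_local_seed(cfg$seed, {
    mat <- matrix(stats::rnorm(length(words) * cfg$embedding_dim),
                  nrow = length(words))
    mat <- mat / sqrt(rowSums(mat^2))
    rownames(mat) <- words
    embedding_source(mat)
  })
}

#' Generate a synthetic term-pair dataset with its toy embedding
#'
#' Generates `cfg$n_terms` synthetic terms, a toy embedding over all their
#' meaning words, and `cfg$n_terms` term pairs whose human score is the cosine
#' of the expected mean-meaning vectors plus Gaussian noise of sd
#' `cfg$noise_sd`. At `noise_sd = 0` a correct encoder chain therefore attains
#' Spearman 1.0 and 100% coverage through [evaluate_pairs()].
#'
#' @inheritParams generate_terms
#' @return List with `pairs` (data frame `term1`, `term2`, `human_score`) and
#'   `emb` (an `embedding_source`).
#' @export
generate_pair_dataset <- function(cfg, lexicon) {
  terms <- generate_terms(cfg, lexicon)
  vocab <- sort(unique(unlist(terms$meaning_words, use.names = FALSE)))
  emb <- generate_embedding(vocab, cfg)
  truth_vec <- lapply(terms$meaning_words, function(mw)
    mean_vector(mw, emb)$vector)
  n <- length(terms$term)
  with_local_seed(cfg$seed + 1L, {
    i <- sample(n, cfg$n_terms, replace = TRUE)
    j <- sample(n, cfg$n_terms, replace = TRUE)
    eq <- which(i == j)
    j[eq] <- (j[eq] %% n) + 1L
    human <- vapply(seq_len(cfg$n_terms), function(p)
      cosine_similarity(truth_vec[[i[p]]], truth_vec[[j[p]]]), 0)
    if (cfg$noise_sd > 0)
      human <- human + stats::rnorm(cfg$n_terms, 0, cfg$noise_sd)
    list(pairs = data.frame(term1 = terms$term[i], term2 = terms$term[j],
                            human_score = human, stringsAsFactors = FALSE),
         emb = emb)
  })
}

#' @export
print.synth_terms <- function(x, ...) {
  cat(sprintf("<synth_terms: %d terms, e.g. %s>\n", length(x$term),
              paste(utils::head(x$term, 3L), collapse = ", ")))
  invisible(x)
}
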