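# Independent oracles and small fixture builders used across tests.

# Deterministic toy embedding: unit-norm rows, one per word.
toy_embedding <- function(words, dim = 8L, seed = 1L) {
  words <- sort(unique(words))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  mat <- matrix(rnorm(length(words) * dim), nrow = length(words))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  mat <- mat / sqrt(rowSums(mat^2))
  rownames(mat) <- words
  embedding_source(mat)
}

# Embedding over every meaning word of a lexicon (plus extras).
meaning_word_embedding <- function(lexicon, dim = 8L, seed = 1L,
                                   extra = character()) {
  words <- unlist(lapply(c(lexicon$prefixes, lexicon$roots, lexicon$suffixes),
                         function(e) e$meaning_words), use.names = FALSE)
  toy_embedding(c(words, extra), dim = dim, seed = seed)
}

fixture_segmenter <- function(lexicon = fixture_lexicon()) {
  words <- unique(unlist(lapply(c(lexicon$prefixes, lexicon$roots,
                                  lexicon$suffixes),
                                function(e) e$meaning_words)))
  train_segmenter(words)
}

# All 2^(n-1) segmentations of a string into contiguous units.
all_segmentations <- function(term) {
  n <- nchar(term)
  if (n == 1L) return(list(term))
  out <- list()
  for (first_len in 1:n) {
    head <- substr(term, 1L, first_len)
    if (first_len == n) out <- c(out, list(head))
    else out <- c(out, lapply(all_segmentations(substr(term, first_len + 1L, n)),
                              function(tail) c(head, tail)))
  }
  out
}

# Exhaustive-maximization oracle for the unigram segmenter, with the same
# tie rules (fewer units, then longer units left to right).
brute_force_segment <- function(term, model) {
  score_units <- function(units) sum(vapply(units, function(u) {
    lp <- model$unit_log_prob[u]
    if (is.na(lp)) -model$unknown_penalty * nchar(u) else as.numeric(lp)
  }, 0))
  cands <- all_segmentations(term)
  best <- NULL; best_score <- -Inf
  lex_longer <- function(a, b) {  # TRUE if unit-length profile of a > b
    la <- nchar(a); lb <- nchar(b)
    k <- min(length(la), length(lb))
    for (j in seq_len(k)) if (la[j] != lb[j]) return(la[j] > lb[j])
    FALSE
  }
  for (u in cands) {
    s <- score_units(u)
    if (is.null(best) || s > best_score + 1e-9 ||
        (abs(s - best_score) <= 1e-9 &&
         (length(u) < length(best) ||
          (length(u) == length(best) && lex_longer(u, best))))) {
      best <- u; best_score <- s
    }
  }
  best
}

# Independent enumeration of every grammar-valid decomposition of a term:
# optional prefix, roots with combining vowels, optional terminal suffix.
# Returns a list of parses: list(surfaces, roles, meanings, n_comp, suffix_len).
enumerate_parses <- function(term, lexicon, min_len = 2L) {
  surf_table <- list()
  slot_of <- c(prefix = "prefixes", root = "roots", suffix = "suffixes")
  for (kind in names(slot_of)) {
    for (entry in lexicon[[slot_of[[kind]]]]) {
      for (surface in unique(c(entry$form, entry$combining_forms))) {
        if (nchar(surface) < min_len) next
        surf_table[[length(surf_table) + 1L]] <-
          list(surface = surface, kind = kind, entry = entry)
      }
    }
  }
  n <- nchar(term)
  results <- list()
  recurse <- function(pos, ctx, surfaces, roles, entries) {
    if (pos > n) {
      if (ctx == "after_comp")
        results[[length(results) + 1L]] <<-
          list(surfaces = surfaces, roles = roles, entries = entries)
      return(invisible())
    }
    ch <- substr(term, pos, pos)
    if (ctx == "after_comp" && ch %in% lexicon$combining_vowels && pos < n)
      recurse(pos + 1L, "after_vowel", c(surfaces, ch),
              c(roles, "combining_vowel"), entries)
    prefix_forms_here <- vapply(
      Filter(function(r) r$kind == "prefix" &&
               substr(term, pos, pos + nchar(r$surface) - 1L) == r$surface,
             surf_table),
      function(r) r$entry$form, "")
    for (r in surf_table) {
      L <- nchar(r$surface)
      if (pos + L - 1L > n) next
      if (substr(term, pos, pos + L - 1L) != r$surface) next
      if (r$kind == "prefix" && ctx != "start") next
      if (r$kind == "root" && ctx == "start" &&
          r$entry$form %in% prefix_forms_here) next
      if (r$kind == "suffix" && pos + L - 1L != n) next
      if (r$kind != "suffix" && r$surface != r$entry$form &&
          startsWith(r$surface, r$entry$form)) {
        fl <- nchar(r$entry$form)
        recurse(pos + L, "after_vowel",
                c(surfaces, r$entry$form, substr(r$surface, fl + 1L, L)),
                c(roles, r$kind, "combining_vowel"),
                c(entries, list(r$entry)))
      } else {
        recurse(pos + L, "after_comp", c(surfaces, r$surface),
                c(roles, r$kind), c(entries, list(r$entry)))
      }
    }
  }
  recurse(1L, "start", character(), character(), list())
  lapply(results, function(p) {
    non_vowel <- p$roles != "combining_vowel"
    list(surfaces = p$surfaces, roles = p$roles,
         meanings = unlist(lapply(p$entries, `[[`, "meaning_words"),
                           use.names = FALSE),
         n_comp = sum(non_vowel),
         suffix_len = if (p$roles[length(p$roles)] == "suffix")
           nchar(p$surfaces[length(p$surfaces)]) else 0L)
  })
}

# Pick the best parse from enumerate_parses() output by the documented
# preference: fewest components, longest suffix, earliest surface tuple.
best_enumerated_parse <- function(parses) {
  if (length(parses) == 0L) return(NULL)
  better <- function(a, b) {
    if (a$n_comp != b$n_comp) return(a$n_comp < b$n_comp)
    if (a$suffix_len != b$suffix_len) return(a$suffix_len > b$suffix_len)
    k <- min(length(a$surfaces), length(b$surfaces))
    for (j in seq_len(k))
      if (a$surfaces[j] != b$surfaces[j]) return(a$surfaces[j] < b$surfaces[j])
    length(a$surfaces) < length(b$surfaces)
  }
  best <- parses[[1L]]
  for (p in parses[-1L]) if (better(p, best)) best <- p
  best
}

# Brute-force Spearman: explicit average ranks via sorting, then the
# sum-form Pearson formula. Independent of stats::cor / rank defaults.
brute_force_spearman <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# First rule (table order) whose singular suffix ends the word; 0 if none.
first_singular_rule <- function(word, rules) {
  for (i in seq_len(nrow(rules)))
    if (nchar(word) > nchar(rules$singular_suffix[i]) &&
        endsWith(word, rules$singular_suffix[i])) return(i)
  0L
}

# Rule chosen by the singularizer: longest plural suffix, then table order.
chosen_plural_rule <- function(word, rules) {
  ord <- order(-nchar(rules$plural_suffix), seq_len(nrow(rules)))
  for (i in ord)
    if (nchar(word) > nchar(rules$plural_suffix[i]) &&
        endsWith(word, rules$plural_suffix[i])) return(i)
  0L
}

random_stem <- function(len = sample(3:8, 1L)) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}
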