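#' Normalize a token for vocabulary lookup
#'
#' Applies, in order: (1) lowercase folding; (2) removal of leading and
#' trailing non-alphanumeric characters, keeping intra-term punctuation
#' (hyphens, slashes, periods inside the token); (3) apostrophe normalization:
#' curly apostrophes are mapped to ASCII, then a terminal `'s` or `'` is
#' removed. Deterministic and idempotent; digits are preserved.
#'
#' @param token Non-empty string (after whitespace strip).
#' @return A list of class `normalization_result` with elements `original`,
#'   `normalized`, and `steps_applied` (the subset of
#'   `c("lowercase", "strip_edge_punct", "apostrophe")` that changed the
#'   string, in application order).
#' @examples
#' normalize_token("Heart.")$normalized      # "heart"
#' normalize_token("x-ray")$normalized       # "x-ray"
#' normalize_token("Alzheimer's")$normalized # "alzheimer"
#' @export
normalize_token <- function(token) {
  if (length(token) != 1L || is.na(token) || !nzchar(trimws(token)))
    stop("normalize_token: empty or whitespace-only input")
  token <- trimws(token)
  steps <- character()

  s <- tolower(token)
  if (!identical(s, token)) steps <- c(steps, "lowercase")

  s2 <- sub("^[^a-z0-9]+", "", s)
  s2 <- sub("[^a-z0-9]+$", "", s2)
  if (!identical(s2, s)) steps <- c(steps, "strip_edge_punct")

  s3 <- gsub("[‘’ʼ´`]", "'", s2)
  s3 <- sub("('s|')$", "", s3)
  if (!identical(s3, s2)) steps <- c(steps, "apostrophe")

  structure(list(original = token, normalized = s3, steps_applied = steps),
            class = "normalization_result")
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf("'%s' -> '%s'%s\n", x$original, x$normalized,
              if (length(x$steps_applied))
                paste0("  (", paste(x$steps_applied, collapse = ", "), ")")
              else "  (unchanged)"))
  invisible(x)
}

#' Test whether a token is known to a vocabulary
#'
#' Tries the token as-is, then its normalized form, against the vocabulary
#' (the surface forms of an embedding table).
#'
#' @param token Non-empty string.
#' @param vocabulary Character vector (or anything [`%in%`] accepts) of known
#'   surface forms.
#' @return A list with `known` (logical) and `match` (the matched surface form,
#'   or `NA_character_` when unknown).
#' @examples
#' is_known("Heart.", c("heart"))  # known, match "heart"
#' @export
is_known <- function(token, vocabulary) {
  if (token %in% vocabulary)
    return(list(known = TRUE, match = token))
  norm <- normalize_token(token)$normalized
  if (nzchar(norm) && norm %in% vocabulary)
    return(list(known = TRUE, match = norm))
  list(known = FALSE, match = NA_character_)
}
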