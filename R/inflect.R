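#' Default medical inflection rule table
#'
#' The standard Greek/Latin suffix substitution rules used by the pluralizer
#' and singularizer, as an ordered table (first match wins for pluralization;
#' longest plural suffix first for singularization). The default set contains
#' only rules whose plural suffix is unambiguous, so the two transformations
#' invert each other. `extended = TRUE` appends rules whose plural suffix
#' collides with a default rule (`ex -> ices` with `ix -> ices`, `on -> a`
#' with `um -> a`); with those enabled the singular of an `-ices`/`-a` plural
#' is resolved by table order and round trips are no longer guaranteed.
#'
#' @param extended Include the ambiguous extra rules; default `FALSE`.
#' @param append_s Append a final generic `"" -> s` rule; disabled by default
#'   because it collides with medical endings.
#' @return Data frame with columns `rule_id`, `singular_suffix`,
#'   `plural_suffix`, in precedence order.
#' @examples
#' default_inflection_rules()
#' @export
default_inflection_rules <- function(extended = FALSE, append_s = FALSE) {
  rules <- data.frame(
    rule_id = c("r_ix", "r_nx", "r_ma", "r_is", "r_um", "r_us",
                "r_a", "r_y", "r_x"),
    singular_suffix = c("ix", "nx", "ma", "is", "um", "us", "a", "y", "x"),
    plural_suffix = c("ices", "nges", "mata", "es", "a", "i", "ae", "ies",
                      "ges"),
    stringsAsFactors = FALSE)
  if (extended) {
    # ex follows ix, on follows um, matching their precedence
    ex <- data.frame(rule_id = c("r_ex", "r_on"),
                     singular_suffix = c("ex", "on"),
                     plural_suffix = c("ices", "a"),
                     stringsAsFactors = FALSE)
    rules <- rbind(rules[1L, ], ex[1L, ], rules[2:5, ], ex[2L, ],
                   rules[6:9, ])
    rownames(rules) <- NULL
  }
  if (append_s)
    rules <- rbind(rules,
                   data.frame(rule_id = "r_s", singular_suffix = "",
                              plural_suffix = "s", stringsAsFactors = FALSE))
  rules
}

check_inflect_word <- function(word) {
  if (length(word) != 1L || is.na(word) || !grepl("^[a-z]+$", word))
    stop("inflection expects a single lowercase alphabetic word, got: ",
         deparse(word))
}

# First rule (in table order) whose `side` suffix matches the end of `word`,
# with a non-empty stem. Returns the row index or 0L.
first_matching_rule <- function(word, rules, side) {
  for (i in seq_len(nrow(rules))) {
    suf <- rules[[side]][i]
    if (nchar(word) > nchar(suf) && endsWith(word, suf)) return(i)
  }
  0L
}

apply_rule <- function(word, from, to) {
  paste0(substr(word, 1L, nchar(word) - nchar(from)), to)
}

#' Pluralize a word by the medical rule table
#'
#' The first rule (in table order) whose singular suffix matches the end of
#' the word is applied; `NULL` if no rule matches.
#'
#' @param word Lowercase alphabetic word.
#' @param rules Inflection rule table; default [default_inflection_rules()].
#' @return The plural form, or `NULL`.
#' @examples
#' pluralize("vertebra")   # "vertebrae"
#' pluralize("diagnosis")  # "diagnoses"
#' pluralize("xyz")        # NULL
#' @export
pluralize <- function(word, rules = default_inflection_rules()) {
  check_inflect_word(word)
  i <- first_matching_rule(word, rules, "singular_suffix")
  if (i == 0L) return(NULL)
  apply_rule(word, rules$singular_suffix[i], rules$plural_suffix[i])
}

#' Singularize a word by the medical rule table
#'
#' The reverse transformation of [pluralize()]: among rules whose plural
#' suffix matches the end of the word, the longest plural suffix wins (then
#' table order), and it is replaced by the rule's singular suffix. `NULL` if
#' no rule matches.
#'
#' @inheritParams pluralize
#' @return The singular form, or `NULL`.
#' @examples
#' singularize("vertebrae")  # "vertebra"
#' singularize("diagnoses")  # "diagnosis"
#' singularize("lung")       # NULL
#' @export
singularize <- function(word, rules = default_inflection_rules()) {
  check_inflect_word(word)
  ord <- order(-nchar(rules$plural_suffix), seq_len(nrow(rules)))
  reordered <- rules[ord, , drop = FALSE]
  i <- first_matching_rule(word, reordered, "plural_suffix")
  if (i == 0L) return(NULL)
  apply_rule(word, reordered$plural_suffix[i], reordered$singular_suffix[i])
}

#' Singular/plural lookup candidates for a word
#'
#' Returns the singular candidate (if any) then the plural candidate (if
#' any), duplicates removed. Wrong candidates are filtered downstream by
#' vocabulary lookup.
#'
#' @inheritParams pluralize
#' @return Character vector of length 0, 1 or 2.
#' @examples
#' inflection_candidates("vertebrae")  # "vertebra"
#' inflection_candidates("bacterium") # "bacteria"
#' @export
inflection_candidates <- function(word, rules = default_inflection_rules()) {
  check_inflect_word(word)
  out <- c(singularize(word, rules), pluralize(word, rules))
  if (is.null(out)) character() else unique(out)
}
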