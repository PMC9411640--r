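#' Create a component-lexicon entry
#'
#' A `component_entry` describes one medical word part: a prefix, root or
#' suffix, its surface variants with combining vowels (e.g. `"pneumo"` for the
#' root `"pneum"`), and the plain-language words that carry its meaning
#' (`"pneum"` -> `"lung"`).
#'
#' @param form Lowercase alphabetic string: the component as matched inside a
#'   term, e.g. `"pnea"`.
#' @param kind One of `"prefix"`, `"root"`, `"suffix"`.
#' @param combining_forms Character vector of surface variants; each must start
#'   with `form` or equal `form` with its terminal vowel substituted. Empty
#'   means no variants beyond `form` itself.
#' @param meaning_words Non-empty character vector of lowercase meaning words,
#'   in order (e.g. `c("common", "bile", "duct")`).
#' @param organ_system Optional label, e.g. `"respiratory"`; `NA` if unknown.
#' @return An object of class `component_entry`.
#' @examples
#' component_entry("pnea", "suffix", meaning_words = "breathing",
#'                 organ_system = "respiratory")
#' @export
component_entry <- function(form, kind, combining_forms = character(),
                            meaning_words, organ_system = NA_character_) {
  form <- tolower(trimws(form))
  if (!nzchar(form) || !grepl("^[a-z]+$", form))
    stop("'form' must be a non-empty lowercase alphabetic string, got: ",
         deparse(form))
  kind <- match.arg(kind, c("prefix", "root", "suffix"))
  combining_forms <- tolower(trimws(as.character(combining_forms)))
  combining_forms <- combining_forms[nzchar(combining_forms)]
  ok <- startsWith(combining_forms, form) |
    startsWith(combining_forms, substr(form, 1L, nchar(form) - 1L))
  if (any(!ok))
    stop("combining form(s) ", paste(combining_forms[!ok], collapse = ", "),
         " do not extend form '", form, "'")
  meaning_words <- tolower(trimws(as.character(meaning_words)))
  meaning_words <- meaning_words[nzchar(meaning_words)]
  if (length(meaning_words) == 0L)
    stop("entry '", form, "' has no meaning words")
  organ_system <- if (is.null(organ_system) || is.na(organ_system) ||
                      !nzchar(trimws(organ_system))) NA_character_
                  else tolower(trimws(organ_system))
  structure(list(form = form, kind = kind,
                 combining_forms = unique(combining_forms),
                 meaning_words = meaning_words,
                 organ_system = organ_system),
            class = "component_entry")
}

#' @export
print.component_entry <- function(x, ...) {
  cat(sprintf("<%s '%s' -> %s%s>\n", x$kind, x$form,
              paste(x$meaning_words, collapse = " "),
              if (is.na(x$organ_system)) "" else paste0(" [", x$organ_system, "]")))
  invisible(x)
}

new_lexicon <- function(prefixes, roots, suffixes, inflection_rules,
                        combining_vowels = "o") {
  structure(list(prefixes = prefixes, roots = roots, suffixes = suffixes,
                 inflection_rules = inflection_rules,
                 combining_vowels = combining_vowels),
            class = "med_lexicon")
}

lexicon_columns <- c("form", "kind", "combining_forms", "meanings", "organ_system")

#' Load a component lexicon from tab-separated files
#'
#' Each file is TSV with header columns `form`, `kind`, `combining_forms`
#' (comma-joined, may be empty), `meanings` (comma-joined) and `organ_system`
#' (may be empty). Entries are lowercased; later files override earlier files
#' on the same (kind, form). Rows with an empty `meanings` cell are rejected
#' with a warning and loading continues. When `combining_forms` is empty for a
#' prefix or root, variants `form` + each combining vowel are auto-generated.
#'
#' @param paths Character vector of TSV file paths, in override order.
#' @param inflection_rules Data frame of inflection rules (see
#'   [default_inflection_rules()]); attached to the returned lexicon.
#' @param combining_vowels Characters usable as combining vowels between
#'   components; default `"o"` as in pneum/o.
#' @return A `med_lexicon`: named entry lists `prefixes`, `roots`, `suffixes`,
#'   plus `inflection_rules` and `combining_vowels`.
#' @seealso [fixture_lexicon()], [write_lexicon()]
#' @export
load_lexicon <- function(paths, inflection_rules = default_inflection_rules(),
                         combining_vowels = "o") {
  store <- list(prefix = list(), root = list(), suffix = list())
  for (path in paths) {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                             colClasses = "character", fill = TRUE,
                             fileEncoding = "UTF-8",
                             stringsAsFactors = FALSE)
    missing_cols <- setdiff(lexicon_columns, names(tab))
    if (length(missing_cols) > 0L)
      stop("lexicon file '", path, "' is missing column(s): ",
           paste(missing_cols, collapse = ", "))
    for (i in seq_len(nrow(tab))) {
      meanings <- split_cell(tab$meanings[i])
      if (length(meanings) == 0L) {
        warning("lexicon file '", path, "' row ", i, " ('",
                trimws(tab$form[i]), "'): empty meanings, entry rejected")
        next
      }
      kind <- tolower(trimws(tab$kind[i]))
      cf <- split_cell(tab$combining_forms[i])
      if (length(cf) == 0L && kind %in% c("prefix", "root"))
        cf <- paste0(tolower(trimws(tab$form[i])), combining_vowels)
      entry <- component_entry(tab$form[i], kind, cf, meanings,
                               tab$organ_system[i])
      store[[entry$kind]][[entry$form]] <- entry
    }
  }
  new_lexicon(store$prefix, store$root, store$suffix,
              inflection_rules, combining_vowels)
}

split_cell <- function(x) {
  if (is.na(x)) return(character())
  parts <- tolower(trimws(strsplit(x, ",", fixed = TRUE)[[1L]]))
  parts[nzchar(parts)]
}

#' Load an inflection rule table
#'
#' TSV with header columns `rule_id`, `singular_suffix`, `plural_suffix`.
#'
#' @param path File path.
#' @return Data frame with those three character columns, in file order.
#' @export
load_inflection_rules <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  needed <- c("rule_id", "singular_suffix", "plural_suffix")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L)
    stop("inflection rule file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  rules <- data.frame(rule_id = trimws(tab$rule_id),
                      singular_suffix = tolower(trimws(tab$singular_suffix)),
                      plural_suffix = tolower(trimws(tab$plural_suffix)),
                      stringsAsFactors = FALSE)
  bad <- rules$singular_suffix == rules$plural_suffix
  if (any(bad))
    stop("inflection rule(s) ", paste(rules$rule_id[bad], collapse = ", "),
         " have identical singular and plural suffixes")
  rules
}

#' The built-in fixture lexicon
#'
#' A small prefix/root/suffix lexicon shipped with the package, sufficient for
#' the worked examples (dyspnea, mastodynia, dermatitis, arteriosclerosis,
#' prostatism, urethrorrhea, choledocholithiasis, ...) and for the synthetic
#' term generator. It is a fixture, not a full medical dictionary.
#'
#' @return A `med_lexicon`.
#' @examples
#' lex <- fixture_lexicon()
#' lex$suffixes[["pnea"]]$meaning_words   # "breathing"
#' @export
fixture_lexicon <- function() {
  dir <- system.file("extdata", "lexicon", package = "medparts",
                     mustWork = TRUE)
  load_lexicon(file.path(dir, c("prefixes.tsv", "roots.tsv", "suffixes.tsv")),
               inflection_rules =
                 load_inflection_rules(file.path(dir, "inflection_rules.tsv")))
}

#' Write a lexicon back to the TSV format
#'
#' Writes `prefixes.tsv`, `roots.tsv`, `suffixes.tsv` and
#' `inflection_rules.tsv` into `dir`, such that reloading with
#' [load_lexicon()] reproduces the lexicon field by field.
#'
#' @param lexicon A `med_lexicon`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the four file paths written.
#' @export
write_lexicon <- function(lexicon, dir) {
  stopifnot(inherits(lexicon, "med_lexicon"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_kind <- function(entries, file) {
    rows <- lapply(entries, function(e) {
      data.frame(form = e$form, kind = e$kind,
                 combining_forms = paste(e$combining_forms, collapse = ","),
                 meanings = paste(e$meaning_words, collapse = ","),
                 organ_system = if (is.na(e$organ_system)) "" else e$organ_system,
                 stringsAsFactors = FALSE)
    })
    tab <- if (length(rows)) do.call(rbind, rows)
           else as.data.frame(stats::setNames(rep(list(character()), 5L),
                                             lexicon_columns))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    file
  }
  paths <- c(write_kind(lexicon$prefixes, file.path(dir, "prefixes.tsv")),
             write_kind(lexicon$roots, file.path(dir, "roots.tsv")),
             write_kind(lexicon$suffixes, file.path(dir, "suffixes.tsv")))
  rules_path <- file.path(dir, "inflection_rules.tsv")
  utils::write.table(lexicon$inflection_rules, rules_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(paths, rules_path))
}

#' @export
print.med_lexicon <- function(x, ...) {
  cat(sprintf(paste0("<med_lexicon: %d prefixes, %d roots, %d suffixes, ",
                     "%d inflection rules>\n"),
              length(x$prefixes), length(x$roots), length(x$suffixes),
              nrow(x$inflection_rules)))
  invisible(x)
}
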