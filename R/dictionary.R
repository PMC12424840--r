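#' Compile an indication term dictionary
#'
#' Builds a term dictionary from a two-column table (`category`,
#' `terms`) where `terms` is a comma-separated list of patterns. A pattern
#' is a literal word, a suffix wildcard (`"depress*"`, fires on tokens that
#' start with the stem) or a prefix wildcard (`"*ache"`, fires on tokens
#' that end with the stem). At most one asterisk is allowed, only at the
#' start or end; anything else is a compile error naming the pattern.
#'
#' @param source A data frame with columns `category` and `terms`, or a
#'   path to a CSV file with those columns.
#' @return A tibble with class `"term_dictionary"` and columns `category`,
#'   `raw`, `kind` (`"literal"`, `"prefix-wildcard"`, `"suffix-wildcard"`)
#'   and `stem` (asterisk-stripped, lower-cased).
#' @export
#' @examples
#' compile_dictionary(data.frame(category = "Pain",
#'                               terms = "*ache, aching, pain"))
compile_dictionary <- function(source) {
  if (is.character(source) && length(source) == 1) {
    source <- readr::read_csv(source, col_types = "cc", progress = FALSE)
  }
  source <- as_tibble(source)
  assert_columns(source, c("category", "terms"), "dictionary source")

  rows <- source |>
    mutate(raw = str_split(.data$terms, ",")) |>
    tidyr::unnest("raw") |>
    mutate(raw = str_trim(.data$raw)) |>
    filter(nzchar(.data$raw)) |>
    select("category", "raw")

  n_star <- vapply(gregexpr("*", rows$raw, fixed = TRUE), function(m) {
    if (m[1] == -1) 0L else length(m)
  }, integer(1))
  at_edge <- str_starts(rows$raw, fixed("*")) | str_ends(rows$raw, fixed("*"))
  bad <- n_star > 1 | (n_star == 1 & !at_edge)
  if (any(bad)) {
    abort(sprintf("malformed term pattern(s): %s",
                  paste(unique(rows$raw[bad]), collapse = ", ")))
  }

  rows <- rows |>
    mutate(
      kind = case_when(
        str_starts(.data$raw, fixed("*")) ~ "prefix-wildcard",
        str_ends(.data$raw, fixed("*")) ~ "suffix-wildcard",
        TRUE ~ "literal"
      ),
      stem = str_to_lower(gsub("*", "", .data$raw, fixed = TRUE))
    )
  if (any(!nzchar(rows$stem))) abort("term pattern with empty stem")
  dup <- duplicated(rows[, c("category", "raw")])
  if (any(dup)) {
    warn("duplicate (category, term) pairs dropped")
    rows <- rows[!dup, ]
  }
  structure(rows, class = c("term_dictionary", class(rows)))
}

#' The packaged four-category indication dictionary
#'
#' The default dictionary shipped with the package: wildcard and literal
#' terms for the four categories Anxiety/Mood (18 patterns),
#' Movement/Seizure (15), Pain (13) and Sleep (9). It lives in
#' `inst/extdata/indication_terms.csv` and can be replaced by any file in
#' the same two-column format.
#'
#' @return A `term_dictionary` tibble.
#' @export
#' @examples
#' dplyr::count(default_dictionary(), category)
default_dictionary <- function() {
  compile_dictionary(pkg_extdata("indication_terms.csv"))
}

#' Match free-text indications against a term dictionary
#'
#' Tokenizes each text on non-alphanumeric boundaries and matches tokens
#' case-insensitively: a literal pattern fires when some token equals its
#' stem, a suffix wildcard when some token starts with the stem, a prefix
#' wildcard when some token ends with the stem. Literal terms never match
#' inside a longer token ("benefits" does not fire "fits"). A substring
#' mode (every stem matched anywhere in the raw text) is available for
#' sensitivity analysis.
#'
#' @param text Character vector of free-text indication strings.
#' @param dict A `term_dictionary` (default: [default_dictionary()]).
#' @param mode `"token"` (default, whole-token semantics) or
#'   `"substring"`.
#' @return A tibble with one row per (text, category, term) firing:
#'   columns `indication_text`, `category`, `term`. Texts with no firing
#'   term contribute no rows.
#' @export
#' @examples
#' match_indication(c("insomnia", "chronic headache", "benefits"))
match_indication <- function(text, dict = default_dictionary(),
                             mode = c("token", "substring")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dict, "term_dictionary"))
  if (length(text) == 0) {
    return(tibble(indication_text = character(), category = character(),
                  term = character()))
  }
  texts <- unique(text)
  lowered <- str_to_lower(texts)

  if (mode == "token") {
    token_list <- str_split(lowered, "[^[:alnum:]]+")
    token_list <- lapply(token_list, function(t) unique(t[nzchar(t)]))
    tok <- tibble(
      indication_text = rep(texts, lengths(token_list)),
      token = unlist(token_list) %||% character(0)
    )
    if (nrow(tok) == 0) {
      return(tibble(indication_text = character(), category = character(),
                    term = character()))
    }
    hits <- lapply(seq_len(nrow(dict)), function(i) {
      stem <- dict$stem[i]
      sel <- switch(dict$kind[i],
        "literal" = tok$token == stem,
        "suffix-wildcard" = startsWith(tok$token, stem),
        "prefix-wildcard" = endsWith(tok$token, stem)
      )
      if (!any(sel)) return(NULL)
      tibble(indication_text = unique(tok$indication_text[sel]),
             category = dict$category[i], term = dict$raw[i])
    })
  } else {
    hits <- lapply(seq_len(nrow(dict)), function(i) {
      sel <- str_detect(lowered, fixed(dict$stem[i]))
      if (!any(sel)) return(NULL)
      tibble(indication_text = texts[sel],
             category = dict$category[i], term = dict$raw[i])
    })
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(indication_text = character(), category = character(),
                  term = character()))
  }
  out |>
    distinct() |>
    arrange(.data$indication_text, .data$category, .data$term)
}

#' Assign indication categories to formulas
#'
#' Applies [match_indication()] to every indication string of every formula
#' and returns the union of firing categories per formula, in long format.
#' Formulas whose indications fire no term contribute no rows (their
#' category set is empty); formulas without indications never match.
#'
#' @param dataset A `formula_dataset`.
#' @param dict A `term_dictionary`.
#' @param mode Matching mode, see [match_indication()].
#' @return A tibble (`formula_id`, `category`, `term`) with one row per
#'   firing term. Use `dplyr::distinct(formula_id, category)` for the plain
#'   category sets.
#' @export
categorize_formulas <- function(dataset, dict = default_dictionary(),
                                mode = c("token", "substring")) {
  stopifnot(inherits(dataset, "formula_dataset"))
  fi <- dataset$formula_indications
  if (nrow(fi) == 0) {
    return(tibble(formula_id = character(), category = character(),
                  term = character()))
  }
  hits <- match_indication(fi$indication, dict, mode = match.arg(mode))
  fi |>
    inner_join(hits, by = c(indication = "indication_text"),
               relationship = "many-to-many") |>
    distinct(.data$formula_id, .data$category, .data$term) |>
    arrange(.data$formula_id, .data$category, .data$term)
}

# distinct (formula_id, category) pairs — the working unit of the
# association statistics
formula_categories <- function(dataset, dict = default_dictionary(),
                               mode = "token") {
  categorize_formulas(dataset, dict, mode = mode) |>
    distinct(.data$formula_id, .data$category)
}
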