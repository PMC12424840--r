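# Internal helpers shared across modules.

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "phytomine", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is on the search path directly
    path <- system.file("inst", "extdata", file, package = "phytomine",
                        mustWork = TRUE)
  }
  path
}

# Evaluate `code` under a fixed, fully specified RNG state and restore the
# caller's state afterwards. All generator randomness flows through this so
# that a seed fixes every draw, independent of the session's RNG settings.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Case-fold a compound name and collapse punctuation/whitespace so that
# "Camphor." and " camphor" compare equal.
normalize_compound_name <- function(x) {
  x <- str_to_lower(x)
  x <- str_replace_all(x, "[^a-z0-9]+", " ")
  x <- str_squish(x)
  x[!nzchar(x)] <- NA_character_
  x
}

is_valid_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

# Deterministic CSV writer used for all interchange outputs: fixed column
# order is the caller's, row order must be pre-sorted, eol is "\n" on every
# platform so re-runs are byte-identical.
write_stable_csv <- function(x, path) {
  readr::write_csv(x, path, na = "", eol = "\n", progress = FALSE)
  invisible(path)
}

read_interchange_csv <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, na = "", progress = FALSE)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
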