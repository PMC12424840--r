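# Association statistics between compounds/species and indication
# categories. Two distinct percentage definitions coexist and are never
# interchangeable:
#   * association percentage — denominator is the set of formulas
#     CONTAINING the compound (bubble-heatmap statistic, candidate filter);
#   * containment percentage — denominator is the set of formulas TREATING
#     the category (compound-index statistic).

# distinct (formula_id, compound_key) pairs under the any-member-species
# attribution rule
formula_compounds <- function(dataset) {
  dataset$formula_species |>
    inner_join(dataset$species_compounds, by = "species",
               relationship = "many-to-many") |>
    distinct(.data$formula_id, .data$compound_key)
}

check_known_compounds <- function(dataset, compounds) {
  unknown <- setdiff(compounds, dataset$compounds$compound_key)
  if (length(unknown) > 0) {
    abort(sprintf("unknown compound_key(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  compounds
}

#' Per-compound indication-association profiles
#'
#' For every compound, counts the formulas containing it (via any member
#' species) and, for each of the four categories, the percentage of those
#' formulas whose category set includes the category. Percentages are on
#' the 0-100 scale; a compound contained in no formula gets `NA`
#' percentages (flagged undefined, never 0).
#'
#' @param dataset A `formula_dataset`.
#' @param dict A `term_dictionary`.
#' @param compounds Optional character vector restricting the profile to
#'   these compound keys; unknown keys are an error.
#' @param mode Matching mode passed to the dictionary.
#' @return A tibble with class `"association_profiles"`, one row per
#'   (compound, category): `compound_key`, `n_formulas`, `category`, `pct`.
#' @seealso [association_summary()], [candidate_filter()],
#'   [compound_index()]
#' @export
association_profiles <- function(dataset, dict = default_dictionary(),
                                 compounds = NULL, mode = "token") {
  stopifnot(inherits(dataset, "formula_dataset"))
  keys <- if (is.null(compounds)) dataset$compounds$compound_key else
    check_known_compounds(dataset, compounds)
  fc <- formula_compounds(dataset) |>
    filter(.data$compound_key %in% keys)
  cats <- formula_categories(dataset, dict, mode)

  n_formulas <- fc |> count(.data$compound_key, name = "n_formulas")
  numer <- fc |>
    inner_join(cats, by = "formula_id", relationship = "many-to-many") |>
    count(.data$compound_key, .data$category, name = "n_cat")

  grid <- tidyr::expand_grid(compound_key = sort(keys),
                             category = indication_categories())
  out <- grid |>
    left_join(n_formulas, by = "compound_key") |>
    left_join(numer, by = c("compound_key", "category")) |>
    mutate(
      n_formulas = ifelse(is.na(.data$n_formulas), 0L, .data$n_formulas),
      n_cat = ifelse(is.na(.data$n_cat), 0L, .data$n_cat),
      pct = ifelse(.data$n_formulas > 0,
                   100 * .data$n_cat / .data$n_formulas, NA_real_)
    ) |>
    select("compound_key", "n_formulas", "category", "pct") |>
    arrange(.data$compound_key, .data$category)
  structure(out, class = c("association_profiles", class(out)))
}

#' Summarise association profiles and apply the candidate filter
#'
#' `association_summary()` pivots profiles to one row per compound with the
#' four category percentages, their sum (`pct_sum`, range 0-400) and the
#' filter flag `passes_filter = pct_sum > threshold` (strict inequality:
#' "exceeding"). `candidate_filter()` returns only the passing compounds,
#' sorted by `pct_sum` descending with ties broken by `n_formulas`
#' descending then `compound_key`, so outputs are byte-stable.
#'
#' @param profiles An `"association_profiles"` tibble.
#' @param threshold Percentage-sum threshold (default 300).
#' @return A tibble with one row per compound: `compound_key`,
#'   `n_formulas`, one column per category, `pct_sum`, `passes_filter`.
#' @export
association_summary <- function(profiles, threshold = 300) {
  stopifnot(inherits(profiles, "association_profiles"))
  as_tibble(profiles) |>
    tidyr::pivot_wider(names_from = "category", values_from = "pct") |>
    mutate(
      pct_sum = rowSums(across(all_of(indication_categories()))),
      passes_filter = !is.na(.data$pct_sum) & .data$pct_sum > threshold
    ) |>
    arrange(desc(.data$pct_sum), desc(.data$n_formulas),
            .data$compound_key)
}

#' @rdname association_summary
#' @export
candidate_filter <- function(profiles, threshold = 300) {
  association_summary(profiles, threshold) |>
    filter(.data$passes_filter)
}

#' Compound index: mean containment across the four categories
#'
#' For each category, the containment percentage is 100 x (number of
#' category-treating formulas that contain the compound) / (number of
#' category-treating formulas). The compound index is the arithmetic mean
#' of the four containment percentages. Note the denominator is the
#' category's formulas, not the compound's — the converse of
#' [association_profiles()].
#'
#' @param dataset A `formula_dataset`.
#' @param dict A `term_dictionary`.
#' @param compounds Optional character vector of compound keys.
#' @param strict If `TRUE`, a category treated by no formula is an error
#'   naming the category; otherwise it is excluded from the mean with a
#'   warning.
#' @param mode Matching mode.
#' @return A tibble with class `"compound_index"`, one row per
#'   (compound, category): `compound_key`, `category`, `containment_pct`,
#'   plus the per-compound `index` repeated on each row.
#' @export
compound_index <- function(dataset, dict = default_dictionary(),
                           compounds = NULL, strict = FALSE,
                           mode = "token") {
  stopifnot(inherits(dataset, "formula_dataset"))
  keys <- if (is.null(compounds)) dataset$compounds$compound_key else
    check_known_compounds(dataset, compounds)
  cats <- formula_categories(dataset, dict, mode)
  denom <- cats |> count(.data$category, name = "n_cat_formulas")
  empty <- setdiff(indication_categories(), denom$category)
  if (length(empty) > 0) {
    msg <- sprintf("no formula treats category: %s",
                   paste(empty, collapse = ", "))
    if (strict) abort(msg)
    warn(paste0(msg, " — excluded from the index"))
  }

  fc <- formula_compounds(dataset) |>
    filter(.data$compound_key %in% keys)
  numer <- cats |>
    inner_join(fc, by = "formula_id", relationship = "many-to-many") |>
    count(.data$compound_key, .data$category, name = "n_containing")

  grid <- tidyr::expand_grid(compound_key = sort(keys),
                             category = indication_categories())
  out <- grid |>
    left_join(denom, by = "category") |>
    left_join(numer, by = c("compound_key", "category")) |>
    mutate(
      n_containing = ifelse(is.na(.data$n_containing), 0L,
                            .data$n_containing),
      containment_pct = ifelse(is.na(.data$n_cat_formulas), NA_real_,
                               100 * .data$n_containing /
                                 .data$n_cat_formulas)
    ) |>
    group_by(.data$compound_key) |>
    mutate(index = mean(.data$containment_pct, na.rm = TRUE)) |>
    ungroup() |>
    select("compound_key", "category", "containment_pct", "index") |>
    arrange(.data$compound_key, .data$category)
  structure(out, class = c("compound_index", class(out)))
}

#' Species-indication linkage counts
#'
#' Counts (formula, species, category) triples: a formula with s qualifying
#' species treating c categories contributes s x c linkages, each pairing
#' represented individually. This is the statistic behind chord-diagram
#' link files.
#'
#' @param dataset A `formula_dataset`.
#' @param dict A `term_dictionary`.
#' @param genus Optional genus restricting the qualifying species.
#' @param mode Matching mode.
#' @return A tibble (`species`, `category`, `linkages`) sorted by species
#'   then category; only observed pairs appear.
#' @export
species_indication_linkages <- function(dataset,
                                        dict = default_dictionary(),
                                        genus = NULL, mode = "token") {
  stopifnot(inherits(dataset, "formula_dataset"))
  fs <- dataset$formula_species
  if (!is.null(genus)) {
    keep <- dataset$species$species[dataset$species$genus == genus]
    fs <- filter(fs, .data$species %in% keep)
  }
  cats <- formula_categories(dataset, dict, mode)
  fs |>
    inner_join(cats, by = "formula_id", relationship = "many-to-many") |>
    count(.data$species, .data$category, name = "linkages") |>
    arrange(.data$species, .data$category)
}

#' Species over-representation in category-treating formulas
#'
#' Compares a species' share of category-linked formula-species
#' memberships with its share of all memberships. A ratio above 1 flags a
#' species that is over-represented in formulas treating the four
#' categories relative to its overall usage.
#'
#' @param dataset A `formula_dataset`.
#' @param dict A `term_dictionary`.
#' @param species Optional character vector of normalized species names
#'   (default: all species appearing in formulas). A species with no
#'   formula membership is an error.
#' @param mode Matching mode.
#' @return A tibble per species: membership counts, `category_share`,
#'   `overall_share` and `enrichment` (the ratio).
#' @export
species_enrichment <- function(dataset, dict = default_dictionary(),
                               species = NULL, mode = "token") {
  stopifnot(inherits(dataset, "formula_dataset"))
  fs <- distinct(dataset$formula_species)
  if (is.null(species)) species <- sort(unique(fs$species))
  missing <- setdiff(species, fs$species)
  if (length(missing) > 0) {
    abort(sprintf("species with no formula membership: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  cat_formulas <- unique(formula_categories(dataset, dict,
                                            mode)$formula_id)
  fs_cat <- filter(fs, .data$formula_id %in% cat_formulas)
  total_all <- nrow(fs)
  total_cat <- nrow(fs_cat)

  tibble(species = species) |>
    left_join(count(fs, .data$species, name = "n_memberships"),
              by = "species") |>
    left_join(count(fs_cat, .data$species, name = "n_category_memberships"),
              by = "species") |>
    mutate(
      n_category_memberships = ifelse(is.na(.data$n_category_memberships),
                                      0L, .data$n_category_memberships),
      overall_share = .data$n_memberships / total_all,
      category_share = if (total_cat > 0)
        .data$n_category_memberships / total_cat else NA_real_,
      enrichment = .data$category_share / .data$overall_share
    ) |>
    arrange(.data$species)
}

#' Per-compound source-species counts, split by focal genus
#'
#' Counts the distinct species containing each compound, split into the
#' focal genus (e.g. Piper) and all other genera. Each species counts once.
#'
#' @param dataset A `formula_dataset`.
#' @param compounds Optional character vector of compound keys (unknown
#'   keys are an error); default all compounds.
#' @return A tibble (`compound_key`, `n_target_genus`, `n_other_genus`).
#' @export
compound_source_counts <- function(dataset, compounds = NULL) {
  stopifnot(inherits(dataset, "formula_dataset"))
  keys <- if (is.null(compounds)) dataset$compounds$compound_key else
    check_known_compounds(dataset, compounds)
  counts <- dataset$species_compounds |>
    filter(.data$compound_key %in% keys) |>
    inner_join(dataset$species, by = "species") |>
    distinct(.data$compound_key, .data$species, .data$is_target_genus) |>
    group_by(.data$compound_key) |>
    summarise(n_target_genus = sum(.data$is_target_genus),
              n_other_genus = sum(!.data$is_target_genus),
              .groups = "drop")
  tibble(compound_key = sort(keys)) |>
    left_join(counts, by = "compound_key") |>
    mutate(n_target_genus = ifelse(is.na(.data$n_target_genus), 0L,
                                   .data$n_target_genus),
           n_other_genus = ifelse(is.na(.data$n_other_genus), 0L,
                                  .data$n_other_genus))
}

#' Write a Circos-compatible chord-diagram link file
#'
#' Tab-delimited (species, category, linkage weight) rows without a
#' header, sorted by species then category, for rendering by external
#' chord-diagram tools.
#'
#' @param linkages Output of [species_indication_linkages()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_circos_links <- function(linkages, path) {
  assert_columns(linkages, c("species", "category", "linkages"),
                 "linkages")
  df <- arrange(linkages, .data$species, .data$category)
  readr::write_tsv(df, path, col_names = FALSE, eol = "\n",
                   progress = FALSE)
  invisible(path)
}
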