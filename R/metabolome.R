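#' Default phytochemical class map
#'
#' The packaged two-layer classification rules: identifier-level overrides
#' (`match_kind == "identifier"`, matched exactly against a compound's
#' InChIKey or key) take precedence; keyword rules
#' (`match_kind == "keyword"`) then match case-insensitively inside the
#' source-supplied classification string, in file order. Anything unmatched
#' falls through to `"miscellaneous"`. The map is an editable CSV
#' (`inst/extdata/class_map.csv`); pass your own to extend it.
#'
#' @return A tibble (`match_kind`, `pattern`, `bin`).
#' @export
default_class_map <- function() {
  readr::read_csv(pkg_extdata("class_map.csv"), col_types = "ccc",
                  progress = FALSE)
}

#' Assign a chemical-class bin to each compound
#'
#' Applies the class map to a compound table: identifier overrides first
#' (against `inchikey` then `compound_key`), then keyword rules on
#' `chem_class_raw`; unmatched compounds are binned `"miscellaneous"`.
#'
#' @param compounds Data frame with `compound_key` and optionally
#'   `inchikey` and `chem_class_raw`.
#' @param class_map A class map, see [default_class_map()].
#' @return `compounds` with an added `bin` column.
#' @export
#' @examples
#' classify_compounds(data.frame(compound_key = "x",
#'                               chem_class_raw = "Sesquiterpenoids"))
classify_compounds <- function(compounds, class_map = default_class_map()) {
  compounds <- as_tibble(compounds)
  assert_columns(compounds, "compound_key", "compounds")
  assert_columns(class_map, c("match_kind", "pattern", "bin"), "class_map")
  ids <- filter(class_map, .data$match_kind == "identifier")
  kws <- filter(class_map, .data$match_kind == "keyword")

  ik <- if ("inchikey" %in% names(compounds)) compounds$inchikey else
    rep(NA_character_, nrow(compounds))
  raw <- if ("chem_class_raw" %in% names(compounds))
    str_to_lower(compounds$chem_class_raw) else
    rep(NA_character_, nrow(compounds))

  bin <- rep(NA_character_, nrow(compounds))
  if (nrow(ids) > 0) {
    hit <- match(ik, ids$pattern)
    hit2 <- match(compounds$compound_key, ids$pattern)
    use <- ifelse(!is.na(hit), hit, hit2)
    bin[!is.na(use)] <- ids$bin[use[!is.na(use)]]
  }
  for (i in seq_len(nrow(kws))) {
    sel <- is.na(bin) & !is.na(raw) &
      str_detect(raw, fixed(str_to_lower(kws$pattern[i])))
    bin[sel] <- kws$bin[i]
  }
  bin[is.na(bin)] <- "miscellaneous"
  compounds$bin <- bin
  compounds
}

#' Assemble a composite meta-metabolome from multiple sources
#'
#' Merges per-source compound lists (literature compilations, databases,
#' extraction studies) for one species into a reconciled compound set with
#' a presence matrix recording which sources report each compound, assigns
#' the eight chemical-class bins and tallies them. Within-source
#' duplicates count once — the unit is the compound, not the report.
#' Assembly is source-order invariant.
#'
#' @param source_compounds Long data frame, one row per reported compound:
#'   `source_id` plus at least one of `name`, `cid`, `inchikey`, `smiles`,
#'   and optionally `chem_class_raw`.
#' @param sources Optional source metadata table (`source_id`,
#'   `source_kind` in `{"literature-compilation","database",
#'   "extraction-study"}`, `extraction_method`, `solvent`).
#' @param species Species name the metabolome belongs to.
#' @param class_map Class map for binning, see [default_class_map()].
#' @param lookup Optional identifier-enrichment table, see
#'   [reconcile_compounds()].
#' @return A `meta_metabolome` object: list with `species`, `compounds`
#'   (reconciled tibble with `bin`), `presence` (tibble `compound_key`,
#'   `source_id`), `class_tally` (tibble `bin`, `n`, all eight default bins
#'   always present), `total`, `sources`.
#' @export
assemble_meta_metabolome <- function(source_compounds, sources = NULL,
                                     species = NA_character_,
                                     class_map = default_class_map(),
                                     lookup = NULL) {
  source_compounds <- as_tibble(source_compounds)
  assert_columns(source_compounds, "source_id", "source_compounds")
  if (nrow(source_compounds) == 0) {
    abort("assemble_meta_metabolome: empty source union")
  }
  source_compounds$record_id <- as.character(seq_len(nrow(source_compounds)))
  rec <- reconcile_compounds(source_compounds, lookup = lookup)

  presence <- source_compounds |>
    select("record_id", "source_id") |>
    inner_join(rec$mapping, by = "record_id") |>
    distinct(.data$compound_key, .data$source_id) |>
    arrange(.data$compound_key, .data$source_id)

  compounds <- classify_compounds(select(rec$compounds, -"n_records"),
                                  class_map)
  bins <- union(phytochemical_classes(), unique(compounds$bin))
  class_tally <- compounds |>
    count(bin = factor(.data$bin, levels = bins), name = "n",
          .drop = FALSE) |>
    mutate(bin = as.character(.data$bin))

  structure(
    list(species = species, compounds = compounds, presence = presence,
         class_tally = as_tibble(class_tally), total = nrow(compounds),
         sources = if (is.null(sources)) NULL else as_tibble(sources),
         conflicts = rec$conflicts),
    class = "meta_metabolome"
  )
}

#' @export
print.meta_metabolome <- function(x, ...) {
  cat(sprintf("<meta_metabolome> %s: %d compounds from %d source(s)\n",
              x$species %||% "?", x$total,
              length(unique(x$presence$source_id))))
  tl <- x$class_tally[x$class_tally$n > 0, ]
  cat(paste(sprintf("  %-13s %d", tl$bin, tl$n), collapse = "\n"), "\n")
  invisible(x)
}

#' Extraction-study provenance table (Sankey input)
#'
#' One row per (extraction-study source, compound) pair with the study's
#' extraction method and solvent; database and literature-compilation
#' sources are excluded. This long table is the input contract for Sankey
#' rendering by external tools.
#'
#' @param meta A `meta_metabolome`.
#' @param sources Source metadata table; defaults to the one stored in
#'   `meta`.
#' @return A tibble (`source_id`, `extraction_method`, `solvent`,
#'   `compound_key`).
#' @export
solvent_provenance_table <- function(meta, sources = meta$sources) {
  stopifnot(inherits(meta, "meta_metabolome"))
  if (is.null(sources)) abort("source metadata required")
  assert_columns(sources, c("source_id", "source_kind"), "sources")
  for (col in c("extraction_method", "solvent")) {
    if (!col %in% names(sources)) sources[[col]] <- NA_character_
  }
  sources |>
    filter(.data$source_kind == "extraction-study") |>
    inner_join(meta$presence, by = "source_id") |>
    select("source_id", "extraction_method", "solvent", "compound_key") |>
    arrange(.data$source_id, .data$compound_key)
}

#' Write meta-metabolome interchange tables
#'
#' Writes `meta_metabolome.csv` (compound, name, bin), `presence.csv`
#' (compound, source) and, when source metadata is available,
#' `sankey_links.csv` (the [solvent_provenance_table()]).
#'
#' @param meta A `meta_metabolome`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_meta_metabolome <- function(meta, dir) {
  stopifnot(inherits(meta, "meta_metabolome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stable_csv(
    select(meta$compounds, "compound_key", "name", "bin"),
    file.path(dir, "meta_metabolome.csv"))
  write_stable_csv(meta$presence, file.path(dir, "presence.csv"))
  if (!is.null(meta$sources)) {
    write_stable_csv(solvent_provenance_table(meta),
                     file.path(dir, "sankey_links.csv"))
  }
  invisible(dir)
}

#' Packaged synthetic meta-metabolome fixture
#'
#' A synthetic stand-in for a multi-source compound survey of the kava
#' metabolome: four sources whose union holds 268 compounds with class
#' sizes 29 alkaloids, 31 benzenoids, 39 terpenes, 28 cinnamic acids,
#' 10 flavonoids, 35 kavalactones, 17 chalcones and 79 miscellaneous
#' compounds. Generated by [simulate_source_tables()] (seed 268) and
#' shipped as plain CSVs under `inst/extdata/synthetic_pm_meta/`; the
#' compound identities are synthetic, only the class-size structure
#' mirrors the published survey.
#'
#' @return A list: `source_compounds` (long per-source compound table)
#'   and `sources` (source metadata).
#' @export
#' @examples
#' fx <- synthetic_pm_sources()
#' meta <- assemble_meta_metabolome(fx$source_compounds, fx$sources,
#'                                  species = "Piper methysticum")
#' meta$total
synthetic_pm_sources <- function() {
  dir <- dirname(pkg_extdata(file.path("synthetic_pm_meta",
                                       "sources.csv")))
  list(
    source_compounds = readr::read_csv(
      file.path(dir, "source_compounds.csv"),
      col_types = readr::cols(cid = "i", .default = "c"),
      na = "", progress = FALSE),
    sources = readr::read_csv(file.path(dir, "sources.csv"),
                              col_types = "cccc", na = "",
                              progress = FALSE)
  )
}
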