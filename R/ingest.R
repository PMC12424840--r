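#' Ingest configuration for formula tables
#'
#' Describes how a delimited pharmacopeia export maps onto the canonical
#' data model: the field delimiter, the mapping from canonical fields to the
#' file's header names, how multiple indications are packed into one cell,
#' and optional lookup tables for species synonyms and region codes.
#'
#' @param delimiter Single-character field delimiter (default tab).
#' @param columns Named list mapping canonical fields (`formula_id`,
#'   `species`, and optionally `txm_system`, `region`, `compound_name`,
#'   `cid`, `inchikey`, `smiles`, `chem_class`, `indications`) to header
#'   names in the file. `formula_id` and `species` are required.
#' @param indication_sep Separator splitting several indications packed in
#'   one cell (default `";"`).
#' @param synonyms Optional two-column data frame (`raw`, `accepted`) of
#'   species synonyms, applied after normalization.
#' @param region_map Optional two-column data frame (`raw`, `iso3166`)
#'   mapping source region strings to ISO 3166 codes. Unmapped regions keep
#'   their raw string with a warning.
#' @param target_genus Genus flagged as the focal genus in species records
#'   (default `"Piper"`).
#'
#' @return A list with class `"ingest_config"`.
#' @export
ingest_config <- function(delimiter = "\t",
                          columns = list(
                            formula_id = "formula",
                            txm_system = "txm",
                            species = "species",
                            compound_name = "compound",
                            cid = "cid",
                            inchikey = "inchikey",
                            smiles = "smiles",
                            chem_class = "classification",
                            indications = "indications",
                            region = "region"
                          ),
                          indication_sep = ";",
                          synonyms = NULL,
                          region_map = NULL,
                          target_genus = "Piper") {
  for (req in c("formula_id", "species")) {
    if (is.null(columns[[req]])) {
      abort(sprintf("ingest_config: `columns$%s` must be supplied", req))
    }
  }
  structure(
    list(delimiter = delimiter, columns = columns,
         indication_sep = indication_sep, synonyms = synonyms,
         region_map = region_map, target_genus = target_genus),
    class = "ingest_config"
  )
}

#' Normalize species scientific names
#'
#' Reduces raw species strings to a clean binomial: collapses whitespace,
#' drops authority strings and infraspecific ranks beyond the first two
#' tokens, capitalizes the genus and lower-cases the epithet
#' (`"Piper methysticum G. Forst."` becomes `"Piper methysticum"`). An
#' optional synonym table is applied after normalization. The operation is
#' idempotent.
#'
#' @param x Character vector of raw species names.
#' @param synonyms Optional data frame with columns `raw` and `accepted`;
#'   both sides are themselves normalized before lookup.
#' @return Character vector of normalized binomials.
#' @export
#' @examples
#' normalize_species_name("  piper   NIGRUM ")
#' normalize_species_name("Piper methysticum G. Forst.")
normalize_species_name <- function(x, synonyms = NULL) {
  if (any(is.na(x) | !nzchar(str_squish(x)))) {
    abort("normalize_species_name: empty species name")
  }
  norm_one <- function(s) {
    tokens <- strsplit(str_squish(s), " ", fixed = TRUE)[[1]]
    genus <- paste0(toupper(substr(tokens[1], 1, 1)),
                    tolower(substr(tokens[1], 2, nchar(tokens[1]))))
    if (length(tokens) == 1) return(genus)
    paste(genus, tolower(tokens[2]))
  }
  out <- vapply(x, norm_one, character(1), USE.NAMES = FALSE)
  if (!is.null(synonyms)) {
    assert_columns(synonyms, c("raw", "accepted"), "synonyms")
    key <- vapply(synonyms$raw, norm_one, character(1), USE.NAMES = FALSE)
    val <- vapply(synonyms$accepted, norm_one, character(1), USE.NAMES = FALSE)
    hit <- match(out, key)
    out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  out
}

#' Reconcile compound records across identifier systems
#'
#' Merges raw compound records into canonical compounds using identifier
#' precedence InChIKey > CID > normalized name: two records merge when they
#' share an InChIKey; records without an InChIKey merge when they share a
#' CID; records with neither merge when their normalized names (case-folded,
#' punctuation and whitespace collapsed) are equal. Merged records keep the
#' union of their identifiers; conflicting identifiers inside an InChIKey
#' group (e.g. two different CIDs) are kept as the smallest value and logged
#' as a conflict, never a failure. The result is a partition of the input:
#' every record maps to exactly one `compound_key`, independent of input
#' order.
#'
#' @param records Data frame with at least one of the columns `name`,
#'   `cid`, `inchikey`, `smiles` per row; an optional `record_id` column is
#'   preserved in the mapping (row numbers otherwise). An optional
#'   `chem_class_raw` column is carried through.
#' @param lookup Optional identifier-enrichment table with columns `name`
#'   and `inchikey`: records whose normalized name matches gain the listed
#'   InChIKey before grouping (emulating database enrichment of raw names).
#'
#' @return A list with class `"compound_reconciliation"`:
#'   `mapping` (tibble `record_id`, `compound_key`), `compounds` (one row
#'   per merged compound with the union of identifiers and `n_records`),
#'   and `conflicts` (tibble of identifier conflicts).
#' @export
reconcile_compounds <- function(records, lookup = NULL) {
  records <- as_tibble(records)
  for (col in c("name", "cid", "inchikey", "smiles", "chem_class_raw")) {
    if (!col %in% names(records)) records[[col]] <- NA
  }
  if (!"record_id" %in% names(records)) {
    records$record_id <- as.character(seq_len(nrow(records)))
  }
  records$record_id <- as.character(records$record_id)
  records$name <- as.character(records$name)
  records$cid <- suppressWarnings(as.integer(records$cid))
  records$inchikey <- as.character(records$inchikey)
  records$smiles <- as.character(records$smiles)
  records$chem_class_raw <- as.character(records$chem_class_raw)

  records$.name_norm <- normalize_compound_name(records$name)
  bad_ik <- !is.na(records$inchikey) & !is_valid_inchikey(records$inchikey)
  if (any(bad_ik)) {
    warn(sprintf("reconcile_compounds: %d malformed InChIKey(s) ignored",
                 sum(bad_ik)))
    records$inchikey[bad_ik] <- NA_character_
  }
  no_id <- is.na(records$.name_norm) & is.na(records$cid) &
    is.na(records$inchikey) & is.na(records$smiles)
  if (any(no_id)) {
    abort(sprintf("reconcile_compounds: %d record(s) carry no identifier",
                  sum(no_id)))
  }

  if (!is.null(lookup)) {
    assert_columns(lookup, c("name", "inchikey"), "lookup")
    lk_name <- normalize_compound_name(lookup$name)
    hit <- match(records$.name_norm, lk_name)
    fill <- !is.na(hit) & is.na(records$inchikey)
    records$inchikey[fill] <- lookup$inchikey[hit[fill]]
  }

  group <- ifelse(
    !is.na(records$inchikey), paste0("ik:", records$inchikey),
    ifelse(!is.na(records$cid), paste0("cid:", records$cid),
           ifelse(!is.na(records$.name_norm),
                  paste0("name:", records$.name_norm),
                  paste0("smiles:", records$smiles)))
  )
  records$.group <- group

  # Deterministic, order-independent compound keys: groups are processed in
  # lexicographic group-id order; the key is the smallest normalized name in
  # the group (or the group id when no name exists), disambiguated by suffix.
  group_ids <- sort(unique(group))
  base_key <- vapply(group_ids, function(g) {
    nm <- sort(records$.name_norm[records$.group == g])
    if (length(nm) > 0 && !is.na(nm[1])) gsub(" ", "-", nm[1]) else g
  }, character(1))
  key <- base_key
  dup <- duplicated(base_key) | duplicated(base_key, fromLast = TRUE)
  if (any(dup)) {
    for (b in unique(base_key[dup])) {
      idx <- which(base_key == b)
      key[idx] <- paste0(b, "#", seq_along(idx))
    }
  }
  key_of <- setNames(key, group_ids)

  pick <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(v[NA_integer_])
    sort(v)[1]
  }
  compounds <- lapply(group_ids, function(g) {
    rr <- records[records$.group == g, ]
    tibble(
      compound_key = key_of[[g]],
      name = pick(rr$name),
      cid = pick(rr$cid),
      inchikey = pick(rr$inchikey),
      smiles = pick(rr$smiles),
      chem_class_raw = pick(rr$chem_class_raw),
      n_records = nrow(rr)
    )
  })
  compounds <- bind_rows(compounds) |> arrange(.data$compound_key)

  conflicts <- list()
  for (g in group_ids[startsWith(group_ids, "ik:")]) {
    rr <- records[records$.group == g, ]
    for (field in c("cid", "name")) {
      vals <- if (field == "cid") unique(rr$cid[!is.na(rr$cid)]) else
        unique(rr$.name_norm[!is.na(rr$.name_norm)])
      if (length(vals) > 1) {
        conflicts[[length(conflicts) + 1]] <- tibble(
          compound_key = key_of[[g]], field = field,
          values = paste(sort(as.character(vals)), collapse = " | ")
        )
      }
    }
  }
  conflicts <- if (length(conflicts) > 0) bind_rows(conflicts) else
    tibble(compound_key = character(), field = character(),
           values = character())

  structure(
    list(
      mapping = tibble(record_id = records$record_id,
                       compound_key = unname(key_of[records$.group])),
      compounds = compounds,
      conflicts = conflicts
    ),
    class = "compound_reconciliation"
  )
}

new_formula_dataset <- function(formulas, formula_species,
                                formula_indications, species,
                                species_compounds, compounds,
                                report = NULL) {
  assert_columns(formulas, c("formula_id", "txm_system", "region"),
                 "formulas")
  assert_columns(formula_species, c("formula_id", "species"),
                 "formula_species")
  assert_columns(formula_indications, c("formula_id", "indication"),
                 "formula_indications")
  assert_columns(species, c("species", "genus", "is_target_genus"),
                 "species")
  assert_columns(species_compounds, c("species", "compound_key"),
                 "species_compounds")
  assert_columns(compounds, "compound_key", "compounds")
  if (anyDuplicated(formulas$formula_id)) {
    abort("formula_id must be unique within a dataset")
  }
  orphan <- setdiff(formulas$formula_id, formula_species$formula_id)
  if (length(orphan) > 0) {
    abort(sprintf("formula(s) without any species: %s",
                  paste(head(orphan, 5), collapse = ", ")))
  }
  structure(
    list(
      formulas = arrange(as_tibble(formulas), .data$formula_id),
      formula_species = distinct(arrange(as_tibble(formula_species),
                                         .data$formula_id, .data$species)),
      formula_indications = distinct(arrange(as_tibble(formula_indications),
                                             .data$formula_id,
                                             .data$indication)),
      species = arrange(as_tibble(species), .data$species),
      species_compounds = distinct(arrange(as_tibble(species_compounds),
                                           .data$species,
                                           .data$compound_key)),
      compounds = arrange(as_tibble(compounds), .data$compound_key),
      report = report
    ),
    class = "formula_dataset"
  )
}

#' @export
print.formula_dataset <- function(x, ...) {
  cat("<formula_dataset>\n")
  cat(sprintf("  formulas:    %d\n", nrow(x$formulas)))
  cat(sprintf("  species:     %d (%d %s)\n", nrow(x$species),
              sum(x$species$is_target_genus),
              if (any(x$species$is_target_genus))
                paste0("in genus ", x$species$genus[
                  x$species$is_target_genus][1]) else "focal"))
  cat(sprintf("  compounds:   %d\n", nrow(x$compounds)))
  cat(sprintf("  indications: %d\n", nrow(x$formula_indications)))
  invisible(x)
}

#' Read a delimited formula table into the canonical data model
#'
#' Parses a pharmacopeia export with one row per
#' (formula, species, compound) combination, normalizes species names,
#' reconciles compound identifiers and aggregates rows into formula
#' records. Rows with no formula identifier or no species are rejected with
#' row-level diagnostics; loading is idempotent under duplicated rows. A
#' compound is attributed to a formula when any member species of that
#' formula is linked to the compound.
#'
#' @param path Path to the delimited text file (UTF-8, header row).
#' @param config An [ingest_config()].
#' @param lookup Optional identifier-enrichment table passed to
#'   [reconcile_compounds()].
#'
#' @return A `formula_dataset`: a list of normalized tibbles (`formulas`,
#'   `formula_species`, `formula_indications`, `species`,
#'   `species_compounds`, `compounds`) with a load report in `$report`.
#' @export
read_formula_table <- function(path, config = ingest_config(),
                               lookup = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = config$delimiter,
                           col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE)
  cols <- config$columns
  present <- intersect(unlist(cols), names(raw))
  for (req in c("formula_id", "species")) {
    if (!cols[[req]] %in% names(raw)) {
      abort(sprintf("required column `%s` (mapped from `%s`) not in file",
                    cols[[req]], req))
    }
  }
  get_col <- function(field) {
    nm <- cols[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else
      rep(NA_character_, nrow(raw))
  }

  df <- tibble(
    row = seq_len(nrow(raw)),
    formula_id = get_col("formula_id"),
    txm_system = get_col("txm_system"),
    species_raw = get_col("species"),
    compound_name = get_col("compound_name"),
    cid = get_col("cid"),
    inchikey = get_col("inchikey"),
    smiles = get_col("smiles"),
    chem_class_raw = get_col("chem_class"),
    indications = get_col("indications"),
    region = get_col("region")
  )

  bad <- is.na(df$formula_id) | !nzchar(str_squish(df$formula_id)) |
    is.na(df$species_raw) | !nzchar(str_squish(df$species_raw))
  rejected <- df[bad, c("row", "formula_id", "species_raw")]
  rejected$reason <- ifelse(
    is.na(df$formula_id[bad]) | !nzchar(str_squish(df$formula_id[bad])),
    "missing formula_id", "missing species")
  df <- df[!bad, ]
  if (nrow(df) == 0) abort("no loadable rows in file")

  df$species <- normalize_species_name(df$species_raw, config$synonyms)

  # regions: verbatim carry after optional ISO 3166 lookup
  if (!is.null(config$region_map)) {
    assert_columns(config$region_map, c("raw", "iso3166"), "region_map")
    hit <- match(df$region, config$region_map$raw)
    unmapped <- !is.na(df$region) & is.na(hit)
    if (any(unmapped)) {
      warn(sprintf("read_formula_table: %d region value(s) not in region_map; raw strings kept",
                   length(unique(df$region[unmapped]))))
    }
    df$region[!is.na(hit)] <- config$region_map$iso3166[hit[!is.na(hit)]]
  }

  has_cpd <- !(is.na(df$compound_name) & is.na(df$cid) &
                 is.na(df$inchikey) & is.na(df$smiles))
  cpd_rows <- df[has_cpd, ]
  if (nrow(cpd_rows) > 0) {
    rec <- reconcile_compounds(
      tibble(record_id = as.character(cpd_rows$row),
             name = cpd_rows$compound_name, cid = cpd_rows$cid,
             inchikey = cpd_rows$inchikey, smiles = cpd_rows$smiles,
             chem_class_raw = cpd_rows$chem_class_raw),
      lookup = lookup)
    compounds <- select(rec$compounds, -"n_records")
    species_compounds <- distinct(tibble(
      species = cpd_rows$species,
      compound_key = rec$mapping$compound_key))
  } else {
    compounds <- tibble(compound_key = character(), name = character(),
                        cid = integer(), inchikey = character(),
                        smiles = character(), chem_class_raw = character())
    species_compounds <- tibble(species = character(),
                                compound_key = character())
  }

  first_value <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_character_ else v[1]
  }
  formulas <- df |>
    group_by(.data$formula_id) |>
    summarise(txm_system = first_value(.data$txm_system),
              region = first_value(.data$region), .groups = "drop")

  formula_species <- distinct(df[, c("formula_id", "species")])

  ind <- df[!is.na(df$indications), c("formula_id", "indications")]
  formula_indications <- if (nrow(ind) > 0) {
    ind |>
      mutate(indication = str_split(.data$indications,
                                    fixed(config$indication_sep))) |>
      tidyr::unnest("indication") |>
      mutate(indication = str_squish(.data$indication)) |>
      filter(nzchar(.data$indication)) |>
      distinct(.data$formula_id, .data$indication)
  } else {
    tibble(formula_id = character(), indication = character())
  }

  genus <- vapply(strsplit(unique(df$species), " ", fixed = TRUE),
                  `[`, character(1), 1)
  species <- tibble(species = unique(df$species), genus = genus,
                    is_target_genus = genus == config$target_genus)

  report <- list(
    rows_read = nrow(raw), rows_rejected = nrow(rejected),
    rejected = as_tibble(rejected),
    n_formulas = nrow(formulas), n_species = nrow(species),
    n_compounds = nrow(compounds)
  )
  new_formula_dataset(formulas, formula_species, formula_indications,
                      species, species_compounds, compounds, report)
}

#' Write / read the interchange directory of a formula dataset
#'
#' The interchange contract for downstream modules is a directory of
#' long-format CSVs: `formulas.csv`, `formula_species.csv`,
#' `formula_indications.csv`, `species.csv`, `species_compounds.csv`,
#' `compounds.csv`, plus a machine-readable `load_report.json`. Writing is
#' byte-stable for a fixed dataset; `read_formula_dataset()` restores an
#' identical object (round trip).
#'
#' @param dataset A `formula_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_formula_dataset()` returns `dir` invisibly;
#'   `read_formula_dataset()` returns a `formula_dataset`.
#' @export
write_formula_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "formula_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stable_csv(dataset$formulas, file.path(dir, "formulas.csv"))
  write_stable_csv(dataset$formula_species,
                   file.path(dir, "formula_species.csv"))
  write_stable_csv(dataset$formula_indications,
                   file.path(dir, "formula_indications.csv"))
  write_stable_csv(dataset$species, file.path(dir, "species.csv"))
  write_stable_csv(dataset$species_compounds,
                   file.path(dir, "species_compounds.csv"))
  write_stable_csv(dataset$compounds, file.path(dir, "compounds.csv"))
  if (!is.null(dataset$report)) {
    rep <- dataset$report
    rep$rejected <- NULL
    jsonlite::write_json(rep, file.path(dir, "load_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_formula_dataset
#' @export
read_formula_dataset <- function(dir) {
  rd <- function(file, spec) {
    read_interchange_csv(file.path(dir, file), spec)
  }
  new_formula_dataset(
    formulas = rd("formulas.csv", "ccc"),
    formula_species = rd("formula_species.csv", "cc"),
    formula_indications = rd("formula_indications.csv", "cc"),
    species = rd("species.csv", "ccl"),
    species_compounds = rd("species_compounds.csv", "cc"),
    compounds = rd("compounds.csv", readr::cols(
      compound_key = "c", name = "c", cid = "i", inchikey = "c",
      smiles = "c", chem_class_raw = "c"))
  )
}
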