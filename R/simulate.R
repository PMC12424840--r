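# Seeded generators producing datasets with known ground truth. The
# defaults are the package's reference study conditions (see the methods
# vignette); the same seed always yields byte-identical tables.

# phrases guaranteed to fire exactly their category's terms, and decoys
# guaranteed to fire nothing under whole-token matching (e.g. "calmness"
# does NOT fire the literal "calm"; "benefits" does not fire "fits")
category_phrases <- function() {
  list(
    "Anxiety/Mood" = c("anxiety and agitation", "severe panic attacks",
                       "depression", "nervousness and worry",
                       "emotional stress"),
    "Movement/Seizure" = c("epileptic seizure", "muscle spasm",
                           "trembling limbs", "convulsions",
                           "tremor of the hands"),
    "Pain" = c("chronic headache", "joint pain", "rheumatism",
               "stomach ache", "muscle aching"),
    "Sleep" = c("insomnia", "sedative tonic", "hypnotic",
                "soporific remedy", "helps sleep")
  )
}

decoy_phrases <- function() {
  c("benefits", "calmness", "digestive aid", "skin rash",
    "fever and cough")
}

random_inchikeys <- function(n) {
  blocks <- function(k) {
    vapply(seq_len(n), function(i)
      paste(sample(LETTERS, k, replace = TRUE), collapse = ""),
      character(1))
  }
  paste0(blocks(14), "-", blocks(10), "-", "N")
}

#' Simulate a pharmacopeia formula dataset with known ground truth
#'
#' Generates formulas, species, compounds and indication strings in the
#' canonical data model. Each formula independently treats each category
#' with the configured prevalence; its indication phrases are drawn from a
#' phrase bank guaranteed to fire exactly the drawn categories (decoy
#' phrases fire nothing). Compounds attach to formulas through member
#' species: beyond the uniformly sampled species, a carrier species of
#' compound j is added with probability `baseline_inclusion` always, plus
#' `association_uplift[j, c]` when the formula treats category c. An
#' optional `planted` compound is carried by a dedicated focal-genus
#' species inserted only into formulas whose category set covers the
#' planted categories, which drives its percentage sum towards 400.
#'
#' @param n_formulas,n_species,n_compounds Panel sizes.
#' @param target_genus_fraction Fraction of species in the focal genus.
#' @param category_prevalence Named probability per category that a
#'   formula treats it.
#' @param association_uplift Optional `n_compounds` x 4 matrix of
#'   per-(compound, category) inclusion-probability uplifts (default 0).
#' @param baseline_inclusion Baseline carrier-inclusion probability.
#' @param species_compound_density Bernoulli probability of each
#'   species-compound membership.
#' @param species_per_formula Integer vector of candidate formula sizes.
#' @param planted Optional list with elements `categories` (character) —
#'   a planted compound `"planted-compound"` carried only by the dedicated
#'   species `"Piper plantatum"` in formulas covering those categories.
#' @param seed Integer seed; fixes every draw.
#' @return A list: `dataset` (a `formula_dataset`) and `truth` (the drawn
#'   per-formula categories, species-compound membership matrix, uplift
#'   matrix and planted design).
#' @export
simulate_formula_dataset <- function(n_formulas = 200, n_species = 30,
                                     n_compounds = 40,
                                     target_genus_fraction = 0.4,
                                     category_prevalence =
                                       c("Anxiety/Mood" = 0.35,
                                         "Movement/Seizure" = 0.25,
                                         "Pain" = 0.4, "Sleep" = 0.3),
                                     association_uplift = NULL,
                                     baseline_inclusion = 0.08,
                                     species_compound_density = 0.15,
                                     species_per_formula = 1:3,
                                     planted = NULL, seed = 1L) {
  if (n_species < 1 || n_formulas < 1 || n_compounds < 1) {
    abort("simulate_formula_dataset: sizes must be positive")
  }
  cats <- indication_categories()
  stopifnot(all(cats %in% names(category_prevalence)))
  prev <- category_prevalence[cats]
  if (any(prev < 0 | prev > 1)) abort("prevalences must be in [0, 1]")
  if (is.null(association_uplift)) {
    association_uplift <- matrix(0, n_compounds, 4,
                                 dimnames = list(NULL, cats))
  }
  stopifnot(nrow(association_uplift) == n_compounds,
            ncol(association_uplift) == 4)

  with_seed(seed, {
    n_piper <- max(1, round(target_genus_fraction * n_species))
    other_genera <- c("Zingiber", "Curcuma", "Ocimum", "Withania",
                      "Valeriana", "Passiflora")
    genus <- c(rep("Piper", n_piper),
               rep_len(other_genera, n_species - n_piper))
    species_names <- paste(genus,
                           sprintf("simulatum%03d", seq_len(n_species)))
    species <- tibble(species = species_names, genus = genus,
                      is_target_genus = genus == "Piper")

    compound_keys <- sprintf("compound-%03d", seq_len(n_compounds))
    class_pool <- c("Alkaloids", "Benzenoids", "Sesquiterpenoids",
                    "Cinnamic acids", "Flavonoids", "Kavalactones",
                    "Chalcones", "Unclassified")
    compounds <- tibble(
      compound_key = compound_keys,
      name = compound_keys,
      cid = 100000L + seq_len(n_compounds),
      inchikey = random_inchikeys(n_compounds),
      smiles = NA_character_,
      chem_class_raw = sample(class_pool, n_compounds, replace = TRUE)
    )

    # species-compound memberships; every species and compound linked
    membership <- matrix(rbinom(n_species * n_compounds, 1,
                                species_compound_density) == 1,
                         n_species, n_compounds,
                         dimnames = list(species_names, compound_keys))
    for (j in which(colSums(membership) == 0)) {
      membership[sample.int(n_species, 1), j] <- TRUE
    }
    for (i in which(rowSums(membership) == 0)) {
      membership[i, sample.int(n_compounds, 1)] <- TRUE
    }

    formula_ids <- sprintf("F%04d", seq_len(n_formulas))
    cat_draw <- matrix(rbinom(n_formulas * 4, 1, rep(prev,
                                                     each = n_formulas)),
                       n_formulas, 4, dimnames = list(formula_ids, cats))
    phrases <- category_phrases()
    decoys <- decoy_phrases()

    fs_rows <- vector("list", n_formulas)
    fi_rows <- vector("list", n_formulas)
    for (f in seq_len(n_formulas)) {
      n_sp <- species_per_formula[sample.int(length(species_per_formula),
                                             1)]
      base_sp <- sample(species_names, min(n_sp, n_species))
      extra <- character(0)
      treated <- cats[cat_draw[f, ] == 1]
      for (j in seq_len(n_compounds)) {
        p <- baseline_inclusion +
          sum(association_uplift[j, treated, drop = TRUE])
        if (p > 0 && runif(1) < min(p, 1)) {
          carriers <- species_names[membership[, j]]
          extra <- c(extra, sample(carriers, 1))
        }
      }
      fs_rows[[f]] <- tibble(formula_id = formula_ids[f],
                             species = unique(c(base_sp, extra)))
      ind <- vapply(treated, function(ct) sample(phrases[[ct]], 1),
                    character(1))
      if (runif(1) < 0.3 || length(ind) == 0) {
        ind <- c(ind, sample(decoys, 1))
      }
      fi_rows[[f]] <- tibble(formula_id = formula_ids[f],
                             indication = unname(ind))
    }
    formula_species <- bind_rows(fs_rows)
    formula_indications <- bind_rows(fi_rows)

    if (!is.null(planted)) {
      stopifnot(is.list(planted), all(planted$categories %in% cats))
      pl_species <- "Piper plantatum"
      pl_compound <- "planted-compound"
      species <- bind_rows(species,
                           tibble(species = pl_species, genus = "Piper",
                                  is_target_genus = TRUE))
      compounds <- bind_rows(compounds, tibble(
        compound_key = pl_compound, name = pl_compound,
        cid = 999999L, inchikey = random_inchikeys(1),
        smiles = NA_character_, chem_class_raw = "Kavalactones"))
      covered <- formula_ids[rowSums(
        cat_draw[, planted$categories, drop = FALSE] == 1) ==
          length(planted$categories)]
      membership <- rbind(membership,
                          setNames(rep(FALSE, n_compounds),
                                   compound_keys))
      rownames(membership)[nrow(membership)] <- pl_species
      membership <- cbind(membership, setNames(
        c(rep(FALSE, nrow(membership) - 1), TRUE), NULL))
      colnames(membership)[ncol(membership)] <- pl_compound
      if (length(covered) > 0) {
        formula_species <- bind_rows(
          formula_species,
          tibble(formula_id = covered, species = pl_species))
      }
    }

    mem_long <- which(membership, arr.ind = TRUE)
    species_compounds <- tibble(
      species = rownames(membership)[mem_long[, 1]],
      compound_key = colnames(membership)[mem_long[, 2]])

    txm_pool <- c("TCM", "Ayurveda", "Kampo", "Unani")
    regions <- c("CN", "IN", "JP", "FJ", "VU")
    formulas <- tibble(
      formula_id = formula_ids,
      txm_system = sample(txm_pool, n_formulas, replace = TRUE),
      region = sample(regions, n_formulas, replace = TRUE)
    )

    dataset <- new_formula_dataset(formulas, formula_species,
                                   formula_indications, species,
                                   species_compounds, compounds)
    truth <- list(
      categories = as_tibble(cat_draw, rownames = "formula_id"),
      membership = membership,
      association_uplift = association_uplift,
      planted = if (is.null(planted)) NULL else
        list(compound = "planted-compound", species = "Piper plantatum",
             categories = planted$categories)
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate compound records with blanked identifiers
#'
#' Draws `n_records` raw records from `n_true` underlying compounds and
#' blanks identifiers at random, in a way that keeps the true partition
#' recoverable by the single-pass precedence merge of
#' [reconcile_compounds()]: each compound follows one of three identity
#' regimes (InChIKey-bearing, CID-only, name-only), and within a regime
#' non-essential identifiers are blanked independently at `blank_rate`.
#'
#' @param n_true Number of underlying compounds.
#' @param n_records Number of raw records (>= `n_true`; every compound
#'   gets at least one record).
#' @param blank_rate Probability of blanking each non-essential
#'   identifier.
#' @param seed Integer seed.
#' @return A list: `records` (tibble with `record_id`, `name`, `cid`,
#'   `inchikey`) and `truth` (tibble `record_id`, `true_compound`).
#' @export
simulate_compound_records <- function(n_true = 20, n_records = 50,
                                      blank_rate = 0.3, seed = 1L) {
  stopifnot(n_records >= n_true, n_true >= 1)
  with_seed(seed, {
    true_names <- sprintf("compound %03d", seq_len(n_true))
    cids <- 5000L + seq_len(n_true)
    iks <- random_inchikeys(n_true)
    regime <- sample(c("inchikey", "cid", "name"), n_true, replace = TRUE)

    owner <- c(seq_len(n_true),
               sample.int(n_true, n_records - n_true, replace = TRUE))
    owner <- sample(owner)  # shuffle record order
    records <- tibble(
      record_id = sprintf("r%03d", seq_len(n_records)),
      name = true_names[owner],
      cid = cids[owner],
      inchikey = iks[owner]
    )
    # regime-dependent essential identifiers are kept; the rest blank at
    # blank_rate; case/punctuation noise exercises name normalization
    for (i in seq_len(n_records)) {
      rg <- regime[owner[i]]
      if (rg == "inchikey") {
        if (runif(1) < blank_rate) records$cid[i] <- NA_integer_
        if (runif(1) < blank_rate) records$name[i] <- NA_character_
      } else if (rg == "cid") {
        records$inchikey[i] <- NA_character_
        if (runif(1) < blank_rate) records$name[i] <- NA_character_
      } else {
        records$inchikey[i] <- NA_character_
        records$cid[i] <- NA_integer_
      }
      if (!is.na(records$name[i]) && runif(1) < 0.5) {
        records$name[i] <- paste0(toupper(records$name[i]), ".")
      }
    }
    list(records = records,
         truth = tibble(record_id = records$record_id,
                        true_compound = true_names[owner]))
  })
}

#' Simulate per-source compound lists for meta-metabolome assembly
#'
#' Creates compounds with the given per-bin class sizes and scatters them
#' over sources: each compound appears in one home source and in every
#' other source independently with probability `overlap`. Identifier
#' blanking (as in [simulate_compound_records()]) exercises
#' reconciliation.
#'
#' @param class_sizes Named integer vector over chemical-class bins (see
#'   [phytochemical_classes()]).
#' @param n_sources Number of sources.
#' @param overlap Probability a compound is repeated in each non-home
#'   source.
#' @param blank_rate Identifier blanking rate (0 keeps all identifiers).
#' @param seed Integer seed.
#' @return A list: `source_compounds` (long tibble: `source_id`, `name`,
#'   `cid`, `inchikey`, `chem_class_raw`), `sources` (metadata tibble
#'   mixing extraction studies with database/literature sources) and
#'   `truth` (`n_true`, per-compound bin, per-record owner).
#' @export
simulate_source_tables <- function(class_sizes, n_sources = 3,
                                   overlap = 0.5, blank_rate = 0,
                                   seed = 1L) {
  stopifnot(all(class_sizes >= 0), n_sources >= 1)
  stopifnot(!is.null(names(class_sizes)))
  with_seed(seed, {
    bins <- rep(names(class_sizes), class_sizes)
    n_true <- length(bins)
    if (n_true == 0) abort("class_sizes sum to zero")
    # raw classification strings that the default keyword map bins back
    class_string <- c(
      alkaloid = "Alkaloids", benzenoid = "Benzenoid compounds",
      terpene = "Sesquiterpenoids", `cinnamic acid` = "Cinnamic acids",
      flavonoid = "Flavonoids", kavalactone = "Kavalactones",
      chalcone = "Chalcones", miscellaneous = "Unclassified")
    raw_class <- unname(class_string[bins])
    raw_class[is.na(raw_class)] <- "Unclassified"

    compounds <- tibble(
      true_compound = sprintf("%s %03d", bins, seq_len(n_true)),
      bin = bins,
      cid = 10000L + seq_len(n_true),
      inchikey = random_inchikeys(n_true),
      chem_class_raw = raw_class
    )

    sources <- tibble(
      source_id = sprintf("S%02d", seq_len(n_sources)),
      source_kind = rep_len(c("extraction-study", "database",
                              "literature-compilation"), n_sources)
    )
    sources$extraction_method <- ifelse(
      sources$source_kind == "extraction-study",
      rep_len(c("sonication", "SFE", "SPME", "crude solvent"), n_sources),
      NA_character_)
    sources$solvent <- ifelse(
      sources$source_kind == "extraction-study",
      rep_len(c("water", "ethanol", "methanol", "acetone"), n_sources),
      NA_character_)

    home <- sample.int(n_sources, n_true, replace = TRUE)
    rows <- list()
    for (i in seq_len(n_true)) {
      in_src <- unique(c(home[i],
                         which(runif(n_sources) < overlap)))
      rows[[i]] <- tibble(source_id = sources$source_id[sort(in_src)],
                          owner = i)
    }
    long <- bind_rows(rows)
    source_compounds <- tibble(
      source_id = long$source_id,
      name = compounds$true_compound[long$owner],
      cid = compounds$cid[long$owner],
      inchikey = compounds$inchikey[long$owner],
      chem_class_raw = compounds$chem_class_raw[long$owner]
    )
    if (blank_rate > 0) {
      regime <- sample(c("inchikey", "cid", "name"), n_true,
                       replace = TRUE)
      for (i in seq_len(nrow(source_compounds))) {
        rg <- regime[long$owner[i]]
        if (rg == "inchikey") {
          if (runif(1) < blank_rate)
            source_compounds$cid[i] <- NA_integer_
          if (runif(1) < blank_rate)
            source_compounds$name[i] <- NA_character_
        } else if (rg == "cid") {
          source_compounds$inchikey[i] <- NA_character_
          if (runif(1) < blank_rate)
            source_compounds$name[i] <- NA_character_
        } else {
          source_compounds$inchikey[i] <- NA_character_
          source_compounds$cid[i] <- NA_integer_
        }
      }
    }
    list(source_compounds = source_compounds, sources = sources,
         truth = list(n_true = n_true,
                      compounds = compounds,
                      owner = long$owner))
  })
}

#' Simulate a molecule panel with NP-likeness labels
#'
#' Enumerates a packaged library of scaffold templates with two
#' substituent positions (every combination is a valid SMILES), samples
#' `n` molecules, and labels each with a fixed, documented linear function
#' of its scalar descriptors plus seeded Gaussian noise, clipped to
#' [-5, 5]. The label-generating coefficients are returned so recovery
#' checks have a closed form.
#'
#' @param n Panel size.
#' @param seed Integer seed.
#' @param noise_sd Gaussian label noise standard deviation (0 for exact
#'   labels).
#' @param coefficients Optional named numeric vector (`intercept`, `mw`,
#'   `alogp`, `tpsa`, `hbd`, `rotb`) overriding the default
#'   label-generating function.
#' @param shuffle_labels If `TRUE`, labels are randomly permuted across
#'   molecules after generation, destroying every label-feature
#'   relationship (a null panel for calibration checks).
#' @return A list: `panel` (tibble `compound_key`, `smiles`,
#'   `np_likeness`), `descriptors` (scalar descriptor tibble used for the
#'   labels) and `truth` (coefficients and `noise_sd`).
#' @export
simulate_molecule_panel <- function(n = 500, seed = 1L, noise_sd = 0.25,
                                    coefficients = NULL,
                                    shuffle_labels = FALSE) {
  stopifnot(n >= 1)
  tpl <- readr::read_csv(pkg_extdata("smiles_templates.csv"),
                         col_types = "ccc", progress = FALSE)
  sub <- readr::read_csv(pkg_extdata("smiles_substituents.csv"),
                         col_types = "c", progress = FALSE)
  combos <- tidyr::expand_grid(template = tpl$template,
                               r1 = sub$fragment, r2 = sub$fragment)
  combos$smiles <- mapply(function(t, r1, r2) {
    gsub("{R2}", r2, gsub("{R1}", r1, t, fixed = TRUE), fixed = TRUE)
  }, combos$template, combos$r1, combos$r2, USE.NAMES = FALSE)

  if (is.null(coefficients)) {
    coefficients <- c(intercept = 1.2, mw = -0.004, alogp = -0.35,
                      tpsa = 0.012, hbd = 0.25, rotb = -0.15)
  }
  with_seed(seed, {
    take <- if (n <= nrow(combos)) sample.int(nrow(combos), n) else
      sample.int(nrow(combos), n, replace = TRUE)
    smiles <- combos$smiles[take]
    ids <- sprintf("mol%04d", seq_len(n))
    desc <- compute_descriptors(smiles, ids = ids, fingerprint = FALSE)
    stopifnot(nrow(desc) == n)
    mu <- coefficients["intercept"] +
      coefficients["mw"] * (desc$mw - 300) +
      coefficients["alogp"] * desc$alogp +
      coefficients["tpsa"] * desc$tpsa +
      coefficients["hbd"] * desc$hbd +
      coefficients["rotb"] * desc$rotb
    labels <- mu + rnorm(n, 0, noise_sd)
    labels <- pmin(5, pmax(-5, labels))
    if (shuffle_labels) labels <- sample(labels)
    list(
      panel = tibble(compound_key = ids, smiles = smiles,
                     np_likeness = unname(labels)),
      descriptors = desc,
      truth = list(coefficients = coefficients, noise_sd = noise_sd,
                   shuffled = shuffle_labels)
    )
  })
}
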