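# Independent brute-force oracles: plain base-R triple loops over the raw
# tables, written without the package's dplyr pipelines so agreement is a
# genuine cross-check.

oracle_formula_species <- function(dataset, fid) {
  dataset$formula_species$species[dataset$formula_species$formula_id == fid]
}

oracle_formula_has_compound <- function(dataset, fid, key) {
  found <- FALSE
  for (s in oracle_formula_species(dataset, fid)) {
    links <- dataset$species_compounds$compound_key[
      dataset$species_compounds$species == s]
    if (key %in% links) found <- TRUE
  }
  found
}

oracle_text_categories <- function(text, dict) {
  toks <- unlist(strsplit(tolower(text), "[^a-z0-9]+"))
  toks <- toks[nzchar(toks)]
  cats <- character(0)
  for (i in seq_len(nrow(dict))) {
    stem <- dict$stem[i]
    fire <- switch(
      dict$kind[i],
      "literal" = stem %in% toks,
      "suffix-wildcard" = any(substr(toks, 1, nchar(stem)) == stem),
      "prefix-wildcard" = any(substring(
        toks, pmax(1, nchar(toks) - nchar(stem) + 1)) == stem))
    if (isTRUE(fire)) cats <- c(cats, dict$category[i])
  }
  unique(cats)
}

oracle_formula_categories <- function(dataset, dict, fid) {
  inds <- dataset$formula_indications$indication[
    dataset$formula_indications$formula_id == fid]
  cats <- character(0)
  for (ind in inds) cats <- c(cats, oracle_text_categories(ind, dict))
  unique(cats)
}

# Precomputed per-formula maps (category sets and compound containment),
# built once per dataset by plain loops, then reused by the statistic
# oracles below.
oracle_maps <- function(dataset, dict) {
  fids <- dataset$formulas$formula_id
  cats_map <- list()
  comp_map <- list()
  keys <- dataset$compounds$compound_key
  for (fid in fids) {
    cats_map[[fid]] <- oracle_formula_categories(dataset, dict, fid)
    has <- character(0)
    for (key in keys) {
      if (oracle_formula_has_compound(dataset, fid, key)) {
        has <- c(has, key)
      }
    }
    comp_map[[fid]] <- has
  }
  list(fids = fids, keys = keys, cats = cats_map, comps = comp_map)
}

oracle_profile_from_maps <- function(maps, key) {
  containing <- maps$fids[vapply(maps$fids, function(f)
    key %in% maps$comps[[f]], logical(1))]
  n <- length(containing)
  pct <- setNames(rep(NA_real_, 4), indication_categories())
  if (n > 0) {
    for (cat in indication_categories()) {
      k <- sum(vapply(containing, function(f)
        cat %in% maps$cats[[f]], logical(1)))
      pct[cat] <- 100 * k / n
    }
  }
  list(n_formulas = n, pct = pct)
}

oracle_index_from_maps <- function(maps, key) {
  cont <- setNames(rep(NA_real_, 4), indication_categories())
  for (cat in indication_categories()) {
    treating <- maps$fids[vapply(maps$fids, function(f)
      cat %in% maps$cats[[f]], logical(1))]
    if (length(treating) > 0) {
      k <- sum(vapply(treating, function(f)
        key %in% maps$comps[[f]], logical(1)))
      cont[cat] <- 100 * k / length(treating)
    }
  }
  list(containment = cont, index = mean(cont, na.rm = TRUE))
}

# per-compound association percentages (denominator: compound's formulas)
oracle_association_profile <- function(dataset, dict, key) {
  fids <- dataset$formulas$formula_id
  containing <- character(0)
  for (fid in fids) {
    if (oracle_formula_has_compound(dataset, fid, key)) {
      containing <- c(containing, fid)
    }
  }
  n <- length(containing)
  pct <- setNames(rep(NA_real_, 4), indication_categories())
  if (n > 0) {
    for (cat in indication_categories()) {
      k <- 0
      for (fid in containing) {
        if (cat %in% oracle_formula_categories(dataset, dict, fid)) {
          k <- k + 1
        }
      }
      pct[cat] <- 100 * k / n
    }
  }
  list(n_formulas = n, pct = pct)
}

# per-compound containment percentages (denominator: category's formulas)
oracle_compound_index <- function(dataset, dict, key) {
  fids <- dataset$formulas$formula_id
  cont <- setNames(rep(NA_real_, 4), indication_categories())
  for (cat in indication_categories()) {
    treating <- character(0)
    for (fid in fids) {
      if (cat %in% oracle_formula_categories(dataset, dict, fid)) {
        treating <- c(treating, fid)
      }
    }
    if (length(treating) > 0) {
      k <- 0
      for (fid in treating) {
        if (oracle_formula_has_compound(dataset, fid, key)) k <- k + 1
      }
      cont[cat] <- 100 * k / length(treating)
    }
  }
  list(containment = cont, index = mean(cont, na.rm = TRUE))
}

oracle_linkages <- function(dataset, dict, genus = NULL) {
  keep <- dataset$species$species
  if (!is.null(genus)) {
    keep <- dataset$species$species[dataset$species$genus == genus]
  }
  counts <- list()
  for (fid in dataset$formulas$formula_id) {
    cats <- oracle_formula_categories(dataset, dict, fid)
    sps <- intersect(oracle_formula_species(dataset, fid), keep)
    for (s in sps) for (cat in cats) {
      k <- paste(s, cat, sep = "\r")
      counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  counts
}

oracle_source_counts <- function(dataset, key) {
  sps <- unique(dataset$species_compounds$species[
    dataset$species_compounds$compound_key == key])
  tg <- dataset$species$is_target_genus[match(sps, dataset$species$species)]
  c(target = sum(tg), other = sum(!tg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# python RDKit bridge used as the independent QED reference
rdkit_qed_reference <- function(smiles) {
  script <- '
import sys, json
from rdkit import Chem
from rdkit.Chem import QED
out = []
for smi in sys.argv[1:]:
    m = Chem.MolFromSmiles(smi)
    p = QED.properties(m)
    out.append({"smiles": smi, "mw": p.MW, "alogp": p.ALOGP, "hba": p.HBA,
                "hbd": p.HBD, "psa": p.PSA, "rotb": p.ROTB, "arom": p.AROM,
                "alerts": p.ALERTS, "qed": QED.qed(m)})
print(json.dumps(out))
'
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  on.exit(unlink(f))
  out <- system2("python", c(f, shQuote(smiles)), stdout = TRUE,
                 stderr = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}
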