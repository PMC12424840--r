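test_that("species names normalize to clean binomials, idempotently", {
  expect_equal(normalize_species_name("Piper methysticum G. Forst."),
               "Piper methysticum")
  expect_equal(normalize_species_name("  piper   NIGRUM "), "Piper nigrum")
  expect_equal(normalize_species_name("Piper nigrum var. alba"),
               "Piper nigrum")
  syn <- data.frame(raw = "Macropiper methysticum",
                    accepted = "Piper methysticum")
  expect_equal(normalize_species_name("Macropiper methysticum",
                                      synonyms = syn),
               "Piper methysticum")
  # idempotence over a spread of messy inputs
  raw <- c("piper LONGUM L.", " Zingiber  officinale Roscoe",
           "Ocimum basilicum", "Piper methysticum G. Forst.")
  once <- normalize_species_name(raw)
  expect_equal(normalize_species_name(once), once)
  expect_error(normalize_species_name(""), "empty")
})

test_that("compound reconciliation follows identifier precedence", {
  ik <- "ABCDEFGHIJKLMN-OPQRSTUVWX-N"
  rec <- reconcile_compounds(data.frame(
    name = c("Piperine", "piperine "),
    inchikey = c(ik, ik)))
  expect_equal(nrow(rec$compounds), 1)
  expect_equal(rec$compounds$inchikey, ik)

  rec2 <- reconcile_compounds(data.frame(
    name = c("camphor", "Camphor."), cid = c(NA, NA)))
  expect_equal(nrow(rec2$compounds), 1)

  # same InChIKey but different CIDs: merged under the key, conflict logged
  rec3 <- reconcile_compounds(data.frame(
    name = c("a", "a"), cid = c(10L, 20L), inchikey = c(ik, ik)))
  expect_equal(nrow(rec3$compounds), 1)
  expect_equal(rec3$compounds$cid, 10L)
  expect_equal(nrow(rec3$conflicts), 1)

  # records sharing a CID but one carrying an InChIKey do NOT merge
  rec4 <- reconcile_compounds(data.frame(
    name = c("x", "y"), cid = c(7L, 7L), inchikey = c(ik, NA)))
  expect_equal(nrow(rec4$compounds), 2)
})

test_that("reconciliation recovers the generator's true partition and is order-independent", {
  for (seed in c(2, 17)) {
    sim <- simulate_compound_records(n_true = 20, n_records = 50,
                                     blank_rate = 0.3, seed = seed)
    rec <- reconcile_compounds(sim$records)
    expect_equal(nrow(rec$compounds), 20)
    joined <- merge(rec$mapping, sim$truth, by = "record_id")
    split_keys <- tapply(joined$compound_key, joined$true_compound,
                         function(x) length(unique(x)))
    expect_true(all(split_keys == 1))

    # permutation invariance of the partition
    perm <- phytomine:::with_seed(99, sample.int(nrow(sim$records)))
    rec_p <- reconcile_compounds(sim$records[perm, ])
    m1 <- rec$mapping[order(rec$mapping$record_id), ]
    m2 <- rec_p$mapping[order(rec_p$mapping$record_id), ]
    expect_equal(m1, m2, ignore_attr = TRUE)
  }
})

test_that("an identifier lookup row bridges name-only and key-bearing records", {
  ik <- "QWERTYUIOPASDF-GHJKLZXCVB-N"
  rec <- reconcile_compounds(
    data.frame(name = c("yangonin", NA), inchikey = c(NA, ik)),
    lookup = data.frame(name = "Yangonin", inchikey = ik))
  expect_equal(nrow(rec$compounds), 1)
})

test_that("formula tables load, deduplicate and round-trip", {
  tsv <- paste(
    "formula\ttxm\tspecies\tcompound\tindications\tregion",
    "F1\tTCM\tPiper nigrum\tpiperine\tinsomnia; chronic pain\tCN",
    "F1\tTCM\tZingiber officinale Roscoe\tgingerol\tinsomnia; chronic pain\tCN",
    "\tTCM\tPiper nigrum\tpiperine\tx\tCN",
    sep = "\n")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tsv, f)
  ds <- read_formula_table(f)
  expect_equal(nrow(ds$formulas), 1)
  expect_equal(nrow(ds$formula_species), 2)
  expect_equal(sort(ds$formula_indications$indication),
               c("chronic pain", "insomnia"))
  expect_equal(ds$report$rows_rejected, 1)
  expect_equal(ds$report$rejected$reason, "missing formula_id")

  # duplicated rows load to the identical dataset
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(tsv, "F1\tTCM\tPiper nigrum\tpiperine\tinsomnia; chronic pain\tCN",
                   sep = "\n"), f2)
  ds2 <- read_formula_table(f2)
  for (tab in c("formulas", "formula_species", "formula_indications",
                "species", "species_compounds", "compounds")) {
    expect_equal(ds[[tab]], ds2[[tab]])
  }

  expect_error(read_formula_table(f, ingest_config(
    columns = list(formula_id = "nope", species = "species"))),
    "required column")
})

test_that("interchange write/read round-trips a synthetic dataset", {
  sim <- simulate_formula_dataset(n_formulas = 10, n_species = 6,
                                  n_compounds = 8, seed = 4)
  dir <- withr::local_tempdir()
  write_formula_dataset(sim$dataset, dir)
  back <- read_formula_dataset(dir)
  for (tab in c("formulas", "formula_species", "formula_indications",
                "species", "species_compounds", "compounds")) {
    expect_equal(as.data.frame(back[[tab]]),
                 as.data.frame(sim$dataset[[tab]]))
  }
})
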