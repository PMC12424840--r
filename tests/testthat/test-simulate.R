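test_that("the formula generator is deterministic and internally consistent", {
  a <- simulate_formula_dataset(n_formulas = 25, n_species = 8,
                                n_compounds = 10, seed = 42)
  b <- simulate_formula_dataset(n_formulas = 25, n_species = 8,
                                n_compounds = 10, seed = 42)
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth$categories, b$truth$categories)
  c <- simulate_formula_dataset(n_formulas = 25, n_species = 8,
                                n_compounds = 10, seed = 43)
  expect_false(identical(a$dataset, c$dataset))

  # byte-identical interchange files under a fixed seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_formula_dataset(a$dataset, d1)
  write_formula_dataset(b$dataset, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_error(simulate_formula_dataset(n_species = 0), "positive")
})

test_that("indication phrases encode exactly the drawn category sets", {
  sim <- simulate_formula_dataset(n_formulas = 80, n_species = 10,
                                  n_compounds = 10, seed = 55)
  cats <- categorize_formulas(sim$dataset)
  got <- split(cats$category, cats$formula_id)
  truth <- sim$truth$categories
  for (i in seq_len(nrow(truth))) {
    fid <- truth$formula_id[i]
    drawn <- indication_categories()[
      unlist(truth[i, indication_categories()]) == 1]
    expect_setequal(unique(got[[fid]] %||% character(0)), drawn)
  }
})

test_that("zero uplift leaves the compound index at baseline containment", {
  sim <- simulate_formula_dataset(n_formulas = 2000, n_species = 12,
                                  n_compounds = 6,
                                  baseline_inclusion = 0.1,
                                  species_compound_density = 0.12,
                                  seed = 77)
  ds <- sim$dataset
  ci <- compound_index(ds)
  fc <- phytomine:::formula_compounds(ds)
  n_f <- nrow(ds$formulas)
  for (key in ds$compounds$compound_key) {
    overall <- 100 * sum(fc$compound_key == key) / n_f
    idx <- ci$index[ci$compound_key == key][1]
    # index deviates from overall containment only by binomial noise;
    # 3 standard errors on the category-conditional percentages
    se <- 100 * sqrt(overall / 100 * (1 - overall / 100) / (n_f * 0.25))
    expect_lt(abs(idx - overall), 3 * se + 1e-9)
  }
})

test_that("a compound planted in all-four-category formulas saturates the filter", {
  sim <- simulate_formula_dataset(
    n_formulas = 400, n_species = 10, n_compounds = 8,
    category_prevalence = c("Anxiety/Mood" = 0.5,
                            "Movement/Seizure" = 0.5,
                            "Pain" = 0.5, "Sleep" = 0.5),
    planted = list(categories = indication_categories()), seed = 91)
  prof <- association_profiles(sim$dataset)
  s <- association_summary(prof)
  planted_row <- s[s$compound_key == "planted-compound", ]
  expect_equal(planted_row$pct_sum, 400)
  expect_true(planted_row$passes_filter)
  expect_gt(planted_row$n_formulas, 0)
})

test_that("molecule panels parse, label deterministically, and respect the scale", {
  pan <- simulate_molecule_panel(n = 120, seed = 31, noise_sd = 0)
  expect_equal(nrow(pan$panel), 120)
  # validity by construction: the descriptor backend parsed every SMILES
  expect_equal(nrow(pan$descriptors), 120)
  expect_true(all(pan$panel$np_likeness >= -5 &
                    pan$panel$np_likeness <= 5))

  # zero noise: labels reproducible from descriptors and coefficients
  co <- pan$truth$coefficients
  mu <- co["intercept"] + co["mw"] * (pan$descriptors$mw - 300) +
    co["alogp"] * pan$descriptors$alogp +
    co["tpsa"] * pan$descriptors$tpsa +
    co["hbd"] * pan$descriptors$hbd +
    co["rotb"] * pan$descriptors$rotb
  expect_equal(pan$panel$np_likeness, unname(pmin(5, pmax(-5, mu))))

  pan2 <- simulate_molecule_panel(n = 120, seed = 31, noise_sd = 0)
  expect_identical(pan$panel, pan2$panel)
})

test_that("source-table generation honours overlap and blanking contracts", {
  # overlap 0 across 3 sources: total equals the sum of per-source counts
  st0 <- simulate_source_tables(c(alkaloid = 5, terpene = 7),
                                n_sources = 3, overlap = 0, seed = 1)
  m0 <- assemble_meta_metabolome(st0$source_compounds, st0$sources)
  expect_equal(m0$total, 12)
  expect_equal(nrow(st0$source_compounds), 12)

  # 30% blanking from 20 true compounds still reconciles to exactly 20
  st <- simulate_source_tables(c(miscellaneous = 20), n_sources = 3,
                               overlap = 0.6, blank_rate = 0.3,
                               seed = 19)
  m <- assemble_meta_metabolome(st$source_compounds, st$sources)
  expect_equal(m$total, 20)
})
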