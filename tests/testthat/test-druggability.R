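test_that("descriptors match independent chemistry facts", {
  d <- compute_descriptors(c("CCO", "C", "CCCCC"), extras = TRUE)
  eth <- d[d$smiles == "CCO", ]
  expect_equal(eth$hbd, 1L)
  expect_equal(eth$hba, 1L)
  expect_equal(eth$rotb, 0L)
  expect_equal(eth$mw, 46.07, tolerance = 0.01)
  methane <- d[d$smiles == "C", ]
  expect_equal(methane$tpsa, 0)
  pentane <- d[d$smiles == "CCCCC", ]
  expect_equal(pentane$rotb, 2L)
  expect_equal(pentane$hba, 0L)
  expect_true(all(lengths(d$fp_bits[d$smiles != "C"]) > 0))
  expect_true(all(unlist(d$fp_bits) >= 0 & unlist(d$fp_bits) < 2048))

  expect_error(compute_descriptors("not-a-smiles"), "not-a-smiles")
  dropped <- compute_descriptors(c("CCO", "not-a-smiles"),
                                 strict = FALSE)
  expect_equal(nrow(dropped), 1)
})

test_that("the circular fingerprint distinguishes structure, not input order", {
  d <- compute_descriptors(c("CCO", "OCC", "CCN", "c1ccccc1O"))
  # same molecule written in two directions -> identical bits
  expect_equal(d$fp_bits[[1]], d$fp_bits[[2]])
  expect_false(identical(d$fp_bits[[1]], d$fp_bits[[3]]))
  m <- fingerprint_matrix(d)
  expect_equal(dim(m), c(4L, 2048L))
  expect_equal(unname(rowSums(m)), lengths(d$fp_bits))
})

test_that("rule-of-five boundaries are strict and monotone", {
  expect_equal(lipinski_violations(
    data.frame(mw = 500, alogp = 5, hbd = 5, hba = 10)), 0L)
  expect_equal(lipinski_violations(
    data.frame(mw = 600, alogp = 6, hbd = 6, hba = 11)), 4L)

  rules <- phytomine:::with_seed(77, data.frame(
    mw = runif(1000, 100, 900), alogp = runif(1000, -2, 9),
    hbd = sample(0:9, 1000, TRUE), hba = sample(0:15, 1000, TRUE)))
  oracle <- with(rules, (mw > 500) + (alogp > 5) + (hbd > 5) + (hba > 10))
  expect_equal(lipinski_violations(rules), as.integer(oracle))

  # monotone in each argument
  base <- data.frame(mw = 400, alogp = 4, hbd = 4, hba = 8)
  for (col in names(base)) {
    up <- base
    up[[col]] <- up[[col]] * 2
    expect_true(lipinski_violations(up) >= lipinski_violations(base))
  }
})

test_that("weighted QED reduces to the geometric mean under equal weights", {
  props <- data.frame(mw = 300, alogp = 2.5, hba = 3, hbd = 1, psa = 60,
                      rotb = 4, arom = 2, alerts = 0)
  params <- default_qed_params()
  d <- vapply(params$property, function(p)
    qed_desirability(props[[p]], p, params), numeric(1))
  eq <- weighted_qed(props, weights = setNames(rep(1, 8),
                                               params$property))
  expect_equal(eq, exp(mean(log(d))), tolerance = 1e-12)
  # range bound on assorted molecules
  desc <- compute_descriptors(
    c("CCO", "CC(=O)Oc1ccccc1C(=O)O",
      "COC1=CC(=O)OC(C=Cc2ccccc2)C1"), extras = TRUE)
  q <- weighted_qed(desc)
  expect_true(all(q > 0 & q <= 1))
})

test_that("weighted QED agrees with the reference implementation on its own properties", {
  fixtures <- c(
    "CCO",
    "CC(=O)Oc1ccccc1C(=O)O",
    "COC1=CC(=O)OC(C=Cc2ccccc2)C1",
    "O=C(N1CCCCC1)C=Cc1ccc2OCOc2c1",
    "CN1CCC[C@H]1c1cccnc1",
    "Oc1ccc(C=CC(=O)c2ccccc2O)cc1",
    "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
    "CC(=O)Nc1ccc(O)cc1",
    "O=c1cc(-c2ccccc2)oc2ccccc12",
    "NCCc1ccc(O)c(O)c1")
  ref <- rdkit_qed_reference(fixtures)
  ours <- weighted_qed(ref[, c("mw", "alogp", "hba", "hbd", "psa",
                               "rotb", "arom", "alerts")])
  expect_equal(ours, ref$qed, tolerance = 1e-6)
})

test_that("the NP-likeness imputer recovers planted structure on a small panel", {
  pan <- simulate_molecule_panel(n = 300, seed = 3, noise_sd = 0)
  desc <- compute_descriptors(pan$panel$smiles,
                              ids = pan$panel$compound_key)
  imp <- train_np_imputer(pan$panel, imputer_config(seed = 11),
                          descriptors = desc)
  expect_gt(imp$evaluation$r_squared, 0.9)
  expect_equal(imp$evaluation$n_train + imp$evaluation$n_valid, 300)
  expect_equal(imp$evaluation$n_train, round(0.85 * 300))

  # seeded determinism: identical evaluation on re-train
  imp2 <- train_np_imputer(pan$panel, imputer_config(seed = 11),
                           descriptors = desc)
  expect_identical(imp$evaluation, imp2$evaluation)

  g <- glance(imp)
  expect_equal(g$n_trees, 150L)
  expect_equal(g$max_depth, 80L)

  expect_error(train_np_imputer(pan$panel[1:5, ]), "at least 10")
  bad <- pan$panel
  bad$np_likeness[3] <- NA
  expect_error(train_np_imputer(bad), "non-finite")
})

test_that("imputation fills only missing scores and reports the fraction", {
  pan <- simulate_molecule_panel(n = 200, seed = 6, noise_sd = 0)
  imp <- train_np_imputer(pan$panel, imputer_config(seed = 2))
  records <- pan$panel
  hide <- phytomine:::with_seed(8, sample.int(200, 80))
  observed_truth <- records$np_likeness
  records$np_likeness[hide] <- NA

  out <- impute_np_likeness(imp, records)
  expect_equal(out$np_likeness[-hide], observed_truth[-hide])
  expect_equal(unique(out$np_source[-hide]), "observed")
  expect_equal(unique(out$np_source[hide]), "imputed")
  expect_equal(attr(out, "imputed_fraction"), 80 / 200)
  # zero-noise linear ground truth is recovered closely
  expect_lt(mean(abs(out$np_likeness[hide] - observed_truth[hide])),
            0.25)

  empty <- impute_np_likeness(imp, records[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("set comparison summarises bands and violation proportions", {
  records <- tibble::tibble(
    compound_key = c("a", "b", "c", "d"),
    wqed = c(0.5, 0.9, 0.42, 0.65),
    np_likeness = c(1.0, 3.5, 0.7, 2.0),
    ro5_violations = c(0L, 2L, 0L, 0L))
  cmp <- compare_sets(records, list(
    one = "a", clean = c("a", "c", "d"), all = letters[1:4],
    all2 = letters[1:4], none = character(0)))
  s <- cmp$summary
  expect_equal(s$in_band_fraction[s$set == "one" & s$metric == "wqed"], 1)
  expect_equal(cmp$ro5$prop_zero_violations[cmp$ro5$set == "clean"], 1)
  expect_equal(cmp$ro5$prop_with_violations[cmp$ro5$set == "all"], 0.25)
  # identical sets give identical rows
  expect_equal(s[s$set == "all", -1], s[s$set == "all2", -1],
               ignore_attr = TRUE)
  expect_equal(cmp$ro5$n[cmp$ro5$set == "none"], 0L)
  expect_true(is.na(cmp$ro5$prop_zero_violations[cmp$ro5$set == "none"]))
})
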