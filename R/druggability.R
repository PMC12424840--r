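#' Lipinski rule-of-five violation counts
#'
#' Counts breached rules among molecular weight > 500 Da, ALogP > 5,
#' H-bond donors > 5 and H-bond acceptors > 10 (strict inequalities, so a
#' molecule exactly at every threshold has zero violations).
#'
#' @param descriptors Data frame with numeric columns `mw`, `alogp`,
#'   `hbd`, `hba` (e.g. from [compute_descriptors()]).
#' @return Integer vector in 0..4, one per row.
#' @export
#' @examples
#' lipinski_violations(data.frame(mw = 500, alogp = 5, hbd = 5, hba = 10))
lipinski_violations <- function(descriptors) {
  assert_columns(descriptors, c("mw", "alogp", "hbd", "hba"),
                 "descriptors")
  with(descriptors,
       as.integer((mw > 500) + (alogp > 5) + (hbd > 5) + (hba > 10)))
}

#' Imputer configuration
#'
#' Hyperparameters of the natural-product-likeness random-forest imputer:
#' 150 trees with maximum depth 80, trained on an 85%/15% random
#' train/validation split. One seed governs the split, the bootstrap and
#' the feature subsampling.
#'
#' @param n_trees Number of trees (default 150).
#' @param max_depth Maximum tree depth (default 80).
#' @param train_fraction Training fraction in (0, 1) (default 0.85).
#' @param seed Integer random seed.
#' @param mtry Features considered per split; `NULL` (default) uses all
#'   features, mirroring the reference RandomForestRegressor whose
#'   default considers every feature for regression splits.
#' @param min_node_size Minimum node size eligible for splitting
#'   (default 2, again the reference regressor's behaviour).
#' @return A list with class `"imputer_config"`.
#' @export
imputer_config <- function(n_trees = 150, max_depth = 80,
                           train_fraction = 0.85, seed = 1L,
                           mtry = NULL, min_node_size = 2) {
  stopifnot(n_trees >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 train_fraction = train_fraction,
                 seed = as.integer(seed),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_node_size = as.integer(min_node_size)),
            class = "imputer_config")
}

imputer_features <- function(descriptors) {
  scalar <- as.matrix(descriptors[, c("mw", "hba", "hbd", "tpsa",
                                      "rotb", "alogp")])
  cbind(scalar, fingerprint_matrix(descriptors))
}

#' Train the NP-likeness random-forest imputer
#'
#' Fits a random-forest regression of observed natural-product-likeness
#' scores on the 2048-bit circular fingerprint plus molecular weight,
#' H-bond acceptor and donor counts, polar surface area, rotatable bonds
#' and ALogP. The labeled records are split at `train_fraction` with the
#' configured seed; the held-out split yields the validation R^2
#' (coefficient of determination) and mean squared error.
#'
#' @param labeled Data frame with columns `smiles` and `np_likeness`
#'   (finite numeric label per record) and optionally `compound_key`.
#' @param config An [imputer_config()].
#' @param descriptors Optional precomputed [compute_descriptors()] output
#'   for `labeled$smiles` (with fingerprints), to avoid recomputation.
#' @return An `np_imputer`: list with the fitted `ranger` model, the
#'   config and an `evaluation` list (`r_squared`, `mse`, `n_train`,
#'   `n_valid`). Supports [glance()] and `predict()`.
#' @export
train_np_imputer <- function(labeled, config = imputer_config(),
                             descriptors = NULL) {
  labeled <- as_tibble(labeled)
  assert_columns(labeled, c("smiles", "np_likeness"), "labeled")
  if (nrow(labeled) < 10) {
    abort("train_np_imputer: need at least 10 labeled records")
  }
  bad <- !is.finite(labeled$np_likeness)
  if (any(bad)) {
    who <- if ("compound_key" %in% names(labeled))
      labeled$compound_key[bad] else which(bad)
    abort(sprintf("non-finite np_likeness label for record(s): %s",
                  paste(head(who, 5), collapse = ", ")))
  }
  if (is.null(descriptors)) {
    descriptors <- compute_descriptors(labeled$smiles, fingerprint = TRUE)
  }
  stopifnot(nrow(descriptors) == nrow(labeled))
  x <- imputer_features(descriptors)
  y <- labeled$np_likeness

  n <- nrow(x)
  idx_train <- with_seed(config$seed,
                         sort(sample.int(n, round(config$train_fraction * n))))
  idx_valid <- setdiff(seq_len(n), idx_train)

  fit <- ranger::ranger(
    x = x[idx_train, , drop = FALSE], y = y[idx_train],
    num.trees = config$n_trees, max.depth = config$max_depth,
    mtry = config$mtry %||% ncol(x),
    min.node.size = config$min_node_size %||% 2L,
    seed = config$seed, num.threads = 1, verbose = FALSE
  )
  pred <- predict(fit, data = x[idx_valid, , drop = FALSE],
                  num.threads = 1)$predictions
  yv <- y[idx_valid]
  evaluation <- list(
    r_squared = 1 - sum((yv - pred)^2) / sum((yv - mean(yv))^2),
    mse = mean((yv - pred)^2),
    n_train = length(idx_train), n_valid = length(idx_valid)
  )
  structure(list(model = fit, config = config, evaluation = evaluation,
                 feature_names = colnames(x)),
            class = "np_imputer")
}

#' @export
print.np_imputer <- function(x, ...) {
  e <- x$evaluation
  cat(sprintf(paste0("<np_imputer> %d trees, depth <= %d | validation R^2 ",
                     "%.4f, MSE %.4f (n_train %d, n_valid %d)\n"),
              x$config$n_trees, x$config$max_depth, e$r_squared, e$mse,
              e$n_train, e$n_valid))
  invisible(x)
}

#' @export
predict.np_imputer <- function(object, descriptors, ...) {
  x <- imputer_features(descriptors)
  predict(object$model, data = x, num.threads = 1)$predictions
}

#' Impute missing NP-likeness scores
#'
#' Fills `NA` NP-likeness values with random-forest predictions; observed
#' values are never overwritten. Records whose structure cannot be
#' featurized are skipped with a message and keep `NA`. The fraction of
#' records with imputed scores is attached as attribute
#' `"imputed_fraction"`.
#'
#' @param imputer A trained `np_imputer`.
#' @param records Data frame with `smiles`, optional `compound_key`, and
#'   `np_likeness` (`NA` where unobserved).
#' @return `records` with `np_likeness` filled where possible and a new
#'   `np_source` column (`"observed"` / `"imputed"` / `NA` for skipped).
#' @export
impute_np_likeness <- function(imputer, records) {
  stopifnot(inherits(imputer, "np_imputer"))
  records <- as_tibble(records)
  assert_columns(records, c("smiles", "np_likeness"), "records")
  records$np_source <- ifelse(is.na(records$np_likeness), NA_character_,
                              "observed")
  todo <- which(is.na(records$np_likeness))
  if (length(todo) > 0) {
    desc <- compute_descriptors(records$smiles[todo],
                                ids = paste0("r", todo),
                                fingerprint = TRUE, strict = FALSE)
    ok <- as.integer(sub("^r", "", desc$id))
    if (nrow(desc) > 0) {
      records$np_likeness[ok] <- predict(imputer, desc)
      records$np_source[ok] <- "imputed"
    }
    skipped <- setdiff(todo, ok)
    if (length(skipped) > 0) {
      inform(sprintf("impute_np_likeness: %d record(s) skipped (bad structure)",
                     length(skipped)))
    }
  }
  attr(records, "imputed_fraction") <-
    mean(records$np_source == "imputed", na.rm = FALSE)
  records
}

#' Compare druggability metric distributions across compound sets
#'
#' Summarises weighted QED, NP-likeness and rule-of-five violations for
#' named, possibly overlapping compound sets: per-set n, mean and
#' quartiles of each metric, the fraction inside the desirable bands
#' (wQED 0.4-0.7, NP-likeness 0.5-2.5) and the proportions with zero
#' versus one-or-more RO5 violations.
#'
#' @param records Data frame with `compound_key`, `wqed`, `np_likeness`,
#'   `ro5_violations`.
#' @param sets Named list of compound-key character vectors.
#' @param wqed_band,np_band Desirable bands (inclusive).
#' @return A list with class `"druggability_comparison"`: `summary` (long
#'   tibble: set, metric, n, mean, q25, median, q75, in_band_fraction) and
#'   `ro5` (tibble: set, n, prop_zero_violations, prop_with_violations).
#' @export
compare_sets <- function(records, sets, wqed_band = c(0.4, 0.7),
                         np_band = c(0.5, 2.5)) {
  records <- as_tibble(records)
  assert_columns(records,
                 c("compound_key", "wqed", "np_likeness",
                   "ro5_violations"), "records")
  if (length(sets) == 0 || is.null(names(sets))) {
    abort("compare_sets: `sets` must be a non-empty named list")
  }
  summarise_metric <- function(v, band) {
    if (length(v) == 0) {
      return(tibble(mean = NA_real_, q25 = NA_real_, median = NA_real_,
                    q75 = NA_real_, in_band_fraction = NA_real_))
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    tibble(mean = mean(v, na.rm = TRUE), q25 = q[1], median = q[2],
           q75 = q[3],
           in_band_fraction = mean(v >= band[1] & v <= band[2],
                                   na.rm = TRUE))
  }
  rows <- imap(sets, function(keys, nm) {
    sub <- filter(records, .data$compound_key %in% keys)
    bind_rows(
      mutate(summarise_metric(sub$wqed, wqed_band),
             set = nm, metric = "wqed", n = nrow(sub), .before = 1),
      mutate(summarise_metric(sub$np_likeness, np_band),
             set = nm, metric = "np_likeness", n = nrow(sub), .before = 1)
    )
  })
  ro5 <- imap(sets, function(keys, nm) {
    sub <- filter(records, .data$compound_key %in% keys)
    tibble(set = nm, n = nrow(sub),
           prop_zero_violations = if (nrow(sub) > 0)
             mean(sub$ro5_violations == 0) else NA_real_,
           prop_with_violations = if (nrow(sub) > 0)
             mean(sub$ro5_violations >= 1) else NA_real_)
  })
  structure(list(summary = bind_rows(rows), ro5 = bind_rows(ro5)),
            class = "druggability_comparison")
}

#' Full druggability record table for a compound panel
#'
#' One-call convenience wrapper: descriptors (with QED extras), rule-of-
#' five violations, weighted QED, and NP-likeness (observed from
#' `np_labels` where available, imputed by `imputer` otherwise).
#'
#' @param compounds Data frame with `compound_key` and `smiles`.
#' @param np_labels Optional two-column data frame (`compound_key`,
#'   `np_likeness`) of observed scores.
#' @param imputer Optional trained `np_imputer` for the unlabeled rest.
#' @param hba_mode Acceptor definition, see [compute_descriptors()].
#' @return A tibble with one druggability record per parseable compound.
#' @export
druggability_records <- function(compounds, np_labels = NULL,
                                 imputer = NULL,
                                 hba_mode = "pharmacophore") {
  compounds <- as_tibble(compounds)
  assert_columns(compounds, c("compound_key", "smiles"), "compounds")
  desc <- compute_descriptors(compounds$smiles, ids = compounds$compound_key,
                              fingerprint = !is.null(imputer),
                              extras = TRUE, hba_mode = hba_mode,
                              strict = FALSE)
  out <- desc |>
    rename(compound_key = "id") |>
    mutate(ro5_violations = lipinski_violations(desc),
           wqed = weighted_qed(desc))
  out$np_likeness <- NA_real_
  if (!is.null(np_labels)) {
    assert_columns(np_labels, c("compound_key", "np_likeness"),
                   "np_labels")
    hit <- match(out$compound_key, np_labels$compound_key)
    out$np_likeness[!is.na(hit)] <- np_labels$np_likeness[hit[!is.na(hit)]]
  }
  if (!is.null(imputer)) {
    out <- impute_np_likeness(imputer, out)
  } else {
    out$np_source <- ifelse(is.na(out$np_likeness), NA_character_,
                            "observed")
  }
  select(out, -any_of("fp_bits"))
}
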