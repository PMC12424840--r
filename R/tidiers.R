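#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname assemble_meta_metabolome
#' @param x A `meta_metabolome` (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @method tidy meta_metabolome
#' @export
tidy.meta_metabolome <- function(x, ...) {
  x$compounds
}

#' @rdname assemble_meta_metabolome
#' @method glance meta_metabolome
#' @export
glance.meta_metabolome <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$class_tally, names_from = "bin",
                             values_from = "n")
  bind_cols(tibble(species = x$species, total = x$total,
                   n_sources = length(unique(x$presence$source_id))),
            wide)
}

#' @rdname train_np_imputer
#' @param x An `np_imputer` (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @method tidy np_imputer
#' @export
tidy.np_imputer <- function(x, ...) {
  tibble(metric = c("r_squared", "mse"),
         value = c(x$evaluation$r_squared, x$evaluation$mse))
}

#' @rdname train_np_imputer
#' @method glance np_imputer
#' @export
glance.np_imputer <- function(x, ...) {
  tibble(r_squared = x$evaluation$r_squared, mse = x$evaluation$mse,
         n_train = x$evaluation$n_train, n_valid = x$evaluation$n_valid,
         n_trees = x$config$n_trees, max_depth = x$config$max_depth)
}

#' @rdname reconcile_compounds
#' @param x A `compound_reconciliation` (for `tidy()`/`glance()`).
#' @param ... Unused.
#' @method tidy compound_reconciliation
#' @export
tidy.compound_reconciliation <- function(x, ...) {
  x$mapping
}

#' @rdname reconcile_compounds
#' @method glance compound_reconciliation
#' @export
glance.compound_reconciliation <- function(x, ...) {
  tibble(n_records = nrow(x$mapping), n_compounds = nrow(x$compounds),
         n_conflicts = nrow(x$conflicts))
}

#' @rdname compare_sets
#' @param x A `druggability_comparison` (for `tidy()`).
#' @param ... Unused.
#' @method tidy druggability_comparison
#' @export
tidy.druggability_comparison <- function(x, ...) {
  x$summary
}

#' @export
print.druggability_comparison <- function(x, ...) {
  cat("<druggability_comparison>\n$summary\n")
  print(x$summary)
  cat("$ro5\n")
  print(x$ro5)
  invisible(x)
}
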