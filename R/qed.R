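#' Canonical weighted-QED parameterization
#'
#' The asymmetric double sigmoid (ADS) desirability parameters and mean
#' weights of the published quantitative estimate of drug-likeness, one
#' row per property (`mw`, `alogp`, `hba`, `hbd`, `psa`, `rotb`, `arom`,
#' `alerts`). Shipped as an editable CSV so alternative weight sets can be
#' supplied.
#'
#' @return A tibble (`property`, `a`..`f`, `dmax`, `weight`).
#' @export
default_qed_params <- function() {
  readr::read_csv(pkg_extdata("qed_params.csv"),
                  col_types = readr::cols(property = "c", .default = "d"),
                  progress = FALSE)
}

# Asymmetric double sigmoid desirability, normalized by its maximum.
qed_ads <- function(x, p) {
  raw <- p$a + p$b /
    (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
    (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))
  raw / p$dmax
}

#' Per-property QED desirability
#'
#' @param x Numeric vector of property values.
#' @param property One of `"mw"`, `"alogp"`, `"hba"`, `"hbd"`, `"psa"`,
#'   `"rotb"`, `"arom"`, `"alerts"`.
#' @param params Parameter table, see [default_qed_params()].
#' @return Desirability values in (0, 1].
#' @export
qed_desirability <- function(x, property, params = default_qed_params()) {
  p <- params[params$property == property, ]
  if (nrow(p) != 1) abort(sprintf("unknown QED property: %s", property))
  qed_ads(x, as.list(p))
}

#' Weighted quantitative estimate of drug-likeness
#'
#' The exponentially weighted geometric mean of the eight property
#' desirabilities: `exp(sum(w_i log d_i) / sum(w_i))`. With equal weights
#' this reduces to the plain geometric mean; the result is always in
#' (0, 1]. Property columns follow [compute_descriptors()] naming with
#' `psa` taken from `tpsa` when no `psa` column is present.
#'
#' @param properties Data frame with numeric columns `mw`, `alogp`,
#'   `hba`, `hbd`, `psa` (or `tpsa`), `rotb`, `arom`, `alerts`.
#' @param params Desirability parameter table.
#' @param weights Optional named numeric vector overriding the weights in
#'   `params` (names = property names).
#' @return Numeric vector of wQED scores, one per row.
#' @export
#' @examples
#' weighted_qed(data.frame(mw = 300, alogp = 2.5, hba = 3, hbd = 1,
#'                         psa = 60, rotb = 4, arom = 2, alerts = 0))
weighted_qed <- function(properties, params = default_qed_params(),
                         weights = NULL) {
  properties <- as_tibble(properties)
  if (!"psa" %in% names(properties) && "tpsa" %in% names(properties)) {
    properties$psa <- properties$tpsa
  }
  assert_columns(properties, params$property, "properties")
  w <- setNames(params$weight, params$property)
  if (!is.null(weights)) {
    stopifnot(!is.null(names(weights)))
    w[names(weights)] <- weights
  }
  d <- vapply(params$property, function(pr) {
    qed_desirability(properties[[pr]], pr, params)
  }, numeric(nrow(properties)))
  d <- matrix(d, nrow = nrow(properties))
  if (any(!is.finite(d)) || any(d <= 0)) {
    abort("weighted_qed: non-computable desirability (missing property?)")
  }
  exp(as.vector(log(d) %*% w[params$property]) / sum(w[params$property]))
}
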