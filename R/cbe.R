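#' Convert a sample table to milliequivalents per litre
#'
#' Ionic parameters only.  Nitrogen species reported as mg N/L are first
#' converted to the ion mass (NO3 = 62/14 x NO3-N, NO2 = 46/14 x NO2-N),
#' then divided by the equivalent mass.  TDS, TH and pH are not ionic and
#' are excluded.
#'
#' @param x a [sample_table] (or numeric matrix with parameter columns).
#' @param catalog parameter catalog; ionic rows define the conversion.
#' @return An object of class `meq_table`: list with `meq` (matrix m x
#'   n_ions), `cations`, `anions` (per-sample meq sums) and `ions`
#'   (the catalog subset used).
#' @examples
#' tab <- sample_table(matrix(c(40.08, 61.02), 1,
#'                     dimnames = list(NULL, c("Ca", "HCO3"))))
#' to_meq(tab)$meq   # 2.0 and 1.0 meq/L
#' @export
to_meq <- function(x, catalog = param_catalog()) {
  vals <- .as_sample_matrix(x)
  ions <- catalog[catalog$role %in% c("cation", "anion") &
                    catalog$parameter %in% colnames(vals), , drop = FALSE]
  meq <- vals[, ions$parameter, drop = FALSE]
  meq <- sweep(meq, 2L, ions$ion_mass_factor / ions$equivalent_mass, `*`)
  structure(list(
    meq = meq,
    cations = rowSums(meq[, ions$parameter[ions$role == "cation"], drop = FALSE]),
    anions = rowSums(meq[, ions$parameter[ions$role == "anion"], drop = FALSE]),
    ions = ions
  ), class = "meq_table")
}

#' Charge balance error (CBE)
#'
#' `CBE = 100 (sum cations - sum anions) / (sum cations + sum anions)` with
#' both sums in meq/L.  Used as the laboratory acceptance gate: samples with
#' |CBE| beyond 5% are conventionally rejected.
#'
#' @param x a [sample_table], or a named numeric vector of one sample.
#' @param catalog parameter catalog.
#' @return Named numeric vector of CBE percentages, one per sample.
#' @export
charge_balance_error <- function(x, catalog = param_catalog()) {
  if (is.numeric(x) && !is.matrix(x)) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  mq <- to_meq(x, catalog)
  tot <- mq$cations + mq$anions
  if (any(tot == 0)) {
    stop("undefined CBE: all ionic concentrations are zero for sample(s) ",
         paste(which(tot == 0), collapse = ", "), call. = FALSE)
  }
  cbe <- 100 * (mq$cations - mq$anions) / tot
  names(cbe) <- rownames(mq$meq)
  cbe
}

#' Filter samples by charge balance error
#'
#' Keeps samples with `|CBE| < threshold` (strict, matching the "less than
#' +/-5%" acceptance convention) and reports the rejects.
#'
#' @param x a validated [sample_table].
#' @param threshold CBE acceptance threshold in percent (default 5).
#' @param catalog parameter catalog.
#' @return List with `table` (retained samples), `rejected` (data.frame
#'   `sample_id`, `cbe`) and `cbe` (all CBE values).  Warns if nothing
#'   survives.
#' @export
filter_by_cbe <- function(x, threshold = 5, catalog = param_catalog()) {
  stopifnot(inherits(x, "sample_table"), threshold >= 0)
  cbe <- charge_balance_error(x, catalog)
  keep <- abs(cbe) < threshold
  rejected <- data.frame(sample_id = x$sample_id[!keep],
                         cbe = unname(cbe[!keep]),
                         stringsAsFactors = FALSE, row.names = NULL)
  if (!any(keep)) {
    warning("no samples pass the CBE filter at threshold ", threshold, "%")
    return(list(table = NULL, rejected = rejected, cbe = cbe))
  }
  list(table = .subset_samples(x, which(keep)), rejected = rejected, cbe = cbe)
}
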