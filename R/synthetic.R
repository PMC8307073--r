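#' Published marginal summaries for the two seasonal campaigns
#'
#' The per-parameter min, max, mean and SD (mg/L; pH unitless) of the 28
#' dry-season and 28 wet-season well samples, stored verbatim from the
#' published summary table.  Two entries are internally awkward and kept
#' as printed: the dry-season Fe row (max 16 with mean 0.19) cannot be
#' realized by any 28-sample set, and the wet-season NO2-N SD prints 0.00
#' despite min < max; [generate_samples()] warns on both.
#'
#' @param season `"dry"` or `"wet"`.
#' @return data.frame with columns `parameter`, `min`, `max`, `mean`,
#'   `sd`, rows in catalog order.
#' @export
table3_marginals <- function(season = c("dry", "wet")) {
  season <- match.arg(season)
  all <- utils::read.csv(system.file("extdata", "table3_marginals.csv",
                                     package = "iwqi", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  out <- all[all$season == season, c("parameter", "min", "max", "mean", "sd")]
  rownames(out) <- NULL
  out
}

#' Truncated-normal draws by inverse CDF
#'
#' Underlying Normal(mean, sd) truncated to `[lower, upper]`; `sd = 0`
#' collapses to the (clipped) mean.
#' @keywords internal
.rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0 || lower == upper) {
    return(rep(min(max(mean, lower), upper), n))
  }
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, pl, pu)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}

#' Quantile function of the truncated normal (internal)
#' @keywords internal
.qtnorm <- function(p, mean, sd, lower, upper) {
  if (sd <= 0 || lower == upper) return(rep(min(max(mean, lower), upper), length(p)))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  pmin(pmax(stats::qnorm(pl + p * (pu - pl), mean, sd), lower), upper)
}

#' Moment-feasibility screen for a marginal spec
#' @keywords internal
.check_marginals <- function(spec, n) {
  msg <- character(0)
  bad <- spec$mean < spec$min | spec$mean > spec$max
  if (any(bad)) {
    stop("infeasible marginal spec (mean outside [min, max]) for: ",
         paste(spec$parameter[bad], collapse = ", "), call. = FALSE)
  }
  # hitting the printed max with the other n-1 samples at the min already
  # forces a larger mean than stated -> the printed moments are inconsistent
  reach <- (spec$max + (n - 1) * spec$min) / n > spec$mean & spec$max > spec$min
  if (any(reach)) {
    msg <- c(msg, paste0("max unreachable at stated mean (n = ", n, "): ",
                         paste(spec$parameter[reach], collapse = ", ")))
  }
  zero_sd <- spec$sd == 0 & spec$min < spec$max
  if (any(zero_sd)) {
    msg <- c(msg, paste0("sd = 0 with min < max (constant draws at the mean): ",
                         paste(spec$parameter[zero_sd], collapse = ", ")))
  }
  if (length(msg)) warning("moment-infeasible marginal spec: ",
                           paste(msg, collapse = "; "))
  invisible(TRUE)
}

#' Plausibility correlation preset (synthetic)
#'
#' A demonstration rank-correlation matrix coupling the mineralization
#' block (TDS, TH, Ca, Mg, HCO3) at rho 0.7, all other parameters
#' independent.  Synthetic: not estimated from any real data set.
#'
#' @param parameters parameter names defining the matrix order.
#' @return Correlation matrix with unit diagonal.
#' @export
plausibility_correlation <- function(parameters = param_catalog()$parameter) {
  R <- diag(length(parameters))
  dimnames(R) <- list(parameters, parameters)
  block <- intersect(c("TDS", "TH", "Ca", "Mg", "HCO3"), parameters)
  R[block, block] <- 0.7
  diag(R) <- 1
  R
}

#' Generate a synthetic sample table from marginal summaries
#'
#' Each parameter is drawn from a normal with the spec's mean and SD,
#' truncated to the spec's `[min, max]` (inverse-CDF sampling, so
#' truncation costs no rejections).  Optional rank-correlation coupling
#' uses a latent jointly normal driver mapped through the truncated-
#' normal quantile function, preserving the marginals.  In `"tied"`
#' consistency mode the derived bulk quantities are recomputed from the
#' ions — TH = 2.497 Ca + 4.118 Mg and TDS = (sum of measured ion mass)
#' - 0.5 HCO3, standard approximations — then clipped to the spec range.
#'
#' @param spec marginal spec ([table3_marginals()]) with columns
#'   `parameter`, `min`, `max`, `mean`, `sd`.
#' @param n number of samples (default 28, the published campaign size).
#' @param season season label stamped on the table.
#' @param seed integer seed; same seed, same table, bit for bit.
#' @param correlation optional rank-correlation matrix over (a subset of)
#'   the spec's parameters, e.g. [plausibility_correlation()].
#' @param consistency `"free"` (independent columns as specified) or
#'   `"tied"` (TH and TDS recomputed from the ions).
#' @return A [sample_table] that passes [validate_sample_table()].
#' @export
generate_samples <- function(spec, n = 28L, season = "dry", seed = 1L,
                             correlation = NULL,
                             consistency = c("free", "tied")) {
  consistency <- match.arg(consistency)
  stopifnot(n >= 1L, all(c("parameter", "min", "max", "mean", "sd") %in% names(spec)))
  .check_marginals(spec, n)
  p <- nrow(spec)
  set.seed(as.integer(seed %% 2147483629))
  if (is.null(correlation)) {
    vals <- vapply(seq_len(p), function(j)
      .rtnorm(n, spec$mean[j], spec$sd[j], spec$min[j], spec$max[j]),
      numeric(n))
  } else {
    R <- correlation[spec$parameter, spec$parameter]
    if (max(abs(R - t(R))) > 1e-12 || any(diag(R) != 1)) {
      stop("correlation matrix must be symmetric with unit diagonal", call. = FALSE)
    }
    L <- tryCatch(chol(R), error = function(e)
      stop("correlation matrix is not positive semidefinite", call. = FALSE))
    z <- matrix(stats::rnorm(n * p), n, p) %*% L
    u <- stats::pnorm(z)
    vals <- vapply(seq_len(p), function(j)
      .qtnorm(u[, j], spec$mean[j], spec$sd[j], spec$min[j], spec$max[j]),
      numeric(n))
  }
  if (n == 1L) vals <- matrix(vals, 1L, p)
  colnames(vals) <- spec$parameter
  if (consistency == "tied") {
    cat_ <- param_catalog()
    ions <- intersect(cat_$parameter[cat_$role %in% c("cation", "anion")],
                      spec$parameter)
    clip <- function(v, par) {
      i <- match(par, spec$parameter)
      pmin(pmax(v, spec$min[i]), spec$max[i])
    }
    if (all(c("TH", "Ca", "Mg") %in% spec$parameter)) {
      vals[, "TH"] <- clip(2.497 * vals[, "Ca"] + 4.118 * vals[, "Mg"], "TH")
    }
    if (all(c("TDS", "HCO3") %in% spec$parameter)) {
      vals[, "TDS"] <- clip(rowSums(vals[, ions, drop = FALSE]) -
                              0.5 * vals[, "HCO3"], "TDS")
    }
  }
  tab <- sample_table(vals, season = season)
  validate_sample_table(tab, .catalog_subset(param_catalog(), spec$parameter))
}

#' Cation-exchange fixture
#'
#' Synthetic waters along a pure exchange trajectory: sodium is gained as
#' calcium and magnesium are lost, milliequivalent for milliequivalent,
#' so the exchange panel (Ca+Mg)-(HCO3+SO4) against (Na-Cl) lies exactly
#' on a slope -1 line when `noise = 0`.  All concentrations stay
#' positive, the tables validate, and every sample balances charge well
#' inside the 5% CBE gate.
#'
#' @param n number of samples (>= 2).
#' @param seed integer seed.
#' @param noise relative multiplicative noise SD applied to the ion
#'   concentrations (default 0).
#' @return A validated [sample_table] with all 14 catalog parameters.
#' @export
make_exchange_fixture <- function(n = 100L, seed = 1L, noise = 0) {
  stopifnot(n >= 2L, noise >= 0)
  set.seed(as.integer(seed %% 2147483629))
  t <- seq(-0.8, 0.8, length.out = n)             # exchange extent, meq/L
  meq <- cbind(
    Ca = 3.0 - 0.6 * t, Mg = 2.0 - 0.4 * t, Na = 2.0 + t, K = 0.04,
    Fe = 0, HCO3 = 5.0, SO4 = 1.0, Cl = 1.0, NO3_N = 0.01, F = 0.01,
    NO2_N = 0
  )
  if (noise > 0) {
    meq <- meq * matrix(exp(stats::rnorm(length(meq), 0, noise)),
                        nrow(meq), ncol(meq))
  }
  cat_ <- param_catalog()
  ions <- cat_[match(colnames(meq), cat_$parameter), ]
  mg <- sweep(meq, 2L, ions$equivalent_mass / ions$ion_mass_factor, `*`)
  vals <- cbind(
    pH = 7.3 + 0.2 * stats::runif(n),
    TDS = pmax(rowSums(mg) - 0.5 * mg[, "HCO3"], 1),
    TH = 2.497 * mg[, "Ca"] + 4.118 * mg[, "Mg"],
    mg
  )
  validate_sample_table(sample_table(vals[, param_catalog()$parameter]))
}
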