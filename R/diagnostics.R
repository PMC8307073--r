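#' Seasonal descriptive statistics with exceedance rates
#'
#' Min, max, mean and sample standard deviation per parameter within each
#' season group, plus %SES — the percentage of samples strictly exceeding
#' the parameter's permissible limit, rounded to 2 decimals.  A single-
#' sample group has no defined SD; it is reported as 0 and flagged.
#'
#' @param x a [sample_table].
#' @param standards standards table providing the `limit` column (a
#'   parameter with `NA` limit gets `NA` %SES).
#' @return data.frame with columns `season`, `parameter`, `n`, `min`,
#'   `max`, `mean`, `sd`, `sd_flag`, `pct_ses`.
#' @export
descriptive_stats <- function(x, standards = default_standards()) {
  stopifnot(inherits(x, "sample_table"))
  lim <- standards$limit[match(colnames(x$values), standards$parameter)]
  out <- lapply(unique(x$season), function(s) {
    vals <- x$values[x$season == s, , drop = FALSE]
    m <- nrow(vals)
    data.frame(
      season = s, parameter = colnames(vals), n = m,
      min = apply(vals, 2L, min), max = apply(vals, 2L, max),
      mean = colMeans(vals),
      sd = if (m >= 2L) apply(vals, 2L, stats::sd) else 0,
      sd_flag = m < 2L,
      pct_ses = round(100 * colSums(sweep(vals, 2L, lim, `>`)) / m, 2),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Piper trilinear coordinates
#'
#' Cation triangle shares (Ca, Mg, Na+K as percent of the cation meq sum
#' over those three vertices) and anion triangle shares (HCO3, SO4, Cl);
#' CO3 is not among the measured parameters, so the carbonate vertex is
#' HCO3 alone.  The diamond position is carried as the (Na+K)% and
#' (SO4+Cl)% pair per the standard trilinear projection.
#'
#' @param meq a `meq_table` from [to_meq()].
#' @return data.frame with per-sample columns `cat_Ca`, `cat_Mg`,
#'   `cat_NaK`, `an_HCO3`, `an_SO4`, `an_Cl`, `diamond_NaK`,
#'   `diamond_SO4Cl` and a logical `flagged` for zero triangle sums
#'   (fractions `NA`).
#' @export
piper_coordinates <- function(meq) {
  stopifnot(inherits(meq, "meq_table"))
  g <- function(p) if (p %in% colnames(meq$meq)) meq$meq[, p] else 0
  cat3 <- cbind(Ca = g("Ca"), Mg = g("Mg"), NaK = g("Na") + g("K"))
  an3 <- cbind(HCO3 = g("HCO3"), SO4 = g("SO4"), Cl = g("Cl"))
  cs <- rowSums(cat3); as_ <- rowSums(an3)
  flagged <- cs == 0 | as_ == 0
  cs[cs == 0] <- NA; as_[as_ == 0] <- NA
  cat3 <- 100 * cat3 / cs
  an3 <- 100 * an3 / as_
  data.frame(sample_id = rownames(meq$meq) %||% seq_len(nrow(cat3)),
             cat_Ca = cat3[, "Ca"], cat_Mg = cat3[, "Mg"],
             cat_NaK = cat3[, "NaK"],
             an_HCO3 = an3[, "HCO3"], an_SO4 = an3[, "SO4"],
             an_Cl = an3[, "Cl"],
             diamond_NaK = cat3[, "NaK"],
             diamond_SO4Cl = an3[, "SO4"] + an3[, "Cl"],
             flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hydrochemical facies (water type) from Piper coordinates
#'
#' The label concatenates the dominant anion(s) then the dominant
#' cation(s), each group ordered by decreasing meq share; an ion appears
#' when its share is at or above the dominance threshold (default 25
#' meq%, the conventional trilinear rule).  Examples: `"HCO3-Ca"`,
#' `"HCO3-Ca-Mg"`.
#'
#' @param coords data.frame from [piper_coordinates()].
#' @param threshold dominance threshold in meq percent (inclusive).
#' @return Character vector of facies labels (`NA` for flagged samples).
#' @export
classify_water_type <- function(coords, threshold = 25) {
  an_names <- c("HCO3", "SO4", "Cl")
  cat_names <- c("Ca", "Mg", "Na+K")
  vapply(seq_len(nrow(coords)), function(i) {
    if (isTRUE(coords$flagged[i])) return(NA_character_)
    an <- c(coords$an_HCO3[i], coords$an_SO4[i], coords$an_Cl[i])
    ct <- c(coords$cat_Ca[i], coords$cat_Mg[i], coords$cat_NaK[i])
    pick <- function(v, nm) {
      o <- order(v, decreasing = TRUE)
      sel <- o[v[o] >= threshold]
      if (!length(sel)) sel <- o[1L]     # always name at least the largest
      nm[sel]
    }
    paste(c(pick(an, an_names), pick(ct, cat_names)), collapse = "-")
  }, character(1))
}

#' Gibbs ratios and source-mechanism zone
#'
#' The two Gibbs panels plot TDS against Na/(Na+Ca) and Cl/(Cl+HCO3) (meq
#' basis).  Ratios below 0.5 at mid-range TDS indicate water-rock
#' interaction (rock weathering); high-ratio waters split into evaporation
#' (high TDS) and precipitation (low TDS) dominance.  Zone boundaries are
#' implemented as simple documented rectangles in (ratio, TDS) space —
#' TDS above 1000 mg/L with Cl ratio at or above 0.5 is `"evaporation"`,
#' TDS below 100 with Cl ratio at or above 0.5 is `"precipitation"`,
#' everything else `"rock-weathering"` — and labelled heuristic because
#' the classical figure has no published boundary equations.
#'
#' @param x a [sample_table] providing TDS.
#' @param meq optional precomputed [to_meq()] result.
#' @return data.frame with `sample_id`, `na_ratio`, `cl_ratio`, `TDS`,
#'   `zone` (`"rock-weathering"`, `"evaporation"`, `"precipitation"`) and
#'   `flagged` for zero denominators.
#' @export
gibbs_ratios <- function(x, meq = to_meq(x)) {
  stopifnot(inherits(x, "sample_table"), "TDS" %in% colnames(x$values))
  mq <- meq$meq
  na_den <- mq[, "Na"] + mq[, "Ca"]
  cl_den <- mq[, "Cl"] + mq[, "HCO3"]
  flagged <- na_den == 0 | cl_den == 0
  na_ratio <- ifelse(na_den > 0, mq[, "Na"] / na_den, NA_real_)
  cl_ratio <- ifelse(cl_den > 0, mq[, "Cl"] / cl_den, NA_real_)
  tds <- x$values[, "TDS"]
  zone <- rep("rock-weathering", length(tds))
  zone[!is.na(cl_ratio) & cl_ratio >= 0.5 & tds > 1000] <- "evaporation"
  zone[!is.na(cl_ratio) & cl_ratio >= 0.5 & tds < 100] <- "precipitation"
  zone[flagged] <- NA_character_
  data.frame(sample_id = x$sample_id, na_ratio = na_ratio,
             cl_ratio = cl_ratio, TDS = tds, zone = zone, flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ion-ratio diagnostic panels
#'
#' The six classical source-attribution scatter pairs, all in meq/L:
#' Na vs Cl (halite), Ca+Mg vs HCO3+SO4 (carbonate/silicate weathering),
#' Ca vs HCO3, Ca vs SO4 (gypsum), Ca vs Mg, and the cation-exchange
#' panel (Ca+Mg)-(HCO3+SO4) vs (Na-Cl), whose ordinary least-squares
#' slope is near -1 when cation exchange (Na gained, Ca+Mg lost, charge
#' conserved) drives the chemistry.  For each panel the fraction of
#' samples strictly above and below the y = x reference line is reported.
#'
#' @param meq a `meq_table` from [to_meq()] with at least 2 samples.
#' @return List with `panels` (named list of data.frames `x`, `y`),
#'   `reference_line` (data.frame `panel`, `frac_above`, `frac_below`),
#'   and `exchange_fit` (list `slope`, `intercept`, `flagged`; OLS of the
#'   exchange panel, `NA`/flagged when the x-variance is zero).
#' @export
ion_ratio_panel <- function(meq) {
  stopifnot(inherits(meq, "meq_table"))
  mq <- meq$meq
  if (nrow(mq) < 2L) stop("slope fitting needs at least 2 samples", call. = FALSE)
  panels <- list(
    na_cl = data.frame(x = mq[, "Cl"], y = mq[, "Na"]),
    camg_hco3so4 = data.frame(x = mq[, "HCO3"] + mq[, "SO4"],
                              y = mq[, "Ca"] + mq[, "Mg"]),
    ca_hco3 = data.frame(x = mq[, "HCO3"], y = mq[, "Ca"]),
    ca_so4 = data.frame(x = mq[, "SO4"], y = mq[, "Ca"]),
    ca_mg = data.frame(x = mq[, "Mg"], y = mq[, "Ca"]),
    exchange = data.frame(x = mq[, "Na"] - mq[, "Cl"],
                          y = (mq[, "Ca"] + mq[, "Mg"]) -
                            (mq[, "HCO3"] + mq[, "SO4"]))
  )
  ref <- do.call(rbind, lapply(names(panels), function(nm) {
    p <- panels[[nm]]
    data.frame(panel = nm,
               frac_above = mean(p$y > p$x),
               frac_below = mean(p$y < p$x),
               stringsAsFactors = FALSE)
  }))
  ex <- panels$exchange
  vx <- stats::var(ex$x)
  if (vx > 0) {
    slope <- stats::cov(ex$x, ex$y) / vx
    fit <- list(slope = slope, intercept = mean(ex$y) - slope * mean(ex$x),
                flagged = FALSE)
  } else {
    fit <- list(slope = NA_real_, intercept = NA_real_, flagged = TRUE)
  }
  list(panels = panels, reference_line = ref, exchange_fit = fit)
}
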