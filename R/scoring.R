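#' Per-parameter quality rating Q
#'
#' `Q_j = 100 (C_j - C_jp) / (T_j - C_jp)` with ideal value `C_jp = 0` for
#' every parameter except pH, where `C_jp = 7` and `T = 8.5`, giving
#' `Q_pH = 100 (pH - 7) / 1.5`.  A rating of 100 means "exactly at the
#' standard limit"; ratings above 100 (and, for pH < 7, below 0 in the
#' default signed mode) are legitimate.
#'
#' @param x a [sample_table] or numeric matrix.
#' @param standards standards table ([default_standards()]), must cover
#'   every table parameter.
#' @param ph_mode `"signed"` keeps the sign of pH - 7 (the printed
#'   formula); `"symmetric"` rates `|pH - 7| / 1.5`, penalizing acidity
#'   and alkalinity alike.
#' @return Numeric matrix of ratings, same dimnames as the input values.
#' @export
quality_rating <- function(x, standards = default_standards(),
                           ph_mode = c("signed", "symmetric")) {
  ph_mode <- match.arg(ph_mode)
  vals <- .as_sample_matrix(x)
  absent <- setdiff(colnames(vals), standards$parameter)
  if (length(absent)) {
    stop("no standard defined for parameter(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  std <- standards[match(colnames(vals), standards$parameter), , drop = FALSE]
  if (any(std$T == std$C_ideal)) {
    stop("configuration error: T equals C_ideal for ",
         paste(std$parameter[std$T == std$C_ideal], collapse = ", "),
         call. = FALSE)
  }
  q <- sweep(sweep(vals, 2L, std$C_ideal, `-`), 2L,
             std$T - std$C_ideal, `/`) * 100
  if (ph_mode == "symmetric" && "pH" %in% colnames(q)) {
    q[, "pH"] <- abs(q[, "pH"])
  }
  q
}

#' Aggregate ratings into an IWQI score
#'
#' The weighted sum `IWQI_i = sum_j W_j Q_ij` per sample.
#'
#' @param Q rating matrix from [quality_rating()] (samples x parameters).
#' @param W a normalized [weight_vector] aligned with the columns of `Q`.
#' @return Named numeric vector of scores.
#' @export
iwqi_score <- function(Q, W) {
  Q <- as.matrix(Q)
  if (ncol(Q) != length(W) || !identical(colnames(Q), names(W))) {
    stop("rating matrix columns and weight vector are not aligned", call. = FALSE)
  }
  drop(Q %*% as.numeric(W))
}

#' Baseline single-weight WQI
#'
#' The conventional WQI uses one externally supplied weight vector (for
#' example the literature means, or entropy weights alone) with the same
#' weighted-sum aggregation as the IWQI; it exists to reproduce
#' IWQI-vs-WQI comparisons.
#'
#' @inheritParams iwqi_score
#' @param weights the externally chosen [weight_vector].
#' @return Named numeric vector of scores.
#' @export
baseline_wqi <- function(Q, weights) iwqi_score(Q, weights)

#' Classify IWQI scores
#'
#' Five classes: Excellent below 25, Good `[25, 50)`, Medium `[50, 75)`,
#' Poor `[75, 100]`, Extremely Poor above 100.
#'
#' @param score numeric vector of finite scores.
#' @param scheme a [classification_scheme()].
#' @return Factor of class labels, levels in scheme order.
#' @examples
#' classify_iwqi(c(57.65, 106.53, 25, 100))
#' @export
classify_iwqi <- function(score, scheme = classification_scheme()) {
  stopifnot(all(is.finite(score)))
  b <- scheme$boundaries
  idx <- findInterval(score, b, left.open = FALSE) + 1L
  # findInterval puts a score equal to the top boundary past it; the Poor
  # class is closed at 100 (only strictly greater scores are Extremely Poor)
  idx[score == b[length(b)]] <- length(b)
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Class counts and percentages
#'
#' @param classes factor from [classify_iwqi()] (or an `iwqi_result`).
#' @param scheme a [classification_scheme()].
#' @return data.frame with `class`, `count` and `percent` (percent of
#'   samples, rounded to 2 decimals).
#' @export
class_distribution <- function(classes, scheme = classification_scheme()) {
  if (inherits(classes, "iwqi_result")) classes <- classes$class
  classes <- factor(classes, levels = scheme$labels)
  if (!length(classes)) stop("no classified samples", call. = FALSE)
  counts <- table(classes)
  data.frame(class = scheme$labels,
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / length(classes), 2),
             stringsAsFactors = FALSE)
}

#' Integrated-weight water quality index (IWQI) of a sample table
#'
#' End-to-end assessment: entropy (subjective) weights from the data,
#' simulation (objective) weights from the literature database, preference
#' integration, quality ratings against the standards, weighted-sum score
#' and five-class label per sample.
#'
#' @param table a validated [sample_table].
#' @param standards standards table.
#' @param db literature weight database.
#' @param n_sims,seed,negative_policy,normalize_draws simulation settings,
#'   see [simulate_objective_weights()].
#' @param ph_mode see [quality_rating()].
#' @param scheme a [classification_scheme()].
#' @return Object of class `iwqi_result`: list with `score`, `class`,
#'   `Q`, `weights` (the full [compute_weights()] bundle), `sample_id`,
#'   `season`, `standards`.
#' @export
iwqi <- function(table, standards = default_standards(),
                 db = literature_weight_db(), n_sims = 2000L, seed = 1L,
                 negative_policy = "clip", normalize_draws = TRUE,
                 ph_mode = "signed", scheme = classification_scheme()) {
  stopifnot(inherits(table, "sample_table"))
  wts <- compute_weights(table, db = db, n_sims = n_sims, seed = seed,
                         negative_policy = negative_policy,
                         normalize_draws = normalize_draws)
  Q <- quality_rating(table, standards, ph_mode = ph_mode)
  score <- iwqi_score(Q, wts$W)
  structure(list(score = score, class = classify_iwqi(score, scheme),
                 Q = Q, weights = wts, sample_id = table$sample_id,
                 season = table$season, standards = standards),
            class = "iwqi_result")
}

#' @export
print.iwqi_result <- function(x, ...) {
  cat("<iwqi_result> ", length(x$score), " samples; G = ",
      round(x$weights$G, 4), "\n", sep = "")
  print(data.frame(sample_id = x$sample_id, season = x$season,
                   IWQI = round(x$score, 3), class = x$class,
                   row.names = NULL))
  invisible(x)
}

#' @export
as.data.frame.iwqi_result <- function(x, ...) {
  data.frame(sample_id = x$sample_id, season = x$season,
             IWQI = x$score, class = as.character(x$class),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Index-removal sensitivity analysis
#'
#' For each parameter i, the full weighting pipeline (entropy weights,
#' simulation weights, integration) is recomputed on the remaining n - 1
#' parameters — the weights are data-dependent, so removal changes them,
#' not just their normalization — the reduced index v is rescored, and the
#' sensitivity is `S_i = |V/N - v/n| / V x 100` per sample (V = full
#' score over N parameters).  The alternative denominator v is available
#' behind `denominator = "v"` (the formula's denominator symbol is
#' ambiguous in this index family).  Parameter RNG streams are keyed by
#' name, so the surviving parameters' simulated draws are identical in the
#' full and reduced runs.
#'
#' @inheritParams iwqi
#' @param denominator `"V"` (default; full-index score) or `"v"`
#'   (reduced-index score).
#' @return Object of class `iwqi_sensitivity`: list with `S` (matrix m
#'   samples x N removed parameters, percent), `mean` (per-parameter mean
#'   over samples), `score_full` (V), `flagged` (parameters whose removal
#'   left a degenerate pipeline, `S = NA`), `season`.
#' @export
iwqi_sensitivity <- function(table, standards = default_standards(),
                             db = literature_weight_db(), n_sims = 2000L,
                             seed = 1L, negative_policy = "clip",
                             normalize_draws = TRUE, ph_mode = "signed",
                             denominator = c("V", "v")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(table, "sample_table"))
  params <- colnames(table$values)
  N <- length(params)
  if (N < 2L) stop("sensitivity needs at least 2 parameters", call. = FALSE)

  full <- iwqi(table, standards, db, n_sims = n_sims, seed = seed,
               negative_policy = negative_policy,
               normalize_draws = normalize_draws, ph_mode = ph_mode)
  V <- full$score
  S <- matrix(NA_real_, nrow(table$values), N,
              dimnames = list(table$sample_id, params))
  flagged <- character(0)
  for (p in params) {
    red <- .drop_parameter(table, p)
    v <- tryCatch({
      wts <- compute_weights(red, db = db, n_sims = n_sims, seed = seed,
                             negative_policy = negative_policy,
                             normalize_draws = normalize_draws)
      iwqi_score(quality_rating(red, standards, ph_mode = ph_mode), wts$W)
    }, error = function(e) {
      warning("removal of ", p, " left a degenerate pipeline: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(v)) { flagged <- c(flagged, p); next }
    n <- N - 1L
    den <- if (denominator == "V") V else v
    S[, p] <- abs(V / N - v / n) / den * 100
  }
  structure(list(S = S,
                 mean = colMeans(S),
                 score_full = V,
                 flagged = flagged,
                 denominator = denominator,
                 season = table$season),
            class = "iwqi_sensitivity")
}

#' @export
print.iwqi_sensitivity <- function(x, ...) {
  cat("<iwqi_sensitivity> denominator = ", x$denominator, "\n", sep = "")
  print(round(sort(x$mean, decreasing = TRUE), 4))
  invisible(x)
}
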