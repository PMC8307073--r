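#' Construct a weight vector
#'
#' Named, non-negative weights that sum to 1 (within 1e-9), tagged with
#' their role in the integration chain: subjective (entropy), objective
#' (stochastic simulation), product-combined, or integrated.
#'
#' @param w named non-negative numeric vector.
#' @param role one of `"subjective"`, `"objective"`, `"combined"`,
#'   `"integrated"`.
#' @return A numeric vector of class `weight_vector` with a `role` attribute.
#' @export
weight_vector <- function(w, role = c("subjective", "objective",
                                      "combined", "integrated")) {
  role <- match.arg(role)
  if (is.null(names(w))) stop("weights must be named by parameter", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("weights must sum to 1 (got ", format(sum(w), digits = 12), ")",
         call. = FALSE)
  }
  structure(as.numeric(stats::setNames(w, names(w))), names = names(w),
            role = role, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector role=", attr(x, "role"), ">\n", sep = "")
  print(round(stats::setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' Shannon-entropy (subjective) weights
#'
#' From the m x n matrix of raw measurements r_ij, each column is
#' self-normalized to shares P_ij = r_ij / sum_i r_ij; the per-parameter
#' entropy is e_j = -(1/ln m) sum_i P_ij ln P_ij (with 0 ln 0 = 0) and the
#' subjective weight W_sj = (1 - e_j) / sum_j (1 - e_j).  Parameters that
#' are constant across samples carry maximal entropy and get weight 0.
#'
#' @param x a [sample_table] or numeric matrix (m >= 2 rows, all values
#'   >= 0, named columns).
#' @param pre_normalize optional min-max pre-scaling of each column into
#'   `[eps, 1]` before computing shares; OFF by default (the shares are
#'   computed on the raw matrix).
#' @param equal_weight_fallback if every column is constant the entropy
#'   weight is undefined; with this flag the function returns uniform
#'   weights instead of erroring.
#' @return List with `weights` (a subjective [weight_vector]) and
#'   `entropy` (named e_j vector).
#' @examples
#' entropy_weights(matrix(c(1, 1, 1, 3), 2, dimnames = list(NULL, c("a", "b"))))
#' @export
entropy_weights <- function(x, pre_normalize = FALSE,
                            equal_weight_fallback = FALSE) {
  r <- .as_sample_matrix(x)
  m <- nrow(r)
  if (m < 2L) stop("entropy weights need at least 2 samples", call. = FALSE)
  if (any(r < 0)) stop("entropy weights need non-negative values", call. = FALSE)
  if (pre_normalize) {
    rng <- apply(r, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    r <- sweep(sweep(r, 2L, rng[1L, ], `-`), 2L, span, `/`) + 1e-4
  }
  csum <- colSums(r)
  if (any(csum == 0)) {
    stop("column(s) sum to zero: ",
         paste(colnames(r)[csum == 0], collapse = ", "), call. = FALSE)
  }
  P <- sweep(r, 2L, csum, `/`)
  plogp <- P * log(P)
  plogp[P == 0] <- 0                      # 0 ln 0 := 0
  e <- -colSums(plogp) / log(m)
  d <- 1 - e
  d[d < 0 & d > -1e-12] <- 0              # constant columns hit e = 1 up to fp noise
  if (sum(d) <= 0) {
    if (!equal_weight_fallback) {
      stop("degenerate entropy: every column is constant; ",
           "set equal_weight_fallback = TRUE for uniform weights", call. = FALSE)
    }
    ws <- rep(1 / ncol(r), ncol(r))
  } else {
    ws <- d / sum(d)
  }
  names(ws) <- colnames(r)
  list(weights = weight_vector(ws, "subjective"),
       entropy = stats::setNames(e, colnames(r)))
}

#' Per-parameter statistics of a literature weight database
#'
#' Mean and sample standard deviation over the studies that actually weight
#' each parameter (blank cells are excluded, not treated as zero).  A
#' parameter weighted by fewer than two studies gets `sd = 0` and is
#' flagged degenerate.
#'
#' @param db a data.frame as returned by [read_weight_db()]: one row per
#'   study, a `reference` column, and one numeric column per parameter with
#'   `NA` for missing.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `n_studies`,
#'   `degenerate`.
#' @export
literature_stats <- function(db) {
  cols <- setdiff(names(db), "reference")
  if (!nrow(db) || !length(cols)) stop("empty weight database", call. = FALSE)
  out <- do.call(rbind, lapply(cols, function(p) {
    v <- db[[p]][!is.na(db[[p]])]
    n <- length(v)
    data.frame(parameter = p,
               mean = if (n) mean(v) else NA_real_,
               sd = if (n >= 2L) stats::sd(v) else 0,
               n_studies = n,
               degenerate = n < 2L,
               stringsAsFactors = FALSE)
  }))
  if (any(out$degenerate)) {
    warning("parameter(s) with < 2 literature entries (sd set to 0): ",
            paste(out$parameter[out$degenerate], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

# One RNG stream per parameter, seeded from the parameter NAME, so that
# adding/removing a parameter never shifts another parameter's draws.
.param_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) * 7919
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

#' Stochastic-simulation (objective) weights
#'
#' Draws `n_sims` random weight vectors, component j distributed
#' Normal(mean_j, sd_j) with moments taken from the literature weight
#' database (the Norminv(u, m, s), u ~ U(0,1) construction).  Negative
#' draws are clipped to zero (default) or resampled; each draw is
#' normalized to sum 1 and the objective weight is the renormalized
#' ensemble mean.  Fully reproducible given `seed`.
#'
#' @param stats data.frame from [literature_stats()] (columns `parameter`,
#'   `mean`, `sd`).
#' @param n_sims number of simulated weight vectors (default 2000).
#' @param seed integer seed; one independent sub-stream per parameter is
#'   derived from it and the parameter name.
#' @param negative_policy `"clip"` (set negative draws to 0) or
#'   `"resample"` (redraw negatives, bounded retries).
#' @param normalize_draws normalize each draw before averaging (default
#'   TRUE); FALSE averages raw draws and normalizes once at the end.
#' @return List with `weights` (objective [weight_vector]) and `ensemble`
#'   (list: per-parameter `mean` and `sd` of the normalized draws,
#'   `n_sims`, `seed`, `negative_policy`).
#' @export
simulate_objective_weights <- function(stats, n_sims = 2000L, seed = 1L,
                                       negative_policy = c("clip", "resample"),
                                       normalize_draws = TRUE) {
  negative_policy <- match.arg(negative_policy)
  stopifnot(n_sims >= 1L, all(c("parameter", "mean", "sd") %in% names(stats)))
  if (anyNA(stats$mean) || anyNA(stats$sd)) {
    stop("mean/sd missing for parameter(s): ",
         paste(stats$parameter[is.na(stats$mean) | is.na(stats$sd)],
               collapse = ", "), call. = FALSE)
  }
  p <- nrow(stats)
  draws <- matrix(NA_real_, n_sims, p, dimnames = list(NULL, stats$parameter))
  for (j in seq_len(p)) {                 # parameter-major, name-keyed streams
    set.seed(.param_seed(seed, stats$parameter[j]))
    v <- stats::rnorm(n_sims, stats$mean[j], stats$sd[j])
    if (negative_policy == "resample") {
      for (try in seq_len(100L)) {
        neg <- v < 0
        if (!any(neg)) break
        v[neg] <- stats::rnorm(sum(neg), stats$mean[j], stats$sd[j])
      }
      if (any(v < 0)) stop("resample policy failed to obtain non-negative draws for ",
                           stats$parameter[j], call. = FALSE)
    } else {
      v[v < 0] <- 0
    }
    draws[, j] <- v
  }
  rs <- rowSums(draws)
  if (any(rs == 0)) {
    stop("simulated draw(s) with all-zero weights after clipping; ",
         "use negative_policy = \"resample\" or check the database", call. = FALSE)
  }
  norm_draws <- draws / rs
  wo <- if (normalize_draws) colMeans(norm_draws) else colMeans(draws)
  wo <- wo / sum(wo)
  list(weights = weight_vector(wo, "objective"),
       ensemble = list(mean = colMeans(norm_draws),
                       sd = apply(norm_draws, 2L, stats::sd),
                       n_sims = n_sims, seed = seed,
                       negative_policy = negative_policy,
                       normalize_draws = normalize_draws))
}

#' Product-combined weights
#'
#' `w_j = W_sj W_oj / sum_j W_sj W_oj`: the elementwise product of the
#' subjective and objective weights, renormalized.
#'
#' @param ws,wo subjective and objective [weight_vector]s over the same
#'   parameters in the same order.
#' @return A combined [weight_vector].
#' @export
combined_product_weights <- function(ws, wo) {
  .check_aligned(ws, wo)
  prod <- as.numeric(ws) * as.numeric(wo)
  if (sum(prod) == 0) {
    stop("subjective and objective weights have disjoint supports; ",
         "product weights undefined", call. = FALSE)
  }
  weight_vector(stats::setNames(prod / sum(prod), names(ws)), "combined")
}

#' Preference coefficient G
#'
#' `G_raw = sum_j [(w_j - W_sj)^2 + (w_j - W_oj)^2]`, the summed squared
#' deviation of the product-combined weights from both parents.  The
#' integration step requires G in `[0, 1]`, which the raw sum does not
#' guarantee, so both the raw value and the clamped `G = min(max(G_raw,
#' 0), 1)` are returned.
#'
#' @param w,ws,wo combined, subjective and objective [weight_vector]s.
#' @return List with `G_raw` and `G`.
#' @export
preference_coefficient <- function(w, ws, wo) {
  .check_aligned(w, ws)
  .check_aligned(w, wo)
  g_raw <- sum((as.numeric(w) - as.numeric(ws))^2 +
                 (as.numeric(w) - as.numeric(wo))^2)
  list(G_raw = g_raw, G = min(max(g_raw, 0), 1))
}

#' Integrated weights
#'
#' The convex combination `W_j = G W_sj + (1 - G) W_oj` balancing the
#' subjective (entropy) and objective (simulation) weights.
#'
#' @param G preference coefficient in `[0, 1]`.
#' @param ws,wo subjective and objective [weight_vector]s.
#' @return An integrated [weight_vector].
#' @export
integrated_weights <- function(G, ws, wo) {
  stopifnot(is.numeric(G), length(G) == 1L, G >= 0, G <= 1)
  .check_aligned(ws, wo)
  w <- G * as.numeric(ws) + (1 - G) * as.numeric(wo)
  weight_vector(stats::setNames(w, names(ws)), "integrated")
}

#' @keywords internal
.check_aligned <- function(a, b) {
  if (length(a) != length(b) || !identical(names(a), names(b))) {
    stop("weight vectors are not aligned (same parameters, same order)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Full weighting pipeline
#'
#' Convenience wrapper running entropy weights on the sample table,
#' literature statistics + stochastic simulation on the weight database,
#' and the product/preference/convex integration chain.
#'
#' @param table a validated [sample_table].
#' @param db literature weight database (defaults to the packaged one);
#'   only the table's parameters are used, in the table's column order.
#' @param n_sims,seed,negative_policy,normalize_draws passed to
#'   [simulate_objective_weights()].
#' @param equal_weight_fallback passed to [entropy_weights()].
#' @return List with `entropy` (e_j), `ws`, `stats`, `wo`, `ensemble`,
#'   `w`, `G_raw`, `G`, `W`.
#' @export
compute_weights <- function(table, db = literature_weight_db(),
                            n_sims = 2000L, seed = 1L,
                            negative_policy = "clip",
                            normalize_draws = TRUE,
                            equal_weight_fallback = FALSE) {
  params <- colnames(.as_sample_matrix(table))
  ent <- entropy_weights(table, equal_weight_fallback = equal_weight_fallback)
  absent <- setdiff(params, names(db))
  if (length(absent)) {
    stop("weight database has no column for parameter(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  st <- literature_stats(db[, c("reference", params)])
  st <- st[match(params, st$parameter), , drop = FALSE]
  sim <- simulate_objective_weights(st, n_sims = n_sims, seed = seed,
                                    negative_policy = negative_policy,
                                    normalize_draws = normalize_draws)
  w <- combined_product_weights(ent$weights, sim$weights)
  pref <- preference_coefficient(w, ent$weights, sim$weights)
  W <- integrated_weights(pref$G, ent$weights, sim$weights)
  list(entropy = ent$entropy, ws = ent$weights, stats = st,
       wo = sim$weights, ensemble = sim$ensemble, w = w,
       G_raw = pref$G_raw, G = pref$G, W = W)
}
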