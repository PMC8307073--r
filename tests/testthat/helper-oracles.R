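# Independent oracles and fixture builders shared across test files.
# The oracles are deliberately written loop-by-loop, without reusing any
# package internals, so they stay independent of the code paths they check.

# Brute-force entropy weights: shares, entropy, weight, straight off the
# formulas.
oracle_entropy <- function(r) {
  m <- nrow(r); n <- ncol(r)
  e <- numeric(n)
  for (j in seq_len(n)) {
    colsum <- 0
    for (i in seq_len(m)) colsum <- colsum + r[i, j]
    acc <- 0
    for (i in seq_len(m)) {
      p <- r[i, j] / colsum
      if (p > 0) acc <- acc + p * log(p)
    }
    e[j] <- -acc / log(m)
  }
  d <- 1 - e
  d[d < 0 & d > -1e-12] <- 0
  list(e = e, ws = d / sum(d))
}

# Closed-form moments of a Normal(mu, sigma) truncated to [a, b].
oracle_tnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  mean <- mu + sigma * (dnorm(al) - dnorm(be)) / Z
  var <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                      ((dnorm(al) - dnorm(be)) / Z)^2)
  list(mean = mean, var = var)
}

# A perfectly charge-balanced water in mg/L across the full catalog.
# cat_meq/an_meq: target meq sums (cations and anions must be equal for
# exact balance, but the helper lets tests unbalance deliberately).
make_ion_sample <- function(cat_meq = 5, an_meq = 5) {
  # shares sum to 1 within each group; chosen so that any meq total up to 9
  # stays below every default exceedance limit (K, Fe, HCO3, F, NO2 are the
  # tight ones)
  c(pH = 7.5, TDS = 500, TH = 300,
    Ca = 0.5 * cat_meq * 20.04, Na = 0.329 * cat_meq * 22.99,
    Mg = 0.15 * cat_meq * 12.15, K = 0.02 * cat_meq * 39.10,
    Fe = 0.001 * cat_meq * 18.62,
    HCO3 = 0.45 * an_meq * 61.02, SO4 = 0.30 * an_meq * 48.03,
    Cl = 0.21 * an_meq * 35.45, NO3_N = 0.03 * an_meq * 62 / (62 / 14),
    F = 0.005 * an_meq * 19, NO2_N = 0.005 * an_meq * 46.01 / (46 / 14))
}

make_balanced_table <- function(n = 6, seed = 42) {
  set.seed(seed)
  rows <- t(vapply(seq_len(n), function(i) {
    meq <- runif(1, 3, 9)
    make_ion_sample(meq, meq)
  }, numeric(14)))
  sample_table(rows, season = "dry")
}

# A sd = 0 single-study weight db over the given parameters: the SSA
# becomes deterministic (objective weights = normalized means), which keeps
# symmetry-based expectations exact.
flat_weight_db <- function(parameters, w = 0.07) {
  db <- data.frame(reference = c("syn_a", "syn_b"), stringsAsFactors = FALSE)
  for (p in parameters) db[[p]] <- c(w, w)
  db
}

# Table whose quality ratings are constant within each sample:
# C_ij = c_i * T_j for non-pH and pH_i = 7 + 1.5 c_i, so Q_ij = 100 c_i.
make_constant_Q_table <- function(ci, standards = default_standards()) {
  params <- param_catalog()$parameter
  std <- standards[match(params, standards$parameter), ]
  vals <- t(vapply(ci, function(c_) {
    v <- c_ * std$T
    v[params == "pH"] <- 7 + 1.5 * c_
    v
  }, numeric(length(params))))
  colnames(vals) <- params
  sample_table(vals, season = "dry")
}

uniform_weights <- function(parameters, role = "integrated") {
  weight_vector(setNames(rep(1 / length(parameters), length(parameters)),
                         parameters), role)
}
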