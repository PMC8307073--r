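# Quality rating, IWQI aggregation, classification, baseline WQI and
# index-removal sensitivity.

test_that("quality rating follows the sub-index formula", {
  std <- default_standards()
  params <- c("pH", "TDS", "TH")
  vals <- matrix(c(8.5, 1000, 450,    # everything exactly at the standard
                   7.0, 500, 225),
                 2, byrow = TRUE, dimnames = list(NULL, params))
  q <- quality_rating(vals, std)
  expect_equal(unname(q[1, ]), c(100, 100, 100), tolerance = 1e-12)
  expect_equal(unname(q[2, ]), c(0, 50, 50), tolerance = 1e-12)

  # signed vs symmetric pH below 7
  acid <- matrix(c(6.4, 100, 100), 1, dimnames = list(NULL, params))
  expect_equal(unname(quality_rating(acid, std)[1, "pH"]),
               100 * (6.4 - 7) / 1.5)
  expect_equal(unname(quality_rating(acid, std, ph_mode = "symmetric")[1, "pH"]),
               100 * 0.6 / 1.5)

  bad <- std; bad$C_ideal[bad$parameter == "TDS"] <- bad$T[bad$parameter == "TDS"]
  expect_error(quality_rating(vals, bad), "configuration error")
  expect_error(quality_rating(cbind(vals, Zn = 1), std), "Zn")
})

test_that("IWQI aggregation is a weighted sum, linear and monotone", {
  w <- uniform_weights(c("a", "b"))
  expect_equal(unname(iwqi_score(matrix(100, 3, 2,
                                        dimnames = list(NULL, c("a", "b"))), w)),
               rep(100, 3))
  expect_equal(unname(iwqi_score(matrix(c(0, 100), 1,
                                        dimnames = list(NULL, c("a", "b"))), w)),
               50)
  set.seed(5)
  Q <- matrix(runif(12, 0, 150), 3, 4, dimnames = list(NULL, letters[1:4]))
  x <- runif(4); W <- weight_vector(setNames(x / sum(x), letters[1:4]),
                                    "integrated")
  # brute-force dot product oracle
  want <- vapply(1:3, function(i) sum(Q[i, ] * as.numeric(W)), numeric(1))
  expect_equal(unname(iwqi_score(Q, W)), want, tolerance = 1e-12)
  # linearity in Q
  expect_equal(unname(iwqi_score(3 * Q, W)), 3 * want, tolerance = 1e-12)
  # monotonicity: raising one rating with positive weight raises the score
  Q2 <- Q; Q2[2, "c"] <- Q2[2, "c"] + 10
  expect_gt(iwqi_score(Q2, W)[2], iwqi_score(Q, W)[2])
  expect_error(iwqi_score(Q[, 1:3], W), "aligned")
})

test_that("classification matches the five-band convention", {
  got <- classify_iwqi(c(57.65, 106.53, 24.999, 25, 50, 75, 100, 100.0001))
  expect_equal(as.character(got),
               c("Medium (III)", "Extremely Poor (V)", "Excellent (I)",
                 "Good (II)", "Medium (III)", "Poor (IV)", "Poor (IV)",
                 "Extremely Poor (V)"))
  # partition: every finite score gets exactly one label
  set.seed(8)
  s <- c(runif(200, -50, 200), 25, 50, 75, 100)
  expect_false(anyNA(classify_iwqi(s)))
})

test_that("class distributions reproduce the printed seasonal percentages", {
  sch <- classification_scheme()
  dry <- class_distribution(factor(rep(sch$labels, c(0, 13, 10, 4, 1)),
                                   levels = sch$labels))
  expect_equal(dry$count, c(0, 13, 10, 4, 1))
  expect_equal(dry$percent, c(0.00, 46.43, 35.71, 14.29, 3.57))
  wet <- class_distribution(factor(rep(sch$labels, c(1, 13, 9, 4, 1)),
                                   levels = sch$labels))
  expect_equal(wet$percent, c(3.57, 46.43, 32.14, 14.29, 3.57))
  one <- class_distribution(factor(rep(sch$labels[1], 7), levels = sch$labels))
  expect_equal(one$percent, c(100, 0, 0, 0, 0))
  expect_equal(sum(dry$count), 28)
  expect_equal(sum(dry$percent), 100, tolerance = 0.05)
})

test_that("baseline WQI is the same aggregation under external weights", {
  tab <- suppressWarnings(generate_samples(table3_marginals("dry"), n = 12,
                                           seed = 21))
  res <- iwqi(tab, n_sims = 300, seed = 2)
  # with the integrated weights the baseline IS the IWQI
  expect_equal(unname(baseline_wqi(res$Q, res$weights$W)), unname(res$score))
  # literature-mean weights give a different but rank-correlated score
  st <- literature_stats(literature_weight_db())
  mm <- st$mean[match(colnames(res$Q), st$parameter)]
  wlit <- weight_vector(setNames(mm / sum(mm), colnames(res$Q)), "integrated")
  base <- baseline_wqi(res$Q, wlit)
  expect_false(isTRUE(all.equal(unname(base), unname(res$score))))
  expect_gt(cor(base, res$score, method = "spearman"), 0.5)
})

test_that("sensitivity hits the symmetric closed form when ratings are flat", {
  # Q_ij = 100 c_i for every j: the score no longer depends on the weights,
  # so S = |1/N - 1/(N-1)| * 100 exactly, for every sample and parameter
  tab <- make_constant_Q_table(seq(0.3, 0.9, length.out = 6))
  db <- flat_weight_db(colnames(tab$values))
  sens <- iwqi_sensitivity(tab, db = db, n_sims = 50, seed = 3)
  expect_equal(dim(sens$S), c(6, 14))
  expect_equal(unname(as.vector(sens$S)),
               rep(abs(1 / 14 - 1 / 13) * 100, 6 * 14), tolerance = 1e-9)
  expect_equal(unname(sens$mean), rep(100 / 182, 14), tolerance = 1e-9)
  # alternative denominator v: here V = v (flat ratings), so it coincides
  sv <- iwqi_sensitivity(tab, db = db, n_sims = 50, seed = 3,
                         denominator = "v")
  expect_equal(unname(as.vector(sv$S)),
               rep(abs(1 / 14 - 1 / 13) * 100, 6 * 14), tolerance = 1e-9)
})

test_that("sensitivity is symmetric under duplicated parameters", {
  # four parameters; b and c are exact duplicates with identical literature
  # stats and a zero-variance db, so removal of either must match exactly
  set.seed(13)
  vals <- cbind(a = runif(5, 1, 9), b = runif(5, 1, 9))
  vals <- cbind(vals, c = vals[, "b"], d = runif(5, 1, 9))
  tab <- sample_table(vals)
  db <- flat_weight_db(colnames(vals))
  std <- data.frame(parameter = colnames(vals), T = c(10, 8, 8, 12),
                    C_ideal = 0, limit = c(10, 8, 8, 12))
  sens <- iwqi_sensitivity(tab, standards = std, db = db, n_sims = 20, seed = 1)
  expect_equal(unname(sens$S[, "b"]), unname(sens$S[, "c"]), tolerance = 1e-12)
  expect_true(all(sens$S >= 0))
})

test_that("sensitivity works at the n = 2 boundary", {
  set.seed(17)
  vals <- cbind(a = runif(4, 1, 5), b = runif(4, 2, 9))
  tab <- sample_table(vals)
  db <- flat_weight_db(c("a", "b"))
  std <- data.frame(parameter = c("a", "b"), T = c(5, 10), C_ideal = 0,
                    limit = c(5, 10))
  sens <- iwqi_sensitivity(tab, standards = std, db = db, n_sims = 20, seed = 1)
  expect_equal(dim(sens$S), c(4, 2))
  expect_true(all(is.finite(sens$S)))
  # removal leaves a single parameter: v is its rating, n = 1
  q <- quality_rating(tab, std)
  V <- iwqi_score(q, suppressWarnings(
    iwqi(tab, standards = std, db = db, n_sims = 20, seed = 1))$weights$W)
  expect_equal(unname(sens$S[, "a"]),
               unname(abs(V / 2 - q[, "b"] / 1) / V * 100), tolerance = 1e-9)
})
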