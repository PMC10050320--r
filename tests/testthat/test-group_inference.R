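test_that("symptom correlations use the kind-appropriate method and match oracles", {
  x <- c(2.1, -0.5, 0.3, 1.8, -1.2, 0.9)
  y <- c(14, 3, 9, 22, 1, 11)

  r_caps <- correlate_with_symptoms(x, y, "caps")
  # hand Spearman for untied data: 1 - 6 sum(d^2) / (n (n^2 - 1))
  d <- rank(x) - rank(y)
  rho <- 1 - 6 * sum(d^2) / (6 * (36 - 1))
  expect_equal(r_caps$statistic, rho, tolerance = 1e-12)
  expect_equal(r_caps$statistic_type, "spearman_rho")
  # rank invariance under a monotone transform of the score
  r_mono <- correlate_with_symptoms(x, exp(y / 5), "caps")
  expect_equal(r_mono$statistic, r_caps$statistic, tolerance = 1e-12)

  r_pcl <- correlate_with_symptoms(x, y, "pcl5")
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_pcl$statistic, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(r_pcl$p_raw, 2 * pt(-abs(t_hand), 4), tolerance = 1e-10)

  expect_equal(correlate_with_symptoms(x, x, "pc")$statistic, 1)
  expect_error(correlate_with_symptoms(x, y[1:5], "caps"), "length")
})

test_that("the covariate-adjusted symptom test isolates the symptom term", {
  set.seed(31)
  n <- 80
  dat <- tibble::tibble(
    caps_total = sample(0:100, n, replace = TRUE),
    age = sample(23:60, n, replace = TRUE),
    income_band = sample(1:3, n, replace = TRUE),
    education_band = sample(1:4, n, replace = TRUE),
    kbit = rnorm(n, 105, 10),
    bic = rnorm(n, 150, 20))
  dat$outcome <- 0.05 * dat$caps_total  # exact linear, no noise
  res <- covariate_adjusted_effect(dat, "outcome")
  expect_equal(res$df1, 1)
  expect_lt(res$p_raw, 1e-12)
  # dummy coding: 3-level income adds 2 columns, 4-level education adds 3;
  # residual df = n - (1 + 1 + 1 + 2 + 3 + 1 + 1)
  expect_equal(res$df2, n - 10)
  expect_error(covariate_adjusted_effect(dat, "missing_outcome"),
               "missing columns")
})

test_that("the covariate-adjusted F is calibrated under the null", {
  set.seed(32)
  reps <- 500
  f <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 200
    dat <- tibble::tibble(
      caps_total = sample(0:100, n, replace = TRUE),
      age = sample(23:60, n, replace = TRUE),
      income_band = sample(1:3, n, replace = TRUE),
      education_band = sample(1:4, n, replace = TRUE),
      kbit = rnorm(n, 105, 10),
      bic = rnorm(n, 150, 20),
      outcome = rnorm(n))
    f[r] <- covariate_adjusted_effect(dat, "outcome")$statistic
  }
  # mean of F(1, large) is ~ df2 / (df2 - 2) ~ 1.01
  expect_lt(abs(mean(f) - 1), 0.2)
})

test_that("value/saliency group tests report FDR-corrected one-sample and Welch results", {
  set.seed(33)
  group <- rep(c("control", "ptsd"), c(20, 20))
  value <- ifelse(group == "control", 0.4, 0) + rnorm(40, 0, 0.2)
  sal <- ifelse(group == "ptsd", 0.4, 0) + rnorm(40, 0, 0.2)
  res <- value_saliency_group_tests(value, sal, group)
  expect_equal(nrow(res), 5)
  one <- res[grepl("^one_sample", res$analysis), ]
  expect_equal(one$p_fdr, p.adjust(one$p_raw, "BH"))
  expect_true(is.na(res$p_fdr[res$analysis ==
                                "two_sample_saliency_control_vs_ptsd"]))

  # Welch df reduces to pooled df when variances and ns are equal
  x <- rnorm(15); y <- x + 1  # identical variance
  res2 <- value_saliency_group_tests(
    c(x, y), c(x, y), rep(c("control", "ptsd"), each = 15))
  welch_df <- res2$df[res2$analysis == "two_sample_saliency_control_vs_ptsd"]
  expect_equal(welch_df, 28, tolerance = 1e-8)

  # hand oracles: one-sample t and Welch t on the same cells
  xc <- value[group == "control"]
  t_hand <- mean(xc) / (sd(xc) / sqrt(length(xc)))
  expect_equal(res$statistic[res$analysis == "one_sample_value_control"],
               t_hand, tolerance = 1e-10)
  sc <- sal[group == "control"]; sp <- sal[group == "ptsd"]
  tw <- (mean(sc) - mean(sp)) /
    sqrt(var(sc) / length(sc) + var(sp) / length(sp))
  expect_equal(res$statistic[res$analysis ==
                               "two_sample_saliency_control_vs_ptsd"],
               tw, tolerance = 1e-10)

  expect_error(value_saliency_group_tests(value, sal, rep("control", 40)),
               "group")
})

test_that("BH FDR matches a brute-force step-up implementation", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04))$p_adjusted,
               rep(0.04, 4))
  expect_equal(fdr_correct(0.037)$p_adjusted, 0.037)
  all1 <- fdr_correct(rep(1, 6))
  expect_true(all(all1$p_adjusted == 1) && !any(all1$reject))
  expect_error(fdr_correct(c(0.2, 1.4)), "p")

  bh_brute <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))       # enforce monotonicity
    pmin(1, adj)[order(o)]
  }
  set.seed(34)
  for (r in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_correct(p)$p_adjusted, bh_brute(p),
                 tolerance = 1e-12)
  }
})

test_that("exhaustive subset selection enumerates and ranks all models", {
  set.seed(35)
  n <- 40
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  y <- 2 * X$a + rnorm(n, 0, 0.2)
  sel <- exhaustive_subset_selection(y, X)
  expect_equal(nrow(sel$table), 3)

  # hand oracle over the 3 subsets
  bic_hand <- function(formula) {
    f <- lm(formula, data = cbind(X, y = y))
    rss <- sum(resid(f)^2)
    k <- length(coef(f)) - 1
    n * log(rss / n) + (k + 1) * log(n)
  }
  hand <- sort(c(bic_hand(y ~ a), bic_hand(y ~ b), bic_hand(y ~ a + b)))
  expect_equal(sel$table$bic, hand, tolerance = 1e-10)
  expect_equal(sel$best_set, "a")
  # self-consistency: the best model tops its own ranked table
  expect_true(all(sel$table$bic[1] <= sel$table$bic))
  expect_equal(nrow(sel$best_by_size), 2)

  expect_error(exhaustive_subset_selection(y, cbind(X, a2 = X$a)),
               "collinear")
  expect_error(exhaustive_subset_selection(y, as.data.frame(
    matrix(rnorm(n * 16), n))), "15")
})

test_that("subset selection matches an independent enumeration for p = 5", {
  set.seed(36)
  n <- 50
  X <- as.data.frame(matrix(rnorm(n * 5), n,
                            dimnames = list(NULL, letters[1:5])))
  y <- X$b - 0.5 * X$d + rnorm(n, 0, 0.3)
  sel <- exhaustive_subset_selection(y, X)
  # independent path: lm() over explicit formulas
  combos <- unlist(lapply(1:5, function(k) {
    utils::combn(letters[1:5], k, paste, collapse = "+")
  }))
  oracle <- vapply(combos, function(m) {
    f <- lm(as.formula(paste("y ~", m)), data = cbind(X, y = y))
    rss <- sum(resid(f)^2)
    k <- length(strsplit(m, "+", fixed = TRUE)[[1]])
    n * log(rss / n) + (k + 1) * log(n)
  }, numeric(1))
  expect_equal(nrow(sel$table), 31)
  expect_equal(sort(sel$table$bic), sort(unname(oracle)),
               tolerance = 1e-10)
  expect_equal(sel$best_set,
               strsplit(names(oracle)[which.min(oracle)], "+",
                        fixed = TRUE)[[1]])
})

test_that("clinical PCA is an orthonormal correlation-matrix decomposition", {
  pop <- sample_population(300, cohort_config(), seed = 37)
  meas <- pop[, c("caps_total", "bdi", "stai_trait", "des", "ces", "ctq")]
  pc <- pca_clinical(meas)
  expect_equal(sum(pc$var_explained), 100, tolerance = 1e-10)
  expect_equal(t(pc$loadings) %*% pc$loadings, diag(6),
               tolerance = 1e-10, ignore_attr = TRUE)
  # one dominant severity factor: PC1 tracks CAPS almost perfectly
  expect_gt(abs(cor(pc$scores[, 1], pop$caps_total)), 0.9)
  # sign convention: largest loading of each component is positive
  for (j in 1:6) {
    v <- pc$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_clinical(meas[1:4, ]), "complete cases")
  # missing data: complete-case deletion
  meas2 <- meas
  meas2$bdi[1:5] <- NA
  expect_equal(pca_clinical(meas2)$n, 295)
})
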