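test_that("the double-gamma HRF has the canonical shape", {
  t <- seq(0, 30, by = 0.01)
  h <- double_gamma_hrf(t)
  expect_equal(double_gamma_hrf(0), 0)
  peak <- t[which.max(h)]
  expect_gte(peak, 5); expect_lte(peak, 6)
  expect_equal(max(h), 1, tolerance = 1e-6)          # peak-normalized
  expect_lt(min(h), 0)                               # undershoot exists
  auc <- sum(h) * 0.01
  expect_true(is.finite(auc) && auc > 0)
  expect_error(double_gamma_hrf(-1), "non-negative")
  expect_error(double_gamma_hrf(1, peak_delay = -2), "positive")
})

test_that("percent signal change is a per-run mean normalization", {
  expect_equal(percent_signal_change(c(90, 110)), c(-10, 10))
  expect_equal(percent_signal_change(rep(7, 5)), rep(0, 5))
  x <- rnorm(50, mean = 100)
  expect_equal(mean(percent_signal_change(x)), 0, tolerance = 1e-12)
  expect_error(percent_signal_change(c(-1, 1)), "mean")
})

test_that("per-block z-normalization uses sample SD and zeroes degenerate blocks", {
  expect_equal(z_normalize_per_block(c(1, 2, 3), rep("a", 3)),
               c(-1, 0, 1))
  expect_warning(
    z <- z_normalize_per_block(c(2, 2, 2, 1, 5), c("a", "a", "a", "b",
                                                   "b")),
    "degenerate")
  expect_equal(z[1:3], c(0, 0, 0))
  x <- rnorm(40)
  blocks <- rep(1:4, each = 10)
  z <- z_normalize_per_block(x, blocks)
  for (b in 1:4) {
    expect_equal(mean(z[blocks == b]), 0, tolerance = 1e-12)
    expect_equal(sd(z[blocks == b]), 1, tolerance = 1e-12)
  }
})

test_that("SV bins split each uncertainty domain into ordered equal thirds", {
  sub <- make_test_subject()
  svs <- subject_svs(sub, schedule_o1)
  tr <- schedule_o1$trials
  bins <- assign_sv_bins(tr, svs)
  for (unc in c("risk", "ambiguity")) {
    sel <- tr$uncertainty == unc
    expect_equal(as.vector(table(bins[sel & tr$domain == "loss"])),
                 c(20, 20, 20))
    expect_equal(sort(unique(bins[sel & tr$domain == "gain"])), 4:6)
    means <- tapply(svs[sel], bins[sel], mean)
    expect_true(all(diff(means) >= 0))  # non-decreasing bin 1 -> 6
  }
  # all-equal SVs: sizes still equal, assignment by trial_id tie-break
  const_bins <- assign_sv_bins(tr, rep(1, nrow(tr)))
  expect_equal(as.vector(table(const_bins[tr$uncertainty == "risk" &
                                         tr$domain == "gain"])),
               c(20, 20, 20))
})

test_that("design matrices have the variant-specific column structure", {
  sub <- make_test_subject()
  svs <- subject_svs(sub, schedule_o1)
  d1 <- build_design_matrix(schedule_o1, "glm1")
  X1 <- d1$X[["1"]]  # a gain run
  expect_setequal(colnames(X1),
                  c("risky_gain", "ambiguous_gain", "risky_loss",
                    "ambiguous_loss", "response"))
  expect_true(all(X1[, "risky_loss"] == 0))
  expect_true(all(X1[, "ambiguous_loss"] == 0))
  expect_gt(max(X1[, "risky_gain"]), 0)

  d2 <- build_design_matrix(schedule_o1, "glm2", svs)
  expect_equal(sum(grepl("_mod$", colnames(d2$X[["1"]]))), 4)

  d5 <- build_design_matrix(schedule_o1, "glm5", svs)
  bin_cols <- grep("_bin[1-6]$", colnames(d5$X[["1"]]), value = TRUE)
  expect_length(bin_cols, 12)

  expect_error(build_design_matrix(schedule_o1, "glm3"), "svs")
  expect_error(build_design_matrix(schedule_o1, "glm3", svs[1:5]), "svs")

  # constant SV within a block yields an all-zero modulator column there
  const_svs <- ifelse(schedule_o1$trials$domain == "gain", 1, -1)
  w <- capture_warnings(
    dc <- build_design_matrix(schedule_o1, "glm3", const_svs))
  expect_true(all(grepl("degenerate", w)) && length(w) == 16)
  expect_true(all(dc$X[["1"]][, "risky_mod"] == 0))
})

test_that("OLS betas match the normal-equations solution on a toy run", {
  set.seed(12)
  n <- 20
  X <- cbind(a = rnorm(n), b = rnorm(n), c = runif(n))
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(n, 0, 0.1)
  toy <- structure(list(X = list(`1` = X), spec = glm_spec("glm1"),
                        bins = NULL, run_id = 1), class = "glm_design")
  fit <- fit_glm(list(list(values = y)), toy)
  Xi <- cbind(X, 1)
  oracle <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(fit$beta, drop(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)

  # intercept-only recovery of the mean (all task columns zero get dropped)
  Xz <- cbind(zero = numeric(n))
  toyz <- structure(list(X = list(`1` = Xz), spec = glm_spec("glm1"),
                         bins = NULL, run_id = 1), class = "glm_design")
  fitz <- fit_glm(list(list(values = rep(3.5, n))), toyz)
  expect_equal(nrow(fitz), 1)
  expect_equal(fitz$beta, 3.5)
  expect_equal(attr(fitz, "dropped"), "zero")

  # jointly permuting rows leaves betas unchanged
  perm <- sample(n)
  toyp <- structure(list(X = list(`1` = X[perm, ]),
                         spec = glm_spec("glm1"), bins = NULL,
                         run_id = 1), class = "glm_design")
  fitp <- fit_glm(list(list(values = y[perm])), toyp)
  expect_equal(fitp$beta, fit$beta, tolerance = 1e-10)

  # duplicated columns are reported by name
  Xd <- cbind(a = X[, 1], dup = X[, 1])
  toyd <- structure(list(X = list(`1` = Xd), spec = glm_spec("glm1"),
                         bins = NULL, run_id = 1), class = "glm_design")
  expect_error(fit_glm(list(list(values = y)), toyd), "rank deficient")
})

test_that("glm2 betas are invariant to block-constant SV shifts (z-normalization)", {
  sub <- make_test_subject(noise_sd = 0.2)
  svs <- subject_svs(sub, schedule_o1)
  roi <- simulate_roi_timeseries(sub, schedule_o1, svs = svs, seed = 3)
  shifted <- svs + 2 * (schedule_o1$trials$domain == "gain")
  b1 <- fit_glm(roi, build_design_matrix(schedule_o1, "glm2", svs))
  b2 <- fit_glm(roi, build_design_matrix(schedule_o1, "glm2", shifted))
  expect_equal(b1$beta, b2$beta, tolerance = 1e-10)
})
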