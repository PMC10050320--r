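test_that("subjective value follows the discounted power-utility form", {
  expect_equal(subjective_value(0.5, 0, 5, alpha = 1, beta = 0.7, "gain"),
               2.5)
  expect_equal(subjective_value(1, 0, 5, alpha = 1, beta = 0, "gain"), 5)
  expect_equal(subjective_value(1, 0, 5, alpha = 1, beta = 0, "loss"), -5)
  # hand-evaluated: (0.5 - 1 * 0.74 / 2) * 10^0.8 = 0.13 * 10^0.8
  expect_equal(subjective_value(0.5, 0.74, 10, alpha = 0.8, beta = 1,
                                "gain"),
               0.13 * 10^0.8, tolerance = 1e-12)
  expect_error(subjective_value(0.5, 0, -1, 1, 0, "gain"), "V")
  expect_error(subjective_value(1.2, 0, 5, 1, 0, "gain"), "P")
  expect_error(subjective_value(0.5, 0, 5, 1, 0, "win"), "domain")
})

test_that("subjective value is monotone in V, P, and A as expected", {
  V <- c(5, 10, 20, 50, 120)
  for (alpha in c(0.5, 1, 1.5)) {
    sv_g <- subjective_value(0.5, 0, V, alpha, 0, "gain")
    sv_l <- subjective_value(0.5, 0, V, alpha, 0, "loss")
    expect_true(all(diff(sv_g) > 0))
    expect_true(all(diff(sv_l) < 0))
  }
  P <- c(0.25, 0.5, 0.75)
  expect_true(all(diff(subjective_value(P, 0, 10, 0.8, 0, "gain")) > 0))
  A <- c(0.24, 0.5, 0.74)
  expect_true(all(diff(subjective_value(0.5, A, 10, 0.8, 0.5, "gain")) < 0))
})

test_that("softmax choice probability behaves like a logistic in the SV gap", {
  expect_equal(choice_probability(3, 3, gamma = 2), 0.5)
  expect_equal(choice_probability(10, -4, gamma = 0), 0.5)
  expect_equal(choice_probability(log(3), 0, gamma = 1), 0.75)
  gaps <- seq(-5, 5, by = 0.5)
  p <- choice_probability(gaps, 0, gamma = 1.3)
  expect_true(all(diff(p) > 0))
  # numerically stable at extreme gaps
  expect_equal(choice_probability(1e6, 0, gamma = 20), 1)
  expect_equal(choice_probability(-1e6, 0, gamma = 20), 0)
  expect_error(choice_probability(1, 0, gamma = -1), "gamma")
})

test_that("negative log-likelihood matches closed forms and a brute-force sum", {
  one <- design_240[1, ]
  one$chose_lottery <- TRUE
  # gamma = 0: p = 0.5 exactly
  expect_equal(negative_log_likelihood(
    list(alpha = 1, beta = 0, gamma = 0), one), log(2))

  set.seed(4)
  ten <- design_240[design_240$domain == "gain", ][sample(120, 10), ]
  ten$chose_lottery <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  pars <- list(alpha = 0.7, beta = 0.5, gamma = 2)
  # independent oracle: plain arithmetic, term by term
  oracle <- 0
  for (i in 1:10) {
    sv_l <- (ten$P[i] - pars$beta * ten$A[i] / 2) * ten$V[i]^pars$alpha
    sv_c <- 1 * 5^pars$alpha
    p <- 1 / (1 + exp(-pars$gamma * (sv_l - sv_c)))
    oracle <- oracle - log(if (ten$chose_lottery[i]) p else 1 - p)
  }
  expect_equal(negative_log_likelihood(pars, ten), oracle,
               tolerance = 1e-10)

  # consistent choices + huge gamma: likelihood tends to 1, NLL to 0
  cons <- ten
  sv_l <- (cons$P - 0.5 * cons$A / 2) * cons$V^0.7
  cons$chose_lottery <- sv_l > 5^0.7
  expect_lt(negative_log_likelihood(
    list(alpha = 0.7, beta = 0.5, gamma = 500), cons), 1e-6)

  expect_error(negative_log_likelihood(pars, ten[0, ]), "empty")
  ten$chose_lottery[1] <- NA
  expect_error(negative_log_likelihood(pars, ten), "missed")
})

test_that("fitting recovers parameters as well as a grid-search oracle", {
  truth <- make_test_subject(alpha_gain = 0.7, beta_gain = 0.5,
                             gamma_gain = 2)
  ch <- simulate_choices(truth, schedule_o1, seed = 21)
  gain <- ch[ch$trial_id %in% design_240$trial_id[design_240$domain ==
                                                    "gain"], ]
  fit <- fit_subject_domain(gain, design_240, fit_config(seed = 2))

  dat <- dplyr::inner_join(gain, design_240, by = "trial_id")
  dat <- dat[!is.na(dat$chose_lottery), ]
  grid <- expand.grid(alpha = seq(0.3, 1.6, by = 0.05),
                      beta = seq(-1, 1.5, by = 0.1),
                      gamma = c(0.5, 1, 2, 4))
  grid$nll <- vapply(seq_len(nrow(grid)), function(i) {
    negative_log_likelihood(as.list(grid[i, 1:3]), dat)
  }, numeric(1))
  best <- grid[which.min(grid$nll), ]

  # the optimizer must be at least as good as the grid optimum,
  # and land no farther from the truth than the grid (plus its resolution)
  expect_lte(fit$nll, best$nll + 1e-6)
  expect_lte(abs(fit$alpha - 0.7), abs(best$alpha - 0.7) + 0.05)
  expect_lte(abs(fit$beta - 0.5), abs(best$beta - 0.5) + 0.1)
  expect_equal(fit$bic, 2 * fit$nll + 3 * log(fit$n_trials))
  expect_false(fit$low_identifiability)
})

test_that("fitting is deterministic and flags signal-free choice data", {
  sub <- make_test_subject(gamma_gain = 0)  # pure coin-flip agent
  ch <- simulate_choices(sub, schedule_o1, seed = 31)
  gain_ids <- design_240$trial_id[design_240$domain == "gain"]
  gain <- ch[ch$trial_id %in% gain_ids, ]
  f1 <- fit_subject_domain(gain, design_240, fit_config(seed = 3))
  f2 <- fit_subject_domain(gain, design_240, fit_config(seed = 3))
  expect_identical(f1, f2)
  expect_true(f1$low_identifiability)
  expect_error(fit_subject_domain(gain[1:10, ], design_240), "30")
})

test_that("data generated at a parameter bound is fitted without error", {
  sub <- make_test_subject(alpha_gain = 4.34, beta_gain = 0,
                           gamma_gain = 2)
  ch <- simulate_choices(sub, schedule_o1, seed = 41)
  gain_ids <- design_240$trial_id[design_240$domain == "gain"]
  fit <- fit_subject_domain(ch[ch$trial_id %in% gain_ids, ], design_240,
                            fit_config(seed = 4))
  expect_gte(fit$alpha, 0.0894)
  expect_lte(fit$alpha, 4.34)
  expect_gt(fit$alpha, 3)  # lands near the generative bound
})

test_that("attitude transforms follow the aversion-negative convention", {
  neutral <- transform_attitudes(list(alpha = 1, beta = 0),
                                 list(alpha = 1, beta = 0))
  expect_equal(unlist(neutral), c(risk_gain = 0, risk_loss = 0,
                                  amb_gain = 0, amb_loss = 0))
  a <- transform_attitudes(list(alpha = 0.8, beta = 0.6),
                           list(alpha = 1.3, beta = -0.3))
  expect_equal(a$risk_gain, -0.2)   # alpha_gain - 1: averse
  expect_equal(a$risk_loss, -0.3)   # 1 - alpha_loss
  expect_equal(a$amb_gain, -0.6)    # -beta_gain
  expect_equal(a$amb_loss, -0.3)    # beta_loss: averse
})

test_that("catch-trial quality control fails only above 50% inferior choices", {
  catch <- identify_catch_trials(design_240)
  base <- tibble::tibble(trial_id = catch$trial_id,
                         chose_lottery = ifelse(catch$domain == "gain",
                                                FALSE, TRUE))
  q <- catch_trial_quality(base, design_240)
  expect_true(q$pass)
  expect_equal(q$inferior_fraction, 0)
  expect_equal(q$n_catch, 12)

  bad7 <- base
  bad7$chose_lottery[1:7] <- !bad7$chose_lottery[1:7]
  q7 <- catch_trial_quality(bad7, design_240)
  expect_false(q7$pass)
  expect_equal(q7$inferior_fraction, 7 / 12, tolerance = 1e-12)

  bad6 <- base
  bad6$chose_lottery[1:6] <- !bad6$chose_lottery[1:6]
  expect_true(catch_trial_quality(bad6, design_240)$pass)  # exactly 50%
})
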