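# Simulation studies packaged as reusable functions so that the same code
# paths back the test suite, the acceptance report, and user replications.

#' Parameter-recovery study for the choice model
#'
#' Samples a synthetic cohort, forward-simulates each subject's choices on
#' the full 240-trial schedule, refits the valuation model in one domain
#' from the simulated choices, and returns generative ("true") and
#' recovered parameters side by side. Rank correlations between the two
#' columns measure identifiability of the model at the task's trial count.
#'
#' @param n_subjects Number of simulated subjects.
#' @param domain Domain to fit, `"gain"` or `"loss"`.
#' @param config A [cohort_config()] supplying the generative priors.
#' @param fit A [fit_config()].
#' @param seed Integer root seed.
#' @return A tibble with one row per subject: `true_alpha`, `est_alpha`,
#'   `true_beta`, `est_beta`, `true_gamma`, `est_gamma`, `nll`, `bic`.
#' @export
parameter_recovery_study <- function(n_subjects = 50, domain = "gain",
                                     config = cohort_config(),
                                     fit = fit_config(), seed = 1) {
  design <- generate_design()
  schedule <- schedule_blocks(design, order = 1,
                              seed = .derive_seed(seed, 11))
  pop <- sample_population(n_subjects, config,
                           seed = .derive_seed(seed, 12))
  ids <- design$trial_id[design$domain == domain]
  sfx <- if (domain == "gain") "gain" else "loss"
  rows <- lapply(seq_len(n_subjects), function(i) {
    ch <- simulate_choices(pop[i, ], schedule,
                           seed = .derive_seed(seed, 13, i))
    f <- fit_subject_domain(ch[ch$trial_id %in% ids, ], design, fit)
    tibble::tibble(
      true_alpha = pop[[paste0("alpha_", sfx)]][i], est_alpha = f$alpha,
      true_beta = pop[[paste0("beta_", sfx)]][i], est_beta = f$beta,
      true_gamma = pop[[paste0("gamma_", sfx)]][i], est_gamma = f$gamma,
      nll = f$nll, bic = f$bic)
  })
  dplyr::bind_rows(rows)
}

#' Closed-loop GLM amplitude recovery on noiseless data
#'
#' Simulates a noiseless ROI series for one subject under a pure value or
#' pure saliency encoding at a known amplitude, then estimates both the
#' matching ("on-mode") and the opposite ("off-mode") first-level GLM.
#' When the estimation design equals the generative design the on-mode
#' modulator beta must equal the generative amplitude to numerical
#' precision, while the off-mode beta stays near zero.
#'
#' @param mode `"value"` (glm3 is on-mode) or `"saliency"` (glm4).
#' @param amplitude Generative modulator amplitude.
#' @param seed Integer seed (subject draw and schedule shuffling).
#' @return A list: `on_beta`, `off_beta`, `relative_error`
#'   (|on - amplitude| / amplitude), `off_ratio` (|off| / |on|).
#' @export
closed_loop_recovery <- function(mode = c("value", "saliency"),
                                 amplitude = 0.3, seed = 1) {
  mode <- match.arg(mode)
  design <- generate_design()
  schedule <- schedule_blocks(design, order = 1,
                              seed = .derive_seed(seed, 21))
  sub <- sample_population(2, cohort_config(), seed = .derive_seed(seed, 22))[1, ]
  sub$mix_weight <- if (mode == "saliency") 1 else 0
  sub$amplitude <- amplitude
  sub$noise_sd <- 0; sub$drift <- 0; sub$motion_coupling <- 0
  svs <- subject_svs(sub, schedule)
  designs <- list(glm3 = build_design_matrix(schedule, "glm3", svs),
                  glm4 = build_design_matrix(schedule, "glm4", svs))
  roi <- simulate_roi_timeseries(sub, schedule, svs = svs,
                                 seed = .derive_seed(seed, 23),
                                 designs = designs)
  mod_mean <- function(variant) {
    b <- fit_glm(roi, designs[[variant]])
    mean(b$beta[b$role == "modulator"])
  }
  on <- mod_mean(if (mode == "value") "glm3" else "glm4")
  off <- mod_mean(if (mode == "value") "glm4" else "glm3")
  list(on_beta = on, off_beta = off,
       relative_error = abs(on - amplitude) / amplitude,
       off_ratio = abs(off) / abs(on))
}

#' Replicated group-level value/saliency dissociation study
#'
#' Repeatedly simulates a cohort in which controls carry a monotonic value
#' code and PTSD subjects a U-shaped saliency code in the ROI, estimates
#' the value (glm3) and saliency (glm4) modulator betas per subject using
#' the subjects' generative subjective values, and runs the four
#' FDR-corrected one-sample group tests. A replicate reproduces the target
#' pattern when the control value beta and the PTSD saliency beta are both
#' significantly positive after correction.
#'
#' @param n_replicates Number of seeded cohort replicates.
#' @param n_subjects Cohort size per replicate.
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @param fdr_q Significance level applied to FDR-adjusted p values.
#' @return A tibble with one row per replicate: the four one-sample
#'   statistics and adjusted p values, the Welch statistic, and `pass`.
#' @export
encoding_dissociation_study <- function(n_replicates = 20, n_subjects = 48,
                                        config = cohort_config(), seed = 1,
                                        fdr_q = 0.05) {
  design <- generate_design()
  schedules <- list(
    schedule_blocks(design, 1, seed = .derive_seed(seed, 31)),
    schedule_blocks(design, 2, seed = .derive_seed(seed, 32)))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    pop <- sample_population(n_subjects, config,
                             seed = .derive_seed(seed, 33, r))
    value_beta <- saliency_beta <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      sch <- schedules[[1 + (i - 1) %% 2]]
      sub <- pop[i, ]
      svs <- subject_svs(sub, sch)
      designs <- list(glm3 = build_design_matrix(sch, "glm3", svs),
                      glm4 = build_design_matrix(sch, "glm4", svs))
      roi <- simulate_roi_timeseries(
        sub, sch, svs = svs,
        seed = .derive_seed(seed, 34, (r - 1) * n_subjects + i),
        designs = designs)
      b3 <- fit_glm(roi, designs$glm3)
      b4 <- fit_glm(roi, designs$glm4)
      value_beta[i] <- mean(b3$beta[b3$role == "modulator"])
      saliency_beta[i] <- mean(b4$beta[b4$role == "modulator"])
    }
    tests <- value_saliency_group_tests(value_beta, saliency_beta,
                                        pop$group)
    get <- function(an, col) tests[[col]][tests$analysis == an]
    rows[[r]] <- tibble::tibble(
      replicate = r,
      t_value_control = get("one_sample_value_control", "statistic"),
      p_fdr_value_control = get("one_sample_value_control", "p_fdr"),
      t_saliency_ptsd = get("one_sample_saliency_ptsd", "statistic"),
      p_fdr_saliency_ptsd = get("one_sample_saliency_ptsd", "p_fdr"),
      t_welch = get("two_sample_saliency_control_vs_ptsd", "statistic"),
      pass = get("one_sample_value_control", "statistic") > 0 &
        get("one_sample_value_control", "p_fdr") < fdr_q &
        get("one_sample_saliency_ptsd", "statistic") > 0 &
        get("one_sample_saliency_ptsd", "p_fdr") < fdr_q)
  }
  dplyr::bind_rows(rows)
}

#' Replicated best-subset sanity study
#'
#' Repeatedly draws a synthetic cohort, generates an outcome ("ROI
#' activity") from the emotional-numbing symptom factor alone plus Gaussian
#' noise, and runs exhaustive best-subset selection over the seven
#' candidate predictors of the symptom regression (the five CAPS symptom
#' factors, age, and intelligence). Reports how often the single-predictor
#' numbing model attains the lowest BIC despite the strong correlations
#' among symptom factors.
#'
#' @param n_replicates Number of replicates.
#' @param n_subjects Cohort size per replicate.
#' @param noise_sd Noise SD in units of the standardized numbing score.
#' @param config A [cohort_config()].
#' @param seed Integer root seed.
#' @return A tibble per replicate: `best_set` (collapsed with `+`),
#'   `selected_numbing_only` (logical).
#' @export
numbing_subset_study <- function(n_replicates = 100, n_subjects = 48,
                                 noise_sd = 0.15,
                                 config = cohort_config(), seed = 1) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    pop <- sample_population(n_subjects, config,
                             seed = .derive_seed(seed, 41, r))
    set.seed(.derive_seed(seed, 42, r))
    y <- as.numeric(scale(pop$caps_numb)) +
      stats::rnorm(n_subjects, 0, noise_sd)
    preds <- pop[, c("caps_reexp", "caps_avoid", "caps_numb",
                     "caps_dysarousal", "caps_anxarousal", "age", "kbit")]
    sel <- exhaustive_subset_selection(y, preds)
    rows[[r]] <- tibble::tibble(
      replicate = r,
      best_set = paste(sel$best_set, collapse = "+"),
      selected_numbing_only = identical(sel$best_set, "caps_numb"))
  }
  dplyr::bind_rows(rows)
}
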