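#' Configuration of the synthetic-cohort generator
#'
#' Defaults describe a combat-veteran-like cohort with a wide range of
#' posttraumatic symptom severity. A latent PTSD class (prevalence 19/48)
#' determines a severity score that drives all clinical scales (one general
#' affective factor, with weaker loadings on combat exposure and childhood
#' trauma), couples to behavior (higher severity: more risk aversion in
#' gains, more ambiguity aversion in losses), and selects the neural
#' encoding mode (controls: monotonic value coding; PTSD: U-shaped saliency
#' coding). All amplitudes are on a percent-signal-change-like scale.
#' See the methods vignette for the rationale behind each default.
#'
#' @param prevalence Fraction of subjects in the PTSD class.
#' @param caps_threshold CAPS total at or above which a subject is labelled
#'   `ptsd`.
#' @param alpha_gain_meanlog,alpha_gain_sdlog,alpha_loss_meanlog,alpha_loss_sdlog
#'   Log-normal priors for the curvature parameters.
#' @param beta_gain_mean,beta_gain_sd,beta_loss_mean,beta_loss_sd Normal
#'   priors for the ambiguity weights.
#' @param gamma_meanlog,gamma_sdlog Log-normal prior for softmax noise.
#' @param coupling_risk_gain Decrease in log(alpha_gain) per unit latent
#'   severity.
#' @param coupling_amb_loss Decrease in beta_loss per unit latent severity.
#' @param lapse_rate Probability of a missed response per trial.
#' @param value_amplitude,saliency_amplitude Mean neural modulator
#'   amplitude for each encoding mode (percent signal change per unit
#'   z-scored SV).
#' @param amplitude_sd Between-subject SD of the amplitude.
#' @param condition_amplitude Amplitude of the condition (box-car) response.
#' @param response_amplitude Amplitude of the button-press response.
#' @param encoding_noise_sd SD of white noise added to the ROI series.
#' @param drift_amplitude Amplitude of slow cosine drift.
#' @param motion_coupling Leakage of the motion nuisance series into the
#'   signal.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(prevalence = 19 / 48,
                          caps_threshold = 40,
                          alpha_gain_meanlog = log(0.85),
                          alpha_gain_sdlog = 0.30,
                          alpha_loss_meanlog = log(0.95),
                          alpha_loss_sdlog = 0.25,
                          beta_gain_mean = 0.25, beta_gain_sd = 0.40,
                          beta_loss_mean = 0.00, beta_loss_sd = 0.40,
                          gamma_meanlog = log(1.0), gamma_sdlog = 0.5,
                          coupling_risk_gain = 0.14,
                          coupling_amb_loss = 0.14,
                          lapse_rate = 0.02,
                          value_amplitude = 0.3,
                          saliency_amplitude = 0.3,
                          amplitude_sd = 0.15,
                          condition_amplitude = 0.3,
                          response_amplitude = 0.2,
                          encoding_noise_sd = 1.0,
                          drift_amplitude = 0.5,
                          motion_coupling = 0.1) {
  cfg <- as.list(environment())
  if (prevalence < 0 || prevalence > 1) {
    stop("configuration error: `prevalence` must lie in [0, 1]")
  }
  if (any(c(alpha_gain_sdlog, alpha_loss_sdlog, beta_gain_sd, beta_loss_sd,
            gamma_sdlog) <= 0)) {
    stop("configuration error: prior SDs must be positive")
  }
  if (lapse_rate < 0 || lapse_rate > 1) {
    stop("configuration error: `lapse_rate` must lie in [0, 1]")
  }
  if (any(c(value_amplitude, saliency_amplitude, amplitude_sd,
            encoding_noise_sd, drift_amplitude, motion_coupling,
            condition_amplitude, response_amplitude) < 0)) {
    stop("configuration error: amplitudes and noise SDs must be >= 0")
  }
  structure(cfg, class = "cohort_config")
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample a synthetic cohort with known ground truth
#'
#' Draws, for each subject: a latent PTSD class and severity score; a
#' clinical profile (CAPS total and its 5 symptom factors, PCL-5, BDI,
#' state/trait anxiety, dissociation, combat exposure, childhood trauma,
#' age, income and education bands, and IQ), all clamped to instrument
#' ranges and with CAPS total equal to the sum of its factors; generative
#' valuation parameters per domain (alpha, beta, gamma), with severity
#' coupled to risk attitude in gains and ambiguity attitude in losses; and
#' a neural encoding specification (mode, amplitude, noise, drift, motion
#' coupling) with mode determined by group.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param config A [cohort_config()].
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A tibble with one row per subject carrying the clinical profile,
#'   generative parameters, and encoding fields.
#' @export
sample_population <- function(n_subjects = 48, config = cohort_config(),
                              seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_subjects < 2) stop("`n_subjects` must be at least 2")
  set.seed(as.integer(seed))
  n <- n_subjects

  n_ptsd <- round(n * config$prevalence)
  cls <- sample(rep(c("ptsd", "control"), c(n_ptsd, n - n_ptsd)))

  # CAPS total: class-conditional, factor split near the empirical shares
  caps_draw <- ifelse(cls == "ptsd",
                      stats::rnorm(n, 71, 15), abs(stats::rnorm(n, 4, 9)))
  caps_draw <- .clamp(caps_draw, 0, 136)
  shares <- c(reexp = 0.278, avoid = 0.143, numb = 0.252,
              dysarousal = 0.209, anxarousal = 0.118)
  w <- matrix(stats::rlnorm(n * 5, 0, 0.25), n, 5) *
    matrix(shares, n, 5, byrow = TRUE)
  w <- w / rowSums(w)
  factors <- round(w * caps_draw)
  caps_total <- rowSums(factors)
  group <- ifelse(caps_total >= config$caps_threshold, "ptsd", "control")

  # latent severity on a roughly standardized scale drives everything else
  z <- (caps_total - 35) / 33

  profile <- tibble::tibble(
    subject = sprintf("sub-%03d", seq_len(n)),
    group = group,
    caps_total = caps_total,
    caps_reexp = factors[, 1], caps_avoid = factors[, 2],
    caps_numb = factors[, 3], caps_dysarousal = factors[, 4],
    caps_anxarousal = factors[, 5],
    pcl5 = .clamp(round(25 + 19 * z + stats::rnorm(n, 0, 8)), 0, 80),
    bdi = .clamp(round(15 + 11 * z + stats::rnorm(n, 0, 6)), 0, 63),
    stai_state = .clamp(round(40 + 9 * z + stats::rnorm(n, 0, 6)), 20, 80),
    stai_trait = .clamp(round(39 + 10 * z + stats::rnorm(n, 0, 6)), 20, 80),
    des = .clamp(round(30 + 15 * z + stats::rnorm(n, 0, 15)), 0, 100),
    ces = .clamp(round(16 + 3 * z + stats::rnorm(n, 0, 8)), 0, 41),
    ctq = .clamp(round(37 + 3 * z + stats::rnorm(n, 0, 10)), 25, 125),
    age = .clamp(round(stats::rlnorm(n, log(36), 0.22)), 23, 70),
    income_band = sample(1:5, n, replace = TRUE,
                         prob = c(0.15, 0.3, 0.3, 0.15, 0.1)),
    education_band = sample(1:5, n, replace = TRUE,
                            prob = c(0.1, 0.3, 0.3, 0.2, 0.1)),
    kbit = .clamp(round(109 - 3 * z + stats::rnorm(n, 0, 12)), 40, 160))

  fc <- fit_config()
  params <- tibble::tibble(
    alpha_gain = .clamp(
      exp(stats::rnorm(n, config$alpha_gain_meanlog, config$alpha_gain_sdlog)
          - config$coupling_risk_gain * z),
      fc$alpha_bounds[1], fc$alpha_bounds[2]),
    alpha_loss = .clamp(
      exp(stats::rnorm(n, config$alpha_loss_meanlog,
                       config$alpha_loss_sdlog)),
      fc$alpha_bounds[1], fc$alpha_bounds[2]),
    beta_gain = .clamp(
      stats::rnorm(n, config$beta_gain_mean, config$beta_gain_sd),
      fc$beta_bounds[1], fc$beta_bounds[2]),
    beta_loss = .clamp(
      stats::rnorm(n, config$beta_loss_mean, config$beta_loss_sd)
      - config$coupling_amb_loss * z,
      fc$beta_bounds[1], fc$beta_bounds[2]),
    gamma_gain = .clamp(
      stats::rlnorm(n, config$gamma_meanlog, config$gamma_sdlog),
      fc$gamma_bounds[1], fc$gamma_bounds[2]),
    gamma_loss = .clamp(
      stats::rlnorm(n, config$gamma_meanlog, config$gamma_sdlog),
      fc$gamma_bounds[1], fc$gamma_bounds[2]))

  encoding <- tibble::tibble(
    mode = ifelse(group == "ptsd", "saliency", "value"),
    amplitude = pmax(0.01, ifelse(group == "ptsd",
                                  config$saliency_amplitude,
                                  config$value_amplitude) +
                       stats::rnorm(n, 0, config$amplitude_sd)),
    mix_weight = ifelse(group == "ptsd", 1, 0),
    noise_sd = config$encoding_noise_sd,
    drift = config$drift_amplitude,
    motion_coupling = config$motion_coupling,
    condition_amplitude = config$condition_amplitude,
    response_amplitude = config$response_amplitude,
    lapse_rate = config$lapse_rate)

  dplyr::bind_cols(profile, params, encoding)
}

.subject_params <- function(subject, domain) {
  sfx <- if (domain == "gain") "gain" else "loss"
  list(alpha = subject[[paste0("alpha_", sfx)]],
       beta = subject[[paste0("beta_", sfx)]],
       gamma = subject[[paste0("gamma_", sfx)]])
}

#' Trial-wise signed subjective values for a scheduled subject
#'
#' Evaluates the valuation model at the subject's per-domain parameters for
#' every trial of a schedule, in schedule order.
#'
#' @param subject One row of [sample_population()] output (or any list with
#'   `alpha_gain`, `beta_gain`, `alpha_loss`, `beta_loss`).
#' @param schedule A `block_schedule`.
#' @return Numeric vector of signed SVs aligned with `schedule$trials`.
#' @export
subject_svs <- function(subject, schedule) {
  tr <- schedule$trials
  alpha <- ifelse(tr$domain == "gain", subject$alpha_gain,
                  subject$alpha_loss)
  beta <- ifelse(tr$domain == "gain", subject$beta_gain, subject$beta_loss)
  subjective_value(tr$P, tr$A, tr$V, alpha, beta, tr$domain)
}

#' Simulate one subject's choices on a schedule
#'
#' Forward-simulates the valuation + softmax model: each trial's lottery
#' choice is a Bernoulli draw from [choice_probability()] at the subject's
#' generative parameters. Response times are drawn from a log-normal
#' truncated at the 3.5-s response window; a small lapse rate produces
#' missed responses (`NA` choice and response time).
#'
#' @param subject One row of [sample_population()] output.
#' @param schedule A `block_schedule`.
#' @param seed Integer seed.
#' @param lapse_rate Miss probability per trial; defaults to the subject's
#'   generative `lapse_rate` when present.
#' @return A tibble aligned with `schedule$trials`: `trial_id`, `run_id`,
#'   `chose_lottery`, `response_time`.
#' @export
simulate_choices <- function(subject, schedule, seed = 1,
                             lapse_rate = NULL) {
  stopifnot(inherits(schedule, "block_schedule"))
  if (is.null(lapse_rate)) {
    lapse_rate <- if (!is.null(subject$lapse_rate)) subject$lapse_rate else 0
  }
  set.seed(as.integer(seed))
  tr <- schedule$trials
  n <- nrow(tr)
  sv_l <- subject_svs(subject, schedule)
  gamma <- ifelse(tr$domain == "gain", subject$gamma_gain,
                  subject$gamma_loss)
  alpha <- ifelse(tr$domain == "gain", subject$alpha_gain,
                  subject$alpha_loss)
  beta <- ifelse(tr$domain == "gain", subject$beta_gain, subject$beta_loss)
  sv_c <- subjective_value(1, 0, tr$sure_amount, alpha, beta, tr$domain)
  p <- choice_probability(sv_l, sv_c, gamma)
  chose <- stats::runif(n) < p
  # truncated log-normal RT via inverse CDF
  u <- stats::runif(n) * stats::plnorm(schedule$response_window,
                                       log(1.1), 0.35)
  rt <- stats::qlnorm(u, log(1.1), 0.35)
  miss <- stats::runif(n) < lapse_rate
  chose[miss] <- NA
  rt[miss] <- NA
  tibble::tibble(trial_id = tr$trial_id, run_id = tr$run_id,
                 chose_lottery = chose, response_time = rt)
}

#' Simulate ROI BOLD-like time series for a scheduled subject
#'
#' Forward model mirroring the first-level GLMs: per run, the signal is the
#' sum of condition box-car responses, a parametric value component
#' (per-block z-scored signed SV) weighted by `1 - mix_weight`, a saliency
#' component (z-scored |SV|) weighted by `mix_weight`, and a button-press
#' response — each constructed with the same microtime/HRF machinery as
#' [build_design_matrix()], so noiseless simulations are exactly
#' recoverable by [fit_glm()]. Gaussian white noise, slow cosine drift, and
#' a leakage of the 6 motion-like nuisance series are then added. The
#' series is on a percent-signal-change-like scale (no raw baseline);
#' [percent_signal_change()] is for raw scanner units.
#'
#' @param subject One row of [sample_population()] output (provides
#'   encoding fields and, via [subject_svs()], default SVs).
#' @param schedule A `block_schedule`.
#' @param svs Optional signed SVs per scheduled trial; defaults to the
#'   subject's generative values.
#' @param response_times Optional per-trial response times for the
#'   button-press regressor (e.g. from [simulate_choices()]).
#' @param seed Integer seed for noise, drift phases, and motion series.
#' @param dt Microtime resolution (s), matching the GLM builder.
#' @param designs Optional list with prebuilt `glm3` and `glm4`
#'   `glm_design` objects for these SVs, to avoid rebuilding them (they are
#'   rebuilt from `svs` otherwise).
#' @return An object of class `roi_timeseries`: `runs` is a list with
#'   `values` (percent-signal-change scale, TR = 1 s) and `nuisance`
#'   (6-column motion-like matrix) per run; `tr = 1`.
#' @export
simulate_roi_timeseries <- function(subject, schedule, svs = NULL,
                                    response_times = NULL, seed = 1,
                                    dt = 0.1, designs = NULL) {
  stopifnot(inherits(schedule, "block_schedule"))
  if (is.null(svs)) svs <- subject_svs(subject, schedule)
  if (length(svs) != nrow(schedule$trials)) {
    stop("`svs` length does not match the scheduled trials")
  }
  set.seed(as.integer(seed))

  if (is.null(designs)) {
    designs <- list(
      glm3 = build_design_matrix(schedule, "glm3", svs,
                                 response_times = response_times, dt = dt),
      glm4 = build_design_matrix(schedule, "glm4", svs,
                                 response_times = response_times, dt = dt))
  }
  d_val <- designs$glm3
  d_sal <- designs$glm4
  w <- subject$mix_weight
  amp <- subject$amplitude

  runs <- list()
  for (id in as.character(schedule$runs$run_id)) {
    Xv <- d_val$X[[id]]; Xs <- d_sal$X[[id]]
    n_tr <- nrow(Xv)
    mod_v <- Xv[, grepl("_mod$", colnames(Xv)), drop = FALSE]
    mod_s <- Xs[, grepl("_mod$", colnames(Xs)), drop = FALSE]
    conds <- Xv[, c("risky", "ambiguous")]
    signal <- subject$condition_amplitude * rowSums(conds) +
      amp * (1 - w) * rowSums(mod_v) +
      amp * w * rowSums(mod_s) +
      subject$response_amplitude * Xv[, "response"]

    t <- seq_len(n_tr)
    drift <- numeric(n_tr)
    if (subject$drift > 0) {
      for (k in 1:3) {
        drift <- drift + subject$drift / k *
          cos(2 * pi * (k * t / (2 * n_tr) + stats::runif(1)))
      }
    }
    motion <- matrix(stats::rnorm(n_tr * 6, 0, 0.02), n_tr, 6)
    motion <- apply(motion, 2, cumsum)
    colnames(motion) <- paste0("motion", 1:6)
    leak <- motion %*% stats::rnorm(6, 0, subject$motion_coupling)
    noise <- stats::rnorm(n_tr, 0, subject$noise_sd)
    runs[[id]] <- list(run_id = as.integer(id),
                       values = as.numeric(signal + drift + leak + noise),
                       nuisance = motion)
  }
  structure(list(runs = runs, tr = 1), class = "roi_timeseries")
}

#' Write a cohort's ground truth to JSON
#'
#' Serializes the full generative table (parameters, clinical profile,
#' encoding spec) for parameter-recovery audits.
#'
#' @param population Output of [sample_population()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(population, path) {
  jsonlite::write_json(population, path, digits = NA, pretty = TRUE)
  invisible(path)
}
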