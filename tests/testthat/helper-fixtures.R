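# Shared fixtures, built once per test session.

design_240 <- generate_design()
schedule_o1 <- schedule_blocks(design_240, order = 1, seed = 11)

# A deterministic "subject" list for forward simulations, with all the
# fields sample_population() would provide.
make_test_subject <- function(alpha_gain = 0.8, beta_gain = 0.4,
                              gamma_gain = 1, alpha_loss = 0.95,
                              beta_loss = -0.3, gamma_loss = 1,
                              mode = c("value", "saliency"),
                              amplitude = 0.3, noise_sd = 0,
                              drift = 0, motion_coupling = 0,
                              condition_amplitude = 0.3,
                              response_amplitude = 0.2,
                              lapse_rate = 0) {
  mode <- match.arg(mode)
  tibble::tibble(
    subject = "sub-test", alpha_gain = alpha_gain, beta_gain = beta_gain,
    gamma_gain = gamma_gain, alpha_loss = alpha_loss,
    beta_loss = beta_loss, gamma_loss = gamma_loss,
    mode = mode, mix_weight = as.numeric(mode == "saliency"),
    amplitude = amplitude, noise_sd = noise_sd, drift = drift,
    motion_coupling = motion_coupling,
    condition_amplitude = condition_amplitude,
    response_amplitude = response_amplitude, lapse_rate = lapse_rate)
}

# Deterministic choices consistent with given parameters (greedy agent).
make_greedy_choices <- function(design, subject = make_test_subject()) {
  sv_l <- subjective_value(design$P, design$A, design$V,
                           ifelse(design$domain == "gain",
                                  subject$alpha_gain, subject$alpha_loss),
                           ifelse(design$domain == "gain",
                                  subject$beta_gain, subject$beta_loss),
                           design$domain)
  sv_c <- subjective_value(1, 0, design$sure_amount,
                           ifelse(design$domain == "gain",
                                  subject$alpha_gain, subject$alpha_loss),
                           ifelse(design$domain == "gain",
                                  subject$beta_gain, subject$beta_loss),
                           design$domain)
  tibble::tibble(trial_id = design$trial_id,
                 chose_lottery = sv_l > sv_c,
                 response_time = 1)
}
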