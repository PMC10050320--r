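#' Subjective value of an uncertain option
#'
#' Computes the model-derived worth of a lottery (or the sure option) for a
#' subject with curvature `alpha` and ambiguity-discounting weight `beta`:
#'
#' \deqn{SV = [P - \beta (A/2)] \times V^{\alpha}}
#'
#' `P` is the outcome probability (0.25/0.50/0.75 for risky lotteries, 0.50
#' for ambiguous ones, 1 for the sure option), `A` the ambiguity level (0
#' for risky lotteries and the sure option), and `V` the unsigned dollar
#' magnitude. Risk attitude enters through the power `alpha`; ambiguity
#' attitude discounts the probability linearly by `beta * A / 2`.
#'
#' Internally the package uses a signed representation: loss-domain values
#' are returned negative, so that a single softmax with noise
#' `gamma >= 0` prefers higher-valued options in both domains. See the
#' methods vignette for the sign conventions.
#'
#' @param P Outcome probability in \[0, 1\]. Vectorized.
#' @param A Ambiguity level in \[0, 1). Vectorized.
#' @param V Unsigned magnitude in dollars, `V >= 0`. Vectorized.
#' @param alpha Curvature exponent, `alpha > 0`.
#' @param beta Ambiguity-discounting weight.
#' @param domain `"gain"` or `"loss"` (scalar or vector).
#' @return Signed subjective value (positive for gains, negative for losses).
#' @examples
#' subjective_value(0.5, 0, 5, alpha = 1, beta = 0, domain = "gain")  # 2.5
#' @export
subjective_value <- function(P, A, V, alpha, beta, domain) {
  if (any(V < 0)) stop("`V` must be non-negative")
  if (any(P < 0 | P > 1)) stop("`P` must lie in [0, 1]")
  if (any(A < 0 | A >= 1)) stop("`A` must lie in [0, 1)")
  if (any(alpha <= 0)) stop("`alpha` must be positive")
  if (!all(domain %in% c("gain", "loss"))) {
    stop("`domain` must be 'gain' or 'loss'")
  }
  sv <- (P - beta * A / 2) * V^alpha
  sign <- ifelse(domain == "gain", 1, -1)
  sign * sv
}

#' Softmax probability of choosing the lottery
#'
#' Standard logistic choice rule on the signed subjective-value difference:
#' `1 / (1 + exp(-gamma * (sv_lottery - sv_sure)))`. With `gamma = 0`
#' choices are random (probability 0.5); as `gamma` grows choices become
#' deterministic in favour of the higher-valued option. Numerically stable
#' for arbitrarily large value differences.
#'
#' @param sv_lottery,sv_sure Signed subjective values (see
#'   [subjective_value()]).
#' @param gamma Softmax noise (inverse temperature), `gamma >= 0`.
#' @return Probability of choosing the lottery.
#' @export
choice_probability <- function(sv_lottery, sv_sure, gamma) {
  if (any(gamma < 0)) stop("`gamma` must be non-negative")
  stats::plogis(gamma * (sv_lottery - sv_sure))
}

#' Negative log-likelihood of a choice set
#'
#' Sums `-log` of the softmax probability of each observed choice under
#' parameters `(alpha, beta, gamma)`. Uses the numerically stable
#' log1p-exp form, equivalent to clamping probabilities away from 0 and 1
#' at machine precision. Missed responses must be removed beforehand.
#'
#' @param params Named numeric vector or list with `alpha`, `beta`, `gamma`.
#' @param choices A data frame with columns `P`, `A`, `V`, `sure_amount`,
#'   `domain`, and logical `chose_lottery`; one domain only.
#' @return The negative log-likelihood (scalar).
#' @export
negative_log_likelihood <- function(params, choices) {
  if (nrow(choices) == 0) stop("`choices` is empty")
  if (any(is.na(choices$chose_lottery))) {
    stop("remove missed responses (NA `chose_lottery`) before computing NLL")
  }
  alpha <- params[["alpha"]]; beta <- params[["beta"]]
  gamma <- params[["gamma"]]
  sv_l <- subjective_value(choices$P, choices$A, choices$V,
                           alpha, beta, choices$domain)
  sv_c <- subjective_value(1, 0, choices$sure_amount,
                           alpha, beta, choices$domain)
  x <- gamma * (sv_l - sv_c)
  # -log p for chosen option: softplus(-x) if lottery chosen, softplus(x) else
  z <- ifelse(choices$chose_lottery, -x, x)
  sum(ifelse(z > 35, z, log1p(exp(pmin(z, 35)))))
}

#' Default configuration for per-subject model fitting
#'
#' Parameter bounds and multistart settings for [fit_subject_domain()].
#' `alpha` is bounded symmetrically in log space around 1
#' (\[exp(-log 4.34), 4.34\] = \[0.0894, 4.34\]); `beta` in \[-4, 4\];
#' `gamma` in \[0, 20\]. Optimization uses `n_starts` L-BFGS-B runs from a
#' seeded Latin-hypercube over the bounded cube.
#'
#' @param n_starts Number of multistart points.
#' @param seed Seed for the Latin-hypercube starts.
#' @param alpha_bounds,beta_bounds,gamma_bounds Length-2 numeric bounds.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, seed = 1,
                       alpha_bounds = c(0.0894, 4.34),
                       beta_bounds = c(-4, 4),
                       gamma_bounds = c(0, 20)) {
  stopifnot(n_starts >= 1, alpha_bounds[1] > 0,
            diff(alpha_bounds) > 0, diff(beta_bounds) > 0,
            gamma_bounds[1] >= 0, diff(gamma_bounds) > 0)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 alpha_bounds = alpha_bounds, beta_bounds = beta_bounds,
                 gamma_bounds = gamma_bounds),
            class = "fit_config")
}

#' Fit the valuation model to one subject's choices in one domain
#'
#' Maximum-likelihood estimation of `(alpha, beta, gamma)` by bounded
#' multistart L-BFGS-B over the [fit_config()] cube. Gain and loss trials
#' are fitted separately; a single `gamma` is shared across risky and
#' ambiguous trials of the domain. Missed responses (`NA chose_lottery`)
#' are dropped from the likelihood. The fit is deterministic given
#' `config$seed`: ties in the objective are broken by the lexicographically
#' smallest parameter vector.
#'
#' A likelihood-ratio comparison against the pure-noise model (`gamma = 0`,
#' all probabilities 0.5) flags low-identifiability fits in which the
#' choices carry no detectable value signal.
#'
#' @param choices A data frame with columns `trial_id`, `chose_lottery`
#'   (logical, `NA` for missed responses), and optionally `response_time`.
#' @param design The trial design tibble (from [generate_design()]),
#'   providing `P`, `A`, `V`, `sure_amount`, `domain` per `trial_id`.
#' @param config A [fit_config()].
#' @return A one-row tibble: `domain`, `alpha`, `beta`, `gamma`, `nll`,
#'   `bic` (`2 nll + 3 log n`), `n_trials`, `converged`,
#'   `low_identifiability`.
#' @export
fit_subject_domain <- function(choices, design, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  dat <- dplyr::inner_join(
    choices[, intersect(c("trial_id", "chose_lottery"), names(choices))],
    design[, c("trial_id", "domain", "uncertainty", "P", "A", "V",
               "sure_amount")],
    by = "trial_id")
  dat <- dat[!is.na(dat$chose_lottery), ]
  if (length(unique(dat$domain)) != 1) {
    stop("`choices` must come from a single domain")
  }
  n <- nrow(dat)
  if (n < 30) stop("need at least 30 non-missed trials per domain, got ", n)

  lower <- c(config$alpha_bounds[1], config$beta_bounds[1],
             config$gamma_bounds[1])
  upper <- c(config$alpha_bounds[2], config$beta_bounds[2],
             config$gamma_bounds[2])

  obj <- function(par) {
    negative_log_likelihood(
      list(alpha = par[1], beta = par[2], gamma = par[3]), dat)
  }

  set.seed(config$seed)
  u <- lhs::randomLHS(config$n_starts, 3)
  # explore small gamma more densely: square the unit draw before scaling
  u[, 3] <- u[, 3]^2
  starts <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)

  fits <- vector("list", config$n_starts)
  for (i in seq_len(config$n_starts)) {
    fits[[i]] <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500,
                                  parscale = c(0.5, 0.5, 0.1))),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop("optimizer failed to converge from every start (n = ", n,
         " trials); check the choice data")
  }
  nlls <- vapply(fits, `[[`, numeric(1), "value")
  best_nll <- min(nlls)
  cands <- fits[nlls <= best_nll + 1e-8]
  pars <- do.call(rbind, lapply(cands, `[[`, "par"))
  pick <- do.call(base::order, as.data.frame(pars))[1]
  best <- cands[[pick]]

  nll <- best$value
  # LR test against random choice (gamma = 0): no signal -> unidentifiable
  lr <- 2 * (n * log(2) - nll)
  tibble::tibble(
    domain = dat$domain[1],
    alpha = best$par[1], beta = best$par[2], gamma = best$par[3],
    nll = nll, bic = 2 * nll + 3 * log(n), n_trials = n,
    converged = best$convergence == 0,
    low_identifiability = lr < stats::qchisq(0.95, df = 1))
}

#' Transform fitted parameters into the four uncertainty attitudes
#'
#' Maps per-domain `(alpha, beta)` estimates onto a common scale where
#' negative values indicate aversion and positive values indicate seeking:
#' risky gains `alpha_gain - 1`, risky losses `1 - alpha_loss`, ambiguous
#' gains `-beta_gain`, ambiguous losses `beta_loss`.
#'
#' @param gain_params,loss_params One-row data frames (or named lists) with
#'   `alpha` and `beta` for the gain and loss fits.
#' @return A one-row tibble: `risk_gain`, `risk_loss`, `amb_gain`,
#'   `amb_loss`.
#' @export
transform_attitudes <- function(gain_params, loss_params) {
  tibble::tibble(
    risk_gain = gain_params[["alpha"]] - 1,
    risk_loss = 1 - loss_params[["alpha"]],
    amb_gain = -gain_params[["beta"]],
    amb_loss = loss_params[["beta"]])
}

#' Catch-trial quality control
#'
#' On catch trials the lottery's non-zero outcome equals the sure amount, so
#' one option dominates: in gains the sure $5 beats any lottery over $5
#' (choosing the lottery is inferior); in losses a chance of losing $5
#' weakly dominates surely losing $5 (choosing the sure loss is inferior).
#' Subjects choosing the inferior option on strictly more than 50% of
#' responded catch trials fail and are excluded from analysis.
#'
#' @param choices Data frame with `trial_id` and logical `chose_lottery`
#'   (`NA` = missed, excluded from the fraction).
#' @param design Trial design containing the catch trials.
#' @return A list: `pass` (logical), `inferior_fraction`, `n_catch`
#'   (responded catch trials).
#' @export
catch_trial_quality <- function(choices, design) {
  catch <- identify_catch_trials(design)
  dat <- dplyr::inner_join(choices[, c("trial_id", "chose_lottery")],
                           catch[, c("trial_id", "domain")],
                           by = "trial_id")
  dat <- dat[!is.na(dat$chose_lottery), ]
  inferior <- ifelse(dat$domain == "gain", dat$chose_lottery,
                     !dat$chose_lottery)
  frac <- if (nrow(dat) == 0) 0 else mean(inferior)
  list(pass = frac <= 0.5, inferior_fraction = frac, n_catch = nrow(dat))
}
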