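#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking around
#' 6 s and an undershoot around 16 s at a 6:1 peak:undershoot ratio,
#' peak-normalized to a maximum of 1. This is the standard shape used to
#' convolve task regressors before sampling at the TR grid.
#'
#' @param t Time in seconds, `t >= 0`. Vectorized.
#' @param peak_delay Time-to-peak of the positive lobe (gamma shape with
#'   unit scale), seconds. Default 6.
#' @param undershoot_delay Time-to-peak of the undershoot, seconds.
#'   Default 16.
#' @param ratio Undershoot-to-peak amplitude ratio. Default 1/6.
#' @return HRF amplitude at `t` (unitless, max 1).
#' @export
double_gamma_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                             ratio = 1 / 6) {
  if (any(t < 0)) stop("`t` must be non-negative")
  if (peak_delay <= 0 || undershoot_delay <= 0 || ratio < 0) {
    stop("HRF shape parameters must be positive")
  }
  h <- function(x) {
    stats::dgamma(x, shape = peak_delay, scale = 1) -
      ratio * stats::dgamma(x, shape = undershoot_delay, scale = 1)
  }
  grid <- seq(0, max(32, undershoot_delay * 2), by = 0.01)
  h(t) / max(h(grid))
}

#' Convert a raw run series to percent signal change
#'
#' `100 * (x - mean(x)) / mean(x)`, applied within one scanning run.
#'
#' @param x Numeric vector, the raw series of one run.
#' @return The percent-signal-change series (mean exactly 0).
#' @export
percent_signal_change <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || abs(m) < sqrt(.Machine$double.eps)) {
    stop("run mean is zero (or not finite); percent signal change undefined")
  }
  100 * (x - m) / m
}

#' z-normalize a modulator within scanning blocks
#'
#' Within each block, subtracts the mean and divides by the sample
#' (n - 1) standard deviation. Degenerate blocks (zero variance or a single
#' value) map to zeros with a warning.
#'
#' @param x Numeric modulator values (e.g. trial-wise subjective values).
#' @param block Block label per value.
#' @return The per-block z-scored vector.
#' @export
z_normalize_per_block <- function(x, block) {
  stopifnot(length(x) == length(block))
  out <- numeric(length(x))
  for (b in unique(block)) {
    sel <- block == b
    s <- stats::sd(x[sel])
    if (length(which(sel)) < 2 || !is.finite(s) || s == 0) {
      warning("degenerate block '", b, "': constant modulator set to zero")
      out[sel] <- 0
    } else {
      out[sel] <- (x[sel] - mean(x[sel])) / s
    }
  }
  out
}

#' GLM variant specification
#'
#' Names the condition predictors and parametric modulators of the five
#' first-level model variants:
#' * `glm1`: 4 binary condition predictors (risky/ambiguous x gain/loss).
#' * `glm2`: the glm1 predictors, each with a signed-SV modulator
#'   (z-normalized per block).
#' * `glm3`: 2 condition predictors (risky, ambiguous) across domains with
#'   signed-SV modulators — monotonic value coding.
#' * `glm4`: as glm3 with unsigned |SV| modulators — U-shaped saliency
#'   coding.
#' * `glm5`: 12 binary predictors, one per subjective-value bin
#'   (2 uncertainty x 2 domain x 3 bins).
#'
#' All variants add a 1-s response regressor at the button press and carry
#' the 6 motion nuisance series at estimation time.
#'
#' @param variant One of `"glm1"` ... `"glm5"`.
#' @return A list of class `glm_spec` with `variant`, `conditions`,
#'   `modulator` (`"none"`, `"sv"`, or `"abs_sv"`), and `by_domain`.
#' @export
glm_spec <- function(variant = c("glm1", "glm2", "glm3", "glm4", "glm5")) {
  variant <- match.arg(variant)
  spec <- switch(variant,
    glm1 = list(modulator = "none", by_domain = TRUE),
    glm2 = list(modulator = "sv", by_domain = TRUE),
    glm3 = list(modulator = "sv", by_domain = FALSE),
    glm4 = list(modulator = "abs_sv", by_domain = FALSE),
    glm5 = list(modulator = "bins", by_domain = TRUE))
  conds <- if (spec$by_domain && variant != "glm5") {
    c("risky_gain", "ambiguous_gain", "risky_loss", "ambiguous_loss")
  } else if (variant == "glm5") {
    as.vector(outer(c("risky", "ambiguous"),
                    paste0("bin", 1:6), paste, sep = "_"))
  } else {
    c("risky", "ambiguous")
  }
  structure(c(list(variant = variant, conditions = conds,
                   epoch_duration = DISPLAY_DURATION), spec),
            class = "glm_spec")
}

# Internal microtime machinery ------------------------------------------

# Sampled HRF kernel on the fine grid.
.hrf_kernel <- function(dt, span = 32) {
  double_gamma_hrf(seq(0, span, by = dt))
}

# Boxcar on the fine time grid: heights applied over [onset, onset + dur).
.boxcar_fine <- function(onsets, durations, heights, n_fine, dt) {
  x <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1
    b <- min(n_fine, ceiling((onsets[i] + durations[i]) / dt))
    if (a <= b) x[a:b] <- x[a:b] + heights[i]
  }
  x
}

# Convolver factory for one run: causal FFT convolution with the HRF,
# zero-padded to a power of two, sampled at the TR grid
# (t = 0, 1, ..., n_tr - 1 seconds). Caches the kernel FFT.
.make_convolver <- function(kernel, n_fine, n_tr, dt, tr = 1) {
  m <- length(kernel)
  L <- stats::nextn(n_fine + m - 1, 2)
  kf <- stats::fft(c(kernel, numeric(L - m)))
  idx <- pmin(round((0:(n_tr - 1)) * tr / dt) + 1, n_fine)
  function(x) {
    y <- Re(stats::fft(stats::fft(c(x, numeric(L - n_fine))) * kf,
                       inverse = TRUE)) / L * dt
    y[idx]
  }
}

# Trial condition label under a glm_spec.
.condition_label <- function(trials, spec, bins = NULL) {
  unc <- ifelse(trials$uncertainty == "risk", "risky", "ambiguous")
  switch(spec$modulator,
    bins = paste0(unc, "_bin", bins),
    if (spec$by_domain) paste0(unc, "_", trials$domain) else unc)
}

#' Assign subjective-value bins for the categorical-value GLM
#'
#' Within each uncertainty domain (risky, ambiguous), ranks the subject's
#' loss trials by signed subjective value and splits them into 3
#' equal-count bins (bins 1-3, ascending SV); gain trials are split the
#' same way into bins 4-6. Ties are broken by `trial_id`; when counts are
#' not divisible by 3 the remainder goes to the lower bins.
#'
#' @param trials Trial tibble with `trial_id`, `domain`, `uncertainty`.
#' @param svs Signed subjective values aligned with `trials`.
#' @return Integer bin labels (1-6) aligned with `trials`.
#' @export
assign_sv_bins <- function(trials, svs) {
  stopifnot(nrow(trials) == length(svs))
  bins <- integer(nrow(trials))
  for (unc in unique(trials$uncertainty)) {
    for (dom in c("loss", "gain")) {
      sel <- which(trials$uncertainty == unc & trials$domain == dom)
      if (length(sel) == 0) next
      ord <- sel[order(svs[sel], trials$trial_id[sel])]
      n <- length(ord)
      sizes <- rep(n %/% 3, 3)
      if (n %% 3 > 0) sizes[seq_len(n %% 3)] <- sizes[seq_len(n %% 3)] + 1
      lab <- rep(1:3, times = sizes)
      bins[ord] <- lab + if (dom == "gain") 3L else 0L
    }
  }
  bins
}

#' Build first-level design matrices for a schedule
#'
#' Constructs, per run, the task regressors of a GLM variant: condition
#' box-cars of 6 s at trial onsets, parametric modulators (per-block
#' z-normalized signed SV or |SV|, multiplied into the box-car before
#' convolution), and a 1-s response regressor at the button press —
#' all convolved with the canonical double-gamma HRF on a 0.1-s microtime
#' grid and sampled at the 1-s TR grid. Modulators are z-normalized within
#' block x uncertainty cells (each block holds one domain). Run intercepts
#' and motion nuisance columns are appended at estimation time by
#' [fit_glm()].
#'
#' @param schedule A `block_schedule`.
#' @param spec A [glm_spec()] (or a variant name).
#' @param svs Signed subjective values for all 240 trials, aligned with
#'   `schedule$trials` rows (required for glm2-glm5).
#' @param response_times Optional response time (s) per scheduled trial
#'   (`NA` = missed, no response event); defaults to the display offset.
#' @param dt Microtime resolution in seconds.
#' @return A list of class `glm_design`: `X` (list of per-run matrices with
#'   identical column sets), `spec`, and `bins` (for glm5).
#' @export
build_design_matrix <- function(schedule, spec, svs = NULL,
                                response_times = NULL, dt = 0.1) {
  stopifnot(inherits(schedule, "block_schedule"))
  if (is.character(spec)) spec <- glm_spec(spec)
  trials <- schedule$trials
  need_sv <- spec$modulator %in% c("sv", "abs_sv", "bins")
  if (need_sv) {
    if (is.null(svs) || length(svs) != nrow(trials) || anyNA(svs)) {
      stop("`svs` must provide a subjective value for every scheduled trial")
    }
  }

  bins <- NULL
  if (spec$modulator == "bins") bins <- assign_sv_bins(trials, svs)

  mod_vals <- NULL
  if (spec$modulator %in% c("sv", "abs_sv")) {
    raw <- if (spec$modulator == "abs_sv") abs(svs) else svs
    cell <- paste(trials$block, trials$uncertainty)
    mod_vals <- z_normalize_per_block(raw, cell)
  }

  if (is.null(response_times)) {
    response_times <- rep(0, nrow(trials))  # press at the response cue
  }
  stopifnot(length(response_times) == nrow(trials))

  cond_labels <- .condition_label(trials, spec, bins)
  all_conds <- spec$conditions
  kernel <- .hrf_kernel(dt)

  X <- list()
  for (r in schedule$runs$run_id) {
    sel <- trials$run_id == r
    tr <- trials[sel, ]
    labs <- cond_labels[sel]
    n_tr <- schedule$runs$n_tr[schedule$runs$run_id == r]
    n_fine <- ceiling(n_tr / dt) + 1
    conv <- .make_convolver(kernel, n_fine, n_tr, dt, schedule$tr)

    cols <- list()
    for (cond in all_conds) {
      on <- tr$onset[labs == cond]
      box <- .boxcar_fine(on, rep(spec$epoch_duration, length(on)),
                          rep(1, length(on)), n_fine, dt)
      cols[[cond]] <- conv(box)
      if (spec$modulator %in% c("sv", "abs_sv")) {
        h <- mod_vals[sel][labs == cond]
        mbox <- .boxcar_fine(on, rep(spec$epoch_duration, length(on)),
                             h, n_fine, dt)
        cols[[paste0(cond, "_mod")]] <- conv(mbox)
      }
    }
    rt <- response_times[sel]
    resp_on <- tr$onset[!is.na(rt)] + spec$epoch_duration +
      rt[!is.na(rt)]
    rbox <- .boxcar_fine(resp_on, rep(schedule$tr, length(resp_on)),
                         rep(1, length(resp_on)), n_fine, dt)
    cols[["response"]] <- conv(rbox)
    X[[as.character(r)]] <- do.call(cbind, cols)
  }
  structure(list(X = X, spec = spec, bins = bins,
                 run_id = schedule$runs$run_id),
            class = "glm_design")
}

#' Estimate first-level GLM betas by ordinary least squares
#'
#' Concatenates the runs of an ROI series, appends per-run intercepts and
#' (when present) the 6 motion nuisance columns, drops all-zero task
#' columns, checks full column rank, and solves the least-squares problem.
#'
#' @param roi An `roi_timeseries` (list of runs with `values` and optional
#'   `nuisance`), or a plain list of numeric vectors per run.
#' @param design A `glm_design` from [build_design_matrix()] covering the
#'   same runs.
#' @param include_nuisance Add motion nuisance columns when available.
#' @return A tibble (one row per estimated column): `predictor`, `beta`,
#'   `role` (`condition` / `modulator` / `response` / `nuisance` /
#'   `intercept`), plus attribute `dropped` naming removed all-zero
#'   columns.
#' @export
fit_glm <- function(roi, design, include_nuisance = TRUE) {
  stopifnot(inherits(design, "glm_design"))
  runs <- if (inherits(roi, "roi_timeseries")) roi$runs else roi
  ids <- as.character(design$run_id)
  if (length(runs) != length(ids)) {
    stop("ROI series has ", length(runs), " runs but the design has ",
         length(ids))
  }
  y <- c(); Xs <- list(); nuis <- list(); n_runs <- length(ids)
  for (i in seq_len(n_runs)) {
    run <- runs[[i]]
    vals <- if (is.list(run)) run$values else run
    Xr <- design$X[[ids[i]]]
    if (length(vals) != nrow(Xr)) {
      stop("run ", ids[i], ": series length ", length(vals),
           " does not match design rows ", nrow(Xr))
    }
    y <- c(y, vals)
    Xs[[i]] <- Xr
    nuis[[i]] <- if (include_nuisance && is.list(run) &&
                       !is.null(run$nuisance)) run$nuisance else NULL
  }
  X <- do.call(rbind, Xs)
  roles <- rep("condition", ncol(X))
  roles[grepl("_mod$", colnames(X))] <- "modulator"
  roles[colnames(X) == "response"] <- "response"

  if (!all(vapply(nuis, is.null, logical(1)))) {
    lens <- vapply(Xs, nrow, integer(1))
    N <- matrix(0, sum(lens), 6,
                dimnames = list(NULL, paste0("motion", 1:6)))
    off <- 0
    for (i in seq_len(n_runs)) {
      if (!is.null(nuis[[i]])) N[off + seq_len(lens[i]), ] <- nuis[[i]]
      off <- off + lens[i]
    }
    X <- cbind(X, N)
    roles <- c(roles, rep("nuisance", 6))
  }
  # per-run intercepts
  lens <- vapply(Xs, nrow, integer(1))
  Ic <- matrix(0, sum(lens), n_runs,
               dimnames = list(NULL, paste0("intercept_run", ids)))
  off <- 0
  for (i in seq_len(n_runs)) {
    Ic[off + seq_len(lens[i]), i] <- 1
    off <- off + lens[i]
  }
  X <- cbind(X, Ic)
  roles <- c(roles, rep("intercept", n_runs))

  zero <- apply(X == 0, 2, all)
  dropped <- colnames(X)[zero]
  X <- X[, !zero, drop = FALSE]
  roles <- roles[!zero]

  qrX <- qr(X)  # LINPACK pivoting exposes the effective rank
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  out <- tibble::tibble(predictor = colnames(X), beta = unname(beta),
                        role = roles)
  attr(out, "dropped") <- dropped
  out
}
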