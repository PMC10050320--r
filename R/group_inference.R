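#' Correlate a per-subject measure with symptom scores
#'
#' Applies the score-kind-appropriate correlation: Spearman's rank-order
#' correlation for CAPS (an ordinal clinician rating with a floor at zero),
#' Pearson's correlation for PCL-5 and for principal-component scores
#' (which vary more smoothly, including among subjects with CAPS of zero).
#'
#' @param values Numeric vector (e.g. attitudes or GLM betas), one per
#'   subject.
#' @param scores Symptom scores, aligned with `values`.
#' @param score_kind `"caps"`, `"pcl5"`, or `"pc"`.
#' @return A one-row tibble: `analysis`, `statistic_type`
#'   (`spearman_rho`/`pearson_r`), `statistic`, `df`, `p_raw`, `n`.
#' @export
correlate_with_symptoms <- function(values, scores,
                                    score_kind = c("caps", "pcl5", "pc")) {
  score_kind <- match.arg(score_kind)
  if (length(values) != length(scores)) {
    stop("`values` and `scores` must have equal length")
  }
  keep <- stats::complete.cases(values, scores)
  values <- values[keep]; scores <- scores[keep]
  n <- length(values)
  if (n < 4) stop("need at least 4 complete pairs")
  method <- if (score_kind == "caps") "spearman" else "pearson"
  ct <- suppressWarnings(
    stats::cor.test(values, scores, method = method, exact = FALSE))
  tibble::tibble(
    analysis = paste0("correlation_", score_kind),
    statistic_type = if (method == "spearman") "spearman_rho"
                     else "pearson_r",
    statistic = unname(ct$estimate),
    df = n - 2,
    p_raw = ct$p.value,
    n = n)
}

#' Covariate-adjusted symptom effect on an outcome
#'
#' Multi-factor analysis through a linear model:
#' `outcome ~ symptom + age + income (categorical) + education
#' (categorical) + intelligence + fit BIC`. The symptom term is tested by
#' comparing the full model against the model without it (type-II style
#' partial F test). Income and education bands are dummy-coded factors;
#' incomplete cases are dropped.
#'
#' @param data Data frame with the outcome, symptom, and covariate columns.
#' @param outcome Name of the outcome column.
#' @param symptom Name of the symptom column (default `"caps_total"`).
#' @param covariates Character vector of covariate columns; those named in
#'   `categorical` are treated as factors.
#' @param categorical Covariates to dummy-code.
#' @return A one-row tibble: `analysis`, `statistic_type = "F"`,
#'   `statistic`, `df1`, `df2`, `p_raw`, `n`.
#' @export
covariate_adjusted_effect <- function(data, outcome,
                                      symptom = "caps_total",
                                      covariates = c("age", "income_band",
                                                     "education_band",
                                                     "kbit", "bic"),
                                      categorical = c("income_band",
                                                      "education_band")) {
  cols <- c(outcome, symptom, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- data[stats::complete.cases(data[cols]), cols]
  for (cc in intersect(categorical, covariates)) {
    df[[cc]] <- factor(df[[cc]])
  }
  rhs_cov <- paste(covariates, collapse = " + ")
  f_full <- stats::as.formula(paste(outcome, "~", symptom, "+", rhs_cov))
  f_red <- stats::as.formula(paste(outcome, "~", rhs_cov))
  fit_full <- stats::lm(f_full, data = df)
  if (nrow(df) < length(stats::coef(fit_full)) + 2) {
    stop("too few complete cases (", nrow(df), ") for the model")
  }
  if (any(is.na(stats::coef(fit_full)))) {
    bad <- names(stats::coef(fit_full))[is.na(stats::coef(fit_full))]
    stop("rank-deficient covariate model; aliased terms: ",
         paste(bad, collapse = ", "))
  }
  fit_red <- stats::lm(f_red, data = df)
  an <- stats::anova(fit_red, fit_full)
  tibble::tibble(
    analysis = paste0("adjusted_", symptom, "_on_", outcome),
    statistic_type = "F",
    statistic = an$F[2],
    df1 = an$Df[2], df2 = an$Res.Df[2],
    p_raw = an$`Pr(>F)`[2],
    n = nrow(df))
}

#' Group tests of value and saliency encoding
#'
#' Tests the neural coding pattern across groups: four one-sample t tests
#' of the value and saliency betas against zero, separately in controls and
#' PTSD, with Benjamini-Hochberg FDR correction across the four; plus a
#' Welch two-sample t test comparing saliency betas between groups
#' (unequal-variance, hence the fractional degrees of freedom).
#'
#' @param value_betas,saliency_betas Per-subject value- and
#'   saliency-encoding betas (e.g. mean GLM3 / GLM4 modulator betas).
#' @param group Group label per subject, `"ptsd"` or `"control"`.
#' @return A tibble of results: `analysis`, `statistic_type`, `statistic`,
#'   `df`, `p_raw`, `p_fdr` (`NA` for the two-sample test), `n`.
#' @export
value_saliency_group_tests <- function(value_betas, saliency_betas, group) {
  stopifnot(length(value_betas) == length(group),
            length(saliency_betas) == length(group))
  if (!all(group %in% c("ptsd", "control"))) {
    stop("`group` must contain only 'ptsd' and 'control'")
  }
  if (any(table(factor(group, c("control", "ptsd"))) < 3)) {
    stop("each group needs at least 3 subjects")
  }
  cells <- list(
    value_control = value_betas[group == "control"],
    value_ptsd = value_betas[group == "ptsd"],
    saliency_control = saliency_betas[group == "control"],
    saliency_ptsd = saliency_betas[group == "ptsd"])
  one <- lapply(cells, function(x) stats::t.test(x, mu = 0))
  res <- tibble::tibble(
    analysis = paste0("one_sample_", names(cells)),
    statistic_type = "t",
    statistic = unname(vapply(one, function(f) unname(f$statistic),
                              numeric(1))),
    df = unname(vapply(one, function(f) unname(f$parameter), numeric(1))),
    p_raw = unname(vapply(one, function(f) f$p.value, numeric(1))),
    n = unname(vapply(cells, length, integer(1))))
  res$p_fdr <- stats::p.adjust(res$p_raw, method = "BH")

  welch <- stats::t.test(saliency_betas[group == "control"],
                         saliency_betas[group == "ptsd"])
  dplyr::bind_rows(res, tibble::tibble(
    analysis = "two_sample_saliency_control_vs_ptsd",
    statistic_type = "t",
    statistic = unname(welch$statistic),
    df = unname(welch$parameter),
    p_raw = welch$p.value,
    p_fdr = NA_real_,
    n = length(group)))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate adjustment of a family of p values, with
#' rejection flags at level `q`.
#'
#' @param p Numeric p values in \[0, 1\].
#' @param q FDR level for the rejection flags.
#' @return A list: `p_adjusted`, `reject` (logical).
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("`p` must contain p values in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' Exhaustive best-subset regression by BIC
#'
#' Enumerates every non-empty subset of up to 15 candidate predictors, fits
#' each by ordinary least squares (always with an intercept), and ranks the
#' models by the Gaussian-likelihood BIC
#' `n * log(RSS / n) + (k + 1) * log(n)` (the `+ 1` counts the intercept).
#' Returns the full ranked table, the best model per subset size, and the
#' overall best set.
#'
#' @param y Numeric outcome vector.
#' @param predictors Data frame (or matrix) of candidate predictors,
#'   `p <= 15` columns.
#' @return A list of class `subset_selection`: `table` (one row per model:
#'   `size`, `members`, `rss`, `bic`, `rank`, plus indicator columns),
#'   `best_set` (character), `best_by_size`.
#' @export
exhaustive_subset_selection <- function(y, predictors) {
  X <- as.data.frame(predictors)
  p <- ncol(X)
  n <- length(y)
  if (p > 15) stop("refusing exhaustive enumeration over more than 15 ",
                   "predictors (got ", p, ")")
  if (n <= p + 2) stop("need n > p + 2 observations")
  if (anyNA(y) || anyNA(X)) stop("missing values in `y` or `predictors`")
  Xm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    bad <- colnames(Xm)[qrX$pivot[(qrX$rank + 1):ncol(Xm)]]
    stop("collinear candidate predictors: ", paste(bad, collapse = ", "))
  }

  n_models <- 2^p - 1
  members <- character(n_models)
  sizes <- integer(n_models)
  rss <- numeric(n_models)
  ind <- matrix(FALSE, n_models, p, dimnames = list(NULL, colnames(X)))
  for (m in seq_len(n_models)) {
    sel <- as.logical(bitwAnd(m, 2^(seq_len(p) - 1)))
    ind[m, ] <- sel
    fit <- stats::lm.fit(Xm[, c(TRUE, sel), drop = FALSE], y)
    rss[m] <- sum(fit$residuals^2)
    sizes[m] <- sum(sel)
    members[m] <- paste(colnames(X)[sel], collapse = "+")
  }
  bic <- n * log(rss / n) + (sizes + 1) * log(n)
  tab <- dplyr::bind_cols(
    tibble::tibble(size = sizes, members = members, rss = rss, bic = bic),
    tibble::as_tibble(ind))
  tab <- tab[order(tab$bic), ]
  tab$rank <- seq_len(nrow(tab))
  best_by_size <- dplyr::slice_min(dplyr::group_by(tab, .data$size),
                                   .data$bic, n = 1, with_ties = FALSE)
  best_by_size <- dplyr::arrange(dplyr::ungroup(best_by_size), .data$size)
  structure(list(
    table = tab,
    best_set = strsplit(tab$members[1], "+", fixed = TRUE)[[1]],
    best_by_size = best_by_size),
    class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  cat("<subset_selection>", nrow(x$table), "models; best set:",
      paste(x$best_set, collapse = " + "),
      sprintf("(BIC = %.2f)\n", x$table$bic[1]))
  invisible(x)
}

#' PCA of clinical and trauma-exposure measures
#'
#' Principal component analysis of the correlation matrix of the clinical
#' battery (by default CAPS total, BDI, trait anxiety, dissociation, combat
#' exposure, childhood trauma). Only complete cases enter. Components are
#' signed so that each component's largest-magnitude loading is positive,
#' making the first component interpretable as a general affective-severity
#' factor when one dominates.
#'
#' @param measures Data frame of numeric clinical measures (columns =
#'   instruments).
#' @return A list of class `clinical_pca`: `loadings` (variables x
#'   components), `scores` (complete cases x components),
#'   `var_explained` (percent, sums to 100), `n` (complete cases used).
#' @export
pca_clinical <- function(measures) {
  measures <- as.data.frame(measures)
  keep <- stats::complete.cases(measures)
  X <- measures[keep, , drop = FALSE]
  if (nrow(X) < ncol(X)) {
    stop("fewer complete cases (", nrow(X), ") than variables (",
         ncol(X), ")")
  }
  if (any(vapply(X, stats::sd, numeric(1)) == 0)) {
    stop("constant measure column; cannot standardize")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(
    loadings = loadings,
    scores = scores,
    var_explained = 100 * pc$sdev^2 / sum(pc$sdev^2),
    n = nrow(X),
    complete_cases = which(keep)),
    class = "clinical_pca")
}
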