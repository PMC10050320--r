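#' Pipeline configuration
#'
#' Collects every knob of the simulate -> fit -> GLM -> group pipeline:
#' cohort size and generator settings, behavioral fit settings, which GLM
#' variants to estimate, the source of trial-wise subjective values for the
#' GLM stage, and the output directory. All randomness derives from the
#' single root `seed`, split deterministically per stage and subject.
#'
#' @param n_subjects Cohort size.
#' @param seed Root integer seed.
#' @param out_dir Output directory for all stage artifacts.
#' @param cohort A [cohort_config()].
#' @param fit A [fit_config()].
#' @param glm_variants GLM variants to estimate (subset of glm1-glm5).
#' @param sv_source Subjective values used for GLM modulators:
#'   `"per_day"` (refit each scanning session separately, mirroring the
#'   per-session refits used for neural analysis), `"combined"` (one fit
#'   over both sessions), or `"true"` (generative parameters; fast, for
#'   simulation studies of the neural chain alone).
#' @param run_behavioral_fits Fit the choice model (needed for attitudes
#'   and `sv_source != "true"`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 48, seed = 1,
                            out_dir = tempfile("riskamb_run_"),
                            cohort = cohort_config(),
                            fit = fit_config(),
                            glm_variants = c("glm3", "glm4"),
                            sv_source = c("per_day", "combined", "true"),
                            run_behavioral_fits = TRUE) {
  sv_source <- match.arg(sv_source)
  stopifnot(inherits(cohort, "cohort_config"), inherits(fit, "fit_config"),
            all(glm_variants %in% paste0("glm", 1:5)))
  if (sv_source != "true" && !run_behavioral_fits) {
    stop("sv_source '", sv_source, "' requires run_behavioral_fits = TRUE")
  }
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 out_dir = out_dir, cohort = cohort, fit = fit,
                 glm_variants = glm_variants, sv_source = sv_source,
                 run_behavioral_fits = run_behavioral_fits),
            class = "pipeline_config")
}

# Deterministic seed splitting below 2^31.
.derive_seed <- function(seed, stage, unit = 0) {
  (as.numeric(seed) * 7919 + stage * 104729 + unit * 31) %%
    .Machine$integer.max
}

.stage_record <- function(name, t0, outputs) {
  files <- outputs[file.exists(outputs)]
  list(stage = name,
       elapsed_s = round(as.numeric(Sys.time()) - t0, 3),
       outputs = as.list(files),
       md5 = as.list(unname(tools::md5sum(files))))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, in order: task-design generation and per-subject block
#' scheduling (counterbalance order alternating across subjects); cohort
#' sampling; choice simulation with catch-trial quality control;
#' behavioral model fitting (combined sessions for attitudes, optionally
#' per-session refits for GLM subjective values); ROI time-series
#' simulation and first-level GLM estimation for the configured variants;
#' and group-level inference (attitude-symptom correlations and
#' value/saliency group tests when glm3 and glm4 are present). Each stage
#' writes CSV/TSV/JSON artifacts under `config$out_dir` and is logged in a
#' manifest with wall time and MD5 checksums; on failure the manifest
#' records the partially completed run before the error is rethrown with
#' the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  jsonlite::write_json(
    config[setdiff(names(config), character(0))],
    file.path(out, "config.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)

  manifest <- list(seed = config$seed, stages = list(), status = "running")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fun) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fun(), error = function(e) {
      manifest$status <<- paste0("failed at stage '", name, "'")
      flush_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- .stage_record(name, t0, res$outputs)
    flush_manifest()
    res$value
  }

  design <- NULL; schedules <- NULL; population <- NULL; choices <- NULL

  design <- run_stage("design", function() {
    d <- generate_design()
    path <- file.path(out, "design.csv")
    readr::write_csv(d, path)
    list(value = d, outputs = path)
  })

  schedules <- run_stage("schedule", function() {
    sch <- lapply(seq_len(config$n_subjects), function(i) {
      schedule_blocks(design, order = 1 + (i - 1) %% 2,
                      seed = .derive_seed(config$seed, 1, i))
    })
    ev_dir <- file.path(out, "events")
    paths <- write_events_tsv(sch[[1]], ev_dir, prefix = "sub-001")
    list(value = sch, outputs = paths)
  })

  population <- run_stage("cohort", function() {
    pop <- sample_population(config$n_subjects, config$cohort,
                             seed = .derive_seed(config$seed, 2))
    p1 <- file.path(out, "clinical.csv")
    clin_cols <- c("subject", "group", "caps_total", "caps_reexp",
                   "caps_avoid", "caps_numb", "caps_dysarousal",
                   "caps_anxarousal", "pcl5", "bdi", "stai_state",
                   "stai_trait", "des", "ces", "ctq", "age", "income_band",
                   "education_band", "kbit")
    readr::write_csv(pop[clin_cols], p1)
    p2 <- file.path(out, "ground_truth.json")
    write_ground_truth(pop, p2)
    list(value = pop, outputs = c(p1, p2))
  })

  choices <- run_stage("choices", function() {
    ch <- lapply(seq_len(config$n_subjects), function(i) {
      ci <- simulate_choices(population[i, ], schedules[[i]],
                             seed = .derive_seed(config$seed, 3, i))
      ci$subject <- population$subject[i]
      ci
    })
    all <- dplyr::bind_rows(ch)
    path <- file.path(out, "choices.csv")
    readr::write_csv(all, path)
    list(value = ch, outputs = path)
  })

  qc <- run_stage("quality_control", function() {
    rows <- lapply(seq_len(config$n_subjects), function(i) {
      q <- catch_trial_quality(choices[[i]], design)
      tibble::tibble(subject = population$subject[i], qc_pass = q$pass,
                     inferior_fraction = q$inferior_fraction,
                     n_catch = q$n_catch)
    })
    tab <- dplyr::bind_rows(rows)
    path <- file.path(out, "qc.csv")
    readr::write_csv(tab, path)
    list(value = tab, outputs = path)
  })

  params <- NULL
  if (config$run_behavioral_fits) {
    params <- run_stage("fit", function() {
      rows <- list()
      for (i in seq_len(config$n_subjects)) {
        if (!qc$qc_pass[i]) next
        ch <- choices[[i]]
        sch <- schedules[[i]]$trials
        for (dom in c("gain", "loss")) {
          ids <- design$trial_id[design$domain == dom]
          fits <- list(combined = ch[ch$trial_id %in% ids, ])
          if (config$sv_source == "per_day") {
            for (day in c("day1", "day2")) {
              day_ids <- sch$trial_id[sch$session == day &
                                        sch$domain == dom]
              fits[[day]] <- ch[ch$trial_id %in% day_ids, ]
            }
          }
          for (fit_name in names(fits)) {
            fr <- fit_subject_domain(fits[[fit_name]], design, config$fit)
            fr$subject <- population$subject[i]
            fr$session <- fit_name
            rows[[length(rows) + 1]] <- fr
          }
        }
      }
      tab <- dplyr::bind_rows(rows)
      p1 <- file.path(out, "params.csv")
      readr::write_csv(tab, p1)
      att <- dplyr::bind_rows(lapply(unique(tab$subject), function(s) {
        g <- tab[tab$subject == s & tab$domain == "gain" &
                   tab$session == "combined", ]
        l <- tab[tab$subject == s & tab$domain == "loss" &
                   tab$session == "combined", ]
        a <- transform_attitudes(g, l)
        a$subject <- s
        a$bic <- g$bic + l$bic
        a
      }))
      p2 <- file.path(out, "attitudes.csv")
      readr::write_csv(att, p2)
      list(value = list(params = tab, attitudes = att),
           outputs = c(p1, p2))
    })
  }

  betas <- run_stage("glm", function() {
    rows <- list()
    for (i in seq_len(config$n_subjects)) {
      sub <- population[i, ]
      sch <- schedules[[i]]
      svs <- switch(config$sv_source,
        true = subject_svs(sub, sch),
        combined = {
          tab <- params$params
          pg <- tab[tab$subject == sub$subject & tab$domain == "gain" &
                      tab$session == "combined", ]
          pl <- tab[tab$subject == sub$subject & tab$domain == "loss" &
                      tab$session == "combined", ]
          fitted_sub <- list(alpha_gain = pg$alpha, beta_gain = pg$beta,
                             alpha_loss = pl$alpha, beta_loss = pl$beta)
          subject_svs(fitted_sub, sch)
        },
        per_day = {
          tab <- params$params
          sv <- numeric(nrow(sch$trials))
          for (day in c("day1", "day2")) {
            sel <- sch$trials$session == day
            pg <- tab[tab$subject == sub$subject & tab$domain == "gain" &
                        tab$session == day, ]
            pl <- tab[tab$subject == sub$subject & tab$domain == "loss" &
                        tab$session == day, ]
            fitted_sub <- list(alpha_gain = pg$alpha, beta_gain = pg$beta,
                               alpha_loss = pl$alpha, beta_loss = pl$beta)
            sv[sel] <- subject_svs(fitted_sub, sch)[sel]
          }
          sv
        })
      rts <- choices[[i]]$response_time
      true_svs <- subject_svs(sub, sch)
      Xs <- lapply(stats::setNames(nm = config$glm_variants), function(v) {
        build_design_matrix(sch, v, svs, response_times = rts)
      })
      gen_designs <- if (identical(svs, true_svs) &&
                           all(c("glm3", "glm4") %in% names(Xs))) {
        Xs[c("glm3", "glm4")]
      } else NULL
      roi <- simulate_roi_timeseries(sub, sch, svs = true_svs,
                                     response_times = rts,
                                     seed = .derive_seed(config$seed, 4, i),
                                     designs = gen_designs)
      for (variant in config$glm_variants) {
        bt <- fit_glm(roi, Xs[[variant]])
        bt$subject <- sub$subject
        bt$variant <- variant
        rows[[length(rows) + 1]] <- bt
      }
    }
    tab <- dplyr::bind_rows(rows)
    path <- file.path(out, "betas.csv")
    readr::write_csv(tab, path)
    list(value = tab, outputs = path)
  })

  run_stage("group", function() {
    outputs <- character(0)
    results <- list()
    if (config$run_behavioral_fits) {
      att <- dplyr::inner_join(params$attitudes, population,
                               by = "subject")
      for (a in c("risk_gain", "risk_loss", "amb_gain", "amb_loss")) {
        r <- correlate_with_symptoms(att[[a]], att$caps_total, "caps")
        r$analysis <- paste0("caps_vs_", a)
        results[[length(results) + 1]] <- r
      }
    }
    if (all(c("glm3", "glm4") %in% config$glm_variants)) {
      summ <- .encoding_summary(betas, population)
      p_enc <- file.path(out, "encoding_betas.csv")
      readr::write_csv(summ, p_enc)
      outputs <- c(outputs, p_enc)
      vs <- value_saliency_group_tests(summ$value_beta, summ$saliency_beta,
                                       summ$group)
      results[[length(results) + 1]] <- vs
    }
    tab <- dplyr::bind_rows(results)
    if (nrow(tab) == 0) {
      tab <- tibble::tibble(analysis = character(),
                            statistic_type = character(),
                            statistic = numeric(), df = numeric(),
                            p_raw = numeric(), p_fdr = numeric(),
                            n = numeric())
    }
    path <- file.path(out, "group_results.csv")
    readr::write_csv(tab, path)
    list(value = tab, outputs = c(path, outputs))
  })

  manifest$status <- "complete"
  flush_manifest()
  invisible(manifest)
}

# Per-subject mean modulator beta for glm3 (value) and glm4 (saliency).
.encoding_summary <- function(betas, population) {
  mods <- betas[betas$role == "modulator" &
                  betas$variant %in% c("glm3", "glm4"), ]
  summ <- dplyr::summarise(
    dplyr::group_by(mods, .data$subject, .data$variant),
    beta = mean(.data$beta), .groups = "drop")
  summ <- tidyr::pivot_wider(summ, names_from = "variant",
                             values_from = "beta")
  summ <- dplyr::rename(summ, value_beta = "glm3", saliency_beta = "glm4")
  dplyr::inner_join(summ,
                    population[, c("subject", "group", "caps_total")],
                    by = "subject")
}

#' Summarize and plot a completed pipeline run
#'
#' Reads a run directory produced by [run_pipeline()] and renders summary
#' tables and figures: a scatter of CAPS total against the value/saliency
#' encoding betas, grouped bars of the mean value and saliency betas per
#' group, and — when glm5 was estimated — the 6-bin mean-activity profile
#' per group, which exposes monotonic (value) versus U-shaped (saliency)
#' coding. Figures are written as PNG under `<run_dir>/report`.
#'
#' @param run_dir A completed run directory containing `manifest.json`.
#' @return A list: `tables` (tibbles: `encoding`, `group_results`,
#'   `bin_profile` when available), `figures` (paths of written PNGs).
#' @export
make_report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop("no manifest found at ", man_path, "; not a pipeline run directory")
  }
  manifest <- jsonlite::read_json(man_path)
  if (!identical(manifest$status, "complete")) {
    warning("run is incomplete (status: ", manifest$status,
            "); reporting what is present")
  }
  rep_dir <- file.path(run_dir, "report")
  if (!dir.exists(rep_dir)) dir.create(rep_dir)
  tables <- list()
  figures <- character(0)

  enc_path <- file.path(run_dir, "encoding_betas.csv")
  if (file.exists(enc_path)) {
    enc <- readr::read_csv(enc_path, show_col_types = FALSE)
    tables$encoding <- enc
    long <- tidyr::pivot_longer(enc, c("value_beta", "saliency_beta"),
                                names_to = "signal", values_to = "beta")
    g1 <- ggplot2::ggplot(long,
            ggplot2::aes(x = .data$caps_total, y = .data$beta,
                         colour = .data$group)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::facet_wrap(~signal) +
      ggplot2::labs(x = "CAPS total", y = "modulator beta (psc / z-SV)")
    f1 <- file.path(rep_dir, "caps_vs_encoding.png")
    ggplot2::ggsave(f1, g1, width = 7, height = 3.5, dpi = 120)
    g2 <- ggplot2::ggplot(long,
            ggplot2::aes(x = .data$signal, y = .data$beta,
                         fill = .data$group)) +
      ggplot2::stat_summary(fun = mean, geom = "bar",
                            position = ggplot2::position_dodge()) +
      ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                            position = ggplot2::position_dodge(0.9),
                            width = 0.25) +
      ggplot2::labs(y = "mean modulator beta")
    f2 <- file.path(rep_dir, "value_saliency_bars.png")
    ggplot2::ggsave(f2, g2, width = 5, height = 3.5, dpi = 120)
    figures <- c(figures, f1, f2)
  }

  res_path <- file.path(run_dir, "group_results.csv")
  if (file.exists(res_path)) {
    tables$group_results <- readr::read_csv(res_path,
                                            show_col_types = FALSE)
  }

  betas_path <- file.path(run_dir, "betas.csv")
  clin_path <- file.path(run_dir, "clinical.csv")
  if (file.exists(betas_path) && file.exists(clin_path)) {
    betas <- readr::read_csv(betas_path, show_col_types = FALSE)
    clin <- readr::read_csv(clin_path, show_col_types = FALSE)
    b5 <- betas[betas$variant == "glm5" &
                  grepl("_bin[1-6]$", betas$predictor), ]
    if (nrow(b5) > 0) {
      b5$bin <- as.integer(sub(".*_bin", "", b5$predictor))
      b5 <- dplyr::inner_join(b5, clin[, c("subject", "group")],
                              by = "subject")
      prof <- dplyr::summarise(
        dplyr::group_by(b5, .data$group, .data$bin),
        mean_beta = mean(.data$beta), se = stats::sd(.data$beta) /
          sqrt(dplyr::n()), .groups = "drop")
      tables$bin_profile <- prof
      g3 <- ggplot2::ggplot(prof,
              ggplot2::aes(x = .data$bin, y = .data$mean_beta,
                           colour = .data$group)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::scale_x_continuous(breaks = 1:6) +
        ggplot2::labs(x = "subjective-value bin (1 = worst loss)",
                      y = "mean bin beta")
      f3 <- file.path(rep_dir, "bin_profile.png")
      ggplot2::ggsave(f3, g3, width = 5, height = 3.5, dpi = 120)
      figures <- c(figures, f3)
    }
  }
  if (length(tables) == 0) {
    warning("run directory contains no reportable outputs")
  }
  list(tables = tables, figures = figures)
}
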