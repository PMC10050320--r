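# Task constants: lottery magnitude menu, uncertainty levels, timing.
LOTTERY_MAGNITUDES <- c(5, 6, 7, 8, 10, 12, 14, 16, 19, 23, 27, 31,
                        37, 44, 52, 61, 73, 86, 101, 120)
RISK_LEVELS <- c(0.25, 0.50, 0.75)
AMBIGUITY_LEVELS <- c(0.24, 0.50, 0.74)
SURE_AMOUNT <- 5
DISPLAY_DURATION <- 6     # seconds options are on screen
RESPONSE_WINDOW <- 3.5    # seconds to register a choice
ITI_MENU <- c(4, 6, 8)    # jittered inter-trial intervals, seconds
POST_RUN_REST <- 16       # seconds appended to each run for the BOLD tail

#' Generate the full 240-trial lottery design
#'
#' Builds the complete factorial of the choice task: for each domain (gain,
#' loss), 3 risk levels plus 3 ambiguity levels crossed with 20 lottery
#' magnitudes, giving 120 unique trials per domain. Every trial offers the
#' lottery against a fixed $5 sure outcome of the same sign. Risky trials
#' have a fully known outcome probability (`P` in 0.25/0.50/0.75, `A = 0`);
#' ambiguous trials have `P = 0.50` with a fraction `A` (0.24/0.50/0.74) of
#' the probability display occluded.
#'
#' Trials are ordered deterministically: domain (gain first), then
#' uncertainty (risk first), then P (risk) or A (ambiguity) ascending, then
#' magnitude ascending. `trial_id` indexes that ordering.
#'
#' @return A tibble with 240 rows and columns `trial_id`, `domain`,
#'   `uncertainty`, `P`, `A`, `V` (unsigned lottery magnitude, dollars),
#'   `sure_amount` (always 5), and `is_catch` (`V == sure_amount`).
#' @examples
#' d <- generate_design()
#' nrow(d)                      # 240
#' sum(d$domain == "gain")      # 120
#' @export
generate_design <- function() {
  one_domain <- function(domain) {
    risky <- tidyr::expand_grid(P = RISK_LEVELS, V = LOTTERY_MAGNITUDES)
    risky$uncertainty <- "risk"
    risky$A <- 0
    ambig <- tidyr::expand_grid(A = AMBIGUITY_LEVELS, V = LOTTERY_MAGNITUDES)
    ambig$uncertainty <- "ambiguity"
    ambig$P <- 0.5
    out <- dplyr::bind_rows(risky, ambig)
    out$domain <- domain
    out
  }
  design <- dplyr::bind_rows(one_domain("gain"), one_domain("loss"))
  design <- dplyr::select(design, "domain", "uncertainty", "P", "A", "V")
  design$sure_amount <- SURE_AMOUNT
  design$is_catch <- design$V == SURE_AMOUNT
  design$trial_id <- seq_len(nrow(design))
  dplyr::relocate(tibble::as_tibble(design), "trial_id")
}

#' Identify catch trials in a design
#'
#' Catch trials are those in which the non-zero lottery outcome equals the
#' sure amount ($5), so one option dominates (a sure $5 gain beats any
#' chance of gaining $5; a lottery over losing $5 weakly beats surely
#' losing $5). They drive the behavioral quality-control rule in
#' [catch_trial_quality()].
#'
#' @param design A trial tibble from [generate_design()].
#' @return The subset of `design` rows with `V == sure_amount`.
#' @export
identify_catch_trials <- function(design) {
  design[design$V == design$sure_amount, , drop = FALSE]
}

#' Schedule the design into 8 blocks over 2 sessions
#'
#' Distributes the 240 trials into 8 single-domain blocks of 30 trials (4
#' gain, 4 loss), 4 blocks per scanning session. Block domain order follows
#' one of two counterbalance orders: order 1 is Gain-Gain-Loss-Loss on day 1
#' and Loss-Loss-Gain-Gain on day 2; order 2 is the reverse.
#'
#' Within each domain, the 60 risky and 60 ambiguous trials are each dealt
#' round-robin by ascending magnitude into the domain's 4 blocks, so every
#' block holds 15 risky and 15 ambiguous trials spanning the magnitude
#' range (this keeps subjective-value variance comparable across blocks,
#' which per-block z-normalization of GLM modulators implicitly assumes).
#' Trial order within block is then shuffled under `seed`, and inter-trial
#' intervals are drawn uniformly from 4/6/8 s. Each trial occupies a fixed
#' 6 s display + 3.5 s response window + ITI; unused response-window time is
#' folded into the ITI at presentation, so scheduled onsets are final.
#'
#' @param design The 240-trial tibble from [generate_design()].
#' @param order Counterbalance order, 1 or 2.
#' @param seed Integer seed controlling within-block shuffling and ITI draws.
#' @return An object of class `block_schedule`: a list with `trials` (the
#'   design plus `block`, `run_id`, `session`, `trial_in_block`, `onset`,
#'   `iti`), `runs` (per-run domain, session and duration in TRs of 1 s),
#'   and the timing constants.
#' @export
schedule_blocks <- function(design, order = 1, seed = 1) {
  if (!is.data.frame(design) || nrow(design) != 240) {
    stop("`design` must be the full 240-trial design from generate_design()")
  }
  if (length(order) != 1 || !order %in% c(1, 2)) {
    stop("`order` must be 1 or 2")
  }
  set.seed(as.integer(seed))

  # deal each domain x uncertainty stratum round-robin by sorted magnitude
  design <- design[order(design$trial_id), ]
  strata_block <- integer(nrow(design))
  for (dom in c("gain", "loss")) {
    for (unc in c("risk", "ambiguity")) {
      sel <- which(design$domain == dom & design$uncertainty == unc)
      lvl <- design$P[sel] + design$A[sel]  # uncertainty level within type
      ord <- sel[order(design$V[sel], lvl, design$trial_id[sel])]
      strata_block[ord] <- rep_len(1:4, length(ord))
    }
  }

  block_domains <- switch(order,
    c("gain", "gain", "loss", "loss", "loss", "loss", "gain", "gain"),
    c("loss", "loss", "gain", "gain", "gain", "gain", "loss", "loss"))
  sessions <- rep(c("day1", "day2"), each = 4)

  counters <- c(gain = 0L, loss = 0L)
  blocks <- vector("list", 8)
  for (b in 1:8) {
    dom <- block_domains[b]
    counters[dom] <- counters[dom] + 1L
    rows <- design[design$domain == dom & strata_block == counters[dom], ]
    rows <- rows[sample.int(nrow(rows)), ]
    iti <- sample(ITI_MENU, nrow(rows), replace = TRUE)
    trial_len <- DISPLAY_DURATION + RESPONSE_WINDOW + iti
    rows$onset <- cumsum(c(0, trial_len[-length(trial_len)]))
    rows$iti <- iti
    rows$block <- b
    rows$run_id <- b
    rows$session <- sessions[b]
    rows$trial_in_block <- seq_len(nrow(rows))
    blocks[[b]] <- rows
  }
  trials <- dplyr::bind_rows(blocks)

  runs <- dplyr::summarise(
    dplyr::group_by(trials, .data$run_id, .data$session),
    domain = .data$domain[1],
    n_trials = dplyr::n(),
    n_tr = ceiling(max(.data$onset + DISPLAY_DURATION + RESPONSE_WINDOW +
                         .data$iti)) + POST_RUN_REST,
    .groups = "drop")

  structure(
    list(trials = trials, runs = runs, order = order, seed = seed,
         display_duration = DISPLAY_DURATION,
         response_window = RESPONSE_WINDOW, iti_menu = ITI_MENU,
         tr = 1),
    class = "block_schedule")
}

#' @export
print.block_schedule <- function(x, ...) {
  cat("<block_schedule>", nrow(x$trials), "trials in", nrow(x$runs),
      "runs; counterbalance order", x$order, "\n")
  print(x$runs)
  invisible(x)
}

#' Write BIDS-style events TSVs for a schedule
#'
#' Writes one `*_run-NN_events.tsv` per run with columns `onset`,
#' `duration`, `trial_type` (e.g. `risky_gain`), `P`, `A`, `V`,
#' `sure_amount`, `is_catch`, `trial_id`.
#'
#' @param schedule A `block_schedule`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix, typically a subject label.
#' @return Invisibly, the paths written.
#' @export
write_events_tsv <- function(schedule, dir, prefix = "sub-01") {
  stopifnot(inherits(schedule, "block_schedule"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (r in schedule$runs$run_id) {
    tr <- schedule$trials[schedule$trials$run_id == r, ]
    ev <- tibble::tibble(
      onset = tr$onset,
      duration = schedule$display_duration,
      trial_type = paste0(ifelse(tr$uncertainty == "risk", "risky",
                                 "ambiguous"), "_", tr$domain),
      P = tr$P, A = tr$A, V = tr$V,
      sure_amount = tr$sure_amount, is_catch = tr$is_catch,
      trial_id = tr$trial_id)
    path <- file.path(dir, sprintf("%s_run-%02d_events.tsv", prefix, r))
    readr::write_tsv(ev, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
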