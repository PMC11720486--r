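#' Trim reaction times for one participant-block
#'
#' Applies the standard trimming sequence: (1) when `for_rt_analysis`, drop
#' probe-incorrect trials; (2) drop trials with RT below 200 ms or above
#' 2000 ms (boundary values are kept); (3) compute the mean and SD of the
#' survivors of step 2 and drop trials outside mean +/- 2 SD. The SD pass is
#' applied once, per participant-block, not per congruency condition.
#'
#' @param trials trial records from a single participant and block.
#' @param for_rt_analysis drop probe-incorrect trials first (as for RT
#'   analyses).
#' @param rt_window lower/upper absolute RT window in ms.
#' @param sd_mult SD multiplier for the distribution-based pass.
#' @return list with `trials` (kept rows) and `audit`, a one-row data.frame
#'   counting removals at each step (`n_input`, `n_removed_incorrect`,
#'   `n_removed_window`, `n_removed_sd`, `n_kept`).
#' @export
trim_rts <- function(trials, for_rt_analysis = TRUE,
                     rt_window = c(200, 2000), sd_mult = 2) {
  n_input <- nrow(trials)
  if (for_rt_analysis) {
    keep <- trials$probe_correct
    n_inc <- sum(!keep)
    trials <- trials[keep, , drop = FALSE]
  } else n_inc <- 0L
  in_window <- trials$rt_ms >= rt_window[1] & trials$rt_ms <= rt_window[2]
  n_win <- sum(!in_window)
  trials <- trials[in_window, , drop = FALSE]
  if (nrow(trials) == 0L)
    stop("degenerate input: no trials inside the RT window (SD undefined)")
  m <- mean(trials$rt_ms)
  s <- stats::sd(trials$rt_ms)
  if (is.na(s)) s <- 0
  keep_sd <- if (s == 0) rep(TRUE, nrow(trials)) else
    trials$rt_ms >= m - sd_mult * s & trials$rt_ms <= m + sd_mult * s
  n_sd <- sum(!keep_sd)
  trials <- trials[keep_sd, , drop = FALSE]
  audit <- data.frame(n_input = n_input, n_removed_incorrect = n_inc,
                      n_removed_window = n_win, n_removed_sd = n_sd,
                      n_kept = nrow(trials))
  list(trials = trials, audit = audit)
}

#' Select subjectively unseen trials (PAS = 1)
#'
#' Returns the subset of trials with a PAS rating of 1 ("no perception"),
#' preserving order. A `low_count` attribute flags participants with fewer
#' than `min_per_cell` PAS-1 trials in either congruency cell, whose mean RTs
#' are unreliable.
#'
#' @param trials trial records with a populated `pas` column.
#' @param min_per_cell reliability threshold per congruency cell (default 10).
#' @return the PAS-1 subset, with attribute `low_count` (logical).
#' @export
select_pas1 <- function(trials, min_per_cell = 10L) {
  out <- trials[trials$pas == 1L, , drop = FALSE]
  present <- out[!is.na(out$congruent), , drop = FALSE]
  low <- sum(present$congruent) < min_per_cell ||
    sum(!present$congruent) < min_per_cell
  attr(out, "low_count") <- low
  out
}

#' Participant exclusion flags
#'
#' Flags participants following the standard rules: probe accuracy lower than
#' 75% in the multiple-task block (`low_accuracy`), and more than 10% PAS-4
#' ("clear perception") reports on catch trials in either the multiple-task
#' or the visibility block (`pas4_catch_abuse`). Both inequalities are
#' strict; a participant at exactly 75% accuracy or exactly 10% PAS-4 catch
#' reports is not flagged. When a block is missing the corresponding flag is
#' `NA`, not `FALSE`.
#'
#' @param cohort trial-level data.frame for several participants.
#' @param accuracy_cut accuracy threshold (default 0.75).
#' @param pas4_cut PAS-4 catch-rate threshold (default 0.10).
#' @return data.frame with one row per participant: `participant`,
#'   `low_accuracy`, `pas4_catch_abuse`, `excluded`.
#' @export
exclusion_flags <- function(cohort, accuracy_cut = 0.75, pas4_cut = 0.10) {
  ids <- sort(unique(cohort$participant))
  pas4_rate <- function(tr) {
    catch <- tr[tr$prime_identity == "none", , drop = FALSE]
    if (nrow(catch) == 0L) return(NA_real_)
    mean(catch$pas == 4L)
  }
  res <- lapply(ids, function(id) {
    p <- cohort[cohort$participant == id, , drop = FALSE]
    mult <- p[p$block == "multiple", , drop = FALSE]
    vis <- p[p$block == "visibility", , drop = FALSE]
    low_acc <- if (nrow(mult)) mean(mult$probe_correct) < accuracy_cut else NA
    r_m <- if (nrow(mult)) pas4_rate(mult) else NA_real_
    r_v <- if (nrow(vis)) pas4_rate(vis) else NA_real_
    abuse <- if (all(is.na(c(r_m, r_v)))) NA else any(c(r_m, r_v) > pas4_cut, na.rm = TRUE)
    data.frame(participant = id, low_accuracy = low_acc,
               pas4_catch_abuse = abuse,
               excluded = isTRUE(low_acc) || isTRUE(abuse))
  })
  do.call(rbind, res)
}

#' Per-participant congruency (priming) effect
#'
#' Mean incongruent RT minus mean congruent RT, with the standard error of
#' the difference of two independent cell means,
#' `sqrt(var_c / n_c + var_i / n_i)`.
#'
#' @param trials trimmed trial records from one participant-block; both
#'   congruency cells must be non-empty.
#' @return one-row data.frame: `effect_ms`, `effect_se_ms`, `n_congruent`,
#'   `n_incongruent`.
#' @export
congruency_effect <- function(trials) {
  trials <- trials[!is.na(trials$congruent), , drop = FALSE]
  rc <- trials$rt_ms[trials$congruent]
  ri <- trials$rt_ms[!trials$congruent]
  if (length(rc) == 0L || length(ri) == 0L)
    stop("degenerate input: empty congruency cell")
  vc <- if (length(rc) >= 2) stats::var(rc) else 0
  vi <- if (length(ri) >= 2) stats::var(ri) else 0
  data.frame(effect_ms = mean(ri) - mean(rc),
             effect_se_ms = sqrt(vc / length(rc) + vi / length(ri)),
             n_congruent = length(rc), n_incongruent = length(ri))
}
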