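#' Signal detection counts from objective discrimination responses
#'
#' Tallies the prime forced-choice task treating square primes as the signal
#' class and diamond primes as noise: a hit is a square prime answered
#' "square", a false alarm a diamond prime answered "square". Catch trials
#' are excluded.
#'
#' @param trials trial records with `prime_identity` and `prime_choice`.
#' @return an `sdt_counts` data.frame: `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`, `signal_definition`.
#' @export
counts_objective <- function(trials) {
  pres <- trials[trials$prime_identity %in% c("square", "diamond"), , drop = FALSE]
  if (nrow(pres) == 0L) stop("no prime-present trials")
  sq <- pres$prime_identity == "square"
  said_sq <- pres$prime_choice == "square"
  structure(data.frame(hits = sum(sq & said_sq),
                       misses = sum(sq & !said_sq),
                       false_alarms = sum(!sq & said_sq),
                       correct_rejections = sum(!sq & !said_sq),
                       signal_definition = "square prime = signal"),
            class = c("sdt_counts", "data.frame"))
}

#' Signal detection counts from subjective visibility reports
#'
#' Tallies prime detection from PAS ratings: a hit is a prime-present trial
#' with any reported awareness (PAS 2, 3 or 4); a false alarm is a catch
#' trial with reported awareness. Catch trials are required, otherwise the
#' false-alarm rate is undefined.
#'
#' @param trials trial records with `prime_identity` and `pas`.
#' @return an `sdt_counts` data.frame.
#' @export
counts_subjective <- function(trials) {
  pres <- trials$prime_identity %in% c("square", "diamond")
  if (!any(!pres)) stop("no catch trials: false-alarm rate undefined")
  if (!any(pres)) stop("no prime-present trials")
  aware <- trials$pas >= 2L
  structure(data.frame(hits = sum(pres & aware),
                       misses = sum(pres & !aware),
                       false_alarms = sum(!pres & aware),
                       correct_rejections = sum(!pres & !aware),
                       signal_definition = "PAS >= 2 on prime-present = hit"),
            class = c("sdt_counts", "data.frame"))
}

#' Sensitivity (d') and criterion from SDT counts
#'
#' Computes `d' = qnorm(H) - qnorm(F)` and criterion
#' `c = -(qnorm(H) + qnorm(F)) / 2`. The log-linear correction (add 0.5 to
#' each cell, 1 to each denominator) is applied unconditionally so the
#' estimate is finite and continuous in the counts; the uncorrected rates
#' are reported alongside for audit.
#'
#' @param counts an `sdt_counts` row (from [counts_objective()] or
#'   [counts_subjective()]).
#' @param source label recorded in the result (`"objective"` or
#'   `"subjective"`).
#' @param block block label recorded in the result.
#' @return a `sensitivity_estimate` data.frame: `d_prime`, `criterion_c`,
#'   `hit_rate`, `fa_rate` (post-correction), `hit_rate_raw`, `fa_rate_raw`,
#'   `d_prime_raw` (uncorrected, possibly infinite), `correction`, `source`,
#'   `block`.
#' @export
dprime <- function(counts, source = "objective", block = NA_character_) {
  n_sig <- counts$hits + counts$misses
  n_noise <- counts$false_alarms + counts$correct_rejections
  if (n_sig == 0L || n_noise == 0L)
    stop("zero total count in signal or noise class")
  h <- (counts$hits + 0.5) / (n_sig + 1)
  f <- (counts$false_alarms + 0.5) / (n_noise + 1)
  h_raw <- counts$hits / n_sig
  f_raw <- counts$false_alarms / n_noise
  structure(data.frame(d_prime = stats::qnorm(h) - stats::qnorm(f),
                       criterion_c = -(stats::qnorm(h) + stats::qnorm(f)) / 2,
                       hit_rate = h, fa_rate = f,
                       hit_rate_raw = h_raw, fa_rate_raw = f_raw,
                       d_prime_raw = stats::qnorm(h_raw) - stats::qnorm(f_raw),
                       correction = "log-linear",
                       source = source, block = block),
            class = c("sensitivity_estimate", "data.frame"))
}

#' Per-participant sensitivity table for one block
#'
#' Convenience wrapper: computes one [dprime()] row per participant from
#' either the objective forced-choice responses or the subjective PAS-based
#' detection counts. Group-level d' is the mean of per-participant d's, never
#' the d' of pooled counts.
#'
#' @param cohort trial-level data.frame.
#' @param block block label to analyse.
#' @param measure `"objective"` or `"subjective"`.
#' @return data.frame with one row per participant.
#' @export
sdt_by_participant <- function(cohort, block, measure = c("objective", "subjective")) {
  measure <- match.arg(measure)
  sub <- cohort[cohort$block == block, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no trials for block '", block, "'")
  ids <- sort(unique(sub$participant))
  rows <- lapply(ids, function(id) {
    tr <- sub[sub$participant == id, , drop = FALSE]
    cnt <- if (measure == "objective") counts_objective(tr) else counts_subjective(tr)
    cbind(participant = id, dprime(cnt, source = measure, block = block))
  })
  do.call(rbind, rows)
}
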