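#' Describe a masked-priming experiment design
#'
#' A design specification holds the block structure and timing of a masked
#' hierarchical-priming experiment: per block, 320 trials of which 20% are
#' prime-absent catch trials, the remaining trials split equally between the
#' two prime identities (square, diamond) and, within each identity, between
#' congruent and incongruent prime-probe pairings. Event durations default to
#' the 40 ms prime / 107 ms prime-to-probe SOA timing used with hierarchical
#' shape stimuli; the two masking settings (ISI 0 + mask 67, ISI 13 + mask 53)
#' give the same SOA.
#'
#' @param n_participants number of participants to simulate.
#' @param blocks character vector of block labels, each one of
#'   `"single"`, `"multiple"`, `"visibility"`.
#' @param trials_per_block trials per block (default 320).
#' @param catch_proportion proportion of prime-absent catch trials
#'   (default 0.20, i.e. 64 of 320).
#' @param event_durations_ms named list of event durations in milliseconds;
#'   must contain `fixation`, `forward_mask`, `prime`, `isi`, `backward_mask`,
#'   `iti`.
#' @param congruency_balance proportion of congruent trials among prime-present
#'   trials (default 0.5).
#' @param refresh_rate_hz display refresh rate; event durations are quantized
#'   to frames of this rate (default 75).
#' @param seed master integer seed; per-participant substreams are derived
#'   from it so a cohort can be extended without reshuffling earlier
#'   participants.
#'
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_participants = 24,
                        blocks = c("single", "multiple", "visibility"),
                        trials_per_block = 320L,
                        catch_proportion = 0.20,
                        event_durations_ms = list(fixation = 1000, forward_mask = 100,
                                                  prime = 40, isi = 0,
                                                  backward_mask = 67, iti = 800),
                        congruency_balance = 0.5,
                        refresh_rate_hz = 75,
                        seed = 1L) {
  if (length(blocks) < 1L || !all(blocks %in% c("single", "multiple", "visibility")))
    stop("blocks must be a non-empty subset of 'single', 'multiple', 'visibility'")
  if (trials_per_block < 1L) stop("invalid design: non-positive trial count")
  if (catch_proportion < 0 || catch_proportion >= 1)
    stop("catch_proportion must be in [0, 1)")
  if (congruency_balance < 0 || congruency_balance > 1)
    stop("congruency_balance must be in [0, 1]")
  structure(list(n_participants = as.integer(n_participants),
                 blocks = blocks,
                 trials_per_block = as.integer(trials_per_block),
                 catch_proportion = catch_proportion,
                 event_durations_ms = event_durations_ms,
                 prime_labels = c("square", "diamond"),
                 congruency_balance = congruency_balance,
                 refresh_rate_hz = refresh_rate_hz,
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Prime-to-probe stimulus onset asynchrony
#'
#' Onset-to-onset interval between the prime and the probe: prime duration +
#' inter-stimulus interval + backward mask duration. Displays on a CRT/LCD
#' refresh at discrete frames, so each nominal duration is first snapped to
#' the nearest multiple of the frame period (13.33 ms at the default 75 Hz)
#' and the sum is rounded to the millisecond. Both standard masking settings
#' then give the same 107 ms SOA: 40 + 0 + 66.7 and 40 + 13.3 + 53.3 (the
#' nominal "67", "13" and "53" are the conventional rounded labels of 5-, 1-
#' and 4-frame durations).
#'
#' @param spec a [design_spec()].
#' @return SOA in milliseconds (integer-rounded).
#' @export
soa_ms <- function(spec) {
  d <- spec$event_durations_ms
  need <- c("prime", "isi", "backward_mask")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("configuration error: missing event duration(s): ",
         paste(missing, collapse = ", "))
  frame <- 1000 / spec$refresh_rate_hz
  snap <- function(ms) round(ms / frame) * frame
  round(snap(d$prime) + snap(d$isi) + snap(d$backward_mask))
}

#' Build the randomized trial list for one block
#'
#' Expands a design into per-trial specifications: catch count =
#' `round(catch_proportion * trials_per_block)`; prime-present trials split
#' equally between square and diamond primes; probe identity balanced
#' orthogonally to prime identity, so the congruent:incongruent split follows
#' `congruency_balance` within each prime identity. Trial order is randomized
#' by `rng`.
#'
#' @param spec a [design_spec()].
#' @param rng an integer seed for the trial-order randomization.
#' @return a data.frame with one row per trial: `index`, `prime_identity`
#'   (`"square"`, `"diamond"`, `"none"`), `probe_identity`, `congruent`
#'   (logical, `NA` on catch trials).
#' @export
build_design <- function(spec, rng = spec$seed) {
  n <- spec$trials_per_block
  if (n < 1L) stop("invalid design: non-positive trial count")
  n_catch <- as.integer(round(spec$catch_proportion * n))
  n_present <- n - n_catch
  if (n_present %% 2L != 0L)
    stop("invalid design: prime-present trials cannot be split equally between identities")
  per_identity <- n_present %/% 2L
  n_congr <- as.integer(round(spec$congruency_balance * per_identity))

  one_identity <- function(prime) {
    congr <- c(rep(TRUE, n_congr), rep(FALSE, per_identity - n_congr))
    probe <- ifelse(congr, prime, setdiff(spec$prime_labels, prime))
    data.frame(prime_identity = prime, probe_identity = probe,
               congruent = congr, stringsAsFactors = FALSE)
  }
  present <- rbind(one_identity("square"), one_identity("diamond"))
  catch <- if (n_catch > 0L) {
    # catch trials still show a probe; balance its identity
    data.frame(prime_identity = "none",
               probe_identity = rep_len(spec$prime_labels, n_catch),
               congruent = NA, stringsAsFactors = FALSE)
  } else NULL
  trials <- rbind(present, catch)
  ord <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(rng)
    sample.int(nrow(trials))
  })
  trials <- trials[ord, , drop = FALSE]
  trials$index <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials[, c("index", "prime_identity", "probe_identity", "congruent")]
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
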