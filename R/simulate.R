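#' Generative parameters for the synthetic masked-priming experiment
#'
#' The simulator draws, on every trial, a bivariate percept over an identity
#' evidence axis (square vs diamond) and an awareness evidence axis, from the
#' Gaussian distribution of the trial's stimulus class (square, diamond, or
#' absent on catch trials). The absent class is anchored at mean (0, 0) with
#' unit variances; present-class mean vectors are multiplied by a block-wise
#' attention scale and a per-participant attention factor kappa. The prime
#' forced-choice response is the side of the identity criterion; the PAS
#' rating is the bin of the awareness percept among three increasing
#' cutpoints. Probe RTs are drawn as mean-one multiplicative lognormal noise
#' around `base + (alpha + beta * a) * incongruent`, where `a` is the trial's
#' awareness percept relative to the participant's no-prime baseline, so
#' `alpha` is the true congruency effect at zero awareness and `beta` scales
#' awareness-driven priming.
#'
#' @param group_distributions named list (`square`, `diamond`, `absent`) of
#'   lists with `mean` (length-2: identity, awareness) and `cov` (2x2,
#'   positive-definite).
#' @param attention_scale_by_block named positive multipliers applied to
#'   present-class mean vectors per block.
#' @param pas_criteria three strictly increasing cutpoints on the awareness
#'   axis.
#' @param identity_criterion scalar cutpoint on the identity axis.
#' @param rt_model list with `base_ms_by_block` (named), `alpha_ms`,
#'   `beta_ms`, `sdlog`, `probe_error_rate`.
#' @param participant_sd standard deviation of participant-level awareness
#'   offsets (shifts both present and absent awareness means, i.e. a
#'   subjective-report trait).
#' @param kappa_sdlog standard deviation of per-participant log attention
#'   scaling kappa; kappa multiplies present-class mean vectors on both axes,
#'   giving true between-subject spread in prime visibility.
#'
#' @return an object of class `generative_params`.
#' @export
generative_params <- function(group_distributions = list(
                                square  = list(mean = c(0.4, 0.4), cov = diag(2)),
                                diamond = list(mean = c(-0.4, 0.4), cov = diag(2)),
                                absent  = list(mean = c(0, 0), cov = diag(2))),
                              attention_scale_by_block = c(single = 0.8,
                                                           multiple = 1.0,
                                                           visibility = 1.5),
                              pas_criteria = c(0.85, 1.75, 2.6),
                              identity_criterion = 0,
                              rt_model = list(base_ms_by_block = c(single = 520,
                                                                   multiple = 780,
                                                                   visibility = 650),
                                              alpha_ms = 0, beta_ms = 30,
                                              sdlog = 0.2, probe_error_rate = 0.03),
                              participant_sd = 0.3,
                              kappa_sdlog = 0.3) {
  for (cl in c("square", "diamond", "absent")) {
    g <- group_distributions[[cl]]
    if (is.null(g)) stop("group_distributions must contain '", cl, "'")
    ev <- eigen(g$cov, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariance for '", cl, "' is not positive-definite")
  }
  if (length(pas_criteria) != 3L || any(diff(pas_criteria) <= 0))
    stop("pas_criteria must be 3 strictly increasing cutpoints")
  if (any(attention_scale_by_block <= 0))
    stop("attention scales must be positive")
  p_err <- rt_model$probe_error_rate
  if (p_err < 0 || p_err >= 1) stop("probe_error_rate must be in [0, 1)")
  structure(list(group_distributions = group_distributions,
                 attention_scale_by_block = attention_scale_by_block,
                 pas_criteria = pas_criteria,
                 identity_criterion = identity_criterion,
                 rt_model = rt_model,
                 participant_sd = participant_sd,
                 kappa_sdlog = kappa_sdlog),
            class = "generative_params")
}

# deterministic per-participant substream seed (counter-based, < 2^31)
participant_seed <- function(seed, participant) {
  as.integer((seed %% 90000L) * 20011L + participant)
}

# draw one participant's latent traits from their substream
draw_traits <- function(params) {
  list(kappa = exp(stats::rnorm(1, 0, params$kappa_sdlog)),
       aw_offset = stats::rnorm(1, 0, params$participant_sd))
}

#' Simulate one participant's trials for one block
#'
#' @param params a [generative_params()].
#' @param design trial list from [build_design()].
#' @param block block label (must be present in the attention-scale and
#'   base-RT maps).
#' @param rng integer seed for this participant-block stream.
#' @param participant participant id recorded in the output.
#' @param traits optional list with `kappa` and `aw_offset`; drawn from `rng`
#'   when `NULL`.
#' @return a data.frame of trial records: `participant`, `block`, `trial`,
#'   `prime_identity`, `congruent`, `probe_identity`, `rt_ms`,
#'   `probe_correct`, `prime_choice`, `pas`.
#' @export
simulate_participant <- function(params, design, block, rng,
                                 participant = 1L, traits = NULL) {
  s_b <- params$attention_scale_by_block[block]
  base <- params$rt_model$base_ms_by_block[block]
  if (is.na(s_b) || is.na(base))
    stop("unknown block label '", block, "' in generative parameters")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng)
  if (is.null(traits)) traits <- draw_traits(params)

  n <- nrow(design)
  cls <- ifelse(design$prime_identity == "none", "absent", design$prime_identity)
  # per-class mean (attention-scaled for present classes) + awareness offset
  mu <- t(vapply(cls, function(cl) {
    m <- params$group_distributions[[cl]]$mean
    if (cl != "absent") m <- m * s_b * traits$kappa
    m + c(0, traits$aw_offset)
  }, numeric(2)))
  # draw correlated bivariate percepts class by class
  x <- y <- numeric(n)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    S <- params$group_distributions[[cl]]$cov
    L <- t(chol(S))
    z <- matrix(stats::rnorm(2 * length(idx)), nrow = 2)
    per <- L %*% z
    x[idx] <- mu[idx, 1] + per[1, ]
    y[idx] <- mu[idx, 2] + per[2, ]
  }

  prime_choice <- ifelse(x > params$identity_criterion, "square", "diamond")
  pas <- 1L + rowSums(outer(y, params$pas_criteria, ">"))

  incong <- !is.na(design$congruent) & !design$congruent
  a_centered <- y - traits$aw_offset        # awareness relative to no-prime baseline
  effect <- (params$rt_model$alpha_ms + params$rt_model$beta_ms * a_centered) * incong
  sdlog <- params$rt_model$sdlog
  noise <- exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)  # mean-one lognormal
  rt <- pmax(base + effect, 1) * noise

  probe_correct <- stats::runif(n) >= params$rt_model$probe_error_rate

  data.frame(participant = participant, block = block, trial = design$index,
             prime_identity = design$prime_identity,
             congruent = design$congruent,
             probe_identity = design$probe_identity,
             rt_ms = rt, probe_correct = probe_correct,
             prime_choice = prime_choice, pas = pas,
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Simulates every participant in every block of the design. Each
#' participant's traits and trials are generated from a substream derived
#' from `spec$seed` and the participant counter, so individual participants
#' can be regenerated in isolation and a cohort can be extended without
#' changing earlier participants.
#'
#' @param spec a [design_spec()].
#' @param params a [generative_params()].
#' @return a trial-level data.frame (all participants and blocks).
#' @export
simulate_experiment <- function(spec, params) {
  out <- vector("list", spec$n_participants * length(spec$blocks))
  k <- 0L
  for (i in seq_len(spec$n_participants)) {
    pseed <- participant_seed(spec$seed, i)
    old <- .Random.seed_save()
    set.seed(pseed)
    traits <- draw_traits(params)
    .Random.seed_restore(old)
    for (b in seq_along(spec$blocks)) {
      block <- spec$blocks[b]
      bseed <- as.integer(pseed + 499979L * b)
      design <- build_design(spec, rng = bseed)
      k <- k + 1L
      out[[k]] <- simulate_participant(params, design, block,
                                       rng = bseed + 1L,
                                       participant = i, traits = traits)
    }
  }
  do.call(rbind, out)
}

#' Write / read trial tables as CSV
#'
#' The on-disk schema is one row per trial with header
#' `participant,block,trial,prime_identity,congruent,probe_identity,rt_ms,probe_correct,prime_choice,pas`;
#' the congruency field is empty on catch trials.
#'
#' @param trials a trial-level data.frame.
#' @param path file path.
#' @return `read_trials_csv` returns the trial data.frame.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(congruent = "character"))
  df$congruent <- ifelse(df$congruent == "" | is.na(df$congruent), NA,
                         df$congruent == "TRUE")
  df$probe_correct <- as.logical(df$probe_correct)
  df
}
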