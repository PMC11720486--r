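# shared fixture builders (everything is generated in code)

study_params <- function(alpha_ms = 0, beta_ms = 30, sdlog = 0.2,
                         kappa_sdlog = 0.3, participant_sd = 0.3) {
  generative_params(
    rt_model = list(base_ms_by_block = c(single = 520, multiple = 780,
                                         visibility = 650),
                    alpha_ms = alpha_ms, beta_ms = beta_ms, sdlog = sdlog,
                    probe_error_rate = 0.03),
    kappa_sdlog = kappa_sdlog, participant_sd = participant_sd)
}

# a filled GRT spec with given constraint flags and P participants
make_grt_spec <- function(P = 20, seed = 3,
                          flags = c(equal_variances = TRUE,
                                    perceptual_separability = TRUE,
                                    perceptual_independence = TRUE,
                                    decisional_separability = TRUE),
                          mx = 0.45, my = 0.5,
                          rhos = c(square = 0, diamond = 0, absent = 0),
                          sds = NULL, slope = 0) {
  spec <- grt_model_spec()
  spec$flags <- flags
  spec$means <- list(square = c(mx, my), diamond = c(-mx, my), absent = c(0, 0))
  spec$sds <- if (is.null(sds))
    list(square = c(1, 1), diamond = c(1, 1), absent = c(1, 1)) else sds
  spec$rhos <- rhos
  spec$slope <- slope
  set.seed(seed)
  k <- exp(stats::rnorm(P, 0, 0.3))
  spec$kappa <- k / exp(mean(log(k)))
  spec$identity_bound <- stats::rnorm(P, 0, 0.3)
  spec$aw_bounds <- cbind(stats::rnorm(P, 0.8, 0.2), stats::rnorm(P, 1.7, 0.2),
                          stats::rnorm(P, 2.5, 0.2))
  spec
}

# regression harness: one synthetic cohort -> per-participant input table
regression_cohort_input <- function(seed, alpha_ms, beta_ms,
                                    n_participants = 24) {
  spec <- design_spec(n_participants = n_participants,
                      blocks = c("single", "visibility"), seed = seed)
  params <- study_params(alpha_ms = alpha_ms, beta_ms = beta_ms)
  # effects are computed untrimmed: the generator plants no artifact trials,
  # so trimming would only shave the planted effect
  me_regression_input(simulate_experiment(spec, params),
                      "single", "visibility", trim = FALSE)
}

quick_sampler <- function(seed) {
  list(seed = seed, chains = 2L, adapt = 300L, burnin = 300L, draws = 1200L)
}
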