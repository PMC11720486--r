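#' Bayesian measurement-error regression of priming on awareness
#'
#' Estimates the priming effect expected at exactly chance-level awareness
#' while modelling measurement error in both variables, correcting the
#' attenuation bias of the ordinary (Greenwald) regression. Generative model,
#' per participant i:
#' \preformatted{
#'   correct_count_i ~ Binomial(trial_count_i, theta_i)
#'   theta_i         ~ Beta(mu_theta * kappa_theta, (1 - mu_theta) * kappa_theta)
#'   a_i              = theta_i - 0.5                  (centered awareness)
#'   effect_ms_i     ~ Normal(alpha + beta * a_i, sqrt(effect_se_ms_i^2 + tau^2))
#' }
#' with weakly-informative priors on the RT-millisecond scale:
#' `alpha ~ Normal(0, alpha_sd)`, `beta ~ Normal(0, beta_sd)`,
#' `tau ~ half-Normal(0, tau_sd)`, `mu_theta ~ Beta(5, 5)`,
#' `kappa_theta ~ Gamma(2, 0.05)`. The intercept alpha is the predicted
#' effect for a completely unaware participant (theta = 0.5). The Bayes
#' factor for alpha != 0 is the Savage-Dickey density ratio at alpha = 0:
#' prior density (analytic) over posterior density (Gaussian kernel with
#' Sheather-Jones bandwidth; a normal-approximation estimate is reported
#' alongside as a cross-check).
#'
#' @param data data.frame with columns `correct_count`, `trial_count`,
#'   `effect_ms`, `effect_se_ms` (one row per participant).
#' @param priors list overriding `alpha_sd` (ms, default 50), `beta_sd`
#'   (ms per awareness unit, default 300), `tau_sd` (ms, default 30).
#' @param sampler list overriding `chains` (default 4), `adapt` (500),
#'   `burnin` (500), `draws` (post-warmup per chain, default 2000), `seed`
#'   (required), `rhat_limit` (default 1.01), `max_extend` (times the chains
#'   are extended with doubled draws when the limit is exceeded, default 2).
#' @return a `regression_posterior` list: `intercept_mean_ms`,
#'   `intercept_ci95`, `slope_mean`, `slope_ci95`, `tau_mean`,
#'   `bf10_intercept`, `bf10_intercept_normal`, `rhat_max`, `ess_min`,
#'   `n_chains`, `n_draws`, `seed`, and the pooled `draws` matrix
#'   (columns `alpha`, `beta`, `sigma_tau`).
#' @export
fit_me_regression <- function(data, priors = list(), sampler = list()) {
  stopifnot(all(c("correct_count", "trial_count", "effect_ms", "effect_se_ms")
                %in% names(data)))
  if (nrow(data) < 5L) stop("need at least 5 participants")
  if (any(data$trial_count <= 0) || any(data$correct_count < 0) ||
      any(data$correct_count > data$trial_count))
    stop("invalid awareness counts")
  if (any(data$effect_se_ms <= 0)) stop("effect_se_ms must be positive")
  pr <- utils::modifyList(list(alpha_sd = 50, beta_sd = 300, tau_sd = 30), priors)
  sm <- utils::modifyList(list(chains = 4L, adapt = 500L, burnin = 500L,
                               draws = 2000L, seed = NULL, rhat_limit = 1.01,
                               max_extend = 2L), sampler)
  if (is.null(sm$seed)) stop("sampler$seed is required for reproducibility")

  theta_hat <- data$correct_count / data$trial_count
  if (stats::sd(theta_hat) == 0)
    warning("all observed awareness proportions identical: slope weakly identified")

  # sampled in terms of the intercept at the sample-mean awareness
  # (alpha_star = alpha + beta * c0, c0 = mean observed centered awareness),
  # which decorrelates the Gibbs updates; alpha keeps its declared
  # Normal(0, alpha_sd) prior exactly and is monitored as a derived node
  model_str <- "
  model {
    for (i in 1:P) {
      k[i] ~ dbin(theta[i], n[i])
      theta[i] ~ dbeta(a_th, b_th)
      e[i] ~ dnorm(alpha_star + beta * (theta[i] - 0.5 - c0),
                   1 / (se2[i] + sigma_tau^2))
    }
    a_th <- mu_th * kappa_th
    b_th <- (1 - mu_th) * kappa_th
    mu_th ~ dbeta(5, 5)
    kappa_th ~ dgamma(2, 0.05)
    beta ~ dnorm(0, prec_beta)
    alpha_star ~ dnorm(beta * c0, prec_alpha)
    alpha <- alpha_star - beta * c0
    sigma_tau ~ dnorm(0, prec_tau) T(0,)
  }"
  c0 <- mean(theta_hat) - 0.5
  jdata <- list(P = nrow(data), k = data$correct_count, n = data$trial_count,
                e = data$effect_ms, se2 = data$effect_se_ms^2, c0 = c0,
                prec_alpha = 1 / pr$alpha_sd^2, prec_beta = 1 / pr$beta_sd^2,
                prec_tau = 1 / pr$tau_sd^2)
  inits <- lapply(seq_len(sm$chains), function(ch) {
    list(theta = pmin(pmax(theta_hat, 0.02), 0.98),
         alpha_star = 0, beta = 0, sigma_tau = pr$tau_sd / 10,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(sm$seed + ch))
  })
  jm <- rjags::jags.model(textConnection(model_str), data = jdata,
                          inits = inits, n.chains = sm$chains,
                          n.adapt = sm$adapt, quiet = TRUE)
  stats::update(jm, n.iter = sm$burnin, progress.bar = "none")
  # sample; when the Gelman-Rubin diagnostic exceeds the limit, extend the
  # chains with a doubled draw count (up to max_extend times) before failing
  n_iter <- sm$draws
  for (attempt in 0:sm$max_extend) {
    samp <- rjags::coda.samples(jm, c("alpha", "beta", "sigma_tau"),
                                n.iter = n_iter, progress.bar = "none")
    rhat <- tryCatch(
      max(coda::gelman.diag(samp, autoburnin = FALSE,
                            multivariate = FALSE)$psrf[, 1]),
      error = function(e) NA_real_)
    if (!is.finite(rhat) || rhat < sm$rhat_limit) break
    n_iter <- 2L * n_iter
  }
  ess <- min(coda::effectiveSize(samp))
  if (is.finite(rhat) && rhat >= sm$rhat_limit)
    stop(sprintf("MCMC did not converge: max Rhat = %.4f (limit %.3f)",
                 rhat, sm$rhat_limit))

  dm <- as.matrix(samp)
  alpha_d <- dm[, "alpha"]
  beta_d <- dm[, "beta"]

  prior0 <- stats::dnorm(0, 0, pr$alpha_sd)
  post0 <- savage_dickey_density0(alpha_d)
  post0_norm <- stats::dnorm(0, mean(alpha_d), stats::sd(alpha_d))

  structure(list(
    intercept_mean_ms = mean(alpha_d),
    intercept_ci95 = unname(stats::quantile(alpha_d, c(0.025, 0.975))),
    slope_mean = mean(beta_d),
    slope_ci95 = unname(stats::quantile(beta_d, c(0.025, 0.975))),
    tau_mean = mean(dm[, "sigma_tau"]),
    bf10_intercept = prior0 / post0,
    bf10_intercept_normal = prior0 / post0_norm,
    rhat_max = rhat, ess_min = unname(ess),
    n_chains = sm$chains, n_draws = n_iter, seed = sm$seed,
    priors = pr, draws = dm), class = "regression_posterior")
}

# posterior density at 0 by Gaussian kernel, Sheather-Jones bandwidth
savage_dickey_density0 <- function(draws) {
  bw <- tryCatch(stats::bw.SJ(draws), error = function(e) stats::bw.nrd0(draws))
  d <- stats::density(draws, bw = bw, n = 1024,
                      from = min(draws, 0) - 3 * bw, to = max(draws, 0) + 3 * bw)
  max(stats::approx(d$x, d$y, xout = 0)$y, .Machine$double.xmin)
}

#' @export
print.regression_posterior <- function(x, ...) {
  cat(sprintf("Measurement-error regression (%d chains x %d draws)\n",
              x$n_chains, x$n_draws))
  cat(sprintf("  intercept: %.2f ms [%.2f, %.2f], BF10 = %.3g\n",
              x$intercept_mean_ms, x$intercept_ci95[1], x$intercept_ci95[2],
              x$bf10_intercept))
  cat(sprintf("  slope: %.1f ms/unit [%.1f, %.1f]\n",
              x$slope_mean, x$slope_ci95[1], x$slope_ci95[2]))
  cat(sprintf("  max Rhat %.3f, min ESS %.0f\n", x$rhat_max, x$ess_min))
  invisible(x)
}

#' Ordinary (uncorrected) Greenwald regression
#'
#' Ordinary least squares of the priming effect on the centered observed
#' awareness proportion (`correct_count / trial_count - 0.5`), ignoring
#' measurement error. Provided as the comparison baseline that exhibits
#' regression attenuation: noise in the predictor flattens the slope and,
#' when mean awareness is above chance, biases the intercept upward.
#'
#' @param data as in [fit_me_regression()] (>= 2 non-collinear points).
#' @return list with `intercept`, `slope`.
#' @export
naive_greenwald_regression <- function(data) {
  if (nrow(data) < 2L) stop("need at least 2 participants")
  a <- data$correct_count / data$trial_count - 0.5
  if (stats::sd(a) == 0) stop("degenerate input: constant awareness predictor")
  fit <- stats::lm(data$effect_ms ~ a)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]))
}

#' Assemble regression input from a simulated or observed cohort
#'
#' Builds the per-participant [fit_me_regression()] input: the congruency
#' effect (with its SE) from RT-trimmed trials of `effect_block`, and the
#' awareness counts from prime-present forced-choice responses in
#' `awareness_block`.
#'
#' @param cohort trial-level data.frame.
#' @param effect_block block providing RTs (default `"single"`).
#' @param awareness_block block providing the 2AFC awareness counts
#'   (default `"visibility"`).
#' @param trim apply [trim_rts()] before computing effects (default TRUE).
#' @return data.frame with one row per participant.
#' @export
me_regression_input <- function(cohort, effect_block = "single",
                                awareness_block = "visibility", trim = TRUE) {
  ids <- sort(unique(cohort$participant))
  rows <- lapply(ids, function(id) {
    rt_tr <- cohort[cohort$participant == id & cohort$block == effect_block, ,
                    drop = FALSE]
    if (trim) rt_tr <- trim_rts(rt_tr, for_rt_analysis = TRUE)$trials
    eff <- congruency_effect(rt_tr)
    aw <- cohort[cohort$participant == id & cohort$block == awareness_block &
                   cohort$prime_identity != "none", , drop = FALSE]
    data.frame(participant = id,
               correct_count = sum(aw$prime_choice == aw$prime_identity),
               trial_count = nrow(aw),
               effect_ms = eff$effect_ms,
               effect_se_ms = eff$effect_se_ms)
  })
  do.call(rbind, rows)
}
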