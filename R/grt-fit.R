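# Maximum-likelihood fitting of the GRT-wIND model family.
#
# The likelihood separates over participants given the global (distribution)
# parameters, so finite-difference gradients are computed block-wise: one
# full evaluation per global parameter, plus one evaluation per
# participant-parameter type in which all participants are perturbed
# simultaneously and each participant's own likelihood term supplies their
# partial derivative. This keeps a gradient at ~20 likelihood evaluations
# regardless of the number of participants.

grt_nll_by_participant <- function(spec, counts) {
  pr <- grt_predict_all(spec)
  -apply(counts * log(pmax(pr, 1e-12)), 1, sum)
}

# soft pin for the scale trade-off between present-class means and the
# per-participant attention factors (likelihood is flat along mean log kappa)
.kappa_pen_w <- 50

grt_objective <- function(par, template, counts, P, n_glob) {
  spec <- grt_unpack(template, par, P)
  lk <- par[n_glob + seq_len(P)]
  sum(grt_nll_by_participant(spec, counts)) + .kappa_pen_w * mean(lk)^2
}

grt_gradient <- function(par, template, counts, P, n_glob) {
  eps <- 1e-6 * pmax(1, abs(par))
  spec0 <- grt_unpack(template, par, P)
  f0_p <- grt_nll_by_participant(spec0, counts)
  lk <- par[n_glob + seq_len(P)]
  pen0 <- .kappa_pen_w * mean(lk)^2
  f0 <- sum(f0_p) + pen0
  gr <- numeric(length(par))
  for (j in seq_len(n_glob)) {
    p2 <- par; p2[j] <- p2[j] + eps[j]
    gr[j] <- (grt_objective(p2, template, counts, P, n_glob) - f0) / eps[j]
  }
  for (t in 0:4) {
    idx <- n_glob + t * P + seq_len(P)
    p2 <- par; p2[idx] <- p2[idx] + eps[idx]
    f1_p <- grt_nll_by_participant(grt_unpack(template, p2, P), counts)
    gr[idx] <- (f1_p - f0_p) / eps[idx]
  }
  # analytic penalty gradient for the kappa block
  gr[n_glob + seq_len(P)] <- gr[n_glob + seq_len(P)] +
    2 * .kappa_pen_w * mean(lk) / P
  gr
}

# moment-based starting values from the observed proportions
grt_init_par <- function(template, counts) {
  P <- dim(counts)[1]
  clamp <- function(p) pmin(pmax(p, 0.02), 0.98)
  tot <- apply(counts, c(1, 2), sum)
  sq_resp <- apply(counts[, , 1:4, drop = FALSE], c(1, 2), sum)
  # pooled identity separation
  H <- clamp(sum(sq_resp[, "square"]) / max(sum(tot[, "square"]), 1))
  F <- clamp(sum(sq_resp[, "diamond"]) / max(sum(tot[, "diamond"]), 1))
  sep <- (stats::qnorm(H) - stats::qnorm(F)) / 2
  # pooled awareness separation (PAS >= 2 given present vs absent)
  aware <- apply(counts[, , c(2:4, 6:8), drop = FALSE], c(1, 2), sum)
  ap <- clamp(sum(aware[, c("square", "diamond")]) /
                max(sum(tot[, c("square", "diamond")]), 1))
  aa <- clamp(sum(aware[, "absent"]) / max(sum(tot[, "absent"]), 1))
  my <- max(stats::qnorm(ap) - stats::qnorm(aa), 0.1)

  spec <- template
  spec$means <- list(square = c(max(sep, 0.1), my),
                     diamond = c(min(-sep, -0.1), my), absent = c(0, 0))
  spec$sds <- list(square = c(1, 1), diamond = c(1, 1), absent = c(1, 1))
  spec$rhos <- c(square = 0, diamond = 0, absent = 0)
  spec$slope <- 0
  spec$kappa <- rep(1, P)
  # per-participant criteria from their own marginal response proportions
  p_di <- clamp((tot %*% rep(1, 3) - sq_resp %*% rep(1, 3)) / pmax(tot %*% rep(1, 3), 1))
  spec$identity_bound <- as.vector(stats::qnorm(p_di))
  pas_tot <- sapply(1:4, function(k) {
    apply(counts[, , c(k, 4 + k), drop = FALSE], 1, sum)
  })
  if (is.null(dim(pas_tot))) pas_tot <- matrix(pas_tot, nrow = P)
  cum <- t(apply(pas_tot, 1, cumsum)) / pmax(rowSums(pas_tot), 1)
  cum <- clamp(cum[, 1:3, drop = FALSE])
  cum <- t(apply(cum, 1, function(x) pmin(cummax(x + c(0, 0.02, 0.04)), 0.98)))
  b <- stats::qnorm(cum) + 0.4 * my
  b2 <- pmax(b[, 2], b[, 1] + 0.05)
  b3 <- pmax(b[, 3], b2 + 0.05)
  spec$aw_bounds <- cbind(b[, 1], b2, b3)
  grt_pack(spec, P)
}

grt_par_bounds <- function(template, P) {
  lay <- grt_par_template(template$flags, P)
  g <- lay$global
  lo <- hi <- numeric(length(g))
  for (j in seq_along(g)) {
    nm <- g[j]
    if (startsWith(nm, "m_")) { lo[j] <- -8; hi[j] <- 8 }
    else if (startsWith(nm, "ls_")) { lo[j] <- -2.5; hi[j] <- 2.5 }
    else if (startsWith(nm, "z_rho")) { lo[j] <- -3; hi[j] <- 3 }
    else { lo[j] <- -5; hi[j] <- 5 }   # slope
  }
  list(lower = c(lo, rep(c(-3, -8, -10, -7, -7), each = P)),
       upper = c(hi, rep(c(3, 8, 10, 3, 3), each = P)))
}

#' Fit a GRT-wIND model by maximum likelihood
#'
#' Multi-start bounded quasi-Newton (L-BFGS-B) optimization of the
#' multinomial negative log-likelihood under a template's constraint flags.
#' Parameters are transformed to an unconstrained scale (log SDs and
#' attention factors, Fisher-z correlations, ordered awareness criteria via
#' log gaps). Catch trials (absent-stimulus counts) are required: they
#' anchor the awareness dimension. After fitting, the attention factors are
#' renormalized to geometric mean 1 (absorbing the scale into the
#' present-class means), which leaves the likelihood unchanged.
#'
#' @param counts array `[participant, stimulus, response]`, stimulus levels
#'   square/diamond/absent, 8 response cells.
#' @param template a [grt_model_spec()] giving the constraint flags.
#' @param restarts number of optimization starts (first from moment-based
#'   or supplied inits, the rest jittered).
#' @param rng integer seed for restart jitter.
#' @param init optional packed parameter vector (e.g. a previous fit's
#'   `$par`) used as the first start.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return a `grt_fit` list: `spec` (fitted), `flags`, `loglik`, `n_params`,
#'   `aic`, `pct_accounted`, `mad`, `convergence`, `n_restarts`, `par`,
#'   `dataset_id`.
#' @export
fit_grt_wind <- function(counts, template, restarts = 10L, rng = 1L,
                         init = NULL, maxit = 400L) {
  P <- dim(counts)[1]
  if (sum(counts[, "absent", ]) == 0)
    stop("no catch trials: the awareness dimension cannot be anchored")
  n_glob <- length(grt_par_template(template$flags, P)$global)
  bounds <- grt_par_bounds(template, P)
  base_init <- grt_init_par(template, counts)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng)
  best <- NULL
  n_ok <- 0L
  for (s in seq_len(restarts)) {
    par0 <- if (s == 1L && !is.null(init)) init
            else if (s == 1L) base_init
            else base_init + stats::rnorm(length(base_init), 0, 0.25)
    par0 <- pmin(pmax(par0, bounds$lower + 1e-6), bounds$upper - 1e-6)
    res <- tryCatch(
      stats::optim(par0, grt_objective, gr = grt_gradient,
                   template = template, counts = counts, P = P, n_glob = n_glob,
                   method = "L-BFGS-B", lower = bounds$lower, upper = bounds$upper,
                   control = list(maxit = maxit, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimization restarts failed")

  spec <- grt_unpack(template, best$par, P)
  # renormalize the attention scale (likelihood-invariant)
  mlk <- mean(log(spec$kappa))
  spec$kappa <- spec$kappa / exp(mlk)
  spec$means$square <- spec$means$square * exp(mlk)
  spec$means$diamond <- spec$means$diamond * exp(mlk)

  loglik <- -negloglik(spec, counts)
  n_par <- grt_n_params(template$flags, P)
  pr <- grt_predict_all(spec)
  tot <- apply(counts, c(1, 2), sum)
  obs <- sweep(counts, c(1, 2), pmax(tot, 1), "/")
  use <- array(rep(tot > 0, 8), dim(counts))
  mad <- mean(abs(obs - pr)[use])
  structure(list(spec = spec, flags = template$flags, loglik = loglik,
                 n_params = n_par, aic = 2 * n_par - 2 * loglik,
                 pct_accounted = 100 * (1 - mad / mean(obs[use])),
                 mad = mad,
                 convergence = best$convergence, n_restarts = n_ok,
                 par = grt_pack(spec, P),
                 dataset_id = c(sum(counts), sum(counts * seq_along(counts)))),
            class = "grt_fit")
}

#' @export
print.grt_fit <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat("GRT-wIND fit | constraints:",
      if (length(on)) paste(on, collapse = ", ") else "none (full model)", "\n")
  cat(sprintf("  logLik %.2f | %d params | AIC %.2f | %.2f%% of response proportions accounted\n",
              x$loglik, x$n_params, x$aic, x$pct_accounted))
  invisible(x)
}

#' Fit all 16 GRT model variants
#'
#' Fits the full model first with `restarts` multi-starts, then each
#' constrained variant warm-started from the full-model solution projected
#' into its parameter space (plus one jittered start).
#'
#' @inheritParams fit_grt_wind
#' @param warm_restarts starts per constrained variant (first one projected
#'   from the full fit).
#' @return list of 16 `grt_fit` objects.
#' @export
fit_all_grt_models <- function(counts, restarts = 4L, rng = 1L, maxit = 400L,
                               warm_restarts = 1L) {
  templates <- enumerate_models()
  full_idx <- which(vapply(templates, function(m) !any(m$flags), logical(1)))
  fits <- vector("list", length(templates))
  fits[[full_idx]] <- fit_grt_wind(counts, templates[[full_idx]],
                                   restarts = restarts, rng = rng, maxit = maxit)
  full_spec <- fits[[full_idx]]$spec
  for (i in seq_along(templates)) {
    if (i == full_idx) next
    tmpl <- templates[[i]]
    proj <- grt_project_spec(full_spec, tmpl$flags)
    fits[[i]] <- fit_grt_wind(counts, tmpl, restarts = warm_restarts,
                              rng = rng + i,
                              init = grt_pack(proj, length(full_spec$kappa)),
                              maxit = maxit)
  }
  fits
}

# project a spec into a constrained template's space (for warm starts)
grt_project_spec <- function(spec, flags) {
  out <- spec
  out$flags <- flags
  if (flags["perceptual_separability"]) {
    my <- mean(c(spec$means$square[2], spec$means$diamond[2]))
    out$means$square[2] <- my; out$means$diamond[2] <- my
    sy <- exp(mean(log(c(spec$sds$square[2], spec$sds$diamond[2]))))
    out$sds$square[2] <- sy; out$sds$diamond[2] <- sy
  }
  if (flags["equal_variances"])
    out$sds <- list(square = c(1, 1), diamond = c(1, 1), absent = c(1, 1))
  if (flags["perceptual_independence"])
    out$rhos <- c(square = 0, diamond = 0, absent = 0)
  if (flags["decisional_separability"]) out$slope <- 0
  out
}

#' Select the best model by AIC
#'
#' Minimum AIC wins; ties go to the model with fewer parameters, then to
#' the earlier fit in the list. All fits must be of the same dataset.
#'
#' @param fits list of `grt_fit` objects (or a single fit, returned as is).
#' @return the selected `grt_fit`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "grt_fit")) return(fits)
  if (length(fits) == 1L) return(fits[[1]])
  ids <- vapply(fits, function(f) paste(f$dataset_id, collapse = "/"), character(1))
  if (length(unique(ids)) != 1L) stop("fits are not all of the same dataset")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  npar <- vapply(fits, `[[`, numeric(1), "n_params")
  ord <- order(aic, npar, seq_along(fits))
  fits[[ord[1]]]
}
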