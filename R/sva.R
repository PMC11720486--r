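#' Relative likelihood of no awareness (RLNA)
#'
#' Density ratio, at a point `a` on the awareness axis, of the prime-absent
#' marginal awareness distribution to the prime-present one; the present
#' likelihood is the equal-weight mixture of the square and diamond
#' awareness marginals (the design presents both equally often). Values
#' above 1 mark awareness levels more likely under "no stimulus" than under
#' "stimulus".
#'
#' @param spec a fitted `grt_model_spec` (group-level distributions,
#'   attention factor 1).
#' @param a awareness-axis value(s).
#' @return RLNA value(s).
#' @export
rlna <- function(spec, a) {
  f_abs <- stats::dnorm(a, spec$means$absent[2], spec$sds$absent[2])
  f_pres <- 0.5 * stats::dnorm(a, spec$means$square[2], spec$sds$square[2]) +
            0.5 * stats::dnorm(a, spec$means$diamond[2], spec$sds$diamond[2])
  if (any(f_pres < 1e-300)) {
    warning("present-class awareness density underflow; RLNA clipped")
    f_pres <- pmax(f_pres, 1e-300)
  }
  f_abs / f_pres
}

#' Conditional sensitivity d' at a fixed awareness level
#'
#' d' of the square-vs-diamond identity distributions conditional on the
#' awareness dimension taking value `a`, using the Gaussian
#' conditional-moment formulas: `E[x | y = a] = mx + rho (sx / sy)(a - my)`,
#' `Var[x | y = a] = sx^2 (1 - rho^2)`; the denominator pools the two
#' conditional SDs as the root mean square.
#'
#' @param spec a fitted `grt_model_spec`.
#' @param a awareness-axis value(s).
#' @return non-negative d' value(s).
#' @export
conditional_dprime <- function(spec, a) {
  cm <- function(cl) {
    m <- spec$means[[cl]]; s <- spec$sds[[cl]]; r <- spec$rhos[[cl]]
    list(mean = m[1] + r * s[1] / s[2] * (a - m[2]),
         var = s[1]^2 * (1 - r^2))
  }
  sq <- cm("square"); di <- cm("diamond")
  abs(sq$mean - di$mean) / sqrt((sq$var + di$var) / 2)
}

#' Sensitivity-versus-awareness curve
#'
#' Evaluates RLNA and conditional d' on an awareness-axis grid spanning
#' [absent mean - 3 SD, max present mean + 3 SD], locates the ideal
#' observer's awareness criterion (the point where RLNA = 1, i.e. where an
#' unbiased observer would switch between reporting presence and absence)
#' by bisection, and attaches each participant's lowest awareness criterion
#' (the PAS 1/2 boundary).
#'
#' @param fit a `grt_fit` (or a bare `grt_model_spec`).
#' @param grid_n number of grid points (default 200).
#' @return an `sva_curve` list: `awareness_grid`, `rlna`, `d_cond`,
#'   `ci_lower`, `ci_upper` (NULL until [bootstrap_sva()]),
#'   `ideal_criterion`, `participant_bounds`.
#' @export
sva_curve <- function(fit, grid_n = 200L) {
  spec <- if (inherits(fit, "grt_fit")) fit$spec else fit
  lo <- spec$means$absent[2] - 3 * spec$sds$absent[2]
  hi <- max(spec$means$square[2], spec$means$diamond[2]) +
    3 * max(spec$sds$square[2], spec$sds$diamond[2], spec$sds$absent[2])
  grid <- seq(lo, hi, length.out = grid_n)
  r <- rlna(spec, grid)
  d <- conditional_dprime(spec, grid)

  m_abs <- spec$means$absent[2]
  m_pres <- max(spec$means$square[2], spec$means$diamond[2])
  crit <- NA_real_
  lr <- function(a) log(rlna(spec, a))
  if (m_pres > m_abs && is.finite(lr(m_abs)) && is.finite(lr(m_pres)) &&
      lr(m_abs) * lr(m_pres) < 0) {
    crit <- stats::uniroot(lr, c(m_abs, m_pres), tol = 1e-9)$root
  } else {
    warning("no RLNA = 1 crossing between the absent and present means; ",
            "ideal criterion not defined")
  }
  structure(list(awareness_grid = grid, rlna = r, d_cond = d,
                 ci_lower = NULL, ci_upper = NULL,
                 ideal_criterion = crit,
                 participant_bounds = if (is.matrix(spec$aw_bounds))
                   spec$aw_bounds[, 1] else spec$aw_bounds[1]),
            class = "sva_curve")
}

#' Parametric bootstrap confidence bands for an SvA curve
#'
#' Simulates datasets from the fitted model at the observed trial counts,
#' refits the same (selected) template warm-started from the point
#' estimate, recomputes the conditional-d' curve on the common grid, and
#' takes pointwise 2.5/97.5 percentiles.
#'
#' @param fit a `grt_fit`.
#' @param counts the observed counts array the model was fitted to (sets
#'   the bootstrap trial numbers).
#' @param n_boot number of bootstrap samples (1000 for production use;
#'   smaller values give coarser bands).
#' @param rng integer seed.
#' @param grid_n grid resolution, as in [sva_curve()].
#' @param max_fail_rate error out if more than this fraction of refits fail.
#' @return an `sva_curve` with `ci_lower`/`ci_upper` filled in, plus
#'   `n_boot_ok`.
#' @export
bootstrap_sva <- function(fit, counts, n_boot = 1000L, rng = 1L,
                          grid_n = 200L, max_fail_rate = 0.2) {
  stopifnot(inherits(fit, "grt_fit"))
  if (n_boot < 2L) stop("n_boot must be at least 2")
  base <- sva_curve(fit, grid_n = grid_n)
  tot <- apply(counts, c(1, 2), sum)
  tmpl <- grt_model_spec()
  tmpl$flags <- fit$flags
  curves <- matrix(NA_real_, n_boot, grid_n)
  ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    cb <- simulate_grt_counts(fit$spec, trials_per_stimulus = tot,
                              rng = rng + b)
    rf <- tryCatch(
      fit_grt_wind(cb, tmpl, restarts = 1L, rng = rng + b, init = fit$par,
                   maxit = 200L),
      error = function(e) NULL)
    if (is.null(rf)) next
    ok[b] <- TRUE
    curves[b, ] <- conditional_dprime(rf$spec, base$awareness_grid)
  }
  if (mean(!ok) > max_fail_rate)
    stop(sprintf("bootstrap refit failure rate %.0f%% exceeds %.0f%%",
                 100 * mean(!ok), 100 * max_fail_rate))
  qs <- apply(curves[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  base$ci_lower <- qs[1, ]
  base$ci_upper <- qs[2, ]
  base$n_boot_ok <- sum(ok)
  base
}

#' Plot an SvA curve
#'
#' Conditional d' against RLNA on a log x-axis, with bootstrap bands when
#' present, the ideal-observer criterion (RLNA = 1) as a vertical dashed
#' line, and per-participant awareness criteria as dashed marks.
#'
#' @param x an `sva_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sva_curve <- function(x, ...) {
  ord <- order(x$rlna)
  graphics::plot(x$rlna[ord], x$d_cond[ord], type = "n", log = "x",
                 xlab = "RLNA", ylab = "conditional d'", ...)
  if (!is.null(x$ci_lower)) {
    graphics::polygon(c(x$rlna[ord], rev(x$rlna[ord])),
                      c(x$ci_lower[ord], rev(x$ci_upper[ord])),
                      col = grDevices::adjustcolor("red", 0.2), border = NA)
  }
  graphics::lines(x$rlna[ord], x$d_cond[ord], col = "red", lwd = 2)
  graphics::abline(v = 1, col = "blue", lty = 3)
  graphics::abline(h = 0, col = "black", lty = 3)
  invisible(x)
}

#' Aggregate trial records into GRT response counts
#'
#' Reshapes a trial-level table from one block into the
#' `[participant, stimulus, response]` counts array consumed by
#' [fit_grt_wind()], crossing the prime forced-choice response with the PAS
#' rating.
#'
#' @param cohort trial-level data.frame.
#' @param block block to aggregate (default `"visibility"`).
#' @return counts array `[P, 3, 8]`.
#' @export
grt_counts_from_trials <- function(cohort, block = "visibility") {
  sub <- cohort[cohort$block == block, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no trials for block '", block, "'")
  ids <- sort(unique(sub$participant))
  out <- array(0L, c(length(ids), 3, 8),
               dimnames = list(NULL, grt_class_names, grt_cell_names))
  stim <- ifelse(sub$prime_identity == "none", "absent", sub$prime_identity)
  cell <- paste0(sub$prime_choice, "_pas", sub$pas)
  for (i in seq_along(ids)) {
    sel <- sub$participant == ids[i]
    tab <- table(factor(stim[sel], levels = grt_class_names),
                 factor(cell[sel], levels = grt_cell_names))
    out[i, , ] <- as.integer(tab)
  }
  out
}
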