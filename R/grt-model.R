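#' Two-dimensional GRT model templates with individual differences
#'
#' The model represents each stimulus class (square prime, diamond prime,
#' prime absent) as a bivariate Gaussian over an identity-evidence axis and
#' an awareness-evidence axis. The absent class is anchored at mean (0, 0)
#' with unit variances for identifiability. Individual differences follow
#' the GRT-wIND scheme: participant i scales present-class mean vectors by
#' an attention factor kappa_i (geometric mean fixed at 1) and owns an
#' identity criterion plus three ordered awareness criteria. The identity
#' decision bound is always perpendicular to the identity axis; awareness
#' bounds are perpendicular to the awareness axis under decisional
#' separability and share a common linear slope otherwise.
#'
#' Constraint flags (each `TRUE` removes parameters from the full model):
#' * `equal_variances` - all class variances fixed at 1 on both axes;
#' * `perceptual_separability` - square and diamond share the same
#'   awareness-axis marginal (mean and SD);
#' * `perceptual_independence` - zero identity-awareness correlation within
#'   every class;
#' * `decisional_separability` - awareness bounds orthogonal to the
#'   awareness axis (slope 0).
#'
#' @param equal_variances,perceptual_separability,perceptual_independence,decisional_separability
#'   constraint flags.
#' @return an object of class `grt_model_spec` (a template; parameter slots
#'   are filled by [fit_grt_wind()]).
#' @export
grt_model_spec <- function(equal_variances = FALSE,
                           perceptual_separability = FALSE,
                           perceptual_independence = FALSE,
                           decisional_separability = FALSE) {
  structure(list(flags = c(equal_variances = equal_variances,
                           perceptual_separability = perceptual_separability,
                           perceptual_independence = perceptual_independence,
                           decisional_separability = decisional_separability),
                 means = list(square = c(1, 0.8), diamond = c(-1, 0.8),
                              absent = c(0, 0)),
                 sds = list(square = c(1, 1), diamond = c(1, 1),
                            absent = c(1, 1)),
                 rhos = c(square = 0, diamond = 0, absent = 0),
                 slope = 0,
                 kappa = 1, identity_bound = 0,
                 aw_bounds = matrix(c(0.5, 1.5, 2.5), nrow = 1)),
            class = "grt_model_spec")
}

#' Enumerate the 16 GRT model variants
#'
#' All 2^4 combinations of the four constraint flags; the full model has all
#' flags `FALSE`, the most constrained all `TRUE`.
#'
#' @return list of 16 `grt_model_spec` templates.
#' @export
enumerate_models <- function() {
  grid <- expand.grid(equal_variances = c(FALSE, TRUE),
                      perceptual_separability = c(FALSE, TRUE),
                      perceptual_independence = c(FALSE, TRUE),
                      decisional_separability = c(FALSE, TRUE))
  lapply(seq_len(nrow(grid)), function(i) {
    do.call(grt_model_spec, as.list(grid[i, ]))
  })
}

# number of free parameters for a template with P participants
grt_n_params <- function(flags, P) {
  n_global <- 2 +                                     # identity means
    (if (flags["perceptual_separability"]) 1 else 2) +  # awareness means
    (if (flags["equal_variances"]) 0 else
       if (flags["perceptual_separability"]) 3 else 4) + # log SDs
    (if (flags["perceptual_independence"]) 0 else 3) +   # correlations
    (if (flags["decisional_separability"]) 0 else 1)     # bound slope
  unname(n_global + (P - 1) + P + 3 * P)
}

# ---- parameter vector layout -------------------------------------------
# global block (order): mean_sq_x, mean_di_x, mean_sq_y [, mean_di_y],
#   [log sds], [atanh rhos], [slope]; then per-participant blocks:
#   log kappa (P), identity bound (P), b1 (P), log gap2 (P), log gap3 (P).

grt_par_template <- function(flags, P) {
  g <- c("m_sq_x", "m_di_x", "m_sq_y")
  if (!flags["perceptual_separability"]) g <- c(g, "m_di_y")
  if (!flags["equal_variances"]) {
    g <- c(g, "ls_sq_x", "ls_di_x", "ls_sq_y")
    if (!flags["perceptual_separability"]) g <- c(g, "ls_di_y")
  }
  if (!flags["perceptual_independence"]) g <- c(g, "z_rho_sq", "z_rho_di", "z_rho_ab")
  if (!flags["decisional_separability"]) g <- c(g, "slope")
  list(global = g,
       n_total = length(g) + 5L * P,
       P = P)
}

grt_unpack <- function(template, par, P) {
  flags <- template$flags
  lay <- grt_par_template(flags, P)
  g <- par[seq_along(lay$global)]
  names(g) <- lay$global
  pp <- matrix(par[-seq_along(lay$global)], nrow = P,
               dimnames = list(NULL, c("lk", "c", "b1", "lg2", "lg3")))

  m_sq_y <- g[["m_sq_y"]]
  m_di_y <- if (flags["perceptual_separability"]) m_sq_y else g[["m_di_y"]]
  if (flags["equal_variances"]) {
    sds <- list(square = c(1, 1), diamond = c(1, 1))
  } else {
    s_sq_y <- exp(g[["ls_sq_y"]])
    s_di_y <- if (flags["perceptual_separability"]) s_sq_y else exp(g[["ls_di_y"]])
    sds <- list(square = c(exp(g[["ls_sq_x"]]), s_sq_y),
                diamond = c(exp(g[["ls_di_x"]]), s_di_y))
  }
  rhos <- if (flags["perceptual_independence"]) c(square = 0, diamond = 0, absent = 0)
          else c(square = tanh(g[["z_rho_sq"]]), diamond = tanh(g[["z_rho_di"]]),
                 absent = tanh(g[["z_rho_ab"]]))
  slope <- if (flags["decisional_separability"]) 0 else g[["slope"]]

  lk <- pp[, "lk"]   # raw; the fit pins mean(lk) and renormalizes afterwards
  b1 <- pp[, "b1"]
  b2 <- b1 + exp(pp[, "lg2"])
  b3 <- b2 + exp(pp[, "lg3"])

  spec <- grt_model_spec()
  spec$flags <- flags
  spec$means <- list(square = c(g[["m_sq_x"]], m_sq_y),
                     diamond = c(g[["m_di_x"]], m_di_y),
                     absent = c(0, 0))
  spec$sds <- c(sds, list(absent = c(1, 1)))
  spec$rhos <- rhos
  spec$slope <- unname(slope)
  spec$kappa <- exp(lk)
  spec$identity_bound <- unname(pp[, "c"])
  spec$aw_bounds <- unname(cbind(b1, b2, b3))
  spec
}

grt_pack <- function(spec, P) {
  flags <- spec$flags
  g <- c(spec$means$square[1], spec$means$diamond[1], spec$means$square[2])
  if (!flags["perceptual_separability"]) g <- c(g, spec$means$diamond[2])
  if (!flags["equal_variances"]) {
    g <- c(g, log(spec$sds$square[1]), log(spec$sds$diamond[1]),
           log(spec$sds$square[2]))
    if (!flags["perceptual_separability"]) g <- c(g, log(spec$sds$diamond[2]))
  }
  if (!flags["perceptual_independence"])
    g <- c(g, atanh(spec$rhos[["square"]]), atanh(spec$rhos[["diamond"]]),
           atanh(spec$rhos[["absent"]]))
  if (!flags["decisional_separability"]) g <- c(g, spec$slope)
  kappa <- rep_len(spec$kappa, P)
  cb <- rep_len(spec$identity_bound, P)
  bd <- spec$aw_bounds
  if (nrow(bd) == 1L) bd <- bd[rep(1, P), , drop = FALSE]
  c(g, log(kappa), cb, bd[, 1], log(bd[, 2] - bd[, 1]), log(bd[, 3] - bd[, 2]))
}

# ---- response probabilities --------------------------------------------

grt_class_names <- c("square", "diamond", "absent")
grt_cell_names <- c(paste0("square_pas", 1:4), paste0("diamond_pas", 1:4))

# probabilities for all participants and classes: array [P, 3, 8]
grt_predict_all <- function(spec) {
  P <- length(spec$kappa)
  out <- array(NA_real_, c(P, 3, 8),
               dimnames = list(NULL, grt_class_names, grt_cell_names))
  s0 <- spec$slope
  for (cl in grt_class_names) {
    mu <- spec$means[[cl]]
    sd2 <- spec$sds[[cl]]
    rho <- spec$rhos[[cl]]
    if (cl == "absent") {
      mx <- rep(0, P); my <- rep(0, P)
    } else {
      mx <- mu[1] * spec$kappa; my <- mu[2] * spec$kappa
    }
    sx <- sd2[1]; sy <- sd2[2]
    # u = y - slope * x is jointly Gaussian with x
    mu_u <- my - s0 * mx
    var_u <- sy^2 + s0^2 * sx^2 - 2 * s0 * rho * sx * sy
    su <- sqrt(max(var_u, 1e-12))
    r_xu <- (rho * sx * sy - s0 * sx^2) / (sx * su)
    r_xu <- min(max(r_xu, -0.999999), 0.999999)

    z_c <- (spec$identity_bound - mx) / sx                    # length P
    Zb <- (spec$aw_bounds - mu_u) / su                        # P x 3
    Fk <- matrix(bvn_lower(rep(z_c, 3), as.vector(Zb), r_xu), nrow = P)
    Pc <- stats::pnorm(z_c)
    Pb <- stats::pnorm(Zb)
    # diamond response: x <= c; cells are CDF differences over awareness bins
    Fd <- cbind(0, Fk, Pc)        # F at b0 = -Inf .. b4 = +Inf
    Pbm <- cbind(0, Pb, 1)
    diam <- Fd[, 2:5, drop = FALSE] - Fd[, 1:4, drop = FALSE]
    sq <- (Pbm[, 2:5, drop = FALSE] - Pbm[, 1:4, drop = FALSE]) - diam
    probs <- cbind(sq, diam)
    probs[probs < 0] <- 0
    out[, cl, ] <- probs / rowSums(probs)
  }
  out
}

#' Predicted response probabilities for one participant and stimulus
#'
#' Probability mass of the participant's attention-scaled stimulus
#' distribution over the eight response regions (2 shape responses x 4 PAS
#' levels). Regions are rectangles in the plane spanned by identity evidence
#' x and the bound-aligned coordinate `u = y - slope * x`, so each cell is an
#' exact bivariate-normal rectangle probability; the eight probabilities sum
#' to 1.
#'
#' @param spec a fitted or constructed `grt_model_spec`.
#' @param participant participant index.
#' @param stimulus `"square"`, `"diamond"` or `"absent"`.
#' @return named numeric vector of 8 probabilities.
#' @export
predict_response_probs <- function(spec, participant = 1L,
                                   stimulus = c("square", "diamond", "absent")) {
  stimulus <- match.arg(stimulus)
  for (cl in grt_class_names) {
    ev <- eigen(grt_cov(spec, cl), symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariance for '", cl, "' is not positive-definite")
  }
  all <- grt_predict_all(spec)
  all[participant, stimulus, ]
}

grt_cov <- function(spec, cl) {
  s <- spec$sds[[cl]]
  r <- spec$rhos[[cl]]
  matrix(c(s[1]^2, r * s[1] * s[2], r * s[1] * s[2], s[2]^2), 2)
}

#' Multinomial negative log-likelihood of a GRT model
#'
#' Counts are an array `[participant, stimulus, response]` with stimulus
#' levels square, diamond, absent (catch trials) and the 8 response cells
#' (shape response x PAS). The multinomial coefficient is omitted, so an
#' empty dataset scores 0 and duplicating the data doubles the value.
#'
#' @param spec a `grt_model_spec` with parameters set.
#' @param counts counts array.
#' @return negative log-likelihood (a single number).
#' @export
negloglik <- function(spec, counts) {
  P <- length(spec$kappa)
  if (dim(counts)[1] != P)
    stop("participant count mismatch between spec and dataset")
  pr <- grt_predict_all(spec)
  -sum(counts * log(pmax(pr, 1e-12)))
}

#' Simulate response counts from a GRT model
#'
#' Draws multinomial response counts at given per-stimulus trial numbers,
#' for every participant; used by the parametric bootstrap and the
#' recovery harnesses.
#'
#' @param spec a `grt_model_spec` with parameters set.
#' @param trials_per_stimulus named vector (square, diamond, absent) or a
#'   `P x 3` matrix of per-participant trial counts.
#' @param rng integer seed.
#' @return counts array `[P, 3, 8]`.
#' @export
simulate_grt_counts <- function(spec, trials_per_stimulus = c(square = 128, diamond = 128, absent = 64),
                                rng = 1L) {
  P <- length(spec$kappa)
  if (is.null(dim(trials_per_stimulus)))
    trials_per_stimulus <- matrix(rep(trials_per_stimulus[grt_class_names], each = P),
                                  nrow = P, dimnames = list(NULL, grt_class_names))
  pr <- grt_predict_all(spec)
  out <- array(0, dim(pr), dimnames = dimnames(pr))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng)
  for (i in seq_len(P)) for (s in grt_class_names) {
    out[i, s, ] <- stats::rmultinom(1, trials_per_stimulus[i, s], pr[i, s, ])
  }
  out
}
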