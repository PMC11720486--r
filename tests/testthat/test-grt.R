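test_that("the model family enumerates 2^4 nested variants", {
  mods <- enumerate_models()
  expect_length(mods, 16)
  flags <- t(sapply(mods, `[[`, "flags"))
  expect_equal(nrow(unique(flags)), 16)
  np <- sapply(mods, function(m) awarekit:::grt_n_params(m$flags, P = 10))
  full <- which(rowSums(flags) == 0)
  most <- which(rowSums(flags) == 4)
  expect_equal(np[full], max(np))
  expect_equal(np[most], min(np))
  # every constrained template's parameter names are a subset of the full's
  full_names <- awarekit:::grt_par_template(mods[[full]]$flags, 10)$global
  for (m in mods) {
    expect_true(all(awarekit:::grt_par_template(m$flags, 10)$global
                    %in% full_names))
  }
})

test_that("response probabilities are symmetric, degenerate-safe and sum to 1", {
  spec <- make_grt_spec(P = 2)
  spec$means$diamond <- spec$means$square   # identical distributions
  spec$kappa <- c(1, 1)
  spec$identity_bound <- rep(spec$means$square[1], 2)
  pr <- predict_response_probs(spec, 1, "square")
  expect_equal(sum(pr[1:4]), 0.5, tolerance = 1e-9)  # shape marginal 50/50
  expect_equal(sum(pr), 1, tolerance = 1e-8)

  far <- make_grt_spec(P = 1)
  far$aw_bounds <- matrix(c(50, 51, 52), 1)  # criteria far above any percept
  prf <- predict_response_probs(far, 1, "square")
  expect_equal(sum(prf[c(1, 5)]), 1, tolerance = 1e-9)  # all mass in PAS 1

  bad <- make_grt_spec(P = 1)
  bad$rhos <- c(square = 1.5, diamond = 0, absent = 0)
  bad$sds <- list(square = c(1, 1), diamond = c(1, 1), absent = c(1, 1))
  expect_error(predict_response_probs(bad, 1, "square"), "positive-definite")
})

test_that("probabilities match Monte-Carlo sampling for correlated, sloped models", {
  set.seed(50)
  for (rep in 1:3) {
    spec <- make_grt_spec(P = 2, seed = 50 + rep,
                          flags = c(equal_variances = FALSE,
                                    perceptual_separability = FALSE,
                                    perceptual_independence = FALSE,
                                    decisional_separability = FALSE),
                          rhos = c(square = runif(1, -0.6, 0.6),
                                   diamond = runif(1, -0.6, 0.6),
                                   absent = runif(1, -0.6, 0.6)),
                          sds = list(square = runif(2, 0.7, 1.4),
                                     diamond = runif(2, 0.7, 1.4),
                                     absent = c(1, 1)),
                          slope = runif(1, -0.8, 0.8))
    stim <- sample(c("square", "diamond", "absent"), 1)
    pr <- predict_response_probs(spec, 2, stim)
    expect_equal(sum(pr), 1, tolerance = 1e-8)

    n <- 2e5
    mu <- if (stim == "absent") c(0, 0) else spec$means[[stim]] * spec$kappa[2]
    L <- t(chol(awarekit:::grt_cov(spec, stim)))
    X <- t(mu + L %*% matrix(rnorm(2 * n), 2))
    u <- X[, 2] - spec$slope * X[, 1]
    shp <- ifelse(X[, 1] > spec$identity_bound[2], "square", "diamond")
    pas <- 1 + findInterval(u, spec$aw_bounds[2, ])
    emp <- as.vector(table(factor(pas, 1:4),
                           factor(shp, c("square", "diamond")))) / n
    emp <- c(emp[1:4], emp[5:8])
    se <- sqrt(pmax(pr * (1 - pr), 1e-8) / n)
    expect_true(all(abs(pr - emp) <= 4 * se))
  }
})

test_that("the multinomial likelihood is additive and anchored", {
  spec <- make_grt_spec(P = 3)
  cnt <- simulate_grt_counts(spec, rng = 5)[, , ]
  expect_equal(negloglik(spec, array(0, dim(cnt))), 0)
  one <- negloglik(spec, cnt)
  expect_equal(negloglik(spec, 2 * cnt), 2 * one, tolerance = 1e-10)
  expect_error(negloglik(make_grt_spec(P = 2), cnt), "mismatch")
})

test_that("expected-count data score best at the generating parameters", {
  spec <- make_grt_spec(P = 4)
  pr <- awarekit:::grt_predict_all(spec)
  counts <- pr * 320                      # exact model expectation
  base <- negloglik(spec, counts)
  set.seed(51)
  for (i in 1:20) {
    pert <- spec
    pert$means$square <- pert$means$square + rnorm(2, 0, 0.15)
    pert$means$diamond <- pert$means$diamond + rnorm(2, 0, 0.15)
    pert$identity_bound <- pert$identity_bound + rnorm(4, 0, 0.1)
    expect_gt(negloglik(pert, counts), base - 1e-4)
  }
})

test_that("fitting recovers a known model and respects nesting", {
  true <- make_grt_spec(P = 12, seed = 7)
  cnt <- simulate_grt_counts(true, rng = 60)
  tmpl <- grt_model_spec(TRUE, TRUE, TRUE, TRUE)
  fit <- fit_grt_wind(cnt, tmpl, restarts = 2, rng = 1)
  expect_equal(fit$spec$means$square[1], true$means$square[1], tolerance = 0.15)
  expect_equal(fit$spec$means$square[2], true$means$square[2], tolerance = 0.2)
  expect_lte(-fit$loglik, negloglik(true, cnt) + 1e-4)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_true(fit$pct_accounted >= 0 && fit$pct_accounted <= 100)
  expect_gte(median(fit$spec$kappa / true$kappa), 0.7)
  expect_lte(median(fit$spec$kappa / true$kappa), 1.4)

  # the full model can only fit better in likelihood
  full <- fit_grt_wind(cnt, grt_model_spec(), restarts = 2, rng = 1)
  expect_gte(full$loglik, fit$loglik - 1e-4)

  nocatch <- cnt; nocatch[, "absent", ] <- 0
  expect_error(fit_grt_wind(nocatch, tmpl), "catch")
})

test_that("AIC selection breaks ties toward parsimony and guards datasets", {
  true <- make_grt_spec(P = 6)
  cnt <- simulate_grt_counts(true, rng = 61)
  f1 <- fit_grt_wind(cnt, grt_model_spec(TRUE, TRUE, TRUE, TRUE),
                     restarts = 1, rng = 1)
  f2 <- f1
  f2$aic <- f1$aic
  f2$n_params <- f1$n_params + 5
  expect_identical(select_model(list(f2, f1)), f1)
  expect_identical(select_model(list(f1)), f1)
  other <- fit_grt_wind(simulate_grt_counts(true, rng = 62),
                        grt_model_spec(TRUE, TRUE, TRUE, TRUE),
                        restarts = 1, rng = 1)
  expect_error(select_model(list(f1, other)), "same dataset")
})
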