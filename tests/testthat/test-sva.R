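test_that("RLNA has the Gaussian closed form and the identity limit", {
  spec <- make_grt_spec(P = 2, my = 1)      # awareness: absent N(0,1), present N(1,1)
  expect_equal(rlna(spec, 0.5), 1, tolerance = 1e-12)
  a <- seq(-2, 3, length.out = 40)
  lr <- log(rlna(spec, a))
  slopes <- diff(lr) / diff(a)
  expect_equal(slopes, rep(-1, length(slopes)), tolerance = 1e-6)

  same <- make_grt_spec(P = 2, my = 0)      # absent and present identical
  same$means$square[2] <- 0; same$means$diamond[2] <- 0
  expect_equal(rlna(same, c(-1, 0, 2)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("conditional d' is constant under separability + independence", {
  spec <- make_grt_spec(P = 2, mx = 0.6)
  a <- seq(-3, 3, length.out = 11)
  expect_equal(conditional_dprime(spec, a), rep(1.2, 11), tolerance = 1e-10)
  same <- spec
  same$means$diamond <- same$means$square
  expect_equal(conditional_dprime(same, a), rep(0, 11))
})

test_that("conditional d' matches numerical conditional moments when correlated", {
  spec <- make_grt_spec(P = 1,
                        flags = c(equal_variances = FALSE,
                                  perceptual_separability = FALSE,
                                  perceptual_independence = FALSE,
                                  decisional_separability = TRUE),
                        rhos = c(square = 0.5, diamond = -0.3, absent = 0),
                        sds = list(square = c(1.2, 0.9), diamond = c(0.8, 1.1),
                                   absent = c(1, 1)))
  for (a in c(-0.5, 0.4, 1.3)) {
    num <- function(cl) {
      mu <- spec$means[[cl]]; S <- awarekit:::grt_cov(spec, cl)
      f <- function(x) mvtnorm::dmvnorm(cbind(x, a), mu, S)
      z <- integrate(f, -12, 12, rel.tol = 1e-10)$value
      m1 <- integrate(function(x) x * f(x), -12, 12, rel.tol = 1e-10)$value / z
      m2 <- integrate(function(x) x^2 * f(x), -12, 12, rel.tol = 1e-10)$value / z
      c(m1, m2 - m1^2)
    }
    sq <- num("square"); di <- num("diamond")
    oracle <- abs(sq[1] - di[1]) / sqrt((sq[2] + di[2]) / 2)
    expect_equal(conditional_dprime(spec, a), oracle, tolerance = 1e-6)
  }
})

test_that("SvA curves are grid-consistent with a stable ideal criterion", {
  spec <- make_grt_spec(P = 3, my = 1)
  curve <- sva_curve(spec, grid_n = 200)
  expect_equal(curve$ideal_criterion, 0.5, tolerance = 1e-6)  # symmetric case
  i <- c(5, 57, 199)
  expect_equal(curve$rlna[i], rlna(spec, curve$awareness_grid[i]))
  expect_equal(curve$d_cond[i],
               conditional_dprime(spec, curve$awareness_grid[i]))
  fine <- sva_curve(spec, grid_n = 2000)
  expect_lt(abs(fine$ideal_criterion - curve$ideal_criterion), 1e-3)
  expect_length(curve$participant_bounds, 3)

  flat <- make_grt_spec(P = 2, my = 0)
  flat$means$square[2] <- 0; flat$means$diamond[2] <- 0
  expect_warning(sva_curve(flat), "no RLNA")
})

test_that("bootstrap bands are deterministic, ordered, and tighten with data", {
  true <- make_grt_spec(P = 8, seed = 70)
  cnt <- simulate_grt_counts(true, rng = 71)
  tmpl <- grt_model_spec(TRUE, TRUE, TRUE, TRUE)
  fit <- fit_grt_wind(cnt, tmpl, restarts = 1, rng = 1)
  b1 <- bootstrap_sva(fit, cnt, n_boot = 12, rng = 9, grid_n = 60)
  b2 <- bootstrap_sva(fit, cnt, n_boot = 12, rng = 9, grid_n = 60)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_true(all(b1$ci_lower <= b1$ci_upper))
  expect_true(all(b1$ci_lower <= b1$d_cond + 1e-9))
  expect_true(all(b1$ci_upper >= b1$d_cond - 1e-9))

  cnt_big <- simulate_grt_counts(true, trials_per_stimulus =
                                   c(square = 12800, diamond = 12800,
                                     absent = 6400), rng = 72)
  fit_big <- fit_grt_wind(cnt_big, tmpl, restarts = 1, rng = 1)
  b_big <- bootstrap_sva(fit_big, cnt_big, n_boot = 12, rng = 9, grid_n = 60)
  expect_lt(mean(b_big$ci_upper - b_big$ci_lower),
            mean(b1$ci_upper - b1$ci_lower))
  expect_error(bootstrap_sva(fit, cnt, n_boot = 1), "at least 2")
})

test_that("trial tables aggregate into the counts array exactly", {
  spec <- design_spec(n_participants = 2, blocks = "visibility",
                      trials_per_block = 160, seed = 13)
  coh <- simulate_experiment(spec, study_params())
  cnt <- grt_counts_from_trials(coh, "visibility")
  expect_equal(dim(cnt), c(2, 3, 8))
  expect_equal(sum(cnt), nrow(coh))
  one <- coh[coh$participant == 1 & coh$prime_identity == "square" &
               coh$prime_choice == "diamond" & coh$pas == 2, ]
  expect_equal(cnt[1, "square", "diamond_pas2"], nrow(one))
  expect_error(grt_counts_from_trials(coh, "multiple"), "no trials")
})
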