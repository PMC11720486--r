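test_that("JZS t-test favors the null at zero evidence and grows with |t|", {
  for (n in c(5, 12, 40)) for (r in c(0.5, sqrt(2) / 2, 1)) {
    b <- awarekit:::jzs_bf_from_t(0, n, prior_scale = r)
    expect_lt(b$bf10, 1)
  }
  grid <- sapply(seq(0, 5, by = 0.5), function(t) {
    awarekit:::jzs_bf_from_t(t, 24)$bf10
  })
  expect_true(all(diff(grid) > 0))
})

test_that("paired and one-sample JZS calls agree bit for bit", {
  set.seed(30)
  x <- rnorm(18, 520, 40); y <- x + rnorm(18, 8, 20)
  expect_identical(jzs_paired_bf(x, y), jzs_ttest_bf(x - y))
  b <- jzs_ttest_bf(x - y)
  expect_equal(b$bf10 * b$bf01, 1, tolerance = 1e-12)
})

test_that("evidence accumulates with n under a fixed true effect", {
  bf_at <- function(n) awarekit:::jzs_bf_from_t(0.5 * sqrt(n), n)$bf10
  bfs <- sapply(c(10, 20, 40, 80, 160), bf_at)
  expect_true(all(diff(bfs) > 0))
  expect_gt(bfs[5], 1000)
})

test_that("one-sided tests double the directional evidence appropriately", {
  b2 <- awarekit:::jzs_bf_from_t(2.5, 20, sided = "two")
  b1 <- awarekit:::jzs_bf_from_t(2.5, 20, sided = "one")
  expect_gt(b1$bf10, b2$bf10)      # evidence concentrated in the right tail
  bneg <- awarekit:::jzs_bf_from_t(-2.5, 20, sided = "one")
  expect_lt(bneg$bf10, 1)
})

test_that("JZS t-test rejects degenerate input", {
  expect_error(jzs_ttest_bf(c(1, 1, 1)), "zero variance")
  expect_error(jzs_ttest_bf(1), "at least 2")
})

test_that("correlation BF: r matches brute force, extremes behave", {
  set.seed(31)
  x <- rnorm(15); y <- 0.4 * x + rnorm(15)
  b <- jeffreys_corr_bf(x, y)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(b$r, r_brute, tolerance = 1e-12)
  z <- rnorm(10)
  expect_gt(jeffreys_corr_bf(z, z)$bf10, 100)   # r = 1 exactly
  expect_error(jeffreys_corr_bf(rep(1, 5), rnorm(5)), "constant")
  expect_error(jeffreys_corr_bf(rnorm(2), rnorm(2)), "at least 3")
})

test_that("correlation BF matches an independent Euler-integral oracle", {
  # oracle: rho-kernel with the hypergeometric factor evaluated through its
  # integral representation and adaptive quadrature throughout
  bf_oracle <- function(r, n) {
    kern <- function(rho) sapply(rho, function(p) {
      f <- function(tt) tt^(-0.5) * (1 - tt)^(n - 2) *
        (1 - (1 + p * r) / 2 * tt)^(-0.5)
      h <- integrate(f, 0, 1, rel.tol = 1e-10)$value
      (1 - p^2)^((n - 1) / 2) * (1 - p * r)^(-(n - 1.5)) * h
    })
    integrate(function(p) kern(p) / 2, -1, 1, rel.tol = 1e-9)$value / kern(0)
  }
  set.seed(32)
  for (i in 1:4) {
    n <- sample(8:30, 1)
    x <- rnorm(n); y <- runif(1, -0.8, 0.8) * x + rnorm(n)
    b <- jeffreys_corr_bf(x, y)
    expect_equal(b$bf10, bf_oracle(b$r, n), tolerance = 1e-6)
  }
})

test_that("correlation BF favors the null for independent draws", {
  set.seed(33)
  bfs <- replicate(200, jeffreys_corr_bf(rnorm(20), rnorm(20))$bf10)
  expect_lt(median(bfs), 1)
})

mk_anova_data <- function(seed, a_eff = 0, b_eff = 0, ab_eff = 0, n = 20) {
  set.seed(seed)
  g <- expand.grid(participant = seq_len(n), A = c("a1", "a2"),
                   B = c("b1", "b2"))
  subj <- rnorm(n)[g$participant]
  xa <- ifelse(g$A == "a2", 0.5, -0.5)
  xb <- ifelse(g$B == "b2", 0.5, -0.5)
  g$value <- subj + a_eff * xa + b_eff * xb + ab_eff * 2 * xa * xb +
    rnorm(nrow(g))
  g
}

test_that("ANOVA inclusion BFs are calibrated under the null", {
  incl <- t(sapply(1:100, function(s) rm_anova_bf(mk_anova_data(s))$bf_incl))
  expect_lt(median(incl[, "A"]), 1)
  expect_lt(median(incl[, "B"]), 1)
  expect_lt(median(incl[, "A:B"]), 1)
})

test_that("ANOVA detects a large planted main effect", {
  res <- rm_anova_bf(mk_anova_data(1, a_eff = 5))
  expect_gt(res$bf_incl[["A"]], 100)
  expect_lt(res$bf_incl[["A:B"]], 1)
  expect_true(all(res$model_bf10 > 0))
  expect_equal(length(res$model_bf10), 5)
})

test_that("ANOVA Monte-Carlo refinement is seed-stable within reported error", {
  d <- mk_anova_data(2)
  m1 <- rm_anova_bf(d, method = "mc", mc_draws = 20000L, seed = 5)
  m2 <- rm_anova_bf(d, method = "mc", mc_draws = 20000L, seed = 9)
  rel_err <- (max(m1$error_pct) + max(m2$error_pct)) / 100
  expect_lt(max(abs(log(m1$model_bf10[-1] / m2$model_bf10[-1]))),
            3 * sqrt(2) * rel_err)
  expect_true(all(m1$error_pct[-1] > 0))
})

test_that("ANOVA rejects incomplete designs", {
  d <- mk_anova_data(3)
  expect_error(rm_anova_bf(d[-1, ]), "complete and balanced")
})
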