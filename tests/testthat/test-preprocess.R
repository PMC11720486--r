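mk_trials <- function(rt, congruent = rep(TRUE, length(rt)),
                      correct = rep(TRUE, length(rt)),
                      pas = rep(1L, length(rt))) {
  data.frame(participant = 1L, block = "single",
             trial = seq_along(rt), prime_identity = "square",
             congruent = congruent, probe_identity = "square",
             rt_ms = rt, probe_correct = correct,
             prime_choice = "square", pas = pas)
}

test_that("the absolute RT window keeps boundary values and drops outliers", {
  tr <- mk_trials(c(150, 500, 600, 2500))
  out <- trim_rts(tr, for_rt_analysis = FALSE)
  expect_equal(out$trials$rt_ms, c(500, 600))
  expect_equal(out$audit$n_removed_window, 2)
  # exact boundaries are kept ("below 200 and above 2000" are removed)
  kept <- trim_rts(mk_trials(c(200, 2000, 500)), for_rt_analysis = FALSE)
  expect_equal(kept$audit$n_removed_window, 0)
})

test_that("zero spread disables the SD pass and empty windows error", {
  out <- trim_rts(mk_trials(rep(700, 5)), for_rt_analysis = FALSE)
  expect_equal(out$audit$n_removed_sd, 0)
  expect_equal(out$audit$n_kept, 5)
  expect_error(trim_rts(mk_trials(c(100, 2100)), for_rt_analysis = FALSE),
               "degenerate")
})

test_that("SD trimming matches a brute-force pass and audits balance", {
  set.seed(10)
  rt <- c(exp(rnorm(100, log(550), 0.15)), 1900, 1950, 205)
  correct <- rep(TRUE, length(rt)); correct[c(5, 20)] <- FALSE
  tr <- mk_trials(rt, correct = correct)
  out <- trim_rts(tr, for_rt_analysis = TRUE)
  # independent brute force
  r1 <- rt[correct]
  r2 <- r1[r1 >= 200 & r1 <= 2000]
  m <- mean(r2); s <- sd(r2)
  keep <- r2[r2 >= m - 2 * s & r2 <= m + 2 * s]
  expect_equal(sort(out$trials$rt_ms), sort(keep))
  expect_equal(out$audit$n_removed_sd, length(r2) - length(keep))
  expect_gt(out$audit$n_removed_sd, 0)
  with(out$audit, expect_equal(
    n_input, n_removed_incorrect + n_removed_window + n_removed_sd + n_kept))
})

test_that("trimming steps 1-2 are idempotent", {
  set.seed(2)
  tr <- mk_trials(exp(rnorm(200, log(600), 0.4)))
  once <- trim_rts(tr, for_rt_analysis = TRUE)
  twice <- trim_rts(once$trials, for_rt_analysis = TRUE)
  expect_equal(twice$audit$n_removed_incorrect, 0)
  expect_equal(twice$audit$n_removed_window, 0)
})

test_that("PAS-1 selection subsets in order and flags low counts", {
  tr <- mk_trials(rep(500, 30), congruent = rep(c(TRUE, FALSE), 15),
                  pas = rep(c(1L, 2L, 2L), 10))
  sel <- select_pas1(tr)
  expect_equal(nrow(sel), sum(tr$pas == 1))
  expect_identical(sel$trial, tr$trial[tr$pas == 1])
  expect_true(attr(sel, "low_count"))  # only 5 PAS-1 trials per cell
  all1 <- select_pas1(mk_trials(rep(500, 44),
                                congruent = rep(c(TRUE, FALSE), 22)))
  expect_equal(nrow(all1), 44)
  expect_false(attr(all1, "low_count"))
  none <- select_pas1(mk_trials(rep(500, 4), pas = rep(2L, 4)))
  expect_equal(nrow(none), 0)
  expect_true(attr(none, "low_count"))
})

test_that("exclusion rules use strict thresholds on the right blocks", {
  mk_block <- function(id, block, acc_n, n = 320, pas4_catch = 0, catch = 64) {
    pas <- rep(1L, n)
    prime <- c(rep("none", catch), rep("square", n - catch))
    if (pas4_catch > 0) pas[seq_len(pas4_catch)] <- 4L
    data.frame(participant = id, block = block, trial = 1:n,
               prime_identity = prime, congruent = NA,
               probe_identity = "square", rt_ms = 500,
               probe_correct = c(rep(TRUE, acc_n), rep(FALSE, n - acc_n)),
               prime_choice = "square", pas = pas)
  }
  cohort <- rbind(
    mk_block(1, "multiple", acc_n = 240),                  # exactly 75%
    mk_block(1, "visibility", acc_n = 320),
    mk_block(2, "multiple", acc_n = 239),                  # below 75%
    mk_block(2, "visibility", acc_n = 320),
    mk_block(3, "multiple", acc_n = 320),
    mk_block(3, "visibility", acc_n = 320, pas4_catch = 7),  # 7/64 > 10%
    mk_block(4, "multiple", acc_n = 320, pas4_catch = 6),    # 6/64 <= 10%
    mk_block(4, "visibility", acc_n = 320))
  fl <- exclusion_flags(cohort)
  expect_equal(fl$excluded, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(fl$low_accuracy, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fl$pas4_catch_abuse, c(FALSE, FALSE, TRUE, FALSE))
  # missing block -> NA, not FALSE
  fl1 <- exclusion_flags(mk_block(9, "single", acc_n = 100))
  expect_true(is.na(fl1$low_accuracy))
  expect_true(is.na(fl1$pas4_catch_abuse))
})

test_that("congruency effects match brute force and negate under label swap", {
  tr <- mk_trials(c(500, 500, 530, 530),
                  congruent = c(TRUE, TRUE, FALSE, FALSE))
  eff <- congruency_effect(tr)
  expect_equal(eff$effect_ms, 30)
  expect_equal(eff$effect_se_ms, 0)

  set.seed(6)
  tr2 <- mk_trials(rnorm(60, 600, 40), congruent = rep(c(TRUE, FALSE), 30))
  e2 <- congruency_effect(tr2)
  rc <- tr2$rt_ms[tr2$congruent]; ri <- tr2$rt_ms[!tr2$congruent]
  expect_equal(e2$effect_ms, mean(ri) - mean(rc), tolerance = 1e-12)
  expect_equal(e2$effect_se_ms,
               sqrt(var(rc) / length(rc) + var(ri) / length(ri)),
               tolerance = 1e-12)
  swapped <- tr2; swapped$congruent <- !swapped$congruent
  expect_equal(congruency_effect(swapped)$effect_ms, -e2$effect_ms)
  expect_error(congruency_effect(mk_trials(c(500, 510))), "empty congruency")
})
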