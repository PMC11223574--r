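make_ratings <- function(values_by_participant, stimuli, category = "joy",
                         group = "G") {
  do.call(rbind, lapply(names(values_by_participant), function(p) {
    data.frame(participant = p, group = group, stimulus = stimuli,
               category = category, value = values_by_participant[[p]],
               stringsAsFactors = FALSE)
  }))
}

test_that("identical raters give reliability one, independent raters near zero", {
  stimuli <- sprintf("v%02d", 1:20)
  base <- seq(5, 90, length.out = 20)
  r <- make_ratings(list(p1 = base, p2 = base, p3 = base), stimuli)
  est <- interrater_reliability(r, n_reps = 20, seed = 1)
  expect_equal(est$r1, 1)
  expect_equal(est$index_of_reliability, 1)

  set.seed(2)
  stimuli <- sprintf("v%03d", 1:400)
  rn <- make_ratings(list(p1 = rnorm(400), p2 = rnorm(400), p3 = rnorm(400)),
                     stimuli)
  est2 <- interrater_reliability(rn, n_reps = 50, seed = 3)
  expect_lt(abs(est2$r1), 0.15)
})

test_that("simulated reliability matches the generator's closed form", {
  # unit signal, sigma_r = sigma_ind = 1: r1 = 1/3 (averaged over study
  # replicates; the exponential signal makes single-study variances noisy)
  ests <- vapply(1:4, function(s) {
    cfg <- linear_config(seed = s, n_stimuli = 600, n_categories = 2,
                         n_latent = 1, n_expressible = 1, n_features = 2,
                         n_raters = c(6, 2), latent_scale = 1, support_max = 1,
                         rater_noise_sd = 1, individual_effect_sd = 1)
    if (s == 1) {
      expect_equal(unname(oracle_reliability(cfg)$r1_sq$a[1]), 1 / 3,
                   tolerance = 1e-12)
    }
    b <- simulate_emotion_study(cfg)
    interrater_reliability(b$ratings$a, category = "cat01",
                           n_reps = 50, seed = 100 + s)$r1
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1 / 3), 0.05)
})

test_that("oracle reliability limits behave", {
  cfg0 <- linear_config(seed = 1, n_stimuli = 50, n_categories = 4,
                        n_latent = 2, n_expressible = 1, n_features = 2,
                        n_raters = c(2, 2), rater_noise_sd = 0,
                        individual_effect_sd = 0)
  expect_equal(unname(oracle_reliability(cfg0)$r1_sq$a), rep(1, 4))
})

test_that("noise ceiling is the product of reliability indices", {
  expect_equal(noise_ceiling(1, 1), 1)
  expect_equal(noise_ceiling(0.64, 0.25), 0.4)
  expect_error(noise_ceiling(-0.1, 0.5), "undefined")
  expect_equal(noise_ceiling(0, 0.5), 0)
  expect_warning(out <- adjust_correlation(0.3, noise_ceiling(0, 0.5)), "ceiling")
  expect_true(is.na(out))
})

test_that("attenuation adjustment divides by the ceiling and flags overshoot", {
  expect_equal(adjust_correlation(0.5, 1), 0.5)
  expect_equal(adjust_correlation(0.36, 0.4), 0.9, ignore_attr = TRUE)
  over <- adjust_correlation(0.5, 0.4)
  expect_equal(as.numeric(over), 1.25)
  expect_true(isTRUE(attr(over, "exceeds_one")))
})

test_that("explainable variance follows the N-response formula", {
  ev <- explainable_variance(0.145, 1)
  expect_equal(ev$rn_sq, 0.145)
  expect_equal(round(ev$max_correlation, 2), 0.38)
  expect_equal(ev$snr, 0.145 / (1 - 0.145))

  expect_equal(explainable_variance(0.5, 3)$rn_sq, 0.75)
  expect_lt(abs(explainable_variance(0.3, 1e6)$rn_sq - 1), 1e-4)
  expect_equal(explainable_variance(0, 10)$rn_sq, 0)

  # monotone in N and in r1^2
  n <- c(1, 2, 4, 8, 32)
  expect_true(all(diff(explainable_variance(0.25, n)$rn_sq) > 0))
  r1s <- vapply(c(0.1, 0.3, 0.5, 0.9),
                function(r) explainable_variance(r, 4)$rn_sq, numeric(1))
  expect_true(all(diff(r1s) > 0))
  expect_error(explainable_variance(1.2, 1), "r1_sq")
  expect_error(explainable_variance(0.5, 0), "n")
})

test_that("cross-group correlation is near one for identical populations and near zero for noise", {
  stimuli <- sprintf("v%03d", 1:60)
  base <- seq(0, 95, length.out = 60)
  set.seed(4)
  mk <- function(group, pids, sd = 6) {
    do.call(rbind, lapply(pids, function(p) {
      data.frame(participant = p, group = group, stimulus = stimuli,
                 category = "joy", value = base + rnorm(60, sd = sd),
                 stringsAsFactors = FALSE)
    }))
  }
  ra <- mk("A", c("a1", "a2", "a3"))
  rb <- mk("B", c("b1", "b2", "b3"))
  out <- cross_group_correlation(ra, rb, "joy", n_reps = 50, seed = 8)
  expect_equal(out$adjusted, 1, tolerance = 0.05)
  expect_lt(out$raw, out$adjusted + 1e-9)

  # a pure-noise group kills the raw correlation (its ceiling collapses
  # towards zero, so the adjusted ratio is unstable and not asserted)
  rb_noise <- mk("B", c("b1", "b2", "b3"))
  rb_noise$value <- rnorm(nrow(rb_noise), 50, 20)
  out2 <- cross_group_correlation(ra, rb_noise, "joy", n_reps = 50, seed = 9)
  expect_lt(abs(out2$raw), 0.15)
  expect_lt(out2$ceiling, 0.5)
})
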