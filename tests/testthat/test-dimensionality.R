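test_that("partial Spearman reproduces plain Spearman without controls", {
  expect_equal(partial_spearman(1:5, 1:5), 1)
  expect_equal(partial_spearman(1:4, c(9, 4, 2, 1)), -1)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(partial_spearman(a, b), cor(a, b, method = "spearman"))
})

test_that("partial Spearman equals brute-force residual correlation of ranks", {
  a <- c(1, 2, 3, 4, 7, 5)
  b <- c(1, 3, 2, 4, 6, 8)
  ctrl <- cbind(c(1, 2, 3, 4, 5, 6), c(2, 1, 5, 3, 6, 4))
  # oracle: explicit lm() on ranks
  ra <- rank(a); rb <- rank(b); rc <- apply(ctrl, 2, rank)
  res_a <- resid(lm(ra ~ rc)); res_b <- resid(lm(rb ~ rc))
  expect_equal(partial_spearman(a, b, ctrl), cor(res_a, res_b),
               tolerance = 1e-12)
})

test_that("partial Spearman flags degenerate inputs", {
  expect_true(is.na(partial_spearman(rep(1, 5), 1:5)))
  expect_error(partial_spearman(1:3, 1:3), "at least 4")
})

test_that("one-tailed signed-rank p-values match exact enumeration", {
  # 5 positive values: only the all-positive sign assignment reaches the
  # observed rank sum, so p = 1/2^5
  expect_equal(signed_rank_test(c(0.1, 0.2, 0.3, 0.4, 0.5)), 1 / 32)
  expect_gte(signed_rank_test(-c(0.1, 0.2, 0.3, 0.4, 0.5)), 1 - 1 / 32)
  expect_warning(p <- signed_rank_test(c(0, 0, 0)), "zero")
  expect_equal(p, 1)
  # exactly symmetric sample: p near one half
  x <- c(seq(-1, -0.1, by = 0.1), seq(0.1, 1, by = 0.1))
  expect_lt(abs(signed_rank_test(x) - 0.5), 0.1)
})

test_that("ForwardStop selects by the running mean of -log(1 - p)", {
  expect_identical(forward_stop(c(0.01, 0.02, 0.5, 0.04), 0.05), 2L)
  expect_identical(forward_stop(rep(0, 7), 0.05), 7L)
  expect_identical(forward_stop(c(0.9, 0.01, 0.01), 0.05), 0L)
  expect_identical(forward_stop(numeric(0), 0.05), 0L)
  # p = 1 contributes +Inf and caps the selection below its position
  expect_identical(forward_stop(c(0, 1, 0), 0.05), 1L)
  expect_error(forward_stop(c(0.1, NA), 0.05), "0, 1")
  expect_error(forward_stop(0.5, 1.5), "alpha")
})

test_that("ForwardStop is monotone in alpha", {
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(12)^2
    ks <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5),
                 function(a) forward_stop(p, a), integer(1))
    expect_true(all(diff(ks) >= 0))
  }
})

test_that("preserved_dims pinpoints noiseless planted structure", {
  cfg <- generator_config(n_stimuli = 80, n_categories = 12, n_latent = 3,
                          n_expressible = 2, n_features = 6,
                          n_raters = c(8, 8), rater_noise_sd = 0,
                          individual_effect_sd = 0,
                          loading_perturbation_sd = 0,
                          selection_threshold = NULL, clip = NULL, seed = 9)
  b <- simulate_emotion_study(cfg)
  # beyond the planted rank the projections are constant: NA correlations,
  # p = 1 (with a warning per degenerate dimension)
  d <- suppressWarnings(
    preserved_dims(b$ratings$a, b$ratings$b, n_components = 8))
  expect_identical(d$n_significant, 3L)
  expect_true(all(d$p_joint[1:3] < 0.001))
  expect_true(all(d$p_joint[4:8] >= 0.05))
  expect_s3_class(d, "preserved_dims")
  expect_output(print(d), "significant dimensions: 3")
})

test_that("destroying the stimulus correspondence removes significance", {
  cfg <- generator_config(n_stimuli = 80, n_categories = 10, n_latent = 3,
                          n_expressible = 2, n_features = 6,
                          n_raters = c(5, 5), seed = 3)
  b <- simulate_emotion_study(cfg)
  rb <- b$ratings$b
  set.seed(99)
  stim <- unique(rb$stimulus)
  perm <- setNames(sample(stim), stim)
  rb$stimulus <- unname(perm[rb$stimulus])
  d <- preserved_dims(b$ratings$a, rb, n_components = 8)
  expect_lte(d$n_significant, 1L)
})

test_that("participants with too few rated stimuli are excluded with a message", {
  b <- tiny_bundle()
  ra <- b$ratings$a
  # cripple one participant down to 2 rated stimuli
  p1 <- sort(unique(ra$participant))[1]
  keep_stim <- sort(unique(ra$stimulus))[1:2]
  ra <- ra[ra$participant != p1 |
             (ra$participant == p1 & ra$stimulus %in% keep_stim), ]
  expect_message(
    d <- preserved_dims(ra, b$ratings$b, n_components = 4),
    "excluded")
  expect_lt(sum(rowSums(!is.na(d$heldout_correlations)) > 0),
            length(unique(c(ra$participant, b$ratings$b$participant))))
})

test_that("preserved_dims rejects degenerate group sizes", {
  b <- tiny_bundle()
  one <- b$ratings$b[b$ratings$b$participant ==
                       sort(unique(b$ratings$b$participant))[1], ]
  expect_error(preserved_dims(b$ratings$a[0, ], one), "columns|stimuli")
  two <- b$ratings$a[b$ratings$a$participant %in%
                       sort(unique(b$ratings$a$participant))[1], ]
  expect_error(preserved_dims(two, one, n_components = 3), "6 participants")
})
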