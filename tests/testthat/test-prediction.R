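test_that("LOO prediction is exact for realizable linear targets and null for noise", {
  set.seed(1)
  x <- matrix(rnorm(40 * 3), 40, 3)
  w <- matrix(rnorm(6), 3, 2)
  y <- x %*% w + 5
  out <- loo_predict(x, y)
  expect_equal(out$overall_r, 1, tolerance = 1e-8)
  expect_equal(out$predicted, out$observed, tolerance = 1e-8)

  y0 <- matrix(rnorm(40 * 2), 40, 2)
  out0 <- loo_predict(x, y0)
  expect_lt(abs(out0$overall_r), 2 / sqrt(40 * 2) + 0.15)
  expect_s3_class(out0, "loo_prediction")
  expect_output(print(out0), "Leave-one-stimulus-out")
})

test_that("held-out predictions equal hand-computed three-point OLS lines", {
  x <- matrix(c(1, 2, 3, 5), 4, 1)
  y <- matrix(c(2.0, 2.9, 4.2, 6.1), 4, 1)
  out <- loo_predict(x, y)
  # oracle: fit lm() on the other three stimuli, predict the held-out one
  for (i in 1:4) {
    df <- data.frame(xx = x[-i, 1], yy = y[-i, 1])
    fit <- lm(yy ~ xx, data = df)
    expect_equal(out$predicted[i, 1],
                 unname(predict(fit, data.frame(xx = x[i, 1]))),
                 tolerance = 1e-10)
  }
})

test_that("underdetermined designs fall back to ridge; collinearity is named", {
  set.seed(2)
  x <- matrix(rnorm(6 * 8), 6, 8)
  y <- matrix(rnorm(6), 6, 1)
  expect_warning(out <- loo_predict(x, y), "ridge")
  expect_true(out$ridge)

  xc <- cbind(a = rnorm(20), b = rnorm(20))
  xc <- cbind(xc, c = xc[, 1] + xc[, 2])
  expect_error(loo_predict(xc, matrix(rnorm(20)), ridge = FALSE),
               "rank-deficient")
})

test_that("within-group z-scoring standardizes per group and is idempotent", {
  # sample-SD (n - 1) convention: (2, 4) has mean 3, sd sqrt(2)
  f <- rbind(c(2, 10), c(4, 30))
  z <- zscore_within_group(f, c("g", "g"))
  expect_equal(z, rbind(c(-1, -1), c(1, 1)) / sqrt(2),
               ignore_attr = TRUE, tolerance = 1e-12)

  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  g <- rep(c("a", "b"), 10)
  z1 <- zscore_within_group(x, g)
  expect_equal(zscore_within_group(z1, g), z1, tolerance = 1e-12)

  # zero-variance features flagged and zeroed
  x[, 2] <- 7
  colnames(x) <- c("f1", "f2", "f3")
  z2 <- zscore_within_group(x, g)
  expect_equal(unname(z2[, 2]), rep(0, 20))
  expect_identical(attr(z2, "zero_sd"), "f2")

  # a pure per-feature gain difference disappears after normalization
  fa <- matrix(rnorm(50), 10, 5)
  fb <- sweep(fa, 2, seq(0.2, 1, length.out = 5), "*")
  z3 <- zscore_within_group(rbind(fa, fb), rep(c("a", "b"), each = 10))
  expect_equal(z3[1:10, ], z3[11:20, ], tolerance = 1e-10)
})

test_that("target calibration inverts affine maps and learns permutations", {
  set.seed(4)
  ta <- matrix(rnorm(30 * 3), 30, 3)
  expect_equal(calibrate_targets(ta, ta), ta, tolerance = 1e-8)
  expect_equal(calibrate_targets(2 * ta + 3, ta), ta, tolerance = 1e-6)
  perm <- ta[, c(3, 1, 2)]
  expect_equal(calibrate_targets(perm, ta), ta, tolerance = 1e-6)
})

test_that("transfer between identical groups equals the within-group fit", {
  set.seed(5)
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- x %*% matrix(rnorm(8), 4, 2) + matrix(rnorm(60, sd = 0.3), 30, 2)
  within <- loo_predict(x, y)
  trans <- cross_group_transfer(x, y, x, y, calibrate = FALSE)
  expect_equal(trans$overall_r, within$overall_r, tolerance = 1e-10)
  expect_equal(trans$predicted, within$predicted, tolerance = 1e-8)

  # pure-noise features in the evaluation group predict nothing
  trans0 <- cross_group_transfer(x, y, matrix(rnorm(120), 30, 4), y,
                                 calibrate = FALSE)
  expect_lt(abs(trans0$overall_r), 0.35)
})

test_that("intensity profiles scale linearly with feature gains", {
  set.seed(6)
  fa <- matrix(rnorm(40 * 3), 40, 3)
  y <- fa %*% matrix(rnorm(6), 3, 2)
  map <- linear_map(fa, y)
  feats <- rbind(fa, 0.5 * fa)
  groups <- rep(c("A", "B"), each = 40)
  prof <- intensity_profile(map, feats, groups)
  expect_equal(unname(prof$ratio[, "A/B"]), c(2, 2), tolerance = 1e-10)
  prof_eq <- intensity_profile(map, rbind(fa, fa), groups)
  expect_equal(unname(prof_eq$ratio[, "A/B"]), c(1, 1), tolerance = 1e-12)
})

test_that("shared variance fraction is the squared ratio of mean correlations", {
  expect_equal(shared_variance_fraction(c(0.8, 0.8), c(0.8, 0.8)), 1)
  expect_equal(shared_variance_fraction(c(0.8, 0.8), c(0.4, 0.4)), 0.25)
  expect_warning(out <- shared_variance_fraction(c(0, 0), c(0.1, 0.1)), "zero")
  expect_true(is.na(out))
  expect_error(shared_variance_fraction(c(1.2, 0.5), c(0.1, 0.1)), "correlations")
})

test_that("feature associations recover planted support and compare across groups", {
  set.seed(7)
  s <- matrix(rnorm(100 * 2), 100, 2)
  feats <- cbind(s[, 1], s[, 2], rnorm(100))
  assoc <- feature_association(feats, s)
  expect_equal(assoc[1, 1], 1, tolerance = 1e-12)
  expect_equal(assoc[2, 2], 1, tolerance = 1e-12)
  expect_lt(max(abs(assoc[3, ])), 0.3)
  expect_equal(association_similarity(assoc, assoc), 1)
})

test_that("variance decomposition attributes idiosyncrasy to individuals", {
  # shared deviations across rating and feature channels -> own expressions
  # explain own experience best
  cfg <- linear_config(seed = 23, n_stimuli = 80, n_categories = 6,
                       n_latent = 3, n_expressible = 3, n_features = 6,
                       n_raters = c(4, 4), rater_noise_sd = 4,
                       individual_effect_sd = 25, feature_noise_sd = 2)
  b <- simulate_emotion_study(cfg)
  fcols <- b$truth$feature_ids
  stimuli <- b$truth$stimulus_ids
  cats <- b$truth$category_ids
  mfa <- mean_feature_matrix(b$features$a, stimuli)
  mfb <- mean_feature_matrix(b$features$b, stimuli)
  ma <- mean_rating_matrix(b$ratings$a, stimuli, cats)
  mb <- mean_rating_matrix(b$ratings$b, stimuli, cats)
  map <- linear_map(rbind(mfa, mfb), rbind(ma, mb))
  feats <- rbind(b$features$a, b$features$b)
  wide <- function(r) {
    w <- stats::reshape(r, idvar = c("participant", "group", "stimulus"),
                        timevar = "category", direction = "wide")
    names(w) <- sub("^value\\.", "", names(w))
    w
  }
  targ <- rbind(wide(b$ratings$a), wide(b$ratings$b))
  dec <- variance_decomposition(map, feats, targ, seed = 11)
  expect_gt(dec$r2_own, dec$r2_same_group)
  expect_gt(dec$shares[["unique"]], 0.3)
  expect_equal(sum(dec$shares), 1, tolerance = 1e-12)

  # with no individual deviations, another rater's expressions do as well
  cfg0 <- linear_config(seed = 24, n_stimuli = 80, n_categories = 6,
                        n_latent = 3, n_expressible = 3, n_features = 6,
                        n_raters = c(4, 4), rater_noise_sd = 4,
                        individual_effect_sd = 0, feature_noise_sd = 2)
  b0 <- simulate_emotion_study(cfg0)
  mfa0 <- mean_feature_matrix(b0$features$a, stimuli)
  mfb0 <- mean_feature_matrix(b0$features$b, stimuli)
  ma0 <- mean_rating_matrix(b0$ratings$a, stimuli, cats)
  mb0 <- mean_rating_matrix(b0$ratings$b, stimuli, cats)
  map0 <- linear_map(rbind(mfa0, mfb0), rbind(ma0, mb0))
  dec0 <- variance_decomposition(map0,
                                 rbind(b0$features$a, b0$features$b),
                                 rbind(wide(b0$ratings$a), wide(b0$ratings$b)),
                                 seed = 12)
  expect_lt(abs(dec0$shares[["unique"]]), 0.15)
})

test_that("bootstrap SEs are deterministic, degenerate at one replicate, and scale with n", {
  cfg <- linear_config(seed = 31, n_stimuli = 50, n_categories = 5,
                       n_latent = 2, n_expressible = 2, n_features = 4,
                       n_raters = c(6, 2))
  b <- simulate_emotion_study(cfg)
  stimuli <- b$truth$stimulus_ids
  cats <- b$truth$category_ids
  ma <- mean_rating_matrix(b$ratings$a, stimuli, cats)
  mfa <- mean_feature_matrix(b$features$a, stimuli)
  pred <- loo_predict(mfa, ma)$predicted
  wide <- function(r) {
    w <- stats::reshape(r, idvar = c("participant", "group", "stimulus"),
                        timevar = "category", direction = "wide")
    names(w) <- sub("^value\\.", "", names(w))
    w
  }
  wa <- wide(b$ratings$a)

  expect_warning(one <- bootstrap_se(pred, wa, n_bootstrap = 1, seed = 1),
                 "degenerate")
  expect_equal(one$se, 0)

  b1 <- bootstrap_se(pred, wa, n_bootstrap = 60, seed = 2)
  b2 <- bootstrap_se(pred, wa, n_bootstrap = 60, seed = 2)
  expect_identical(b1$se, b2$se)

  # duplicating every participant roughly halves the SE by sqrt(2)
  wa2 <- wa
  wa2$participant <- paste0(wa2$participant, "_dup")
  bdup <- bootstrap_se(pred, rbind(wa, wa2), n_bootstrap = 200, seed = 3)
  bref <- bootstrap_se(pred, wa, n_bootstrap = 200, seed = 3)
  expect_equal(bref$se / bdup$se, sqrt(2), tolerance = 0.45)
})

test_that("within-group fits are invariant to feature standardization", {
  set.seed(8)
  x <- matrix(rnorm(35 * 4), 35, 4)
  y <- x %*% matrix(rnorm(8), 4, 2) + matrix(rnorm(70, sd = 0.5), 35, 2)
  z <- zscore_within_group(x, rep("g", 35))
  expect_equal(loo_predict(z, y)$overall_r, loo_predict(x, y)$overall_r,
               tolerance = 1e-10)
})

test_that("prediction accuracy grows with the number of averaged responses", {
  cfg <- linear_config(seed = 41, n_stimuli = 150, n_categories = 8,
                       n_latent = 4, n_expressible = 4, n_features = 10,
                       n_raters = c(9, 2), feature_noise_sd = 40)
  b <- simulate_emotion_study(cfg)
  stimuli <- b$truth$stimulus_ids
  cats <- b$truth$category_ids
  targets <- mean_rating_matrix(b$ratings$a, stimuli, cats)
  fcols <- b$truth$feature_ids
  fa <- b$features$a
  pids <- sort(unique(fa$participant))
  mean_feats <- function(n) {
    sub <- fa[fa$participant %in% pids[seq_len(n)], ]
    mean_feature_matrix(sub, stimuli)
  }
  rs <- vapply(c(1, 3, 9),
               function(n) loo_predict(mean_feats(n), targets)$overall_r,
               numeric(1))
  expect_true(all(diff(rs) > 0))
  # and the ceiling implied by single-response reliability is approached,
  # not exceeded, once adjusted
  expect_lt(rs[1], rs[3])
})
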