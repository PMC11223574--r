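# Linear prediction of experience from expression features: leave-one-stimulus-out
# fits, cross-group transfer with target calibration, intensity normalization and
# profiles, association matrices, and individual-level variance decomposition.

# Internal: design matrix with intercept, solved normal equations, leverages.
# Ridge (excluding the intercept) engages automatically when the design is not
# comfortably overdetermined or is rank-deficient; leave-one-out predictions use
# the exact PRESS identity pred_loo = y - e / (1 - h), valid for any linear
# smoother of this form.
ols_machine <- function(features, targets, ridge = NULL, ridge_lambda = 1e-4) {
  x <- cbind(`(intercept)` = 1, as.matrix(features))
  y <- as.matrix(targets)
  n <- nrow(x); p <- ncol(x)
  if (nrow(y) != n) stop("'features' and 'targets' must have aligned rows")
  auto <- is.null(ridge)
  use_ridge <- isTRUE(ridge)
  if (auto) {
    r <- qr(x)$rank
    use_ridge <- p >= n - 1L || r < p
    if (use_ridge) {
      warning(sprintf(
        "design has %d columns for %d stimuli (rank %d); using ridge penalty %g",
        p, n, r, ridge_lambda))
    }
  }
  xtx <- crossprod(x)
  if (use_ridge) {
    pen <- diag(p) * ridge_lambda * mean(diag(xtx)[-1])
    pen[1, 1] <- 0
    xtx <- xtx + pen
  } else if (qr(x)$rank < p) {
    bad <- colnames(x)[-1][is.na(stats::lm.fit(x, y[, 1])$coefficients[-1])]
    stop("rank-deficient design; collinear features: ",
         paste(bad, collapse = ", "), " (set ridge = TRUE for a penalized fit)")
  }
  xtx_inv <- chol2inv(chol(xtx))
  w <- xtx_inv %*% crossprod(x, y)
  h <- rowSums((x %*% xtx_inv) * x)
  list(x = x, y = y, w = w, xtx_inv = xtx_inv, h = h,
       fitted = x %*% w, ridge = use_ridge)
}

#' Leave-one-stimulus-out linear prediction
#'
#' Fits ordinary least squares from expression features to experience
#' targets, leaving out one stimulus at a time, and evaluates how well the
#' held-out predictions track the observed targets. The overall correlation
#' flattens the predicted and observed matrices into vectors before
#' correlating. When the design is rank deficient or has at least as many
#' columns as stimuli, a small fixed ridge penalty replaces OLS (with a
#' warning).
#'
#' @param features stimuli-by-F numeric matrix.
#' @param targets stimuli-by-k numeric matrix (aligned rows).
#' @param ridge \code{NULL} (auto), \code{TRUE} or \code{FALSE}.
#' @param ridge_lambda relative ridge penalty (times the mean feature
#'   Gram-diagonal).
#' @param ceiling optional noise ceiling; when given, the adjusted overall
#'   correlation \code{overall_r / ceiling} is reported too.
#' @return an object of class \code{"loo_prediction"}: list with
#'   \code{predicted}, \code{observed}, \code{overall_r},
#'   \code{per_dimension_r}, \code{adjusted_overall_r} (NA without a
#'   ceiling) and \code{ridge}.
#' @export
loo_predict <- function(features, targets, ridge = NULL, ridge_lambda = 1e-4,
                        ceiling = NULL) {
  m <- ols_machine(features, targets, ridge, ridge_lambda)
  e <- m$y - m$fitted
  pred <- m$y - e / (1 - m$h)
  new_loo_prediction(pred, m$y, ceiling, ridge = m$ridge)
}

new_loo_prediction <- function(pred, obs, ceiling = NULL, ridge = FALSE) {
  overall <- stats::cor(as.vector(pred), as.vector(obs))
  per_dim <- vapply(seq_len(ncol(obs)), function(j) {
    if (stats::sd(pred[, j]) == 0 || stats::sd(obs[, j]) == 0) NA_real_
    else stats::cor(pred[, j], obs[, j])
  }, numeric(1))
  names(per_dim) <- colnames(obs)
  adj <- if (is.null(ceiling)) NA_real_ else as.numeric(adjust_correlation(overall, ceiling))
  structure(
    list(predicted = pred, observed = obs,
         overall_r = overall, per_dimension_r = per_dim,
         adjusted_overall_r = adj, ridge = ridge),
    class = "loo_prediction")
}

#' @export
print.loo_prediction <- function(x, ...) {
  cat(sprintf(
    "Leave-one-stimulus-out prediction: overall r = %.3f over %d stimuli x %d dimensions%s\n",
    x$overall_r, nrow(x$observed), ncol(x$observed),
    if (x$ridge) " (ridge)" else ""))
  if (!is.na(x$adjusted_overall_r)) {
    cat(sprintf("  noise-ceiling adjusted r = %.3f\n", x$adjusted_overall_r))
  }
  invisible(x)
}

#' Fit a plain linear map from features to targets
#'
#' Full-data least-squares fit (no cross-validation), used for intensity
#' profiles and individual-level analyses where one common model is applied
#' to many responses.
#'
#' @inheritParams loo_predict
#' @return object of class \code{"linear_map"} with \code{weights}
#'   (including the intercept row) and a \code{predict} method.
#' @export
linear_map <- function(features, targets, ridge = NULL, ridge_lambda = 1e-4) {
  m <- ols_machine(features, targets, ridge, ridge_lambda)
  structure(list(weights = m$w, ridge = m$ridge,
                 feature_names = colnames(m$x)[-1]),
            class = "linear_map")
}

#' @export
predict.linear_map <- function(object, newdata, ...) {
  cbind(1, as.matrix(newdata)) %*% object$weights
}

#' @export
coef.linear_map <- function(object, ...) object$weights

#' Z-score features within each group
#'
#' Per group and feature, subtracts the mean and divides by the sample
#' standard deviation, removing group-level differences in expression
#' intensity (display tendencies) while preserving each feature's pattern
#' across stimuli. Zero-variance features within a group are set to 0 and
#' flagged via the \code{"zero_sd"} attribute.
#'
#' @param features observations-by-F matrix.
#' @param groups group label per row.
#' @return normalized matrix of the same shape.
#' @export
zscore_within_group <- function(features, groups) {
  x <- as.matrix(features)
  if (length(groups) != nrow(x)) stop("'groups' must have one label per row")
  zeroed <- character(0)
  for (g in unique(groups)) {
    sel <- groups == g
    if (sum(sel) < 2L) stop("each group needs at least 2 observations")
    m <- colMeans(x[sel, , drop = FALSE])
    s <- apply(x[sel, , drop = FALSE], 2L, stats::sd)
    z <- sweep(x[sel, , drop = FALSE], 2L, m)
    bad <- s == 0
    s[bad] <- 1
    z <- sweep(z, 2L, s, "/")
    z[, bad] <- 0
    if (any(bad)) zeroed <- union(zeroed, colnames(x)[bad])
    x[sel, ] <- z
  }
  if (length(zeroed) > 0L) attr(x, "zero_sd") <- zeroed
  x
}

#' Leave-one-out calibration of one group's targets to another's
#'
#' For each held-out stimulus, a multivariate linear regression from group
#' B's target matrix to group A's is fit on the remaining stimuli and
#' applied to the held-out row. This aligns rating spaces whose category
#' labels translate imperfectly before cross-group model evaluation.
#'
#' @param targets_from stimuli-by-k matrix to be mapped (evaluation group).
#' @param targets_to stimuli-by-k matrix defining the target space
#'   (training group), aligned rows.
#' @inheritParams loo_predict
#' @return calibrated matrix, same shape as \code{targets_to}.
#' @export
calibrate_targets <- function(targets_from, targets_to, ridge = NULL,
                              ridge_lambda = 1e-4) {
  m <- ols_machine(targets_from, targets_to, ridge, ridge_lambda)
  e <- m$y - m$fitted
  m$y - e / (1 - m$h)
}

#' Cross-group transfer of an expression-to-experience model
#'
#' Trains the linear model in group A and evaluates it on group B's
#' features, in a leave-one-stimulus-out fashion on the training side (the
#' model applied to stimulus v never saw group A's data for v). Group B's
#' observed targets are first calibrated to group A's target space via
#' [calibrate_targets()] (disable with \code{calibrate = FALSE}). With
#' \code{normalize = TRUE} the features of each group are z-scored within
#' group first, which removes display-tendency differences in intensity.
#'
#' @param features_a,targets_a training group's stimulus-level features and
#'   targets.
#' @param features_b,targets_b evaluation group's features and targets,
#'   aligned to the same stimuli.
#' @param normalize z-score features within each group before fitting.
#' @param calibrate calibrate evaluation targets to the training target
#'   space.
#' @inheritParams loo_predict
#' @return a \code{"loo_prediction"} object (predictions for group B against
#'   its calibrated targets).
#' @export
cross_group_transfer <- function(features_a, targets_a, features_b, targets_b,
                                 normalize = FALSE, calibrate = TRUE,
                                 ridge = NULL, ridge_lambda = 1e-4,
                                 ceiling = NULL) {
  fa <- as.matrix(features_a); fb <- as.matrix(features_b)
  if (!all(dim(fa) == dim(fb))) stop("feature matrices must share shape (same stimuli, same features)")
  if (normalize) {
    both <- zscore_within_group(rbind(fa, fb),
                                rep(c("a", "b"), c(nrow(fa), nrow(fb))))
    fa <- both[seq_len(nrow(fa)), , drop = FALSE]
    fb <- both[nrow(fa) + seq_len(nrow(fb)), , drop = FALSE]
  }
  m <- ols_machine(fa, as.matrix(targets_a), ridge, ridge_lambda)
  e <- m$y - m$fitted
  # leave-one-out coefficient downdate applied at group B's feature rows:
  # pred_b[v] = xb_v' W_{-v} = xb_v' W - c_v * e_v / (1 - h_v),
  # c_v = xb_v' (X'X)^-1 xa_v
  xb <- cbind(1, fb)
  cv <- rowSums((xb %*% m$xtx_inv) * m$x)
  pred_b <- xb %*% m$w - (cv / (1 - m$h)) * e
  obs_b <- as.matrix(targets_b)
  if (calibrate) obs_b <- calibrate_targets(obs_b, as.matrix(targets_a),
                                            ridge, ridge_lambda)
  new_loo_prediction(pred_b, obs_b, ceiling, ridge = m$ridge)
}

#' Per-group standard deviation of model predictions
#'
#' Applies one fitted linear map to every response and computes, per
#' predicted dimension, the standard deviation within each group, plus the
#' matrix of pairwise group ratios. Because the predictions are linear in
#' the features, systematic group differences in these SDs measure
#' display-tendency differences in expression intensity.
#'
#' @param map a [linear_map()].
#' @param features responses-by-F matrix (individual responses, all groups).
#' @param groups group label per row.
#' @return list with \code{sd} (groups x targets matrix) and \code{ratio}
#'   (targets x group-pairs matrix of SD ratios).
#' @export
intensity_profile <- function(map, features, groups) {
  pred <- predict(map, features)
  gs <- sort(unique(groups))
  sds <- do.call(rbind, lapply(gs, function(g)
    apply(pred[groups == g, , drop = FALSE], 2L, stats::sd)))
  rownames(sds) <- gs
  pairs <- utils::combn(gs, 2L)
  ratio <- matrix(NA_real_, ncol(pred), ncol(pairs),
                  dimnames = list(colnames(pred),
                                  apply(pairs, 2L, paste, collapse = "/")))
  for (j in seq_len(ncol(pairs))) {
    ratio[, j] <- sds[pairs[1, j], ] / sds[pairs[2, j], ]
  }
  list(sd = sds, ratio = ratio)
}

#' Fraction of within-group explainable variance shared across groups
#'
#' Averages the cross-group prediction correlations, averages the
#' within-group prediction correlations, squares both, and returns their
#' ratio: the proportion of the variance explained within groups that is
#' also explained across groups.
#'
#' @param within_rs within-group prediction correlations (one per group).
#' @param cross_rs cross-group prediction correlations (one per direction).
#' @return \code{mean(cross_rs)^2 / mean(within_rs)^2}.
#' @export
shared_variance_fraction <- function(within_rs, cross_rs) {
  if (any(abs(c(within_rs, cross_rs)) > 1, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  w <- mean(within_rs)
  if (is.na(w) || w == 0) {
    warning("within-group correlations average to zero; fraction undefined")
    return(NA_real_)
  }
  mean(cross_rs)^2 / w^2
}

#' Feature-by-dimension association matrix
#'
#' Pearson correlation of each feature (e.g. a facial action unit output)
#' with each dimension score across stimuli. Constant columns give NA
#' entries. Two groups' association matrices can be compared with
#' [association_similarity()].
#'
#' @param features stimuli-by-F matrix (e.g. 36 AU outputs).
#' @param scores stimuli-by-k matrix of dimension scores.
#' @return an F-by-k correlation matrix.
#' @export
feature_association <- function(features, scores) {
  f <- as.matrix(features); s <- as.matrix(scores)
  if (nrow(f) != nrow(s)) stop("'features' and 'scores' must have aligned rows")
  suppressWarnings(stats::cor(f, s))
}

#' Similarity of two association matrices
#'
#' Flattens two feature-by-dimension association matrices and correlates
#' them, quantifying how similar the facial-movement signatures of each
#' dimension are across groups.
#'
#' @param assoc_a,assoc_b matrices of identical shape.
#' @return a single correlation.
#' @export
association_similarity <- function(assoc_a, assoc_b) {
  a <- as.vector(as.matrix(assoc_a)); b <- as.vector(as.matrix(assoc_b))
  ok <- !is.na(a) & !is.na(b)
  stats::cor(a[ok], b[ok])
}

#' Individual, cultural and universal variance in expression
#'
#' For each individual, compares how well their own self-reported experience
#' is explained (squared flattened correlation) by a common model applied to
#' (a) their own expression features, (b) a random same-group individual's
#' features on shared stimuli, and (c) a random other-group individual's
#' features. Averaged over individuals, the decomposition reports the
#' universal share \code{c/a}, the culture-specific share \code{(b - c)/a}
#' and the individual-unique share \code{(a - b)/a}.
#'
#' @param map a [linear_map()] trained on all data.
#' @param features data frame: \code{participant}, \code{group},
#'   \code{stimulus}, then one numeric column per feature (one row per
#'   individual response).
#' @param targets data frame: \code{participant}, \code{group},
#'   \code{stimulus}, then one numeric column per target dimension.
#' @param min_stimuli individuals with fewer paired stimuli are excluded.
#' @param seed optional seed for the random partner draws.
#' @return list with mean \code{r2_own}, \code{r2_same_group},
#'   \code{r2_other_group}, the \code{shares} vector (unique, cultural,
#'   universal) and \code{n_individuals}.
#' @export
variance_decomposition <- function(map, features, targets, min_stimuli = 4L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fkey <- interaction(features$participant, features$stimulus, drop = TRUE)
  tkey <- interaction(targets$participant, targets$stimulus, drop = TRUE)
  fcols <- setdiff(names(features), c("participant", "group", "stimulus"))
  tcols <- setdiff(names(targets), c("participant", "group", "stimulus"))
  people <- unique(features[, c("participant", "group")])
  feat_of <- function(p, stims) {
    sel <- features$participant == p & features$stimulus %in% stims
    rows <- features[sel, , drop = FALSE]
    rows <- rows[match(stims, rows$stimulus), , drop = FALSE]
    as.matrix(rows[, fcols, drop = FALSE])
  }
  r2 <- function(pred, obs) {
    if (stats::sd(as.vector(pred)) == 0 || stats::sd(as.vector(obs)) == 0) return(NA_real_)
    stats::cor(as.vector(pred), as.vector(obs))^2
  }
  res <- matrix(NA_real_, nrow(people), 3L,
                dimnames = list(NULL, c("own", "same_group", "other_group")))
  for (i in seq_len(nrow(people))) {
    p <- people$participant[i]; g <- people$group[i]
    stims_p <- intersect(features$stimulus[features$participant == p],
                         targets$stimulus[targets$participant == p])
    if (length(stims_p) < min_stimuli) next
    tsel <- targets$participant == p & targets$stimulus %in% stims_p
    trows <- targets[tsel, , drop = FALSE]
    trows <- trows[match(stims_p, trows$stimulus), , drop = FALSE]
    obs <- as.matrix(trows[, tcols, drop = FALSE])
    res[i, "own"] <- r2(predict(map, feat_of(p, stims_p)), obs)
    pick_partner <- function(cands) {
      cands <- setdiff(cands, p)
      shared <- vapply(cands, function(q) {
        length(intersect(stims_p, features$stimulus[features$participant == q]))
      }, integer(1))
      cands <- cands[shared >= min_stimuli]
      if (length(cands) == 0L) return(NULL)
      cands[sample.int(length(cands), 1L)]
    }
    q_same <- pick_partner(people$participant[people$group == g])
    if (!is.null(q_same)) {
      stims <- intersect(stims_p, features$stimulus[features$participant == q_same])
      res[i, "same_group"] <- r2(predict(map, feat_of(q_same, stims)),
                                 obs[match(stims, stims_p), , drop = FALSE])
    }
    q_other <- pick_partner(people$participant[people$group != g])
    if (!is.null(q_other)) {
      stims <- intersect(stims_p, features$stimulus[features$participant == q_other])
      res[i, "other_group"] <- r2(predict(map, feat_of(q_other, stims)),
                                  obs[match(stims, stims_p), , drop = FALSE])
    }
  }
  keep <- stats::complete.cases(res)
  if (!any(keep)) stop("no individual had enough paired stimuli and partners")
  m <- colMeans(res[keep, , drop = FALSE])
  shares <- c(unique = (m["own"] - m["same_group"]) / m["own"],
              cultural = (m["same_group"] - m["other_group"]) / m["own"],
              universal = m["other_group"] / m["own"])
  names(shares) <- c("unique", "cultural", "universal")
  list(r2_own = unname(m["own"]),
       r2_same_group = unname(m["same_group"]),
       r2_other_group = unname(m["other_group"]),
       shares = shares,
       n_individuals = sum(keep))
}

#' Bootstrap standard error of the overall prediction correlation
#'
#' Resamples participants (with replacement, within each group), recomputes
#' the per-stimulus mean observed targets from the resampled participants,
#' and re-evaluates the flattened correlation against the fixed stimulus-level
#' predictions. The standard error is the standard deviation of the
#' correlation across resamples.
#'
#' @param predicted stimuli-by-k matrix of model predictions (rows named by
#'   stimulus, or aligned with the sorted shared stimuli).
#' @param ratings participant-level target table: data frame with
#'   \code{participant}, \code{group}, \code{stimulus}, then one numeric
#'   column per target dimension.
#' @param n_bootstrap number of resamples; 1 returns 0 with a warning.
#' @param seed optional seed.
#' @return list with \code{se}, \code{replicates} and \code{r_original}.
#' @export
bootstrap_se <- function(predicted, ratings, n_bootstrap = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pred <- as.matrix(predicted)
  tcols <- setdiff(names(ratings), c("participant", "group", "stimulus"))
  stimuli <- if (!is.null(rownames(pred))) rownames(pred) else
    as.character(sort(unique(ratings$stimulus)))
  ratings <- ratings[as.character(ratings$stimulus) %in% stimuli, , drop = FALSE]
  people <- unique(ratings[, c("participant", "group")])
  mean_targets <- function(tab) {
    out <- matrix(NA_real_, length(stimuli), length(tcols),
                  dimnames = list(stimuli, tcols))
    for (j in seq_along(tcols)) {
      agg <- tapply(tab[[tcols[j]]], as.character(tab$stimulus), mean)
      out[names(agg), j] <- agg
    }
    out
  }
  eval_r <- function(tab) {
    obs <- mean_targets(tab)
    ok <- stats::complete.cases(obs)
    stats::cor(as.vector(pred[ok, , drop = FALSE]),
               as.vector(obs[ok, , drop = FALSE]))
  }
  r0 <- eval_r(ratings)
  if (n_bootstrap < 2L) {
    warning("n_bootstrap < 2: standard error degenerate, returning 0")
    return(list(se = 0, replicates = r0, r_original = r0))
  }
  reps <- vapply(seq_len(n_bootstrap), function(b) {
    draw <- unlist(lapply(split(people$participant, people$group), function(ps) {
      sample(ps, length(ps), replace = TRUE)
    }), use.names = FALSE)
    idx <- unlist(lapply(draw, function(p) which(ratings$participant == p)),
                  use.names = FALSE)
    eval_r(ratings[idx, , drop = FALSE])
  }, numeric(1))
  list(se = stats::sd(reps), replicates = reps, r_original = r0)
}
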