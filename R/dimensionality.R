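#' Partial Spearman correlation
#'
#' Rank-transforms \code{a}, \code{b} and every column of \code{controls},
#' residualizes the ranks of \code{a} and \code{b} on the control ranks
#' (OLS with intercept), and returns the Pearson correlation of the
#' residuals. With no controls this is the ordinary Spearman rho. Used when
#' testing each preserved dimension while controlling for projections onto
#' the previous dimensions, which absorbs curvilinear dependence on them.
#'
#' @param a,b numeric vectors of equal length (>= 4).
#' @param controls optional numeric matrix of control variables (columns),
#'   same number of rows as \code{length(a)}.
#' @return the partial Spearman correlation, or \code{NA} if either input is
#'   constant after ranking (zero variance).
#' @export
partial_spearman <- function(a, b, controls = NULL) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 4L) stop("need at least 4 observations")
  ok <- stats::complete.cases(a, b, if (is.null(controls)) rep(0, length(a)) else controls)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 4L) return(NA_real_)
  ra <- rank(a)
  rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(NA_real_)
  if (!is.null(controls)) {
    controls <- as.matrix(controls)[ok, , drop = FALSE]
    if (ncol(controls) > 0L) {
      rc <- apply(controls, 2L, rank)
      q <- qr(cbind(1, rc))
      ra <- qr.resid(q, ra)
      rb <- qr.resid(q, rb)
      if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(NA_real_)
    }
  }
  stats::cor(ra, rb)
}

#' One-tailed Wilcoxon signed-rank p-value
#'
#' Tests whether a sample of correlations (one per held-out rater) has
#' median greater than zero. Zeros are dropped (standard signed-rank
#' convention); the exact null distribution is used for n <= 25 when the
#' absolute values are tie-free, otherwise the normal approximation with
#' continuity correction.
#'
#' @param x numeric vector.
#' @return the one-tailed p-value (alternative: median > 0).
#' @export
signed_rank_test <- function(x) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  if (length(x) == 0L) {
    warning("all values are zero or missing; returning p = 1")
    return(1)
  }
  exact <- length(x) <= 25L && !any(duplicated(abs(x)))
  suppressWarnings(
    stats::wilcox.test(x, alternative = "greater", mu = 0,
                       exact = exact, correct = TRUE)$p.value)
}

#' ForwardStop sequential FDR stopping rule
#'
#' Given p-values in their natural testing order (component order, never
#' sorted by magnitude), returns the largest k such that the running mean of
#' \code{-log(1 - p)} over the first k p-values does not exceed
#' \code{alpha}. Returns 0 when no k qualifies (or the list is empty); a
#' p-value of 1 contributes \code{+Inf} and so caps k below its position.
#'
#' @param p numeric vector of p-values in testing order.
#' @param alpha target FDR level in (0, 1).
#' @return integer, the number of rejected (significant) leading hypotheses.
#' @examples
#' forward_stop(c(0.01, 0.02, 0.5, 0.04), alpha = 0.05) # 2
#' @export
forward_stop <- function(p, alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single value in (0, 1)")
  }
  if (length(p) == 0L) return(0L)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  running <- cumsum(-log1p(-p)) / seq_along(p)
  ok <- which(running <= alpha)
  if (length(ok) == 0L) 0L else max(ok)
}

#' How many preserved dimensions are statistically significant?
#'
#' Leave-one-rater-out test of the dimensionality shared by two groups'
#' ratings. For each held-out participant, PPCA is fit between the
#' per-stimulus mean matrix of their own group (recomputed without them) and
#' the mean matrix of the other group; the held-out participant's own
#' ratings and the other group's means are projected onto each component,
#' and their partial Spearman correlation across stimuli is computed,
#' controlling for both series' projections on all previous components.
#' Per dimension, a one-tailed Wilcoxon signed-rank test across held-out
#' participants (jointly, and within each group) yields ordered p-values,
#' to which the ForwardStop rule is applied.
#'
#' The dual criterion (\code{criterion = "dual"}, the default) requires a
#' dimension to survive ForwardStop on the joint test at \code{alpha_strict}
#' and on each group's own test at \code{alpha}; \code{criterion = "joint"}
#' uses only the joint p-values at \code{alpha}.
#'
#' By default (\code{comparison = "stimulus_split"}) the stimuli are split
#' deterministically in two: PPCA is fit on one half and the held-out
#' correlations are evaluated on the other. This matters for calibration.
#' Components fitted and evaluated on the same stimuli overfit the realized
#' stimulus sample: even when the two groups' signals are independent, some
#' direction aligns them by chance across a finite stimulus set, and since
#' every rater of a group shares that group's signal, all held-out raters
#' inherit the same spurious correlation -- which a rater-level signed-rank
#' test then declares significant. Evaluating on stimuli the fit never saw
#' removes this: a fixed direction has zero expected cross-group
#' correlation on fresh stimuli unless the dimension is genuinely
#' preserved. Two alternatives are retained for comparison:
#' \code{"rater_split"} (fit against one half of the other group's raters,
#' compare against the other half, all stimuli) removes rater-noise
#' overfitting but not signal overfitting; \code{"full_mean"} (fit and
#' compare against the full other-group mean on all stimuli) is the naive
#' reading.
#'
#' @param ratings_a,ratings_b rating tables (data frames with columns
#'   \code{participant}, \code{group}, \code{stimulus}, \code{category},
#'   \code{value}), one per group, sharing stimuli.
#' @param n_components number of leading components to test; default
#'   \code{min(15, n_categories)}.
#' @param alpha FDR level for the per-group (and joint, under
#'   \code{criterion = "joint"}) tests.
#' @param alpha_strict stricter FDR level for the joint test under the dual
#'   criterion.
#' @param criterion \code{"dual"} or \code{"joint"}.
#' @param comparison \code{"stimulus_split"} (default), \code{"rater_split"}
#'   or \code{"full_mean"}; see Details.
#' @param min_stimuli participants who rated fewer stimuli are excluded
#'   (with a message).
#' @return an object of class \code{"preserved_dims"}: list with
#'   \code{n_significant}, per-dimension p-values (\code{p_joint},
#'   \code{p_group_a}, \code{p_group_b}), the participants-by-dimensions
#'   matrix of held-out partial Spearman rhos, the levels used, and the
#'   number of usable participants.
#' @export
preserved_dims <- function(ratings_a, ratings_b, n_components = NULL,
                           alpha = 0.05, alpha_strict = 0.005,
                           criterion = c("dual", "joint"),
                           comparison = c("stimulus_split", "rater_split",
                                          "full_mean"),
                           min_stimuli = 4L) {
  criterion <- match.arg(criterion)
  comparison <- match.arg(comparison)
  ratings_a <- validate_ratings(ratings_a)
  ratings_b <- validate_ratings(ratings_b)
  stimuli <- sort(intersect(unique(ratings_a$stimulus), unique(ratings_b$stimulus)))
  if (length(stimuli) < 3L) stop("groups share fewer than 3 stimuli")
  categories <- sort(union(unique(ratings_a$category), unique(ratings_b$category)))
  if (is.null(n_components)) n_components <- min(15L, length(categories))
  n_components <- min(n_components, length(categories))

  ga <- rating_cube(ratings_a, stimuli, categories)
  gb <- rating_cube(ratings_b, stimuli, categories)
  if (length(ga$participants) + length(gb$participants) < 6L) {
    stop("need at least 6 participants in total for leave-one-out testing")
  }

  mean_of <- function(cube, idx) {
    s <- Reduce(`+`, lapply(cube$mats[idx], function(m) ifelse(is.na(m), 0, m)))
    cnt <- Reduce(`+`, lapply(cube$mats[idx], function(m) !is.na(m)))
    s / pmax(cnt, 1)
  }
  nstim <- length(stimuli)
  # deterministic splits (odd/even positions in sorted order)
  if (comparison == "stimulus_split") {
    fit_rows <- seq(1L, nstim, by = 2L)
    eval_rows <- seq(2L, nstim, by = 2L)
  } else {
    fit_rows <- eval_rows <- seq_len(nstim)
  }
  # other-group series used for the fit and for the held-out comparison
  halves <- function(cube) {
    n <- length(cube$mats)
    if (comparison == "rater_split" && n >= 2L) {
      list(fit = mean_of(cube, seq(1L, n, by = 2L)),
           cmp = mean_of(cube, seq(2L, n, by = 2L)))
    } else {
      m <- cube$sum / pmax(cube$count, 1)
      list(fit = m, cmp = m)
    }
  }
  half_a <- halves(ga)
  half_b <- halves(gb)

  held_out <- function(cube, own_mean_excl, other_fit, other_cmp, p_idx) {
    xp <- cube$mats[[p_idx]]                      # stimuli x categories, NA unrated
    rated <- intersect(which(rowSums(!is.na(xp)) > 0), eval_rows)
    if (length(rated) < min_stimuli) return(NULL)
    xp <- xp[rated, , drop = FALSE]
    xp[is.na(xp)] <- 0                            # unrated category within a rated stimulus
    fit <- ppca(own_mean_excl[fit_rows, , drop = FALSE],
                other_fit[fit_rows, , drop = FALSE])
    ps <- predict(fit, xp, k = n_components)
    po <- predict(fit, other_cmp[rated, , drop = FALSE], k = n_components)
    rho <- rep(NA_real_, n_components)
    # eigenvalue-null components carry only numerical roundoff, which is
    # spuriously self-consistent across the two projections; skip them
    lam <- fit$eigenvalues[seq_len(n_components)]
    dead <- abs(lam) <= 1e-10 * max(abs(fit$eigenvalues), 1e-300)
    for (i in seq_len(n_components)) {
      if (dead[i]) next
      ctrl <- if (i > 1L) cbind(ps[, seq_len(i - 1L), drop = FALSE],
                                po[, seq_len(i - 1L), drop = FALSE]) else NULL
      rho[i] <- partial_spearman(ps[, i], po[, i], ctrl)
    }
    rho
  }

  run_group <- function(cube, other_half) {
    np <- length(cube$participants)
    out <- matrix(NA_real_, np, n_components,
                  dimnames = list(cube$participants, NULL))
    excluded <- character(0)
    for (j in seq_len(np)) {
      m <- cube$mats[[j]]
      cnt <- cube$count - !is.na(m)
      s <- cube$sum - ifelse(is.na(m), 0, m)
      if (any(cnt == 0)) {
        excluded <- c(excluded, cube$participants[j])
        next                                       # removing p empties a cell
      }
      rho <- held_out(cube, s / cnt, other_half$fit, other_half$cmp, j)
      if (is.null(rho)) {
        excluded <- c(excluded, cube$participants[j])
        next
      }
      out[j, ] <- rho
    }
    if (length(excluded) > 0L) {
      message("excluded participants (too few rated stimuli or degenerate group): ",
              paste(excluded, collapse = ", "))
    }
    out
  }

  rho_a <- run_group(ga, half_b)
  rho_b <- run_group(gb, half_a)
  rho <- rbind(rho_a, rho_b)
  usable <- rowSums(!is.na(rho)) > 0

  pval <- function(m) {
    vapply(seq_len(n_components),
           function(i) signed_rank_test(m[, i]), numeric(1))
  }
  p_joint <- pval(rho)
  p_a <- pval(rho_a)
  p_b <- pval(rho_b)

  n_sig <- if (criterion == "joint") {
    forward_stop(p_joint, alpha)
  } else {
    min(forward_stop(p_joint, alpha_strict),
        forward_stop(p_a, alpha),
        forward_stop(p_b, alpha))
  }

  structure(
    list(n_significant = as.integer(n_sig),
         p_joint = p_joint, p_group_a = p_a, p_group_b = p_b,
         heldout_correlations = rho,
         alpha = alpha, alpha_strict = alpha_strict, criterion = criterion,
         comparison = comparison,
         n_components = n_components,
         n_participants = sum(usable)),
    class = "preserved_dims")
}

#' @export
print.preserved_dims <- function(x, ...) {
  cat("Preserved dimensionality (leave-one-rater-out)\n")
  cat(sprintf("  %d participants, %d components tested, criterion: %s\n",
              x$n_participants, x$n_components, x$criterion))
  cat(sprintf("  significant dimensions: %d\n", x$n_significant))
  cat("  joint p-values:\n  ")
  cat(format.pval(x$p_joint, digits = 3), fill = TRUE)
  invisible(x)
}

# Internal: per-participant stimulus x category matrices plus group totals.
rating_cube <- function(ratings, stimuli, categories) {
  ratings <- ratings[ratings$stimulus %in% stimuli, , drop = FALSE]
  participants <- sort(unique(ratings$participant))
  si <- match(ratings$stimulus, stimuli)
  ci <- match(ratings$category, categories)
  template <- matrix(NA_real_, length(stimuli), length(categories),
                     dimnames = list(stimuli, categories))
  mats <- lapply(participants, function(p) {
    sel <- ratings$participant == p
    m <- template
    m[cbind(si[sel], ci[sel])] <- ratings$value[sel]
    m
  })
  sum_m <- matrix(0, length(stimuli), length(categories),
                  dimnames = dimnames(template))
  count <- sum_m
  for (m in mats) {
    has <- !is.na(m)
    sum_m <- sum_m + ifelse(has, m, 0)
    count <- count + has
  }
  list(participants = participants, mats = mats, sum = sum_m, count = count)
}
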