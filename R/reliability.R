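#' Interrater reliability by random response pairing
#'
#' Estimates the reliability of single ratings of one category: on each of
#' \code{n_reps} repetitions, two responses from distinct participants are
#' drawn at random for every stimulus and the Pearson correlation between
#' the two drawn series is computed across stimuli; the estimate is the mean
#' correlation over repetitions. This random-pair correlation is the
#' explainable variance of an individual-level response (r1 squared in the
#' explainable-variance formula); its square root is the index of
#' reliability.
#'
#' @param ratings a rating table (data frame with \code{participant},
#'   \code{stimulus}, \code{category}, \code{value}) for one group.
#' @param category the category to analyse; default uses all rows.
#' @param n_reps number of random pairings (default 100).
#' @param seed optional integer seed for the pairing draws.
#' @return an object of class \code{"reliability_estimate"}: list with
#'   \code{r1} (mean random-pair correlation, the explainable variance of a
#'   single response), \code{index_of_reliability} (\code{sqrt(r1)}, NA when
#'   \code{r1 < 0}), \code{n_reps} and \code{n_stimuli} used.
#' @export
interrater_reliability <- function(ratings, category = NULL, n_reps = 100L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(category)) ratings <- ratings[ratings$category == category, , drop = FALSE]
  if (nrow(ratings) == 0L) stop("no ratings for the requested category")
  by_stim <- split(seq_len(nrow(ratings)), ratings$stimulus)
  by_stim <- Filter(function(ix) length(unique(ratings$participant[ix])) >= 2L, by_stim)
  if (length(by_stim) < 4L) {
    stop("fewer than 4 stimuli have ratings from 2 or more participants")
  }
  vals <- ratings$value
  parts <- ratings$participant
  rs <- vapply(seq_len(n_reps), function(rep) {
    pair <- vapply(by_stim, function(ix) {
      up <- unique(parts[ix])
      p2 <- up[sample.int(length(up), 2L)]
      v1 <- vals[ix][parts[ix] == p2[1]]
      v2 <- vals[ix][parts[ix] == p2[2]]
      c(v1[sample.int(length(v1), 1L)], v2[sample.int(length(v2), 1L)])
    }, numeric(2))
    if (stats::sd(pair[1, ]) == 0 || stats::sd(pair[2, ]) == 0) return(NA_real_)
    stats::cor(pair[1, ], pair[2, ])
  }, numeric(1))
  r1 <- mean(rs, na.rm = TRUE)
  structure(
    list(r1 = r1,
         index_of_reliability = if (!is.na(r1) && r1 >= 0) sqrt(r1) else NA_real_,
         n_reps = n_reps,
         n_stimuli = length(by_stim)),
    class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf(
    "Interrater reliability: r1 = %.3f (index of reliability %.3f), %d reps, %d stimuli\n",
    x$r1, x$index_of_reliability, x$n_reps, x$n_stimuli))
  invisible(x)
}

#' Noise ceiling for a cross-group correlation
#'
#' The maximum correlation attainable between two noisy series given their
#' single-response reliabilities: the product of the two indices of
#' reliability, \code{sqrt(r1_x) * sqrt(r1_y)} (equivalently the geometric
#' mean \code{sqrt(r1_x * r1_y)}).
#'
#' @param r1_x,r1_y single-response reliabilities (random-pair correlations)
#'   of the two series; must be non-negative.
#' @return the ceiling in [0, 1] for reliabilities in [0, 1].
#' @export
noise_ceiling <- function(r1_x, r1_y) {
  if (any(is.na(c(r1_x, r1_y)))) stop("reliabilities must not be missing")
  if (r1_x < 0 || r1_y < 0) {
    stop("negative reliability: the noise ceiling is undefined")
  }
  sqrt(r1_x) * sqrt(r1_y)
}

#' Attenuation-adjusted correlation
#'
#' Divides a raw correlation by the noise ceiling. Adjusted values above 1
#' (possible when the ceiling is underestimated) are reported as-is with an
#' attribute flag rather than clipped.
#'
#' @param raw_r observed correlation.
#' @param ceiling noise ceiling from [noise_ceiling()]; must exceed
#'   \code{eps}.
#' @param eps smallest admissible ceiling.
#' @return adjusted correlation, with attribute \code{exceeds_one} when
#'   above 1.
#' @export
adjust_correlation <- function(raw_r, ceiling, eps = 1e-8) {
  if (is.na(ceiling) || ceiling <= eps) {
    warning("noise ceiling is zero or undefined; adjusted correlation is NA")
    return(NA_real_)
  }
  out <- raw_r / ceiling
  if (!is.na(out) && abs(out) > 1) attr(out, "exceeds_one") <- TRUE
  out
}

#' Explainable variance of an N-response average
#'
#' Spearman-Brown style projection of single-response reliability to the
#' reliability of a mean of N responses:
#' \code{r_N^2 = ((1 - r1^2) / (N * r1^2) + 1)^-1}, derived from the
#' signal-to-noise ratio \code{r_N^2 / (1 - r_N^2) = N * r1^2 / (1 - r1^2)}
#' being proportional to sample size. The maximum attainable prediction
#' correlation for the average is \code{sqrt(r_N^2)}.
#'
#' @param r1_sq explainable variance of a single response (the random-pair
#'   correlation), in [0, 1].
#' @param n sample size N (>= 1), possibly vectorized.
#' @return an object of class \code{"explainable_variance"}: list with
#'   \code{rn_sq}, \code{max_correlation = sqrt(rn_sq)}, \code{snr}
#'   (\code{n * r1_sq / (1 - r1_sq)}), \code{r1_sq} and \code{n}.
#' @examples
#' explainable_variance(0.145, 1)$max_correlation # 0.38: single-rater bound
#' @export
explainable_variance <- function(r1_sq, n) {
  if (length(r1_sq) != 1L || is.na(r1_sq) || r1_sq < 0 || r1_sq > 1) {
    stop("'r1_sq' must be a single value in [0, 1]")
  }
  if (any(n < 1)) stop("'n' must be >= 1")
  if (r1_sq == 0) {
    rn <- rep(0, length(n))
    snr <- rep(0, length(n))
  } else {
    rn <- 1 / ((1 - r1_sq) / (n * r1_sq) + 1)
    snr <- n * r1_sq / (1 - r1_sq)
  }
  structure(
    list(rn_sq = rn, max_correlation = sqrt(rn), snr = snr,
         r1_sq = r1_sq, n = n),
    class = "explainable_variance")
}

#' @export
print.explainable_variance <- function(x, ...) {
  m <- rbind(N = x$n, rn_sq = x$rn_sq, max_r = x$max_correlation, snr = x$snr)
  cat(sprintf("Explainable variance of N-response means (r1^2 = %.3f)\n", x$r1_sq))
  print(signif(m, 3), ...)
  invisible(x)
}

#' Noise-ceiling-adjusted cross-group correlation for one category
#'
#' On each repetition, one rating of every shared stimulus is drawn at
#' random from each group and the two series are correlated across stimuli;
#' the raw estimate is the mean over repetitions. The adjusted estimate
#' divides by the noise ceiling built from each group's random-pair
#' interrater reliability (same repetitions count, same RNG stream).
#'
#' @param ratings_a,ratings_b rating tables for the two groups.
#' @param category category to analyse.
#' @param n_reps repetitions for both the cross-group draws and the
#'   within-group pairings (default 100).
#' @param seed optional integer seed.
#' @return list with \code{raw}, \code{adjusted}, \code{ceiling},
#'   \code{r1_a}, \code{r1_b} and \code{n_stimuli}.
#' @export
cross_group_correlation <- function(ratings_a, ratings_b, category,
                                    n_reps = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ra <- ratings_a[ratings_a$category == category, , drop = FALSE]
  rb <- ratings_b[ratings_b$category == category, , drop = FALSE]
  stimuli <- intersect(unique(ra$stimulus), unique(rb$stimulus))
  if (length(stimuli) < 4L) stop("fewer than 4 shared stimuli")
  ra <- ra[ra$stimulus %in% stimuli, , drop = FALSE]
  rb <- rb[rb$stimulus %in% stimuli, , drop = FALSE]
  ia <- split(ra$value, factor(ra$stimulus, levels = stimuli))
  ib <- split(rb$value, factor(rb$stimulus, levels = stimuli))
  draws <- vapply(seq_len(n_reps), function(rep) {
    va <- vapply(ia, function(v) v[sample.int(length(v), 1L)], numeric(1))
    vb <- vapply(ib, function(v) v[sample.int(length(v), 1L)], numeric(1))
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
    stats::cor(va, vb)
  }, numeric(1))
  raw <- mean(draws, na.rm = TRUE)
  r1a <- interrater_reliability(ra, n_reps = n_reps)$r1
  r1b <- interrater_reliability(rb, n_reps = n_reps)$r1
  adjusted <- if (is.na(r1a) || is.na(r1b) || r1a < 0 || r1b < 0) {
    warning("negative or undefined within-group reliability; adjusted value is NA")
    NA_real_
  } else {
    adjust_correlation(raw, noise_ceiling(r1a, r1b))
  }
  list(raw = raw, adjusted = as.numeric(adjusted),
       ceiling = if (!is.na(r1a) && !is.na(r1b) && r1a >= 0 && r1b >= 0)
         noise_ceiling(r1a, r1b) else NA_real_,
       r1_a = r1a, r1_b = r1b, n_stimuli = length(stimuli))
}
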