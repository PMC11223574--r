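# End-to-end analysis: cross-group category correlations, preserved
# dimensionality, rotation, prediction within/across groups, display-tendency
# normalization, and the variance decompositions.

#' Run configuration for the full analysis pipeline
#'
#' @param alpha_fdr ForwardStop FDR level for the per-group dimension tests.
#' @param alpha_fdr_strict stricter level for the joint test
#'   (dual criterion); must satisfy
#'   \code{0 < alpha_fdr_strict <= alpha_fdr < 1}.
#' @param n_reliability_reps repetitions for random-pairing reliability and
#'   cross-group draws.
#' @param n_bootstrap participant resamples for prediction standard errors.
#' @param seed integer seed consumed by every stochastic step.
#' @param normalization \code{"none"} or \code{"within_group_zscore"}
#'   (z-score expression features within each group before cross-group
#'   transfer).
#' @param n_components number of leading PPCA dimensions to test.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(alpha_fdr = 0.05, alpha_fdr_strict = 0.005,
                       n_reliability_reps = 100L, n_bootstrap = 200L,
                       seed = 1L,
                       normalization = c("none", "within_group_zscore"),
                       n_components = 15L) {
  normalization <- match.arg(normalization)
  if (!(alpha_fdr_strict > 0 && alpha_fdr_strict <= alpha_fdr && alpha_fdr < 1)) {
    stop("need 0 < alpha_fdr_strict <= alpha_fdr < 1")
  }
  structure(list(alpha_fdr = alpha_fdr, alpha_fdr_strict = alpha_fdr_strict,
                 n_reliability_reps = as.integer(n_reliability_reps),
                 n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
                 normalization = normalization,
                 n_components = as.integer(n_components)),
            class = "run_config")
}

#' Per-stimulus mean rating matrix
#'
#' Averages a long rating table into a stimuli-by-categories matrix of mean
#' ratings, the unit of analysis for PPCA between groups.
#'
#' @param ratings long rating table.
#' @param stimuli,categories row/column universes (and order); cells with no
#'   ratings are 0.
#' @return numeric matrix with \code{stimuli} rows and \code{categories}
#'   columns.
#' @export
mean_rating_matrix <- function(ratings, stimuli, categories) {
  si <- match(ratings$stimulus, stimuli)
  ci <- match(ratings$category, categories)
  ok <- !is.na(si) & !is.na(ci)
  m <- matrix(0, length(stimuli), length(categories),
              dimnames = list(stimuli, categories))
  if (any(ok)) {
    cell <- (ci[ok] - 1L) * length(stimuli) + si[ok]
    sums <- rowsum(ratings$value[ok], cell)
    cnts <- rowsum(rep(1, sum(ok)), cell)
    m[as.integer(rownames(sums))] <- sums / cnts
  }
  m
}

#' Per-stimulus mean expression feature matrix
#'
#' Averages a wide per-response feature table into a stimuli-by-features
#' matrix.
#'
#' @param features wide feature table.
#' @param stimuli stimulus universe (row order); stimuli with no responses
#'   get NA rows.
#' @return numeric matrix.
#' @export
mean_feature_matrix <- function(features, stimuli) {
  fcols <- setdiff(names(features), c("participant", "group", "stimulus"))
  out <- matrix(NA_real_, length(stimuli), length(fcols),
                dimnames = list(stimuli, fcols))
  sp <- split(seq_len(nrow(features)), as.character(features$stimulus))
  for (s in intersect(stimuli, names(sp))) {
    out[s, ] <- colMeans(as.matrix(features[sp[[s]], fcols, drop = FALSE]))
  }
  out
}

#' Run the full cross-cultural experience/expression analysis
#'
#' Composes the package's stages on two groups' ratings and expression
#' features: (1) noise-ceiling-adjusted per-category cross-group
#' correlations; (2) PPCA between the groups' mean rating matrices with
#' leave-one-rater-out dimensionality testing (ForwardStop); (3) varimax
#' rotation and labelling of the significant dimensions; (4)
#' leave-one-stimulus-out prediction of experience (dimension scores) from
#' mean expression features within each group, and cross-group transfer with
#' target calibration, raw and intensity-normalized; (5) per-group
#' prediction-SD intensity profiles; (6) shared-variance fractions before
#' and after normalization; (7) individual-level decomposition of explained
#' experience variance into unique, cultural and universal shares; (8)
#' bootstrap standard errors. All randomness derives from
#' \code{config$seed}.
#'
#' @param ratings list of two rating tables (one per group) or a
#'   \code{synthetic_bundle}.
#' @param features list of two wide feature tables; ignored when
#'   \code{ratings} is a bundle.
#' @param config a [run_config()].
#' @return a list of class \code{"semspace_report"} (JSON-serializable via
#'   [write_report()]).
#' @export
run_pipeline <- function(ratings, features = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(ratings, "synthetic_bundle")) {
    features <- ratings$features
    ratings <- ratings$ratings
  }
  if (length(ratings) != 2L || length(features) != 2L) {
    stop("'ratings' and 'features' must each hold two groups")
  }
  ra <- validate_ratings(ratings[[1]]); rb <- validate_ratings(ratings[[2]])
  fa <- validate_features(features[[1]]); fb <- validate_features(features[[2]])
  for (r in list(ra, rb)) {
    if (length(unique(r$participant)) < 2L) {
      stop("each group needs at least 2 participants")
    }
  }
  stimuli <- sort(intersect(unique(ra$stimulus), unique(rb$stimulus)))
  if (length(stimuli) < 3L) stop("need at least 3 shared stimuli")
  for (f in list(fa, fb)) {
    missing <- setdiff(stimuli, unique(as.character(f$stimulus)))
    if (length(missing) > 0L) {
      stop("feature table is missing stimuli present in ratings: ",
           paste(utils::head(missing, 10L), collapse = ", "))
    }
  }
  categories <- sort(union(unique(ra$category), unique(rb$category)))
  set.seed(config$seed)

  ## 1. per-category adjusted cross-group correlations
  category_r <- lapply(categories, function(cc) {
    tryCatch(cross_group_correlation(ra, rb, cc,
                                     n_reps = config$n_reliability_reps),
             error = function(e) list(raw = NA_real_, adjusted = NA_real_,
                                      ceiling = NA_real_,
                                      r1_a = NA_real_, r1_b = NA_real_))
  })
  names(category_r) <- categories

  ## 2. dimensionality
  dims <- preserved_dims(ra, rb, n_components = config$n_components,
                         alpha = config$alpha_fdr,
                         alpha_strict = config$alpha_fdr_strict)
  k_sig <- dims$n_significant

  ## 3. PPCA on the mean matrices + rotation of significant components
  ma <- mean_rating_matrix(ra, stimuli, categories)
  mb <- mean_rating_matrix(rb, stimuli, categories)
  fit <- ppca(ma, mb)
  if (k_sig >= 2L) {
    rot <- label_dimensions(
      varimax_rotate(fit$components[, seq_len(k_sig), drop = FALSE]))
    basis <- fit$components[, seq_len(k_sig), drop = FALSE] %*% rot$rotmat
  } else {
    rot <- NULL
    basis <- fit$components[, seq_len(max(k_sig, 1L)), drop = FALSE]
  }

  targets_a <- sweep(ma, 2L, colMeans(ma)) %*% basis
  targets_b <- sweep(mb, 2L, colMeans(mb)) %*% basis
  colnames(targets_a) <- colnames(targets_b) <-
    if (!is.null(rot)) rot$labels else colnames(basis)

  ## 4. prediction within and across groups
  mfa <- mean_feature_matrix(fa, stimuli)
  mfb <- mean_feature_matrix(fb, stimuli)
  within_a <- loo_predict(mfa, targets_a)
  within_b <- loo_predict(mfb, targets_b)
  cross_raw_ab <- cross_group_transfer(mfa, targets_a, mfb, targets_b)
  cross_raw_ba <- cross_group_transfer(mfb, targets_b, mfa, targets_a)
  cross_nrm_ab <- cross_group_transfer(mfa, targets_a, mfb, targets_b,
                                       normalize = TRUE)
  cross_nrm_ba <- cross_group_transfer(mfb, targets_b, mfa, targets_a,
                                       normalize = TRUE)

  ## 5. intensity profiles from a model trained on all stimulus-level data
  map_all <- linear_map(rbind(mfa, mfb), rbind(targets_a, targets_b))
  fcols <- setdiff(names(fa), c("participant", "group", "stimulus"))
  resp_features <- rbind(as.matrix(fa[fcols]), as.matrix(fb[fcols]))
  resp_groups <- c(rep("A", nrow(fa)), rep("B", nrow(fb)))
  profile <- intensity_profile(map_all, resp_features, resp_groups)

  ## 6. shared-variance fractions
  within_rs <- c(within_a$overall_r, within_b$overall_r)
  svf_raw <- shared_variance_fraction(
    within_rs, c(cross_raw_ab$overall_r, cross_raw_ba$overall_r))
  svf_nrm <- shared_variance_fraction(
    within_rs, c(cross_nrm_ab$overall_r, cross_nrm_ba$overall_r))

  ## 7. individual-level decomposition (targets in raw category space)
  wide_targets <- function(r) {
    w <- stats::reshape(r, idvar = c("participant", "group", "stimulus"),
                        timevar = "category", direction = "wide")
    names(w) <- sub("^value\\.", "", names(w))
    w[is.na(w)] <- 0
    w
  }
  targets_resp <- rbind(wide_targets(ra), wide_targets(rb))
  features_resp <- rbind(fa, fb)
  map_cat <- linear_map(rbind(mfa, mfb), rbind(ma, mb))
  decomp <- tryCatch(
    variance_decomposition(map_cat, features_resp, targets_resp),
    error = function(e) NULL)

  ## 8. bootstrap SEs for within-group predictions (participant ratings
  ## projected onto the same dimension basis as the targets)
  dim_targets <- function(r) {
    w <- wide_targets(r)
    scores <- as.matrix(w[, categories, drop = FALSE]) %*% basis
    out <- w[, c("participant", "group", "stimulus")]
    out[colnames(targets_a)] <- as.data.frame(scores)
    out
  }
  boot_a <- bootstrap_se(within_a$predicted, dim_targets(ra),
                         n_bootstrap = config$n_bootstrap)
  boot_b <- bootstrap_se(within_b$predicted, dim_targets(rb),
                         n_bootstrap = config$n_bootstrap)

  structure(list(
    config = unclass(config),
    n_stimuli = length(stimuli),
    n_categories = length(categories),
    eigenvalues = fit$eigenvalues,
    significant_dimensions = k_sig,
    dimension_pvalues = list(joint = dims$p_joint,
                             group_a = dims$p_group_a,
                             group_b = dims$p_group_b),
    rotated_loadings = if (!is.null(rot)) rot$loadings else NULL,
    dimension_labels = if (!is.null(rot)) rot$labels else NULL,
    category_correlations = list(
      raw = vapply(category_r, `[[`, numeric(1), "raw"),
      adjusted = vapply(category_r, `[[`, numeric(1), "adjusted")),
    prediction = list(
      within_a = within_a$overall_r, within_b = within_b$overall_r,
      within_a_se = boot_a$se, within_b_se = boot_b$se,
      cross_ab_raw = cross_raw_ab$overall_r,
      cross_ba_raw = cross_raw_ba$overall_r,
      cross_ab_normalized = cross_nrm_ab$overall_r,
      cross_ba_normalized = cross_nrm_ba$overall_r,
      per_dimension_within_a = within_a$per_dimension_r,
      per_dimension_within_b = within_b$per_dimension_r),
    shared_variance_fraction = list(raw = svf_raw, normalized = svf_nrm),
    intensity_profile = profile,
    variance_decomposition = decomp),
    class = "semspace_report")
}

#' @export
print.semspace_report <- function(x, ...) {
  cat("Cross-group experience/expression analysis\n")
  cat(sprintf("  %d shared stimuli, %d categories\n", x$n_stimuli, x$n_categories))
  cat(sprintf("  significant preserved dimensions: %d\n", x$significant_dimensions))
  if (!is.null(x$dimension_labels)) {
    cat("  labels:", paste(x$dimension_labels, collapse = ", "), "\n")
  }
  cat(sprintf("  mean adjusted category correlation: %.3f\n",
              mean(x$category_correlations$adjusted, na.rm = TRUE)))
  p <- x$prediction
  cat(sprintf("  within-group prediction r: %.3f / %.3f\n", p$within_a, p$within_b))
  cat(sprintf("  cross-group r raw: %.3f / %.3f; normalized: %.3f / %.3f\n",
              p$cross_ab_raw, p$cross_ba_raw,
              p$cross_ab_normalized, p$cross_ba_normalized))
  cat(sprintf("  shared variance fraction raw %.2f -> normalized %.2f\n",
              x$shared_variance_fraction$raw, x$shared_variance_fraction$normalized))
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Deterministic for a fixed-seed run: identical inputs give byte-identical
#' files.
#'
#' @param report a [run_pipeline()] result.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "semspace_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
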