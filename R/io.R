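# Reading, writing and validating the package's tabular formats.
# Dialect: comma-separated UTF-8 with a header row and "." decimal.

rating_scales <- list(intensity_0_100 = c(0, 100), bipolar_1_9 = c(1, 9))

# Internal: structural checks shared by load_ratings and the analysis entry
# points. Returns the validated data frame.
validate_ratings <- function(ratings, scale = NULL) {
  req <- c("participant", "group", "stimulus", "category", "value")
  if (!all(req %in% names(ratings))) {
    stop("rating table must have columns: ", paste(req, collapse = ", "))
  }
  ratings <- as.data.frame(ratings)[req]
  for (col in c("participant", "group", "stimulus", "category")) {
    ratings[[col]] <- as.character(ratings[[col]])
  }
  if (!is.numeric(ratings$value) || anyNA(ratings$value)) {
    stop("'value' must be numeric with no missing entries")
  }
  if (!is.null(scale)) {
    bounds <- rating_scales[[scale]]
    bad <- which(ratings$value < bounds[1] | ratings$value > bounds[2])
    if (length(bad) > 0L) {
      stop(sprintf("value %g out of range [%g, %g] for scale '%s' at row %d",
                   ratings$value[bad[1]], bounds[1], bounds[2], scale, bad[1]))
    }
  }
  key <- paste(ratings$participant, ratings$stimulus, ratings$category, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf("duplicate (participant, stimulus, category) key at row %d: %s / %s / %s",
                 dup[1], ratings$participant[dup[1]], ratings$stimulus[dup[1]],
                 ratings$category[dup[1]]))
  }
  pg <- unique(ratings[, c("participant", "group")])
  multi <- pg$participant[duplicated(pg$participant)]
  if (length(multi) > 0L) {
    stop("participants assigned to more than one group: ",
         paste(unique(multi), collapse = ", "))
  }
  ratings
}

#' Read a long-format rating table
#'
#' Reads a comma-separated UTF-8 file with header
#' \code{participant,group,stimulus,category,value}, validates scale bounds
#' and key uniqueness, and (for the intensity scale) materializes the
#' unselected categories of each (participant, stimulus) response as zeros,
#' matching a select-then-rate survey in which unselected emotions were
#' implicitly rated 0.
#'
#' @param path file path.
#' @param scale \code{"intensity_0_100"} or \code{"bipolar_1_9"}.
#' @param categories declared category set; for the intensity scale, absent
#'   categories are zero-filled per response. \code{NULL} uses only the
#'   categories present in the file (no fill).
#' @return validated rating data frame with attribute \code{"scale"}.
#' @export
load_ratings <- function(path, scale = c("intensity_0_100", "bipolar_1_9"),
                         categories = NULL) {
  scale <- match.arg(scale)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  out <- validate_ratings(raw, scale)
  if (!is.null(categories) && scale == "intensity_0_100") {
    extra <- setdiff(unique(out$category), categories)
    if (length(extra) > 0L) {
      stop("file contains undeclared categories: ", paste(extra, collapse = ", "))
    }
    resp <- unique(out[, c("participant", "group", "stimulus")])
    full <- merge(resp, data.frame(category = categories), by = NULL)
    out <- merge(full, out, all.x = TRUE,
                 by = c("participant", "group", "stimulus", "category"))
    out$value[is.na(out$value)] <- 0
    out <- out[order(out$participant, out$stimulus, out$category), ]
    rownames(out) <- NULL
    out <- validate_ratings(out, scale)
  }
  attr(out, "scale") <- scale
  out
}

#' Write a rating table
#'
#' @param ratings rating data frame.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  utils::write.csv(ratings, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Internal: checks for a wide feature table.
validate_features <- function(features) {
  req <- c("participant", "group", "stimulus")
  if (!all(req %in% names(features))) {
    stop("feature table must start with columns: ", paste(req, collapse = ", "))
  }
  features <- as.data.frame(features)
  fcols <- setdiff(names(features), req)
  if (length(fcols) == 0L) stop("feature table has no feature columns")
  fm <- features[fcols]
  if (!all(vapply(fm, is.numeric, logical(1))) || anyNA(fm)) {
    stop("every (participant, stimulus) row must have a numeric value for every feature")
  }
  key <- paste(features$participant, features$stimulus, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (participant, stimulus) feature rows")
  features
}

#' Read a wide-format expression feature table
#'
#' CSV with header \code{participant,group,stimulus} followed by one column
#' per feature; each row is one response with a value for every feature.
#'
#' @param path file path.
#' @return validated feature data frame.
#' @export
read_features <- function(path) {
  validate_features(utils::read.csv(path, stringsAsFactors = FALSE,
                                    encoding = "UTF-8"))
}

#' Write a feature table
#'
#' @param features feature data frame.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_features <- function(features, path) {
  features <- validate_features(features)
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a synthetic bundle to a directory
#'
#' Writes \code{ratings_A.csv}, \code{ratings_B.csv}, \code{features_A.csv},
#' \code{features_B.csv} and \code{truth.json} (planted structure, matrices
#' as nested arrays).
#'
#' @param bundle a [simulate_emotion_study()] result.
#' @param dir destination directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ratings(bundle$ratings$a, file.path(dir, "ratings_A.csv"))
  write_ratings(bundle$ratings$b, file.path(dir, "ratings_B.csv"))
  write_features(bundle$features$a, file.path(dir, "features_A.csv"))
  write_features(bundle$features$b, file.path(dir, "features_B.csv"))
  truth <- bundle$truth
  truth$deviations <- NULL    # bulky per-response arrays stay in memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
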