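#' Varimax rotation of component loadings
#'
#' Orthogonally rotates a loadings matrix to maximize the varimax simplicity
#' criterion, \code{sum_j [ mean(L[,j]^4) - mean(L[,j]^2)^2 ]}, so that each
#' rotated dimension loads on as few categories as possible. Kaiser row
#' normalization is off by default, keeping the covariance interpretation of
#' PPCA loadings; set \code{normalize = TRUE} for the normalized variant.
#' After rotation, columns are reordered by decreasing sum of squared
#' loadings and sign-flipped so each column's largest-magnitude loading is
#' positive; the rotation matrix is adjusted to match, so
#' \code{loadings \%*\% rotmat} always reproduces the rotated loadings.
#'
#' @param loadings categories-by-k numeric matrix, k >= 1.
#' @param normalize Kaiser row normalization flag (default \code{FALSE}).
#' @param tol convergence tolerance on the relative criterion gain.
#' @return an object of class \code{"rotated_loadings"}: list with
#'   \code{loadings} (rotated), \code{rotmat} (k x k orthogonal),
#'   \code{criterion} (varimax criterion of the rotated solution), and
#'   \code{labels} (set by [label_dimensions()], initially row-name based).
#' @export
varimax_rotate <- function(loadings, normalize = FALSE, tol = 1e-10) {
  l <- as.matrix(loadings)
  k <- ncol(l)
  if (k < 1L) stop("'loadings' must have at least one column")
  if (k == 1L) {
    rot <- matrix(1, 1, 1)
    out <- l
  } else {
    # the iteration can stall on symmetric saddle points (e.g. an exact
    # 45-degree mixture of a simple structure), so run it from several
    # deterministic starting rotations and keep the best criterion
    rot <- diag(k)
    out <- l
    crit <- -Inf
    for (start in varimax_starts(k)) {
      vr <- stats::varimax(l %*% start, normalize = normalize, eps = tol)
      cand_rot <- start %*% vr$rotmat
      cand <- l %*% cand_rot
      cand_crit <- varimax_criterion(cand)
      if (cand_crit > crit + 1e-12) {
        crit <- cand_crit
        out <- cand
        rot <- cand_rot
      }
    }
  }
  ord <- order(colSums(out^2), decreasing = TRUE)
  out <- out[, ord, drop = FALSE]
  rot <- rot[, ord, drop = FALSE]
  flip <- apply(out, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  out <- sweep(out, 2L, flip, "*")
  rot <- sweep(rot, 2L, flip, "*")
  colnames(out) <- paste0("D", seq_len(k))
  rownames(out) <- rownames(l)
  structure(
    list(loadings = out, rotmat = rot,
         criterion = varimax_criterion(out),
         labels = NULL),
    class = "rotated_loadings")
}

# Internal: deterministic starting rotations (identity plus two fixed
# pseudo-random orthogonal matrices) used to escape saddle points.
varimax_starts <- function(k) {
  mk <- function(offset) {
    m <- outer(seq_len(k), seq_len(k), function(i, j) sin(i * j + offset))
    qr.Q(qr(m + diag(k)))
  }
  list(diag(k), mk(0.3), mk(1.1))
}

#' Varimax simplicity criterion
#'
#' @param loadings a numeric loadings matrix.
#' @return \code{sum_j [ mean(L[,j]^4) - mean(L[,j]^2)^2 ]}.
#' @export
varimax_criterion <- function(loadings) {
  l2 <- as.matrix(loadings)^2
  sum(colMeans(l2^2) - colMeans(l2)^2)
}

#' Name rotated dimensions by their dominant category
#'
#' Labels each rotated dimension with the category (row) on which it loads
#' maximally in absolute value. When two dimensions share a maximal
#' category, both are suffixed with the dimension index and the collision is
#' flagged.
#'
#' @param rotated a [varimax_rotate()] result (or any loadings matrix).
#' @param category_names optional character vector aligned with rows;
#'   defaults to row names.
#' @return for a \code{"rotated_loadings"} input, the object with
#'   \code{labels} and \code{label_collisions} filled in; for a matrix, the
#'   label vector.
#' @export
label_dimensions <- function(rotated, category_names = NULL) {
  l <- if (inherits(rotated, "rotated_loadings")) rotated$loadings else as.matrix(rotated)
  if (is.null(category_names)) category_names <- rownames(l)
  if (is.null(category_names)) category_names <- paste0("cat", seq_len(nrow(l)))
  if (length(category_names) != nrow(l)) {
    stop("'category_names' must align with the loading rows")
  }
  top <- apply(abs(l), 2L, which.max)
  labels <- category_names[top]
  dup <- duplicated(labels) | duplicated(labels, fromLast = TRUE)
  if (any(dup)) {
    labels[dup] <- paste0(labels[dup], ".", which(dup))
  }
  if (inherits(rotated, "rotated_loadings")) {
    rotated$labels <- labels
    rotated$label_collisions <- any(dup)
    rotated
  } else {
    labels
  }
}

#' @export
print.rotated_loadings <- function(x, ...) {
  cat(sprintf("Varimax-rotated loadings: %d categories x %d dimensions\n",
              nrow(x$loadings), ncol(x$loadings)))
  cat(sprintf("  criterion: %.6g\n", x$criterion))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  }
  invisible(x)
}
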