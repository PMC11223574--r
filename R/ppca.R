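#' Sample cross-covariance between two aligned matrices
#'
#' Column-centers both matrices and returns \code{t(Xc) \%*\% Yc / (n - 1)},
#' the sample cross-covariance with the usual \code{n - 1} denominator. Rows
#' of \code{x} and \code{y} must correspond to the same observations
#' (e.g. the same stimuli rated by two groups).
#'
#' @param x numeric matrix, observations in rows.
#' @param y numeric matrix with the same dimensions as \code{x}.
#' @return a \code{ncol(x)} by \code{ncol(y)} cross-covariance matrix.
#' @examples
#' x <- matrix(rnorm(20), 5, 4)
#' all.equal(cross_covariance(x, x), cov(x), check.attributes = FALSE)
#' @export
cross_covariance <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) {
    stop("'x' and 'y' must have identical dimensions (aligned observations)")
  }
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to estimate covariance")
  xc <- sweep(x, 2L, colMeans(x))
  yc <- sweep(y, 2L, colMeans(y))
  crossprod(xc, yc) / (n - 1)
}

#' Principal preserved components analysis
#'
#' Extracts orthonormal directions that maximize the covariance preserved
#' between two parallel datasets measuring the same variables on the same
#' observations (e.g. mean emotion ratings of the same stimuli from two
#' cultural groups). The components are the eigenvectors of the symmetrized
#' cross-covariance matrix \code{R = (Cov(X, Y) + Cov(Y, X)) / 2}; the
#' eigenvalue of each component equals the sample covariance between the two
#' datasets projected onto it, so negative eigenvalues flag directions of
#' covariance with opposite sign in the two datasets. When \code{y = x} the
#' method reduces exactly to principal components analysis of \code{x}.
#'
#' Columns are not variance-standardized: the objective is covariance, not
#' correlation. Standardize beforehand if a correlation-scale analysis is
#' wanted. Each component is sign-flipped so that its largest-magnitude
#' loading is positive, giving deterministic output; eigenvalue-degenerate
#' subspaces are only defined up to rotation.
#'
#' @param x numeric matrix, observations by variables.
#' @param y numeric matrix of the same shape; defaults to \code{x}
#'   (ordinary PCA).
#' @return an object of class \code{"ppca"}: a list with
#'   \item{components}{variables by k orthonormal loading matrix (alpha).}
#'   \item{eigenvalues}{signed eigenvalues, sorted decreasing; the i-th equals
#'     \code{Cov(X alpha_i, Y alpha_i)}.}
#'   \item{R}{the symmetrized cross-covariance matrix.}
#'   \item{center_x, center_y}{column means used for centering.}
#' @seealso [predict.ppca()] to project new data, [preserved_dims()] for
#'   significance testing, [varimax_rotate()] for rotation.
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x + matrix(rnorm(60, sd = 0.5), 20, 3)
#' fit <- ppca(x, y)
#' fit$eigenvalues
#' # eigenvalue identity: lambda_i = Cov(X a_i, Y a_i)
#' diag(cross_covariance(x %*% fit$components, y %*% fit$components))
#' @export
ppca <- function(x, y = x) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) {
    stop("'x' and 'y' must be commensurate: identical dimensions, aligned rows")
  }
  if (nrow(x) < 2L) stop("need at least 2 observations")
  cxy <- cross_covariance(x, y)
  r <- (cxy + t(cxy)) / 2
  e <- eigen(r, symmetric = TRUE)
  a <- e$vectors
  # deterministic sign: largest-magnitude loading of each component positive
  flip <- apply(a, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  a <- sweep(a, 2L, flip, "*")
  vn <- colnames(x)
  if (is.null(vn)) vn <- paste0("v", seq_len(ncol(x)))
  dimnames(a) <- list(vn, paste0("PPC", seq_len(ncol(a))))
  structure(
    list(components = a,
         eigenvalues = e$values,
         R = r,
         center_x = colMeans(x),
         center_y = colMeans(y),
         n = nrow(x),
         call = match.call()),
    class = "ppca")
}

#' @export
print.ppca <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat("Principal preserved components analysis\n")
  cat(sprintf("  %d variables, %d observations\n", nrow(x$components), x$n))
  cat(sprintf("  %d components (%d with negative preserved covariance)\n",
              k, sum(x$eigenvalues < 0)))
  cat("Eigenvalues (preserved covariance per component):\n")
  print(signif(x$eigenvalues, 4), ...)
  invisible(x)
}

#' @export
summary.ppca <- function(object, ...) {
  lam <- object$eigenvalues
  tot <- sum(abs(lam))
  out <- list(eigenvalues = lam,
              share = if (tot > 0) abs(lam) / tot else rep(NA_real_, length(lam)),
              n_negative = sum(lam < 0),
              n = object$n)
  class(out) <- "summary.ppca"
  out
}

#' @export
print.summary.ppca <- function(x, ...) {
  cat("PPCA eigenvalue summary\n")
  m <- rbind(eigenvalue = x$eigenvalues,
             `|share|` = x$share,
             cumulative = cumsum(x$share))
  colnames(m) <- paste0("PPC", seq_along(x$eigenvalues))
  print(signif(m, 3), ...)
  invisible(x)
}

#' @export
coef.ppca <- function(object, ...) object$components

#' Project data onto principal preserved components
#'
#' Centers \code{newdata} (by its own column means, so that held-out raters
#' with different baselines project onto the shared axes) and returns its
#' scores on the first \code{k} components.
#'
#' @param object a fitted [ppca()] object.
#' @param newdata matrix with the same variables (columns) as the fit.
#' @param k number of leading components to use; defaults to all. \code{k = 0}
#'   returns a zero-column matrix.
#' @param center one of \code{"newdata"} (default: subtract newdata's own
#'   column means) or \code{"none"}.
#' @param ... unused.
#' @return a \code{nrow(newdata)} by \code{k} score matrix.
#' @export
predict.ppca <- function(object, newdata, k = NULL,
                         center = c("newdata", "none"), ...) {
  center <- match.arg(center)
  m <- as.matrix(newdata)
  p <- nrow(object$components)
  if (ncol(m) != p) {
    stop(sprintf("'newdata' has %d columns; fit has %d variables", ncol(m), p))
  }
  if (is.null(k)) k <- ncol(object$components)
  if (k > ncol(object$components)) {
    stop(sprintf("k = %d exceeds the %d available components",
                 k, ncol(object$components)))
  }
  if (center == "newdata") m <- sweep(m, 2L, colMeans(m))
  m %*% object$components[, seq_len(k), drop = FALSE]
}

#' @export
plot.ppca <- function(x, ...) {
  lam <- x$eigenvalues
  graphics::plot(seq_along(lam), lam, type = "b", pch = 19,
                 xlab = "component", ylab = "preserved covariance (eigenvalue)",
                 main = "PPCA scree", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
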