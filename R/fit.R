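#' Ordinary least squares fit
#'
#' Solves `min ||y - X b||^2` by QR decomposition (never by explicit
#' inversion of the normal equations). The design must have full column
#' rank; a rank-deficient design raises an error naming the collinear
#' columns.
#'
#' @param X Numeric design matrix (or an `fmri_design`, whose `$X` is used).
#' @param y Response vector or scans x voxels matrix with `nrow(X)` rows.
#' @param qr_cache Optional precomputed `qr(X)` (internal cache used by the
#'   sweep driver).
#' @return Coefficient vector (or coefficient matrix, one column per voxel).
#' @export
fit_ols <- function(X, y, qr_cache = NULL) {
  roles <- NULL
  if (inherits(X, "fmri_design")) { roles <- X$roles; X <- X$X }
  y <- as.matrix(y)
  if (nrow(y) != nrow(X))
    stop("'y' must have as many rows as the design has scans", call. = FALSE)
  qx <- if (is.null(qr_cache)) qr(X) else qr_cache
  p <- ncol(X)
  if (qx$rank < p) {
    bad <- qx$pivot[(qx$rank + 1L):p]
    nm <- if (!is.null(roles)) roles[bad]
          else if (!is.null(colnames(X))) colnames(X)[bad]
          else as.character(bad)
    stop("design matrix is rank deficient; collinear columns: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  if (ncol(y) == 1L) drop(beta) else beta
}

#' Ridge-regularized least squares fit
#'
#' Solves `(X'X + lambda * D) b = X'y`, where `D` is a diagonal matrix with
#' ones for the task (trial or condition) columns and zeros for the
#' constant and other nuisance columns, so that only the parameters of
#' interest are shrunk towards zero. With `lambda = 0` this reproduces
#' [fit_ols()].
#'
#' @param X Design matrix or `fmri_design`. For a bare matrix, all columns
#'   except the last (the constant) are penalized unless `penalize` says
#'   otherwise.
#' @param y Response vector or matrix.
#' @param lambda Non-negative ridge penalty.
#' @param penalize Logical vector marking the penalized columns.
#' @return Coefficient vector (or matrix, one column per voxel).
#' @export
fit_ridge <- function(X, y, lambda, penalize = NULL) {
  if (inherits(X, "fmri_design")) {
    if (is.null(penalize)) penalize <- X$penalize
    X <- X$X
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("'lambda' must be a single non-negative number", call. = FALSE)
  if (is.null(penalize))
    penalize <- c(rep(TRUE, ncol(X) - 1L), FALSE)
  y <- as.matrix(y)
  if (lambda == 0) return(fit_ols(X, y))
  A <- crossprod(X)
  diag(A) <- diag(A) + lambda * as.numeric(penalize)
  beta <- solve(A, crossprod(X, y))
  if (ncol(y) == 1L) drop(beta) else beta
}
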