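#' Radial basis function kernel matrix
#'
#' Computes `K[i, j] = exp(-||A_i - B_j||^2 / sigma2)` between the rows of two
#' feature matrices. Note the convention: the squared distance is divided by
#' `sigma2` directly, with no factor of 2.
#'
#' @param A,B Numeric matrices with the same number of columns (rows are
#'   observations on the normalized feature scale).
#' @param sigma2 Kernel width, > 0.
#' @return A `nrow(A) x nrow(B)` matrix; `rbf_kernel(A, A, s)` is symmetric
#'   with a unit diagonal.
#' @export
rbf_kernel <- function(A, B, sigma2) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("feature dimension mismatch: ", ncol(A), " vs ", ncol(B))
  stopifnot(sigma2 > 0)
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clipped at 0 against roundoff
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma2)
}

#' Fit a least-squares support vector machine
#'
#' Trains an RBF-kernel LSSVM regression by solving the linear system that the
#' Karush-Kuhn-Tucker stationarity conditions reduce to. With kernel matrix
#' `K`, targets `y` and regularization `gamma`, the bordered symmetric system
#'
#' \deqn{\begin{bmatrix} 0 & 1^T \\ 1 & K + I/\gamma \end{bmatrix}
#'       \begin{bmatrix} b \\ a \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ y \end{bmatrix}}
#'
#' is solved by dense direct factorization. The solution satisfies the KKT
#' identities `sum(a) = 0` and `a_k = gamma * e_k` where `e_k` is the training
#' residual. If the system is near-singular (reciprocal condition estimate
#' below `rcond_min`) a warning is emitted and a QR least-squares solve is
#' used instead.
#'
#' @param x Matrix (or data.frame) of normalized training features.
#' @param y Numeric vector of training targets.
#' @param gamma Regularization weight on the squared training errors, > 0.
#'   Large `gamma` approaches interpolation.
#' @param sigma2 RBF kernel width, > 0.
#' @param rcond_min Condition threshold below which the least-squares
#'   fallback is taken (default 1e-14).
#' @return An object of class `lssvm`: list with `alphas`, `bias`, `gamma`,
#'   `sigma2`, the stored `x`, `y`, and `fitted` values.
#' @examples
#' x <- matrix(runif(20), ncol = 2)
#' y <- sin(x[, 1]) + x[, 2]
#' fit <- lssvm_fit(x, y, gamma = 100, sigma2 = 0.5)
#' all.equal(sum(fit$alphas), 0)
#' @export
lssvm_fit <- function(x, y, gamma, sigma2, rcond_min = 1e-14) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  stopifnot(n >= 1L, length(y) == n)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  K <- rbf_kernel(x, x, sigma2)
  M <- matrix(0, n + 1L, n + 1L)
  M[1L, -1L] <- 1
  M[-1L, 1L] <- 1
  M[-1L, -1L] <- K + diag(n) / gamma
  rhs <- c(0, y)
  rc <- rcond(M)
  if (is.finite(rc) && rc > rcond_min) {
    sol <- solve(M, rhs)
  } else {
    warning(sprintf("ill-conditioned KKT system (rcond = %.2e); using least-squares solve", rc))
    sol <- qr.solve(qr(M, LAPACK = TRUE), rhs)
  }
  alphas <- sol[-1L]
  bias <- sol[1L]
  fitted <- as.numeric(K %*% alphas + bias)
  structure(list(alphas = alphas, bias = bias, gamma = gamma,
                 sigma2 = sigma2, x = x, y = y, fitted = fitted),
            class = "lssvm")
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf("LSSVM regression: %d support values, gamma = %.6g, sigma2 = %.6g\n",
              length(x$alphas), x$gamma, x$sigma2))
  cat(sprintf("  bias b = %.6g, training RMSE = %.4g\n",
              x$bias, sqrt(mean((x$y - x$fitted)^2))))
  invisible(x)
}

#' Predict from a fitted LSSVM
#'
#' Evaluates `f(x) = sum_k a_k K(x, x_k) + b` at each row of `newx`.
#'
#' @param object An `lssvm` fit.
#' @param newx Matrix of features on the same normalized scale as training;
#'   defaults to the training inputs.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lssvm <- function(object, newx = object$x, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != ncol(object$x))
    stop("newx has ", ncol(newx), " columns; model expects ", ncol(object$x))
  K <- rbf_kernel(newx, object$x, object$sigma2)
  as.numeric(K %*% object$alphas + object$bias)
}

#' @export
residuals.lssvm <- function(object, ...) object$y - object$fitted

#' @export
fitted.lssvm <- function(object, ...) object$fitted

#' @export
coef.lssvm <- function(object, ...) {
  c(bias = object$bias, alpha = object$alphas)
}
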