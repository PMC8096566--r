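#' Regression statistic suite
#'
#' Computes the standard accuracy statistics for predicted vs observed
#' breakthrough ratios:
#' \itemize{
#'   \item `r2`: 1 - SS_res / SS_tot, with SS_tot about the observed mean;
#'   \item `mae`: mean absolute error; `aad_percent` = 100 * mae, the
#'     percent average absolute deviation conventional in adsorption work
#'     when the output is the dimensionless C/C0;
#'   \item `rmse`, `mse`: root mean squared and mean squared error
#'     (`mse == rmse^2` exactly);
#'   \item `std_resid`: standard deviation of the residuals about their own
#'     mean (population form, 1/N), i.e. the spread of the errors.
#' }
#' `std_printed = TRUE` swaps `std_resid` for the deviation of predictions
#' about the observed mean, a variant that measures prediction spread rather
#' than error spread; it is provided for comparison with sources that tabulate
#' it.
#'
#' @param predicted,observed Equal-length numeric vectors, length >= 2.
#' @param label Partition label carried in the report (e.g. "train").
#' @param std_printed Use the prediction-spread variant of STD (default
#'   FALSE).
#' @return Object of class `stat_report`: list with `r2, mae, rmse, mse,
#'   aad_percent, std_resid, n, label`.
#' @examples
#' regression_stats(c(0.5, 0.7), c(0.4, 0.8))
#' @export
regression_stats <- function(predicted, observed, label = "total",
                             std_printed = FALSE) {
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  if (length(predicted) != length(observed))
    stop("length mismatch: ", length(predicted), " vs ", length(observed))
  n <- length(observed)
  stopifnot(n >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("degenerate observed vector: all values identical")
  e <- observed - predicted
  mse <- mean(e^2)
  mae <- mean(abs(e))
  std <- if (std_printed) {
    sqrt(mean((predicted - mean(observed))^2))
  } else {
    sqrt(mean((e - mean(e))^2))
  }
  structure(list(r2 = 1 - sum(e^2) / ss_tot,
                 mae = mae, rmse = sqrt(mse), mse = mse,
                 aad_percent = 100 * mae, std_resid = std,
                 n = n, label = label),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): R2 = %.4f, %%AAD = %.4f, MSE = %.3e, RMSE = %.4f, STD = %.4f\n",
              x$label, x$n, x$r2, x$aad_percent, x$mse, x$rmse, x$std_resid))
  invisible(x)
}

#' @noRd
stat_report_row <- function(x) {
  data.frame(label = x$label, n = x$n, MSE = x$mse, AAD = x$aad_percent,
             R2 = x$r2, STD = x$std_resid)
}

#' Hat (projection) matrix of a design matrix
#'
#' `H = X (X'X)^-1 X'`, computed by a direct normal-equations solve. The
#' diagonal `h_ii` is each point's leverage. If `X'X` is numerically
#' singular (rank-deficient design), a warning is emitted and the
#' Moore-Penrose pseudo-inverse (via SVD) is used, which still yields the
#' orthogonal projector onto the column space.
#'
#' @param X Numeric design matrix (rows = observations).
#' @return The n x n projection matrix: symmetric, idempotent, diagonal in
#'   \[0, 1\], trace equal to the rank of `X`.
#' @export
hat_matrix <- function(X) {
  X <- as.matrix(X)
  XtX <- crossprod(X)
  inv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(inv) || !is.finite(rcond(XtX)) || rcond(XtX) < 1e-12) {
    warning("rank-deficient design; using pseudo-inverse")
    s <- svd(XtX)
    keep <- s$d > max(s$d) * 1e-12
    inv <- s$v[, keep, drop = FALSE] %*%
      (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  }
  X %*% inv %*% t(X)
}

#' Warning leverage threshold
#'
#' `H* = 3 (f + 1) / p`, the conventional cutoff above which a point is
#' structurally influential in a Williams plot.
#'
#' @param f Number of model input parameters (design-matrix columns).
#' @param p Number of data points.
#' @return The scalar threshold.
#' @examples
#' warning_leverage(4, 204) # 15/204
#' @export
warning_leverage <- function(f, p) {
  stopifnot(f >= 0, p >= 1)
  3 * (f + 1) / p
}

#' Standardized residuals given leverages
#'
#' `R_i = e_i / (s * sqrt(1 - h_ii))` with `e_i = observed_i - predicted_i`
#' and `s` the root mean square of the residuals.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @param hat_diagonals Leverages `h_ii`, each < 1.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(predicted, observed, hat_diagonals) {
  stopifnot(length(predicted) == length(observed),
            length(observed) == length(hat_diagonals))
  if (any(hat_diagonals >= 1))
    stop("exact leverage point: h_ii >= 1 at index ",
         which(hat_diagonals >= 1)[1L])
  e <- observed - predicted
  s <- sqrt(mean(e^2))
  if (s == 0) return(rep(0, length(e)))
  e / (s * sqrt(1 - hat_diagonals))
}

#' Applicability-domain classification by the leverage method
#'
#' Builds the Williams-plot quantities for a set of predictions: leverages
#' from the Hat matrix of the normalized design, standardized residuals, and
#' the warning leverage `H* = 3(f+1)/p`. A point is inside the applicability
#' domain iff `|R_i| <= 3` and `0 < h_ii < H*`; otherwise it is tagged
#' `high_leverage` (h_ii >= H*), `outlier_residual` (|R_i| > 3), or `both`.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @param X Design matrix of (normalized) model inputs, one row per point.
#' @param f Number of model input parameters for the H* formula; defaults to
#'   `ncol(X)` (no intercept column in the design).
#' @return Object of class `leverage_report`: list with `hat_diagonals`,
#'   `std_residuals`, `warning_leverage`, `flags` (factor with the four
#'   levels above), and `counts`.
#' @export
classify_domain <- function(predicted, observed, X, f = ncol(X)) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(predicted))
  h <- diag(hat_matrix(X))
  hstar <- warning_leverage(f, nrow(X))
  R <- standardized_residuals(predicted, observed, h)
  lev_levels <- c("in_domain", "high_leverage", "outlier_residual", "both")
  high <- h >= hstar | h <= 0
  outl <- abs(R) > 3
  flags <- factor(ifelse(high & outl, "both",
                  ifelse(high, "high_leverage",
                  ifelse(outl, "outlier_residual", "in_domain"))),
                  levels = lev_levels)
  structure(list(hat_diagonals = h, std_residuals = R,
                 warning_leverage = hstar, flags = flags,
                 counts = table(flags)),
            class = "leverage_report")
}

#' @export
print.leverage_report <- function(x, ...) {
  n <- length(x$flags)
  n_out <- n - sum(x$flags == "in_domain")
  cat(sprintf("leverage applicability domain: H* = %.5f, %d/%d points in domain (%d outside)\n",
              x$warning_leverage, n - n_out, n, n_out))
  print(x$counts)
  invisible(x)
}

#' Williams plot of a leverage report
#'
#' Standardized residuals against leverage, with the applicability-domain
#' rectangle `|R| <= 3`, `0 < h < H*` drawn; points outside the domain are
#' highlighted.
#'
#' @param x A `leverage_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.leverage_report <- function(x, ...) {
  inside <- x$flags == "in_domain"
  graphics::plot(x$hat_diagonals, x$std_residuals,
                 xlab = "leverage h_ii", ylab = "standardized residual R",
                 pch = ifelse(inside, 1, 19),
                 col = ifelse(inside, "grey30", "red"),
                 ylim = range(c(x$std_residuals, -3.5, 3.5)),
                 xlim = range(c(0, x$hat_diagonals, x$warning_leverage * 1.1)),
                 ...)
  graphics::abline(h = c(-3, 3), lty = 2)
  graphics::abline(v = x$warning_leverage, lty = 2)
  invisible(x)
}
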