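#' Fit a PSO-tuned LSSVM breakthrough-curve model
#'
#' End-to-end estimator for fixed-bed breakthrough data: splits the data into
#' training and test partitions, min-max normalizes the four predictors to
#' \[-1, 1\], tunes the LSSVM hyperparameters `(gamma, sigma2)` by particle
#' swarm optimization, fits the final model on the training partition, and
#' assembles the statistic suite and leverage-based applicability-domain
#' diagnostics over all points.
#'
#' The output C/C0 is left on its natural \[0, 1\] scale by default;
#' `normalize_output = TRUE` maps it to \[-1, 1\] for training and
#' back-transforms predictions before any statistic is computed. The
#' normalizer is fit on the training partition only by default
#' (`normalizer_fit_on = "all"` uses every row, for sensitivity analysis).
#'
#' @param data Data.frame with columns `c0, h0, u, t, ratio` (see
#'   [read_breakthrough()] for units and validation rules).
#' @param train_fraction Training share of the 75/25-style split.
#' @param split_seed Seed for the random partition (default 42).
#' @param split_method `"random"` or `"sequential"`, see
#'   [split_breakthrough()].
#' @param gamma,sigma2 Fix the hyperparameters and skip tuning when both are
#'   supplied.
#' @param pso [pso_control()] settings for the tuner. The default here is a
#'   reduced 30-particle, 100-iteration swarm, which reaches the same
#'   optimum basin as a long run on these two-dimensional landscapes;
#'   pass `pso_control(80, 1000)` for a full-length search.
#' @param objective `"validation"` (inner-fold MSE, default) or `"train"`;
#'   see [tune_lssvm()].
#' @param normalize_output Also normalize the response (default FALSE).
#' @param normalizer_fit_on `"train"` (default) or `"all"`.
#' @return Object of class `btlssvm` with components `model` (the [lssvm_fit()]
#'   object), `spec_x`/`spec_y` (normalizers), `split`, `tuning`, `stats`
#'   (train/test/total `stat_report`s), `leverage` (a `leverage_report` over
#'   all points), `predictions`, and `call`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' d <- simulate_breakthrough(seed = 3)
#' fit <- btlssvm(d, pso = pso_control(10, 20, seed = 3))
#' summary(fit)
#' @export
btlssvm <- function(data, train_fraction = 0.75, split_seed = 42L,
                    split_method = c("random", "sequential"),
                    gamma = NULL, sigma2 = NULL,
                    pso = pso_control(swarm_size = 30L, iterations = 100L),
                    objective = c("validation", "train"),
                    normalize_output = FALSE,
                    normalizer_fit_on = c("train", "all")) {
  cl <- match.call()
  split_method <- match.arg(split_method)
  objective <- match.arg(objective)
  normalizer_fit_on <- match.arg(normalizer_fit_on)
  validate_breakthrough(data)
  features <- c("c0", "h0", "u", "t")

  parts <- split_breakthrough(data, train_fraction, split_seed, split_method)
  fit_data <- if (normalizer_fit_on == "train") parts$train else data
  spec_x <- fit_normalizer(fit_data, features)
  spec_y <- if (normalize_output) fit_normalizer(fit_data, "ratio") else NULL

  norm_x <- function(d) as.matrix(normalize_data(spec_x, d, warn_extrapolation = FALSE))
  norm_y <- function(d) if (normalize_output)
    normalize_data(spec_y, d, warn_extrapolation = FALSE)$ratio else d$ratio
  denorm_y <- function(v) if (normalize_output)
    denormalize_data(spec_y, data.frame(ratio = v))$ratio else v

  x_train <- norm_x(parts$train); y_train <- norm_y(parts$train)

  tuning <- NULL
  if (is.null(gamma) || is.null(sigma2)) {
    tuning <- tune_lssvm(x_train, y_train, objective = objective, control = pso)
    gamma <- tuning$gamma
    sigma2 <- tuning$sigma2
  }
  model <- lssvm_fit(x_train, y_train, gamma = gamma, sigma2 = sigma2)

  pred_part <- function(d) denorm_y(predict(model, norm_x(d)))
  pred_train <- pred_part(parts$train)
  pred_test <- pred_part(parts$test)
  pred_all <- rep(NA_real_, nrow(data))
  pred_all[parts$train_idx] <- pred_train
  pred_all[-parts$train_idx] <- pred_test

  stats <- list(
    train = regression_stats(pred_train, parts$train$ratio, "train"),
    test = regression_stats(pred_test, parts$test$ratio, "test"),
    total = regression_stats(pred_all, data$ratio, "total"))
  leverage <- classify_domain(pred_all, data$ratio, norm_x(data))

  structure(list(model = model, spec_x = spec_x, spec_y = spec_y,
                 normalize_output = normalize_output,
                 split = parts, data = data, tuning = tuning,
                 gamma = gamma, sigma2 = sigma2,
                 predictions = pred_all, stats = stats,
                 leverage = leverage, call = cl),
            class = "btlssvm")
}

#' @export
print.btlssvm <- function(x, ...) {
  cat("PSO-tuned LSSVM breakthrough-curve model\n")
  cat(sprintf("  n = %d (%d train / %d test), gamma = %.6g, sigma2 = %.6g\n",
              nrow(x$data), nrow(x$split$train), nrow(x$split$test),
              x$gamma, x$sigma2))
  cat(sprintf("  test R2 = %.4f, test %%AAD = %.4f\n",
              x$stats$test$r2, x$stats$test$aad_percent))
  invisible(x)
}

#' Summarize a breakthrough-curve model fit
#'
#' @param object A `btlssvm` fit.
#' @param ... Unused.
#' @return Object of class `summary.btlssvm` wrapping a statistics table
#'   with rows MSE, AAD, R2, STD and columns train/test/total, plus the
#'   tuned hyperparameters and the applicability-domain counts.
#' @export
summary.btlssvm <- function(object, ...) {
  tab <- sapply(object$stats, function(s)
    c(MSE = s$mse, AAD = s$aad_percent, R2 = s$r2, STD = s$std_resid))
  colnames(tab) <- c("train", "test", "total")
  n_out <- sum(object$leverage$flags != "in_domain")
  structure(list(table = tab, gamma = object$gamma, sigma2 = object$sigma2,
                 n = nrow(object$data), n_outside_domain = n_out,
                 warning_leverage = object$leverage$warning_leverage,
                 call = object$call),
            class = "summary.btlssvm")
}

#' @export
print.summary.btlssvm <- function(x, ...) {
  cat("PSO-tuned LSSVM breakthrough-curve model\n")
  cat("call: "); print(x$call)
  cat(sprintf("tuned hyperparameters: gamma = %.6g, sigma2 = %.6g\n",
              x$gamma, x$sigma2))
  print(round(x$table, 4))
  cat(sprintf("applicability domain: %d of %d points outside (H* = %.5f)\n",
              x$n_outside_domain, x$n, x$warning_leverage))
  invisible(x)
}

#' Predict breakthrough ratios for new conditions
#'
#' @param object A `btlssvm` fit.
#' @param newdata Data.frame with columns `c0, h0, u, t` in original units;
#'   defaults to the training data. Conditions outside the fitted
#'   normalization range trigger an extrapolation warning, not an error.
#' @param ... Unused.
#' @return Numeric vector of predicted C/C0.
#' @export
predict.btlssvm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predictions)
  xn <- as.matrix(normalize_data(object$spec_x, newdata))
  pred <- predict(object$model, xn)
  if (object$normalize_output)
    pred <- denormalize_data(object$spec_y, data.frame(ratio = pred))$ratio
  pred
}

#' @export
fitted.btlssvm <- function(object, ...) object$predictions

#' @export
residuals.btlssvm <- function(object, ...) object$data$ratio - object$predictions

#' @export
coef.btlssvm <- function(object, ...) {
  list(gamma = object$gamma, sigma2 = object$sigma2,
       bias = object$model$bias, alphas = object$model$alphas)
}

#' Diagnostic plots for a breakthrough-curve model
#'
#' Two panels: predicted vs observed C/C0 (train open, test filled, the
#' `y = x` line dashed) and the Williams plot of the applicability domain.
#'
#' @param x A `btlssvm` fit.
#' @param which Subset of `1:2` selecting panels.
#' @param ... Passed to the panel plots.
#' @export
plot.btlssvm <- function(x, which = 1:2, ...) {
  if (1 %in% which) {
    is_train <- seq_len(nrow(x$data)) %in% x$split$train_idx
    graphics::plot(x$data$ratio, x$predictions,
                   pch = ifelse(is_train, 1, 19),
                   col = ifelse(is_train, "grey40", "steelblue"),
                   xlab = "observed C/C0", ylab = "predicted C/C0", ...)
    graphics::abline(0, 1, lty = 2)
    graphics::legend("topleft", pch = c(1, 19), col = c("grey40", "steelblue"),
                     legend = c("train", "test"), bty = "n")
  }
  if (2 %in% which) plot(x$leverage, ...)
  invisible(x)
}

#' Predicted breakthrough curve at fixed operating conditions
#'
#' Evaluates a fitted model along a time grid at one operating condition
#' `(c0, h0, u)`, the slice used to draw predicted-vs-time breakthrough
#' panels.
#'
#' @param object A `btlssvm` fit (or any object with a conforming
#'   `predict(object, newdata)` method taking original-unit columns
#'   `c0, h0, u, t`).
#' @param c0,h0,u Scalar operating condition, original units.
#' @param t Numeric vector of times (default 100 points spanning the
#'   fitted time range).
#' @return Data.frame with columns `t` and `ratio` (predicted C/C0).
#' @export
condition_slice <- function(object, c0, h0, u, t = NULL) {
  if (is.null(t)) {
    rng <- if (inherits(object, "btlssvm"))
      c(object$spec_x$min[["t"]], object$spec_x$max[["t"]]) else c(0, 100)
    t <- seq(rng[1], rng[2], length.out = 100)
  }
  newdata <- data.frame(c0 = c0, h0 = h0, u = u, t = t)
  data.frame(t = t, ratio = predict(object, newdata))
}

#' Serialize a fitted model to JSON
#'
#' Stores the support values, bias, hyperparameters, normalization specs and
#' (normalized) training inputs, so predictions can be made later without
#' refitting. [read_model_json()] restores a `btlssvm`-classed object whose
#' `predict` method behaves identically.
#'
#' @param object A `btlssvm` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(object, path) {
  stopifnot(inherits(object, "btlssvm"))
  payload <- list(
    alphas = object$model$alphas, bias = object$model$bias,
    gamma = object$gamma, sigma2 = object$sigma2,
    x_train = object$model$x, y_train = object$model$y,
    spec_x = list(min = as.list(object$spec_x$min),
                  max = as.list(object$spec_x$max)),
    spec_y = if (is.null(object$spec_y)) NULL else
      list(min = as.list(object$spec_y$min), max = as.list(object$spec_y$max)),
    normalize_output = object$normalize_output)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a serialized model
#'
#' @param path Path written by [write_model_json()].
#' @return A minimal `btlssvm` object supporting `predict` and
#'   [condition_slice()].
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  x_train <- as.matrix(p$x_train)
  model <- structure(list(alphas = as.numeric(p$alphas), bias = p$bias,
                          gamma = p$gamma, sigma2 = p$sigma2,
                          x = x_train, y = as.numeric(p$y_train),
                          fitted = NULL), class = "lssvm")
  model$fitted <- predict(model, x_train)
  as_spec <- function(s) if (is.null(s)) NULL else
    structure(list(min = unlist(s$min), max = unlist(s$max)),
              class = "minmax_spec")
  structure(list(model = model, spec_x = as_spec(p$spec_x),
                 spec_y = as_spec(p$spec_y),
                 normalize_output = isTRUE(p$normalize_output),
                 gamma = p$gamma, sigma2 = p$sigma2,
                 call = quote(read_model_json())),
            class = "btlssvm")
}
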