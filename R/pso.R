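#' Particle swarm optimizer settings
#'
#' Defaults follow the constriction-equivalent parametrization (inertia
#' 0.7298, cognitive = social = 1.49618), which gives stable convergence
#' without velocity explosion; swarm size and iteration count default to the
#' values used for the breakthrough-curve tuning study (80 particles, 1000
#' iterations).
#'
#' @param swarm_size Number of particles, >= 2.
#' @param iterations Number of update sweeps, >= 1.
#' @param inertia Inertia weight w on the previous velocity.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param vmax_frac Velocity clamp as a fraction of each dimension's range.
#' @param seed Integer seed; same seed gives a bitwise-identical trajectory.
#' @return A list of class `pso_control`.
#' @export
pso_control <- function(swarm_size = 80L, iterations = 1000L,
                        inertia = 0.7298, c1 = 1.49618, c2 = 1.49618,
                        vmax_frac = 0.2, seed = 1L) {
  stopifnot(swarm_size >= 2L, iterations >= 1L, vmax_frac > 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, c1 = c1, c2 = c2,
                 vmax_frac = vmax_frac, seed = as.integer(seed)),
            class = "pso_control")
}

#' Minimize a function by particle swarm optimization
#'
#' Standard global-best PSO: each particle's velocity is updated as
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with uniform random
#' `r1, r2` drawn per dimension, then positions move by `v`. Positions are
#' clamped to the bounds with the corresponding velocity component zeroed;
#' velocities are clamped to `vmax_frac` of each dimension's range.
#' Non-finite objective values are treated as a large penalty rather than an
#' error, so a rough objective (e.g. one with occasional solver failures)
#' can still be searched.
#'
#' @param fn Objective, called as `fn(par)` with a numeric vector, returning
#'   a scalar to minimize.
#' @param lower,upper Numeric vectors of per-dimension bounds.
#' @param control A [pso_control()] list.
#' @return List with `par` (best position), `value` (best objective), and
#'   `trace`, a data.frame with one row per iteration of the best-so-far
#'   objective and position (non-increasing in `value`).
#' @examples
#' res <- pso_optimize(function(p) sum((p - c(3, 2))^2),
#'                     lower = c(0, 0), upper = c(10, 10),
#'                     control = pso_control(20, 100, seed = 7))
#' res$par
#' @export
pso_optimize <- function(fn, lower, upper, control = pso_control()) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  ns <- control$swarm_size
  range_ <- upper - lower
  vmax <- control$vmax_frac * range_
  penalty <- 1e10

  eval_fn <- function(p) {
    v <- tryCatch(fn(p), error = function(e) penalty)
    if (!is.finite(v)) penalty else v
  }

  with_seed(control$seed, {
    pos <- matrix(stats::runif(ns * d), ns, d)
    pos <- sweep(sweep(pos, 2, range_, "*"), 2, lower, "+")
    vel <- matrix(stats::runif(ns * d, -1, 1), ns, d)
    vel <- sweep(vel, 2, vmax, "*")

    pbest <- pos
    pbest_val <- apply(pos, 1, eval_fn)
    if (all(pbest_val >= penalty))
      stop("objective unevaluable everywhere on the bounds")
    gi <- which.min(pbest_val)
    gbest <- pbest[gi, ]
    gbest_val <- pbest_val[gi]

    trace <- data.frame(iteration = seq_len(control$iterations),
                        value = NA_real_)
    trace_par <- matrix(NA_real_, control$iterations, d)

    for (it in seq_len(control$iterations)) {
      r1 <- matrix(stats::runif(ns * d), ns, d)
      r2 <- matrix(stats::runif(ns * d), ns, d)
      vel <- control$inertia * vel +
        control$c1 * r1 * (pbest - pos) +
        control$c2 * r2 * (sweep(-pos, 2, gbest, "+"))
      vel <- pmin(pmax(vel, matrix(-vmax, ns, d, byrow = TRUE)),
                  matrix(vmax, ns, d, byrow = TRUE))
      pos <- pos + vel
      low_m <- matrix(lower, ns, d, byrow = TRUE)
      up_m <- matrix(upper, ns, d, byrow = TRUE)
      out_of_bounds <- pos < low_m | pos > up_m
      vel[out_of_bounds] <- 0
      pos <- pmin(pmax(pos, low_m), up_m)

      vals <- apply(pos, 1, eval_fn)
      improved <- vals < pbest_val
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_val[improved] <- vals[improved]
      gi <- which.min(pbest_val)
      if (pbest_val[gi] < gbest_val) {
        gbest_val <- pbest_val[gi]
        gbest <- pbest[gi, ]
      }
      trace$value[it] <- gbest_val
      trace_par[it, ] <- gbest
    }
    colnames(trace_par) <- paste0("par", seq_len(d))
    list(par = gbest, value = gbest_val, trace = cbind(trace, trace_par))
  })
}

#' Tune LSSVM hyperparameters by particle swarm optimization
#'
#' Searches `(gamma, sigma2)` on the log10 scale, minimizing the mean squared
#' error of an LSSVM fit. By default the MSE is measured on an inner
#' validation fold (20% of the supplied training rows, drawn with a fixed
#' seed): measuring on the training points themselves drives `gamma` toward
#' the degenerate interpolation optimum. `objective = "train"` restores the
#' training-MSE objective for comparison.
#'
#' @param x Matrix of normalized training features.
#' @param y Numeric vector of training targets.
#' @param objective `"validation"` (default) or `"train"`.
#' @param bounds_log10_gamma,bounds_log10_sigma2 Search brackets on the
#'   log10 scale; defaults span gamma in \[1e-2, 1e8\] and sigma2 in
#'   \[1e-3, 1e3\].
#' @param control A [pso_control()]; the swarm seed also seeds the inner
#'   validation split.
#' @param val_fraction Fraction of rows held out for the inner fold.
#' @return List with `gamma`, `sigma2`, `mse` (best objective) and the PSO
#'   `trace` (with `gamma`/`sigma2` columns on the natural scale).
#' @export
tune_lssvm <- function(x, y, objective = c("validation", "train"),
                       bounds_log10_gamma = c(-2, 8),
                       bounds_log10_sigma2 = c(-3, 3),
                       control = pso_control(), val_fraction = 0.2) {
  objective <- match.arg(objective)
  x <- as.matrix(x)
  n <- nrow(x)
  if (objective == "validation") {
    n_val <- max(2L, round(n * val_fraction))
    val_idx <- with_seed(control$seed + 1L, sort(sample.int(n, n_val)))
    x_fit <- x[-val_idx, , drop = FALSE]; y_fit <- y[-val_idx]
    x_val <- x[val_idx, , drop = FALSE];  y_val <- y[val_idx]
  } else {
    x_fit <- x; y_fit <- y
    x_val <- x; y_val <- y
  }
  obj <- function(p) {
    fit <- suppressWarnings(
      lssvm_fit(x_fit, y_fit, gamma = 10^p[1], sigma2 = 10^p[2]))
    mean((predict(fit, x_val) - y_val)^2)
  }
  res <- pso_optimize(obj,
                      lower = c(bounds_log10_gamma[1], bounds_log10_sigma2[1]),
                      upper = c(bounds_log10_gamma[2], bounds_log10_sigma2[2]),
                      control = control)
  trace <- res$trace
  trace$gamma <- 10^trace$par1
  trace$sigma2 <- 10^trace$par2
  list(gamma = 10^res$par[1], sigma2 = 10^res$par[2],
       mse = res$value, trace = trace)
}
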