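#' Noiseless logistic breakthrough front
#'
#' Model curve used by the synthetic generator: a fixed-bed breakthrough
#' front is a monotone sigmoid in run time whose midpoint shifts with the
#' operating conditions,
#' \deqn{C/C_0(t) = \frac{1}{1 + e^{-k (t - t_{50})}}, \qquad
#'       t_{50} = \frac{a\, h_0}{u\, c_0^{\beta}}.}
#' The midpoint `t50` grows with bed height (more capacity to saturate),
#' shrinks with flow velocity (faster loading), and, for `beta > 0`, shrinks
#' with feed concentration. This mimics the qualitative behaviour of
#' mechanistic fronts (Thomas, Yoon-Nelson) in a closed form.
#'
#' @param t Run time (min), vectorized.
#' @param c0 Initial concentration (mg/L), > 0.
#' @param h0 Bed height (cm), > 0.
#' @param u Flow velocity, > 0.
#' @param a Midpoint scale (default 700).
#' @param beta Concentration exponent >= 0 (default 0.5).
#' @param k Front steepness > 0 (default 0.05 per min).
#' @return C/C0 in (0, 1); exactly 0.5 at `t = t50`.
#' @export
breakthrough_curve <- function(t, c0, h0, u, a = 700, beta = 0.5, k = 0.05) {
  stopifnot(a > 0, beta >= 0, k > 0, all(c0 > 0), all(h0 > 0), all(u > 0))
  t50 <- a * h0 / (u * c0^beta)
  1 / (1 + exp(-k * (t - t50)))
}

#' Simulate a breakthrough-curve dataset
#'
#' Generates the Cartesian product of a condition grid (c0 x h0 x u) with a
#' time grid, evaluates the logistic front [breakthrough_curve()] at every
#' point, and adds Gaussian noise truncated to \[0, 1\]. The defaults emulate
#' a 204-point study design: 12 operating conditions (h0 in \{7, 11\} cm,
#' u in \{80, 160, 240\}, c0 in \{8, 24\} mg/L) each sampled at 17 times over
#' \[0, 100\] min, with noise sd 0.01 on the dimensionless ratio.
#'
#' @param c0,h0,u Numeric vectors of condition-grid levels.
#' @param t Numeric vector of sampling times (>= 2 values).
#' @param a,beta,k Front parameters, see [breakthrough_curve()].
#' @param noise_sd Standard deviation of additive Gaussian noise on C/C0
#'   (>= 0); the noisy ratio is clipped to \[0, 1\].
#' @param seed Integer seed; same seed gives a bitwise-identical dataset.
#' @return Data.frame with columns `c0, h0, u, t, ratio` and attribute
#'   `"true_ratio"` holding the noiseless curve (handy for recovery checks).
#' @examples
#' d <- simulate_breakthrough(seed = 1)
#' nrow(d) # 204
#' @export
simulate_breakthrough <- function(c0 = c(8, 24), h0 = c(7, 11),
                                  u = c(80, 160, 240),
                                  t = seq(0, 100, length.out = 17),
                                  a = 700, beta = 0.5, k = 0.05,
                                  noise_sd = 0.01, seed = 1L) {
  stopifnot(length(c0) >= 1L, length(h0) >= 1L, length(u) >= 1L,
            length(t) >= 2L, noise_sd >= 0)
  grid <- expand.grid(t = t, u = u, h0 = h0, c0 = c0,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("c0", "h0", "u", "t")]
  truth <- breakthrough_curve(grid$t, grid$c0, grid$h0, grid$u,
                              a = a, beta = beta, k = k)
  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(nrow(grid), sd = noise_sd))
  else rep(0, nrow(grid))
  grid$ratio <- pmin(pmax(truth + noise, 0), 1)
  rownames(grid) <- NULL
  attr(grid, "true_ratio") <- truth
  grid
}
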