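test_that("statistic suite reproduces the hand-worked two-point example", {
  s <- regression_stats(c(0.5, 0.7), c(0.4, 0.8))
  # residuals (-0.1, 0.1): SS_res = 0.02, SS_tot = 0.08
  expect_equal(s$mae, 0.1)
  expect_equal(s$mse, 0.01)
  expect_equal(s$rmse, 0.1)
  expect_equal(s$aad_percent, 10)
  expect_equal(s$r2, 0.75)
  expect_equal(s$mse, s$rmse^2, tolerance = 1e-12)
})

test_that("statistic suite edge cases: perfect fit and null model", {
  obs <- c(0.2, 0.5, 0.9, 0.4)
  perfect <- regression_stats(obs, obs)
  expect_equal(perfect$r2, 1)
  expect_equal(c(perfect$mae, perfect$rmse, perfect$mse, perfect$aad_percent,
                 perfect$std_resid), rep(0, 5))

  null_model <- regression_stats(rep(mean(obs), 4), obs)
  expect_equal(null_model$r2, 0)

  expect_error(regression_stats(1:3, 1:4), "length mismatch")
  expect_error(regression_stats(c(1, 2), c(0.5, 0.5)), "degenerate")
})

test_that("statistics transform correctly under shift and scale", {
  set.seed(13)
  obs <- runif(30); pred <- obs + rnorm(30, sd = 0.1)
  base <- regression_stats(pred, obs)
  shifted <- regression_stats(pred + 5, obs + 5)
  for (f in c("mae", "rmse", "mse", "std_resid", "r2"))
    expect_equal(shifted[[f]], base[[f]], tolerance = 1e-12)
  scaled <- regression_stats(3 * pred, 3 * obs)
  expect_equal(scaled$mae, 3 * base$mae, tolerance = 1e-12)
  expect_equal(scaled$rmse, 3 * base$rmse, tolerance = 1e-12)
  expect_equal(scaled$std_resid, 3 * base$std_resid, tolerance = 1e-12)
  expect_equal(scaled$r2, base$r2, tolerance = 1e-12)
})

test_that("printed-variant STD measures prediction spread, not error spread", {
  obs <- c(0.1, 0.4, 0.8); pred <- c(0.15, 0.38, 0.85)
  s <- regression_stats(pred, obs, std_printed = TRUE)
  expect_equal(s$std_resid, sqrt(mean((pred - mean(obs))^2)))
})

test_that("hat matrix matches hand and QR oracles and is a projector", {
  X1 <- matrix(c(1, 2), 2, 1)
  H1 <- hat_matrix(X1)  # X'X = 5
  expect_equal(H1, matrix(c(0.2, 0.4, 0.4, 0.8), 2, 2))
  expect_equal(sum(diag(H1)), 1)

  # orthonormal columns: H = QQ', trace = k
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  expect_equal(sum(diag(hat_matrix(Q))), 3, tolerance = 1e-10)

  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(80), 20, 4)
    H <- hat_matrix(X)
    H_qr <- tcrossprod(qr.Q(qr(X)))  # independent QR-based projector
    expect_equal(H, H_qr, tolerance = 1e-10)
    expect_equal(H, t(H), tolerance = 1e-10)
    expect_equal(H %*% H, H, tolerance = 1e-8)        # idempotent
    expect_true(all(diag(H) >= -1e-12 & diag(H) <= 1 + 1e-12))
    expect_equal(sum(diag(H)), qr(X)$rank, tolerance = 1e-8)
  }

  # rank-deficient design falls back to the pseudo-inverse projector
  Xd <- cbind(1:6, (1:6) * 2)
  expect_warning(Hd <- hat_matrix(Xd), "rank-deficient")
  expect_equal(sum(diag(Hd)), 1, tolerance = 1e-8)
  expect_equal(Hd %*% Hd, Hd, tolerance = 1e-8)
})

test_that("warning leverage follows 3(f+1)/p", {
  expect_equal(warning_leverage(4, 204), 15 / 204)
  expect_equal(warning_leverage(0, 3), 1)
  expect_equal(warning_leverage(4, 408), warning_leverage(4, 204) / 2)
})

test_that("standardized residuals match a hand loop and reduce correctly", {
  obs <- c(0.2, 0.5, 0.9)
  expect_equal(standardized_residuals(obs, obs, rep(0.1, 3)), rep(0, 3))

  set.seed(17)
  pred <- runif(10); obsv <- pred + rnorm(10, sd = 0.05)
  h <- runif(10, 0, 0.5)
  e <- obsv - pred
  s <- sqrt(mean(e^2))
  by_hand <- numeric(10)
  for (i in 1:10) by_hand[i] <- e[i] / (s * sqrt(1 - h[i]))
  expect_equal(standardized_residuals(pred, obsv, h), by_hand,
               tolerance = 1e-12)
  # zero leverage reduces to plain standardization
  expect_equal(standardized_residuals(pred, obsv, rep(0, 10)), e / s,
               tolerance = 1e-12)
  expect_error(standardized_residuals(pred, obsv, c(rep(0.1, 9), 1)),
               "leverage point")
})

test_that("applicability-domain classification flags the right points", {
  set.seed(19)
  X <- matrix(rnorm(40), 20, 2)
  obs <- runif(20)
  pred <- obs + rnorm(20, sd = 0.02)
  rep0 <- classify_domain(pred, obs, X)
  expect_s3_class(rep0, "leverage_report")
  expect_equal(rep0$warning_leverage, warning_leverage(2, 20))
  # every point gets exactly one label
  expect_equal(sum(rep0$counts), 20)
  expect_equal(length(rep0$flags), 20)

  # one grossly mispredicted point becomes the single residual outlier
  pred_bad <- pred
  pred_bad[7] <- obs[7] + 1
  rep1 <- classify_domain(pred_bad, obs, X)
  expect_gt(abs(rep1$std_residuals[7]), 3)
  expect_equal(as.character(rep1$flags[7]), "outlier_residual")
  expect_equal(unname(rep1$counts[["outlier_residual"]]), 1)

  # a far-out design point is flagged by leverage
  X2 <- rbind(X, c(25, 25))
  o2 <- c(obs, 0.5); p2 <- c(pred, 0.5 + 1e-3)
  rep2 <- classify_domain(p2, o2, X2)
  expect_true(rep2$flags[21] %in% c("high_leverage", "both"))
})
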