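# Independently transcribed coefficient table (A, B, C, D, E, F per node),
# kept as a literal fixture so a typo in the network constructor cannot
# silently propagate.
gmdh_coef_fixture <- list(
  z1 = c(0.183, 0.149, 0.165, -0.242, -0.048, 0.678),
  z2 = c(0.141, -1.6, -0.21, -0.028, 2.76, -0.167),
  z3 = c(0.182, -1.606, -0.124, -0.075, 2.778, -0.167),
  z4 = c(-0.002, -1.64, 0.172, -0.169, 2.684, -0.075),
  w1 = c(-0.253, 0.248, -0.319, -0.05, 0.948, -0.044),
  w2 = c(4.923, 0.234, -0.057, -5.738, 0.794, 1.676),
  w3 = c(2.915, 0.237, -0.535, -2.733, 1.097, 0.577),
  u1 = c(-0.802, -1.248, 1.972, 0.419, 0.666, -0.011),
  u2 = c(1.433, 1.571, -3.077, 0.603, 0.48, -0.014),
  out = c(-0.802, -1.24, -1.972, 0.419, 0.666, -0.011))

test_that("network coefficients match the transcription fixture digit-for-digit", {
  net <- gmdh_network()
  flat <- unlist(lapply(net$layers, function(l) lapply(l, `[[`, "coef")),
                 recursive = FALSE)
  names(flat) <- sub("^layers\\.", "", names(flat))
  for (nm in names(gmdh_coef_fixture))
    expect_identical(unname(flat[[nm]]), gmdh_coef_fixture[[nm]], label = nm)
  # fixed wiring
  wiring <- lapply(unlist(net$layers, recursive = FALSE), `[[`, "inputs")
  expect_equal(unname(wiring),
               list(c(1L, 2L), c(2L, 4L), c(3L, 4L), c(1L, 4L),
                    c(1L, 2L), c(1L, 3L), c(1L, 4L),
                    c(1L, 2L), c(2L, 3L), c(1L, 2L)))
})

test_that("quadratic nodes reproduce hand-computed values", {
  net <- gmdh_network()
  z1 <- net$layers[[1]]$z1$coef
  z2 <- net$layers[[1]]$z2$coef
  expect_equal(gmdh_node_eval(z1, 0, 0), 0.678)   # constant term only
  expect_equal(gmdh_node_eval(z2, 0, 0), -0.167)
  # z1(1,1): sum of all six printed coefficients
  expect_equal(gmdh_node_eval(z1, 1, 1), 0.885)
  # generic point against the explicit polynomial
  expect_equal(gmdh_node_eval(z2, 0.3, -0.7),
               0.141 * 0.09 - 1.6 * 0.49 - 0.21 * 0.3 * (-0.7) -
                 0.028 * 0.3 + 2.76 * (-0.7) - 0.167)
})

test_that("zero input propagates layer constants through the network", {
  # hand propagation: at x = 0 each layer-1 node returns its constant term
  z <- c(0.678, -0.167, -0.167, -0.075)
  poly <- function(cf, p, q)
    cf[1] * p^2 + cf[2] * q^2 + cf[3] * p * q + cf[4] * p + cf[5] * q + cf[6]
  w <- c(poly(gmdh_coef_fixture$w1, z[1], z[2]),
         poly(gmdh_coef_fixture$w2, z[1], z[3]),
         poly(gmdh_coef_fixture$w3, z[1], z[4]))
  u <- c(poly(gmdh_coef_fixture$u1, w[1], w[2]),
         poly(gmdh_coef_fixture$u2, w[2], w[3]))
  expected <- poly(gmdh_coef_fixture$out, u[1], u[2])

  got <- predict(gmdh_network(), matrix(0, 1, 4))
  expect_equal(got, expected, tolerance = 1e-14)
})

test_that("prediction is pure, batch-consistent, and shape-checked", {
  net <- gmdh_network()
  set.seed(6)
  X <- matrix(runif(204 * 4, -1, 1), 204, 4)
  batch <- predict(net, X)
  rowwise <- vapply(seq_len(nrow(X)),
                    function(i) predict(net, X[i, , drop = FALSE]), numeric(1))
  expect_identical(batch, rowwise)
  expect_identical(batch, predict(net, X))  # referential transparency
  # two identical rows give identical outputs
  expect_identical(batch[c(1, 1)], predict(net, X[c(1, 1), ]))
  expect_error(predict(net, X[, 1:3]), "4 input columns")
})

test_that("the layer3 output variant differs only in the output node", {
  net_p <- gmdh_network("printed")
  net_l <- gmdh_network("layer3")
  expect_identical(net_p$layers[1:3], net_l$layers[1:3])
  expect_identical(net_l$layers[[4]]$out$coef,
                   net_l$layers[[3]]$u1$coef)
  X <- matrix(seq(-1, 1, length.out = 20), 5, 4)
  expect_false(identical(predict(net_p, X), predict(net_l, X)))
})

test_that("evaluate_gmdh computes the statistic suite under a chosen convention", {
  d <- simulate_breakthrough(seed = 8)
  rep_n <- evaluate_gmdh(d)
  expect_s3_class(rep_n, "stat_report")
  expect_equal(rep_n$n, nrow(d))
  expect_length(attr(rep_n, "predictions"), nrow(d))
  # raw scaling and reordering change the result
  rep_raw <- evaluate_gmdh(d, scaling = "raw")
  rep_perm <- evaluate_gmdh(d, ordering = c(4, 2, 3, 1))
  expect_false(isTRUE(all.equal(rep_n$mse, rep_raw$mse)))
  expect_false(isTRUE(all.equal(rep_n$mse, rep_perm$mse)))
  expect_error(evaluate_gmdh(d, ordering = c(1, 1, 2, 3)))
})

test_that("convention search recovers a known generating convention", {
  # build targets FROM the network itself under a hidden convention, then
  # check that the search ranks that convention first when asked to match
  # its own statistics
  d <- simulate_breakthrough(seed = 12, noise_sd = 0)
  hidden <- c(2L, 3L, 1L, 4L)
  spec <- fit_normalizer(d, c("c0", "h0", "u", "t"))
  X <- as.matrix(normalize_data(spec, d))
  pred <- predict(gmdh_network(), X[, hidden])
  d$ratio <- pmin(pmax(pred, 0), 1.05)
  target <- evaluate_gmdh(d, ordering = hidden)
  search <- gmdh_convention_search(
    d, reference = c(aad = target$aad_percent, r2 = target$r2,
                     mse = target$mse, std = target$std_resid))
  expect_equal(nrow(search), 24 * 2 * 2)  # all conventions evaluated
  expect_equal(search$ordering[1], paste(hidden, collapse = ""))
  expect_equal(search$scaling[1], "normalized")
  expect_equal(search$variant[1], "printed")
  expect_equal(search$distance[1], 0, tolerance = 1e-12)
  expect_true(!is.unsorted(search$distance))
})
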