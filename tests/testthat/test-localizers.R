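# The affine forward mode gives algebraically exact ground truth: waveforms
# are affine in position with a per-lead orthogonal design, so QIM/DEM/DDM
# should recover positions to numerical precision on noiseless data.

cfg <- affine_config()
ds <- make_dataset(cfg)
sites <- ds$sites

test_that("QIM recovers held-out sites exactly on affine data", {
  fit <- fit_qim(sites[1:6])
  for (i in c(8, 15, 22)) {
    tgt <- sites[[i]]
    onset <- detect_qrs_onset(tgt$representative)
    p <- predict_qim(fit, qrs_integrals(tgt$representative, onset))
    expect_lt(dist3(p$position, tgt$position), 1e-6)
    expect_false(p$diagnostics$rank_deficient)
  }
  # in-sample exactness under an exact fit
  tr <- sites[[2]]
  p <- predict_qim(fit, qrs_integrals(tr$representative,
                                      detect_qrs_onset(tr$representative)))
  expect_lt(dist3(p$position, tr$position), 1e-6)
})

test_that("QIM needs 5 sites and flags rank-deficient designs", {
  expect_error(fit_qim(sites[1:4]), "at least 5")

  # collinear pacing positions make the integral predictors collinear too
  base <- c(0, 0, 44.9)
  line_sites <- lapply(1:6, function(i) {
    pos <- base + (i - 1) * c(1.5, 0, -0.4)
    affine_site_at(pos, cfg, sprintf("L%d", i))
  })
  fit <- fit_qim(line_sites)
  expect_true(fit$rank_deficient)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("QIM equals a hand-rolled normal-equations solve", {
  set.seed(31)
  rsites <- lapply(1:8, function(i) {
    pacing_site(sprintf("R%d", i), runif(3, -20, 20), list(random_beat()))
  })
  fit <- fit_qim(rsites)
  X <- cbind(1, t(sapply(rsites, function(s) {
    as.numeric(qrs_integrals(s$representative,
                             detect_qrs_onset(s$representative)))
  })))
  Y <- t(sapply(rsites, function(s) s$position))
  beta <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(fit$coefficients, t(beta), ignore_attr = TRUE,
               tolerance = 1e-8)
  q <- c(0.4, -1.2, 2.0)
  expect_equal(predict_qim(fit, q)$position,
               as.numeric(t(beta) %*% c(1, q)), tolerance = 1e-8)

  # zero slopes: intercepts are returned for any input
  fit0 <- fit
  fit0$coefficients <- cbind(c(1, 2, 3), matrix(0, 3, 3))
  expect_equal(predict_qim(fit0, c(9, -9, 99))$position, c(1, 2, 3))
})

test_that("through-origin slope fit matches closed form and a grid search", {
  m <- c(1, 2, 3)
  expect_equal(fit_scalar_distance(m, 2 * m)$k, 2)
  expect_equal(fit_scalar_distance(0.5, 7)$k, 14)
  expect_error(fit_scalar_distance(c(0, 0), c(1, 2)), "zero")

  set.seed(32)
  for (i in 1:10) {
    met <- runif(10, 0.1, 3)
    d <- 2.7 * met + rnorm(10, sd = 0.3)
    k_hat <- fit_scalar_distance(met, d)$k
    grid <- seq(0.1, 6, by = 1e-4)
    sse <- vapply(grid, function(k) sum((d - k * met)^2), numeric(1))
    expect_lt(abs(k_hat - grid[which.min(sse)]), 1e-4 + 1e-8)
  }
})

test_that("multilateration recovers a point from exact distances", {
  anchors <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0), c(10, 10, 35))
  truth <- c(12, 18, 9)
  d <- apply(anchors, 1, function(a) dist3(a, truth))
  p <- multilaterate(anchors, d)
  expect_lt(dist3(p$position, truth), 1e-6)
  expect_lt(p$diagnostics$cost, 1e-10)

  expect_error(multilaterate(anchors[1:2, ], d[1:2]), "at least 3")
})

test_that("coplanar anchors give one of the two mirror solutions", {
  anchors <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0))  # z = 0 plane
  truth <- c(10, 8, 12)
  mirror <- c(10, 8, -12)
  d <- apply(anchors, 1, function(a) dist3(a, truth))
  p <- multilaterate(anchors, d)
  expect_lt(min(dist3(p$position, truth), dist3(p$position, mirror)), 1e-5)
  expect_lt(p$diagnostics$cost, 1e-10)
})

test_that("all-zero distances give the minimizer of summed squared distances", {
  set.seed(33)
  anchors <- matrix(runif(12, 0, 50), 4, 3)
  p <- multilaterate(anchors, rep(0, 4))
  # J = sum ||x - a_i||^2 is minimized at the centroid (direct optimization)
  expect_lt(dist3(p$position, colMeans(anchors)), 1e-6)
})

test_that("DEM is exact when E12 is exactly proportional to distance", {
  modeling <- sites[c(3, 7, 11, 18)]
  tgt <- sites[[20]]
  p <- predict_dem(modeling, tgt$splice)
  expect_lt(dist3(p$position, tgt$position), 1e-3)

  # target coincides with a modeling site: zero distance anchors the solve
  p2 <- predict_dem(modeling, modeling[[2]]$splice)
  expect_lt(dist3(p2$position, modeling[[2]]$position), 1e-3)

  # the internal slope equals fit_scalar_distance on the pairwise pairs
  m3 <- sites[c(1, 2, 3)]
  p3 <- predict_dem(m3, tgt$splice)
  pairs <- combn(3, 2)
  met <- apply(pairs, 2, function(ij) e12(m3[[ij[1]]]$splice,
                                          m3[[ij[2]]]$splice))
  dd <- apply(pairs, 2, function(ij) dist3(m3[[ij[1]]]$position,
                                           m3[[ij[2]]]$position))
  expect_equal(p3$diagnostics$k, fit_scalar_distance(met, dd)$k)
})

test_that("DCM estimates zero distance to an identical waveform", {
  modeling <- sites[c(3, 7, 11, 18)]
  p <- predict_dcm(modeling, modeling[[1]]$splice)
  expect_equal(p$diagnostics$d_hat[[1]], 0, tolerance = 1e-9)
  expect_gt(p$diagnostics$k, 0)  # k2 positive on non-degenerate training
})

test_that("DDM recovers in-plane targets to machine precision", {
  m3 <- sites[c(2, 9, 16)]
  P <- t(sapply(m3, function(s) s$position))
  # target inside the modeling sites' affine span
  q <- P[1, ] + 0.3 * (P[2, ] - P[1, ]) + 0.45 * (P[3, ] - P[1, ])
  tgt <- affine_site_at(q, cfg)
  p <- predict_ddm(m3, tgt$splice)
  expect_lt(dist3(p$position, q), 1e-9)

  # with 4+ non-coplanar sites any target is recovered exactly
  m4 <- sites[c(2, 9, 16, 23)]
  p4 <- predict_ddm(m4, sites[[12]]$splice)
  expect_lt(dist3(p4$position, sites[[12]]$position), 1e-9)
})

test_that("DDM maps a modeling site's own waveform to its position", {
  m3 <- sites[c(4, 10, 19)]
  p <- predict_ddm(m3, m3[[2]]$splice)
  expect_lt(dist3(p$position, m3[[2]]$position), 1e-9)
})

test_that("DDM projects out-of-plane targets onto the modeling plane", {
  m3 <- sites[c(2, 9, 16)]
  P <- t(sapply(m3, function(s) s$position))
  q <- sites[[24]]$position
  p <- predict_ddm(m3, sites[[24]]$splice)
  # closed-form orthogonal projection of q onto the modeling plane
  U <- qr.Q(qr(cbind(P[2, ] - P[1, ], P[3, ] - P[1, ])))
  center <- colMeans(P)
  proj <- center + U %*% crossprod(U, q - center)
  expect_lt(dist3(p$position, as.numeric(proj)), 1e-8)
})

test_that("all four localizers are equivariant under rigid translation", {
  shift <- c(13, -8, 21)
  modeling <- sites[c(3, 7, 11, 18, 21)]
  tgt <- sites[[14]]
  translated <- lapply(modeling, function(s) {
    s$position <- s$position + shift
    s
  })
  for (model in c("QIM", "DEM", "DCM", "DDM")) {
    p0 <- predict_origin(model, modeling, tgt)
    p1 <- predict_origin(model, translated, tgt)
    expect_equal(p1$position, p0$position + shift, tolerance = 1e-5)
  }
})

test_that("more noiseless modeling sites never hurt DDM on affine data", {
  tgt <- sites[[25]]
  errs <- sapply(4:8, function(m) {
    dist3(predict_ddm(sites[1:m], tgt$splice)$position, tgt$position)
  })
  expect_true(all(diff(errs) <= 1e-9))
})
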