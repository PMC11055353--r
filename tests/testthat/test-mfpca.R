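test_that("mean and day-shift estimates honor exact symmetric cases", {
  Tn <- 10
  X <- matrix(3, 6, Tn)
  mask <- matrix(TRUE, 6, Tn)
  day_order <- rep(1:2, 3)
  ms <- estimate_mean_and_shift(X, mask, day_order)
  expect_equal(ms$mu, rep(3, Tn))
  expect_equal(ms$eta, matrix(0, 2, Tn))

  X2 <- matrix(rep(c(4, 2), 3), 6, Tn)  # day 1 rows = 4, day 2 rows = 2
  ms2 <- estimate_mean_and_shift(X2, mask, day_order)
  expect_equal(ms2$mu, rep(3, Tn))
  expect_equal(ms2$eta[1, ], rep(1, Tn))
  expect_equal(ms2$eta[2, ], rep(-1, Tn))

  mask[, 4] <- FALSE
  expect_error(estimate_mean_and_shift(X, mask, day_order), "t = 4")
})

test_that("mean estimate converges to the truth on simulated curves", {
  truth <- default_curve_truth(B = 10, profile = "recovery")
  sim <- simulate_curves(truth, n = 500, days_per_subject = 2, seed = 13)
  ms <- estimate_mean_and_shift(sim$curves, sim$mask, sim$index$day_order)
  # pointwise sd ~ sqrt(total variance)/sqrt(rows); allow 5 x
  se <- sqrt(sum(truth$lambda1) + sum(truth$lambda2) + truth$noise_sd^2) /
    sqrt(nrow(sim$curves))
  expect_lt(max(abs(ms$mu - truth$mean_fn)), 5 * se)
})

test_that("covariance decomposition recovers a rank-1 between structure", {
  Tn <- triangular_length(8)
  basis <- make_fourier_eigenbasis(3, Tn)
  truth <- curve_truth(mean_fn = rep(0, Tn),
                       phi1 = basis[, 2, drop = FALSE], lambda1 = 2,
                       phi2 = basis[, 3, drop = FALSE], lambda2 = 0,
                       noise_sd = 0)
  sim <- simulate_curves(truth, n = 300, days_per_subject = 3, seed = 17)
  cov <- estimate_covariances(sim$curves, sim$mask, sim$subject,
                              sim$index$day_order)
  eb <- eigendecompose_level(cov$K_between)
  expect_equal(eb$values[1], 2, tolerance = 0.1)
  expect_gt(cs_abs(eb$functions[1, ], basis[, 2]), 0.99)
  # K_between carries essentially all structure: K_within stays negligible
  expect_lt(max(abs(cov$K_within)), 0.1 * max(abs(cov$K_between)))
  expect_lt(cov$sigma2, 0.02)
  # additivity holds by construction
  expect_equal(cov$K_between + cov$K_within, cov$K_total, tolerance = 1e-12)
})

test_that("pure noise yields a flat total surface and sigma2 near 1", {
  Tn <- triangular_length(8)
  basis <- make_fourier_eigenbasis(2, Tn)
  truth <- curve_truth(mean_fn = rep(0, Tn),
                       phi1 = basis[, 1, drop = FALSE], lambda1 = 0,
                       phi2 = basis[, 2, drop = FALSE], lambda2 = 0,
                       noise_sd = 1)
  sim <- simulate_curves(truth, n = 200, days_per_subject = 3, seed = 19)
  cov <- estimate_covariances(sim$curves, sim$mask, sim$subject,
                              sim$index$day_order)
  off <- cov$K_total[upper.tri(cov$K_total)]
  expect_lt(mean(abs(off)), 0.02)
  expect_equal(cov$sigma2, 1, tolerance = 0.1)

  # fully deterministic rows: every surface identically zero
  truth0 <- curve_truth(mean_fn = rep(5, Tn),
                        phi1 = basis[, 1, drop = FALSE], lambda1 = 0,
                        phi2 = basis[, 2, drop = FALSE], lambda2 = 0,
                        noise_sd = 0)
  sim0 <- simulate_curves(truth0, n = 5, days_per_subject = 2, seed = 1)
  cov0 <- estimate_covariances(sim0$curves, sim0$mask, sim0$subject,
                               sim0$index$day_order)
  expect_equal(max(abs(cov0$K_total)), 0)
  expect_equal(max(abs(cov0$K_between)), 0)
  expect_equal(cov0$sigma2, 0)
})

test_that("eigendecomposition matches a direct solver and fixes signs", {
  Tn <- 40
  basis <- make_fourier_eigenbasis(4, Tn)
  phi <- basis[, 2]
  e <- eigendecompose_level(2 * tcrossprod(phi))
  expect_equal(length(e$values), 1L)
  expect_equal(e$values[1], 2, tolerance = 1e-10)
  expect_equal(abs(sum(e$functions[1, ] * phi)), 1, tolerance = 1e-10)
  i <- which.max(abs(e$functions[1, ]))
  expect_gt(e$functions[1, i], 0)

  # random rank-3 PSD surface vs base eigen() oracle
  set.seed(42)
  Q <- qr.Q(qr(matrix(rnorm(Tn * 3), Tn, 3)))
  K <- Q %*% diag(c(5, 2, 1)) %*% t(Q)
  e3 <- eigendecompose_level(K)
  oracle <- eigen(K, symmetric = TRUE)
  expect_equal(e3$values[1:3], oracle$values[1:3], tolerance = 1e-8)
  for (k in 1:3)
    expect_equal(abs(sum(e3$functions[k, ] * oracle$vectors[, k])), 1,
                 tolerance = 1e-8)
  expect_error(eigendecompose_level(matrix(c(1, 2, 0, 1), 2, 2)),
               "symmetric")
})

test_that("pooled-greedy component selection follows the 90% rule", {
  # traced by hand: shares 5/10 then 9/10 >= 0.9 stops after two pooled
  # components -> one per level
  sel <- select_components(5, c(4, 1), total_pve = 0.90)
  expect_equal(sel, list(N1 = 1L, N2 = 1L))
  # level-2 floor: a level with a negligible eigenvalue still retains one
  sel2 <- select_components(c(9, 1), 1e-4, total_pve = 0.90)
  expect_equal(sel2$N2, 1L)
  expect_equal(select_components(c(1, 1), c(1, 1), total_pve = 1),
               list(N1 = 2L, N2 = 2L))
  expect_error(select_components(0, 0), "all-zero")
})

test_that("BLUP scores reduce to projections without noise and shrink with it", {
  truth <- default_curve_truth(B = 10, profile = "recovery", noise_sd = 0)
  sim <- simulate_curves(truth, n = 20, days_per_subject = 3, seed = 23)
  model <- truth_model(truth, sim)
  model$sigma2 <- 0
  sc <- estimate_scores(model, sim$curves, sim$mask)
  expect_equal(unname(sc$scores1), unname(sim$scores1), tolerance = 1e-6)
  expect_equal(unname(sc$scores2), unname(sim$scores2), tolerance = 1e-6)

  # single-component shrinkage: |BLUP| <= |projection| entrywise
  Tn <- length(truth$mean_fn)
  b1 <- make_fourier_eigenbasis(2, Tn)
  tr1 <- curve_truth(mean_fn = rep(0, Tn), phi1 = b1[, 1, drop = FALSE],
                     lambda1 = 1, phi2 = b1[, 2, drop = FALSE],
                     lambda2 = 0.5, noise_sd = 2)
  s1 <- simulate_curves(tr1, n = 15, days_per_subject = 2, seed = 3)
  m_noise <- truth_model(tr1, s1)
  m_proj <- m_noise; m_proj$sigma2 <- 0
  blup <- estimate_scores(m_noise, s1$curves, s1$mask)
  proj <- estimate_scores(m_proj, s1$curves, s1$mask)
  expect_true(all(abs(blup$scores1) <= abs(proj$scores1) + 1e-12))

  bad_mask <- s1$mask
  bad_mask[s1$index$participant == "S001", ] <- FALSE
  expect_error(estimate_scores(m_noise, s1$curves, bad_mask),
               "zero observed")
})

test_that("reconstruction stages are nested and reproduce noiseless data", {
  truth <- default_curve_truth(B = 10, profile = "recovery", noise_sd = 0)
  sim <- simulate_curves(truth, n = 10, days_per_subject = 2, seed = 29)
  model <- truth_model(truth, sim)
  model$sigma2 <- 0
  sc <- estimate_scores(model, sim$curves, sim$mask)
  model$scores1 <- sc$scores1
  model$scores2 <- sc$scores2

  s1a <- reconstruct(model, "S001", 1, stage = 1)
  s1b <- reconstruct(model, "S007", 2, stage = 1)
  expect_identical(s1a, s1b)  # stage 1 is the overall mean for everyone

  s3 <- reconstruct(model, "S004", 2, stage = 3)
  s4 <- reconstruct(model, "S004", 2, stage = 4)
  diff <- s4 - s3
  P2 <- t(model$phi2)
  resid <- diff - P2 %*% crossprod(P2, diff)
  expect_lt(max(abs(resid)), 1e-8)  # stage increment lies in span(phi2)

  row <- which(sim$index$participant == "S004" & sim$index$day_order == 2)
  expect_equal(s4, unname(sim$curves[row, ]), tolerance = 1e-6)
  expect_error(reconstruct(model, "S099", 1), "unknown")
})

test_that("fitted reconstruction RSS decreases across stages", {
  truth <- default_curve_truth(B = 10, profile = "recovery")
  sim <- simulate_curves(truth, n = 80, days_per_subject = 3, seed = 31)
  fit <- mfpca(sim)
  rss <- sapply(2:4, function(st) {
    sum(vapply(seq_len(nrow(sim$curves)), function(r) {
      fitc <- reconstruct(fit, sim$index$participant[r],
                          sim$index$day_order[r], stage = st)
      sum((sim$curves[r, ] - fitc)^2)
    }, numeric(1)))
  })
  expect_true(all(diff(rss) <= 0))
})

test_that("variance summary reports within-level shares and rho", {
  truth <- default_curve_truth(B = 8, profile = "recovery")
  sim <- simulate_curves(truth, n = 10, days_per_subject = 2, seed = 1)
  model <- truth_model(truth, sim)
  model$lambda1_full <- c(3, 1); model$lambda2_full <- 4
  vs <- variance_summary(model)
  expect_equal(attr(vs, "rho"), 0.5)
  expect_equal(vs$prop_within_level[1:2], c(0.75, 0.25))
  model$lambda2_full <- numeric(0)
  expect_equal(attr(variance_summary(model), "rho"), 1)
})

test_that("fitted eigenfunctions are orthonormal within each level", {
  truth <- default_curve_truth(B = 10)
  sim <- simulate_curves(truth, n = 100, days_per_subject = 3, seed = 37)
  fit <- mfpca(sim)
  expect_equal(tcrossprod(fit$phi1), diag(fit$N1), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tcrossprod(fit$phi2), diag(fit$N2), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$lambda1) <= 0))
  expect_true(all(diff(fit$lambda2) <= 0))
  expect_gte(fit$rho, 0); expect_lte(fit$rho, 1)
})
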