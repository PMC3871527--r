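test_that("all model orders are causal and vanish for a zero AIF", {
  spec <- acq_spec()
  zero <- plasma_curve(frame_times(spec), rep(0, spec$n_frames))
  for (ord in 1:3)
    expect_true(all(forward_model(ord, 0.03, 0.02, 0.3, zero) == 0))
  expect_error(forward_model(4, 0.03, aif = zero), "order")
  expect_error(forward_model(3, 0.03, 0.02, kep = -1, aif = zero), "kep")
})

test_that("Patlak model integrates a constant AIF in closed form", {
  # Cp = 1 mM over 10 min; Ktrans = 0.01 /min, vp = 0 gives Ct(10 min) = 0.1
  t <- seq(0, 600, by = 4)
  cp <- plasma_curve(t, rep(1, length(t)))
  ct <- forward_model(2, vp = 0, ktrans = 0.01, aif = cp)
  expect_equal(ct[length(t)], 0.1, tolerance = 1e-12)
})

test_that("extended Tofts collapses to Patlak as kep tends to zero", {
  spec <- acq_spec()
  aif <- make_aif(spec)
  m2 <- forward_model(2, 0.03, 0.02, aif = aif)
  m3 <- forward_model(3, 0.03, 0.02, kep = 1e-10, aif = aif)
  expect_lt(max(abs(m2 - m3)), 1e-9)
})

test_that("a pure-vp curve is recovered exactly by the order-1 fit", {
  spec <- acq_spec()
  aif <- make_aif(spec)
  ct <- 0.03 * aif$cp
  fit <- fit_pk_models(ct, aif)
  expect_equal(fit$vp1, 0.03, tolerance = 1e-12)
  expect_lt(fit$sse1, 1e-20)
})

test_that("noiseless Patlak recovery matches a normal-equations oracle", {
  spec <- acq_spec()
  aif <- make_aif(spec)
  ct <- forward_model(2, 0.03, 0.015, aif = aif)
  fit <- fit_pk_models(ct, aif)
  expect_equal(fit$vp2, 0.03, tolerance = 1e-8)
  expect_equal(fit$kt2, 0.015, tolerance = 1e-8)
  # independent oracle: solve the normal equations in R
  X <- cbind(aif$cp, r_cumtrapz(aif$cp, diff(aif$time_s)[1] / 60))
  beta <- solve(t(X) %*% X, t(X) %*% ct)
  expect_equal(fit$vp2, beta[1], tolerance = 1e-8)
  expect_equal(fit$kt2, beta[2], tolerance = 1e-8)
})

test_that("noiseless extended-Tofts recovery is exact across the 27-point grid", {
  spec <- acq_spec()
  aif <- make_aif(spec)
  grid <- param_grid_27()
  ct <- sapply(seq_len(nrow(grid)), function(i)
    forward_model(3, grid$vp[i], grid$ktrans[i], grid$kep[i], aif))
  fit <- fit_pk_models(ct, aif)
  expect_lt(max(abs(fit$vp3 / grid$vp - 1)), 1e-4)
  expect_lt(max(abs(fit$kt3 / grid$ktrans - 1)), 1e-4)
  expect_lt(max(abs(fit$kep3 / grid$kep - 1)), 1e-4)
})

test_that("fits are invariant to rescaling Cp and Ct by the same factor", {
  spec <- acq_spec()
  aif <- make_aif(spec)
  set.seed(14)
  ct <- forward_model(3, 0.02, 0.02, 0.4, aif) +
    rnorm(spec$n_frames, 0, 1e-3)
  f1 <- fit_pk_models(ct, aif)
  aif2 <- plasma_curve(aif$time_s, 3.7 * aif$cp, aif$provenance)
  f2 <- fit_pk_models(3.7 * ct, aif2)
  # invariance up to the bounded-search tolerance of the kep refinement
  expect_equal(f1$vp3, f2$vp3, tolerance = 1e-5)
  expect_equal(f1$kt3, f2$kt3, tolerance = 1e-5)
  expect_equal(f1$kep3, f2$kep3, tolerance = 1e-5)
  expect_equal(f1$vp2, f2$vp2, tolerance = 1e-12)
  expect_equal(f1$kt2, f2$kt2, tolerance = 1e-12)
})

test_that("SSE nesting holds voxelwise on noisy data", {
  spec <- acq_spec()
  aif <- make_aif(spec)
  set.seed(10)
  n <- 500
  base <- forward_model(3, 0.02, 0.02, 0.3, aif)
  ct <- matrix(base, spec$n_frames, n) +
    matrix(rnorm(spec$n_frames * n, 0, 0.003), spec$n_frames, n)
  fit <- fit_pk_models(ct, aif)
  expect_true(all(fit$sse1 - fit$sse2 >= -1e-12))
  expect_true(all(fit$sse2 - fit$sse3 >= -1e-12))
  expect_true(all(fit$sse1u - fit$sse2u >= -1e-12))
  expect_true(all(fit$sse2u - fit$sse3u >= -1e-12))
})

test_that("the ve = Ktrans/kep identity holds in every emitted result", {
  spec <- acq_spec()
  aif <- make_aif(spec)
  set.seed(2)
  ct <- matrix(forward_model(3, 0.02, 0.03, 0.4, aif), spec$n_frames, 50) +
    matrix(rnorm(spec$n_frames * 50, 0, 0.002), spec$n_frames, 50)
  fit <- fit_pk_models(ct, aif)
  expect_identical(fit$ve3, fit$kt3 / fit$kep3)
})

test_that("median parameter bias is small at SNR 30", {
  spec <- acq_spec()
  aif <- make_aif(spec)
  set.seed(77)
  n <- 500
  truth <- list(vp = 0.02, kt = 0.025, kep = 0.25)
  base <- forward_model(3, truth$vp, truth$kt, truth$kep, aif)
  # concentration-domain noise scaled to peak tissue signal over 30
  sdn <- max(base) / 30
  ct <- matrix(base, spec$n_frames, n) +
    matrix(rnorm(spec$n_frames * n, 0, sdn), spec$n_frames, n)
  fit <- fit_pk_models(ct, aif)
  expect_lt(abs(median(fit$kt3) / truth$kt - 1), 0.05)
  expect_lt(abs(median(fit$kep3) / truth$kep - 1), 0.10)
})

test_that("unfittable inputs are rejected", {
  spec <- acq_spec()
  zero <- plasma_curve(frame_times(spec), rep(0, spec$n_frames))
  expect_error(fit_pk_models(rep(0, spec$n_frames), zero), "zero")
  aif <- make_aif(spec)
  expect_error(fit_pk_models(rep(0, 10), aif), "grids differ")
})
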