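test_that("default cohort design matches the study layout", {
  d <- cohort_design()
  expect_equal(sum(d$group_sizes), 31L)
  expect_equal(d$group_hours, c(2, 4, 8, 12, 24))
  st <- d$shift_table
  expect_equal(st$ktrans_mean[st$group_h == 2], 0.0050)
  expect_equal(st$ktrans_mean[st$group_h == 24], -0.0039)
  expect_equal(st$ve_mean[st$group_h == 8], 0)
})

test_that("zero-mean zero-SD shift leaves the retest truth identical", {
  st <- default_shift_table()
  st[, grep("_mean$|_sd$", names(st))] <- 0
  d <- cohort_design(group_sizes = rep(1L, 5L), shift_table = st)
  set.seed(1)
  tr <- make_ground_truth(d, acq_spec())
  expect_identical(tr[[1]]$test, tr[[1]]$retest)
})

test_that("a fixed Ktrans shift moves every model-3 voxel by exactly that amount", {
  st <- default_shift_table()
  st[, grep("_mean$|_sd$", names(st))] <- 0
  st$ktrans_mean <- 0.0050
  d <- cohort_design(group_sizes = rep(1L, 5L), shift_table = st)
  set.seed(1)
  tr <- make_ground_truth(d, acq_spec())
  for (an in tr) {
    m3 <- an$test$model == 3L
    expect_true(all(abs((an$retest$ktrans[m3] - an$test$ktrans[m3]) -
                          0.0050) < 1e-12))
    # shift applies only to model-3 voxels
    expect_identical(an$retest$ktrans[!m3], an$test$ktrans[!m3])
  }
})

test_that("drawn shift means converge to the configured group means", {
  d <- cohort_design()
  set.seed(99)
  draws <- replicate(1000, {
    s <- draw_cohort_shifts(d)
    mean(s$d_ktrans[s$group_h %in% c(2, 4)])
  })
  # SE of each cohort mean is sd/sqrt(13); the 1000-rep average is far tighter
  se <- 0.0050 / sqrt(13) / sqrt(1000)
  expect_lt(abs(mean(draws) - 0.0050), 4 * se)
})

test_that("same seed reproduces ground truth and signals bit-identically", {
  d <- small_design(1L)
  spec <- acq_spec()
  aif <- make_aif(spec)
  gen <- function() {
    set.seed(7)
    tr <- make_ground_truth(d, spec)
    synthesize_signals(tr[[1]]$test, aif, spec, noise_sd = 3)
  }
  s1 <- gen(); s2 <- gen()
  expect_identical(s1$echo1, s2$echo1)
  expect_identical(s1$ll_pre, s2$ll_pre)
})

test_that("signals are nonnegative and pre-bolus frames are stationary", {
  d <- small_design(1L)
  spec <- acq_spec()
  set.seed(3)
  tr <- make_ground_truth(d, spec)
  st <- synthesize_signals(tr[[1]]$test, make_aif(spec), spec, noise_sd = 3)
  expect_true(all(st$echo1 >= 0))
  expect_true(all(st$echo2 >= 0))
  nv <- prod(spec$grid_dim)
  e1 <- matrix(st$echo1, nv, spec$n_frames)
  fg <- rowMeans(e1[, 2:14]) > 15
  # pre-bolus frame means agree across frames (no drift before injection)
  frame_means <- colMeans(e1[fg, 1:14])
  expect_lt(max(abs(frame_means - mean(frame_means))) / mean(frame_means),
            0.02)
})

test_that("noiseless signal is constant over time when no contrast arrives", {
  truth <- truth_voxels(vp = 0, ktrans = 0, kep = NA, model = 1L)
  spec <- spec_voxels(1L)
  st <- synthesize_signals(truth, make_aif(spec), spec, noise_sd = 0)
  s <- as.vector(st$echo1)
  expect_lt(diff(range(s)), 1e-9 * mean(s))
})

test_that("echo attenuation follows exp(-TE R2*): 2:1 ratio at R2* = ln2/2ms", {
  truth <- truth_voxels(vp = 0, ktrans = 0, kep = NA, model = 1L)
  spec <- spec_voxels(1L)
  tissue <- default_tissue_properties()
  tissue$r2s[] <- log(2) / 0.002
  st <- synthesize_signals(truth, make_aif(spec), spec, noise_sd = 0,
                           tissue = tissue)
  expect_equal(st$echo2[1, 1, 1, 1] / st$echo1[1, 1, 1, 1], 0.5,
               tolerance = 1e-12)
})

test_that("Rician noise at high SNR leaves the mean signal within 2% of truth", {
  truth <- truth_voxels(vp = rep(0.02, 2000), ktrans = 0.02, kep = 0.2)
  spec <- spec_voxels(2000L, n_frames = 20L, bolus_frame = 15L)
  aif <- make_aif(spec)
  clean <- synthesize_signals(truth, aif, spec, noise_sd = 0)
  set.seed(11)
  sd <- noise_sd_for_snr(spec, 25)
  noisy <- synthesize_signals(truth, aif, spec, noise_sd = sd)
  ratio <- mean(noisy$echo1) / mean(clean$echo1)
  expect_lt(abs(ratio - 1), 0.02)
})

test_that("negative noise SD is rejected", {
  truth <- truth_voxels(0.02, 0.02, 0.2)
  spec <- spec_voxels(1L)
  expect_error(synthesize_signals(truth, make_aif(spec), spec, noise_sd = -1),
               "nonnegative")
})
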