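#' Synthesize the MR signal series of one imaging session
#'
#' Computes the noiseless dual-echo dynamic signal from the ground-truth
#' kinetic maps and the plasma curve, plus the companion Look-Locker
#' inversion-recovery series and the two-point diffusion pair, and applies
#' Rician noise.
#'
#' The dynamic signal follows spoiled gradient-echo steady-state physics
#' with a time-varying longitudinal rate
#' \deqn{R_1(t) = R_{1,pre} + r_1 C_t(t),}
#' \deqn{S(TE, t) = S_0 \sin\alpha \frac{1 - e^{-TR \cdot R_1(t)}}{1 - \cos\alpha\, e^{-TR \cdot R_1(t)}} e^{-TE \cdot R_2^*}.}
#' The tissue curve Ct(t) is generated by [forward_model()] from each
#' voxel's model order and parameters. The Look-Locker series uses the
#' three-parameter magnitude model |A - B exp(-TI/T1*)| with the apparent
#' rate 1/T1* = 1/T1 - ln(cos(beta))/tau (readout flip beta, echo spacing
#' tau) and amplitudes chosen so that the standard correction
#' T1 = T1* (B/A - 1) is exact. Diffusion signals are monoexponential in b.
#'
#' Rician noise replaces each magnitude S by sqrt((S + n1)^2 + n2^2) with
#' n1, n2 ~ N(0, sd). `noise_sd = 0` returns noiseless data.
#'
#' @param truth Ground-truth maps for one session (see [make_ground_truth()]).
#' @param aif A `plasma_curve` on the acquisition grid.
#' @param spec An [acq_spec()].
#' @param noise_sd Rician noise SD in signal units (>= 0).
#' @param tissue Optional list overriding the per-zone tissue properties:
#'   `t1` (s), `r2s` (s^-1), `adc` (mm2/s), `s0` scalar proton-density gain.
#' @return A `dynamic_study`: list with 4D arrays `echo1`, `echo2`
#'   (x,y,z,frame), `ll_pre`, `ll_post` (x,y,z,TI), `dwi` (x,y,z,b),
#'   the true `t1_pre` map, `spec`, `aif` and the noise level.
#' @export
synthesize_signals <- function(truth, aif, spec = acq_spec(), noise_sd = 0,
                               tissue = default_tissue_properties()) {
  validate_acq_spec(spec)
  stopifnot(inherits(aif, "plasma_curve"))
  if (noise_sd < 0) stop("noise SD must be nonnegative")
  if (!all(dim(truth$model) == spec$grid_dim))
    stop("truth grid does not match acquisition grid")
  if (length(aif$time_s) != spec$n_frames)
    stop("AIF not sampled on the acquisition grid")

  dimg <- spec$grid_dim
  nt <- spec$n_frames
  nv <- prod(dimg)
  zone <- as.vector(truth$zone)

  t1_pre <- array(tissue$t1[zone], dimg)
  r2s    <- array(tissue$r2s[zone], dimg)
  adc    <- array(tissue$adc[zone], dimg)
  s0     <- ifelse(zone == "background", 0, tissue$s0)

  # tissue concentration; voxels sharing (model, vp, ktrans, kep) share a curve
  key <- paste(truth$model, truth$vp, truth$ktrans, truth$kep)
  ct <- matrix(0, nv, nt)
  for (k in unique(key[zone != "background"])) {
    idx <- which(key == k & zone != "background")
    i1 <- idx[1]
    ord <- truth$model[i1]
    curve <- if (ord == 0L) rep(0, nt) else
      forward_model(ord,
                    vp = truth$vp[i1], ktrans = truth$ktrans[i1],
                    kep = truth$kep[i1], aif = aif)
    ct[idx, ] <- matrix(curve, length(idx), nt, byrow = TRUE)
  }

  r1 <- 1 / as.vector(t1_pre)
  r1[zone == "background"] <- 0
  r1t <- matrix(r1, nv, nt) + spec$r1 * ct
  sig <- s0 * spgr_signal(r1t, spec$tr, spec$flip_deg)
  e1 <- sig * exp(-spec$te1 * as.vector(r2s))
  e2 <- sig * exp(-spec$te2 * as.vector(r2s))

  # Look-Locker: apparent rate shortened by the readout
  ti <- inversion_times(spec)
  kappa <- -log(cos(spec$ll_flip_deg * pi / 180)) / spec$ll_tau
  ll_series <- function(t1_map, gain) {
    t1v <- as.vector(t1_map)
    t1s <- 1 / (1 / t1v + kappa)
    A <- gain * t1s / t1v
    B <- A * (1 + t1v / t1s)
    S <- abs(outer(A, rep(1, length(ti))) -
               outer(B, rep(1, length(ti))) * exp(-outer(1 / t1s, ti)))
    S[as.vector(t1_map) <= 0 | gain == 0, ] <- 0
    S
  }
  ll_pre <- ll_series(t1_pre, s0)
  # post-contrast T1 from the final-frame concentration (recorded, unused
  # by the default pipeline)
  r1_post <- r1 + spec$r1 * ct[, nt]
  t1_post <- array(ifelse(r1_post > 0, 1 / r1_post, 0), dimg)
  ll_post <- ll_series(t1_post, s0)

  dwi <- cbind(s0 * exp(-spec$b_values[1] * as.vector(adc)),
               s0 * exp(-spec$b_values[2] * as.vector(adc)))
  dwi[zone == "background", ] <- 0

  rician <- function(m) {
    if (noise_sd == 0) return(m)
    sqrt((m + rnorm(length(m), 0, noise_sd))^2 +
           rnorm(length(m), 0, noise_sd)^2)
  }
  study <- list(
    echo1 = array(rician(e1), c(dimg, nt)),
    echo2 = array(rician(e2), c(dimg, nt)),
    ll_pre = array(rician(ll_pre), c(dimg, length(ti))),
    ll_post = array(rician(ll_post), c(dimg, length(ti))),
    dwi = array(rician(dwi), c(dimg, 2L)),
    t1_pre = t1_pre, adc_true = adc, r2s_true = r2s,
    spec = spec, aif = aif, noise_sd = noise_sd
  )
  class(study) <- "dynamic_study"
  study
}

#' @rdname synthesize_signals
#' @export
default_tissue_properties <- function() {
  z <- c("background", "contralateral", "periphery", "body", "core")
  list(
    t1  = setNames(c(0, 1.7, 2.0, 2.2, 2.8), z),
    r2s = setNames(c(0, 25, 30, 30, 20), z),
    adc = setNames(c(0, 0.70e-3, 1.1e-3, 0.9e-3, 1.3e-3), z),
    s0  = 1000
  )
}

#' Rician noise sd for a target baseline SNR
#'
#' SNR is defined on the first-echo pre-contrast signal of tumor-body
#' tissue: sd = S_baseline / snr.
#'
#' @param spec An [acq_spec()].
#' @param snr Target signal-to-noise ratio (> 0).
#' @param tissue Tissue property list, see [default_tissue_properties()].
#' @return Noise SD in signal units.
#' @export
noise_sd_for_snr <- function(spec, snr, tissue = default_tissue_properties()) {
  if (snr <= 0) stop("SNR must be positive")
  s <- tissue$s0 * spgr_signal(1 / tissue$t1[["body"]], spec$tr, spec$flip_deg) *
    exp(-spec$te1 * tissue$r2s[["body"]])
  s / snr
}
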