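#' Split a dual-echo acquisition into S0 and R2*
#'
#' The two echoes of the 2GE readout differ only in T2* weighting, so per
#' voxel and frame
#' \deqn{R_2^* = \ln(S_1/S_2)/(TE_2 - TE_1), \qquad S_0 = S_1 e^{TE_1 R_2^*},}
#' i.e. S0 is the signal extrapolated to TE = 0, free of susceptibility
#' weighting. Noise can make S2 exceed S1 on isolated frames; such frames
#' get R2* clamped to 0 (with a warning). If the inversion is systematic
#' (more than half the frames of a voxel), the voxel is flagged invalid.
#'
#' @param s1,s2 First- and second-echo signals: vectors, matrices
#'   (frames x voxels) or equal-dimension arrays; must be positive where
#'   valid.
#' @param te1,te2 Echo times (s), `te2 > te1`.
#' @return List with `s0`, `r2s` (same shape as input) and logical
#'   `valid` per voxel (for matrix input) or per element otherwise.
#' @export
dual_echo_split <- function(s1, s2, te1, te2) {
  if (te2 <= te1) stop("need TE2 > TE1")
  if (!all(dim(s1) == dim(s2)) || length(s1) != length(s2))
    stop("echo arrays must have identical shape")
  pos <- s1 > 0 & s2 > 0
  r2s <- array(NA_real_, dim = dim(s1) %||% length(s1))
  r2s[pos] <- log(s1[pos] / s2[pos]) / (te2 - te1)
  neg <- !is.na(r2s) & r2s < 0
  if (any(neg)) {
    r2s[neg] <- 0
    warning(sprintf("%d frame(s) with S2 >= S1; R2* clamped to 0", sum(neg)))
  }
  s0 <- s1 * exp(te1 * r2s)
  valid <- if (is.matrix(s1)) {
    colMeans(neg | !pos) <= 0.5
  } else {
    !(neg | !pos)
  }
  list(s0 = s0, r2s = r2s, valid = valid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert TE=0 signal series to contrast-agent concentration
#'
#' Inverts the spoiled gradient-echo steady-state signal equation per frame
#' for R1(t). The voxel scale factor (proton density times receive gain) is
#' fixed from the baseline-window mean together with the pre-contrast T1,
#' then
#' \deqn{C_t(t) = (R_1(t) - R_{1,pre}) / r_1.}
#'
#' Frames whose signal falls outside the invertible domain of the signal
#' equation are flagged and filled by linear interpolation from neighbouring
#' frames; voxels with more than `max_flagged_frac` flagged frames are
#' excluded (all-NA curve, `valid = FALSE`).
#'
#' @param s0 TE=0 extrapolated signal, frames x voxels matrix (or vector).
#' @param t1_pre Pre-contrast T1 (s) per voxel (vector; NA excludes voxel).
#' @param spec An [acq_spec()] (TR, flip angle, r1, baseline window).
#' @param baseline_frames Frames used as the pre-contrast reference; the
#'   default skips frame 1 (steady-state settling) and stops before the
#'   injection frame.
#' @param max_flagged_frac Maximum tolerated fraction of flagged frames.
#' @return List: `ct` (mM, frames x voxels), `r1` (s^-1), `valid` per
#'   voxel, `n_flagged` per voxel.
#' @export
signal_to_concentration <- function(s0, t1_pre, spec,
                                    baseline_frames = seq(2, spec$bolus_frame - 1),
                                    max_flagged_frac = 0.1) {
  if (is.vector(s0)) s0 <- matrix(s0, ncol = 1)
  nt <- nrow(s0); nv <- ncol(s0)
  if (length(t1_pre) != nv) stop("t1_pre length must match voxel count")
  if (max(baseline_frames) >= spec$bolus_frame)
    stop("baseline window must be entirely pre-bolus")
  r1_pre <- 1 / t1_pre
  f_pre <- spgr_signal(r1_pre, spec$tr, spec$flip_deg)
  scale <- colMeans(s0[baseline_frames, , drop = FALSE]) / f_pre
  g <- sweep(s0, 2, scale, "/")
  r1 <- spgr_invert(g, spec$tr, spec$flip_deg)
  flagged <- is.na(r1) & rep(!is.na(r1_pre), each = nt)
  n_flag <- colSums(matrix(flagged, nt, nv))
  valid <- !is.na(r1_pre) & (n_flag / nt) <= max_flagged_frac
  t_idx <- seq_len(nt)
  for (v in which(valid & n_flag > 0)) {
    ok <- !is.na(r1[, v])
    r1[, v] <- approx(t_idx[ok], r1[ok, v], t_idx, rule = 2)$y
  }
  r1[, !valid] <- NA_real_
  ct <- sweep(r1, 2, r1_pre, "-") / spec$r1
  list(ct = ct, r1 = r1, valid = valid, n_flagged = n_flag)
}
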