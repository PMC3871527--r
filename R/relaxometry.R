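#' Voxelwise Look-Locker T1 estimation
#'
#' Fits the three-parameter magnitude model
#' \deqn{|S(TI)| = |A - B e^{-TI/T_1^*}|}
#' to each voxel of an inversion-recovery series and applies the standard
#' Look-Locker correction \eqn{T_1 = T_1^* (B/A - 1)} for the readout-
#' shortened apparent relaxation time. Magnitude data lose the inversion
#' sign, so polarity is restored by a sign-flip search around the
#' minimum-signal inversion time; for each candidate flip index the
#' amplitudes (A, B) are profiled out linearly and T1* found by a bounded
#' 1-D search, and the lowest-SSE candidate wins.
#'
#' Voxels that cannot be fit (all-zero series, or a degenerate solution
#' with B <= A implying T1 <= 0) are flagged rather than failing; their T1
#' is NA and they are excluded from downstream concentration maps.
#'
#' @param series Matrix (inversion times x voxels), vector (one voxel), or
#'   4D array (x, y, z, TI).
#' @param ti Inversion times (s), >= 4 distinct values.
#' @param mask Optional logical vector/array of voxels to fit (others NA).
#' @return data.frame with per-voxel `t1` (s), apparent `t1_star` (s),
#'   amplitudes `A`, `B`, residual `sse` and logical `converged`. For 4D
#'   input, an attribute `dim` carries the spatial grid.
#' @export
fit_look_locker <- function(series, ti, mask = NULL) {
  spatial_dim <- NULL
  if (is.array(series) && length(dim(series)) == 4) {
    spatial_dim <- dim(series)[1:3]
    series <- matrix(series, prod(spatial_dim), dim(series)[4])
    series <- t(series)
  } else if (is.vector(series)) {
    series <- matrix(series, ncol = 1)
  }
  if (length(unique(ti)) < 4) stop("need at least 4 distinct inversion times")
  if (nrow(series) != length(ti)) stop("series rows must match inversion times")
  if (nrow(series) < 3) stop("fewer samples than model parameters")
  if (any(!is.finite(series))) stop("signals must be finite")
  ord <- order(ti)  # estimates are invariant to sample order; sort once
  nv <- ncol(series)
  keep <- if (is.null(mask)) rep(TRUE, nv) else as.vector(mask)
  out <- data.frame(A = rep(NA_real_, nv), B = NA_real_, t1_star = NA_real_,
                    t1 = NA_real_, sse = NA_real_, converged = FALSE)
  if (any(keep)) {
    fit <- .ll_fit_batch(series[ord, keep, drop = FALSE], ti[ord])
    out$A[keep] <- fit[, "A"]
    out$B[keep] <- fit[, "B"]
    out$t1_star[keep] <- fit[, "t1_star"]
    out$t1[keep] <- fit[, "t1"]
    out$sse[keep] <- fit[, "sse"]
    out$converged[keep] <- fit[, "converged"] > 0
  }
  if (!is.null(spatial_dim)) attr(out, "spatial_dim") <- spatial_dim
  out
}

#' T1 map from a fitted Look-Locker table
#'
#' @param fit Result of [fit_look_locker()] on a 4D series.
#' @return 3D array of T1 (s), NA where not converged.
#' @export
t1_map_from_fit <- function(fit) {
  dims <- attr(fit, "spatial_dim")
  if (is.null(dims)) stop("fit does not carry a spatial grid")
  array(ifelse(fit$converged, fit$t1, NA_real_), dims)
}
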