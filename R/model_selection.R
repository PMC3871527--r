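#' Sequential nested F-test model selection per voxel
#'
#' Assigns each fitted voxel a model order by stepping through the nested
#' hierarchy 1 -> 2 -> 3. Each step compares the residual sums of squares
#' of the smaller (a) and larger (b) model with
#' \deqn{F = \frac{(SSE_a - SSE_b)/(p_b - p_a)}{SSE_b/(n - p_b)},}
#' with parameter counts p = 1, 2, 3 and n the number of post-arrival
#' frames. A step is accepted when its p-value is below `alpha`; selection
#' stops at the first non-significant step, so order 3 requires both steps
#' to pass. Perfect fits at both orders (both SSEs zero) favour the lower
#' order (parsimony); a zero SSE only at the larger order is accepted.
#'
#' The F statistics are computed from the unconstrained nested linear SSEs
#' (`sse1u`, `sse2u`, `sse3u`) when present, so that the 1 -> 2 step has
#' its exact F null distribution; the reported parameter values remain the
#' bounded estimates.
#'
#' @param fits data.frame from [fit_pk_models()].
#' @param n_frames Number of frames used in fitting (post-arrival).
#' @param alpha Per-step significance level (default 0.05; no across-voxel
#'   multiplicity correction, the map-making convention).
#' @return data.frame: selected `order`, `f12`, `f23`, `p12`, `p23`, and
#'   the `alpha` used.
#' @export
select_model <- function(fits, n_frames, alpha = 0.05) {
  if (n_frames <= 4) stop("need n_frames > 4 for the nested F-tests")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (!is.null(fits$sse1u)) {
    fits <- data.frame(sse1 = fits$sse1u, sse2 = fits$sse2u,
                       sse3 = fits$sse3u)
  }
  step <- function(sse_a, sse_b, p_b) {
    num <- pmax(sse_a - sse_b, 0)
    den <- sse_b / (n_frames - p_b)
    f <- ifelse(den > 0, num / den,
                ifelse(num > 0, Inf, 0))  # parsimony when both perfect
    p <- pf(f, 1, n_frames - p_b, lower.tail = FALSE)
    list(f = f, p = p, sig = p < alpha)
  }
  s12 <- step(fits$sse1, fits$sse2, 2)
  s23 <- step(fits$sse2, fits$sse3, 3)
  order <- ifelse(!s12$sig, 1L, ifelse(!s23$sig, 2L, 3L))
  data.frame(order = order, f12 = s12$f, f23 = s23$f,
             p12 = s12$p, p23 = s23$p, alpha = alpha)
}

#' Masked parameter maps from fits and selected orders
#'
#' Emits the convention used for reporting: vp is defined wherever a model
#' was selected (order >= 1), Ktrans wherever leakage was detected
#' (order >= 2), and ve only in extended-Tofts regions (order 3). The
#' returned parameter value for each voxel comes from its selected model.
#'
#' @param fits data.frame from [fit_pk_models()].
#' @param sel data.frame from [select_model()] (same rows).
#' @param dim Optional spatial dimensions; when given, maps are 3D arrays.
#' @param voxel_index Optional linear indices of the fitted voxels within
#'   the `dim` grid (defaults to all voxels in order).
#' @return List of maps `vp`, `ktrans`, `ve`, `kep`, integer `order`, and
#'   logical `mask3` (the model-3 mask).
#' @export
make_masked_maps <- function(fits, sel, dim = NULL, voxel_index = NULL) {
  if (nrow(fits) != nrow(sel)) stop("fits and selection tables misaligned")
  ord <- sel$order
  vp <- ifelse(ord >= 3, fits$vp3, ifelse(ord >= 2, fits$vp2, fits$vp1))
  vp[ord < 1] <- NA_real_
  kt <- ifelse(ord >= 3, fits$kt3, fits$kt2)
  kt[ord < 2] <- NA_real_
  ve <- ifelse(ord == 3, fits$ve3, NA_real_)
  kep <- ifelse(ord == 3, fits$kep3, NA_real_)
  m3 <- ord == 3L
  if (is.null(dim)) {
    return(list(vp = vp, ktrans = kt, ve = ve, kep = kep,
                order = ord, mask3 = m3))
  }
  nv <- prod(dim)
  idx <- voxel_index %||% seq_len(nv)
  if (length(idx) != nrow(fits)) stop("voxel_index misaligned with fits")
  put <- function(x, init = NA_real_) {
    a <- array(init, dim); a[idx] <- x; a
  }
  list(vp = put(vp), ktrans = put(kt), ve = put(ve), kep = put(kep),
       order = put(ord, init = 0L), mask3 = put(m3, init = FALSE))
}
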