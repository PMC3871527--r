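#' Two-point apparent diffusion coefficient map
#'
#' Closed-form ADC from a two-b-value acquisition:
#' \deqn{ADC = \ln(S_{b_0}/S_{b_1}) / (b_1 - b_0).}
#' Voxels with a nonpositive signal at either weighting are invalid;
#' negative ADC (noise) is clipped to 0 and annotated in the mask.
#'
#' @param s_b0,s_b1 Signals at the low and high b-value (any equal shape).
#' @param b0,b1 The b-values (s/mm2), `b1 > b0 >= 0`.
#' @return List: `adc` (mm2/s), logical `valid`, logical `clipped`.
#' @export
compute_adc <- function(s_b0, s_b1, b0 = 0, b1 = 1217) {
  if (b1 <= b0 || b0 < 0) stop("need b1 > b0 >= 0")
  if (length(s_b0) != length(s_b1)) stop("signal shapes differ")
  valid <- s_b0 > 0 & s_b1 > 0
  adc <- array(NA_real_, dim = dim(s_b0) %||% length(s_b0))
  adc[valid] <- log(s_b0[valid] / s_b1[valid]) / (b1 - b0)
  clipped <- !is.na(adc) & adc < 0
  adc[clipped] <- 0
  list(adc = adc, valid = valid, clipped = clipped)
}
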