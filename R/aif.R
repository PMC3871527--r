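#' Synthetic arterial input function
#'
#' Builds a plasma contrast-agent concentration curve Cp(t) on the dynamic
#' time grid: zero before bolus arrival, then an instantaneous rise followed
#' by biexponential decay,
#' \deqn{C_p(t) = A_1 e^{-m_1 (t - t_0)} + A_2 e^{-m_2 (t - t_0)}, \quad t \ge t_0,}
#' with t0 the time of the injection frame. Amplitudes are plasma
#' concentrations (mM), i.e. whole-blood values already scaled by
#' 1/(1 - Hct); no further hematocrit correction is applied downstream.
#'
#' @param spec An [acq_spec()]; supplies the time grid and bolus frame.
#' @param a1,a2 Amplitudes (mM) of the fast and slow components.
#' @param m1,m2 Decay rates (s^-1) of the fast and slow components.
#' @return A `plasma_curve`: list with `time_s`, `cp` (mM) and `provenance`.
#' @export
make_aif <- function(spec, a1 = 3.0, m1 = 8e-3, a2 = 1.0, m2 = 4e-4) {
  validate_acq_spec(spec)
  if (a1 < 0 || a2 < 0) stop("AIF amplitudes must be nonnegative")
  if (m1 <= 0 || m2 <= 0) stop("AIF decay rates must be positive")
  t <- frame_times(spec)
  t0 <- t[spec$bolus_frame]
  cp <- ifelse(t >= t0,
               a1 * exp(-m1 * (t - t0)) + a2 * exp(-m2 * (t - t0)),
               0)
  plasma_curve(t, cp, provenance = "synthetic")
}

#' Plasma concentration curve constructor
#'
#' @param time_s Strictly increasing sample times (s).
#' @param cp Plasma concentration (mM), nonnegative.
#' @param provenance `"synthetic"` or `"supplied"`.
#' @return A `plasma_curve` object.
#' @export
plasma_curve <- function(time_s, cp, provenance = "supplied") {
  if (length(time_s) != length(cp)) stop("time and Cp lengths differ")
  if (any(diff(time_s) <= 0)) stop("time grid must be strictly increasing")
  if (any(cp < 0)) stop("Cp must be nonnegative")
  structure(list(time_s = as.numeric(time_s), cp = as.numeric(cp),
                 provenance = provenance),
            class = "plasma_curve")
}

#' Read / write an AIF as a two-column CSV
#'
#' Columns are `time_s` and `cp_mM`.
#'
#' @param path File path.
#' @param aif A `plasma_curve` (for writing).
#' @return `read_aif` returns a `plasma_curve`.
#' @export
read_aif <- function(path) {
  d <- read.csv(path)
  plasma_curve(d$time_s, d$cp_mM, provenance = "supplied")
}

#' @rdname read_aif
#' @export
write_aif <- function(aif, path) {
  stopifnot(inherits(aif, "plasma_curve"))
  write.csv(data.frame(time_s = aif$time_s, cp_mM = aif$cp), path,
            row.names = FALSE)
  invisible(path)
}
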