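# Shared fixtures: small synthetic truths built in code.

# a flat "truth map" holding one voxel per parameter triple, body-zone tissue
truth_voxels <- function(vp, ktrans, kep = NA_real_, model = 3L) {
  n <- length(vp)
  dims <- c(n, 1L, 1L)
  list(model = array(as.integer(model), dims),
       vp = array(vp, dims),
       ktrans = array(ktrans, dims),
       kep = array(kep, dims),
       zone = array("body", dims))
}

spec_voxels <- function(n, ...) acq_spec(grid_dim = c(n, 1L, 1L), ...)

# 3 x 3 x 3 grid of extended-Tofts ground-truth triples
param_grid_27 <- function() {
  expand.grid(vp = c(0.01, 0.02, 0.04),
              ktrans = c(0.01, 0.02, 0.04),
              kep = c(0.1, 0.3, 0.6))
}

default_aif_spec <- function() {
  spec <- acq_spec()
  list(spec = spec, aif = make_aif(spec))
}

# independent R-side trapezoid helpers (oracles stay clear of the C++ path)
r_cumtrapz <- function(x, dt) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2 * dt))
}

# tiny cohort design for fast pipeline tests
small_design <- function(n_per_group = 2L) {
  cohort_design(group_sizes = rep(n_per_group, 5L))
}
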