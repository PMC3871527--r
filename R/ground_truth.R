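#' Default zone parameter table for the simulated glioma
#'
#' Ground-truth kinetic parameters by tissue zone. The simulated tumor has
#' three concentric zones: a well-perfused, highly leaky periphery and body
#' (extended Tofts behaviour, model 3), and a poorly vascularised necrotic
#' core with reduced plasma volume and influx-only leakage (Patlak
#' behaviour, model 2). The outermost shell of the periphery is also
#' model 2 (leakage without measurable backflux), so the tumor contains
#' both model-2 and model-3 voxels. Contralateral caudate-putamen tissue is
#' intact vasculature: plasma volume only (model 1).
#'
#' Values are typical small-rodent glioma magnitudes: vp a few percent,
#' Ktrans a few times 1e-2 min^-1, ve (= Ktrans/kep) around 0.1.
#'
#' @return data.frame with columns `zone`, `model`, `vp`, `ktrans` (min^-1),
#'   `kep` (min^-1).
#' @export
zone_parameter_table <- function() {
  data.frame(
    zone   = c("contralateral", "periphery", "body", "core"),
    model  = c(1L, 3L, 3L, 2L),
    vp     = c(0.010, 0.030, 0.020, 0.006),
    ktrans = c(0.000, 0.035, 0.025, 0.008),
    kep    = c(NA, 0.35, 0.20, NA),
    stringsAsFactors = FALSE
  )
}

#' Test-retest cohort design
#'
#' Describes the five treatment-time cohorts and the distribution of the
#' true test-to-retest shift of each kinetic parameter. Defaults follow the
#' study design: 31 animals in groups of 7, 6, 6, 6 and 6 imaged twice,
#' 24 h apart, with drug given 2, 4, 8, 12 or 24 h before the second
#' session. Per-group shift means and SDs default to the reported pooled
#' group summaries: the 2 h and 4 h groups each take the pooled
#' (2 and 4 h) row, the 12 h and 24 h groups the pooled (12 and 24 h) row,
#' and the 8 h group is centred at zero with SD set to the average of the
#' two pooled SDs.
#'
#' @param group_hours Treatment-to-retest times (h).
#' @param group_sizes Animals per group.
#' @param shift_table data.frame with columns `group_h`, and mean/SD columns
#'   `vp_mean`, `vp_sd`, `ktrans_mean`, `ktrans_sd`, `ve_mean`, `ve_sd`
#'   describing the Gaussian from which each animal's true shift is drawn.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(group_hours = c(2, 4, 8, 12, 24),
                          group_sizes = c(7L, 6L, 6L, 6L, 6L),
                          shift_table = default_shift_table(group_hours)) {
  if (length(group_hours) != length(group_sizes))
    stop("group_hours and group_sizes lengths differ")
  if (any(group_sizes < 1L)) stop("group sizes must be positive")
  sdcols <- grep("_sd$", names(shift_table), value = TRUE)
  if (any(unlist(shift_table[sdcols]) < 0)) stop("shift SDs must be >= 0")
  if (!all(group_hours %in% shift_table$group_h))
    stop("shift_table must cover every group")
  structure(list(group_hours = group_hours,
                 group_sizes = as.integer(group_sizes),
                 shift_table = shift_table),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @export
default_shift_table <- function(group_hours = c(2, 4, 8, 12, 24)) {
  early <- c(ktrans = 0.0050, ktrans_sd = 0.0050,
             ve = 0.0005,  ve_sd = 0.0166,
             vp = 0.0016,  vp_sd = 0.0052)
  late  <- c(ktrans = -0.0039, ktrans_sd = 0.0064,
             ve = -0.0164, ve_sd = 0.0251,
             vp = -0.0006, vp_sd = 0.0030)
  mid   <- c(ktrans = 0,
             ktrans_sd = unname(early["ktrans_sd"] + late["ktrans_sd"]) / 2,
             ve = 0, ve_sd = unname(early["ve_sd"] + late["ve_sd"]) / 2,
             vp = 0, vp_sd = unname(early["vp_sd"] + late["vp_sd"]) / 2)
  pick <- function(h) if (h < 8) early else if (h > 8) late else mid
  rows <- lapply(group_hours, function(h) {
    p <- pick(h)
    data.frame(group_h = h,
               vp_mean = unname(p["vp"]), vp_sd = unname(p["vp_sd"]),
               ktrans_mean = unname(p["ktrans"]), ktrans_sd = unname(p["ktrans_sd"]),
               ve_mean = unname(p["ve"]), ve_sd = unname(p["ve_sd"]))
  })
  do.call(rbind, rows)
}

#' Draw per-animal true test-to-retest shifts
#'
#' Each animal's true shift of (vp, Ktrans, ve) is drawn independently from
#' the Gaussian of its group. Uses the current RNG state; seed externally
#' for reproducibility.
#'
#' @param design A [cohort_design()].
#' @return data.frame: `animal_id`, `group_h`, `d_vp`, `d_ktrans`, `d_ve`.
#' @export
draw_cohort_shifts <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  st <- design$shift_table
  rows <- mapply(function(h, n) {
    r <- st[st$group_h == h, ][1, ]
    data.frame(group_h = rep(h, n),
               d_vp = rnorm(n, r$vp_mean, r$vp_sd),
               d_ktrans = rnorm(n, r$ktrans_mean, r$ktrans_sd),
               d_ve = rnorm(n, r$ve_mean, r$ve_sd))
  }, design$group_hours, design$group_sizes, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  out <- cbind(animal_id = sprintf("A%02d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

# zone geometry: concentric discs on each slice. Returns integer array of
# zone codes: 0 background, 1 contralateral, 2 periphery, 3 body, 4 core,
# 5 peripheral model-2 shell.
zone_geometry <- function(grid_dim, center = c(20, 16), radius = NULL) {
  nx <- grid_dim[1]; ny <- grid_dim[2]; nz <- grid_dim[3]
  if (is.null(radius)) {
    # ellipsoidal cap: largest cross-section on the central slice
    mid <- (nz + 1) / 2
    radius <- 4.2 * sqrt(pmax(0.25, 1 - ((seq_len(nz) - mid) / max(1, mid))^2))
  }
  if (length(radius) != nz) radius <- rep(radius, length.out = nz)
  zone <- array(0L, dim = grid_dim)
  ccontra <- c(nx + 1 - center[1], center[2])
  for (z in seq_len(nz)) {
    R <- radius[z]
    for (x in seq_len(nx)) for (y in seq_len(ny)) {
      r <- sqrt((x - center[1])^2 + (y - center[2])^2)
      rc <- sqrt((x - ccontra[1])^2 + (y - ccontra[2])^2)
      if (r <= R) {
        f <- r / R
        zone[x, y, z] <-
          if (f <= 0.35) 4L else if (f <= 0.65) 3L else if (f <= 0.9) 2L else 5L
      } else if (rc <= 2.5) {
        zone[x, y, z] <- 1L
      }
    }
  }
  zone
}

#' Generate ground-truth parameter maps for a paired test/retest cohort
#'
#' Builds, for every animal, test-session ground truth maps (voxelwise
#' model order, vp, Ktrans, kep and zone label) and retest maps in which
#' the animal's true shift — drawn from its group's Gaussian — is applied
#' to the model-3 tumor voxels. Shifts act on vp, Ktrans and ve; the
#' backflux rate follows as kep = Ktrans/ve. Shifted values that would
#' violate physical bounds (negative fractions, vp + ve >= 1) are clipped
#' with a warning.
#'
#' @param design A [cohort_design()].
#' @param spec An [acq_spec()] (supplies the grid).
#' @param zones Zone parameter table, see [zone_parameter_table()].
#' @return List of animals; each has `animal_id`, `group_h`, `shift`
#'   (named vector), and `test`/`retest` ground-truth maps (lists of arrays
#'   `model`, `vp`, `ktrans`, `kep`, `zone`).
#' @export
make_ground_truth <- function(design, spec = acq_spec(),
                              zones = zone_parameter_table()) {
  stopifnot(inherits(design, "cohort_design"))
  validate_acq_spec(spec)
  check_zone_table(zones)
  shifts <- draw_cohort_shifts(design)
  zgeo <- zone_geometry(spec$grid_dim)
  base <- truth_from_zones(zgeo, zones)
  lapply(seq_len(nrow(shifts)), function(i) {
    sh <- c(vp = shifts$d_vp[i], ktrans = shifts$d_ktrans[i],
            ve = shifts$d_ve[i])
    list(animal_id = shifts$animal_id[i], group_h = shifts$group_h[i],
         shift = sh,
         test = base,
         retest = apply_truth_shift(base, sh))
  })
}

check_zone_table <- function(zones) {
  ve <- ifelse(is.na(zones$kep), 0, zones$ktrans / zones$kep)
  if (any(zones$vp < 0 | zones$vp > 0.2)) stop("zone vp outside [0, 0.2]")
  if (any(zones$ktrans < 0)) stop("zone Ktrans must be >= 0")
  if (any(zones$model == 3 & (is.na(zones$kep) | zones$kep <= 0)))
    stop("model-3 zones need kep > 0")
  if (any(zones$model == 1 & zones$ktrans != 0))
    stop("model-1 zones must have Ktrans = 0")
  if (any(zones$vp + ve >= 1)) stop("zone vp + ve must be < 1")
  invisible(zones)
}

truth_from_zones <- function(zgeo, zones) {
  dimz <- dim(zgeo)
  vp <- array(0, dimz); kt <- array(0, dimz); kep <- array(NA_real_, dimz)
  model <- array(0L, dimz)
  zl <- array("background", dimz)
  zmap <- list(`1` = "contralateral", `2` = "periphery", `3` = "body",
               `4` = "core", `5` = "periphery")
  for (code in 1:5) {
    idx <- zgeo == code
    if (!any(idx)) next
    zname <- zmap[[as.character(code)]]
    row <- zones[zones$zone == zname, ]
    zl[idx] <- zname
    vp[idx] <- row$vp
    model[idx] <- row$model
    if (code == 5L) {
      # outer peripheral shell: leakage without measurable backflux
      model[idx] <- 2L
      kt[idx] <- row$ktrans / 2
    } else {
      kt[idx] <- row$ktrans
      if (row$model == 3L) kep[idx] <- row$kep
    }
  }
  list(model = model, vp = vp, ktrans = kt, kep = kep, zone = zl)
}

apply_truth_shift <- function(truth, shift) {
  out <- truth
  m3 <- truth$model == 3L
  if (!any(m3)) return(out)
  vp <- truth$vp[m3] + shift[["vp"]]
  kt <- truth$ktrans[m3] + shift[["ktrans"]]
  ve <- truth$ktrans[m3] / truth$kep[m3] + shift[["ve"]]
  clipped <- FALSE
  fix <- function(x, lo, hi) {
    bad <- x < lo | x > hi
    if (any(bad)) clipped <<- TRUE
    pmin(pmax(x, lo), hi)
  }
  vp <- fix(vp, 0, 0.2)
  kt <- fix(kt, 1e-4, Inf)
  ve <- fix(ve, 1e-3, 0.99 - vp)
  if (clipped)
    warning("shift clipped to keep vp, Ktrans, ve within physical bounds")
  out$vp[m3] <- vp
  out$ktrans[m3] <- kt
  out$kep[m3] <- kt / ve
  out
}
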