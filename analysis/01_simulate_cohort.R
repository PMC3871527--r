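#!/usr/bin/env Rscript
# Simulate the paired test/retest DCE-MRI cohort: 31 virtual rats with
# orthotopic gliomas in five treatment-time groups (2, 4, 8, 12, 24 h;
# n = 7, 6, 6, 6, 6), imaged twice 24 h apart at SNR 30. Each animal's
# true shift of (vp, Ktrans, ve) between sessions is drawn from its
# group's Gaussian (pooled early/late means and SDs of the reported
# summaries; the 8 h group is centred on zero).
#
# Signal volumes are regenerated deterministically from the seed, so only
# one example animal's imaging sessions are written to disk in full; the
# drawn ground-truth shifts and the cohort manifest cover the rest.

suppressPackageStartupMessages(library(dcepk))

seed <- 1234L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- acq_spec()
design <- cohort_design()
aif <- make_aif(spec)

set.seed(seed)
truth <- make_ground_truth(design, spec)
noise_sd <- noise_sd_for_snr(spec, 30)

shifts <- do.call(rbind, lapply(truth, function(an)
  data.frame(animal_id = an$animal_id, group_h = an$group_h,
             d_vp = an$shift[["vp"]], d_ktrans = an$shift[["ktrans"]],
             d_ve = an$shift[["ve"]])))
write.csv(shifts, file.path(out, "true_shifts.csv"), row.names = FALSE)

manifest <- data.frame(animal_id = shifts$animal_id,
                       group_h = shifts$group_h,
                       sessions = "test,retest", seed = seed, snr = 30)
write.csv(manifest, file.path(out, "cohort_manifest.csv"), row.names = FALSE)
write_aif(aif, file.path(out, "aif.csv"))
write_sidecar(spec, file.path(out, "acquisition.json"),
              extra = list(seed = seed, noise_sd = noise_sd))

# one fully materialised example animal (first of the 2 h group)
an <- truth[[1]]
for (s in c("test", "retest")) {
  study <- synthesize_signals(an[[s]], aif, spec, noise_sd = noise_sd)
  write_study(study, out, paste0(an$animal_id, "_", s))
  write_maps(an[[s]][c("vp", "ktrans", "kep")], out,
             paste0(an$animal_id, "_", s, "_truth"))
}

m3 <- sum(an$test$model == 3L)
cat(sprintf("Simulated %d animals (seed %d).\n", nrow(shifts), seed))
cat(sprintf("Example animal %s (%d h group): %d model-3 tumor voxels,\n",
            an$animal_id, an$group_h, m3))
cat(sprintf("  true Ktrans shift %+0.4f /min, ve shift %+0.4f.\n",
            an$shift[["ktrans"]], an$shift[["ve"]]))
cat(sprintf("Pooled true Ktrans shift, 2&4 h: %+0.4f; 12&24 h: %+0.4f /min.\n",
            mean(shifts$d_ktrans[shifts$group_h %in% c(2, 4)]),
            mean(shifts$d_ktrans[shifts$group_h %in% c(12, 24)])))
cat("Outputs under", out, "\n")
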