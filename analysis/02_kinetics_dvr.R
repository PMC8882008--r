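#!/usr/bin/env Rscript
# Step 2: tracer kinetic modelling.
#
# Simulates reference and target time-activity curves on the standard
# 30-frame / 90-minute schedule with the simplified reference tissue model
# (known ground-truth DVR), then checks that the two-parameter multilinear
# reference tissue fit (MRTM2, k2' supplied by a three-parameter MRTM fit
# on a high-binding curve) recovers DVR across its range, noiselessly and
# under 2% frame noise. Finishes with a voxel-wise DVR parametric map on a
# small synthetic dynamic volume.

suppressPackageStartupMessages(library(petpls))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

sched <- default_frame_schedule()
ref <- generate_reference_tac(sched)
cat(sprintf("frame schedule: %d frames over %.0f min; reference TAC peaks at %.1f min\n",
            length(sched), sum(sched$duration) / 60,
            sched$mid_min[which.max(ref$activity)]))

k2 <- 0.15
hb <- generate_target_tac(ref, R1 = 1, k2 = k2, DVR = 2.0)
k2prime <- fit_mrtm(hb, ref, t_star = 20)$k2prime
cat(sprintf("k2' from MRTM on the high-binding curve: %.4f /min (true %.2f)\n",
            k2prime, k2))

grid <- seq(1.0, 2.4, by = 0.2)
set.seed(20260922L)
recov <- do.call(rbind, lapply(grid, function(d) {
  clean <- generate_target_tac(ref, R1 = 1, k2 = k2, DVR = d)
  fit0 <- fit_mrtm2(clean, ref, k2prime = k2prime)
  sd2 <- 0.02 * max(clean$activity)
  noisy_dvr <- replicate(50, {
    noisy <- tac(sched, clean$activity + rnorm(30, sd = sd2))
    fit_mrtm2(noisy, ref, k2prime = k2prime)$DVR
  })
  data.frame(true_dvr = d, fitted_dvr = fit0$DVR,
             rel_error_pct = 100 * (fit0$DVR / d - 1),
             noisy_mean = mean(noisy_dvr), noisy_sd = sd(noisy_dvr))
}))
write.csv(recov, "results/mrtm2_recovery.csv", row.names = FALSE)
cat("\nMRTM2 recovery over the DVR grid (50 noisy replicates each):\n")
print(recov, digits = 4)
cat(sprintf("max |relative error| noiseless: %.3f%%\n",
            max(abs(recov$rel_error_pct))))

# voxel-wise parametric imaging on a synthetic dynamic volume
dims <- c(8, 8, 8)
true_dvr <- array(1.0, dims)
true_dvr[3:6, 3:6, 3:6] <- 1.5    # high-binding core
curves <- lapply(c(low = 1.0, high = 1.5), function(d)
  generate_target_tac(ref, R1 = 1, k2 = k2, DVR = d)$activity)
dyn <- array(0, c(dims, 30))
for (v in seq_len(prod(dims))) {
  ijk <- arrayInd(v, dims)
  dyn[ijk[1], ijk[2], ijk[3], ] <-
    if (true_dvr[v] > 1) curves$high else curves$low
}
ref_arr <- array(0, dims); ref_arr[, , 1] <- 1
for (v in which(ref_arr == 1)) {
  ijk <- arrayInd(v, dims)
  dyn[ijk[1], ijk[2], ijk[3], ] <- ref$activity
}
hb_arr <- array(0, dims); hb_arr[4:5, 4:5, 4:5] <- 1
dvr_map <- dvr_map_from_dynamic(dyn, parametric_map(ref_arr),
                                parametric_map(hb_arr), sched)
save_volume(dvr_map, "scratch/dvr_map_synthetic.nii.gz")
core <- parametric_map(array(as.numeric(true_dvr > 1), dims))
summ <- summarize_cortical_amyloid(dvr_map, cortical_mask = core)
cat(sprintf("\nvoxel-wise map: mean DVR over the high-binding core %.3f (truth 1.5), status '%s'; %d degenerate voxel(s)\n",
            summ$mean_cortical_dvr, summ$status,
            attr(dvr_map, "n_degenerate")))
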