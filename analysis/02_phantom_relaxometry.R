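#!/usr/bin/env Rscript
# Phantom-based validation of the T2* fitters: noiseless recovery must be
# exact; under Rician noise at a realistic SNR the lung-median estimate
# should stay within a few percent of truth, with NLLS less biased than the
# log-linear fit. Writes a per-GA recovery table.

library(fetalt2star)

out <- "results"
dir.create(out, showWarnings = FALSE)

gas <- c(22, 26, 30, 34, 38)
rows <- lapply(seq_along(gas), function(i) {
  ga <- gas[i]
  ph <- make_phantom(ga, grid_shape = c(32, 28, 24), seed = 10 + i)
  truth <- normative_mean(published_model(), ga)
  lung <- ph$label_map >= 3L

  img0 <- simulate_multiecho(ph, noise_model = "none")
  map0 <- fit_map(img0, mask = lung, method = "loglinear")
  err0 <- max(abs(map0$t2star[lung] - ph$truth_t2star[lung]) /
                ph$truth_t2star[lung])

  imgN <- simulate_multiecho(ph, snr = 30, noise_model = "rician", seed = 20 + i)
  mapN <- fit_map(imgN, mask = lung, method = "nlls")
  med <- median(mapN$t2star[lung], na.rm = TRUE)

  data.frame(ga_weeks = ga, truth_t2star = truth,
             lung_voxels = sum(lung),
             noiseless_max_rel_err = err0,
             snr30_median_t2star = med,
             snr30_median_rel_err = abs(med - truth) / truth)
})
tab <- do.call(rbind, rows)
write_cohort(tab, file.path(out, "relaxometry_recovery.csv"))

cat("Noiseless max relative T2* error by GA:\n")
print(tab[, c("ga_weeks", "noiseless_max_rel_err")], row.names = FALSE)
cat(sprintf("\nRician SNR=30, NLLS: lung-median T2* within %.2f%% of truth at worst.\n",
            100 * max(tab$snr30_median_rel_err)))
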