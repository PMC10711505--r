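#!/usr/bin/env Rscript
# Per-lung ROI metrics and lacunarity across gestation on phantoms whose
# lung texture heterogeneity grows with GA. Reproduces, on synthetic data,
# the qualitative cohort findings: lung volume grows with GA, the left lung
# is smaller than the right, and the lacunarity score increases with GA.

library(fetalt2star)

out <- "results"
dir.create(out, showWarnings = FALSE)

gas <- seq(21, 38, by = 1)
rows <- lapply(seq_along(gas), function(i) {
  ga <- gas[i]
  het <- 0.02 + 0.01 * (ga - 20)   # texture SD grows with gestation
  ph <- make_phantom(ga, grid_shape = c(32, 28, 24),
                     tissues = default_tissues(ga, lung_heterogeneity_sd = het),
                     seed = 40 + i)
  img <- simulate_multiecho(ph, noise_model = "none")
  map <- fit_map(img, mask = ph$label_map >= 3L, method = "loglinear")
  msk <- phantom_lung_mask(ph)
  per_roi <- do.call(rbind, lapply(c("right", "left", "both"), function(roi) {
    sm <- summarize_roi(map, msk, roi)
    cv <- lacunarity_curve(map, msk, roi, box_sizes = c(2, 3, 4))
    cbind(data.frame(ga_weeks = ga), sm,
          lacunarity = lacunarity_score(cv)$value)
  }))
  per_roi
})
tab <- do.call(rbind, rows)
write_cohort(tab, file.path(out, "roi_metrics_by_ga.csv"))

both <- tab[tab$roi == "both", ]
vol_fit <- lm(volume_ml ~ ga_weeks, data = both)
lac_fit <- lm(lacunarity ~ ga_weeks, data = both)
wide_r <- tab[tab$roi == "right", "volume_ml"]
wide_l <- tab[tab$roi == "left", "volume_ml"]

cat(sprintf("Total lung volume grows %.2f mL/week (p = %.2g).\n",
            coef(vol_fit)[2], summary(vol_fit)$coefficients[2, 4]))
cat(sprintf("Left/right volume ratio: %.3f (design value 0.85).\n",
            mean(wide_l / wide_r)))
cat(sprintf("Lacunarity score slope vs GA: %.4f per week (p = %.2g).\n",
            coef(lac_fit)[2], summary(lac_fit)$coefficients[2, 4]))
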