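#!/usr/bin/env Rscript
# Micro-irradiation recruitment quantification on synthetic phantoms:
# (mean in-region - mean nearby) x area per frame, with 5x5 Gaussian blur
# and centroid tracking; laser-track signal over nuclear background; and
# nucleolus-excluded chromatin-retention masking.

library(phosphoscreen)

tab <- "results/tables"
dir.create(tab, recursive = TRUE, showWarnings = FALSE)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20210827L

st <- gen_timelapse(shape = c(12, 64, 64), spot_center = c(32, 32),
                    spot_radius = 4, spot_amplitude = 120, decay_rate = 0.35,
                    background = 40, noise_sd = 3, pre_frames = 2,
                    seed = seed)
sc <- write_stack_tiff(st, "results/data/recruitment_stack.tif")
tr <- recruitment_trace(st, center = c(32, 32), radius = 4, pre_frames = 2)
message(sprintf(
  "Recruitment: peak score %.0f at frame %d; decays to %.0f by frame %d%s.",
  max(tr$score), which.max(tr$score), tr$score[nrow(tr)], nrow(tr),
  if (attr(tr, "static_fallback")) " (static-ROI fallback)" else ""))
write_tsv_prov(tr, file.path(tab, "recruitment_trace.tsv"))

# laser-track signal over nuclear background
img <- matrix(20, 64, 64)
nuc <- disc_mask(c(64, 64), c(32, 32), 24)
img[nuc] <- 60
trk <- matrix(FALSE, 64, 64); trk[30:34, 10:54] <- TRUE
img[trk & nuc] <- 110
set.seed(seed %% 100000L)
img <- img + matrix(rnorm(64 * 64, 0, 2), 64, 64)
tq <- track_quant(img, trk, nuc)
message(sprintf("Track signal over nuclear background: %.1f (true 50).", tq))

# chromatin retention: DAPI region excluding the fibrillarin (nucleolar)
# region
ret <- matrix(15, 64, 64)
ret[nuc] <- 55
nucleolus <- disc_mask(c(64, 64), c(32, 32), 6)
ret[nucleolus] <- 180
retention <- masked_mean_excluding(ret, nuc, nucleolus)
message(sprintf(
  "Chromatin retention (nucleolus excluded): %.1f vs %.1f with nucleolus.",
  retention, mean(ret[nuc])))
write_tsv_prov(data.frame(metric = c("track_signal", "retention_excl",
                                     "retention_incl"),
                          value = c(tq, retention, mean(ret[nuc]))),
               file.path(tab, "imaging_quant.tsv"))
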