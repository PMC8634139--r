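#!/usr/bin/env Rscript
# Simulate the 5-vs-5 TMT10 nuclear phospho screen: 2,000 phosphopeptides
# across 20 fractions, 5% spiked substrates (log2 effect 1.5, WT > KD),
# additive-multiplicative intensity noise, per-channel calibration offsets
# and gains, and PTM localization probabilities spanning the 0.75 gate and
# the 0.994 FLR flag. Writes the PSM table, the ground truth and a planted
# proteome for the motif stages.

library(phosphoscreen)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20210827L

truth <- gen_truth(seed = seed)
psm <- gen_screen(truth)
proteome <- gen_proteome(500, length = 400, plant_rate = 0.15, seed = seed)

write_truth_json(truth, file.path(out, "truth.json"))
write_psm_tsv(psm, file.path(out, "psm_table.tsv"))
write_proteome_fasta(proteome, file.path(out, "proteome.fasta"))
write_tsv_prov(proteome$planted_sites, file.path(out, "planted_sites.tsv"))

message("Simulated ", nrow(psm), " PSMs for ", nrow(truth$peptides),
        " peptides (", sum(truth$peptides$is_substrate),
        " true substrates at log2 effect ",
        unique(truth$peptides$delta[truth$peptides$is_substrate]), ").")
message("Proteome: ", length(proteome$records), " proteins, ",
        nrow(proteome$planted_sites), " planted consensus sites.")
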