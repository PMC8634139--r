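#!/usr/bin/env Rscript
# Targeted (XIC-style) validation statistics for single proteins: median
# collapse of repeated phosphopeptide observations, per-peptide t-tests
# with Bonferroni-corrected thresholds (0.05/4 = 0.0125, 0.05/6 = 0.00833),
# the theoretical inclusion-list mass of the doubly-TMT phosphopeptide, and
# the ddCt fold-change helper used by the silencing experiments.

library(phosphoscreen)

tab <- "results/tables"
dir.create(tab, recursive = TRUE, showWarnings = FALSE)
seed <- 20210827L
design <- group_design()

# a 4-peptide validation protein: one true target among three nulls,
# simulated on the VSN (glog2) scale with replicate noise
set.seed(seed %% 100000L)
m4 <- matrix(rnorm(40, 10, 0.3), 4, 10)
m4[1, design$group == "WT"] <- m4[1, design$group == "WT"] + 1.5
r4 <- targeted_test(m4, design)
r4 <- cbind(peptide = paste0("pep", 1:4), r4)
message(sprintf(
  "Targeted 4-test panel: alpha/m = %.4g; %d peptide(s) significant.",
  r4$alpha_per_test_printed[1], sum(r4$significant)))
m6 <- matrix(rnorm(60, 10, 0.3), 6, 10)
m6[1, design$group == "WT"] <- m6[1, design$group == "WT"] + 1.5
r6 <- targeted_test(m6, design)
message(sprintf("Targeted 6-test panel: alpha/m = %.4g (printed %.5f).",
                0.05 / 6, r6$alpha_per_test_printed[1]))
write_tsv_prov(r4, file.path(tab, "targeted_tests.tsv"))

# inclusion list for the validation phosphopeptide
specs <- data.frame(sequence = "SSPVNRPSSATNK", n_phospho = 1)
incl <- build_inclusion_list(specs, charges = 1:4)
message("Inclusion list (350-1500 m/z): ",
        paste(sprintf("z=%d %.4f", incl$charge, incl$mz), collapse = "; "))
write_tsv_prov(incl, file.path(tab, "inclusion_list.csv"))

# ddCt example: target knocked down to 50% of control against the
# housekeeping reference
fold <- ddct_fold_change(25, 20, 24, 20)
message(sprintf("ddCt example: fold change %.2f relative to control.", fold))
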