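#!/usr/bin/env Rscript
# Consensus-motif scanning of the planted proteome, GO-style
# over-representation of the hit proteins against the full background
# (Fisher exact, p <= 0.01 and >= 3 proteins, enrichment factor
# (k/n)/(K/N)), and confidence binning of a synthetic PPI network at the
# combined-score threshold 150.

library(phosphoscreen)

tab <- "results/tables"
seed <- 20210827L

proteome <- read_proteome_fasta("results/data/proteome.fasta")
planted <- read_tsv_prov("results/data/planted_sites.tsv")
sites <- scan_proteome(proteome)
found <- sum(paste(planted$protein_id, planted$position) %in%
               paste(sites$protein_id, sites$position))
message("Motif scan: ", nrow(sites), " consensus sites; ", found, "/",
        nrow(planted), " planted sites recovered.")
write_tsv_prov(sites, file.path(tab, "motif_sites.tsv"))

hits <- read_tsv_prov(file.path(tab, "hit_table.tsv"))
norm <- read_tsv_prov(file.path(tab, "normalized_matrix.tsv"))
truth <- read_truth_json("results/data/truth.json")
background <- unique(norm$protein_id)
foreground <- unique(hits$protein_id)
truth_sub <- unique(truth$peptides$protein_id[truth$peptides$is_substrate])

ann <- gen_annotations(background, enriched_in = truth_sub, seed = seed)
go <- fisher_enrichment(foreground, background, ann)
sig <- go[go$significant, ]
message("GO enrichment: ", nrow(sig), " significant term(s); top: ",
        paste(utils::head(sig$term, 3), collapse = ", "),
        " (EF ", paste(round(utils::head(sig$enrichment_factor, 3), 1),
                       collapse = ", "), ").")
write_tsv_prov(go, file.path(tab, "go_enrichment.tsv"))

ppi <- bin_ppi(gen_ppi(background, hub_proteins = foreground, seed = seed))
message("PPI network: ", nrow(ppi), " edges >= 150; bins: ",
        paste(names(table(ppi$bin)), table(ppi$bin), collapse = ", "))
write_tsv_prov(ppi, file.path(tab, "ppi_edges.tsv"))
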