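#!/usr/bin/env Rscript
# Generate the desk-scale synthetic study: 8 GWAS loci x 10 cell types,
# 15 risk SNPs per locus, one planted enriched (locus, tissue) pair at
# risk-in-enhancer fraction 0.8 against a 10% background, plus a motif
# contig with planted disrupting alleles and an eQTL table with planted
# significant triples. All downstream scripts read these files.

suppressMessages(library(chromenrich))

seed <- 1L
outdir <- "results/scenario"

scn <- gen_scenario(scenario_config(seed = seed))
paths <- write_scenario(scn, outdir)

message("scenario written to ", outdir)
message("variants in panel: ", nrow(scn$variants),
        " across ", scn$config$n_loci, " loci")
message("planted enrichment pair: ", scn$truth$planted$locus_id[1],
        " in ", scn$truth$planted$cell_type[1],
        " (k/n = ", scn$truth$planted$k[1], "/", scn$truth$planted$n[1], ")")
message("planted motif breaks: ", nrow(scn$truth$motif),
        "; planted eQTL records: ", nrow(scn$truth$eqtl))
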