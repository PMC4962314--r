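#!/usr/bin/env Rscript
# Link risk SNPs to genes through the eQTL table: keep associations whose
# SNP is in the LD-expanded risk set at p < 2.5e-5, then tabulate tissue
# concordance with the chromatin enrichment calls.

suppressMessages(library(chromenrich))

scn_dir <- "results/scenario"
for (f in c("eqtl.tsv", "tissue_map.tsv")) {
  if (!file.exists(file.path(scn_dir, f))) {
    stop("missing ", f, "; run analysis/01_simulate.R first")
  }
}
if (!file.exists("results/enrichment.tsv")) {
  stop("no enrichment results; run analysis/04_enrichment.R first")
}

panel <- read_vcf(file.path(scn_dir, "panel.vcf"))$panel
indices <- filter_index_snps(read_tsv(file.path(scn_dir, "index_snps.tsv")),
                             read_tsv(file.path(scn_dir, "exclusions.tsv")))
locus_snps <- lapply(indices$rsid, function(id) {
  expand_index(id, panel)$members$rsid
})
names(locus_snps) <- indices$rsid

records <- read_eqtl(file.path(scn_dir, "eqtl.tsv"))
links <- subset_eqtl(records, unlist(locus_snps), p_max = 2.5e-5)
write_tsv(links, "results/eqtl_links.tsv")

results <- read_tsv("results/enrichment.tsv")
tmap <- read_tsv(file.path(scn_dir, "tissue_map.tsv"))
conc <- tissue_concordance(results, links, tmap, locus_snps = locus_snps)
write_tsv(conc, "results/concordance.tsv")

message(nrow(links), " significant risk-SNP eQTL association(s)")
hits <- conc[conc$enriched & conc$n_eqtl_genes > 0, ]
message(nrow(hits), " locus-tissue pair(s) concordant between chromatin ",
        "enrichment and eQTL evidence:")
for (i in seq_len(nrow(hits))) {
  message("  ", hits$locus_id[i], " in ", hits$cell_type[i], " (",
          hits$n_eqtl_genes[i], " gene(s))")
}
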