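#!/usr/bin/env Rscript
# Per-locus, per-cell-type, per-category hypergeometric enrichment of risk
# SNPs in regulatory states against the local 1 Mb SNP background, with
# within-locus Benjamini-Hochberg adjustment, and assembly of the
# cell-type x locus -ln(q) matrix for the pooled active category.

suppressMessages(library(chromenrich))

scn_dir <- "results/scenario"
if (!file.exists(file.path(scn_dir, "panel.vcf"))) {
  stop("no scenario found under ", scn_dir, "; run analysis/01_simulate.R first")
}

vcf <- read_vcf(file.path(scn_dir, "panel.vcf"))
indices <- filter_index_snps(read_tsv(file.path(scn_dir, "index_snps.tsv")),
                             read_tsv(file.path(scn_dir, "exclusions.tsv")))

risk_sets <- list(); backgrounds <- list()
for (id in indices$rsid) {
  set <- expand_index(id, vcf$panel)
  risk_sets[[id]] <- set
  v <- vcf$variants
  backgrounds[[id]] <- v[v$chrom == set$locus$chrom, , drop = FALSE]
}

peak_dir <- file.path(scn_dir, "peaks")
beds <- list.files(peak_dir, pattern = "\\.bed$")
tissues <- sort(unique(sub("_[^_]+\\.bed$", "", beds)))
tracks <- lapply(tissues, function(t) {
  classify(read_bed(file.path(peak_dir, paste0(t, "_H3K4me3.bed"))),
           read_bed(file.path(peak_dir, paste0(t, "_H3K4me1.bed"))),
           read_bed(file.path(peak_dir, paste0(t, "_H3K27ac.bed"))), t)
})

results <- enrich_all(risk_sets, backgrounds, tracks, fdr_family = "locus")
write_tsv(results, "results/enrichment.tsv")
m <- build_matrix(results, category = "EAR&PAR", scale = "neg_ln_q")
write_matrix(m, "results/matrix.tsv")

sig <- results[results$q < 0.05, ]
message(nrow(results), " tests; ", nrow(sig), " significant at FDR < 0.05")
message("enriched loci: ",
        paste(unique(sig$locus_id), collapse = ", "))
top <- results[order(results$q), ][1:3, ]
message("top hits (locus / cell type / category / -ln q):")
for (i in 1:3) {
  message("  ", top$locus_id[i], " / ", top$cell_type[i], " / ",
          top$category[i], " / ", round(top$neg_ln_q[i], 2))
}
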