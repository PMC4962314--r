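#!/usr/bin/env Rscript
# Cluster the enrichment matrix (Euclidean distance on -ln q, average
# linkage) on both axes, export the dendrograms as Newick and render the
# white-to-red heatmap.

suppressMessages(library(chromenrich))

if (!file.exists("results/matrix.tsv")) {
  stop("no enrichment matrix; run analysis/04_enrichment.R first")
}
tab <- read_tsv("results/matrix.tsv")
m <- as.matrix(tab[, -1, drop = FALSE])
rownames(m) <- tab$cell_type

row_tree <- average_linkage(euclidean_distances(m, "rows"))
col_tree <- average_linkage(euclidean_distances(m, "cols"))
write_newick(row_tree, "results/cell_types.nwk")
write_newick(col_tree, "results/loci.nwk")
render_heatmap(m, row_tree, col_tree, "results/heatmap.png")

message("cell-type leaf order: ",
        paste(row_tree$labels[row_tree$order], collapse = " "))
message("locus leaf order: ",
        paste(col_tree$labels[col_tree$order], collapse = " "))
message("heatmap -> results/heatmap.png")
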