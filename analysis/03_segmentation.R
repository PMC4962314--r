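#!/usr/bin/env Rscript
# Classify every cell type's genome into regulatory states from the three
# histone-mark peak sets (PAR/PPR promoters from H3K4me3, EAR/EPR
# enhancers from H3K4me1 outside promoters, activity from H3K27ac
# overlap) and write one BED4 segmentation per cell type.

suppressMessages(library(chromenrich))

peak_dir <- "results/scenario/peaks"
if (!dir.exists(peak_dir)) {
  stop("no peaks under ", peak_dir, "; run analysis/01_simulate.R first")
}
dir.create("results/segmentation", showWarnings = FALSE, recursive = TRUE)

beds <- list.files(peak_dir, pattern = "\\.bed$")
tissues <- sort(unique(sub("_[^_]+\\.bed$", "", beds)))
for (t in tissues) {
  track <- classify(
    read_bed(file.path(peak_dir, paste0(t, "_H3K4me3.bed"))),
    read_bed(file.path(peak_dir, paste0(t, "_H3K4me1.bed"))),
    read_bed(file.path(peak_dir, paste0(t, "_H3K27ac.bed"))),
    cell_type = t)
  write_segmentation_bed(track, file.path("results/segmentation",
                                          paste0(t, ".bed")))
  tab <- table(S4Vectors::mcols(track$segments)$label)
  message(t, ": ", paste(names(tab), tab, sep = "=", collapse = " "))
}
message(length(tissues), " segmentations -> results/segmentation/")
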