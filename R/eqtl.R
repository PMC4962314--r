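# eQTL linking: subset association records to the LD-expanded risk-SNP set,
# apply the significance threshold, and report tissue concordance with the
# chromatin enrichment results.

#' Read an eQTL association table
#'
#' Expects a TSV with columns `rsid`, `gene`, `tissue`, `sign` (`+`/`-`,
#' the direction of the association) and `p`.
#'
#' @param path TSV path.
#' @return data.frame of eQTL records.
#' @export
read_eqtl <- function(path) {
  rec <- read_tsv(path)
  .chk(all(c("rsid", "gene", "tissue", "sign", "p") %in% names(rec)),
       "eQTL table needs columns rsid, gene, tissue, sign, p")
  .chk(all(rec$p >= 0 & rec$p <= 1), "eQTL p-values must lie in [0, 1]")
  rec
}

#' Subset eQTL records to a SNP set at a significance threshold
#'
#' Keeps records whose rsid is in the (LD-expanded) SNP set and whose
#' p-value is at most `p_max` (default 2.5e-5), preserving input order.
#'
#' @param records eQTL data.frame (see [read_eqtl()]).
#' @param snps character vector of rsids.
#' @param p_max significance threshold.
#' @return filtered data.frame.
#' @export
subset_eqtl <- function(records, snps, p_max = 2.5e-5) {
  .chk(all(records$p >= 0 & records$p <= 1), "eQTL p-values must lie in [0, 1]")
  out <- records[records$rsid %in% snps & records$p <= p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNPs within a flank of a gene anchor
#'
#' Returns the rsids lying within `flank_bp` (inclusive) of an anchor
#' position on its chromosome — the +/- 50 kb neighbourhood used to gather
#' polymorphisms around a gene of interest.
#'
#' @param variants variant data.frame.
#' @param anchor list or vector with `chrom` and `pos`.
#' @param flank_bp flank size in bp (default 50,000).
#' @return character vector of rsids.
#' @export
window_snps_for_gene <- function(variants, anchor, flank_bp = 50000) {
  if (nrow(variants) == 0L) return(character())
  chrom <- if (is.list(anchor)) anchor$chrom else anchor[["chrom"]]
  pos <- as.numeric(if (is.list(anchor)) anchor$pos else anchor[["pos"]])
  keep <- variants$chrom == chrom & abs(variants$pos - pos) <= flank_bp
  variants$rsid[keep]
}

#' Tissue concordance between chromatin enrichment and eQTL evidence
#'
#' For every (locus, mapped tissue) pair, reports whether the locus is
#' enriched (q < `fdr`) in that cell type and how many distinct genes have
#' matching eQTL records in the corresponding eQTL tissue. Cell types and
#' eQTL tissues come from different ontologies, so an explicit mapping is
#' required; eQTL records in unmapped tissues are excluded with a message.
#'
#' @param enrich_results data.frame from [enrich_all()] (must carry `q`).
#' @param eqtl_records significant eQTL records (after [subset_eqtl()]).
#' @param tissue_map data.frame with columns `cell_type`, `eqtl_tissue`.
#' @param locus_snps optional named list (locus id -> rsids of risk SNPs);
#'   when supplied, eQTL records must also match the locus's SNPs.
#' @param fdr enrichment significance threshold (default 0.05).
#' @param category enrichment category to assess (default the pooled
#'   active category `"EAR&PAR"`).
#' @return data.frame: `locus_id`, `cell_type`, `eqtl_tissue`, `enriched`,
#'   `n_eqtl_genes`.
#' @export
tissue_concordance <- function(enrich_results, eqtl_records, tissue_map,
                               locus_snps = NULL, fdr = 0.05,
                               category = "EAR&PAR") {
  .chk(all(c("cell_type", "eqtl_tissue") %in% names(tissue_map)),
       "tissue_map needs columns cell_type, eqtl_tissue")
  if (nrow(tissue_map) == 0L) {
    return(data.frame(locus_id = character(), cell_type = character(),
                      eqtl_tissue = character(), enriched = logical(),
                      n_eqtl_genes = integer(), stringsAsFactors = FALSE))
  }
  unmapped <- setdiff(unique(eqtl_records$tissue), tissue_map$eqtl_tissue)
  if (length(unmapped) > 0L) {
    message("eQTL tissue(s) without a cell-type mapping excluded: ",
            paste(unmapped, collapse = ", "))
  }
  res <- enrich_results[enrich_results$category == category, , drop = FALSE]
  loci <- unique(res$locus_id)
  rows <- list()
  for (locus in loci) {
    for (i in seq_len(nrow(tissue_map))) {
      ct <- tissue_map$cell_type[i]
      et <- tissue_map$eqtl_tissue[i]
      hit <- res[res$locus_id == locus & res$cell_type == ct, , drop = FALSE]
      if (nrow(hit) == 0L) next
      rec <- eqtl_records[eqtl_records$tissue == et, , drop = FALSE]
      if (!is.null(locus_snps)) {
        rec <- rec[rec$rsid %in% locus_snps[[locus]], , drop = FALSE]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = locus, cell_type = ct, eqtl_tissue = et,
        enriched = any(hit$q < fdr),
        n_eqtl_genes = length(unique(rec$gene)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus_id = character(), cell_type = character(),
                      eqtl_tissue = character(), enriched = logical(),
                      n_eqtl_genes = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
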