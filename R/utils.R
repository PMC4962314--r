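#' @keywords internal
"_PACKAGE"

#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom GenomeInfoDb Seqinfo
#' @importFrom methods is
NULL

# Internal: stop with a consistent prefix so pipeline stages can report the
# failing stage.
.chk <- function(ok, ...) {
  if (!ok) stop(..., call. = FALSE)
  invisible(TRUE)
}

# Derive a reproducible sub-seed from a master seed and a stream counter.
# Keeps all derived seeds strictly below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647)
}

# Validate a variant table: rsid, chrom, pos (1-based), ref, alt.
validate_variants <- function(variants) {
  .chk(is.data.frame(variants), "variants must be a data.frame")
  need <- c("rsid", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  .chk(length(miss) == 0L,
       "variant table is missing columns: ", paste(miss, collapse = ", "))
  .chk(all(variants$pos >= 1L), "variant positions must be 1-based (>= 1)")
  .chk(!anyDuplicated(variants$rsid), "rsids must be unique within a panel")
  .chk(all(variants$ref != variants$alt), "ref and alt alleles must differ")
  invisible(variants)
}

# Variants (1-based pos) -> width-1 GRanges.
variants_to_granges <- function(variants) {
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges   = IRanges::IRanges(start = variants$pos, width = 1L),
    rsid     = variants$rsid
  )
}

#' Write a table as tab-separated text
#'
#' Thin wrapper standardising the TSV dialect used for every result table
#' (no quoting, no row names, header row).
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}
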