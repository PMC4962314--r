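# Rules-based chromatin segmentation from three histone marks.
#
# States: PAR / PPR (active / poised promoter, H3K4me3) and EAR / EPR
# (active / poised enhancer, H3K4me1 outside H3K4me3), with activity decided
# by any >= 1 bp overlap with H3K27ac at the peak level. Promoter marks take
# precedence base-wise where the two methylation marks overlap. Everything
# not covered by H3K4me3 or H3K4me1 is unlabelled (NONE).

SEG_LABELS <- c("PAR", "PPR", "EAR", "EPR", "NONE")

#' Read a BED file of peak calls
#'
#' Reads BED3+ peak intervals into a `GRanges` (1-based internally, as is
#' the Bioconductor convention; BED input is 0-based half-open).
#'
#' @param path BED file path.
#' @return `GRanges` of peak intervals.
#' @export
read_bed <- function(path) {
  .chk(file.exists(path), "BED not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Write a segmentation track as BED4
#'
#' The state label goes in the BED name column; the itemRgb column carries
#' the browser colour scheme (orange EAR, rose PAR, light purple EPR/PPR).
#'
#' @param track a `segmentation_track`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_segmentation_bed <- function(track, path) {
  gr <- track$segments
  colmap <- c(PAR = "#FF9E9E", PPR = "#C5B3E6",
              EAR = "#FFA500", EPR = "#C5B3E6")
  S4Vectors::mcols(gr)$name <- S4Vectors::mcols(gr)$label
  S4Vectors::mcols(gr)$itemRgb <- colmap[S4Vectors::mcols(gr)$label]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Merge (union) intervals of one mark; accepts GRanges or a data.frame of
# (chrom, start, end) in 0-based half-open coordinates. Returns a named
# list of reduced IRanges, one per chromosome.
.peaks_by_chrom <- function(x) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) {
    .chk(all(c("chrom", "start", "end") %in% names(x)),
         "peak data.frame needs chrom, start, end")
    .chk(all(x$start < x$end), "peak intervals must have start < end")
    chrom <- as.character(x$chrom)
    ir <- IRanges::IRanges(start = x$start + 1L, end = x$end)
  } else {
    .chk(methods::is(x, "GRanges"), "peaks must be GRanges or data.frame")
    chrom <- as.character(GenomicRanges::seqnames(x))
    ir <- GenomicRanges::ranges(x)
  }
  idx <- split(seq_along(chrom), chrom)
  lapply(idx, function(i) IRanges::reduce(ir[i]))
}

#' Classify one cell type's genome into regulatory states
#'
#' Applies the precedence rules: H3K4me3 peaks are promoters (PAR if the
#' peak overlaps H3K27ac by >= 1 bp, else PPR); bases covered by H3K4me1 but
#' not H3K4me3 are enhancers (EAR if the containing merged H3K4me1 peak
#' overlaps H3K27ac, else EPR); all remaining bases are unlabelled. Each
#' base receives exactly one state, and adjacent same-label segments are
#' coalesced.
#'
#' @param h3k4me3,h3k4me1,h3k27ac peak sets: `GRanges`, or data.frames with
#'   `chrom`, `start`, `end` in 0-based half-open coordinates, or `NULL`.
#' @param cell_type cell-type identifier attached to the track.
#' @return An object of class `segmentation_track`: list with `cell_type`
#'   and `segments` (sorted disjoint `GRanges` with a `label` metadata
#'   column; unlabelled gaps are not stored).
#' @export
classify <- function(h3k4me3, h3k4me1, h3k27ac, cell_type = "cell") {
  me3 <- .peaks_by_chrom(h3k4me3)
  me1 <- .peaks_by_chrom(h3k4me1)
  ac  <- .peaks_by_chrom(h3k27ac)
  chroms <- sort(unique(c(names(me3), names(me1), names(ac))))

  empty <- IRanges::IRanges()
  per_chrom <- lapply(chroms, function(ch) {
    m3 <- me3[[ch]] %||% empty
    m1 <- me1[[ch]] %||% empty
    a  <- ac[[ch]]  %||% empty
    prom_lab <- ifelse(IRanges::overlapsAny(m3, a), "PAR", "PPR")
    # enhancer bases = H3K4me1 minus every promoter base (precedence)
    pieces <- IRanges::setdiff(m1, m3)
    piece_lab <- character(0)
    if (length(pieces) > 0L) {
      enh_active <- IRanges::overlapsAny(m1, a)
      ov <- IRanges::findOverlaps(pieces, m1)
      # merged me1 peaks are disjoint, so each piece maps to exactly one
      .chk(length(ov) == length(pieces), "internal: enhancer piece mapping")
      piece_lab <- character(length(pieces))
      piece_lab[S4Vectors::queryHits(ov)] <-
        ifelse(enh_active[S4Vectors::subjectHits(ov)], "EAR", "EPR")
    }
    st <- c(IRanges::start(m3), IRanges::start(pieces))
    en <- c(IRanges::end(m3), IRanges::end(pieces))
    lb <- c(prom_lab, piece_lab)
    n <- length(st)
    if (n == 0L) return(NULL)
    ord <- order(st)
    st <- st[ord]; en <- en[ord]; lb <- lb[ord]
    # coalesce adjacent (abutting) same-label segments
    if (n > 1L) {
      fresh <- c(TRUE, !(lb[-1L] == lb[-n] & st[-1L] == en[-n] + 1L))
      last <- c(which(fresh)[-1L] - 1L, n)
      st <- st[fresh]; en <- en[last]; lb <- lb[fresh]
    }
    list(chrom = rep(ch, length(st)), start = st, end = en, label = lb)
  })
  per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
  if (length(per_chrom) == 0L) {
    segs <- GenomicRanges::GRanges()
    S4Vectors::mcols(segs)$label <- character(0)
  } else {
    segs <- GenomicRanges::GRanges(
      unlist(lapply(per_chrom, `[[`, "chrom")),
      IRanges::IRanges(start = unlist(lapply(per_chrom, `[[`, "start")),
                       end = unlist(lapply(per_chrom, `[[`, "end"))),
      label = unlist(lapply(per_chrom, `[[`, "label")))
  }
  structure(list(cell_type = cell_type, segments = segs),
            class = "segmentation_track")
}

#' @export
print.segmentation_track <- function(x, ...) {
  tab <- table(S4Vectors::mcols(x$segments)$label)
  cat("segmentation_track [", x$cell_type, "]: ",
      length(x$segments), " segments (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Annotate SNPs with their chromatin state
#'
#' Labels each SNP by the unique segment containing it (positions are
#' 1-based; segments are disjoint). Uncovered SNPs are labelled `NONE`.
#'
#' @param variants variant data.frame (`rsid`, `chrom`, `pos`, ...).
#' @param track a `segmentation_track` from [classify()].
#' @return data.frame with `rsid`, `chrom`, `pos`, `cell_type`, `label`.
#' @export
annotate_snps <- function(variants, track) {
  .chk(inherits(track, "segmentation_track"), "track must be a segmentation_track")
  lab <- rep("NONE", nrow(variants))
  if (length(track$segments) > 0L && nrow(variants) > 0L) {
    gr <- variants_to_granges(variants)
    ov <- GenomicRanges::findOverlaps(gr, track$segments)
    lab[S4Vectors::queryHits(ov)] <-
      S4Vectors::mcols(track$segments)$label[S4Vectors::subjectHits(ov)]
  }
  data.frame(rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
             cell_type = track$cell_type, label = lab,
             stringsAsFactors = FALSE)
}
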