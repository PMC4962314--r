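# Linkage disequilibrium: haplotype panels, r-squared, and expansion of GWAS
# index SNPs into sets of correlated surrogates ("risk SNPs").

#' Construct a haplotype panel
#'
#' A haplotype panel couples a table of biallelic SNPs with a binary
#' haplotype matrix: one row per phased haplotype, one column per variant,
#' 0 = reference allele, 1 = alternate allele.
#'
#' @param variants data.frame with columns `rsid`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param haplotypes integer/numeric matrix of 0/1 with `ncol ==
#'   nrow(variants)`; at least two rows (one diploid sample).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(variants, haplotypes) {
  validate_variants(variants)
  haplotypes <- as.matrix(haplotypes)
  .chk(ncol(haplotypes) == nrow(variants),
       "haplotype matrix has ", ncol(haplotypes), " columns but ",
       nrow(variants), " variants")
  .chk(nrow(haplotypes) >= 2L, "a panel needs at least 2 haplotypes")
  .chk(all(haplotypes %in% c(0, 1)), "haplotype entries must be 0 or 1")
  storage.mode(haplotypes) <- "integer"
  colnames(haplotypes) <- variants$rsid
  structure(list(variants = variants, haplotypes = haplotypes),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$variants), "variants x",
      nrow(x$haplotypes), "haplotypes on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read phased biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file into a [haplotype_panel()]. Only biallelic SNP
#' records (single-base REF and ALT) are retained; multiallelic records and
#' indels are dropped. Genotypes must be phased (`|` separator) because
#' r-squared is defined on haplotypes, not genotype dosages.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param region optional `"chrom:start-end"` string (1-based, inclusive);
#'   only records inside the region are returned.
#' @return A list with elements `variants` (data.frame) and `panel`
#'   (`haplotype_panel`). Variant order matches file order.
#' @export
read_vcf <- function(path, region = NULL) {
  .chk(file.exists(path), "VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  .chk(nrow(fix) > 0L, "no records in VCF: ", path)
  gt_field <- v@gt
  .chk(!is.null(gt_field) && ncol(gt_field) >= 2L,
       "VCF has no genotype columns: ", path)

  pos <- as.integer(fix$POS)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    .chk(length(m) == 4L, "region must look like 'chr1:100-200', got: ", region)
    keep <- keep & fix$CHROM == m[2] &
      pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  .chk(any(keep), "no biallelic SNP records retained from ", path)

  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  gt <- gt_field[keep, -1, drop = FALSE]          # drop FORMAT column
  fmt <- gt_field[keep, 1]
  .chk(all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1))),
       "record without GT field in ", path)

  # GT is the leading colon-separated field (checked against FORMAT above).
  nrec <- nrow(gt)
  nsamp <- ncol(gt)
  gt_first <- sub(":.*$", "", as.vector(gt))        # column-major flattening
  unph <- grepl("/", gt_first, fixed = TRUE)
  if (any(unph)) {
    bad <- ((which(unph)[1] - 1L) %% nrec) + 1L
    stop("unphased genotype at record ", fix$CHROM[bad], ":", pos[bad],
         " (", fix$ID[bad], "); r-squared requires phased haplotypes",
         call. = FALSE)
  }
  split_gt <- strsplit(gt_first, "|", fixed = TRUE)
  .chk(all(lengths(split_gt) == 2L), "non-diploid genotype encountered in ", path)
  a <- array(as.integer(unlist(split_gt)), dim = c(2L, nrec, nsamp))
  .chk(!anyNA(a), "missing genotype call in ", path)
  # haplotype rows: (allele 1, sample 1), (allele 2, sample 1), (allele 1,
  # sample 2), ... -> 2 * samples rows, one column per variant
  hap <- matrix(aperm(a, c(1L, 3L, 2L)), nrow = 2L * nsamp, ncol = nrec)

  rsid <- fix$ID
  rsid[is.na(rsid) | rsid == "."] <-
    paste0(fix$CHROM, ":", pos)[is.na(rsid) | rsid == "."]
  variants <- data.frame(rsid = rsid, chrom = fix$CHROM, pos = pos,
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  panel <- haplotype_panel(variants, hap)
  list(variants = variants, panel = panel)
}

#' Linkage-disequilibrium r-squared between two variants
#'
#' Computes `r^2 = D^2 / (pA (1-pA) pB (1-pB))` from phased binary allele
#' vectors, where `pA`, `pB` are alternate-allele frequencies and
#' `D = pAB - pA * pB` is the deviation of the joint haplotype frequency
#' from independence. Algebraically identical to the squared Pearson
#' correlation of the two vectors.
#'
#' @param x,y binary (0/1) allele vectors of equal length `>= 2`.
#' @return r-squared in `[0, 1]`.
#' @export
compute_r2 <- function(x, y) {
  .chk(length(x) == length(y), "allele vectors differ in length")
  .chk(length(x) >= 2L, "need at least 2 haplotypes")
  .chk(all(x %in% c(0, 1)) && all(y %in% c(0, 1)),
       "allele vectors must be binary 0/1")
  pA <- mean(x)
  pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("monomorphic variant: LD is undefined", call. = FALSE)
  }
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  (D * D) / (pA * (1 - pA) * pB * (1 - pB))
}

# Vectorised r^2 of one index column against every column of the haplotype
# matrix. Monomorphic columns get NA. Same formula as compute_r2.
r2_against_index <- function(haplotypes, index_col) {
  x <- haplotypes[, index_col]
  n <- nrow(haplotypes)
  pA <- mean(x)
  .chk(!(pA %in% c(0, 1)), "index SNP is monomorphic in the panel")
  p <- colMeans(haplotypes)
  pAB <- as.vector(crossprod(x, haplotypes)) / n
  D <- pAB - pA * p
  r2 <- (D * D) / (pA * (1 - pA) * p * (1 - p))
  r2[p %in% c(0, 1)] <- NA_real_
  r2
}

#' Locus window around an index SNP
#'
#' Builds the background window centred on an index SNP: total span
#' `window_bp` (default 1 Mb, i.e. +/- 500 kb), 0-based half-open, clipped
#' at the chromosome start.
#'
#' @param index single-row variant data.frame (the index SNP).
#' @param window_bp total window span in bp.
#' @return list with `index`, `chrom`, `window_start`, `window_end`
#'   (0-based half-open) and `window_bp`.
#' @export
index_locus <- function(index, window_bp = 1e6) {
  .chk(nrow(index) == 1L, "index must be a single variant row")
  half <- floor(window_bp / 2)
  start0 <- max(0, index$pos - 1 - half)
  end0 <- index$pos - 1 + half
  list(index = index, chrom = index$chrom,
       window_start = start0, window_end = end0, window_bp = window_bp)
}

# Is a 1-based position inside a 0-based half-open window?
in_window <- function(pos, locus) {
  (pos - 1) >= locus$window_start & (pos - 1) < locus$window_end
}

#' Expand an index SNP to its correlated surrogate set
#'
#' Returns every panel variant inside the locus window whose r-squared with
#' the index SNP is at least `r2_min` (default 0.8), plus the index SNP
#' itself at r-squared 1. Members are sorted by position.
#'
#' @param index_rsid rsid of the index SNP; must be present in the panel.
#' @param panel a [haplotype_panel()].
#' @param window_bp total background window span (default 1 Mb).
#' @param r2_min minimum r-squared for surrogate membership (default 0.8).
#' @return An object of class `surrogate_set`: list with `locus` and
#'   `members` (data.frame with variant columns plus `r2` and `index_rsid`).
#' @export
expand_index <- function(index_rsid, panel, window_bp = 1e6, r2_min = 0.8) {
  .chk(inherits(panel, "haplotype_panel"), "panel must be a haplotype_panel")
  idx <- match(index_rsid, panel$variants$rsid)
  .chk(!is.na(idx), "index SNP ", index_rsid, " not found in panel")
  locus <- index_locus(panel$variants[idx, , drop = FALSE], window_bp)

  v <- panel$variants
  cand <- which(v$chrom == locus$chrom & in_window(v$pos, locus))
  r2 <- r2_against_index(panel$haplotypes[, cand, drop = FALSE],
                         match(idx, cand))
  keep <- !is.na(r2) & r2 >= r2_min
  keep[match(idx, cand)] <- TRUE
  members <- v[cand[keep], , drop = FALSE]
  members$r2 <- r2[keep]
  members$r2[members$rsid == index_rsid] <- 1.0
  members$index_rsid <- index_rsid
  members <- members[order(members$pos), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(locus = locus, members = members), class = "surrogate_set")
}

#' @export
print.surrogate_set <- function(x, ...) {
  cat("surrogate_set: index", x$locus$index$rsid, "with",
      nrow(x$members), "risk SNPs (incl. index) in a",
      x$locus$window_bp, "bp window\n")
  invisible(x)
}

#' Apply the index-SNP quality filter
#'
#' Removes listed index SNPs before enrichment analysis (typical reasons:
#' the SNP sits in an assembly exception, or it has no surrogates at
#' r-squared >= 0.8). Each removal is logged with its reason; an exclusion
#' naming an absent rsid yields a warning, not an error.
#'
#' @param indices variant data.frame of index SNPs.
#' @param exclusions data.frame with columns `rsid` and `reason` (may have
#'   zero rows).
#' @return The retained index SNPs, input order preserved.
#' @export
filter_index_snps <- function(indices, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(indices)
  .chk(all(c("rsid", "reason") %in% names(exclusions)),
       "exclusions need columns rsid, reason")
  absent <- setdiff(exclusions$rsid, indices$rsid)
  if (length(absent) > 0L) {
    warning("exclusion rsid(s) not among index SNPs: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  hit <- exclusions$rsid %in% indices$rsid
  for (i in which(hit)) {
    message("removing index SNP ", exclusions$rsid[i], ": ",
            exclusions$reason[i])
  }
  out <- indices[!indices$rsid %in% exclusions$rsid, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write surrogate sets as a TSV table
#'
#' @param sets list of `surrogate_set` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surrogates <- function(sets, path) {
  tab <- do.call(rbind, lapply(sets, function(s) {
    s$members[, c("rsid", "chrom", "pos", "r2", "index_rsid")]
  }))
  write_tsv(tab, path)
}
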