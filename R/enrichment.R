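# Per-locus, per-cell-type, per-category hypergeometric enrichment of risk
# SNPs in chromatin states against the local SNP background, with
# Benjamini-Hochberg FDR control and assembly of the enrichment matrix.

ENRICH_CATEGORIES <- c("EAR", "PAR", "EPR", "PPR", "EAR&PAR")

#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` category SNPs when `n` risk SNPs are
#' drawn without replacement from a window holding `N` background SNPs of
#' which `K` are in the category: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Summation is done in log space for
#' numerical stability of extreme tails.
#'
#' @param k observed overlap count (`0 <= k <= n`).
#' @param N background SNP count in the window.
#' @param K background SNPs in the category (`0 <= K <= N`).
#' @param n risk SNP count (`0 <= n <= N`).
#' @return upper-tail probability in `[0, 1]`.
#' @export
hypergeom_sf <- function(k, N, K, n) {
  .chk(K >= 0 && K <= N, "need 0 <= K <= N (got K=", K, ", N=", N, ")")
  .chk(n >= 0 && n <= N, "need 0 <= n <= N (got n=", n, ", N=", N, ")")
  .chk(k >= 0 && k <= n, "need 0 <= k <= n (got k=", k, ", n=", n, ")")
  lo <- max(0, n - (N - K))     # smallest achievable overlap
  if (k <= lo) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  kk <- k:hi
  lt <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

# Does a state label fall in an enrichment category? The pooled category
# "EAR&PAR" counts a SNP once if its label is either active state.
label_in_category <- function(label, category) {
  .chk(category %in% ENRICH_CATEGORIES,
       "unknown category: ", category)
  if (category == "EAR&PAR") label %in% c("EAR", "PAR") else label == category
}

#' One enrichment test: risk SNPs vs local background in one state category
#'
#' Counts risk and background SNPs falling in the category under one cell
#' type's segmentation and evaluates the hypergeometric upper tail. The
#' background must contain every risk SNP (they are window SNPs too; draws
#' are without replacement).
#'
#' @param locus_id identifier for the locus (usually the index rsid).
#' @param risk `surrogate_set` for the locus.
#' @param background variant data.frame of all window SNPs (risk included).
#' @param track `segmentation_track` for one cell type.
#' @param category one of `"EAR"`, `"PAR"`, `"EPR"`, `"PPR"`, `"EAR&PAR"`.
#' @return one-row data.frame: `locus_id`, `cell_type`, `category`, `k`,
#'   `n`, `K`, `N`, `p`.
#' @export
enrich <- function(locus_id, risk, background, track, category) {
  .chk(inherits(risk, "surrogate_set"), "risk must be a surrogate_set")
  .chk(all(risk$members$rsid %in% background$rsid),
       "risk SNP(s) absent from the background set at locus ", locus_id)
  ann <- annotate_snps(background, track)
  in_cat <- label_in_category(ann$label, category)
  N <- nrow(background)
  K <- sum(in_cat)
  is_risk <- background$rsid %in% risk$members$rsid
  n <- sum(is_risk)
  k <- sum(in_cat & is_risk)
  data.frame(locus_id = locus_id, cell_type = track$cell_type,
             category = category, k = k, n = n, K = K, N = N,
             p = hypergeom_sf(k, N, K, n), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted values (clipped at 1), in the input order.
#' @export
bh_adjust <- function(pvals) {
  .chk(all(is.finite(pvals)) && all(pvals >= 0) && all(pvals <= 1),
       "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Run every enrichment test across loci, cell types and categories
#'
#' Loops the hypergeometric test over all (locus, cell type, category)
#' combinations, then adds BH-adjusted q-values. The multiple-testing
#' family is switchable: `"locus"` (default) adjusts over all cell types
#' and categories within each locus; `"cell_type"` adjusts over all loci
#' and categories within each cell type.
#'
#' Loci whose risk set holds fewer than two SNPs (no surrogates beyond the
#' index) are skipped with a message, mirroring the index-SNP filter.
#'
#' @param risk_sets named list of `surrogate_set`s (names = locus ids).
#' @param backgrounds named list of background variant data.frames, one per
#'   locus id.
#' @param tracks list of `segmentation_track`s (one per cell type).
#' @param categories state categories to test.
#' @param fdr_family `"locus"` or `"cell_type"`.
#' @return data.frame of enrichment results with `q` and `neg_ln_q`.
#' @export
enrich_all <- function(risk_sets, backgrounds, tracks,
                       categories = ENRICH_CATEGORIES,
                       fdr_family = c("locus", "cell_type")) {
  fdr_family <- match.arg(fdr_family)
  .chk(length(risk_sets) > 0L, "no risk sets supplied")
  loci <- names(risk_sets)
  .chk(!is.null(loci) && all(loci %in% names(backgrounds)),
       "risk_sets and backgrounds must be named by locus id")

  testable <- loci[vapply(risk_sets, function(s) nrow(s$members) >= 2L,
                          logical(1))]
  for (locus_id in setdiff(loci, testable)) {
    message("skipping locus ", locus_id,
            ": fewer than 2 risk SNPs (no surrogates at r2 threshold)")
  }
  .chk(length(testable) > 0L, "no testable loci (all skipped)")

  # pool the per-locus backgrounds so each track is annotated only once
  pooled <- do.call(rbind, lapply(testable, function(locus_id) {
    background <- backgrounds[[locus_id]]
    risk <- risk_sets[[locus_id]]
    .chk(all(risk$members$rsid %in% background$rsid),
         "risk SNP(s) absent from background at locus ", locus_id)
    background$.locus <- locus_id
    background$.risk <- background$rsid %in% risk$members$rsid
    background
  }))
  by_locus <- split(seq_len(nrow(pooled)), pooled$.locus)

  rows <- list()
  for (track in tracks) {
    lab <- annotate_snps(pooled, track)$label
    for (locus_id in testable) {
      rws <- by_locus[[locus_id]]
      is_risk <- pooled$.risk[rws]
      N <- length(rws)
      n <- sum(is_risk)
      for (cat in categories) {
        in_cat <- label_in_category(lab[rws], cat)
        K <- sum(in_cat)
        k <- sum(in_cat & is_risk)
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = locus_id, cell_type = track$cell_type, category = cat,
          k = k, n = n, K = K, N = N, p = hypergeom_sf(k, N, K, n),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  fam <- if (fdr_family == "locus") out$locus_id else out$cell_type
  out$q <- stats::ave(out$p, fam, FUN = bh_adjust)
  out$neg_ln_q <- -log(out$q)
  rownames(out) <- NULL
  out
}

#' Assemble the cell-type x locus enrichment matrix
#'
#' Rows are cell types, columns are loci, entries are `-ln(q)` (default) or
#' `-ln(p)` for one category. Combinations without a test are 0.
#'
#' @param results data.frame from [enrich_all()].
#' @param category single category to extract.
#' @param scale `"neg_ln_q"` or `"neg_ln_p"`.
#' @return numeric matrix with cell types as rownames, loci as colnames.
#' @export
build_matrix <- function(results, category = "EAR&PAR",
                         scale = c("neg_ln_q", "neg_ln_p")) {
  scale <- match.arg(scale)
  res <- results[results$category == category, , drop = FALSE]
  .chk(nrow(res) > 0L, "no results for category ", category)
  key <- paste(res$locus_id, res$cell_type)
  .chk(!anyDuplicated(key),
       "duplicate (locus, cell_type) result for category ", category)
  cells <- sort(unique(res$cell_type))
  loci <- sort(unique(res$locus_id))
  m <- matrix(0, nrow = length(cells), ncol = length(loci),
              dimnames = list(cells, loci))
  val <- if (scale == "neg_ln_q") -log(res$q) else -log(res$p)
  m[cbind(match(res$cell_type, cells), match(res$locus_id, loci))] <- val
  m
}

#' Write the enrichment matrix as TSV
#'
#' @param m matrix from [build_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(cell_type = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}
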