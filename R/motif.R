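# Allele-aware transcription-factor motif scanning around SNPs.
#
# Scoring contract: the raw score of a width-w window is the weighted sum
# sum_j log(prob[j, base_j] / background[base_j]); the scaled score maps it
# to [0, 1] by the column-wise extremes of the log-ratio matrix, so the
# consensus sequence scores 1 and the anti-consensus 0. Match p-values are
# exact (up to score discretisation) tail probabilities of the raw score of
# a random background sequence, computed by dynamic programming over the
# binned per-position score distribution.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param motif_id motif identifier.
#' @param probs width x 4 matrix of base probabilities, columns in
#'   A, C, G, T order; each row must sum to 1.
#' @param tf_name transcription-factor name (defaults to `motif_id`).
#' @param background length-4 base composition of the null model (sums to
#'   1; default uniform).
#' @param pseudocount pseudocount used when counts were converted (kept for
#'   provenance).
#' @return object of class `pwm`.
#' @export
pwm <- function(motif_id, probs, tf_name = motif_id,
                background = rep(0.25, 4), pseudocount = 0.8) {
  probs <- as.matrix(probs)
  .chk(ncol(probs) == 4L, "probs must have 4 columns (A,C,G,T)")
  .chk(nrow(probs) >= 2L, "motif width must be >= 2")
  .chk(all(abs(rowSums(probs) - 1) < 1e-9), "each probs row must sum to 1")
  .chk(all(probs > 0), "probs must be strictly positive (apply a pseudocount)")
  .chk(length(background) == 4L && abs(sum(background) - 1) < 1e-9,
       "background must be 4 probabilities summing to 1")
  colnames(probs) <- DNA_BASES
  structure(list(motif_id = motif_id, tf_name = tf_name, probs = probs,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm ", x$motif_id, " (", x$tf_name, "), width ",
      nrow(x$probs), ", consensus ", pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (column-max base at each position)
#'
#' @param p a `pwm`.
#' @return character string of length = motif width.
#' @export
pwm_consensus <- function(p) {
  paste(DNA_BASES[apply(p$probs, 1, which.max)], collapse = "")
}

# Log-ratio matrix log(prob / background), width x 4.
.pwm_logratio <- function(p) {
  sweep(log(p$probs), 2, log(p$background), "-")
}

#' Read position matrices in JASPAR format
#'
#' Accepts the JASPAR text dialects: a `>ID name` header followed by four
#' base rows, either bracketed (`A [ 4 19 0 ]`) or bare numbers. Count
#' matrices are converted to probabilities with a background-weighted
#' pseudocount: `p = (count + pseudocount * bg) / (total + pseudocount)`.
#'
#' @param path JASPAR-format file.
#' @param background length-4 background for the resulting PWMs.
#' @param pseudocount smoothing pseudocount (default 0.8, a common JASPAR
#'   processing choice).
#' @return list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  .chk(file.exists(path), "JASPAR file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  .chk(length(heads) > 0L, "no motif headers ('>') in ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    motif_id <- toks[1]
    tf_name <- if (length(toks) > 1L) toks[2] else toks[1]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    .chk(length(body) == 4L, "motif ", motif_id, ": expected 4 base rows, got ",
         length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- lengths(rows)
    .chk(length(unique(w)) == 1L,
         "motif ", motif_id, ": base rows have unequal lengths (",
         paste(w, collapse = ","), ")")
    counts <- t(do.call(rbind, rows))          # width x 4, A,C,G,T order
    tot <- rowSums(counts)
    if (all(abs(tot - 1) < 1e-6)) {
      probs <- counts                           # already probabilities
      probs <- (probs + 1e-9) / rowSums(probs + 1e-9)
    } else {
      probs <- sweep(counts, 2, pseudocount * background, "+") / (tot + pseudocount)
    }
    out[[i]] <- pwm(motif_id, probs, tf_name, background, pseudocount)
  }
  out
}

#' Write PWMs in JASPAR count format
#'
#' Probabilities are scaled to pseudo-counts (x 100) so the file round-trips
#' through [read_jaspar()] up to smoothing.
#'
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id, " ", p$tf_name), con)
    counts <- round(p$probs * 100, 4)
    for (b in 1:4) {
      writeLines(paste0(DNA_BASES[b], " [ ",
                        paste(counts[, b], collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

.seq_to_idx <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  if (anyNA(idx)) {
    stop("sequence contains non-ACGT base: ", seq, call. = FALSE)
  }
  idx
}

.revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

#' Score one sequence window against a PWM
#'
#' @param p a `pwm`.
#' @param seq A/C/G/T string whose length equals the motif width.
#' @return list with `raw` (weighted log-ratio sum) and `scaled` (min-max
#'   rescaled to `[0, 1]`; consensus scores 1, anti-consensus 0).
#' @export
score_window <- function(p, seq) {
  idx <- .seq_to_idx(seq)
  l <- .pwm_logratio(p)
  .chk(length(idx) == nrow(l), "sequence length (", length(idx),
       ") must equal motif width (", nrow(l), ")")
  raw <- sum(l[cbind(seq_along(idx), idx)])
  lo <- sum(apply(l, 1, min))
  hi <- sum(apply(l, 1, max))
  list(raw = raw, scaled = (raw - lo) / (hi - lo))
}

# Discretised distribution of the raw score of a background-random sequence.
# Returns bin width eps, integer bin offset, and the probability vector over
# achievable binned sums. eps = 1e-3 of the raw-score range, so the
# discretisation error of any sequence score is at most width * eps / 2,
# far below the 5e-5 match cutoff regime.
.pwm_score_dist <- function(p, eps_frac = 1e-3) {
  l <- .pwm_logratio(p)
  w <- nrow(l)
  lo <- sum(apply(l, 1, min))
  hi <- sum(apply(l, 1, max))
  eps <- (hi - lo) * eps_frac
  if (eps == 0) eps <- 1e-12   # degenerate flat motif
  kb <- round(l / eps)         # integer bins, possibly negative
  mins <- apply(kb, 1, min)
  maxs <- apply(kb, 1, max)
  # dense DP over achievable bin sums
  off <- sum(mins)
  len <- sum(maxs - mins) + 1L
  v <- numeric(len)
  v[1] <- 1
  cur_len <- 1L
  for (j in seq_len(w)) {
    span <- maxs[j] - mins[j]
    nv <- numeric(cur_len + span)
    for (b in 1:4) {
      sh <- kb[j, b] - mins[j]
      nv[(1 + sh):(cur_len + sh)] <- nv[(1 + sh):(cur_len + sh)] +
        v[seq_len(cur_len)] * p$background[b]
    }
    cur_len <- cur_len + span
    v <- nv
  }
  list(eps = eps, offset = off, prob = v, lo = lo, hi = hi)
}

#' Exact match p-value of a raw PWM score
#'
#' `P(score of a random background sequence >= raw_score)`, computed by
#' dynamic programming over the discretised per-position score
#' distribution (bin width 1e-3 of the raw-score range), exact up to
#' discretisation.
#'
#' @param p a `pwm`.
#' @param raw_score raw (weighted-sum) score, as returned in
#'   `score_window()$raw`.
#' @return tail probability in `[0, 1]`.
#' @export
score_pvalue <- function(p, raw_score) {
  .chk(is.finite(raw_score), "raw_score must be finite")
  d <- .pwm_score_dist(p)
  if (raw_score <= d$lo) return(1)
  if (raw_score > d$hi) return(0)
  .score_pvalue_from_dist(d, raw_score)
}

.score_pvalue_from_dist <- function(d, raw_score) {
  if (raw_score <= d$lo) return(1)
  if (raw_score > d$hi) return(0)
  kthr <- round(raw_score / d$eps)
  i0 <- kthr - d$offset + 1L       # first bin index meeting the threshold
  if (i0 <= 1L) return(1)
  # an achievable raw score (<= hi) always retains at least the top bin,
  # so the maximal-score sequence never gets tail probability 0
  i0 <- min(i0, length(d$prob))
  min(1, sum(d$prob[i0:length(d$prob)]))
}

#' Allele-aware motif-disruption scan at a SNP
#'
#' Scans every PWM window overlapping the SNP on both strands, scoring the
#' reference and alternate alleles. For each motif the best window/strand
#' (smallest `min(ref_p, alt_p)`) is kept, and a result is emitted when
#' that minimum reaches the match-p cutoff. The effect size is the scaled
#' score difference `alt - ref`: negative = the risk allele weakens the
#' match (motif destroyed), positive = it strengthens/creates one.
#'
#' @param variant single-row variant data.frame (`rsid`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param genome named `Biostrings::DNAStringSet`, or path to a FASTA file.
#' @param pwms list of `pwm` objects.
#' @param cutoff match p-value threshold (default 5e-5).
#' @param effect_threshold absolute scaled-score difference separating
#'   `strong` from `weak` effects (default 0.4).
#' @return data.frame with one row per reported motif: `rsid`, `motif_id`,
#'   `tf_name`, `strand`, `offset` (0-based SNP position inside the plus
#'   strand window), `ref_score`, `alt_score`, `allele_diff`, `ref_p`,
#'   `alt_p`, `effect`. Zero rows when nothing reaches the cutoff.
#' @export
break_snp <- function(variant, genome, pwms, cutoff = 5e-5,
                      effect_threshold = 0.4) {
  .chk(nrow(variant) == 1L, "variant must be a single row")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  .chk(variant$chrom %in% names(genome),
       "chromosome ", variant$chrom, " absent from genome")
  chrseq <- genome[[variant$chrom]]
  pos <- variant$pos
  .chk(pos >= 1 && pos <= length(chrseq), "variant outside chromosome bounds")
  gbase <- as.character(Biostrings::subseq(chrseq, pos, pos))
  .chk(identical(gbase, variant$ref),
       "reference allele mismatch at ", variant$chrom, ":", pos,
       " (genome has ", gbase, ", variant says ", variant$ref, ")")

  rows <- list()
  for (p in pwms) {
    w <- nrow(p$probs)
    dist <- .pwm_score_dist(p)
    best <- NULL
    for (start in (pos - w + 1L):pos) {
      if (start < 1L || start + w - 1L > length(chrseq)) next
      win <- as.character(Biostrings::subseq(chrseq, start, start + w - 1L))
      if (grepl("[^ACGT]", win)) {
        message("skipping window with ambiguous base at ",
                variant$chrom, ":", start, " for motif ", p$motif_id)
        next
      }
      offset <- pos - start                      # 0-based within window
      alt_win <- win
      substr(alt_win, offset + 1L, offset + 1L) <- variant$alt
      for (strand in c("+", "-")) {
        rseq <- if (strand == "+") win else .revcomp(win)
        aseq <- if (strand == "+") alt_win else .revcomp(alt_win)
        rs <- score_window(p, rseq)
        as_ <- score_window(p, aseq)
        rp <- .score_pvalue_from_dist(dist, rs$raw)
        ap <- .score_pvalue_from_dist(dist, as_$raw)
        cand <- list(strand = strand, offset = offset,
                     ref_score = rs$scaled, alt_score = as_$scaled,
                     ref_p = rp, alt_p = ap, minp = min(rp, ap))
        if (is.null(best) || cand$minp < best$minp) best <- cand
      }
    }
    if (!is.null(best) && best$minp <= cutoff) {
      diff <- best$alt_score - best$ref_score
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = variant$rsid, motif_id = p$motif_id, tf_name = p$tf_name,
        strand = best$strand, offset = best$offset,
        ref_score = best$ref_score, alt_score = best$alt_score,
        allele_diff = diff, ref_p = best$ref_p, alt_p = best$alt_p,
        effect = if (abs(diff) >= effect_threshold) "strong" else "weak",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(rsid = character(), motif_id = character(),
                      tf_name = character(), strand = character(),
                      offset = integer(), ref_score = numeric(),
                      alt_score = numeric(), allele_diff = numeric(),
                      ref_p = numeric(), alt_p = numeric(),
                      effect = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Motif-disruption scan over many SNPs
#'
#' Applies [break_snp()] to each variant (typically the risk SNPs falling
#' in enhancers or promoters of any kind) and binds the results.
#'
#' @inheritParams break_snp
#' @param variants variant data.frame.
#' @return combined results data.frame.
#' @export
break_snps <- function(variants, genome, pwms, cutoff = 5e-5,
                       effect_threshold = 0.4) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  out <- lapply(seq_len(nrow(variants)), function(i) {
    break_snp(variants[i, , drop = FALSE], genome, pwms, cutoff,
              effect_threshold)
  })
  do.call(rbind, out)
}
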