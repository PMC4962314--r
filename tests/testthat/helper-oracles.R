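# Independent oracle implementations used to check the package's
# computations. These deliberately take naive routes (direct enumeration,
# brute-force loops) so they share no code with the implementation.

# Hypergeometric upper tail by direct PMF-term enumeration with choose().
oracle_hyper_sf <- function(k, N, K, n) {
  kk <- k:n
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Full tail vector P(X >= k) for k = 0..n, enumerated.
oracle_hyper_tails <- function(N, K, n) {
  kk <- 0:n
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  pmin(rev(cumsum(rev(pmf))), 1)
}

# Benjamini-Hochberg step-up applied by hand: sort, scale by m/rank, take
# the running minimum from the largest p down, restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)[order(o)]
}

# Naive O(n^3) UPGMA: clusters as index sets, average inter-cluster
# distance recomputed from the original matrix at every step.
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d) {
          best_d <- avg
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exhaustive PWM score distribution: enumerate all 4^w sequences.
# Returns vectors of raw scores and their background probabilities.
oracle_pwm_enumeration <- function(p) {
  l <- log(sweep(p$probs, 2, p$background, "/"))
  scores <- 0
  probs <- 1
  for (j in seq_len(nrow(l))) {
    scores <- as.vector(outer(scores, l[j, ], "+"))
    probs <- as.vector(outer(probs, p$background, "*"))
  }
  list(scores = scores, probs = probs)
}

oracle_pwm_tail <- function(enum, raw) {
  sum(enum$probs[enum$scores >= raw - 1e-12])
}

# Reverse-complement of a PWM: reverse positions, swap A<->T and C<->G.
oracle_pwm_revcomp <- function(p) {
  probs <- p$probs[rev(seq_len(nrow(p$probs))), c(4, 3, 2, 1), drop = FALSE]
  colnames(probs) <- c("A", "C", "G", "T")
  pwm(p$motif_id, probs, p$tf_name, p$background[c(4, 3, 2, 1)],
      p$pseudocount)
}

# Random strictly-positive PWM of a given width.
random_pwm <- function(width, id = "RND") {
  m <- matrix(stats::rgamma(width * 4, shape = 1) + 0.05, ncol = 4)
  pwm(id, m / rowSums(m))
}

# Per-base state labels over [1, len] from a segmentation track (single
# chromosome), for base-level segmentation checks.
labels_by_base <- function(track, chrom, len) {
  lab <- rep("NONE", len)
  segs <- track$segments
  segs <- segs[as.character(GenomicRanges::seqnames(segs)) == chrom]
  for (i in seq_along(segs)) {
    lab[GenomicRanges::start(segs)[i]:GenomicRanges::end(segs)[i]] <-
      S4Vectors::mcols(segs)$label[i]
  }
  lab
}

# Per-base coverage indicator of a peak data.frame (0-based half-open) over
# [1, len] 1-based bases.
covered_by_peaks <- function(peaks, len) {
  cov <- rep(FALSE, len)
  if (is.null(peaks) || nrow(peaks) == 0L) return(cov)
  for (i in seq_len(nrow(peaks))) {
    cov[(peaks$start[i] + 1L):peaks$end[i]] <- TRUE
  }
  cov
}

# Random peak data.frame on one chromosome inside [0, len).
random_peaks <- function(n, len, chrom = "chr1") {
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  start <- sample.int(len - 2L, n, replace = TRUE) - 1L
  width <- sample.int(80L, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(start + width, len), stringsAsFactors = FALSE)
}

# Minimal VCF text fixture writer.
write_fixture_vcf <- function(records, path,
                              samples = paste0("S", seq_len(4))) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(lines, records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Conditional surrogate column (generator internal, re-exposed for fixtures).
.gen_surrogate_col <- function(x, pA, r2) {
  chromenrich:::.gen_surrogate_given(x, pA, r2)
}

null_scenario_config <- function(seed, ...) {
  scenario_config(seed = seed,
                  planted = data.frame(locus = integer(), tissue = integer(),
                                       fraction = numeric()), ...)
}

# Smallest-footprint scenario for smoke tests.
tiny_scenario_config <- function(seed, ...) {
  scenario_config(seed = seed, n_hap = 60L, n_loci = 3L, n_tissues = 3L,
                  window_bp = 2e5, background_snp_density = 3e-4,
                  n_surrogates = 8L, ...)
}
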