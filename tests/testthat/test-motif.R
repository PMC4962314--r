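# PWM scoring, exact match p-values and allele-aware disruption calls.

toy_pwm <- function() {
  # width 3, sharply informative
  pwm("TOY0001", rbind(c(0.7, 0.1, 0.1, 0.1),
                       c(0.1, 0.7, 0.1, 0.1),
                       c(0.1, 0.1, 0.7, 0.1)))
}

test_that("read_jaspar parses count blocks into probability matrices", {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TFA",
    "A [ 4 19  0  0  2 ]",
    "C [16  0 20  0  1 ]",
    "G [ 0  1  0 20  0 ]",
    "T [ 0  0  0  0 17 ]",
    ">MA0002.1 TFB",
    "A 1 2 3 4",
    "C 1 2 3 4",
    "G 1 2 3 4",
    "T 1 2 3 4",
    ">MA0003.1 TFC",
    "A [ 10 0 ]",
    "C [ 0 10 ]",
    "G [ 0 0 ]",
    "T [ 0 0 ]"
  ), path)
  pwms <- read_jaspar(path)
  expect_length(pwms, 3L)
  expect_equal(pwms[[1]]$motif_id, "MA0001.1")
  expect_equal(pwms[[1]]$tf_name, "TFA")
  expect_equal(nrow(pwms[[1]]$probs), 5L)
  expect_equal(rowSums(pwms[[1]]$probs), rep(1, 5), tolerance = 1e-9)
  # zero counts smoothed away by the pseudocount
  expect_true(all(pwms[[3]]$probs > 0))

  bad <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA9999.1 BAD", "A [ 1 2 ]", "C [ 1 2 3 ]",
               "G [ 1 2 ]", "T [ 1 2 ]"), bad)
  expect_error(read_jaspar(bad), "MA9999.1")
})

test_that("jaspar files written by the generator round-trip", {
  pwms <- list(toy_pwm())
  path <- tempfile(fileext = ".jaspar")
  write_jaspar(pwms, path)
  back <- read_jaspar(path)
  expect_equal(back[[1]]$probs, pwms[[1]]$probs, tolerance = 0.01)
})

test_that("score_window spans [0,1] from anti-consensus to consensus", {
  p <- toy_pwm()
  expect_equal(pwm_consensus(p), "ACG")
  expect_equal(score_window(p, "ACG")$scaled, 1.0)
  # anti-consensus: any minimal-probability base at each position
  expect_equal(score_window(p, "CAA")$scaled, 0.0)

  # hand-summed log-ratio for "ACG" with uniform background
  raw <- log(0.7 / 0.25) * 3
  expect_equal(score_window(p, "ACG")$raw, raw, tolerance = 1e-12)
  # a mixed window, by direct arithmetic
  expect_equal(score_window(p, "AAG")$raw,
               log(0.7 / 0.25) + log(0.1 / 0.25) + log(0.7 / 0.25),
               tolerance = 1e-12)
  expect_error(score_window(p, "ANG"), "non-ACGT")
  expect_error(score_window(p, "ACGT"), "width")
})

test_that("score_pvalue respects the score range bounds", {
  p <- toy_pwm()
  lo <- score_window(p, "CAA")$raw
  hi <- score_window(p, "ACG")$raw
  expect_equal(score_pvalue(p, lo - 1), 1.0)
  expect_equal(score_pvalue(p, lo), 1.0)
  expect_equal(score_pvalue(p, hi + 1), 0.0)
  expect_error(score_pvalue(p, NaN), "finite")
})

test_that("DP p-values match exhaustive enumeration within discretisation", {
  set.seed(10)
  for (i in 1:6) {
    w <- sample(4:8, 1)
    p <- random_pwm(w)
    enum <- oracle_pwm_enumeration(p)
    eps <- (max(enum$scores) - min(enum$scores)) * 1e-3
    for (q in c(0.05, 0.5, 0.9, 0.999)) {
      thr <- unname(stats::quantile(enum$scores, q))
      exact <- oracle_pwm_tail(enum, thr)
      dp <- score_pvalue(p, thr)
      # misclassification is confined to sequences within ~w bins of the
      # threshold; bound the error by that probability mass
      slack <- (w + 1) * eps / 2
      margin <- sum(enum$probs[abs(enum$scores - thr) <= slack])
      expect_lte(abs(dp - exact), margin + 1e-12)
    }
  }
})

test_that("minus-strand scoring equals scoring the reverse-complement PWM", {
  set.seed(11)
  for (i in 1:50) {
    w <- sample(4:10, 1)
    p <- random_pwm(w)
    seq <- paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                 collapse = "")
    rc_seq <- chromenrich:::.revcomp(seq)
    expect_equal(score_window(p, rc_seq)$raw,
                 score_window(oracle_pwm_revcomp(p), seq)$raw,
                 tolerance = 1e-12)
  }
})

test_that("break_snp reports planted disruptions with correct direction", {
  p <- toy_pwm()
  # genome: consensus ACG planted at positions 11-13 of a fixed background
  seqstr <- paste0("TTTTTTTTTT", "ACG", "TTTTTTTTTT")
  genome <- Biostrings::DNAStringSet(seqstr)
  names(genome) <- "chrZ"
  # SNP destroys the central consensus base (C -> A)
  v <- data.frame(rsid = "rsX", chrom = "chrZ", pos = 12L, ref = "C",
                  alt = "A", stringsAsFactors = FALSE)
  res <- break_snp(v, genome, list(p), cutoff = 0.2)
  expect_equal(nrow(res), 1L)
  expect_equal(res$ref_score, 1.0)
  expect_lt(res$alt_score, 1.0)
  expect_lt(res$allele_diff, 0)

  # nothing reaches a tiny cutoff on this weak toy motif -> empty frame
  res0 <- break_snp(v, genome, list(p), cutoff = 1e-9)
  expect_equal(nrow(res0), 0L)

  # reference mismatch against the genome is a data-integrity error
  v_bad <- v; v_bad$ref <- "G"
  expect_error(break_snp(v_bad, genome, list(p)), "mismatch")
})

test_that("palindromic PWMs score both strands identically", {
  pal <- pwm("PAL", rbind(c(0.7, 0.1, 0.1, 0.1),     # A
                          c(0.1, 0.7, 0.1, 0.1),     # C
                          c(0.1, 0.1, 0.7, 0.1),     # G
                          c(0.1, 0.1, 0.1, 0.7)))    # T: ACGT palindrome
  genome <- Biostrings::DNAStringSet(paste0("GGGGGGGGGG", "ACGT",
                                            "GGGGGGGGGG"))
  names(genome) <- "chrP"
  v <- data.frame(rsid = "rsP", chrom = "chrP", pos = 12L, ref = "C",
                  alt = "T", stringsAsFactors = FALSE)
  res <- break_snp(v, genome, list(pal), cutoff = 1)
  # best window is reported once; both strands give equal scores, so
  # whichever is kept, the scores match the plus-strand computation
  win <- "ACGT"
  expect_equal(res$ref_score, score_window(pal, win)$scaled)
  expect_equal(score_window(pal, win)$raw,
               score_window(pal, chromenrich:::.revcomp(win))$raw,
               tolerance = 1e-12)
})

test_that("synthetic planted breaks are recovered at the study cutoff", {
  scn <- gen_scenario(scenario_config(seed = 21))
  res <- break_snps(scn$motif_variants, scn$genome, scn$pwms, cutoff = 5e-5)
  truth <- scn$truth$motif
  found <- merge(truth, res, by = c("rsid", "motif_id"))
  expect_equal(nrow(found), nrow(truth))      # every plant reported
  expect_true(all(sign(found$allele_diff) == found$direction))
})
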