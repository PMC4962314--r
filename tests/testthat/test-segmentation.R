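# Rules-based segmentation: precedence, activity, half-open coordinates.

pk <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

seg_df <- function(track) {
  s <- track$segments
  data.frame(start = GenomicRanges::start(s) - 1L,   # back to 0-based
             end = GenomicRanges::end(s),
             label = S4Vectors::mcols(s)$label,
             stringsAsFactors = FALSE)
}

test_that("classify applies the promoter/enhancer precedence rules", {
  # promoter peak overlapping H3K27ac -> active promoter over the full peak
  tr <- classify(pk(100, 300), NULL, pk(250, 400))
  expect_equal(seg_df(tr),
               data.frame(start = 100L, end = 300L, label = "PAR",
                          stringsAsFactors = FALSE))

  # H3K4me3 carves the promoter out of a wider H3K4me1 peak; no H3K27ac
  # anywhere -> everything poised
  tr <- classify(pk(100, 300), pk(0, 500), NULL)
  expect_equal(seg_df(tr),
               data.frame(start = c(0L, 100L, 300L), end = c(100L, 300L, 500L),
                          label = c("EPR", "PPR", "EPR"),
                          stringsAsFactors = FALSE))

  # >= 1 bp of H3K27ac overlap activates the whole enhancer peak
  tr <- classify(NULL, pk(0, 200), pk(150, 160))
  expect_equal(seg_df(tr),
               data.frame(start = 0L, end = 200L, label = "EAR",
                          stringsAsFactors = FALSE))
})

test_that("annotate_snps uses half-open segments and defaults to NONE", {
  tr <- classify(pk(100, 300), NULL, pk(250, 400))
  v <- data.frame(rsid = c("a", "b", "c"), chrom = "chr1",
                  pos = c(150L, 301L, 101L),    # 1-based positions
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  ann <- annotate_snps(v, tr)
  # 1-based 150 is inside [100,300); 301 is the first base past the segment
  expect_equal(ann$label, c("PAR", "NONE", "PAR"))

  empty <- classify(NULL, NULL, NULL)
  expect_equal(annotate_snps(v, empty)$label, rep("NONE", 3))
})

test_that("fuzzed peak sets give a disjoint exact partition with precedence", {
  set.seed(99)
  len <- 2000L
  for (trial in 1:150) {
    me3 <- random_peaks(sample(0:5, 1), len)
    me1 <- random_peaks(sample(0:6, 1), len)
    ac <- random_peaks(sample(0:4, 1), len)
    tr <- classify(me3, me1, ac)
    lab <- labels_by_base(tr, "chr1", len)
    c3 <- covered_by_peaks(me3, len)
    c1 <- covered_by_peaks(me1, len)
    # exactly the marked bases are labelled
    expect_true(identical(lab != "NONE", c3 | c1))
    # promoter precedence: no H3K4me3 base is ever an enhancer
    expect_false(any(lab[c3] %in% c("EAR", "EPR")))
    # H3K4me1-only bases are enhancers
    expect_true(all(lab[c1 & !c3] %in% c("EAR", "EPR")))
    # segments within the track never overlap
    s <- tr$segments
    if (length(s) > 1L) {
      expect_true(all(GenomicRanges::countOverlaps(s, s) == 1L))
    }
  }
})

test_that("adding H3K27ac never converts an active label to poised", {
  set.seed(123)
  len <- 2000L
  for (trial in 1:60) {
    me3 <- random_peaks(sample(1:4, 1), len)
    me1 <- random_peaks(sample(1:5, 1), len)
    ac <- random_peaks(sample(0:3, 1), len)
    extra <- rbind(ac, random_peaks(2, len))
    lab0 <- labels_by_base(classify(me3, me1, ac), "chr1", len)
    lab1 <- labels_by_base(classify(me3, me1, extra), "chr1", len)
    was_active <- lab0 %in% c("EAR", "PAR")
    expect_true(all(lab1[was_active] %in% c("EAR", "PAR")))
  }
})

test_that("classification is idempotent on its own output", {
  set.seed(5)
  len <- 2000L
  me3 <- random_peaks(4, len)
  me1 <- random_peaks(5, len)
  ac <- random_peaks(3, len)
  tr <- classify(me3, me1, ac)
  df <- seg_df(tr)
  # re-derive mark peaks from the state labels and re-classify: promoter
  # states came from H3K4me3, enhancer states from H3K4me1-without-H3K4me3,
  # active states from H3K27ac overlap
  me3_re <- pk(df$start[df$label %in% c("PAR", "PPR")],
               df$end[df$label %in% c("PAR", "PPR")])
  me1_re <- pk(df$start[df$label %in% c("EAR", "EPR")],
               df$end[df$label %in% c("EAR", "EPR")])
  ac_re <- pk(df$start[df$label %in% c("EAR", "PAR")],
              df$end[df$label %in% c("EAR", "PAR")])
  tr2 <- classify(me3_re, me1_re, ac_re)
  expect_equal(labels_by_base(tr2, "chr1", len),
               labels_by_base(tr, "chr1", len))
})

test_that("segmentation BED round-trips through rtracklayer", {
  tr <- classify(pk(100, 300), pk(400, 700), pk(250, 500))
  path <- tempfile(fileext = ".bed")
  write_segmentation_bed(tr, path)
  back <- read_bed(path)
  expect_equal(length(back), length(tr$segments))
  expect_equal(S4Vectors::mcols(back)$name,
               S4Vectors::mcols(tr$segments)$label)
})
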