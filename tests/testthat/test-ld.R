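# LD module: VCF parsing, r-squared, index expansion, index-SNP filter.

test_that("read_vcf parses phased biallelic SNPs and applies filters", {
  path <- tempfile(fileext = ".vcf")
  write_fixture_vcf(c(
    vcf_record("chr1", 50, "rs1", "A", "G", rep("0|1", 4)),
    vcf_record("chr1", 150, "rs2", "C", "T", c("1|1", "0|0", "0|1", "1|0")),
    vcf_record("chr1", 180, "rs3", "G", "A", rep("0|0", 4))
  ), path)
  out <- read_vcf(path)
  expect_equal(nrow(out$variants), 3L)
  expect_equal(dim(out$panel$haplotypes), c(8L, 3L))
  expect_equal(out$variants$rsid, c("rs1", "rs2", "rs3"))
  # file order preserved; alleles decoded 0=ref 1=alt
  expect_equal(unname(out$panel$haplotypes[, "rs2"]),
               c(1L, 1L, 0L, 0L, 0L, 1L, 1L, 0L))

  # multiallelic and indel records are dropped
  path2 <- tempfile(fileext = ".vcf")
  write_fixture_vcf(c(
    vcf_record("chr1", 10, "rs10", "A", "G", rep("0|1", 4)),
    vcf_record("chr1", 20, "rs11", "A", "G,T", rep("0|1", 4)),
    vcf_record("chr1", 30, "rs12", "AT", "A", rep("0|1", 4)),
    vcf_record("chr1", 40, "rs13", "C", "T", rep("0|1", 4)),
    vcf_record("chr1", 50, "rs14", "G", "C", rep("0|1", 4)),
    vcf_record("chr1", 60, "rs15", "T", "A", rep("0|1", 4))
  ), path2)
  out2 <- read_vcf(path2)
  expect_equal(out2$variants$rsid, c("rs10", "rs13", "rs14", "rs15"))

  # region filter is 1-based inclusive
  out3 <- read_vcf(path2, region = "chr1:30-50")
  expect_equal(out3$variants$rsid, c("rs13", "rs14"))
})

test_that("read_vcf rejects unphased genotypes, naming the record", {
  path <- tempfile(fileext = ".vcf")
  write_fixture_vcf(c(
    vcf_record("chr1", 50, "rs1", "A", "G", rep("0|1", 4)),
    vcf_record("chr1", 60, "rs2", "C", "T", c("0|1", "0/1", "0|1", "0|1"))
  ), path)
  expect_error(read_vcf(path), "unphased.*rs2")
})

test_that("compute_r2 matches the haplotype-frequency formula", {
  # self-LD of any polymorphic vector is 1
  x <- c(1, 1, 0, 0, 1, 0)
  expect_equal(compute_r2(x, x), 1.0)

  # perfectly balanced 2x2 table -> independence, r2 = 0
  x <- rep(c(0, 0, 1, 1), each = 25)
  y <- rep(c(0, 1, 0, 1), each = 25)
  expect_equal(compute_r2(x, y), 0.0)

  # worked example: 4x(1,1), 1x(1,0), 1x(0,1), 4x(0,0):
  # pA = pB = 0.5, pAB = 0.4, D = 0.15, r2 = 0.0225/0.0625 = 0.36
  x <- c(rep(1, 4), 1, 0, rep(0, 4))
  y <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(compute_r2(x, y), 0.36)

  expect_error(compute_r2(rep(0, 10), x[1:10]), "monomorphic")
})

test_that("compute_r2 equals squared Pearson correlation (oracle sweep)", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(10:200, 1)
    x <- rbinom(n, 1, runif(1, 0.1, 0.9))
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(compute_r2(x, y), cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("expand_index keeps in-window variants above the r2 threshold", {
  set.seed(7)
  n_hap <- 600
  x <- rbinom(n_hap, 1, 0.4)
  hi <- .gen_surrogate_col(x, 0.4, 0.95)       # planted r2 ~ 0.95
  lo <- rbinom(n_hap, 1, 0.5)                  # independent
  far <- .gen_surrogate_col(x, 0.4, 0.95)      # correlated but outside window
  variants <- data.frame(
    rsid = c("idx", "hi", "lo", "far"),
    chrom = "chr1",
    pos = c(600000L, 650000L, 700000L, 1500000L),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- haplotype_panel(variants, cbind(x, hi, lo, far))

  set <- expand_index("idx", panel)
  expect_true("hi" %in% set$members$rsid)       # planted surrogate recovered
  expect_false("lo" %in% set$members$rsid)      # uncorrelated excluded
  expect_false("far" %in% set$members$rsid)     # outside the 1 Mb window
  expect_equal(set$members$r2[set$members$rsid == "idx"], 1.0)
  expect_equal(set$members$pos, sort(set$members$pos))

  # membership agrees with brute-force pairwise r2
  for (j in seq_len(nrow(variants))) {
    rs <- variants$rsid[j]
    if (rs == "idx") next
    r2 <- compute_r2(x, panel$haplotypes[, rs])
    inside <- abs(variants$pos[j] - 600000L) <= 500000L
    expect_equal(rs %in% set$members$rsid, inside && r2 >= 0.8)
  }

  # no variant reaches the threshold -> surrogate set is just the index
  panel2 <- haplotype_panel(variants[1:3, ], cbind(x, lo, rbinom(n_hap, 1, 0.3)))
  set2 <- expand_index("idx", panel2)
  expect_equal(set2$members$rsid, "idx")

  expect_error(expand_index("absent", panel), "not found")
})

test_that("expand_index is invariant to variant ordering in the panel", {
  set.seed(11)
  n_hap <- 400
  x <- rbinom(n_hap, 1, 0.3)
  cols <- cbind(x,
                .gen_surrogate_col(x, 0.3, 0.9),
                .gen_surrogate_col(x, 0.3, 0.85),
                rbinom(n_hap, 1, 0.5))
  variants <- data.frame(rsid = c("idx", "s1", "s2", "b1"), chrom = "chr1",
                         pos = c(500000L, 400000L, 610000L, 550000L),
                         ref = "A", alt = "C", stringsAsFactors = FALSE)
  set_fwd <- expand_index("idx", haplotype_panel(variants, cols))
  perm <- c(3, 1, 4, 2)
  set_perm <- expand_index("idx", haplotype_panel(variants[perm, ],
                                                  cols[, perm]))
  expect_equal(set_fwd$members, set_perm$members)
})

test_that("index-SNP filter removes listed SNPs with logged reasons", {
  indices <- data.frame(rsid = sprintf("rs%02d", 1:26), chrom = "chr1",
                        pos = 1:26 * 1000L, ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
  excl <- data.frame(
    rsid = c("rs01", "rs05", "rs09", "rs12", "rs20"),
    reason = c("assembly exception", rep("no SNPs with r2 >= 0.8", 4)),
    stringsAsFactors = FALSE)
  expect_message(kept <- filter_index_snps(indices, excl),
                 "assembly exception")
  expect_equal(nrow(kept), 21L)              # 26 in, 5 removed, 21 retained
  expect_false(any(excl$rsid %in% kept$rsid))

  # empty exclusion list is the identity
  expect_identical(filter_index_snps(indices, NULL), indices)

  # absent rsid warns but leaves input unchanged
  expect_warning(
    same <- filter_index_snps(indices,
                              data.frame(rsid = "rs99", reason = "ghost")),
    "rs99")
  expect_equal(same, indices)
})
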