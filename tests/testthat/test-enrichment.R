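# Hypergeometric enrichment, BH adjustment and matrix assembly.

test_that("hypergeom_sf handles tail edge cases and the worked example", {
  expect_equal(hypergeom_sf(0, 50, 10, 5), 1.0)          # tail from zero
  expect_equal(hypergeom_sf(4, 10, 10, 4), 1.0)          # K = N: certain
  # N=10, K=5, n=4, k=4: C(5,4)*C(5,0)/C(10,4) = 5/210
  expect_equal(hypergeom_sf(4, 10, 5, 4), 5 / 210, tolerance = 1e-12)
  expect_error(hypergeom_sf(5, 10, 5, 4), "k <= n")
  expect_error(hypergeom_sf(1, 10, 11, 4), "K <= N")
})

test_that("hypergeom_sf agrees with enumeration and phyper on a grid", {
  set.seed(1)
  for (i in 1:200) {
    N <- sample(2:80, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:n, 1)
    mine <- hypergeom_sf(k, N, K, n)
    expect_equal(mine, oracle_hyper_sf(k, N, K, n), tolerance = 1e-10)
    # independent cross-check against the stats library
    expect_equal(mine, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("bh_adjust reproduces hand-applied step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)                      # single p unchanged
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(2)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("enrich counts risk and background SNPs per category", {
  # 20 background SNPs at 1-based positions 1..20 on a track where
  # [0,5) is EAR and [10,12) is PAR; risk = SNPs at 1..4 (k_EAR = 4)
  bg <- data.frame(rsid = sprintf("s%02d", 1:20), chrom = "chr1", pos = 1:20,
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  track <- classify(data.frame(chrom = "chr1", start = 10, end = 12),
                    data.frame(chrom = "chr1", start = 0, end = 5),
                    data.frame(chrom = "chr1", start = 0, end = 12), "T1")
  risk <- structure(list(
    locus = list(index = bg[1, ]),
    members = cbind(bg[1:4, ], r2 = 1, index_rsid = "s01")),
    class = "surrogate_set")

  res <- enrich("L1", risk, bg, track, "EAR")
  expect_equal(res[, c("k", "n", "K", "N")],
               data.frame(k = 4L, n = 4L, K = 5L, N = 20L))
  expect_equal(res$p, oracle_hyper_sf(4, 20, 5, 4), tolerance = 1e-12)

  # no risk SNP in the category -> p = 1
  res_ppr <- enrich("L1", risk, bg, track, "PPR")
  expect_equal(res_ppr$k, 0L)
  expect_equal(res_ppr$p, 1.0)

  # pooled category counts each SNP once and dominates both parts
  res_u <- enrich("L1", risk, bg, track, "EAR&PAR")
  res_par <- enrich("L1", risk, bg, track, "PAR")
  expect_equal(res_u$K, 7L)                      # 5 EAR + 2 PAR bases
  expect_gte(res_u$k, max(res$k, res_par$k))

  # risk SNP missing from the background is a consistency error
  expect_error(enrich("L1", risk, bg[-1, ], track, "EAR"), "absent")
})

test_that("enrichment p ignores relabeling outside the category", {
  bg <- data.frame(rsid = sprintf("s%02d", 1:30), chrom = "chr1", pos = 1:30,
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  risk <- structure(list(locus = list(index = bg[1, ]),
                         members = cbind(bg[1:5, ], r2 = 1, index_rsid = "s01")),
                    class = "surrogate_set")
  # EAR fixed at [0,10); vary what the rest of the window looks like
  t1 <- classify(NULL, data.frame(chrom = "chr1", start = 0, end = 10),
                 data.frame(chrom = "chr1", start = 0, end = 10), "T1")
  t2 <- classify(data.frame(chrom = "chr1", start = 15, end = 25),
                 data.frame(chrom = "chr1", start = 0, end = 10),
                 data.frame(chrom = "chr1", start = 0, end = 10), "T1")
  expect_equal(enrich("L1", risk, bg, t1, "EAR")$p,
               enrich("L1", risk, bg, t2, "EAR")$p)
})

test_that("enrich_all adjusts within the chosen family and skips tiny loci", {
  scn <- gen_scenario(tiny_scenario_config(seed = 2))
  se <- scenario_enrichment(scn)
  res <- se$results
  # q is a within-locus BH pass over p
  for (locus in unique(res$locus_id)) {
    sub <- res[res$locus_id == locus, ]
    expect_equal(sub$q, oracle_bh(sub$p), tolerance = 1e-12)
  }
  expect_true(all(res$q >= res$p))
  expect_equal(res$neg_ln_q, -log(res$q))

  # switching the family changes the grouping
  res_ct <- scenario_enrichment(scn, fdr_family = "cell_type")$results
  for (ct in unique(res_ct$cell_type)) {
    sub <- res_ct[res_ct$cell_type == ct, ]
    expect_equal(sub$q, oracle_bh(sub$p), tolerance = 1e-12)
  }

  # a locus with a single-member risk set is skipped with a message
  rs <- se$risk_sets
  rs[[1]]$members <- rs[[1]]$members[1, , drop = FALSE]
  expect_message(
    res2 <- enrich_all(rs, se$backgrounds, se$tracks[1]),
    "fewer than 2 risk SNPs")
  expect_false(names(rs)[1] %in% res2$locus_id)
})

test_that("build_matrix assembles -ln q with zeros for absent tests", {
  res <- data.frame(
    locus_id = rep(c("L1", "L2", "L3"), each = 2),
    cell_type = rep(c("T1", "T2"), 3),
    category = "EAR&PAR",
    k = 1, n = 2, K = 3, N = 10,
    p = c(1, 0.5, exp(-14), 0.2, 0.9, 0.1),
    q = c(1, 0.5, exp(-14), 0.2, 0.9, 0.1),
    stringsAsFactors = FALSE)
  m <- build_matrix(res)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m["T1", "L2"], 14)                 # q = e^-14 -> 14
  expect_equal(m["T1", "L1"], 0)                  # p = 1 -> 0
  expect_equal(m["T2", "L3"], -log(0.1))
  # absent combination stays 0
  m2 <- build_matrix(res[-1, ])
  expect_equal(m2["T1", "L1"], 0)
  # duplicated test is an error
  expect_error(build_matrix(rbind(res, res[1, ])), "duplicate")
})
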