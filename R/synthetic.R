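# Synthetic-data generator: every pipeline input with known planted truth.
#
# Emulates, at desk scale, the shape of the real inputs (a phased reference
# panel, per-cell-type histone peak calls, a genome with motif instances,
# an eQTL association table): haplotype pairs with a controllable target
# r-squared, peak tracks where chosen (locus, tissue) pairs have risk SNPs
# concentrated in active enhancers against a controllable background
# overlap rate, sequences with planted PWM matches destroyed or created by
# alternate alleles, and eQTL tables with planted significant triples.

#' Scenario configuration
#'
#' Bundles every knob of the synthetic scenario. Defaults describe the
#' reference desk-scale study: 8 loci x 10 tissues, 15 risk SNPs per locus,
#' one planted enriched (locus 1, tissue 1) pair with 80% of risk SNPs in
#' active enhancers against a 10% background category fraction.
#'
#' @param seed master seed; every stream of randomness derives from it.
#' @param n_hap number of haplotypes in the panel (must be even).
#' @param n_loci,n_tissues scenario dimensions.
#' @param window_bp locus window span (1 Mb).
#' @param background_snp_density background SNPs per bp (2e-4 ~ 200 per
#'   window).
#' @param category_fraction fraction of each window covered by active
#'   enhancer peaks.
#' @param peak_width width of each synthetic peak in bp.
#' @param n_surrogates risk SNPs per locus (index included).
#' @param r2_range range of target r-squared values for planted surrogates.
#' @param planted data.frame with columns `locus`, `tissue`, `fraction`
#'   (risk-in-category fraction); zero rows gives an all-null scenario.
#' @param n_poised_peaks poised (H3K27ac-free) enhancer peaks per window.
#' @param n_promoter_peaks H3K4me3 peaks per window (half given H3K27ac).
#' @param with_motifs,with_eqtl include the motif-genome and eQTL parts.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_hap = 400L,
                            n_loci = 8L,
                            n_tissues = 10L,
                            window_bp = 1e6,
                            background_snp_density = 2e-4,
                            category_fraction = 0.1,
                            peak_width = 1000L,
                            n_surrogates = 15L,
                            r2_range = c(0.85, 0.98),
                            planted = data.frame(locus = 1L, tissue = 1L,
                                                 fraction = 0.8),
                            n_poised_peaks = 30L,
                            n_promoter_peaks = 20L,
                            with_motifs = TRUE,
                            with_eqtl = TRUE) {
  .chk(n_hap %% 2L == 0L, "n_hap must be even (haplotypes pair into samples)")
  .chk(category_fraction > 0 && category_fraction < 1,
       "category_fraction must lie in (0, 1)")
  if (nrow(planted) > 0L) {
    .chk(all(planted$locus >= 1L & planted$locus <= n_loci),
         "planted locus out of range")
    .chk(all(planted$tissue >= 1L & planted$tissue <= n_tissues),
         "planted tissue out of range")
    .chk(all(planted$fraction >= 0 & planted$fraction <= 1),
         "planted fraction must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "scenario_config")
}

#' Draw a pair of haplotype columns with a target r-squared
#'
#' Samples `n_hap` haplotypes from the 4-cell joint distribution with
#' `pAB = pA * pB + D`, `D = sqrt(r2_target * pA (1-pA) pB (1-pB))`, so the
#' empirical r-squared converges to the target as `n_hap` grows. The
#' requested `(pA, pB, r2_target)` triple must be feasible: `pAB` has to
#' respect the Frechet bounds `max(0, pA + pB - 1) <= pAB <= min(pA, pB)`.
#'
#' @param pA,pB alternate-allele frequencies of the two variants.
#' @param r2_target target r-squared (positive-D coupling).
#' @param n_hap number of haplotypes to draw.
#' @param seed optional seed (uses the current RNG state when `NULL`).
#' @return list with binary vectors `x` and `y` of length `n_hap`.
#' @export
gen_haplotypes_with_r2 <- function(pA, pB, r2_target, n_hap, seed = NULL) {
  .chk(pA > 0 && pA < 1 && pB > 0 && pB < 1,
       "allele frequencies must lie in (0, 1)")
  .chk(r2_target >= 0 && r2_target <= 1, "r2_target must lie in [0, 1]")
  D <- sqrt(r2_target * pA * (1 - pA) * pB * (1 - pB))
  pAB <- pA * pB + D
  upper <- min(pA, pB)
  if (pAB > upper + 1e-12) {
    stop("infeasible (pA=", pA, ", pB=", pB, ", r2=", r2_target,
         "): requires pAB=", signif(pAB, 6),
         " but the Frechet bound caps pAB at min(pA, pB)=", upper,
         call. = FALSE)
  }
  pAB <- min(pAB, upper)
  cells <- c(`00` = 1 - pA - pB + pAB, `01` = pB - pAB,
             `10` = pA - pAB, `11` = pAB)
  .chk(all(cells > -1e-12), "internal: negative haplotype cell probability")
  cells <- pmax(cells, 0)
  if (!is.null(seed)) set.seed(seed)
  draw <- sample.int(4L, n_hap, replace = TRUE, prob = cells)
  list(x = as.integer(draw >= 3L), y = as.integer(draw %% 2L == 0L))
}

# Surrogate column correlated with an existing index column x: conditional
# Bernoulli draw with pB = pA so that the theoretical r^2 equals the target.
.gen_surrogate_given <- function(x, pA, r2_target) {
  D <- sqrt(r2_target) * pA * (1 - pA)
  pAB <- pA * pA + D
  p1 <- pAB / pA                      # P(y=1 | x=1)
  p0 <- (pA - pAB) / (1 - pA)         # P(y=1 | x=0)
  y <- integer(length(x))
  y[x == 1L] <- stats::rbinom(sum(x == 1L), 1L, p1)
  y[x == 0L] <- stats::rbinom(sum(x == 0L), 1L, p0)
  y
}

# Uniform 0-based peak starts inside [0, window_bp - width]. Drawn with
# replacement: coincident peaks merge into one on reduction.
.uniform_peak_starts <- function(n, window_bp, width) {
  if (n <= 0L) return(integer())
  sample.int(window_bp - width, n, replace = TRUE) - 1L
}

# Highly informative synthetic PWMs with distinct random consensus strings.
.gen_pwms <- function(n = 3L, widths = c(10L, 8L, 12L), peak_prob = 0.85) {
  lapply(seq_len(n), function(i) {
    w <- widths[((i - 1L) %% length(widths)) + 1L]
    cons <- sample.int(4L, w, replace = TRUE)
    probs <- matrix((1 - peak_prob) / 3, nrow = w, ncol = 4L)
    probs[cbind(seq_len(w), cons)] <- peak_prob
    pwm(sprintf("SYN%04d", i), probs, tf_name = sprintf("SynTF%d", i))
  })
}

#' Generate a complete synthetic scenario
#'
#' Builds, in memory, every input the pipeline consumes plus the planted
#' truth: a phased haplotype panel (one chromosome per locus, index SNP at
#' the window centre, surrogates at target r-squared, independent
#' background SNPs), per-tissue peak trios where planted (locus, tissue)
#' pairs have active-enhancer peaks placed over the configured fraction of
#' risk SNPs, a short motif contig with planted PWM matches and
#' motif-breaking alleles, and an eQTL table with planted significant
#' SNP-gene-tissue triples. Use [write_scenario()] to emit files.
#'
#' @param config a [scenario_config()].
#' @return object of class `scenario`; its `truth` element records realised
#'   r-squared values, planted-test counts (k, n, K, N), planted motif
#'   breaks and planted eQTLs.
#' @export
gen_scenario <- function(config) {
  .chk(inherits(config, "scenario_config"), "config must be a scenario_config")
  cfg <- config
  wb <- as.integer(cfg$window_bp)
  tissues <- paste0("T", seq_len(cfg$n_tissues))

  ## --- panel: variants + haplotypes (stream 1..n_loci) ------------------
  var_list <- list()
  hap_list <- list()
  risk_plan <- list()     # per locus: planned surrogate rsids + targets
  for (i in seq_len(cfg$n_loci)) {
    set.seed(derive_seed(cfg$seed, i))
    chrom <- paste0("chr", i)
    index_pos <- as.integer(wb / 2)
    n_bg <- stats::rpois(1, cfg$background_snp_density * wb)
    n_sur <- cfg$n_surrogates - 1L
    pos_pool <- setdiff(sample.int(wb, n_bg + n_sur + 10L), index_pos)
    sur_pos <- sort(pos_pool[seq_len(n_sur)])
    bg_pos <- sort(pos_pool[n_sur + seq_len(n_bg)])

    pA <- stats::runif(1, 0.2, 0.5)
    repeat {
      x <- stats::rbinom(cfg$n_hap, 1L, pA)
      if (sum(x) > 0L && sum(x) < cfg$n_hap) break
    }
    r2_targets <- stats::runif(n_sur, cfg$r2_range[1], cfg$r2_range[2])
    sur_cols <- vapply(r2_targets, function(r2) {
      .gen_surrogate_given(x, pA, r2)
    }, integer(cfg$n_hap))
    bg_freq <- stats::runif(n_bg, 0.1, 0.9)
    bg_cols <- vapply(bg_freq, function(f) stats::rbinom(cfg$n_hap, 1L, f),
                      integer(cfg$n_hap))

    pos <- c(index_pos, sur_pos, bg_pos)
    ord <- order(pos)
    rsid <- sprintf("rs%d%05d", i, seq_along(pos))
    ref_i <- sample.int(4L, length(pos), replace = TRUE)
    alt_i <- ((ref_i - 1L + sample.int(3L, length(pos), replace = TRUE)) %% 4L) + 1L
    v <- data.frame(rsid = rsid, chrom = chrom, pos = pos,
                    ref = DNA_BASES[ref_i], alt = DNA_BASES[alt_i],
                    locus_id = rsid[1], stringsAsFactors = FALSE)
    H <- cbind(x, sur_cols, bg_cols)
    colnames(H) <- rsid
    var_list[[i]] <- v[ord, , drop = FALSE]
    hap_list[[i]] <- H[, ord, drop = FALSE]
    risk_plan[[i]] <- list(index_rsid = rsid[1],
                           surrogate_rsid = rsid[1L + seq_len(n_sur)],
                           r2_target = r2_targets,
                           risk_pos = c(index_pos, sur_pos),
                           risk_rsid = rsid[seq_len(n_sur + 1L)])
  }
  variants <- do.call(rbind, var_list)
  rownames(variants) <- NULL
  haplotypes <- do.call(cbind, hap_list)
  panel <- haplotype_panel(variants[, c("rsid", "chrom", "pos", "ref", "alt")],
                           haplotypes)

  ## --- peaks per tissue (stream 1000 + t) -------------------------------
  pw <- as.integer(cfg$peak_width)
  n_active <- max(1L, round(cfg$category_fraction * wb / pw))
  peaks <- list()
  chroms <- paste0("chr", seq_len(cfg$n_loci))
  for (t in seq_len(cfg$n_tissues)) {
    set.seed(derive_seed(cfg$seed, 1000L + t))
    me1 <- list(); me3 <- list(); ac <- list()   # (chrom, start0) pairs
    for (i in seq_len(cfg$n_loci)) {
      plant <- cfg$planted[cfg$planted$locus == i & cfg$planted$tissue == t, ,
                           drop = FALSE]
      cov_starts <- integer()
      if (nrow(plant) == 1L) {
        n_cov <- round(plant$fraction * cfg$n_surrogates)
        cov_pos <- sample(risk_plan[[i]]$risk_pos, n_cov)
        cov_starts <- pmin(pmax(cov_pos - 1L - pw %/% 2L, 0L), wb - pw)
      }
      act_starts <- c(cov_starts,
                      .uniform_peak_starts(n_active - length(cov_starts), wb, pw))
      poi_starts <- .uniform_peak_starts(cfg$n_poised_peaks, wb, pw)
      pro_starts <- .uniform_peak_starts(cfg$n_promoter_peaks, wb, pw)
      pro_active <- pro_starts[seq_len(cfg$n_promoter_peaks %/% 2L)]
      me1[[i]] <- c(act_starts, poi_starts)
      me3[[i]] <- pro_starts
      ac[[i]] <- c(act_starts, pro_active)
    }
    as_gr <- function(starts_by_locus) {
      n <- lengths(starts_by_locus)
      GenomicRanges::reduce(GenomicRanges::GRanges(
        rep(chroms, n),
        IRanges::IRanges(start = unlist(starts_by_locus) + 1L, width = pw),
        seqinfo = GenomeInfoDb::Seqinfo(seqnames = chroms)))
    }
    peaks[[tissues[t]]] <- list(H3K4me1 = as_gr(me1), H3K4me3 = as_gr(me3),
                                H3K27ac = as_gr(ac))
  }

  ## --- realised LD truth -------------------------------------------------
  r2_truth <- do.call(rbind, lapply(seq_len(cfg$n_loci), function(i) {
    plan <- risk_plan[[i]]
    r2 <- r2_against_index(haplotypes[, plan$risk_rsid, drop = FALSE], 1L)
    data.frame(locus_id = plan$index_rsid,
               rsid = plan$risk_rsid,
               r2_target = c(1, plan$r2_target),
               r2_realized = r2, stringsAsFactors = FALSE)
  }))

  ## --- motif contig (stream 2000) ----------------------------------------
  genome <- NULL; pwms <- NULL
  motif_variants <- data.frame()
  motif_truth <- data.frame()
  if (cfg$with_motifs) {
    set.seed(derive_seed(cfg$seed, 2000L))
    pwms <- .gen_pwms()
    contig_len <- 6000L
    bases <- sample(DNA_BASES, contig_len, replace = TRUE)
    plant_at <- c(800L, 2500L, 4200L)
    direction <- c(-1L, -1L, 1L)       # destroy, destroy, create
    mv <- list(); mt <- list()
    for (j in seq_along(pwms)) {
      p <- pwms[[j]]
      w <- nrow(p$probs)
      cons_idx <- apply(p$probs, 1, which.max)
      worst_idx <- apply(p$probs, 1, which.min)
      offset <- w %/% 2L               # SNP in the middle of the motif
      site <- DNA_BASES[cons_idx]
      if (direction[j] < 0L) {
        ref <- site[offset + 1L]
        alt <- DNA_BASES[worst_idx[offset + 1L]]
      } else {
        site[offset + 1L] <- DNA_BASES[worst_idx[offset + 1L]]
        ref <- site[offset + 1L]
        alt <- DNA_BASES[cons_idx[offset + 1L]]
      }
      bases[plant_at[j]:(plant_at[j] + w - 1L)] <- site
      mv[[j]] <- data.frame(rsid = sprintf("rsTF%d", j), chrom = "chrTF",
                            pos = plant_at[j] + offset, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
      mt[[j]] <- data.frame(rsid = sprintf("rsTF%d", j),
                            motif_id = p$motif_id, direction = direction[j],
                            stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(genome) <- "chrTF"
    motif_variants <- do.call(rbind, mv)
    motif_truth <- do.call(rbind, mt)
  }

  ## --- eQTL table (stream 3000) ------------------------------------------
  eqtl <- data.frame(); tissue_map <- data.frame(); eqtl_truth <- data.frame()
  if (cfg$with_eqtl) {
    set.seed(derive_seed(cfg$seed, 3000L))
    tissue_map <- data.frame(cell_type = tissues,
                             eqtl_tissue = paste0("gtex_", tissues),
                             stringsAsFactors = FALSE)
    planted_rows <- list()
    if (nrow(cfg$planted) > 0L) {
      for (r in seq_len(nrow(cfg$planted))) {
        i <- cfg$planted$locus[r]; t <- cfg$planted$tissue[r]
        rs <- sample(risk_plan[[i]]$risk_rsid, 2L)
        planted_rows[[r]] <- data.frame(
          rsid = rs, gene = sprintf("GENE%d", i),
          tissue = paste0("gtex_", tissues[t]),
          sign = sample(c("+", "-"), 2L, replace = TRUE),
          p = 10^stats::runif(2, -8, -6), stringsAsFactors = FALSE)
      }
    }
    eqtl_truth <- if (length(planted_rows)) do.call(rbind, planted_rows) else
      data.frame()
    all_risk <- unlist(lapply(risk_plan, `[[`, "risk_rsid"))
    non_risk <- setdiff(variants$rsid, all_risk)
    noise <- data.frame(
      rsid = sample(variants$rsid, 100L, replace = TRUE),
      gene = sprintf("NOISE%03d", sample.int(40L, 100L, replace = TRUE)),
      tissue = sample(c(tissue_map$eqtl_tissue, "gtex_unmapped"), 100L,
                      replace = TRUE),
      sign = sample(c("+", "-"), 100L, replace = TRUE),
      p = stats::runif(100, 0.01, 1), stringsAsFactors = FALSE)
    decoys <- data.frame(                      # significant but not risk SNPs
      rsid = sample(non_risk, 10L),
      gene = sprintf("DECOY%02d", 1:10),
      tissue = sample(tissue_map$eqtl_tissue, 10L, replace = TRUE),
      sign = sample(c("+", "-"), 10L, replace = TRUE),
      p = 10^stats::runif(10, -8, -6), stringsAsFactors = FALSE)
    eqtl <- rbind(eqtl_truth, noise, decoys)
    rownames(eqtl) <- NULL
  }

  ## --- planted-test truth counts (via the package's own classifiers) -----
  planted_counts <- data.frame()
  if (nrow(cfg$planted) > 0L) {
    pc <- list()
    for (r in seq_len(nrow(cfg$planted))) {
      i <- cfg$planted$locus[r]; t <- cfg$planted$tissue[r]
      plan <- risk_plan[[i]]
      track <- classify(peaks[[tissues[t]]]$H3K4me3,
                        peaks[[tissues[t]]]$H3K4me1,
                        peaks[[tissues[t]]]$H3K27ac, tissues[t])
      bg <- variants[variants$chrom == paste0("chr", i), , drop = FALSE]
      realized <- r2_truth[r2_truth$locus_id == plan$index_rsid, ]
      risk_rs <- realized$rsid[(!is.na(realized$r2_realized) &
                                  realized$r2_realized >= 0.8) |
                                 realized$rsid == plan$index_rsid]
      ann <- annotate_snps(bg, track)
      in_cat <- label_in_category(ann$label, "EAR")
      is_risk <- bg$rsid %in% risk_rs
      pc[[r]] <- data.frame(locus_id = plan$index_rsid, cell_type = tissues[t],
                            category = "EAR",
                            k = sum(in_cat & is_risk), n = sum(is_risk),
                            K = sum(in_cat), N = nrow(bg),
                            fraction = cfg$planted$fraction[r],
                            stringsAsFactors = FALSE)
    }
    planted_counts <- do.call(rbind, pc)
  }

  structure(list(
    config = cfg, tissues = tissues, variants = variants, panel = panel,
    index_snps = do.call(rbind, lapply(risk_plan, function(p) {
      variants[variants$rsid == p$index_rsid,
               c("rsid", "chrom", "pos", "ref", "alt")]
    })),
    peaks = peaks, genome = genome, pwms = pwms,
    motif_variants = motif_variants, eqtl = eqtl, tissue_map = tissue_map,
    truth = list(r2 = r2_truth, planted = planted_counts,
                 motif = motif_truth, eqtl = eqtl_truth)
  ), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario:", x$config$n_loci, "loci x", x$config$n_tissues,
      "tissues,", nrow(x$variants), "SNPs,",
      nrow(x$config$planted), "planted enrichment pair(s)\n")
  invisible(x)
}

# Minimal VCF emitter for synthetic panels (phased GT only, no INFO).
write_vcf <- function(variants, haplotypes, path) {
  n_samp <- nrow(haplotypes) %/% 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("S", seq_len(n_samp))),
                   collapse = "\t"), con)
  a1 <- haplotypes[seq(1L, by = 2L, length.out = n_samp), , drop = FALSE]
  a2 <- haplotypes[seq(2L, by = 2L, length.out = n_samp), , drop = FALSE]
  for (j in seq_len(nrow(variants))) {
    gt <- paste0(a1[, j], "|", a2[, j])
    writeLines(paste(c(variants$chrom[j], variants$pos[j], variants$rsid[j],
                       variants$ref[j], variants$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a scenario's files to a directory
#'
#' Emits the standard-format inputs the pipeline reads back: `panel.vcf`,
#' `index_snps.tsv`, `exclusions.tsv`, per-tissue BED trios under `peaks/`,
#' `genome.fa`, `motifs.jaspar`, `motif_snps.vcf`, `eqtl.tsv`,
#' `tissue_map.tsv`, `truth.json`, and a `manifest.tsv` of file checksums.
#' Outputs are byte-identical for identical configurations.
#'
#' @param scn a `scenario` from [gen_scenario()].
#' @param outdir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_scenario <- function(scn, outdir) {
  .chk(inherits(scn, "scenario"), "scn must be a scenario")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  paths <- c(panel_vcf = file.path(outdir, "panel.vcf"),
             index_snps = file.path(outdir, "index_snps.tsv"),
             exclusions = file.path(outdir, "exclusions.tsv"),
             eqtl = file.path(outdir, "eqtl.tsv"),
             tissue_map = file.path(outdir, "tissue_map.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_vcf(scn$panel$variants, scn$panel$haplotypes, paths["panel_vcf"])
  write_tsv(scn$index_snps, paths["index_snps"])
  write_tsv(data.frame(rsid = character(), reason = character()),
            paths["exclusions"])
  for (t in names(scn$peaks)) {
    for (mark in names(scn$peaks[[t]])) {
      f <- file.path(outdir, "peaks", paste0(t, "_", mark, ".bed"))
      rtracklayer::export(scn$peaks[[t]][[mark]], f, format = "BED")
      paths[paste0("peaks_", t, "_", mark)] <- f
    }
  }
  if (!is.null(scn$genome)) {
    paths["genome"] <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(scn$genome, paths["genome"])
    paths["pwms"] <- file.path(outdir, "motifs.jaspar")
    write_jaspar(scn$pwms, paths["pwms"])
    paths["motif_vcf"] <- file.path(outdir, "motif_snps.vcf")
    mh <- matrix(c(0L, 1L), nrow = 2L, ncol = nrow(scn$motif_variants))
    write_vcf(scn$motif_variants, mh, paths["motif_vcf"])
  }
  if (nrow(scn$eqtl) > 0L) {
    write_tsv(scn$eqtl, paths["eqtl"])
    write_tsv(scn$tissue_map, paths["tissue_map"])
  }
  jsonlite::write_json(scn$truth, paths["truth"], digits = NA,
                       dataframe = "columns")
  files <- paths[file.exists(paths)]
  manifest <- data.frame(file = basename(unname(files)),
                         md5 = unname(tools::md5sum(unname(files))),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(paths)
}

#' Run the LD-expansion and enrichment stages on an in-memory scenario
#'
#' Convenience front-end used by the recovery analyses: expands every index
#' SNP against the scenario panel, classifies every tissue, and runs all
#' enrichment tests. No files are touched.
#'
#' @param scn a `scenario`.
#' @param r2_min surrogate threshold (default 0.8).
#' @param fdr_family multiple-testing family (see [enrich_all()]).
#' @param categories state categories to test.
#' @return list with `results` (from [enrich_all()]), `risk_sets`,
#'   `backgrounds` and `tracks`.
#' @export
scenario_enrichment <- function(scn, r2_min = 0.8,
                                fdr_family = "locus",
                                categories = ENRICH_CATEGORIES) {
  .chk(inherits(scn, "scenario"), "scn must be a scenario")
  risk_sets <- list()
  backgrounds <- list()
  for (i in seq_len(scn$config$n_loci)) {
    id <- scn$index_snps$rsid[i]
    risk_sets[[id]] <- expand_index(id, scn$panel,
                                    window_bp = scn$config$window_bp,
                                    r2_min = r2_min)
    chrom <- scn$index_snps$chrom[i]
    backgrounds[[id]] <-
      scn$panel$variants[scn$panel$variants$chrom == chrom, , drop = FALSE]
  }
  tracks <- lapply(names(scn$peaks), function(t) {
    classify(scn$peaks[[t]]$H3K4me3, scn$peaks[[t]]$H3K4me1,
             scn$peaks[[t]]$H3K27ac, t)
  })
  results <- enrich_all(risk_sets, backgrounds, tracks,
                        categories = categories, fdr_family = fdr_family)
  list(results = results, risk_sets = risk_sets,
       backgrounds = backgrounds, tracks = tracks)
}
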