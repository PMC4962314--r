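# End-to-end orchestration: simulate (optional) -> LD expansion ->
# segmentation -> annotation -> enrichment -> clustering/heatmap ->
# motif-disruption -> eQTL linking, with preflight validation and a run
# manifest. The numbered scripts under analysis/ are thin drivers over the
# same stages.

#' Default pipeline configuration over a simulated scenario
#'
#' Builds a [run_pipeline()] configuration that first generates the default
#' synthetic scenario under `outdir/scenario` and then analyses it.
#'
#' @param outdir run output directory.
#' @param seed master seed.
#' @param scenario optional [scenario_config()] overriding the default.
#' @return configuration list.
#' @export
default_config <- function(outdir, seed = 1L, scenario = NULL) {
  if (is.null(scenario)) scenario <- scenario_config(seed = seed)
  list(simulate = TRUE, scenario = scenario, outdir = outdir, seed = seed,
       paths = list(),
       params = list(window_bp = 1e6, r2_min = 0.8, fdr = 0.05,
                     motif_cutoff = 5e-5, plot_cutoff = 1e-5,
                     eqtl_p = 2.5e-5, fdr_family = "locus",
                     matrix_scale = "neg_ln_q"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with `paths`, `params`, `outdir`, `seed` keys.
#' @return configuration list.
#' @export
read_config <- function(path) {
  .chk(file.exists(path), "config error: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- default_config(outdir = cfg$outdir %||% "results", seed = 1L)
  cfg$params <- utils::modifyList(defaults$params, cfg$params %||% list())
  cfg$simulate <- isTRUE(cfg$simulate)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Preflight: every declared input must exist before any stage runs.
.preflight <- function(paths) {
  need <- c("index_snps", "panel_vcf", "peak_dir")
  for (key in need) {
    .chk(!is.null(paths[[key]]), "config error: missing path '", key, "'")
  }
  for (key in names(paths)) {
    p <- paths[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config error: input '", key, "' does not exist: ", p,
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Discover per-tissue peak trios in a directory of <tissue>_<mark>.bed files.
.discover_peaks <- function(peak_dir) {
  files <- list.files(peak_dir, pattern = "\\.bed$", full.names = TRUE)
  .chk(length(files) > 0L, "no BED files under ", peak_dir)
  base <- sub("\\.bed$", "", basename(files))
  mark <- sub("^.*_", "", base)
  tissue <- sub("_[^_]+$", "", base)
  .chk(all(mark %in% c("H3K4me1", "H3K4me3", "H3K27ac")),
       "unrecognised mark in peak file name(s): ",
       paste(base[!mark %in% c("H3K4me1", "H3K4me3", "H3K27ac")],
             collapse = ", "))
  out <- list()
  for (t in sort(unique(tissue))) {
    trio <- files[tissue == t]
    names(trio) <- mark[tissue == t]
    out[[t]] <- trio
  }
  out
}

#' Run the whole pipeline
#'
#' Executes every stage over the configured inputs and writes the result
#' tables, the clustered heatmap and a JSON run manifest under
#' `config$outdir`. With `config$simulate = TRUE` the synthetic scenario is
#' generated first and its files become the inputs, so a default run is
#' fully self-contained. Reruns with the same configuration and seed
#' produce identical result tables.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()], or a path to a YAML file.
#' @return (invisibly) list with the main in-memory results: `results`,
#'   `matrix`, `row_tree`, `col_tree`, `motif_breaks`, `eqtl_links`,
#'   `concordance`, `truth` (when simulated) and `files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  outdir <- config$outdir
  .chk(!is.null(outdir), "config error: no outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  seed <- config$seed %||% 1L
  counts <- list()
  truth <- NULL

  if (isTRUE(config$simulate)) {
    message("stage simulate: generating synthetic scenario")
    scn_cfg <- config$scenario %||% scenario_config(seed = seed)
    scn <- gen_scenario(scn_cfg)
    paths <- as.list(write_scenario(scn, file.path(outdir, "scenario")))
    truth <- scn$truth
    config$paths <- utils::modifyList(config$paths %||% list(), list(
      index_snps = paths$index_snps, exclusions = paths$exclusions,
      panel_vcf = paths$panel_vcf, peak_dir = file.path(outdir, "scenario", "peaks"),
      genome_fasta = paths$genome, pwm_file = paths$pwms,
      motif_vcf = paths$motif_vcf, eqtl_tsv = paths$eqtl,
      tissue_map = paths$tissue_map))
  }
  paths <- config$paths
  .preflight(paths)
  files <- character()

  message("stage ld-expand: reading index SNPs and panel")
  indices <- read_tsv(paths$index_snps)
  validate_variants(indices)
  exclusions <- if (!is.null(paths$exclusions)) read_tsv(paths$exclusions) else
    data.frame(rsid = character(), reason = character())
  indices <- filter_index_snps(indices, exclusions)
  counts$index_snps <- nrow(indices)
  vcf <- read_vcf(paths$panel_vcf)
  counts$panel_variants <- nrow(vcf$variants)

  risk_sets <- list()
  backgrounds <- list()
  for (i in seq_len(nrow(indices))) {
    id <- indices$rsid[i]
    set <- expand_index(id, vcf$panel, window_bp = params$window_bp,
                        r2_min = params$r2_min)
    risk_sets[[id]] <- set
    v <- vcf$variants
    backgrounds[[id]] <- v[v$chrom == set$locus$chrom &
                             in_window(v$pos, set$locus), , drop = FALSE]
  }
  files["surrogates"] <- file.path(outdir, "surrogates.tsv")
  write_surrogates(risk_sets, files["surrogates"])
  counts$risk_snps <- sum(vapply(risk_sets, function(s) nrow(s$members), 0L))

  message("stage segment: classifying ", length(.discover_peaks(paths$peak_dir)),
          " cell types")
  trios <- .discover_peaks(paths$peak_dir)
  tracks <- lapply(names(trios), function(t) {
    trio <- trios[[t]]
    classify(if ("H3K4me3" %in% names(trio)) read_bed(trio[["H3K4me3"]]),
             if ("H3K4me1" %in% names(trio)) read_bed(trio[["H3K4me1"]]),
             if ("H3K27ac" %in% names(trio)) read_bed(trio[["H3K27ac"]]),
             cell_type = t)
  })
  for (track in tracks) {
    f <- file.path(outdir, paste0("segmentation_", track$cell_type, ".bed"))
    write_segmentation_bed(track, f)
  }
  counts$cell_types <- length(tracks)

  message("stage annotate + enrich: hypergeometric tests")
  results <- enrich_all(risk_sets, backgrounds, tracks,
                        fdr_family = params$fdr_family)
  files["enrichment"] <- file.path(outdir, "enrichment.tsv")
  write_tsv(results, files["enrichment"])
  counts$enrichment_tests <- nrow(results)

  message("stage cluster: enrichment matrix, dendrograms, heatmap")
  m <- build_matrix(results, category = "EAR&PAR",
                    scale = params$matrix_scale)
  files["matrix"] <- file.path(outdir, "matrix.tsv")
  write_matrix(m, files["matrix"])
  row_tree <- col_tree <- NULL
  if (nrow(m) >= 2L) {
    row_tree <- average_linkage(euclidean_distances(m, "rows"))
    write_newick(row_tree, file.path(outdir, "cell_types.nwk"))
  }
  if (ncol(m) >= 2L) {
    col_tree <- average_linkage(euclidean_distances(m, "cols"))
    write_newick(col_tree, file.path(outdir, "loci.nwk"))
  }
  files["heatmap"] <- file.path(outdir, "heatmap.png")
  render_heatmap(m, row_tree, col_tree, files["heatmap"])

  motif_breaks <- NULL
  if (!is.null(paths$genome_fasta) && !is.null(paths$pwm_file)) {
    message("stage motif-break: allele-aware PWM scan")
    genome <- Biostrings::readDNAStringSet(paths$genome_fasta)
    pwms <- read_jaspar(paths$pwm_file)
    # candidates: risk SNPs in any regulatory state in any cell type, plus
    # any supplementary regulatory-SNP VCF, restricted to sequence we have
    cand <- unique(do.call(rbind, lapply(risk_sets, function(s) {
      s$members[, c("rsid", "chrom", "pos", "ref", "alt")]
    })))
    in_reg <- rep(FALSE, nrow(cand))
    for (track in tracks) {
      in_reg <- in_reg | annotate_snps(cand, track)$label != "NONE"
    }
    cand <- cand[in_reg, , drop = FALSE]
    if (!is.null(paths$motif_vcf)) {
      cand <- unique(rbind(cand, read_vcf(paths$motif_vcf)$variants))
    }
    skipped <- !cand$chrom %in% names(genome)
    if (any(skipped)) {
      message("motif-break: ", sum(skipped),
              " candidate SNP(s) on chromosomes absent from the FASTA; skipped")
    }
    cand <- cand[!skipped, , drop = FALSE]
    motif_breaks <- break_snps(cand, genome, pwms,
                               cutoff = params$motif_cutoff)
    files["motif_breaks"] <- file.path(outdir, "motif_breaks.tsv")
    write_tsv(motif_breaks, files["motif_breaks"])
    counts$motif_breaks <- nrow(motif_breaks)
    counts$motif_breaks_plotworthy <-
      sum(pmin(motif_breaks$ref_p, motif_breaks$alt_p) < params$plot_cutoff)
  }

  eqtl_links <- NULL; concordance <- NULL
  if (!is.null(paths$eqtl_tsv)) {
    message("stage eqtl-link: subsetting associations to the risk-SNP set")
    records <- read_eqtl(paths$eqtl_tsv)
    locus_snps <- lapply(risk_sets, function(s) s$members$rsid)
    eqtl_links <- subset_eqtl(records, unlist(locus_snps),
                              p_max = params$eqtl_p)
    files["eqtl_links"] <- file.path(outdir, "eqtl_links.tsv")
    write_tsv(eqtl_links, files["eqtl_links"])
    counts$eqtl_links <- nrow(eqtl_links)
    if (!is.null(paths$tissue_map)) {
      tmap <- read_tsv(paths$tissue_map)
      concordance <- tissue_concordance(results, eqtl_links, tmap,
                                        locus_snps = locus_snps,
                                        fdr = params$fdr)
      files["concordance"] <- file.path(outdir, "concordance.tsv")
      write_tsv(concordance, files["concordance"])
      counts$concordant_pairs <-
        sum(concordance$enriched & concordance$n_eqtl_genes > 0)
    }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("chromenrich")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, params = params,
    paths = lapply(paths, as.character),
    stage_counts = counts,
    outputs = as.list(tools::md5sum(unname(files[file.exists(files)]))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("pipeline complete: ", length(files), " result files in ", outdir)
  invisible(list(results = results, matrix = m, row_tree = row_tree,
                 col_tree = col_tree, risk_sets = risk_sets,
                 motif_breaks = motif_breaks, eqtl_links = eqtl_links,
                 concordance = concordance, truth = truth, files = files))
}
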