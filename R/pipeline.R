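#' Pipeline configuration
#'
#' One flat configuration object for the end-to-end run. Defaults are the
#' pipeline's standard operating thresholds: the hard-filter and
#' population-genetic screens of [filter_thresholds()], an association
#' threshold of `1e-3`, LD on the densest chromosome's first 1000 markers
#' in 1 kb bins, and all loci as core-set candidates. When `vcf` is `NULL`
#' the run starts from a synthetic panel generated with `sim` (see
#' [sim_config()]).
#'
#' @param vcf optional input VCF path (otherwise a synthetic panel is
#'   generated).
#' @param traits optional traits CSV path (otherwise synthetic phenotypes).
#' @param out_dir output directory.
#' @param sim a [sim_config()] for the synthetic route.
#' @param thresholds a [filter_thresholds()].
#' @param gwas_threshold significance threshold for [significant_hits()].
#' @param ld_max_markers,ld_bin_width LD scan settings.
#' @param heritability,n_categorical synthetic-phenotype settings.
#' @param export_qr write per-accession QR images during the run.
#' @param seed integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, traits = NULL, out_dir = tempfile("germid_run_"),
                            sim = sim_config(seed = seed),
                            thresholds = filter_thresholds(),
                            gwas_threshold = 1e-3, ld_max_markers = 1000,
                            ld_bin_width = 1000, heritability = 0.5,
                            n_categorical = 5, export_qr = FALSE, seed = 1) {
  cfg <- list(vcf = vcf, traits = traits, out_dir = out_dir, sim = sim,
              thresholds = thresholds, gwas_threshold = gwas_threshold,
              ld_max_markers = ld_max_markers, ld_bin_width = ld_bin_width,
              heritability = heritability, n_categorical = n_categorical,
              export_qr = isTRUE(export_qr), seed = as.integer(seed))
  if (!is.null(vcf) && !file.exists(vcf)) {
    stop("input VCF not found: ", vcf, call. = FALSE)
  }
  if (!is.null(traits) && !file.exists(traits)) {
    stop("traits file not found: ", traits, call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full germplasm evaluation pipeline
#'
#' Executes, in order: simulate-or-ingest, the SNP filter cascade, the
#' substitution spectrum, diversity indices (overall and per group),
#' genotype PCA, UPGMA clustering, LD decay, the association scan, greedy
#' core-marker selection, fingerprint codes, and (optionally) QR export.
#' Per-stage tables are written to `config$out_dir` as CSV and the run
#' manifest records the seed, stage row counts and output checksums.
#'
#' @param config a [pipeline_config()].
#' @return A list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if (is.null(config$vcf)) {
    sim <- simulate_panel(config$sim)
    panel <- sim$panel
    ann <- simulate_annotations(panel, fail_fraction = 0.02,
                                seed = config$seed + 1L)
    traits <- simulate_phenotypes(panel, sim$truth,
                                  heritability = config$heritability,
                                  n_categorical = config$n_categorical,
                                  seed = config$seed + 2L)
    res$truth <- sim$truth
  } else {
    inp <- read_vcf(config$vcf)
    panel <- inp$panel
    ann <- inp$annotations
    traits <- NULL
    if (!is.null(config$traits)) {
      traits <- tibble::as_tibble(utils::read.csv(config$traits,
                                                  check.names = FALSE))
    }
  }
  if (is.null(traits)) {
    stop("stage 'traits': no trait table available (supply `traits` or ",
         "use the synthetic route)", call. = FALSE)
  }

  flt <- site_filters(panel, ann, config$thresholds)
  res$filter_report <- flt$report
  panel_f <- flt$panel

  res$spectrum <- substitution_spectrum(panel_f)
  res$locus_stats <- locus_stats(panel_f)
  res$group_diversity <- group_diversity(panel_f)
  res$trait_summary <- trait_summary(traits)
  res$pca <- geno_pca(panel_f)
  res$upgma <- distance_upgma(panel_f)
  res$ld <- ld_decay(ld_scan(panel_f, config$ld_max_markers),
                     config$ld_bin_width)
  quant <- setdiff(names(traits), "accession_id")[1]
  res$gwas <- glm_scan(panel_f, traits, trait_name = quant)
  res$hits <- significant_hits(res$gwas, config$gwas_threshold)
  res$core <- greedy_core_select(panel_f)
  res$codes <- fingerprint_codes(panel_f, res$core$markers$id)
  res$records <- build_records(res$codes, traits)
  if (config$export_qr) {
    res$qr_map <- export_map(res$records, file.path(config$out_dir, "qr"))
  }

  od <- config$out_dir
  utils::write.csv(res$locus_stats, file.path(od, "locus_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(res$group_diversity, file.path(od, "group_diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(res$trait_summary, file.path(od, "trait_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$pca$scores, file.path(od, "pca_scores.csv"),
                   row.names = FALSE)
  writeLines(res$upgma$newick, file.path(od, "upgma.nwk"))
  utils::write.csv(res$ld, file.path(od, "ld_decay.csv"), row.names = FALSE)
  utils::write.csv(tidy(res$gwas), file.path(od, "gwas.csv"),
                   row.names = FALSE)
  utils::write.csv(res$core$markers, file.path(od, "core_markers.csv"),
                   row.names = FALSE)
  utils::write.csv(res$codes, file.path(od, "fingerprint_codes.csv"),
                   row.names = FALSE)
  write_vcf(panel_f[, locus_order(panel_f$loci)], NULL,
            file.path(od, "filtered.vcf"))
  write_filter_report(res$filter_report, file.path(od, "filter_report.json"))

  files <- sort(list.files(od, recursive = TRUE))
  res$manifest <- list(
    seed = config$seed,
    n_samples = nrow(panel$dosage),
    n_input_sites = res$filter_report$n_input,
    n_filtered_sites = res$filter_report$n_output,
    core_set_size = res$core$size,
    outputs = stats::setNames(vapply(file.path(od, files), function(f) {
      unname(tools::md5sum(f))
    }, character(1)), files)
  )
  jsonlite::write_json(res$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}
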