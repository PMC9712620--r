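#' Assemble a pipeline configuration
#'
#' Either simulate a cohort (`simulate` = a [cohort_spec()]) or point the
#' pipeline at fixture files on disk (`input_dir` = a directory laid out
#' as by [write_fixtures()]). Analysis constants default to the package's
#' standard settings: SH threshold at 68% of the cohort, 1000-bp TSS
#' exclusion, GLM significance at p < 0.001, good:poor ratio thresholds
#' 1.2/0.8, bottom-decile prevalence stratum for per-patient annotation
#' counts.
#'
#' @param simulate Optional [cohort_spec()].
#' @param input_dir Optional fixture directory (ignored when `simulate`
#'   is given).
#' @param outdir Output directory.
#' @param sh_fraction,tss_window_bp,glm_alpha,ratio_hi,ratio_lo,stratum_fraction
#'   Analysis constants.
#' @param genome_bp Genome size for mutation-rate tests; inferred from the
#'   simulated genome or the fixtures' `truth.json` when `NULL`.
#' @param seed RNG seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            outdir = tempfile("cistromeHet_run_"),
                            sh_fraction = 0.68, tss_window_bp = 1000L,
                            glm_alpha = 0.001, ratio_hi = 1.2,
                            ratio_lo = 0.8, stratum_fraction = 0.10,
                            genome_bp = NULL, seed = 1L) {
  if (is.null(simulate) && is.null(input_dir))
    stop("configuration error: need either simulate (a cohort_spec) ",
         "or input_dir")
  if (!is.null(simulate) && !inherits(simulate, "cohort_spec"))
    stop("configuration error: simulate must be a cohort_spec")
  if (sh_fraction <= 0 || sh_fraction > 1 || tss_window_bp < 0 ||
      glm_alpha <= 0 || glm_alpha > 1 || ratio_hi <= ratio_lo ||
      stratum_fraction <= 0 || stratum_fraction > 1)
    stop("configuration error: threshold out of range")
  structure(list(simulate = simulate, input_dir = input_dir,
                 outdir = outdir, sh_fraction = sh_fraction,
                 tss_window_bp = as.integer(tss_window_bp),
                 glm_alpha = glm_alpha, ratio_hi = ratio_hi,
                 ratio_lo = ratio_lo, stratum_fraction = stratum_fraction,
                 genome_bp = genome_bp, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full heterogeneity pipeline
#'
#' Stages, in order: simulate/ingest, TSS exclusion, universe
#' construction with ranking and binning, per-bin annotation enrichment
#' and mutation-rate tests, loop-based landscape construction,
#' genome-wide occupancy-expression GLM scan, and patient outcome
#' scoring. Every stage writes its table under `config$outdir`, and a
#' `manifest.json` records parameters, seed, versions, and MD5 hashes of
#' all outputs, so an identical config and seed reproduces identical
#' hashes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`universe`, `enrichment`, `mutation_rates`, `landscapes`, `scan`,
#'   `outcome`, `summary`) plus `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "ingest"
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      cohort <- generate_cohort(config$simulate)
      peak_sets <- cohort$peak_sets
      tss <- GenomicRanges::resize(GenomicRanges::granges(cohort$promoters),
                                   width = 1L, fix = "center")
      loops <- cohort$loops
      expression <- cohort$expression
      mutations <- cohort$mutations
      annotations <- cohort$annotations
      labels <- stats::setNames(cohort$outcome$label,
                                cohort$outcome$patient_id)
      genome_bp <- sum(config$simulate$chrom_sizes)
      promoters <- cohort$promoters
    } else {
      fx <- read_cohort_fixtures(config$input_dir)
      peak_sets <- fx$peak_sets
      tss <- NULL
      loops <- fx$loops
      expression <- fx$expression
      mutations <- fx$mutations
      annotations <- fx$annotations
      labels <- fx$outcome
      genome_bp <- if (!is.null(config$genome_bp)) config$genome_bp
      else sum(fx$chrom_sizes)
      promoters <- NULL
      if (!is.null(loops$name) && !is.null(loops$anchor1)) {
        promoters <- GenomicRanges::granges(loops$anchor1)
        S4Vectors::mcols(promoters)$gene_id <- loops$name
      }
    }
    if (is.null(loops) || length(loops) == 0)
      stop("configuration error: the glm stage requires loops ",
           "(loops.bedpe missing or empty)")

    stage <- "universe"
    if (!is.null(tss))
      peak_sets <- lapply(peak_sets, exclude_tss, tss = tss,
                          window_bp = config$tss_window_bp)
    universe <- rank_and_bin(build_universe(peak_sets),
                             sh_fraction = config$sh_fraction)
    write_universe_tsv(universe, file.path(config$outdir, "universe.tsv"))

    stage <- "enrichment"
    flags <- lapply(annotations, function(a)
      annotate_overlap(universe, a)$flags)
    enr <- do.call(rbind, lapply(names(flags), function(nm) {
      e <- hypergeom_bin_enrichment(universe, flags[[nm]])
      cbind(annotation = nm, e, stringsAsFactors = FALSE)
    }))
    .write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
    mut_rates <- do.call(rbind, lapply(c("SH", "PS", "UN"), function(b) {
      reg <- universe$sites[universe$sites$bin == b]
      if (length(reg) == 0)
        return(NULL)
      r <- mutation_rate_fisher(mutations, reg, genome_bp)
      data.frame(bin = b, o_e = r$o_e, p_value = r$p_value,
                 mut_in = r$mut_in, bp_in = r$bp_in,
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(mut_rates, file.path(config$outdir, "mutation_rates.tsv"))

    stage <- "linking"
    if (is.null(promoters))
      stop("configuration error: the linking stage requires promoters")
    gl <- filter_promoter_loops(loops, promoters)
    landscapes <- build_gene_landscapes(gl, universe)
    ls_df <- do.call(rbind, lapply(names(landscapes), function(g)
      if (nrow(landscapes[[g]]) > 0)
        cbind(gene_id = g, landscapes[[g]], stringsAsFactors = FALSE)))
    if (is.null(ls_df))
      ls_df <- data.frame(gene_id = character(0), site_id = character(0),
                          prevalence = integer(0))
    .write_tsv(ls_df, file.path(config$outdir, "landscapes.tsv"))

    stage <- "glm"
    scan <- genome_scan(landscapes, universe, expression,
                        alpha = config$glm_alpha)
    .write_tsv(scan$results, file.path(config$outdir, "glm_scan.tsv"))

    stage <- "outcome"
    outc <- NULL
    if (all(c("good_outcome", "poor_outcome") %in% names(flags))) {
      outc <- score_patient_outcomes(universe, flags$good_outcome,
                                     flags$poor_outcome, labels,
                                     hi = config$ratio_hi,
                                     lo = config$ratio_lo)
      .write_tsv(outc$scores, file.path(config$outdir,
                                        "outcome_scores.tsv"))
    }
    met_ks <- NULL
    if ("met" %in% names(flags))
      met_ks <- annotation_count_histograms(
        universe, flags$met, labels,
        stratum_fraction = config$stratum_fraction)

    summary <- list(
      n_sites = length(universe$sites),
      n_patients = universe$n_patients,
      sh_min_patients = universe$sh_min_patients,
      bin_counts = as.list(table(universe$sites$bin)),
      n_significant_sites = scan$n_significant_sites,
      n_significant_genes = scan$n_significant_genes,
      outcome_fisher_p = if (!is.null(outc)) outc$fisher_p else NULL,
      met_count_ks_p = if (!is.null(met_ks)) met_ks$ks_p else NULL)
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(universe = universe, enrichment = enr, mutation_rates = mut_rates,
         landscapes = landscapes, scan = scan, outcome = outc,
         met_ks = met_ks, summary = summary, outdir = config$outdir)
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))

  files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
  manifest <- list(
    package = "cistromeHet",
    version = as.character(utils::packageVersion("cistromeHet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[c("sh_fraction", "tss_window_bp", "glm_alpha",
                          "ratio_hi", "ratio_lo", "stratum_fraction")],
    inputs = if (!is.null(config$input_dir)) config$input_dir
    else "simulated",
    outputs = as.list(tools::md5sum(file.path(config$outdir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
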