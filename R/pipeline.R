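#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis with the study's
#' defaults: 200/100 bp depth windows, the 2-SD duplication rule and
#' 0.5/0.1-fold deletion/alternate rule with the 5-of-7 frame, PLINK-style QC
#' thresholds (10% individual missingness, 3% marker missingness, 2% MAF,
#' HWE 1e-6), the four inheritance models with 5e-8 / 1e-5 significance
#' tiers, and the production-trait mixed model.
#'
#' @param sim A [sim_config()] describing the synthetic cohort.
#' @param trait Trait column scanned in the association stage.
#' @param covariates Association covariates.
#' @param out_dir Output directory for result TSVs and the run manifest.
#' @param window,step,dup_sd,high_fold,low_fold,min_high_animals,min_run,frame
#'   Depth-caller parameters.
#' @param mind,geno_miss,maf,hwe QC thresholds.
#' @param models,sig,suggestive,condition_top Association parameters;
#'   `condition_top` > 0 additionally reruns the scan conditioning on that
#'   many top markers.
#' @param prod_traits Production-trait columns for the mixed-model stage.
#' @param min_group_n Contrast support threshold.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            trait = "trait",
                            covariates = c("breed", "age"),
                            out_dir = tempfile("flockgwas_run_"),
                            window = 200L, step = 100L, dup_sd = 2,
                            high_fold = 0.5, low_fold = 0.1,
                            min_high_animals = 5L, min_run = 5L, frame = 7L,
                            mind = 0.10, geno_miss = 0.03, maf = 0.02,
                            hwe = 1e-6,
                            models = assoc_models, sig = 5e-8,
                            suggestive = 1e-5, condition_top = 0L,
                            prod_traits = "trait", min_group_n = 10L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the stages in order — simulate, depth-based region calling,
#' genotype QC, the multi-model association scan (with optional conditional
#' re-analysis), tag-marker LD against the divergent-locus truth, and the
#' production-trait mixed model — writing every stage's table as TSV into
#' `config$out_dir` together with a JSON run manifest (parameters, seed, row
#' counts). Rerunning with the same seed reproduces the outputs byte for
#' byte.
#'
#' @param config A [pipeline_config()].
#' @return List of stage results: `study`, `dup_calls`, `delalt_calls`,
#'   `qc` (filtered genotypes + report), `assoc`, `assoc_best`,
#'   `assoc_conditional` (or `NULL`), `ld`, `production`, `manifest`.
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "pipeline_config"),
           "run_pipeline(): config must come from pipeline_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  study <- stage("simulate", sim_study(config$sim))
  write_depth_tsv(study$depth, file.path(config$out_dir, "depth_panel.tsv"))

  grid <- study$grid
  dup_calls <- stage("depthcnv", call_duplications(
    study$depth, grid, sd_mult = config$dup_sd, min_run = config$min_run,
    frame = config$frame))
  delalt_calls <- stage("depthcnv", call_deletion_or_alternate(
    study$depth, grid, high_fold = config$high_fold,
    low_fold = config$low_fold, min_high_animals = config$min_high_animals,
    min_run = config$min_run, frame = config$frame))
  write_bed_regions(delalt_calls,
                    file.path(config$out_dir, "delalt_regions.bed"))

  geno_qc <- stage("qc", qc_run(study$geno$calls, mind = config$mind,
                                geno_miss = config$geno_miss,
                                maf = config$maf, hwe = config$hwe))
  readr::write_tsv(qc_report(geno_qc),
                   file.path(config$out_dir, "qc_report.tsv"))

  scan <- stage("assoc", assoc_scan(
    study$pheno, geno_qc, trait = config$trait,
    covariates = intersect(config$covariates, names(study$pheno)),
    models = config$models, sig = config$sig,
    suggestive = config$suggestive))
  best <- best_model(scan)
  readr::write_tsv(dplyr::select(best, -"beta"),
                   file.path(config$out_dir, "assoc_best.tsv"))

  cond <- NULL
  if (config$condition_top > 0L) {
    top <- head(dplyr::arrange(best, .data$p_nominal)$marker,
                config$condition_top)
    cond <- stage("assoc_conditional", assoc_scan(
      study$pheno, geno_qc, trait = config$trait,
      covariates = intersect(config$covariates, names(study$pheno)),
      models = "genotypic", sig = config$sig,
      suggestive = config$suggestive, condition_on = top))
  }

  ld <- stage("ld", {
    truth_calls <- study$truth$divergent_genotype
    g <- dplyr::mutate(study$geno$calls, divergent_locus = truth_calls)
    ld_pair(g, "tag_snp", "divergent_locus")
  })
  readr::write_tsv(ld, file.path(config$out_dir, "ld_tag_vs_divergent.tsv"))

  production <- stage("prodtrait", trait_report(
    study$production, traits = config$prod_traits,
    min_group_n = config$min_group_n))
  readr::write_tsv(production,
                   file.path(config$out_dir, "production_contrasts.tsv"))

  manifest <- list(
    package = "flockgwas",
    version = as.character(utils::packageVersion("flockgwas")),
    seed = config$sim$seed,
    parameters = config[setdiff(names(config), c("sim", "out_dir"))],
    rows = list(depth = nrow(study$depth), markers_in = config$sim$n_markers,
                markers_kept = length(geno_cols(geno_qc)),
                assoc_records = nrow(scan), dup_calls = nrow(dup_calls),
                delalt_calls = nrow(delalt_calls))
  )
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  list(study = study, dup_calls = dup_calls, delalt_calls = delalt_calls,
       qc = geno_qc, assoc = scan, assoc_best = best,
       assoc_conditional = cond, ld = ld, production = production,
       manifest = manifest, out_dir = config$out_dir)
}
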