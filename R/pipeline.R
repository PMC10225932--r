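#' Default pipeline configuration
#'
#' Threshold constants default to the analysis conventions: phecodes need
#' more than 20 cases per cohort, lab outliers are trimmed at 7 SD,
#' discoveries are reported at FDR 0.005 and 0.05, local-ancestry calls
#' require posterior > 0.9, and admixture hits are clumped at p < 0.05 within
#' 1 Mb.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(seed = 1L,
       n_individuals = 2000L,
       output_dir = NULL,
       stages = c("simulate", "estimate", "prep", "phewas", "admixmap",
                  "heritability", "mitonuclear"),
       min_cases = 20L,
       trim_sd = 7,
       fdr_levels = c(0.005, 0.05),
       posterior_min = 0.9,
       clump_p = 0.05,
       clump_window = 1e6,
       autosomal_mean_depth = 2.8,
       spike_multiplier = 10,
       n_markers_per_chrom = 150L,
       n_chrom = 3L,
       h2_target = 0.3,
       n_h2_variants = 1000L,
       n_traits = 20L)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a list or a path to a YAML file; fills defaults, rejects unknown
#' keys, and resolves relative paths against the configuration file's
#' directory.
#'
#' @param config List of settings or path to a YAML file.
#' @return Normalized configuration list of class `"pipeline_config"`.
#' @export
validate_config <- function(config = list()) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1) {
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, config)
  if (!is.null(out$output_dir) && !startsWith(out$output_dir, "/"))
    out$output_dir <- file.path(base_dir, out$output_dir)
  bad_stage <- setdiff(out$stages, defaults$stages)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  structure(out, class = c("pipeline_config", "list"))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in dependency order: cohort simulation, depth
#' simulation and copy-number estimation, residualization, phenotype
#' preparation, the copy-number PheWAS, admixture mapping with the empirical
#' multiple-testing burden, heritability estimation, and the mito-nuclear
#' interaction scan. Tables are written to `output_dir` when set; the report
#' is returned invisibly as a list. Identical configurations and seeds yield
#' identical reports.
#'
#' @param config A [validate_config()] result (or raw list/path, validated on
#'   the way in).
#' @return List with one element per executed stage.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  seed <- config$seed
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_tsv(df, file.path(out_dir,
                                                   paste0(name, ".tsv")))
  }
  report <- list()
  stages <- config$stages

  cfg <- cohort_config(n_individuals = config$n_individuals, seed = seed)
  cohort <- simulate_cohort(cfg)
  map <- marker_map(config$n_chrom, config$n_markers_per_chrom)
  local <- simulate_local_ancestry(cohort, map,
                                   g = cfg$generations_since_admixture,
                                   seed = seed)
  geno <- simulate_unlinked_genotypes(config$n_individuals,
                                      config$n_h2_variants, seed = seed)
  true_lr <- simulate_copy_number(cohort, h2_target = config$h2_target,
                                  genotypes = geno, seed = seed)
  if ("simulate" %in% stages) {
    emit(cohort, "cohort")
    report$simulate <- list(n = nrow(cohort),
                            african_lineage_frac =
                              mean(cohort$mt_origin == "African"))
  }

  records <- NULL
  if (any(c("estimate", "prep", "phewas", "admixmap", "heritability",
            "mitonuclear") %in% stages)) {
    profiles <- simulate_depth(true_lr,
                               autosomal_mean = config$autosomal_mean_depth,
                               spike_multiplier = config$spike_multiplier,
                               seed = seed, ids = cohort$individual_id)
    records <- estimate_rmtcn_cohort(profiles)
    records <- standardize(residualize(records, cohort))
    emit(records, "copy_number")
    report$estimate <- list(n = nrow(records),
                            sd_lrmtcn = stats::sd(records$lrmtcn))
  }

  phenome <- NULL
  if (any(c("prep", "phewas", "mitonuclear") %in% stages)) {
    traits <- c(
      list(trait_spec("copy_number_trait", "binary", prevalence = 0.15,
                      beta_rlrmtcn = 0.3)),
      lapply(seq_len(config$n_traits - 1), function(i)
        trait_spec(paste0("null_trait_", i), "binary", prevalence = 0.1))
    )
    phen <- simulate_phenotypes(cohort, records$rlrmtcn, traits, seed = seed)
    status <- assign_case_control(phen$phecodes)
    kept <- filter_phecodes(status, min_cases = config$min_cases)
    phenome <- status[, kept, drop = FALSE]
    report$prep <- list(n_phecodes = ncol(status), n_retained = length(kept))
  }

  covars <- as.matrix(cbind(sex = cohort$sex, age = cohort$age,
                            age2 = cohort$age^2,
                            cohort[grep("^PC", names(cohort))]))
  if ("phewas" %in% stages) {
    recs <- run_phewas(records$rlrmtcn, status = phenome, covariates = covars)
    flags <- bh_fdr(recs$p, config$fdr_levels)
    recs <- cbind(recs, flags[-1])
    emit(recs, "phewas")
    report$phewas <- recs
  }

  if ("admixmap" %in% stages) {
    glob <- global_ancestry(local, config$posterior_min)
    amap <- local_ancestry_assoc(records$rlrmtcn, local, glob,
                                 cohort$duffy_genotype,
                                 config$posterior_min)
    eff <- effective_tests(local, config$posterior_min)
    hits <- clump_hits(amap, config$clump_p, config$clump_window)
    emit(amap, "admixture_mapping")
    report$admixmap <- list(n_eff = eff$n_eff, threshold = eff$threshold,
                            n_clumped_hits = nrow(hits))
  }

  if ("heritability" %in% stages) {
    grm <- build_grm(geno)
    h2 <- estimate_h2_he(records$rlrmtcn, grm)
    emit(h2, "heritability")
    report$heritability <- h2
  }

  if ("mitonuclear" %in% stages) {
    sel <- cohort$mt_origin %in% c("African", "European")
    x <- ifelse(cohort$mt_origin[sel] == "African", 1, -1)
    it <- interaction_test(records$rlrmtcn[sel],
                           cohort$african_ancestry[sel], x,
                           cohort$sex[sel], cohort$age[sel], "linear")
    emit(it, "mitonuclear")
    report$mitonuclear <- it
  }

  invisible(report)
}
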