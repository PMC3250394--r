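#' Read an allele-dosage matrix
#'
#' TSV input: first column `subject_id`, remaining columns one per SNP
#' (header = SNP ids), entries 0..2 (fractional allowed for imputed data).
#' VCF input: the per-sample `DS` FORMAT field when present, else hard `GT`
#' calls converted to 0/1/2 counts of the ALT allele. The returned matrix
#' carries an `alleles` attribute (snp_id, counted, other) used for effect-
#' allele orientation; for VCF the counted allele is ALT.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"`, or `"vcf"`.
#' @return numeric matrix, subjects x SNPs, rownames = subject ids.
#' @export
read_dosages <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("dosage file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    tb <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(tb))
      stop("dosage TSV must have a subject_id column: ", path)
    m <- as.matrix(tb[setdiff(names(tb), "subject_id")])
    if (!is.numeric(m)) stop("non-numeric dosage entries in ", path)
    rownames(m) <- tb$subject_id
    storage.mode(m) <- "double"
    return(m)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  snp_ids <- v@fix[, "ID"]
  fmt <- v@gt[, "FORMAT"]
  if (all(grepl("DS", fmt))) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  m <- t(d)  # samples x SNPs
  colnames(m) <- snp_ids
  attr(m, "alleles") <- data.frame(snp_id = snp_ids,
                                   counted = unname(v@fix[, "ALT"]),
                                   other = unname(v@fix[, "REF"]))
  m
}

#' Read a phenotype/covariate table (CSV)
#'
#' Requires columns `subject_id`, `sex`, `age`, `study`, `smoking`, plus one
#' or more trait columns.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "study", "smoking")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("phenotype file lacks columns: ", paste(miss, collapse = ", "))
  tb
}

#' Run configuration for the analysis pipeline
#'
#' Exactly one of `sim_config` (simulate a cohort) or the three input paths
#' (`genotypes`, `weights`, `phenotypes`) must be supplied.
#'
#' @param sim_config a [simulation_config()], or `NULL`.
#' @param genotypes,weights,phenotypes input paths, or `NULL`.
#' @param trait trait column to analyze.
#' @param grid_step percentile grid step (percent).
#' @param B bootstrap replicates for the profile.
#' @param n_perm residual permutations (0 skips the null check).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return object of class `qp_run_config`.
#' @export
run_config <- function(sim_config = NULL, genotypes = NULL, weights = NULL,
                       phenotypes = NULL, trait = "trait", grid_step = 1,
                       B = 1000L, n_perm = 0L, seed = 1L,
                       out_dir = "quantpen_run") {
  from_files <- !is.null(genotypes) || !is.null(phenotypes)
  if (is.null(sim_config) == !from_files)
    stop("supply exactly one of: a simulation config, or input file paths")
  if (from_files && (is.null(genotypes) || is.null(phenotypes)))
    stop("file input needs both genotypes and phenotypes paths")
  structure(list(sim_config = sim_config, genotypes = genotypes,
                 weights = weights, phenotypes = phenotypes, trait = trait,
                 grid_step = grid_step, B = as.integer(B),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "qp_run_config")
}

#' Run the full quantile-penetrance pipeline
#'
#' Stages: load or simulate the cohort; build the GRS (published weights if
#' given, else the simulator's true weights, plus the sample-fitted
#' variant); residualize phenotype and score on sex, age, age^2, study and
#' smoking; fit the quantile-slope profile with paired-bootstrap covariance;
#' run the linear-contrast trend test; compute variance explained by
#' projection to the mean score; optionally run the residual-permutation
#' null. Writes subject-level data, the profile (TSV + covariance TSV), a
#' JSON report and a manifest to `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (list with `profile`, `trend`, `varexp`,
#'   `summary`, and `perm_null` when requested).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qp_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[quantpen] ", ...)

  if (!is.null(config$sim_config)) {
    log_stage("simulating cohort (n = ", config$sim_config$n_subjects, ")")
    cohort <- simulate_cohort(config$sim_config)
    dosages <- cohort$dosages
    subjects <- cohort$subjects
    y_raw <- cohort$phenotype
    cfg <- config$sim_config
    wt <- weights_table(cfg$snps$id, "G", "A", cfg$snps$beta,
                        trait = config$trait)
  } else {
    log_stage("reading inputs")
    dosages <- read_dosages(config$genotypes)
    ph <- read_phenotypes(config$phenotypes)
    if (!config$trait %in% names(ph))
      stop("trait column '", config$trait, "' absent from phenotype file")
    extra <- setdiff(rownames(dosages), ph$subject_id)
    if (length(extra))
      stop("samples in genotypes but not phenotypes: ",
           paste(extra, collapse = ", "))
    ph <- ph[match(rownames(dosages), ph$subject_id), , drop = FALSE]
    subjects <- ph[c("subject_id", "sex", "age", "study", "smoking")]
    y_raw <- ph[[config$trait]]
    wt <- if (!is.null(config$weights)) read_weights(config$weights) else
      NULL
  }

  log_stage("computing risk score")
  grs <- if (!is.null(wt)) compute_grs(dosages, wt) else
    stop("no weights available: supply a weights file")

  log_stage("adjusting for covariates")
  y_adj <- adjust_covariates(y_raw, subjects)
  g_adj <- adjust_covariates(as.numeric(grs), subjects)

  log_stage("fitting quantile-slope profile (B = ", config$B, ")")
  grid <- quantile_grid(step = config$grid_step)
  prof <- fit_profile(y_adj, g_adj, grid = grid, B = config$B,
                      seed = config$seed)
  tr <- trend_test(prof)
  ve <- variance_explained(y_adj[!is.na(y_adj)], g_adj[!is.na(g_adj)], prof)
  tab <- summary_table(setNames(list(prof), config$trait))

  perm <- NULL
  if (config$n_perm > 0L) {
    log_stage("residual-permutation null (", config$n_perm, " permutations)")
    perm <- permutation_null(y_adj[!is.na(y_adj)], g_adj[!is.na(g_adj)],
                             n_perm = config$n_perm, seed = config$seed)
  }

  log_stage("writing outputs to ", config$out_dir)
  subj_out <- cbind(subjects, trait = y_raw, grs = as.numeric(grs),
                    trait_adj = y_adj, grs_adj = g_adj)
  write.csv(subj_out, file.path(config$out_dir, "subjects.csv"),
            row.names = FALSE)
  write.table(data.frame(percentile = prof$percentile, slope = prof$slope,
                         se = prof$se),
              file.path(config$out_dir, "profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(prof$cov, file.path(config$out_dir, "profile_cov.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = paste0("p", prof$percentile))
  write.table(tab, file.path(config$out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report <- list(
    trait = config$trait, n = prof$n, B = prof$B, seed = config$seed,
    ols = list(slope = prof$ols_slope, se = prof$ols_se, r2 = prof$ols_r2),
    trend = list(delta = tr$delta, se = tr$se, z = tr$z, p = tr$p),
    variance_explained = list(r2_standard = ve$r2_standard,
                              r2_quantile = ve$r2_quantile,
                              relative_improvement_pct =
                                ve$relative_improvement_pct,
                              group_mode = ve$group_mode),
    ci_coverage_band = ci_coverage_band(prof),
    fold_ratio_90_10 = fold_ratio(prof)$ratio,
    permutation_null = if (!is.null(perm))
      list(n_perm = perm$n_perm,
           rejection_fraction = perm$rejection_fraction),
    covariance_file = "profile_cov.tsv")
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "quantpen",
    version = as.character(utils::packageVersion("quantpen")),
    seed = config$seed,
    config = config[setdiff(names(config), "sim_config")],
    simulated = !is.null(config$sim_config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profile = prof, trend = tr, varexp = ve, summary = tab,
                 perm_null = perm, report = report))
}
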