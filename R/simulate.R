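#' SNP specifications for the cohort simulator
#'
#' Builds a deterministic table of SNP ids, minor-allele frequencies and true
#' per-allele effects ("weights" in trait units) spanning the range seen in
#' lipid/BMI meta-analyses: a few SNPs with large effects and a tail of small
#' ones, with allele frequencies spread over (0.05, 0.5].
#'
#' @param n_snps number of independent SNPs (default 31, the size of a
#'   typical published triglyceride score).
#' @param beta_max,beta_min largest and smallest true per-allele effect, in
#'   trait units; effects decay geometrically between them.
#' @return data.frame with columns `id`, `maf`, `beta`.
#' @export
default_snp_specs <- function(n_snps = 31L, beta_max = 8, beta_min = 0.5) {
  stopifnot(n_snps >= 1, beta_max > 0, beta_min > 0)
  data.frame(
    id = sprintf("rs%06d", seq_len(n_snps)),
    maf = seq(0.08, 0.5, length.out = n_snps),
    beta = exp(seq(log(beta_max), log(beta_min), length.out = n_snps))
  )
}

#' Configuration of the synthetic cohort generator
#'
#' The generator draws independent Hardy-Weinberg genotypes, covariates, and
#' a phenotype from the location-scale model
#' \deqn{y = \mu + s + \mathrm{covariates} + \max(1 + \theta z_s, 0.1)\,
#'   \sigma\,\varepsilon,}
#' where \eqn{s = \sum_j \beta_j g_j} is the true genetic score, \eqn{z_s} its
#' standardized value, and \eqn{\varepsilon} standard normal. With
#' \eqn{\theta > 0} the conditional quantile slope of \eqn{y} on \eqn{s} fans
#' out across percentiles: \eqn{\beta(\tau) = 1 + (\theta\sigma/\mathrm{sd}(s))
#' \Phi^{-1}(\tau)} (the coefficient on \eqn{s} itself is 1 by construction).
#' The multiplicative scale is floored at 0.1 so the model stays well defined
#' for extreme scores.
#'
#' @param n_subjects cohort size; defaults to 1930, the size of the
#'   two-study cohort the simulator emulates.
#' @param snps data.frame with columns `id`, `maf` in (0, 0.5], `beta`
#'   (trait units per allele).
#' @param covariate_effects list with elements `sex_effect`, `age_linear`,
#'   `age_quadratic`, `study_offsets` (length 2, first is reference),
#'   `smoking_effect`, all in trait units.
#' @param intercept trait-unit intercept.
#' @param sigma residual SD in trait units (> 0).
#' @param theta heteroscedasticity coefficient (dimensionless); 0 gives a
#'   homoscedastic phenotype with a flat quantile-slope profile.
#' @param seed master integer seed; per-stage streams are derived from it.
#' @return object of class `qp_sim_config`.
#' @export
simulation_config <- function(n_subjects = 1930L,
                              snps = default_snp_specs(),
                              covariate_effects = list(
                                sex_effect = -10,
                                age_linear = 0.5,
                                age_quadratic = -0.003,
                                study_offsets = c(0, 5),
                                smoking_effect = 8),
                              intercept = 140,
                              sigma = 20,
                              theta = 0.3,
                              seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop("n_subjects must be a positive count")
  if (!is.data.frame(snps) || !all(c("id", "maf", "beta") %in% names(snps)))
    stop("snps must be a data.frame with columns id, maf, beta")
  if (any(snps$maf <= 0 | snps$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  if (anyDuplicated(snps$id)) stop("SNP ids must be unique")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.numeric(theta) || length(theta) != 1L) stop("theta must be a scalar")
  need <- c("sex_effect", "age_linear", "age_quadratic", "study_offsets",
            "smoking_effect")
  if (!all(need %in% names(covariate_effects)))
    stop("covariate_effects must name: ", paste(need, collapse = ", "))
  if (length(covariate_effects$study_offsets) != 2L)
    stop("study_offsets must have length 2")
  structure(
    list(n_subjects = as.integer(n_subjects), snps = snps,
         covariate_effects = covariate_effects, intercept = intercept,
         sigma = sigma, theta = theta, seed = as.integer(seed)),
    class = "qp_sim_config")
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each SNP's dosage is the number of effect alleles in two independent
#' Bernoulli(maf) draws, so genotype frequencies follow Hardy-Weinberg
#' proportions and column means converge to 2*maf.
#'
#' @param n number of subjects (>= 1).
#' @param snp_specs data.frame with columns `id`, `maf` in (0, 0.5].
#' @param seed integer seed for the genotype stream.
#' @return numeric matrix, subjects x SNPs, entries in \{0, 1, 2\}, with an
#'   `alleles` attribute recording the counted (effect) and other allele for
#'   each simulated SNP.
#' @export
simulate_genotypes <- function(n, snp_specs, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive count")
  if (any(snp_specs$maf <= 0 | snp_specs$maf > 0.5))
    stop("maf must lie in (0, 0.5]")
  n <- as.integer(n)
  m <- nrow(snp_specs)
  g <- matrix(0, n, m, dimnames = list(NULL, snp_specs$id))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(split_seed(seed, "genotypes"))
  for (j in seq_len(m)) g[, j] <- rbinom(n, 2L, snp_specs$maf[j])
  attr(g, "alleles") <- data.frame(snp_id = snp_specs$id,
                                   counted = "G", other = "A")
  g
}

#' Simulate a cohort phenotype under the location-scale model
#'
#' @param dosages subjects x SNPs dosage matrix whose columns match
#'   `config$snps$id`.
#' @param config a [simulation_config()].
#' @return object of class `qp_cohort`: list with `subjects` (covariate
#'   data.frame), `dosages`, `phenotype`, and `truth` (true score, its SD,
#'   and the config).
#' @export
simulate_phenotype <- function(dosages, config) {
  stopifnot(inherits(config, "qp_sim_config"))
  if (!is.matrix(dosages) || ncol(dosages) != nrow(config$snps) ||
      !identical(colnames(dosages), config$snps$id))
    stop("dosage columns do not match the configured SNP list")
  n <- nrow(dosages)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  set.seed(split_seed(config$seed, "covariates"))
  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = rbinom(n, 1L, 0.5),
    age = runif(n, 30, 75),
    study = sample(c("CAP", "PRINCE"), n, replace = TRUE),
    smoking = rbinom(n, 1L, 0.2))

  s <- drop(dosages %*% config$snps$beta)
  sd_s <- sd(s)
  z <- if (sd_s > 0) (s - mean(s)) / sd_s else rep(0, n)
  ce <- config$covariate_effects
  mu <- config$intercept + s +
    ce$sex_effect * subjects$sex +
    ce$age_linear * subjects$age + ce$age_quadratic * subjects$age^2 +
    ce$study_offsets[match(subjects$study, c("CAP", "PRINCE"))] +
    ce$smoking_effect * subjects$smoking

  set.seed(split_seed(config$seed, "phenotype"))
  eps <- rnorm(n)
  scale <- pmax(1 + config$theta * z, 0.1)
  y <- mu + scale * config$sigma * eps

  structure(list(subjects = subjects, dosages = dosages, phenotype = y,
                 truth = list(score = s, sd_score = sd_s, config = config)),
            class = "qp_cohort")
}

#' Simulate a full cohort (genotypes + covariates + phenotype)
#'
#' @param config a [simulation_config()].
#' @return a `qp_cohort`; identical seeds give bit-identical cohorts.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "qp_sim_config"))
  g <- simulate_genotypes(config$n_subjects, config$snps, seed = config$seed)
  simulate_phenotype(g, config)
}

#' True conditional quantile slope of the simulator
#'
#' Closed form implied by the location-scale model:
#' \eqn{\beta(\tau) = 1 + (\theta\sigma/\mathrm{sd}(s))\Phi^{-1}(\tau)}
#' (ignoring the rarely-binding scale floor).
#'
#' @param config a [simulation_config()].
#' @param tau quantile level(s) in (0,1).
#' @param sd_score SD of the true genetic score; if missing, the population
#'   value \eqn{\sqrt{\sum_j \beta_j^2\, 2\,\mathrm{maf}_j(1-\mathrm{maf}_j)}}
#'   is used.
#' @return numeric vector of slopes (trait units per score unit).
#' @export
true_quantile_slope <- function(config, tau, sd_score = NULL) {
  stopifnot(inherits(config, "qp_sim_config"), all(tau > 0 & tau < 1))
  if (is.null(sd_score)) {
    p <- config$snps$maf
    sd_score <- sqrt(sum(config$snps$beta^2 * 2 * p * (1 - p)))
  }
  1 + (config$theta * config$sigma / sd_score) * qnorm(tau)
}

#' LDL-cholesterol by the Friedewald formula
#'
#' LDL = total cholesterol - HDL - triglycerides/5, all in mg/dL. The formula
#' is unreliable at high triglycerides; values above `tg_limit` return `NA`
#' (flagged missing) rather than an error.
#'
#' @param total_chol,hdl,triglycerides mg/dL, vectorized.
#' @param tg_limit validity bound for triglycerides (default 400 mg/dL,
#'   conventional usage).
#' @return LDL-cholesterol in mg/dL, `NA` where triglycerides exceed the bound.
#' @export
friedewald_ldl <- function(total_chol, hdl, triglycerides, tg_limit = 400) {
  ldl <- total_chol - hdl - triglycerides / 5
  ldl[triglycerides > tg_limit] <- NA_real_
  ldl
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `phenotypes.csv` (subject_id, covariates, trait), `dosages.tsv`
#' (subjects x SNPs, header = SNP ids), optionally `dosages.vcf`, and a
#' sidecar `config.json` recording the full simulation configuration with the
#' ground-truth quantile-slope parameters.
#'
#' @param cohort a `qp_cohort`.
#' @param dir output directory (created if needed).
#' @param trait_name column name for the phenotype in the CSV.
#' @param vcf also write a VCF with a per-sample DS (dosage) FORMAT field.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, trait_name = "trait", vcf = FALSE) {
  stopifnot(inherits(cohort, "qp_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- cbind(cohort$subjects, setNames(data.frame(cohort$phenotype),
                                        trait_name))
  write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  dos <- data.frame(subject_id = cohort$subjects$subject_id,
                    cohort$dosages, check.names = FALSE)
  write.table(dos, file.path(dir, "dosages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- cohort$truth$config
  sidecar <- list(
    config = cfg[setdiff(names(cfg), "snps")],
    snps = cfg$snps,
    truth = list(sd_score = cohort$truth$sd_score,
                 quantile_slope = list(
                   form = "1 + (theta*sigma/sd_score) * qnorm(tau)",
                   theta = cfg$theta, sigma = cfg$sigma,
                   sd_score = cohort$truth$sd_score)))
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (vcf) write_dosage_vcf(cohort, file.path(dir, "dosages.vcf"))
  invisible(dir)
}

# Minimal VCFv4.2 writer: one record per SNP, DS = dosage of the ALT
# (effect) allele.
write_dosage_vcf <- function(cohort, path) {
  al <- attr(cohort$dosages, "alleles") %||%
    data.frame(snp_id = colnames(cohort$dosages), counted = "G", other = "A")
  ids <- cohort$subjects$subject_id
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                  "Description=\"Dosage of the ALT allele\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(cohort$dosages)), function(j) {
    paste(c("1", j * 1000L, colnames(cohort$dosages)[j],
            al$other[j], al$counted[j], ".", "PASS", ".", "DS",
            formatC(cohort$dosages[, j], format = "g", digits = 8)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
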