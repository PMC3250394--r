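#' Construct or validate a per-SNP weights table
#'
#' A weights table carries, for each SNP, the effect allele, the other
#' allele, and the published per-allele effect on the trait (in trait units:
#' kg/m2 for BMI, mg/dL for lipids and lipoproteins, z-score units for
#' height).
#'
#' @param snp_id character SNP ids (unique).
#' @param effect_allele,other_allele single-base alleles.
#' @param weight per-allele effect in trait units (finite).
#' @param trait trait label, consistent across rows.
#' @return data.frame of class `qp_weights`.
#' @export
weights_table <- function(snp_id, effect_allele, other_allele, weight,
                          trait = "trait") {
  if (anyDuplicated(snp_id)) stop("SNP ids in a weights table must be unique")
  if (!all(is.finite(weight))) stop("weights must be finite")
  trait <- rep_len(trait, length(snp_id))
  if (length(unique(trait)) != 1L)
    stop("trait label must be consistent across rows")
  structure(data.frame(snp_id = as.character(snp_id),
                       effect_allele = toupper(effect_allele),
                       other_allele = toupper(other_allele),
                       weight = as.numeric(weight),
                       trait = trait),
            class = c("qp_weights", "data.frame"))
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Orient a dosage column to the effect allele
#'
#' Risk scores count effect alleles; genotype files may record the dose of
#' either allele. If the recorded allele is the effect allele the dosage is
#' returned unchanged, if it is the other allele the dose is complemented to
#' `2 - dosage` (valid for fractional, imputed dosages too).
#'
#' @param dosage numeric doses in \[0, 2\] of `recorded_allele`.
#' @param recorded_allele the allele the file counts.
#' @param effect_allele,other_allele the weights-table alleles.
#' @param snp_id id used in error messages.
#' @return doses of the effect allele.
#' @export
orient_to_effect_allele <- function(dosage, recorded_allele, effect_allele,
                                    other_allele, snp_id = "?") {
  ra <- toupper(recorded_allele); ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  if (identical(ra, ea)) return(dosage)
  if (identical(ra, oa)) return(2 - dosage)
  stop("recorded allele ", ra, " for SNP ", snp_id,
       " matches neither effect (", ea, ") nor other (", oa, ") allele")
}

# Resolve the orientation of every weights SNP against the dosage matrix's
# allele records. Strand-unambiguous flips (direct or after complementing
# both alleles) are applied; ambiguous A/T and C/G SNPs are accepted as
# recorded with a warning, anything irreconcilable errors.
.orient_matrix <- function(dosages, weights) {
  al <- attr(dosages, "alleles")
  if (is.null(al)) return(dosages)  # plain matrix: assume effect allele counted
  out <- dosages
  ambiguous <- character(0)
  for (k in seq_len(nrow(weights))) {
    id <- weights$snp_id[k]
    row <- al[al$snp_id == id, , drop = FALSE]
    if (nrow(row) == 0L) next
    ea <- weights$effect_allele[k]; oa <- weights$other_allele[k]
    if (identical(ea, unname(.complement[oa]))) {
      ambiguous <- c(ambiguous, id)   # A/T or C/G: strand unresolvable
      next
    }
    ca <- toupper(row$counted[1]); ot <- toupper(row$other[1])
    if ((ca == ea && ot == oa) ||
        (ca == .complement[ea] && ot == .complement[oa])) {
      # already counts the effect allele
    } else if ((ca == oa && ot == ea) ||
               (ca == .complement[oa] && ot == .complement[ea])) {
      out[, id] <- 2 - dosages[, id]
    } else {
      stop("alleles for SNP ", id, " (", ca, "/", ot,
           ") cannot be reconciled with the weights table (", ea, "/", oa, ")")
    }
  }
  if (length(ambiguous))
    warning("strand-ambiguous SNPs accepted as recorded: ",
            paste(ambiguous, collapse = ", "))
  out
}

#' Compute a genetic risk score
#'
#' The GRS of subject i is the weighted allele-dosage sum
#' \eqn{\mathrm{GRS}_i = \sum_j d_{ij} w_j}, with dosages oriented to each
#' SNP's effect allele. Its unit is the predicted trait unit (kg/m2, mg/dL
#' or z-score increase). Missing dosage entries are mean-imputed per SNP
#' with a message.
#'
#' @param dosages subjects x SNPs matrix (0..2, fractional allowed); an
#'   optional `alleles` attribute (data.frame snp_id/counted/other) drives
#'   allele orientation. Without it, dosages are assumed to count the effect
#'   allele.
#' @param weights a [weights_table()].
#' @return numeric score per subject with attributes `provenance`
#'   (`"published"`) and `trait`.
#' @export
compute_grs <- function(dosages, weights) {
  stopifnot(is.matrix(dosages))
  missing_snps <- setdiff(weights$snp_id, colnames(dosages))
  if (length(missing_snps))
    stop("weights SNPs absent from dosage matrix: ",
         paste(missing_snps, collapse = ", "))
  d <- .orient_matrix(dosages, weights)[, weights$snp_id, drop = FALSE]
  n_missing <- sum(is.na(d))
  if (n_missing > 0) {
    message("mean-imputing ", n_missing, " missing dosage entries")
    for (j in seq_len(ncol(d))) {
      miss <- is.na(d[, j])
      if (any(miss)) d[miss, j] <- mean(d[, j], na.rm = TRUE)
    }
  }
  score <- drop(d %*% weights$weight)
  attr(score, "provenance") <- "published"
  attr(score, "trait") <- weights$trait[1]
  score
}

#' Fit sample-specific SNP weights by multiple regression
#'
#' Regresses the (covariate-adjusted) phenotype on all dosage columns
#' jointly; the coefficients are the weights that maximize the variance
#' explained in the current sample. The intercept is estimated but not
#' stored as a weight.
#'
#' @param dosages subjects x SNPs matrix.
#' @param adjusted_phenotype numeric response, one value per subject.
#' @param trait trait label for the returned table.
#' @return a [weights_table()] with the fitted coefficients; effect/other
#'   alleles are carried over from the dosage matrix's allele records when
#'   present.
#' @export
fit_weights <- function(dosages, adjusted_phenotype, trait = "trait") {
  stopifnot(is.matrix(dosages),
            length(adjusted_phenotype) == nrow(dosages))
  if (nrow(dosages) <= ncol(dosages) + 1L)
    stop("need more subjects than SNPs + 1 to fit weights")
  X <- cbind(`(Intercept)` = 1, dosages)
  fit <- lm.fit(X, adjusted_phenotype)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient design; collinear SNPs: ",
         paste(setdiff(dropped, "(Intercept)"), collapse = ", "))
  }
  al <- attr(dosages, "alleles")
  ea <- if (!is.null(al)) al$counted[match(colnames(dosages), al$snp_id)] else
    rep("G", ncol(dosages))
  oa <- if (!is.null(al)) al$other[match(colnames(dosages), al$snp_id)] else
    rep("A", ncol(dosages))
  w <- weights_table(colnames(dosages), ea, oa,
                     fit$coefficients[-1L], trait = trait)
  attr(w, "provenance") <- "fitted"
  w
}

#' Two-component risk-score refit
#'
#' Fits separate least-squares coefficients to a primary SNP's dosage and to
#' the weighted combination of the remaining SNPs, and returns the combined
#' score `coef_primary * dosage + coef_rest * rest_grs`. Used when a single
#' variant (e.g. an FTO SNP for BMI) dominates the score.
#'
#' @param primary_snp_dosage dosage vector of the primary SNP.
#' @param rest_grs risk score built from the remaining SNPs.
#' @param adjusted_phenotype numeric response.
#' @return list with `coef_primary`, `coef_rest`, and `combined` (a score
#'   vector with provenance `"two_component"`).
#' @export
two_component_refit <- function(primary_snp_dosage, rest_grs,
                                adjusted_phenotype) {
  if (sd(primary_snp_dosage) == 0 || sd(rest_grs) == 0)
    stop("both predictors must vary")
  X <- cbind(1, primary = primary_snp_dosage, rest = as.numeric(rest_grs))
  fit <- lm.fit(X, adjusted_phenotype)
  if (fit$rank < 3L)
    stop("collinear predictors in the two-component refit")
  cf <- fit$coefficients
  combined <- cf["primary"] * primary_snp_dosage + cf["rest"] * rest_grs
  attributes(combined) <- NULL
  attr(combined, "provenance") <- "two_component"
  list(coef_primary = unname(cf["primary"]),
       coef_rest = unname(cf["rest"]),
       combined = combined)
}

#' Read / write a weights table (TSV)
#'
#' Columns: `snp_id`, `effect_allele`, `other_allele`, `weight`, `trait`.
#'
#' @param path file path.
#' @return [weights_table()] for the reader; `path` invisibly for the writer.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  tb <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "weight", "trait")
  if (!all(need %in% names(tb)))
    stop("weights file must have columns: ", paste(need, collapse = ", "))
  weights_table(tb$snp_id, tb$effect_allele, tb$other_allele, tb$weight,
                tb$trait)
}

#' @rdname read_weights
#' @param weights a [weights_table()] to write.
#' @export
write_weights <- function(weights, path) {
  write.table(as.data.frame(weights), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
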