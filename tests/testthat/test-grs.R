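test_that("dosage columns orient to the effect allele", {
  expect_equal(orient_to_effect_allele(2, "A", "G", "A"), 0)
  expect_equal(orient_to_effect_allele(0.5, "A", "G", "A"), 1.5)
  expect_equal(orient_to_effect_allele(1, "G", "G", "A"), 1)
  expect_error(orient_to_effect_allele(1, "C", "G", "A", snp_id = "rs9"),
               "rs9")
})

test_that("the GRS is the weighted allele-dosage sum", {
  # single-SNP score with the published FTO per-allele BMI effect
  d <- matrix(2, 1, 1, dimnames = list(NULL, "rs1558902"))
  w <- weights_table("rs1558902", "A", "T", 0.39, trait = "bmi")
  expect_equal(as.numeric(compute_grs(d, w)), 0.78)

  d3 <- matrix(c(1, 2, 0), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  w3 <- weights_table(c("a", "b", "c"), "G", "A", c(0.1, 0.2, 0.3))
  expect_equal(as.numeric(compute_grs(d3, w3)), 0.5)

  w0 <- weights_table(c("a", "b", "c"), "G", "A", c(0, 0, 0))
  expect_equal(as.numeric(compute_grs(d3, w0)), 0)

  expect_error(compute_grs(d3, weights_table("zzz", "G", "A", 1)), "zzz")
})

test_that("compute_grs is linear in the weights", {
  set.seed(51)
  d <- matrix(sample(0:2, 200 * 6, replace = TRUE), 200, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  for (r in 1:5) {
    w1 <- runif(6, -1, 1)
    w2 <- runif(6, -1, 1)
    cw <- runif(1, -2, 2)
    g1 <- compute_grs(d, weights_table(paste0("s", 1:6), "G", "A", w1))
    g2 <- compute_grs(d, weights_table(paste0("s", 1:6), "G", "A", w2))
    g12 <- compute_grs(d, weights_table(paste0("s", 1:6), "G", "A", w1 + w2))
    gc <- compute_grs(d, weights_table(paste0("s", 1:6), "G", "A", cw * w1))
    expect_equal(as.numeric(g12), as.numeric(g1) + as.numeric(g2),
                 tolerance = 1e-12)
    expect_equal(as.numeric(gc), cw * as.numeric(g1), tolerance = 1e-12)
  }
})

test_that("allele records drive orientation, flips and ambiguity warnings", {
  d <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2, dimnames = list(NULL, c("s1", "s2")))
  attr(d, "alleles") <- data.frame(snp_id = c("s1", "s2"),
                                   counted = c("G", "C"), other = c("A", "T"))
  # s2's file counts C but the weights' effect allele is T -> flip 2 - d
  w <- weights_table(c("s1", "s2"), c("G", "T"), c("A", "C"), c(1, 1))
  g <- compute_grs(d, w)
  expect_equal(as.numeric(g), d[, "s1"] + (2 - d[, "s2"]))
  # strand flip: file counts the complement base of the effect allele
  attr(d, "alleles")$counted <- c("C", "C")  # C/A vs weights G/A: complement G=C
  attr(d, "alleles")$other <- c("T", "T")
  w2 <- weights_table(c("s1", "s2"), c("G", "A"), c("A", "G"), c(1, 1))
  expect_warning(compute_grs(d, w2), NA) # C/T vs G/A resolves by strand flip
  # ambiguous A/T SNP accepted as recorded, with a warning
  w3 <- weights_table("s1", "A", "T", 1)
  d1 <- d[, 1, drop = FALSE]
  attr(d1, "alleles") <- data.frame(snp_id = "s1", counted = "A", other = "T")
  expect_warning(compute_grs(d1, w3), "ambiguous")
})

test_that("missing dosages are mean-imputed with a message", {
  d <- matrix(c(0, 1, 2, NA), 4, 1, dimnames = list(NULL, "s1"))
  w <- weights_table("s1", "G", "A", 2)
  expect_message(g <- compute_grs(d, w), "mean-imputing")
  expect_equal(as.numeric(g), c(0, 2, 4, 2))
})

test_that("fitted weights recover the simulator's true effects", {
  cfg <- simulation_config(n_subjects = 20000, snps = default_snp_specs(8),
                           theta = 0, sigma = 10, seed = 60)
  ch <- simulate_cohort(cfg)
  ya <- adjust_covariates(ch$phenotype, ch$subjects)
  w <- fit_weights(ch$dosages, ya)
  # compare against lm's own coefficients and SEs
  fit <- lm(ya ~ ch$dosages)
  se <- coef(summary(fit))[-1, "Std. Error"]
  expect_true(all(abs(w$weight - cfg$snps$beta) < 3 * se))

  # one-predictor reduction: weight equals the simple least-squares slope
  d1 <- ch$dosages[, 1, drop = FALSE]
  w1 <- fit_weights(d1, ya)
  expect_equal(w1$weight, unname(coef(lm(ya ~ d1[, 1]))[2]),
               tolerance = 1e-10)
})

test_that("fitted weights vanish for a phenotype unrelated to dosages", {
  set.seed(61)
  d <- matrix(rbinom(3000 * 4, 2, 0.3), 3000, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  y <- rnorm(3000)
  w <- fit_weights(d, y)
  se <- coef(summary(lm(y ~ d)))[-1, "Std. Error"]
  expect_true(all(abs(w$weight) < 3.5 * se))
})

test_that("fit_weights rejects rank-deficient designs, naming the SNPs", {
  set.seed(62)
  d <- matrix(rbinom(100 * 2, 2, 0.4), 100, 2,
              dimnames = list(NULL, c("s1", "s2")))
  d <- cbind(d, s3 = d[, "s1"])  # exact duplicate
  expect_error(fit_weights(d, rnorm(100)), "s3")
  expect_error(fit_weights(d[1:3, ], rnorm(3)), "more subjects")
})

test_that("allele flips leave fitted predictions unchanged", {
  set.seed(63)
  d <- matrix(rbinom(500 * 3, 2, 0.3), 500, 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  y <- d %*% c(1, -0.5, 0.2) + rnorm(500)
  w <- fit_weights(d, y)
  d_flip <- d
  d_flip[, 2] <- 2 - d[, 2]
  w_flip <- fit_weights(d_flip, y)
  expect_equal(w_flip$weight[2], -w$weight[2], tolerance = 1e-10)
  pred <- d %*% w$weight
  pred_flip <- d_flip %*% w_flip$weight
  expect_equal(as.numeric(scale(pred, scale = FALSE)),
               as.numeric(scale(pred_flip, scale = FALSE)),
               tolerance = 1e-8)
})

test_that("fitted-weights GRS never explains less in-sample variance", {
  draw <- make_adjusted_draw(n = 800, n_snps = 10, theta = 0.2, seed = 64)
  ch <- draw$cohort
  pub <- compute_grs(ch$dosages,
                     weights_table(draw$config$snps$id, "G", "A",
                                   draw$config$snps$beta))
  fitted_w <- fit_weights(ch$dosages, draw$y)
  fit_score <- compute_grs(ch$dosages, fitted_w)
  expect_gt(cor(as.numeric(pub), as.numeric(fit_score)), 0)
  r2 <- function(s) summary(lm(draw$y ~ as.numeric(s)))$r.squared
  expect_gte(r2(fit_score) + 1e-12, r2(pub))
})

test_that("two-component refit recovers a primary-SNP-only signal", {
  set.seed(70)
  n <- 5000
  primary <- rbinom(n, 2, 0.4)
  rest <- rnorm(n)  # pure noise score
  y <- 0.8 * primary + rnorm(n)
  fit <- two_component_refit(primary, rest, y)
  se_rest <- coef(summary(lm(y ~ primary + rest)))["rest", "Std. Error"]
  expect_lt(abs(fit$coef_rest), 3 * se_rest)
  expect_lt(abs(fit$coef_primary - 0.8), 0.1)

  # nested-model property: the combined score explains at least as much
  # variance as either component alone
  s <- rbinom(n, 2, 0.3)
  rest2 <- 0.5 * rnorm(n) + 0.3 * s
  y2 <- s + rest2 + rnorm(n)
  f2 <- two_component_refit(s, rest2, y2)
  r2 <- function(p) summary(lm(y2 ~ p))$r.squared
  expect_gte(r2(f2$combined) + 1e-10, max(r2(s), r2(rest2)))

  expect_error(two_component_refit(s, s, y2), "collinear")
  expect_error(two_component_refit(rep(1, n), rest2, y2), "vary")
})

test_that("weights tables round-trip through TSV", {
  w <- weights_table(c("rs1", "rs2"), c("A", "G"), c("C", "T"),
                     c(0.39, -0.12), trait = "bmi")
  path <- tempfile(fileext = ".tsv")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_equal(as.data.frame(w), as.data.frame(w2))
  expect_error(read_weights(tempfile()), "not found")
})
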