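test_that("exact linear outcomes recover the standardized beta exactly", {
  set.seed(1)
  d <- generate_cohort(60, seed = 1)
  z <- function(v) (v - mean(v)) / sd(v)
  # noiseless: outcome perfectly collinear with the predictor, so the
  # standardized beta is the correlation (-1) and p collapses to 0
  d$erc_thk <- -0.5 * z(d$tangles_q)
  fit <- suppressWarnings(   # lm warns on the perfect fit, by design here
    fit_region_model(d, "ERC", "tangles_q", covariates = character(0)))
  expect_equal(unname(fit$coefficients["tangles_q"]), -1, tolerance = 1e-10)
  expect_lt(unname(fit$p_one_sided["tangles_q"]), 1e-12)
  # unit-variance construction: beta = -0.5 is recovered to machine
  # precision when the orthogonal part is scaled to make sd(y) exactly 1
  w <- rnorm(60)
  zr <- z(resid(lm(w ~ z(d$tangles_q))))
  d$ba36_thk <- -0.5 * z(d$tangles_q) + sqrt(0.75) * zr
  fit2 <- fit_region_model(d, "BA36", "tangles_q", covariates = character(0))
  expect_equal(unname(fit2$coefficients["tangles_q"]), -0.5,
               tolerance = 1e-10)
})

test_that("residual df match the predictor and covariate counts", {
  preds <- c("tangles_q", "threads_q", "mtl_ptdp_sq")
  d140 <- generate_cohort(140, seed = 2)
  expect_equal(fit_region_model(d140, "AH", preds)$df_residual, 131L)
  expect_equal(fit_region_model(d140, "ERC", preds)$df_residual, 132L)
  d31 <- generate_cohort(31, seed = 3)
  expect_equal(fit_region_model(d31, "PH", preds)$df_residual, 22L)
  expect_equal(fit_region_model(d31, "BA35", preds)$df_residual, 23L)
  d85 <- generate_cohort(85, seed = 4)
  expect_equal(fit_region_model(d85, "AH", preds)$df_residual, 76L)
  expect_equal(fit_region_model(d85, "PHC", preds)$df_residual, 77L)
})

test_that("coefficients match the normal-equations oracle on small designs", {
  set.seed(6)
  for (i in 1:5) {
    d <- generate_cohort(20, seed = 100 + i)
    fit <- fit_region_model(d, "BA36", c("tangles_q", "threads_q"))
    z <- function(v) (v - mean(v)) / sd(v)
    X <- cbind(1, z(d$tangles_q), z(d$threads_q), z(d$age), d$sex,
               d$field_strength, z(d$antemortem_interval))
    beta <- oracle_ols(X, z(d$ba36_thk))
    expect_equal(unname(fit$coefficients["tangles_q"]), beta[2],
                 tolerance = 1e-8)
    expect_equal(unname(fit$coefficients["threads_q"]), beta[3],
                 tolerance = 1e-8)
  }
})

test_that("a single standardized predictor equals the Pearson correlation", {
  d <- generate_cohort(50, seed = 7)
  fit <- fit_region_model(d, "PHC", "tangles_q", covariates = character(0))
  expect_equal(unname(fit$coefficients["tangles_q"]),
               cor(d$tangles_q, d$phc_thk), tolerance = 1e-10)
})

test_that("one-sided type-I error is nominal under a null effect", {
  null_effects <- default_effect_specs(
    betas = c(tangles_q = 0, threads_q = 0, mtl_ptdp_sq = 0))
  hits <- vapply(seq_len(500), function(i) {
    d <- generate_cohort(60, effects = null_effects, seed = 5000 + i)
    fit <- fit_region_model(d, "ERC", "tangles_q")
    fit$p_one_sided[["tangles_q"]] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(signif(bonferroni_threshold(0.05, 6), 3), 8.33e-3)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 1e-3)
})

test_that("L1 prediction error sums absolute residuals", {
  expect_equal(prediction_error_l1(c(1, -2, 0.5)), 3.5)
  expect_equal(prediction_error_l1(rep(0, 10)), 0)
  d <- generate_cohort(40, seed = 8)
  fit <- fit_region_model(d, "AH", "tangles_q")
  expect_equal(prediction_error_l1(fit), sum(abs(fit$residuals)),
               tolerance = 1e-10)
})

test_that("information criteria match the closed-form oracle and stats::AIC deltas", {
  d <- generate_cohort(50, seed = 9)
  fit <- fit_region_model(d, "ERC", c("tangles_q", "threads_q"))
  rss <- sum(fit$residuals^2)
  oc <- oracle_ic(rss, fit$n, length(fit$coefficients))
  expect_equal(fit$bic, oc[["bic"]], tolerance = 1e-10)
  expect_equal(fit$aicc, oc[["aicc"]], tolerance = 1e-10)

  # deltas agree with stats::AIC/BIC (which keep the likelihood constants)
  fit2 <- fit_region_model(d, "ERC", "tangles_q")
  z <- function(v) (v - mean(v)) / sd(v)
  l1 <- lm(z(d$erc_thk) ~ z(d$tangles_q) + z(d$threads_q) + z(d$age) +
             d$sex + d$field_strength + z(d$antemortem_interval))
  l2 <- lm(z(d$erc_thk) ~ z(d$tangles_q) + z(d$age) +
             d$sex + d$field_strength + z(d$antemortem_interval))
  expect_equal(fit$bic - fit2$bic, BIC(l1) - BIC(l2), tolerance = 1e-8)
  aicc_of <- function(l) {
    k <- length(coef(l)) + 1
    AIC(l) + 2 * k * (k + 1) / (nobs(l) - k - 1)
  }
  expect_equal(fit$aicc - fit2$aicc, aicc_of(l1) - aicc_of(l2),
               tolerance = 1e-8)
})

test_that("AICc is flagged undefined when n <= k + 1", {
  expect_warning(
    ic <- information_criteria(residuals = rnorm(5), n = 5, n_coef = 3),
    "AICc undefined")
  expect_true(is.na(ic[["aicc"]]))
  expect_false(is.na(ic[["bic"]]))
})

test_that("IC deltas are invariant to affine rescaling of the outcome", {
  d <- generate_cohort(60, seed = 10)
  f_a1 <- fit_region_model(d, "BA35", c("tangles_q", "threads_q"))
  f_b1 <- fit_region_model(d, "BA35", "mtl_ptau_sq")
  d2 <- d
  d2$ba35_thk <- 1000 * d2$ba35_thk - 37
  f_a2 <- fit_region_model(d2, "BA35", c("tangles_q", "threads_q"))
  f_b2 <- fit_region_model(d2, "BA35", "mtl_ptau_sq")
  expect_equal(f_a1$bic - f_b1$bic, f_a2$bic - f_b2$bic, tolerance = 1e-8)
  expect_equal(f_a1$aicc - f_b1$aicc, f_a2$aicc - f_b2$aicc,
               tolerance = 1e-8)
})

test_that("adding a pure-noise predictor shifts BIC by about log(n)", {
  # with RSS essentially unchanged, the BIC penalty difference dominates
  set.seed(11)
  n <- 100
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)
  noise <- rnorm(n)
  l_small <- lm(y ~ x)
  l_big <- lm(y ~ x + noise)
  ic_small <- information_criteria(l_small)
  ic_big <- information_criteria(l_big)
  expect_lt(abs((ic_big[["bic"]] - ic_small[["bic"]]) - log(n)), 1.0)
})

test_that("model comparison deltas and evidence labels follow the BIC rules", {
  d <- generate_cohort(80, seed = 12)
  fq <- fit_region_model(d, "ERC", c("tangles_q", "threads_q"))
  same <- compare_models(fq, fq)
  expect_equal(same$delta_bic, 0)
  expect_equal(same$delta_r2_adj, 0)
  expect_equal(same$evidence_label, "none")
  expect_equal(same$favours, "neither")

  fake <- function(bic) {
    f <- fq
    f$bic <- bic
    f
  }
  expect_equal(compare_models(fake(fq$bic - 7), fq)$evidence_label, "strong")
  expect_equal(compare_models(fake(fq$bic - 7), fq)$favours, "quantitative")
  expect_equal(compare_models(fake(fq$bic + 3), fq)$evidence_label, "positive")
  expect_equal(compare_models(fake(fq$bic + 3), fq)$favours,
               "semiquantitative")
  expect_equal(compare_models(fake(fq$bic - 11), fq)$evidence_label,
               "very_strong")

  fs <- fit_region_model(d[1:70, ], "ERC", "mtl_ptau_sq")
  expect_error(compare_models(fq, fs), "different subject sets")
})

test_that("subgroup filters match a direct counting oracle", {
  d <- generate_cohort(200, seed = 13)
  preds <- c("tangles_q", "threads_q", "mtl_ptdp_sq")
  adv <- run_cohort_analyses(d, preds, "advanced_adnc")
  expect_equal(adv$subgroup_n, sum(d$braak_stage >= 5))
  lt <- run_cohort_analyses(d, preds, "late")
  expect_equal(lt$subgroup_n, sum(d$late_stage >= 1))
  whole <- run_cohort_analyses(d, preds, "whole")
  expect_equal(whole$subgroup_n, nrow(d))
  expect_equal(nrow(whole$table), 6L * 3L)
  # bonferroni flags are consistent with the threshold
  expect_equal(whole$table$bonferroni,
               whole$table$p_one_sided < 0.05 / 6)
})

test_that("rank-deficient designs are reported with the offending column", {
  d <- generate_cohort(40, seed = 14)
  d$dup <- d$tangles_q
  expect_error(fit_region_model(d, "ERC", c("tangles_q", "dup")),
               "collinear")
})
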