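#' Planted effect specification for one imaging region
#'
#' Describes how a synthetic regional morphometry outcome is generated:
#' standardized effects for the pathology predictors, effects for the
#' nuisance covariates, and the residual noise level. All effects are on the
#' z-scored outcome scale, so a `beta` of -0.4 for a (z-scored) predictor is
#' the standardized coefficient a correctly specified model should recover.
#'
#' @param region One of `names(imaging_regions())`.
#' @param betas Named numeric vector of standardized pathology effects, e.g.
#'   `c(tangles_q = -0.4, threads_q = 0, mtl_ptdp_sq = -0.3)`.
#' @param covariate_effects Named numeric vector of covariate effects
#'   (continuous covariates act on their z-scores; sex and field strength on
#'   their 0/1 codes).
#' @param noise_sd Residual standard deviation on the z-scored outcome
#'   scale; `NULL` sets it so the outcome has approximately unit variance
#'   (making the planted betas standardized betas). Must be positive.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region,
                        betas = c(tangles_q = -0.4, threads_q = 0,
                                  mtl_ptdp_sq = -0.3),
                        covariate_effects = c(age = -0.15, sex = 0.05,
                                              field_strength = 0.05,
                                              antemortem_interval = -0.05,
                                              icv = 0.3),
                        noise_sd = NULL) {
  region <- match.arg(region, names(imaging_regions()))
  if (imaging_regions()[[region]] == "thickness") {
    covariate_effects <- covariate_effects[names(covariate_effects) != "icv"]
  }
  if (is.null(noise_sd)) {
    # variance budget: continuous effects act on z-scores (variance 1),
    # binary covariates on 0/1 codes (variance p(1-p) <= 1/4)
    binary <- intersect(names(covariate_effects), c("sex", "field_strength"))
    v <- sum(betas^2) +
      sum(covariate_effects[setdiff(names(covariate_effects), binary)]^2) +
      sum(covariate_effects[binary]^2) / 4
    noise_sd <- sqrt(max(0.1, 1 - v))
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(
    list(region = region, betas = betas,
         covariate_effects = covariate_effects, noise_sd = noise_sd),
    class = "effect_spec"
  )
}

#' Default planted effects for all six imaging regions
#'
#' @inheritParams effect_spec
#' @return Named list of [effect_spec()] objects, one per region.
#' @export
default_effect_specs <- function(betas = c(tangles_q = -0.4, threads_q = 0,
                                           mtl_ptdp_sq = -0.3)) {
  specs <- lapply(names(imaging_regions()), effect_spec, betas = betas)
  stats::setNames(specs, names(imaging_regions()))
}

# Braak-stage severity cutpoints: chosen so the synthetic AD-continuum
# cohort has ~60.7% of subjects at stage V/VI (85 of 140) and ~30% at VI.
braak_cutpoints <- function() {
  stats::qgamma(c(0.03, 0.08, 0.15, 0.25, 0.393, 0.70), shape = 2, scale = 1)
}

# LATE-NC severity cutpoints: region positivity thresholds set so
# P(stage >= 1) = 31/140, P(stage >= 2) = 0.10, P(stage >= 3) = 0.029.
late_cutpoints <- function() {
  stats::qexp(c(1 - 31 / 140, 0.90, 0.971))
}

# Ordinal rating from a latent severity with positivity (rating >= 1) at
# threshold t_pos; the 0.5/2/3 cutpoints scale with it.
rating_from_severity <- function(sev, t_pos) {
  th <- t_pos * c(0.5, 1, 1.8, 2.8)
  c(0, 0.5, 1, 2, 3)[findInterval(sev, th) + 1L]
}

#' Generate a synthetic autopsy cohort with planted pathology effects
#'
#' Simulates subject records emulating an Alzheimer's-continuum brain-donor
#' cohort with antemortem MRI: demographics and scan covariates, latent tau
#' and TDP-43 severities, quantitative hippocampal summary measures (noisy
#' monotone transforms of the latent severities), semi-quantitative MTL
#' ratings (ordinal coarsenings of the same severities), Braak and LATE-NC
#' stages derived by thresholding the severities, per-hemisphere QC flags,
#' and regional morphometry outcomes generated as linear combinations of the
#' z-scored measured predictors plus Gaussian noise per [effect_spec()].
#'
#' Covariate distributions: age ~ N(75, 8) years, sex ~ Bernoulli(0.5),
#' 3T field strength ~ Bernoulli(0.7), antemortem interval ~ U(0, 10) years,
#' ICV ~ N(1.4e6, 1.5e5) mm^3. Stage cutpoints are fixed so that the
#' expected subgroup composition matches the study conditions (Braak V/VI
#' 85/140, LATE-NC stage >= 1 31/140).
#'
#' @param n_subjects Number of subjects (0 gives an empty table with the
#'   full schema).
#' @param effects Named list of [effect_spec()] per region.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param rating_model [severity_model()] supplying the cutpoints that map
#'   tau severity to the MTL p-tau rating. The default cutpoints saturate
#'   for a majority of advanced-stage subjects (the ceiling effect of
#'   ordinal burden ratings in severe disease).
#' @param rating_noise_sd Standard deviation of the rater-subjectivity
#'   noise added to the latent severity before it is coarsened into the
#'   ordinal rating.
#' @return Data frame of subject records, one row per subject.
#' @export
generate_cohort <- function(n_subjects,
                            effects = default_effect_specs(),
                            seed = 1L,
                            rating_model = severity_model(
                              rating_thresholds = c(0.4, 0.8, 1.4, 2.2)),
                            rating_noise_sd = 0.35) {
  schema_cols <- c("subject_id", "age", "sex", "field_strength",
                   "antemortem_interval", "icv", "tau_severity",
                   "tdp_severity", "tangles_q", "threads_q", "ng_tdp_q",
                   "nt_tdp_q", "mtl_ptau_sq", "mtl_ptdp_sq",
                   "neuronal_loss_sq", "braak_stage", "late_stage",
                   "amygdala_tdp", "dg_tdp", "ca1_sub_tdp", "erc_tdp",
                   "mfg_tdp", "qc_ipsilateral",
                   "ah_vol", "ph_vol", "erc_thk", "ba35_thk", "ba36_thk",
                   "phc_thk")
  if (n_subjects == 0L) {
    empty <- as.data.frame(stats::setNames(
      replicate(length(schema_cols), numeric(0), simplify = FALSE),
      schema_cols))
    empty$subject_id <- character(0)
    empty$qc_ipsilateral <- logical(0)
    return(empty)
  }
  stopifnot(n_subjects >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- n_subjects

  age <- stats::rnorm(n, 75, 8)
  sex <- stats::rbinom(n, 1, 0.5)
  field_strength <- stats::rbinom(n, 1, 0.7)  # 1 = 3T
  antemortem_interval <- stats::runif(n, 0, 10)
  icv <- stats::rnorm(n, 1.4e6, 1.5e5)

  tau_severity <- stats::rgamma(n, shape = 2, scale = 1)
  tdp_severity <- stats::rexp(n, rate = 1)

  tangles_q <- pmax(0, 0.12 * tau_severity + stats::rnorm(n, 0, 0.045))
  threads_q <- pmax(0, 0.10 * tau_severity + stats::rnorm(n, 0, 0.07))
  ng_tdp_q <- pmax(0, 0.10 * tdp_severity + stats::rnorm(n, 0, 0.04))
  nt_tdp_q <- pmax(0, 0.08 * tdp_severity + stats::rnorm(n, 0, 0.05))

  mtl_ptau_sq <- generate_ordinal_rating(
    pmax(0, tau_severity + stats::rnorm(n, 0, rating_noise_sd)),
    rating_model)
  lc <- late_cutpoints()
  amygdala_tdp <- rating_from_severity(tdp_severity, lc[1L])
  dg_tdp <- rating_from_severity(tdp_severity, lc[2L])
  ca1_sub_tdp <- rating_from_severity(tdp_severity * 0.95, lc[2L])
  erc_tdp <- rating_from_severity(tdp_severity * 0.9, lc[2L])
  mfg_tdp <- rating_from_severity(tdp_severity, lc[3L])
  mtl_ptdp_sq <- mtl_average_rating(erc_tdp, ca1_sub_tdp, dg_tdp)
  neuronal_loss_sq <- rating_from_severity(
    0.6 * tau_severity + 0.4 * tdp_severity, 1.5)

  braak_stage <- findInterval(tau_severity, braak_cutpoints())
  late <- late_stage(amygdala_tdp, dg_tdp, ca1_sub_tdp, erc_tdp, mfg_tdp)

  qc_ipsilateral <- stats::runif(n) < 0.92

  d <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, field_strength = field_strength,
    antemortem_interval = antemortem_interval, icv = icv,
    tau_severity = tau_severity, tdp_severity = tdp_severity,
    tangles_q = tangles_q, threads_q = threads_q,
    ng_tdp_q = ng_tdp_q, nt_tdp_q = nt_tdp_q,
    mtl_ptau_sq = mtl_ptau_sq, mtl_ptdp_sq = mtl_ptdp_sq,
    neuronal_loss_sq = neuronal_loss_sq,
    braak_stage = braak_stage, late_stage = as.integer(late),
    amygdala_tdp = amygdala_tdp, dg_tdp = dg_tdp,
    ca1_sub_tdp = ca1_sub_tdp, erc_tdp = erc_tdp, mfg_tdp = mfg_tdp,
    qc_ipsilateral = qc_ipsilateral,
    stringsAsFactors = FALSE)

  zscore <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
  outcome_scale <- list(
    AH = c(1800, 350), PH = c(1500, 300), ERC = c(2.6, 0.35),
    BA35 = c(2.4, 0.35), BA36 = c(2.7, 0.35), PHC = c(2.4, 0.3))
  for (region in names(imaging_regions())) {
    spec <- effects[[region]]
    if (is.null(spec)) spec <- effect_spec(region)
    y <- rep(0, n)
    for (p in names(spec$betas)) {
      y <- y + spec$betas[[p]] * zscore(d[[p]])
    }
    for (cv in names(spec$covariate_effects)) {
      xv <- if (cv %in% c("sex", "field_strength")) d[[cv]] else zscore(d[[cv]])
      y <- y + spec$covariate_effects[[cv]] * xv
    }
    y <- y + stats::rnorm(n, 0, spec$noise_sd)
    sc <- outcome_scale[[region]]
    d[[region_outcome_column(region)]] <- sc[1L] + sc[2L] * y
  }
  d[, schema_cols]
}
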