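#' Hippocampal subregions eligible for the summary burden measure
#'
#' The seven subfield ROIs that are consistently identifiable along the
#' hippocampal longitudinal axis and therefore pooled into the
#' hippocampus-level summary: CA1, CA2, CA3, the CA1/subiculum and
#' subiculum/presubiculum transition zones, and the two dentate gyrus
#' subregions (hilus and granular cell layer).
#'
#' @return Character vector of eligible anatomical labels.
#' @export
hippocampal_labels <- function() {
  c("CA1", "CA2", "CA3", "CA1-SUB", "SUB-PrS", "DG-H", "DG-GCL")
}

#' Hippocampus-level summary pathology measure for one subject and class
#'
#' Averages ROI-level quantitative burden over the eligible hippocampal
#' subregions, with two inclusion rules: (i) for the threads class, the
#' dentate gyrus hilus (DG-H) is excluded before averaging, because mossy
#' fibres there are systematically misread as threads; (ii) the summary is
#' missing unless at least three anatomical regions are available, where the
#' two dentate gyrus subregions jointly count as a single region towards that
#' threshold (although, when eligible, both their values enter the average
#' separately). The region count is taken after the DG-H threads exclusion.
#'
#' @param values Named numeric vector of ROI-level measures; names must be
#'   drawn from [hippocampal_labels()]. `NA` entries are treated as
#'   unavailable.
#' @param inclusion_class The pathology class the values measure; only
#'   `"threads"` triggers the DG-H exclusion.
#' @return The mean of the available eligible values, or `NA` if fewer than
#'   three regions are available.
#' @export
hippocampal_summary <- function(values, inclusion_class = "tangles") {
  inclusion_class <- match.arg(inclusion_class, inclusion_classes())
  if (is.null(names(values)) || !all(names(values) %in% hippocampal_labels())) {
    stop("values must be named with hippocampal subregion labels: ",
         paste(hippocampal_labels(), collapse = ", "))
  }
  values <- values[!is.na(values)]
  if (inclusion_class == "threads") {
    values <- values[names(values) != "DG-H"]
  }
  if (length(values) == 0L) return(NA_real_)
  labels <- names(values)
  # DG-GCL and DG-H jointly count as one region towards the >= 3 rule
  region_count <- length(setdiff(labels, c("DG-GCL", "DG-H"))) +
    as.integer(any(labels %in% c("DG-GCL", "DG-H")))
  if (region_count < 3L) return(NA_real_)
  mean(values)
}

#' Recalibrate raw summary measures to the 0-3 ordinal rating scale
#'
#' Fits an ordinary least-squares line of the semi-quantitative MTL ratings
#' on the raw quantitative summaries and maps the raw values through the
#' fitted line. This puts the summary measures roughly on the 0-3 rating
#' scale without affecting any association statistics: a positive-slope
#' affine map preserves rank order, Pearson and Spearman correlations, and
#' standardized regression coefficients.
#'
#' @param raw Numeric vector of raw hippocampal summary measures.
#' @param semiquant Numeric vector of matching semi-quantitative MTL ratings.
#' @return A list with `transformed` (same length as `raw`, `NA` preserved),
#'   `intercept` and `slope`.
#' @export
rescale_summary <- function(raw, semiquant) {
  if (length(raw) != length(semiquant)) {
    stop("raw and semiquant must have equal length")
  }
  ok <- !is.na(raw) & !is.na(semiquant)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(raw[ok]) == 0) stop("raw measures have zero variance")
  fit <- stats::lm(semiquant[ok] ~ raw[ok])
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope < 0) {
    warning("negative slope between raw measures and ratings; ",
            "transform applied anyway")
  }
  list(transformed = intercept + slope * raw,
       intercept = intercept, slope = slope)
}

#' Average semi-quantitative MTL rating over the three canonical regions
#'
#' Arithmetic mean of the ordinal ratings in entorhinal cortex,
#' CA1/subiculum, and dentate gyrus. The same operation serves p-tau,
#' pTDP-43 and neuronal-loss ratings. If any of the three regions is
#' missing, the average is missing (the measure is defined as the mean of
#' exactly these three regions).
#'
#' @param erc,ca1_sub,dg Ordinal ratings on the `{0, 0.5, 1, 2, 3}` scale;
#'   vectorised.
#' @return Numeric vector of MTL average ratings.
#' @export
mtl_average_rating <- function(erc, ca1_sub, dg) {
  check_rating <- function(x, nm) {
    bad <- !is.na(x) & !(x %in% c(0, 0.5, 1, 2, 3))
    if (any(bad)) stop(nm, " contains values outside the rating scale")
    x
  }
  erc <- check_rating(erc, "erc")
  ca1_sub <- check_rating(ca1_sub, "ca1_sub")
  dg <- check_rating(dg, "dg")
  (erc + ca1_sub + dg) / 3
}

#' LATE-NC stage from regional pTDP-43 ratings
#'
#' Stages limbic-predominant age-related TDP-43 encephalopathy
#' neuropathologic change from ordinal pTDP-43 ratings: amygdala involvement
#' defines stage 1, spread to hippocampus/entorhinal cortex (any of dentate
#' gyrus, CA1/subiculum, or ERC) defines stage 2, and middle frontal gyrus
#' involvement defines stage 3. A rating of 1 (mild) or greater counts as
#' positive. Staging is hierarchical: stage k requires the stage-k criterion
#' and all lower-stage criteria. Cases whose positivity pattern skips a
#' stage (e.g. hippocampus positive with amygdala negative) are staged by
#' the hierarchical rule and flagged via the `"noncontiguous"` attribute.
#'
#' @param amygdala,dg,ca1_sub,erc,mfg Ordinal ratings `{0, 0.5, 1, 2, 3}`;
#'   vectorised.
#' @return Integer vector of stages 0-3, with attributes `"noncontiguous"`
#'   (logical) and `"indeterminate"` (logical; `TRUE` where the amygdala
#'   rating is missing, in which case the stage is `NA`).
#' @export
late_stage <- function(amygdala, dg, ca1_sub, erc, mfg) {
  pos <- function(x) !is.na(x) & x >= 1
  s1 <- pos(amygdala)
  s2_crit <- pos(dg) | pos(ca1_sub) | pos(erc)
  s3_crit <- pos(mfg)
  stage <- ifelse(s1 & s2_crit & s3_crit, 3L,
           ifelse(s1 & s2_crit, 2L,
           ifelse(s1, 1L, 0L)))
  indeterminate <- is.na(amygdala)
  stage[indeterminate] <- NA_integer_
  noncontiguous <- (!s1 & (s2_crit | s3_crit)) | (s1 & !s2_crit & s3_crit)
  noncontiguous[indeterminate] <- NA
  structure(as.integer(stage),
            noncontiguous = noncontiguous,
            indeterminate = indeterminate)
}
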