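#' Activation heatmap for one sampling box
#'
#' A dense grid of classifier activations in `[0, 1]` with its pixel size in
#' microns and (optionally) the inclusion class it maps.
#'
#' @param values Numeric matrix of activations in `[0, 1]`.
#' @param pixel_size_um Pixel edge length in microns (> 0).
#' @param inclusion_class Optional class label, one of
#'   `"tangles"`, `"threads"`, `"neuronal_glial"`, `"neuritic"`,
#'   `"other"`, `"background"`.
#' @return An object of class `heatmap_grid`.
#' @export
heatmap_grid <- function(values, pixel_size_um,
                         inclusion_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("heatmap values must all be finite")
  }
  if (any(values < 0) || any(values > 1)) {
    stop("heatmap values must lie in [0, 1]")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive scalar")
  }
  if (!is.null(inclusion_class)) {
    inclusion_class <- match.arg(inclusion_class, inclusion_classes())
  }
  structure(
    list(values = values, pixel_size_um = pixel_size_um,
         inclusion_class = inclusion_class),
    class = "heatmap_grid"
  )
}

#' Inclusion-class vocabulary
#'
#' @return Character vector of recognised pathology inclusion classes.
#' @export
inclusion_classes <- function() {
  c("tangles", "threads", "neuronal_glial", "neuritic", "other", "background")
}

#' Anatomical label vocabulary for sampling boxes
#'
#' Hippocampal subfields and MTL cortical areas in which sampling boxes are
#' annotated on hippocampus-level histology sections.
#'
#' @return Character vector of anatomical labels.
#' @export
anatomical_labels <- function() {
  c("CA1", "CA2", "CA3", "DG-GCL", "DG-H", "CA1-SUB", "SUB-PrS",
    "EC-med", "EC-ctr", "EC-lat", "BA35", "BA36")
}

#' Sampling box within an anatomical region of interest
#'
#' @param mask Logical (or 0/1) matrix marking pixels inside the box mask;
#'   must contain at least one `TRUE` pixel and align with the heatmap grid.
#' @param anatomical_label Label from [anatomical_labels()].
#' @param pixel_size_um Pixel edge length in microns.
#' @param box_id,slide_id Optional identifiers.
#' @return An object of class `sampling_box`.
#' @export
sampling_box <- function(mask, anatomical_label, pixel_size_um,
                         box_id = NULL, slide_id = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!any(mask)) stop("mask must be non-empty")
  anatomical_label <- match.arg(anatomical_label, anatomical_labels())
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(
    list(mask = mask, anatomical_label = anatomical_label,
         pixel_size_um = pixel_size_um, box_id = box_id,
         slide_id = slide_id),
    class = "sampling_box"
  )
}

#' Candidate summary statistics for segment-level activations
#'
#' @return Character vector naming the eight candidate statistics: mean,
#'   median, maximum and the 25th/75th/90th/95th/99th quantiles.
#' @export
summary_statistics <- function() {
  c("mean", "median", "max", "q25", "q75", "q90", "q95", "q99")
}

# Quantile by linear interpolation between closest order statistics
# (position p*(n-1), the default convention of mainstream numeric stacks).
interp_quantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

#' Per-segment mean activations
#'
#' Averages the heatmap over each segment of a partition.
#'
#' @param heatmap A [heatmap_grid()].
#' @param partition A [partition_roi()] result aligned to the same grid.
#' @return Numeric vector with one mean activation per segment.
#' @export
segment_averages <- function(heatmap, partition) {
  stopifnot(inherits(heatmap, "heatmap_grid"),
            inherits(partition, "segment_partition"))
  if (!identical(dim(heatmap$values), partition$grid_dim)) {
    stop("heatmap and partition grids are misaligned: ",
         paste(dim(heatmap$values), collapse = "x"), " vs ",
         paste(partition$grid_dim, collapse = "x"))
  }
  vapply(partition$segments,
         function(idx) mean(heatmap$values[idx]),
         numeric(1))
}

#' Summarise segment values into a scalar box-level burden measure
#'
#' @param segment_values Numeric vector of per-segment mean activations.
#' @param statistic One of [summary_statistics()]; default `"q99"`, the
#'   statistic that discriminates expert rating categories most consistently.
#' @return A scalar; `NA` for an empty input (missing, never zero).
#' @export
box_summary <- function(segment_values, statistic = "q99") {
  statistic <- match.arg(statistic, summary_statistics())
  segment_values <- segment_values[!is.na(segment_values)]
  if (length(segment_values) == 0L) return(NA_real_)
  switch(statistic,
         mean = mean(segment_values),
         median = interp_quantile(segment_values, 0.5),
         max = max(segment_values),
         q25 = interp_quantile(segment_values, 0.25),
         q75 = interp_quantile(segment_values, 0.75),
         q90 = interp_quantile(segment_values, 0.90),
         q95 = interp_quantile(segment_values, 0.95),
         q99 = interp_quantile(segment_values, 0.99))
}

#' Pool segment averages across sampling boxes into an ROI-level measure
#'
#' Segment-level averages from all boxes sampling the same anatomical ROI are
#' concatenated and the summary statistic applied to the pooled vector.
#'
#' @param segment_values_by_box List of numeric vectors, one per box.
#' @param statistic One of [summary_statistics()].
#' @return Scalar ROI measure; `NA` if all boxes are empty.
#' @export
pool_roi_measure <- function(segment_values_by_box, statistic = "q99") {
  if (!is.list(segment_values_by_box)) {
    segment_values_by_box <- list(segment_values_by_box)
  }
  pooled <- unlist(segment_values_by_box, use.names = FALSE)
  box_summary(pooled, statistic = statistic)
}
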