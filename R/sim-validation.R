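#' Simulate expert-rated sampling boxes for statistic selection
#'
#' Generates per-box segment-average vectors whose link to the expert rating
#' lives only in the extreme activation tail, emulating focal inclusions on
#' a background of slide-level staining variation: every segment carries a
#' box-specific baseline (between-slide variation) plus noise, a small
#' fraction of segments ("signal" segments, the inclusions) are elevated in
#' proportion to the box's true burden rating, and a couple of segments per
#' box are saturated staining artifacts unrelated to burden. Under this
#' construction central statistics (mean, median, low quantiles) mostly see
#' the baseline, the maximum is corrupted by artifacts, and a high quantile
#' such as the 99th tracks the burden.
#'
#' @param n_per_rating Number of boxes per rating category.
#' @param ratings Rating categories to generate (default `0:3`).
#' @param n_segments Segments per box.
#' @param signal_fraction Fraction of segments elevated by burden.
#' @param signal_base,signal_step Elevation of signal segments:
#'   `signal_base + signal_step * rating` above baseline.
#' @param n_artifacts Saturated artifact segments per box.
#' @param baseline_mean,baseline_sd Box-level baseline distribution.
#' @param noise_sd Within-box segment noise.
#' @param seed Integer seed.
#' @return List with `segment_values` (list of numeric vectors, one per
#'   box), `ratings` (numeric vector) and `box_id`.
#' @export
generate_validation_boxes <- function(n_per_rating = 12L,
                                      ratings = 0:3,
                                      n_segments = 400L,
                                      signal_fraction = 0.03,
                                      signal_base = 0.15,
                                      signal_step = 0.18,
                                      n_artifacts = 2L,
                                      baseline_mean = 0.08,
                                      baseline_sd = 0.04,
                                      noise_sd = 0.02,
                                      seed = 1L) {
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

  rating_vec <- rep(ratings, each = n_per_rating)
  n_signal <- max(1L, round(signal_fraction * n_segments))
  segment_values <- lapply(seq_along(rating_vec), function(i) {
    r <- rating_vec[i]
    baseline <- max(0.01, stats::rnorm(1L, baseline_mean, baseline_sd))
    vals <- baseline + stats::rnorm(n_segments, 0, noise_sd)
    if (r > 0) {
      idx <- sample.int(n_segments, n_signal)
      vals[idx] <- vals[idx] + signal_base + signal_step * r +
        stats::rnorm(n_signal, 0, noise_sd)
    }
    if (n_artifacts > 0L) {
      aidx <- sample.int(n_segments, n_artifacts)
      vals[aidx] <- 1
    }
    pmin(1, pmax(0, vals))
  })
  list(segment_values = segment_values,
       ratings = rating_vec,
       box_id = sprintf("box%03d", seq_along(rating_vec)))
}
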