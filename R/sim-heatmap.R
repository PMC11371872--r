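#' Severity model for synthetic pathology heatmaps and ratings
#'
#' Bundles the parameters that link a latent, non-negative pathology severity
#' to (i) the density of inclusion "blobs" on a simulated attention heatmap
#' and (ii) the ordinal expert rating scale (absent 0, rare 0.5, mild 1,
#' moderate 2, severe 3).
#'
#' @param blob_rate Function mapping severity to expected blobs per mm^2.
#'   Must be non-decreasing; the default is linear, `2 * severity`.
#' @param blob_amplitude Peak activation of a single blob, in `[0, 1]`.
#' @param blob_sigma_um Spatial spread (Gaussian sigma) of a blob, in microns.
#' @param noise_sd Standard deviation of additive background activation noise.
#' @param rating_thresholds Four strictly increasing severity cutpoints that
#'   map latent severity to the ordinal ratings `{0, 0.5, 1, 2, 3}`.
#' @return An object of class `severity_model`.
#' @seealso [generate_heatmap()], [generate_ordinal_rating()]
#' @export
severity_model <- function(blob_rate = function(severity) 2 * severity,
                           blob_amplitude = 0.9,
                           blob_sigma_um = 25,
                           noise_sd = 0.02,
                           rating_thresholds = c(0.5, 1, 2, 3.5)) {
  stopifnot(is.function(blob_rate))
  if (!is.numeric(rating_thresholds) || length(rating_thresholds) != 4L ||
      any(diff(rating_thresholds) <= 0)) {
    stop("rating_thresholds must be 4 strictly increasing cutpoints")
  }
  if (blob_amplitude < 0 || blob_amplitude > 1) {
    stop("blob_amplitude must lie in [0, 1]")
  }
  if (blob_sigma_um <= 0) stop("blob_sigma_um must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(blob_rate = blob_rate,
         blob_amplitude = blob_amplitude,
         blob_sigma_um = blob_sigma_um,
         noise_sd = noise_sd,
         rating_thresholds = rating_thresholds),
    class = "severity_model"
  )
}

#' Simulate an attention heatmap for one sampling box
#'
#' Places a Poisson number of Gaussian-profile inclusion blobs uniformly over
#' the box, with expected count `blob_rate(severity) * area_mm2`. Blob
#' profiles are truncated at 3 sigma and overlapping blobs combine by
#' maximum, so activations stay in `[0, 1]`. Gaussian background noise is
#' added and the result clipped to `[0, 1]`.
#'
#' @param severity Non-negative latent severity driving blob density.
#' @param box_shape_px Integer pair `(rows, cols)` of the activation grid.
#' @param pixel_size_um Pixel edge length in microns.
#' @param model A [severity_model()].
#' @param seed Integer seed; the map is reproducible given the seed.
#' @return A [heatmap_grid()] with the simulated activations.
#' @export
generate_heatmap <- function(severity, box_shape_px, pixel_size_um,
                             model = severity_model(), seed = 1L) {
  if (!is.finite(severity) || severity < 0) {
    stop("severity must be a finite non-negative number")
  }
  stopifnot(length(box_shape_px) == 2L, all(box_shape_px >= 1),
            pixel_size_um > 0)
  nr <- as.integer(box_shape_px[1L])
  nc <- as.integer(box_shape_px[2L])

  # local RNG scope: restore caller's stream on exit
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)

  area_mm2 <- nr * nc * (pixel_size_um / 1000)^2
  lambda <- model$blob_rate(severity) * area_mm2
  if (!is.finite(lambda) || lambda < 0) stop("blob rate must be finite and non-negative")
  n_blob <- stats::rpois(1L, lambda)

  grid <- matrix(0, nr, nc)
  if (n_blob > 0L) {
    cy <- stats::runif(n_blob, 0.5, nr + 0.5)
    cx <- stats::runif(n_blob, 0.5, nc + 0.5)
    sig_px <- model$blob_sigma_um / pixel_size_um
    r3 <- ceiling(3 * sig_px)
    for (b in seq_len(n_blob)) {
      rows <- max(1L, floor(cy[b] - r3)):min(nr, ceiling(cy[b] + r3))
      cols <- max(1L, floor(cx[b] - r3)):min(nc, ceiling(cx[b] + r3))
      d2 <- outer((rows - cy[b])^2, (cols - cx[b])^2, "+")
      prof <- model$blob_amplitude * exp(-d2 / (2 * sig_px^2))
      prof[d2 > (3 * sig_px)^2] <- 0
      grid[rows, cols] <- pmax(grid[rows, cols], prof)
    }
  }
  if (model$noise_sd > 0) {
    grid <- grid + matrix(stats::rnorm(nr * nc, 0, model$noise_sd), nr, nc)
  }
  grid[grid < 0] <- 0
  grid[grid > 1] <- 1
  heatmap_grid(grid, pixel_size_um = pixel_size_um)
}

#' Map a latent severity to an ordinal expert rating
#'
#' Applies the model's four increasing cutpoints, returning one of
#' `{0, 0.5, 1, 2, 3}` (absent, rare, mild, moderate, severe). The mapping is
#' non-decreasing in severity by construction.
#'
#' @param severity Numeric vector of latent severities.
#' @param model A [severity_model()].
#' @return Numeric vector of ratings on the ordinal scale.
#' @export
generate_ordinal_rating <- function(severity, model = severity_model()) {
  th <- model$rating_thresholds
  levels <- c(0, 0.5, 1, 2, 3)
  idx <- findInterval(severity, th) + 1L
  out <- levels[idx]
  out[is.na(severity)] <- NA_real_
  out
}
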