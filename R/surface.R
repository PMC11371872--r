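#' Simulate a surface thickness dataset with a planted deficit cluster
#'
#' Generates per-subject, per-vertex cortical thickness on a template mesh:
#' `thickness = baseline - effect * pathology` inside a planted
#' edge-connected cluster, plus independent Gaussian vertex noise. With the
#' default unit noise and z-scored pathology, `effect` is the standardized
#' per-vertex effect size inside the cluster.
#'
#' @param n_subjects Number of subjects.
#' @param mesh Template `surface_mesh` (default 64 x 64 planar grid).
#' @param pathology Numeric vector, one pathology value per subject;
#'   centred and scaled internally so `effect` is standardized.
#' @param cluster_vertices Integer vertex ids of the planted cluster; must
#'   be edge-connected. Default: a disk of radius `radius` around the mesh
#'   centroid. Use `integer(0)` for a null dataset.
#' @param effect Thickness deficit per unit (z-scored) pathology inside the
#'   cluster, in noise-sd units.
#' @param noise_sd Per-vertex thickness noise sd (mm).
#' @param baseline Baseline thickness (mm).
#' @param radius Radius (mm) of the default planted disk.
#' @param seed Integer seed.
#' @return An object of class `surface_dataset`: list with `mesh`,
#'   `thickness` (subjects x vertices), `pathology`, `planted` (vertex ids),
#'   `effect`.
#' @export
generate_surface_dataset <- function(n_subjects,
                                     mesh = planar_grid_mesh(),
                                     pathology = NULL,
                                     cluster_vertices = NULL,
                                     effect = 0.8,
                                     noise_sd = 1,
                                     baseline = 2.5,
                                     radius = 8,
                                     seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"), n_subjects >= 1)
  nv <- nrow(mesh$vertices)
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

  if (is.null(pathology)) pathology <- stats::rnorm(n_subjects)
  if (length(pathology) != n_subjects) {
    stop("pathology must have one value per subject")
  }
  if (is.null(cluster_vertices)) {
    ctr <- colMeans(mesh$vertices)
    d <- sqrt(rowSums(sweep(mesh$vertices, 2L, ctr)^2))
    cluster_vertices <- which(d <= radius)
  }
  cluster_vertices <- as.integer(cluster_vertices)
  if (length(cluster_vertices)) {
    nbrs <- mesh_adjacency(mesh)
    comps <- vertex_components(cluster_vertices, nbrs)
    if (length(comps) != 1L) {
      stop("planted cluster is not edge-connected (",
           length(comps), " components)")
    }
  }
  z <- if (stats::sd(pathology) > 0) {
    (pathology - mean(pathology)) / stats::sd(pathology)
  } else pathology * 0
  thickness <- baseline +
    matrix(stats::rnorm(n_subjects * nv, 0, noise_sd), n_subjects, nv)
  if (length(cluster_vertices) && effect != 0) {
    thickness[, cluster_vertices] <- thickness[, cluster_vertices] -
      outer(z, rep(effect, length(cluster_vertices)))
  }
  structure(
    list(mesh = mesh, thickness = thickness, pathology = pathology,
         planted = cluster_vertices, effect = effect),
    class = "surface_dataset"
  )
}

# Vectorised per-vertex OLS t-statistics for one contrast column.
# X: n x p design (full column rank), Y: n x V response matrix.
pointwise_t <- function(X, Y, contrast_idx) {
  n <- nrow(X)
  p <- ncol(X)
  XtX <- crossprod(X)
  XtXi <- tryCatch(solve(XtX), error = function(e) {
    stop("rank-deficient design matrix")
  })
  H <- XtXi %*% t(X)
  B <- H %*% Y
  rss <- pmax(0, colSums(Y * Y) - colSums((XtX %*% B) * B))
  df <- n - p
  se <- sqrt(rss / df * XtXi[contrast_idx, contrast_idx])
  tval <- B[contrast_idx, ] / se
  flagged <- !is.finite(tval)
  tval[flagged] <- 0
  attr(tval, "zero_variance") <- which(flagged)
  tval
}

#' Pointwise GLM t-map over a surface
#'
#' Fits the shared linear model at every vertex and returns the t-statistic
#' map for the contrast of interest. Vertices with zero residual variance
#' get `t = 0` and are flagged in the `"zero_variance"` attribute.
#'
#' @param thickness Subjects x vertices matrix.
#' @param design Design matrix or data frame (an intercept column is added
#'   if absent).
#' @param contrast Name or index of the design column to test.
#' @return Numeric t vector over vertices, attribute `"df"` carries the
#'   residual degrees of freedom.
#' @export
fit_pointwise <- function(thickness, design, contrast) {
  X <- build_design(design, nrow(thickness))
  cidx <- contrast_index(X, contrast)
  if (nrow(X) < ncol(X) + 2L) stop("need at least p + 2 subjects")
  tval <- pointwise_t(X, thickness, cidx)
  attr(tval, "df") <- nrow(X) - ncol(X)
  tval
}

build_design <- function(design, n) {
  X <- as.matrix(design)
  if (nrow(X) != n) stop("design rows must match subjects")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!any(apply(X, 2L, function(c_) all(c_ == c_[1L] & c_[1L] != 0)))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  X
}

contrast_index <- function(X, contrast) {
  if (is.character(contrast)) {
    cidx <- match(contrast, colnames(X))
    if (is.na(cidx)) stop("contrast column '", contrast, "' not in design")
    cidx
  } else as.integer(contrast)
}

#' Extract suprathreshold clusters from a t-map
#'
#' Thresholds the (signed) t-map and finds connected components over the
#' mesh edge graph. For a negative contrast direction, clustering is on
#' `-t > threshold`. Cluster surface area uses fractional triangle
#' attribution by default -- each suprathreshold vertex contributes one
#' third of each incident triangle's area -- so the total suprathreshold
#' area always equals the sum of cluster areas; `area_rule = "full"` counts
#' only triangles with all three vertices suprathreshold.
#'
#' @param tmap Numeric t vector over vertices.
#' @param mesh A `surface_mesh`.
#' @param threshold Positive cluster-forming threshold (default 2.0).
#' @param direction `"negative"` (default) or `"positive"` effect direction.
#' @param area_rule `"fractional"` (default) or `"full"`.
#' @return List of clusters, each a list with `vertex_ids`, `area_mm2`,
#'   `peak_t`; sorted by decreasing area. Empty list if nothing survives.
#' @export
extract_clusters <- function(tmap, mesh, threshold = 2.0,
                             direction = c("negative", "positive"),
                             area_rule = c("fractional", "full")) {
  direction <- match.arg(direction)
  area_rule <- match.arg(area_rule)
  if (threshold <= 0) stop("threshold must be positive")
  signed <- if (direction == "negative") -tmap else tmap
  supra <- which(signed > threshold)
  if (length(supra) == 0L) return(list())
  nbrs <- mesh_adjacency(mesh)
  comps <- vertex_components(supra, nbrs)
  va <- vertex_areas(mesh)
  ta <- triangle_areas(mesh)
  out <- lapply(comps, function(ids) {
    area <- if (area_rule == "fractional") {
      sum(va[ids])
    } else {
      inset <- logical(length(tmap))
      inset[ids] <- TRUE
      sum(ta[inset[mesh$triangles[, 1L]] &
             inset[mesh$triangles[, 2L]] &
             inset[mesh$triangles[, 3L]]])
    }
    peak <- if (direction == "negative") min(tmap[ids]) else max(tmap[ids])
    list(vertex_ids = ids, area_mm2 = area, peak_t = peak)
  })
  out[order(-vapply(out, `[[`, numeric(1), "area_mm2"))]
}

#' Freedman-Lane permutation null of maximum cluster area
#'
#' Builds the null distribution of the maximum suprathreshold cluster
#' surface area under the two-step Freedman-Lane procedure: the
#' nuisance-only model is fitted once, its residual rows are permuted at the
#' subject level (one shared permutation for all vertices), pseudo-data are
#' reconstructed as nuisance fit plus permuted residuals, the full model is
#' refitted, and the maximum cluster area at the threshold is recorded
#' (0 when nothing survives). With an intercept-only nuisance model this
#' reduces exactly to permuting thickness rows.
#'
#' @inheritParams fit_pointwise
#' @param mesh A `surface_mesh`.
#' @param n_perm Number of permutations (>= 1).
#' @param threshold Cluster-forming threshold on the t-map.
#' @param direction Effect direction, as in [extract_clusters()].
#' @param area_rule Area attribution rule, as in [extract_clusters()].
#' @param seed Integer seed for the permutation stream.
#' @return Numeric vector of length `n_perm` of maximum cluster areas.
#' @export
freedman_lane_null <- function(thickness, design, contrast, mesh,
                               n_perm = 1000L, threshold = 2.0,
                               direction = c("negative", "positive"),
                               area_rule = c("fractional", "full"),
                               seed = 1L) {
  direction <- match.arg(direction)
  area_rule <- match.arg(area_rule)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  X <- build_design(design, nrow(thickness))
  cidx <- contrast_index(X, contrast)
  n <- nrow(X)

  Z <- X[, -cidx, drop = FALSE]
  ZtZ <- crossprod(Z)
  Gz <- solve(ZtZ, crossprod(Z, thickness))   # q x V nuisance coefficients
  E <- thickness - Z %*% Gz                    # reduced-model residuals

  nbrs <- mesh_adjacency(mesh)
  va <- vertex_areas(mesh)
  ta <- triangle_areas(mesh)
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  H <- XtXi %*% t(X)
  cvar <- XtXi[cidx, cidx]
  df <- n - ncol(X)

  # Per-permutation quantities never touch an n x V matrix: with pseudo-data
  # Y* = Z Gz + P E, the full-model coefficients are B = H Z Gz + H[, s] E
  # (s the permuted column selector) and the total sum of squares splits as
  # ||Y*||^2 = ||Z Gz||^2 + 2 <Z Gz, P E> + ||E||^2, whose pieces reduce to
  # q x V elementwise products.
  B0 <- (H %*% Z) %*% Gz                       # p x V, fitted-part coefficients
  ss_f <- colSums(Gz * (ZtZ %*% Gz))           # ||Z Gz||^2 per vertex
  ss_e <- colSums(E * E)                       # permutation-invariant

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

  max_area <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    s <- sample.int(n)
    B <- B0 + H[, s, drop = FALSE] %*% E
    cross <- colSums(Gz * crossprod(Z[s, , drop = FALSE], E))
    rss <- pmax(0, ss_f + 2 * cross + ss_e - colSums((XtX %*% B) * B))
    se <- sqrt(rss / df * cvar)
    tval <- B[cidx, ] / se
    tval[!is.finite(tval)] <- 0
    signed <- if (direction == "negative") -tval else tval
    supra <- which(signed > threshold)
    if (length(supra) == 0L) {
      max_area[b] <- 0
      next
    }
    comps <- vertex_components(supra, nbrs, sort = FALSE)
    areas <- vapply(comps, function(ids) {
      if (area_rule == "fractional") {
        sum(va[ids])
      } else {
        inset <- logical(length(va))
        inset[ids] <- TRUE
        sum(ta[inset[mesh$triangles[, 1L]] &
               inset[mesh$triangles[, 2L]] &
               inset[mesh$triangles[, 3L]]])
      }
    }, numeric(1))
    max_area[b] <- max(areas)
  }
  max_area
}

#' Attach permutation-corrected p-values to observed clusters
#'
#' For each observed cluster, the one-sided corrected p-value counts the
#' permutations whose maximum cluster area exceeds the cluster's area. On
#' meshes with continuous-valued areas (real cortical templates) ties never
#' occur and all tie rules coincide with that literal definition. On a
#' regular grid template, however, cluster areas concentrate on a few
#' discrete values (an interior singleton always has area exactly one
#' spacing unit), and the tie rule matters: counting only strictly larger
#' maxima (`"ignore"`) discards the tied mass and is anti-conservative,
#' counting ties fully (`"count"`) is over-conservative, and the mid-p
#' convention (`"midp"`, the default) counts ties half, which calibrates
#' the test at its nominal level under discreteness. `smoothing = TRUE`
#' additionally applies the add-one rule `(b + 1) / (n_perm + 1)` so p can
#' never be exactly zero.
#'
#' @param observed_clusters List of clusters from [extract_clusters()].
#' @param null_max_areas Numeric vector from [freedman_lane_null()].
#' @param ties Tie rule for null maxima equal to the observed area:
#'   `"midp"` (default) counts them half, `"count"` fully, `"ignore"` not
#'   at all.
#' @param smoothing Apply add-one smoothing (default `FALSE`).
#' @return The cluster list with a `p_corrected` element added to each.
#' @export
corrected_p <- function(observed_clusters, null_max_areas,
                        ties = c("midp", "count", "ignore"),
                        smoothing = FALSE) {
  ties <- match.arg(ties)
  if (length(null_max_areas) == 0L) stop("null distribution is empty")
  lapply(observed_clusters, function(cl) {
    s <- sum(null_max_areas > cl$area_mm2 + 1e-12)
    t <- sum(abs(null_max_areas - cl$area_mm2) <= 1e-12)
    b <- switch(ties, midp = s + t / 2, count = s + t, ignore = s)
    cl$p_corrected <- if (smoothing) {
      (b + 1) / (length(null_max_areas) + 1)
    } else {
      b / length(null_max_areas)
    }
    cl
  })
}

#' Surface GLM with cluster-level permutation correction
#'
#' One-stop wrapper: fits the pointwise GLM, extracts suprathreshold
#' clusters, builds the Freedman-Lane null of maximum cluster area, and
#' attaches corrected p-values.
#'
#' @inheritParams freedman_lane_null
#' @param smoothing Passed to [corrected_p()].
#' @return An object of class `surface_glm` with elements `tmap`,
#'   `clusters`, `null_max_areas`, `threshold`, `direction`, `df`, `n`.
#' @export
surface_glm <- function(thickness, design, contrast, mesh,
                        n_perm = 1000L, threshold = 2.0,
                        direction = c("negative", "positive"),
                        area_rule = c("fractional", "full"),
                        ties = c("midp", "count", "ignore"),
                        smoothing = FALSE, seed = 1L) {
  direction <- match.arg(direction)
  area_rule <- match.arg(area_rule)
  ties <- match.arg(ties)
  tmap <- fit_pointwise(thickness, design, contrast)
  clusters <- extract_clusters(tmap, mesh, threshold = threshold,
                               direction = direction, area_rule = area_rule)
  null_max <- freedman_lane_null(thickness, design, contrast, mesh,
                                 n_perm = n_perm, threshold = threshold,
                                 direction = direction,
                                 area_rule = area_rule, seed = seed)
  clusters <- corrected_p(clusters, null_max, ties = ties,
                          smoothing = smoothing)
  structure(
    list(tmap = as.numeric(tmap), clusters = clusters,
         null_max_areas = null_max, threshold = threshold,
         direction = direction, df = attr(tmap, "df"),
         n = nrow(thickness), mesh = mesh),
    class = "surface_glm"
  )
}

#' @export
print.surface_glm <- function(x, ...) {
  cat(sprintf("Surface GLM: %d subjects, %d vertices, t threshold %.1f (%s)\n",
              x$n, length(x$tmap), x$threshold, x$direction))
  cat(sprintf("  %d cluster(s); %d permutations\n",
              length(x$clusters), length(x$null_max_areas)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d vertices, area %.1f mm^2, peak t %.2f, corrected p %.4g\n",
                i, length(cl$vertex_ids), cl$area_mm2, cl$peak_t,
                cl$p_corrected))
  }
  invisible(x)
}

#' @export
summary.surface_glm <- function(object, ...) {
  if (length(object$clusters) == 0L) {
    return(data.frame(cluster = integer(0), n_vertices = integer(0),
                      area_mm2 = numeric(0), peak_t = numeric(0),
                      p_corrected = numeric(0)))
  }
  data.frame(
    cluster = seq_along(object$clusters),
    n_vertices = vapply(object$clusters, function(c_) length(c_$vertex_ids),
                        integer(1)),
    area_mm2 = vapply(object$clusters, `[[`, numeric(1), "area_mm2"),
    peak_t = vapply(object$clusters, `[[`, numeric(1), "peak_t"),
    p_corrected = vapply(object$clusters, `[[`, numeric(1), "p_corrected"))
}

#' @export
plot.surface_glm <- function(x, ...) {
  gd <- attr(x$mesh, "grid_dim")
  if (is.null(gd)) {
    graphics::hist(x$null_max_areas, main = "Null max cluster area",
                   xlab = "area (mm^2)", ...)
    return(invisible(x))
  }
  tm <- matrix(x$tmap, gd[1L], gd[2L])
  graphics::image(tm, main = "Pointwise t-map",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}
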