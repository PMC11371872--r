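test_that("mesh construction validates topology", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- surface_mesh(v, rbind(c(1, 2, 3)))
  expect_s3_class(m, "surface_mesh")
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  # an edge shared by three triangles is non-manifold
  v4 <- rbind(v, c(1, 1, 0), c(-1, -1, 1))
  bad <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  expect_error(surface_mesh(v4, bad), "manifold")
})

test_that("grid mesh has the expected size and area", {
  m <- planar_grid_mesh(8, 8, spacing = 0.5)
  expect_equal(nrow(m$vertices), 81L)
  expect_equal(nrow(m$triangles), 128L)
  expect_equal(sum(triangle_areas(m)), 16, tolerance = 1e-12)  # (8*0.5)^2
})

test_that("surface dataset is reproducible, null-centred, and checks the cluster", {
  mesh <- planar_grid_mesh(12, 12)
  d1 <- generate_surface_dataset(20, mesh = mesh, seed = 5)
  d2 <- generate_surface_dataset(20, mesh = mesh, seed = 5)
  expect_identical(d1$thickness, d2$thickness)
  # effect = 0: vertex-wise correlations with pathology centre on zero
  d0 <- generate_surface_dataset(40, mesh = mesh, effect = 0, seed = 6)
  cors <- apply(d0$thickness, 2, cor, y = d0$pathology)
  expect_lt(abs(mean(cors)), 0.05)
  # a disconnected planted set is rejected
  expect_error(
    generate_surface_dataset(10, mesh = mesh,
                             cluster_vertices = c(1L, 169L), seed = 7),
    "not edge-connected")
})

test_that("pointwise t-map matches a per-vertex lm loop", {
  mesh <- planar_grid_mesh(7, 6)  # 56 vertices
  set.seed(8)
  n <- 25
  path <- rnorm(n)
  age <- rnorm(n)
  thick <- matrix(rnorm(n * 56), n, 56)
  design <- cbind(pathology = path, age = age)
  tmap <- fit_pointwise(thick, design, "pathology")
  loop <- vapply(seq_len(56), function(v) {
    summary(lm(thick[, v] ~ path + age))$coefficients["path", "t value"]
  }, numeric(1))
  expect_equal(as.numeric(tmap), loop, tolerance = 1e-10)
  expect_equal(attr(tmap, "df"), n - 3L)
})

test_that("single-vertex t equals the regional model t on the same data", {
  d <- generate_cohort(60, seed = 9)
  fit <- fit_region_model(d, "ERC", "tangles_q")
  z <- function(v) (v - mean(v)) / sd(v)
  thick <- matrix(z(d$erc_thk), ncol = 1)
  design <- cbind(tangles = z(d$tangles_q), age = z(d$age), sex = d$sex,
                  fs = d$field_strength, ami = z(d$antemortem_interval))
  tmap <- fit_pointwise(thick, design, "tangles")
  expect_equal(as.numeric(tmap), unname(fit$t_statistics["tangles_q"]),
               tolerance = 1e-10)
})

test_that("null t-maps have t-distribution moments", {
  mesh <- planar_grid_mesh(40, 40)
  set.seed(10)
  n <- 30
  thick <- matrix(rnorm(n * 1681), n, 1681)
  design <- cbind(pathology = rnorm(n))
  tmap <- as.numeric(fit_pointwise(thick, design, "pathology"))
  df <- n - 2
  expect_lt(abs(mean(tmap)), 0.05)
  expect_lt(abs(var(tmap) - df / (df - 2)), 0.15)
})

test_that("zero-variance vertices get t = 0 with a flag", {
  set.seed(11)
  thick <- matrix(rnorm(60), 20, 3)
  thick[, 2] <- 1.7  # constant column
  tmap <- fit_pointwise(thick, cbind(x = rnorm(20)), "x")
  expect_equal(as.numeric(tmap)[2], 0)
  expect_true(2L %in% attr(tmap, "zero_variance"))
})

test_that("cluster extraction matches geometry and the flood-fill oracle", {
  # no suprathreshold vertex -> empty
  mesh <- planar_grid_mesh(5, 5)
  expect_equal(extract_clusters(rep(0, 36), mesh), list())

  # one isolated unit right triangle, all vertices suprathreshold: area 1/2
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3)))
  cl <- extract_clusters(c(-3, -3, -3), tri, threshold = 2,
                         direction = "negative")
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$area_mm2, 0.5, tolerance = 1e-12)
  expect_equal(cl[[1]]$vertex_ids, 1:3)

  # two planted disjoint patches: memberships match the oracle components
  mesh2 <- planar_grid_mesh(15, 15)
  tmap <- rep(0, 256)
  patch1 <- c(1L, 2L, 17L)           # corner patch
  patch2 <- c(200L, 201L, 216L, 217L)
  tmap[c(patch1, patch2)] <- -5
  cls <- extract_clusters(tmap, mesh2, threshold = 2, direction = "negative")
  expect_length(cls, 2L)
  got <- lapply(cls, `[[`, "vertex_ids")
  oracle <- oracle_mesh_components(sort(c(patch1, patch2)), mesh2)
  expect_setequal(lapply(got, sort), lapply(oracle, sort))
  # conservation: cluster areas sum to the total suprathreshold area
  va_total <- sum(vapply(cls, `[[`, numeric(1), "area_mm2"))
  supra <- which(-tmap > 2)
  all_one <- extract_clusters(tmap, mesh2, threshold = 2,
                              direction = "negative")
  expect_equal(va_total,
               sum(vapply(all_one, `[[`, numeric(1), "area_mm2")))
  expect_gt(va_total, 0)
})

test_that("cluster areas transform correctly under rigid motion and scaling", {
  mesh <- planar_grid_mesh(10, 10)
  set.seed(12)
  tmap <- -abs(rnorm(121, 0, 2))
  base <- extract_clusters(tmap, mesh, threshold = 2, direction = "negative")
  areas <- vapply(base, `[[`, numeric(1), "area_mm2")

  # translation + rotation about z
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  v2 <- mesh$vertices %*% t(R)
  v2 <- sweep(v2, 2, c(5, -3, 2), "+")
  mesh_rt <- surface_mesh(v2, mesh$triangles)
  rt <- extract_clusters(tmap, mesh_rt, threshold = 2,
                         direction = "negative")
  expect_equal(vapply(rt, `[[`, numeric(1), "area_mm2"), areas,
               tolerance = 1e-10)

  # scaling by s multiplies areas by s^2
  mesh_s <- surface_mesh(mesh$vertices * 3, mesh$triangles)
  sc <- extract_clusters(tmap, mesh_s, threshold = 2, direction = "negative")
  expect_equal(vapply(sc, `[[`, numeric(1), "area_mm2"), areas * 9,
               tolerance = 1e-10)
})

test_that("intercept-only Freedman-Lane equals naive row permutation", {
  mesh <- planar_grid_mesh(9, 9)
  set.seed(13)
  n <- 18
  ds <- generate_surface_dataset(n, mesh = mesh, effect = 1, radius = 2,
                                 seed = 14)
  design <- cbind(pathology = ds$pathology)
  nm <- freedman_lane_null(ds$thickness, design, "pathology", mesh,
                           n_perm = 40, threshold = 2, seed = 15)
  # naive oracle: permute thickness rows with the same seed stream
  set.seed(15)
  naive <- vapply(seq_len(40), function(b) {
    s <- sample.int(n)
    yb <- ds$thickness[order(s), , drop = FALSE]
    tm <- fit_pointwise(yb, design, "pathology")
    cl <- extract_clusters(tm, mesh, threshold = 2, direction = "negative")
    if (length(cl)) cl[[1]]$area_mm2 else 0
  }, numeric(1))
  expect_equal(nm, naive, tolerance = 1e-9)
})

test_that("null data give zero max areas at a high threshold", {
  mesh <- planar_grid_mesh(8, 8)
  ds <- generate_surface_dataset(15, mesh = mesh, effect = 0, seed = 16)
  nm <- freedman_lane_null(ds$thickness, cbind(p = ds$pathology), "p", mesh,
                           n_perm = 30, threshold = 8, seed = 17)
  expect_true(all(nm == 0))
})

test_that("corrected p follows the counting rule, with and without ties", {
  clusters <- list(list(vertex_ids = 1:3, area_mm2 = 10, peak_t = -4),
                   list(vertex_ids = 5:6, area_mm2 = 0.5, peak_t = -2.5))
  null_max <- c(0, 1, 2, 5, 12)   # no ties with the observed areas
  out <- corrected_p(clusters, null_max)
  expect_equal(out[[1]]$p_corrected, 1 / 5)   # only 12 exceeds 10
  expect_equal(out[[2]]$p_corrected, 4 / 5)
  # tie-free data: both tie rules agree
  strict <- corrected_p(clusters, null_max, ties = "ignore")
  expect_equal(vapply(out, `[[`, numeric(1), "p_corrected"),
               vapply(strict, `[[`, numeric(1), "p_corrected"))
  sm <- corrected_p(clusters, null_max, smoothing = TRUE)
  expect_equal(sm[[1]]$p_corrected, 2 / 6)
  # larger than every null max -> 0; smaller than all -> 1
  big <- corrected_p(list(list(area_mm2 = 99)), null_max)
  expect_equal(big[[1]]$p_corrected, 0)
  small <- corrected_p(list(list(area_mm2 = -1)), null_max)
  expect_equal(small[[1]]$p_corrected, 1)
  # tied null maxima: half under the mid-p default, fully under "count",
  # not at all under "ignore"
  tied <- list(list(area_mm2 = 2))  # null maxima {5, 12} exceed, {2} ties
  expect_equal(corrected_p(tied, null_max)[[1]]$p_corrected, 2.5 / 5)
  expect_equal(corrected_p(tied, null_max,
                           ties = "count")[[1]]$p_corrected, 3 / 5)
  expect_equal(corrected_p(tied, null_max,
                           ties = "ignore")[[1]]$p_corrected, 2 / 5)
})

test_that("a strong planted effect dominates the permutation null", {
  mesh <- planar_grid_mesh(20, 20)
  ds <- generate_surface_dataset(60, mesh = mesh, effect = 0.8, radius = 4,
                                 seed = 18)
  sg <- surface_glm(ds$thickness, cbind(p = ds$pathology), "p", mesh,
                    n_perm = 500, seed = 19)
  expect_gte(length(sg$clusters), 1L)
  top <- sg$clusters[[1]]
  expect_equal(top$p_corrected, 0)
  expect_gt(top$area_mm2, max(sg$null_max_areas))
  # detected cluster recovers the planted one
  jac <- length(intersect(top$vertex_ids, ds$planted)) /
    length(union(top$vertex_ids, ds$planted))
  expect_gt(jac, 0.5)
})

test_that("in the vanishing-noise limit the suprathreshold set is the planted set", {
  # outside the planted cluster thickness is exactly constant (zero residual
  # variance, flagged t = 0); inside it carries the pathology effect plus a
  # whisper of noise, driving |t| arbitrarily high
  mesh <- planar_grid_mesh(14, 14)
  nv <- nrow(mesh$vertices)
  set.seed(20)
  n <- 30
  path <- rnorm(n)
  z <- (path - mean(path)) / sd(path)
  ctr <- colMeans(mesh$vertices)
  planted <- which(sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2)) <= 3)
  thick <- matrix(2.5, n, nv)
  thick[, planted] <- 2.5 - 3 * outer(z, rep(1, length(planted))) +
    matrix(rnorm(n * length(planted), 0, 1e-6), n, length(planted))
  tmap <- fit_pointwise(thick, cbind(p = path), "p")
  cl <- extract_clusters(tmap, mesh, threshold = 2, direction = "negative")
  expect_length(cl, 1L)
  expect_equal(sort(cl[[1]]$vertex_ids), sort(planted))
})
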