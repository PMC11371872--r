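#' Triangulated surface mesh
#'
#' Container for a triangle mesh with validity checks: triangle indices in
#' range, no degenerate triangles (repeated vertices), and 2-manifold edge
#' incidence (every edge shared by at most two triangles).
#'
#' @param vertices Numeric matrix, one row per vertex, 3 columns (mm).
#' @param triangles Integer matrix, one row per triangle, 3 vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), nrow(triangles), 3L)
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("vertex coordinates must be finite")
  }
  nv <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > nv)) {
    stop("triangle indices out of range")
  }
  if (any(triangles[, 1L] == triangles[, 2L] |
          triangles[, 1L] == triangles[, 3L] |
          triangles[, 2L] == triangles[, 3L])) {
    stop("degenerate triangle (repeated vertex)")
  }
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
             triangles[, c(1L, 3L)])
  ekey <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  if (any(table(ekey) > 2L)) {
    stop("mesh is not 2-manifold: an edge is shared by more than 2 triangles")
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("Surface mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles, total area",
      format(sum(triangle_areas(x)), digits = 6), "mm^2\n")
  invisible(x)
}

#' Planar triangulated grid mesh
#'
#' Regular triangulated grid in the z = 0 plane with `nx * ny` cells (two
#' triangles per cell), the default template for simulation studies.
#'
#' @param nx,ny Number of grid cells along x and y (so `(nx+1)*(ny+1)`
#'   vertices and `2*nx*ny` triangles).
#' @param spacing Vertex spacing in mm.
#' @return A `surface_mesh` with attribute `"grid_dim" = c(nx + 1, ny + 1)`.
#' @export
planar_grid_mesh <- function(nx = 64L, ny = 64L, spacing = 1) {
  nvx <- nx + 1L
  nvy <- ny + 1L
  xs <- rep(seq_len(nvx) - 1L, times = nvy) * spacing
  ys <- rep(seq_len(nvy) - 1L, each = nvx) * spacing
  vertices <- cbind(xs, ys, 0)
  vid <- function(i, j) (j - 1L) * nvx + i
  tri <- matrix(0L, 2L * nx * ny, 3L)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      a <- vid(i, j); b <- vid(i + 1L, j)
      c_ <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
      tri[k + 1L, ] <- c(a, b, d)
      tri[k + 2L, ] <- c(a, d, c_)
      k <- k + 2L
    }
  }
  m <- surface_mesh(vertices, tri)
  attr(m, "grid_dim") <- c(nvx, nvy)
  m
}

#' Triangle areas of a mesh
#'
#' @param mesh A `surface_mesh`.
#' @return Numeric vector of per-triangle areas (mm^2), via the cross
#'   product.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  t1 <- mesh$triangles[, 1L]
  t2 <- mesh$triangles[, 2L]
  t3 <- mesh$triangles[, 3L]
  u <- v[t2, , drop = FALSE] - v[t1, , drop = FALSE]
  w <- v[t3, , drop = FALSE] - v[t1, , drop = FALSE]
  cx <- u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L]
  cy <- u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L]
  cz <- u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Per-vertex area: one third of each incident triangle's area, so vertex
# areas sum exactly to the total surface area.
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh) / 3
  va <- numeric(nrow(mesh$vertices))
  for (c_ in 1:3) {
    contrib <- tapply(ta, mesh$triangles[, c_], sum)
    idx <- as.integer(names(contrib))
    va[idx] <- va[idx] + as.numeric(contrib)
  }
  va
}

# Vertex adjacency over shared mesh edges, as a list of sorted integer
# neighbour vectors.
mesh_adjacency <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(1L, 3L)])
  e <- unique(rbind(e, e[, c(2L, 1L)]))
  nbrs <- split(e[, 2L], e[, 1L])
  out <- vector("list", nrow(mesh$vertices))
  out[as.integer(names(nbrs))] <- lapply(nbrs, function(v) sort(unique(v)))
  out[vapply(out, is.null, logical(1))] <- list(integer(0))
  out
}

# Connected components of a vertex subset under the mesh edge graph.
# Returns a list of integer vertex-id vectors (sorted unless sort = FALSE;
# the permutation loop skips sorting since only areas are needed).
vertex_components <- function(ids, nbrs, sort = TRUE) {
  if (length(ids) == 0L) return(list())
  member <- logical(length(nbrs))
  member[ids] <- TRUE
  seen <- logical(length(nbrs))
  comps <- list()
  queue <- integer(length(ids))
  for (s in ids) {
    if (seen[s]) next
    queue[1L] <- s
    seen[s] <- TRUE
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      for (nb in nbrs[[cur]]) {
        if (member[nb] && !seen[nb]) {
          tail <- tail + 1L
          queue[tail] <- nb
          seen[nb] <- TRUE
        }
      }
    }
    comp <- queue[seq_len(tail)]
    comps[[length(comps) + 1L]] <- if (sort) sort(comp) else comp
  }
  comps
}

#' Write a mesh (with optional per-vertex scalars) as ASCII PLY
#'
#' @param mesh A `surface_mesh`.
#' @param path Output file path.
#' @param scalars Optional named list of per-vertex numeric vectors written
#'   as extra float vertex properties.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  props <- c("x", "y", "z", names(scalars))
  header <- c(
    "ply", "format ascii 1.0", "comment mtlquant surface mesh",
    paste("element vertex", nv),
    paste("property float", props),
    paste("element face", nt),
    "property list uchar int vertex_indices",
    "end_header")
  vert <- mesh$vertices
  if (!is.null(scalars)) {
    for (s in scalars) stopifnot(length(s) == nv)
    vert <- cbind(vert, do.call(cbind, scalars))
  }
  vlines <- apply(vert, 1L, function(r) paste(format(r, trim = TRUE,
                                                     scientific = FALSE),
                                              collapse = " "))
  flines <- apply(mesh$triangles - 1L, 1L,
                  function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_mesh_ply()]
#'
#' @param path PLY file path.
#' @return A list with `mesh` (a `surface_mesh`) and `scalars` (named list
#'   of per-vertex properties beyond x/y/z, possibly empty).
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "ply") stop("not a PLY file")
  end <- match("end_header", lines)
  header <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", header, value = TRUE)))
  nt <- as.integer(sub("element face ", "",
                       grep("^element face ", header, value = TRUE)))
  pnames <- sub("^property float ", "",
                grep("^property float ", header, value = TRUE))
  vlines <- lines[(end + 1L):(end + nv)]
  vmat <- matrix(as.numeric(unlist(strsplit(vlines, " +"))),
                 nrow = nv, byrow = TRUE)
  colnames(vmat) <- pnames
  flines <- lines[(end + nv + 1L):(end + nv + nt)]
  fmat <- matrix(as.integer(unlist(strsplit(flines, " +"))),
                 nrow = nt, byrow = TRUE)
  if (any(fmat[, 1L] != 3L)) stop("only triangle faces supported")
  mesh <- surface_mesh(vmat[, c("x", "y", "z")], fmat[, 2:4] + 1L)
  extra <- setdiff(pnames, c("x", "y", "z"))
  scalars <- stats::setNames(
    lapply(extra, function(p) vmat[, p]), extra)
  list(mesh = mesh, scalars = scalars)
}
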