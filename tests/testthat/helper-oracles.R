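# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Quantile by explicit sort-and-interpolate at position p*(n-1).
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  pos <- p * (n - 1)
  lo <- floor(pos) + 1
  hi <- ceiling(pos) + 1
  frac <- pos - floor(pos)
  s[lo] * (1 - frac) + s[hi] * frac
}

# AUC by exhaustive pair counting (wins + half ties).
oracle_auc <- function(lower, upper) {
  wins <- 0
  ties <- 0
  for (a in lower) {
    for (b in upper) {
      if (b > a) wins <- wins + 1
      else if (b == a) ties <- ties + 1
    }
  }
  (wins + 0.5 * ties) / (length(lower) * length(upper))
}

# OLS coefficients by the normal equations.
oracle_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Pixel-set connectivity on an nr x nc grid (4-neighbour), by flood fill
# from the first pixel.
oracle_pixels_connected <- function(ids, nr, nc) {
  if (length(ids) <= 1L) return(TRUE)
  m <- logical(nr * nc)
  m[ids] <- TRUE
  seen <- logical(nr * nc)
  stack <- ids[1L]
  seen[ids[1L]] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    row <- ((cur - 1L) %% nr) + 1L
    col <- ((cur - 1L) %/% nr) + 1L
    nbs <- c(if (row > 1L) cur - 1L, if (row < nr) cur + 1L,
             if (col > 1L) cur - nr, if (col < nc) cur + nr)
    for (nb in nbs) {
      if (m[nb] && !seen[nb]) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  sum(seen) == length(ids)
}

# Connected components of a vertex subset of a mesh, straight from the
# triangle edge list (independent of the package's adjacency code).
oracle_mesh_components <- function(ids, mesh) {
  if (length(ids) == 0L) return(list())
  tr <- mesh$triangles
  edges <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(1, 3)])
  inset <- logical(nrow(mesh$vertices))
  inset[ids] <- TRUE
  keep <- inset[edges[, 1]] & inset[edges[, 2]]
  edges <- edges[keep, , drop = FALSE]
  comp <- stats::setNames(seq_along(ids), ids)  # union-find by label sweep
  labels <- rep(NA_integer_, nrow(mesh$vertices))
  labels[ids] <- seq_along(ids)
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      m <- min(labels[a], labels[b])
      if (labels[a] != m) { labels[a] <- m; changed <- TRUE }
      if (labels[b] != m) { labels[b] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  unname(split(ids, labels[ids]))
}

# Gaussian-form information criteria straight from the formulas.
oracle_ic <- function(rss, n, n_coef) {
  k <- n_coef + 1
  aic <- n * log(rss / n) + 2 * k
  c(aicc = aic + 2 * k * (k + 1) / (n - k - 1),
    bic = n * log(rss / n) + k * log(n))
}
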