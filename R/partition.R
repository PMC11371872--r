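#' Partition a sampling-box mask into contiguous, approximately equal segments
#'
#' Splits the mask of a sampling box into `k = max(1, round(area / target))`
#' edge-connected segments of approximately equal pixel count, where `target`
#' is the requested segment area (default 200 x 200 microns). Segments are the
#' spatial support over which heatmap activations are averaged before quantile
#' summarisation, so the invariants that matter are contiguity, disjointness,
#' coverage and approximate balance -- not the specific partitioning
#' heuristic. The implementation works on the 4-neighbour pixel adjacency
#' graph: within each connected component of the mask it repeatedly peels off
#' a balanced-size segment as a breadth-first-search prefix grown from a
#' geodesically peripheral pixel (a BFS prefix from a single source is always
#' connected), reallocating remaining segments among any fragments of the
#' remainder. Disconnected masks are partitioned per component.
#'
#' @param box A [sampling_box()].
#' @param target_area_um2 Target segment area in square microns
#'   (default `200 * 200`).
#' @param seed Accepted for interface stability; the algorithm is
#'   deterministic and ignores it.
#' @return An object of class `segment_partition`: a list with `segments`
#'   (list of integer pixel indices into the grid, column-major), `grid_dim`,
#'   `pixel_size_um` and `target_area_um2`.
#' @export
partition_roi <- function(box, target_area_um2 = 200 * 200, seed = NULL) {
  stopifnot(inherits(box, "sampling_box"))
  if (!is.numeric(target_area_um2) || target_area_um2 <= 0) {
    stop("target_area_um2 must be positive")
  }
  mask <- box$mask
  nr <- nrow(mask)
  nc <- ncol(mask)
  ids <- which(mask)
  if (length(ids) == 0L) stop("mask has zero area")

  px_area <- box$pixel_size_um^2
  target_px <- target_area_um2 / px_area
  k_total <- max(1L, as.integer(round(length(ids) / target_px)))

  comps <- grid_components(ids, nr, nc)
  alloc <- allocate_counts(lengths(comps), k_total)

  segments <- list()
  for (i in seq_along(comps)) {
    segments <- c(segments, split_component(comps[[i]], alloc[i], nr, nc))
  }
  segments <- rebalance_segments(segments, nr, nc)
  structure(
    list(segments = segments,
         grid_dim = c(nr, nc),
         pixel_size_um = box$pixel_size_um,
         target_area_um2 = target_area_um2),
    class = "segment_partition"
  )
}

#' @export
print.segment_partition <- function(x, ...) {
  sizes <- lengths(x$segments)
  cat("Segment partition:", length(sizes), "segments over a",
      paste(x$grid_dim, collapse = " x "), "grid\n")
  cat("  pixel size:", x$pixel_size_um, "um; target area:",
      x$target_area_um2, "um^2\n")
  cat("  segment pixel counts: min", min(sizes), "median",
      stats::median(sizes), "max", max(sizes), "\n")
  invisible(x)
}

# --- grid graph helpers (4-neighbour adjacency, column-major indices) ------

grid_neighbors <- function(id, nr, nc) {
  row <- ((id - 1L) %% nr) + 1L
  col <- ((id - 1L) %/% nr) + 1L
  nb <- integer(0)
  if (row > 1L) nb <- c(nb, id - 1L)
  if (row < nr) nb <- c(nb, id + 1L)
  if (col > 1L) nb <- c(nb, id - nr)
  if (col < nc) nb <- c(nb, id + nr)
  nb
}

# BFS over the pixels in `member` (logical over the full grid) from `start`;
# returns visited ids in visit order.
grid_bfs <- function(start, member, nr, nc) {
  n_max <- sum(member)
  order_out <- integer(n_max)
  queue <- integer(n_max)
  seen <- logical(length(member))
  queue[1L] <- start
  seen[start] <- TRUE
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    cur <- queue[head]
    order_out[head] <- cur
    head <- head + 1L
    for (nb in grid_neighbors(cur, nr, nc)) {
      if (member[nb] && !seen[nb]) {
        tail <- tail + 1L
        queue[tail] <- nb
        seen[nb] <- TRUE
      }
    }
  }
  order_out[seq_len(tail)]
}

# Connected components of a pixel set; list of integer id vectors,
# deterministic (seeded from the smallest unvisited id).
grid_components <- function(ids, nr, nc) {
  member <- logical(nr * nc)
  member[ids] <- TRUE
  remaining <- member
  comps <- list()
  for (id in ids) {
    if (remaining[id]) {
      comp <- grid_bfs(id, remaining, nr, nc)
      remaining[comp] <- FALSE
      comps[[length(comps) + 1L]] <- sort(comp)
    }
  }
  comps
}

# Allocate k segments among units of the given sizes: each unit gets at
# least 1, totals are exact, and counts are proportional to size
# (largest-remainder rounding). Requires k >= length(sizes).
allocate_counts <- function(sizes, k) {
  m <- length(sizes)
  if (k < m) stop("cannot allocate fewer segments than components")
  raw <- sizes / sum(sizes) * k
  alloc <- pmax(1L, floor(raw))
  # fix the total: add to (or remove from) units by largest remainder,
  # never dropping a unit below 1
  while (sum(alloc) < k) {
    resid <- raw - alloc
    i <- which.max(resid)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > k) {
    resid <- raw - alloc
    cand <- which(alloc > 1L)
    i <- cand[which.min(resid[cand])]
    alloc[i] <- alloc[i] - 1L
  }
  as.integer(alloc)
}

# Recursively split one connected pixel set into k connected segments of
# near-equal size by BFS-prefix peeling. Small fragments of the remainder
# (an artefact of the BFS frontier) are absorbed into an adjacent unit
# rather than consuming a segment allocation of their own, so balance is
# preserved through the recursion.
split_component <- function(ids, k, nr, nc) {
  if (k <= 1L || length(ids) <= 1L) return(list(sort(ids)))
  member <- logical(nr * nc)
  member[ids] <- TRUE

  # geodesically peripheral source: BFS from the smallest id, take the last
  # visited pixel, then order the component by BFS from there
  far <- grid_bfs(min(ids), member, nr, nc)
  src <- far[length(far)]
  ord <- grid_bfs(src, member, nr, nc)

  n1 <- max(1L, as.integer(round(length(ids) / k)))
  seg <- ord[seq_len(n1)]
  rest <- ord[(n1 + 1L):length(ord)]

  frags <- grid_components(rest, nr, nc)
  # absorb fragments smaller than half a segment; cap the kept count at k-1
  min_keep <- max(1L, as.integer(ceiling(0.5 * length(ids) / k)))
  res <- absorb_fragments(seg, frags, k - 1L, min_keep, nr, nc)
  seg <- res$seg
  frags <- res$frags
  if (length(frags) == 0L) return(list(sort(seg)))
  alloc <- allocate_counts(lengths(frags), k - 1L)
  out <- list(sort(seg))
  for (i in seq_along(frags)) {
    out <- c(out, split_component(frags[[i]], alloc[i], nr, nc))
  }
  out
}

# Merge remainder fragments that are too small to stand as segments (size
# below min_keep), and in any case reduce the fragment count to at most
# k_keep, by attaching each small fragment to an adjacent unit -- the
# peeled segment or another fragment -- so every unit stays edge-connected.
absorb_fragments <- function(seg, frags, k_keep, min_keep, nr, nc) {
  adjacent_to <- function(a, b_member) {
    for (id in a) {
      for (nb in grid_neighbors(id, nr, nc)) {
        if (b_member[nb]) return(TRUE)
      }
    }
    FALSE
  }
  repeat {
    sizes <- lengths(frags)
    small <- which(sizes < min_keep)
    over <- length(frags) > k_keep
    if (length(small) == 0L && !over) break
    i <- if (length(small)) small[which.min(sizes[small])] else which.min(sizes)
    frag <- frags[[i]]
    rest_frags <- frags[-i]
    if (length(rest_frags) == 0L) {
      # nothing else to merge with: fold into the peeled segment
      seg <- c(seg, frag)
      frags <- rest_frags
      next
    }
    # prefer folding into an adjacent fragment (it stays in the pool and
    # is split properly later); fall back to the peeled segment
    merged <- FALSE
    for (j in order(lengths(rest_frags))) {
      fm <- logical(nr * nc)
      fm[rest_frags[[j]]] <- TRUE
      if (adjacent_to(frag, fm)) {
        rest_frags[[j]] <- c(rest_frags[[j]], frag)
        frags <- rest_frags
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      seg <- c(seg, frag)
      frags <- rest_frags
    }
  }
  list(seg = seg, frags = frags)
}

# Kernighan-Lin-style boundary refinement: move single boundary pixels from
# larger to adjacent smaller segments, only when the donor stays
# edge-connected, until sizes stop improving (or a move cap is reached).
rebalance_segments <- function(segments, nr, nc, max_moves = 500L) {
  k <- length(segments)
  if (k < 2L) return(segments)
  lab <- integer(nr * nc)
  for (i in seq_len(k)) lab[segments[[i]]] <- i
  sizes <- lengths(segments)
  moves <- 0L

  donor_connected_without <- function(seg_ids, px) {
    rest <- seg_ids[seg_ids != px]
    if (length(rest) <= 1L) return(TRUE)
    member <- logical(nr * nc)
    member[rest] <- TRUE
    visited <- grid_bfs(rest[1L], member, nr, nc)
    length(visited) == length(rest)
  }

  repeat {
    moved <- FALSE
    for (a in order(-sizes)) {
      # neighbouring segments of a, via its boundary pixels
      for (px in segments[[a]]) {
        if (moves >= max_moves) return(segments)
        nbs <- grid_neighbors(px, nr, nc)
        bl <- lab[nbs]
        targets <- unique(bl[bl != 0L & bl != a])
        targets <- targets[sizes[targets] + 1L < sizes[a]]
        if (length(targets) == 0L) next
        b <- targets[which.min(sizes[targets])]
        if (!donor_connected_without(segments[[a]], px)) next
        segments[[a]] <- segments[[a]][segments[[a]] != px]
        segments[[b]] <- sort(c(segments[[b]], px))
        lab[px] <- b
        sizes[a] <- sizes[a] - 1L
        sizes[b] <- sizes[b] + 1L
        moves <- moves + 1L
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  segments
}
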