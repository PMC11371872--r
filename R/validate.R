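#' One-sided Mann-Whitney AUC between two adjacent rating groups
#'
#' Computes the probability that a value drawn from the upper group exceeds
#' one from the lower group, with ties counted half:
#' `AUC = (wins + 0.5 * ties) / (n1 * n2)`. Equivalently `AUC = U / (n1*n2)`
#' with the midrank Mann-Whitney U. The one-sided p-value tests the
#' alternative that the upper group is stochastically greater; it is exact
#' (full enumeration of group-label assignments) when `n1 * n2 <= 100`, and
#' uses the normal approximation with tie correction otherwise.
#'
#' @param lower,upper Numeric vectors for the lower and upper rating group.
#' @return An object of class `adjacent_auc`: list with `auc`, `u_statistic`,
#'   `p_one_sided`, `n_lower`, `n_upper`, `method`.
#' @export
adjacent_auc <- function(lower, upper) {
  lower <- lower[!is.na(lower)]
  upper <- upper[!is.na(upper)]
  n1 <- length(lower)
  n2 <- length(upper)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")

  pooled <- c(lower, upper)
  r <- rank(pooled)                      # midranks
  u <- sum(r[(n1 + 1L):(n1 + n2)]) - n2 * (n2 + 1) / 2
  auc <- u / (n1 * n2)

  if (n1 * n2 <= 100) {
    method <- "exact enumeration"
    p <- mw_exact_p(r, n1, n2, u)
  } else {
    method <- "normal approximation"
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1  # all values tied: no evidence either way
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  structure(
    list(auc = auc, u_statistic = u, p_one_sided = p,
         n_lower = n1, n_upper = n2, method = method),
    class = "adjacent_auc"
  )
}

#' @export
print.adjacent_auc <- function(x, ...) {
  cat(sprintf("Mann-Whitney AUC = %.3f (U = %g, n = %d vs %d)\n",
              x$auc, x$u_statistic, x$n_lower, x$n_upper))
  cat(sprintf("  one-sided p = %.4g (%s)\n", x$p_one_sided, x$method))
  invisible(x)
}

# Exact one-sided p by enumerating every assignment of n2 of the pooled
# ranks to the upper group. P(U >= u_obs) under exchangeability, ties kept.
mw_exact_p <- function(r, n1, n2, u_obs) {
  n <- n1 + n2
  combos <- utils::combn(n, n2)
  offset <- n2 * (n2 + 1) / 2
  usim <- colSums(matrix(r[combos], nrow = n2)) - offset
  mean(usim >= u_obs - 1e-9)
}

#' Adjacent-stage AUC comparisons across an ordinal staging system
#'
#' Groups subjects by stage and runs [adjacent_auc()] between each pair of
#' adjacent occupied stages, testing whether the higher stage has
#' stochastically greater quantitative values.
#'
#' @param values Numeric vector of per-subject quantitative measures.
#' @param stages Ordinal stage per subject (numeric or ordered factor).
#' @return A data frame with one row per adjacent occupied stage pair:
#'   `stage_lower`, `stage_upper`, `n_lower`, `n_upper`, `auc`,
#'   `u_statistic`, `p_one_sided`. Zero rows if fewer than two stages are
#'   occupied.
#' @export
stagewise_auc <- function(values, stages) {
  ok <- !is.na(values) & !is.na(stages)
  values <- values[ok]
  stages <- stages[ok]
  levs <- sort(unique(as.numeric(stages)))
  out <- data.frame(stage_lower = numeric(0), stage_upper = numeric(0),
                    n_lower = integer(0), n_upper = integer(0),
                    auc = numeric(0), u_statistic = numeric(0),
                    p_one_sided = numeric(0))
  if (length(levs) < 2L) return(out)
  for (i in seq_len(length(levs) - 1L)) {
    lo <- values[stages == levs[i]]
    hi <- values[stages == levs[i + 1L]]
    cmp <- adjacent_auc(lo, hi)
    out <- rbind(out, data.frame(
      stage_lower = levs[i], stage_upper = levs[i + 1L],
      n_lower = cmp$n_lower, n_upper = cmp$n_upper,
      auc = cmp$auc, u_statistic = cmp$u_statistic,
      p_one_sided = cmp$p_one_sided))
  }
  out
}

#' Spearman rank correlation with two-sided p-value
#'
#' Rank correlation with midranks for ties; the two-sided p-value uses the
#' t approximation (the convention behind reported correlation/p pairs for
#' samples of this size).
#'
#' @param x,y Numeric vectors; pairs with any `NA` are dropped.
#' @return List with `rho` and `p`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    stop("zero rank variance: correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Rank candidate summary statistics by agreement with expert ratings
#'
#' For each candidate statistic, computes the box-level summary for every
#' sampling box, then the adjacent-category Mann-Whitney AUCs against the
#' expert ordinal ratings (within each inclusion class if given), and ranks
#' the candidates by mean AUC across all adjacent pairs and classes (minimum
#' AUC reported as tiebreaker). Rating categories with no boxes are skipped.
#'
#' @param segment_values List of numeric vectors: per-box segment averages.
#' @param ratings Expert ordinal rating (0-3 scale) per box.
#' @param classes Optional inclusion class per box; `NULL` treats all boxes
#'   as one class.
#' @param candidates Candidate statistics (default all of
#'   [summary_statistics()]).
#' @return A data frame ranked by mean AUC: `statistic`, `mean_auc`,
#'   `min_auc`, `n_pairs`, `rank`. Carries attribute `"stable"` = `FALSE`
#'   with a warning when all AUCs hover at chance (no candidate
#'   discriminates).
#' @export
statistic_selection <- function(segment_values, ratings, classes = NULL,
                                candidates = summary_statistics()) {
  stopifnot(is.list(segment_values), length(segment_values) == length(ratings))
  candidates <- match.arg(candidates, summary_statistics(), several.ok = TRUE)
  if (is.null(classes)) classes <- rep("all", length(ratings))

  rows <- lapply(candidates, function(stat) {
    vals <- vapply(segment_values, box_summary, numeric(1), statistic = stat)
    aucs <- numeric(0)
    for (cl in unique(classes)) {
      sel <- classes == cl
      tab <- stagewise_auc(vals[sel], ratings[sel])
      aucs <- c(aucs, tab$auc)
    }
    data.frame(statistic = stat,
               mean_auc = mean(aucs),
               min_auc = if (length(aucs)) min(aucs) else NA_real_,
               n_pairs = length(aucs))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_auc, -out$min_auc), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  stable <- any(abs(out$mean_auc - 0.5) > 0.1, na.rm = TRUE)
  if (!stable) {
    warning("all candidate statistics near chance AUC; ranking is unstable")
  }
  attr(out, "stable") <- stable
  out
}
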