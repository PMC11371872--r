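test_that("adjacent AUC matches exhaustive pair counting", {
  expect_equal(adjacent_auc(c(0, 0, 0), c(1, 1, 1))$auc, 1)
  expect_equal(adjacent_auc(c(2, 2, 2), c(2, 2, 2))$auc, 0.5)
  a <- adjacent_auc(c(1, 2, 3), c(2, 3, 4))
  expect_equal(a$auc, 7 / 9)          # 6 wins + 2 ties over 9 pairs
  expect_equal(a$auc, oracle_auc(c(1, 2, 3), c(2, 3, 4)))
  set.seed(2)
  lo <- rnorm(8); hi <- rnorm(9, 0.5)
  expect_equal(adjacent_auc(lo, hi)$auc, oracle_auc(lo, hi))
  expect_error(adjacent_auc(numeric(0), 1:3), "non-empty")
})

test_that("AUC complement identity holds exactly with the half-tie rule", {
  set.seed(7)
  for (i in 1:20) {
    a <- sample(0:4, 7, replace = TRUE)
    b <- sample(0:4, 5, replace = TRUE)
    expect_equal(adjacent_auc(a, b)$auc + adjacent_auc(b, a)$auc, 1)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(12)
  lo <- rgamma(15, 2); hi <- rgamma(12, 3)
  base <- adjacent_auc(lo, hi)$auc
  expect_equal(adjacent_auc(log(lo + 1), log(hi + 1))$auc, base)
  expect_equal(adjacent_auc(lo^3, hi^3)$auc, base)
})

test_that("exact p agrees with wilcox.test and the normal branch is close", {
  lo <- c(1.2, 0.8, 2.1, 0.3)
  hi <- c(1.9, 2.4, 0.9, 3.1, 2.2)
  a <- adjacent_auc(lo, hi)   # 20 pairs -> exact enumeration
  w <- wilcox.test(hi, lo, alternative = "greater", exact = TRUE)
  expect_equal(a$p_one_sided, w$p.value, tolerance = 1e-12)
  expect_match(a$method, "exact")

  set.seed(31)
  lo2 <- rnorm(15); hi2 <- rnorm(15, 0.8)   # 225 pairs -> approximation
  a2 <- adjacent_auc(lo2, hi2)
  w2 <- wilcox.test(hi2, lo2, alternative = "greater",
                    exact = FALSE, correct = FALSE)
  expect_match(a2$method, "approximation")
  expect_equal(a2$p_one_sided, w2$p.value, tolerance = 1e-10)
})

test_that("one-sided p is super-uniform under exchangeable groups", {
  set.seed(55)
  p <- vapply(seq_len(500), function(i) {
    x <- rnorm(12)
    adjacent_auc(x[1:6], x[7:12])$p_one_sided
  }, numeric(1))
  rate <- mean(p <= 0.05)
  # binomial 95% band around 0.05 at 500 draws, allowing conservatism
  expect_lte(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 500))
})

test_that("stagewise AUC reduces to adjacent_auc and handles edge cases", {
  values <- c(1, 2, 3, 2, 3, 4)
  stages <- c(0, 0, 0, 1, 1, 1)
  tab <- stagewise_auc(values, stages)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$auc, adjacent_auc(c(1, 2, 3), c(2, 3, 4))$auc)
  expect_equal(nrow(stagewise_auc(values, rep(2, 6))), 0L)
  # only occupied stages are compared
  tab2 <- stagewise_auc(c(1, 2, 9, 10), c(0, 0, 3, 3))
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$stage_upper, 3)
})

test_that("stage-linked severities give above-chance AUCs on average", {
  set.seed(77)
  aucs <- replicate(200, {
    stage <- sample(0:3, 40, replace = TRUE)
    value <- stage + rnorm(40, 0, 1.2)
    mean(stagewise_auc(value, stage)$auc)
  })
  expect_gt(mean(aucs), 0.5)
  expect_gt(mean(aucs > 0.5), 0.9)
})

test_that("spearman association matches the midrank oracle", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  s <- spearman_assoc(x, y)
  oracle_rho <- cor(rank(x), rank(y))  # Pearson on midranks
  expect_equal(s$rho, oracle_rho, tolerance = 1e-12)
  expect_equal(spearman_assoc(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_assoc(rep(1, 5), 1:5), "rank variance")
})

test_that("q99 wins statistic selection when only the tail tracks severity", {
  boxes <- generate_validation_boxes(n_per_rating = 12L, seed = 42)
  ranking <- statistic_selection(boxes$segment_values, boxes$ratings)
  expect_equal(ranking$statistic[ranking$rank == 1L], "q99")
  expect_true(attr(ranking, "stable"))
})

test_that("statistic selection flags a null relationship as unstable", {
  set.seed(99)
  vals <- lapply(1:40, function(i) runif(100))
  ratings <- rep(0:3, each = 10)
  expect_warning(rk <- statistic_selection(vals, ratings), "unstable")
  expect_false(attr(rk, "stable"))
  expect_true(all(abs(rk$mean_auc - 0.5) < 0.15))
})

test_that("single-candidate selection reduces to stagewise AUC", {
  boxes <- generate_validation_boxes(n_per_rating = 6L, seed = 5)
  rk <- statistic_selection(boxes$segment_values, boxes$ratings,
                            candidates = "q99")
  vals <- vapply(boxes$segment_values, box_summary, numeric(1),
                 statistic = "q99")
  tab <- stagewise_auc(vals, boxes$ratings)
  expect_equal(rk$mean_auc, mean(tab$auc))
  expect_equal(rk$n_pairs, nrow(tab))
})
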