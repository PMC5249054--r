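test_that("Kruskal-Wallis matches hand-computed and brute-force values", {
  kw <- kruskal_wallis(1:9, rep(1:3, each = 3))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  expect_equal(kw$p_value, 0.0273, tolerance = 1e-2)

  # identical values: degenerate, p = 1 by convention
  expect_message(kw <- kruskal_wallis(rep(5, 6), rep(1:3, each = 2)),
                 "convention")
  expect_equal(kw$p_value, 1)

  # two tiny groups: H matches the exhaustive rank computation and is
  # the most extreme of all 6 labelings of {1,2,3,4}
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$statistic, brute_kruskal_H(c(1, 2, 3, 4),
                                             c("a", "a", "b", "b")))
  all_h <- apply(combn(4, 2), 2, function(ix) {
    g <- rep("b", 4); g[ix] <- "a"
    brute_kruskal_H(1:4, g)
  })
  expect_equal(kw$statistic, max(all_h))
})

test_that("Kruskal-Wallis equals the brute-force H on random inputs,
          with and without ties", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    n <- sample(6:20, 1)
    g <- sample(k, n, replace = TRUE)
    if (length(unique(g)) < k) next
    x <- if (i %% 2) rnorm(n) else sample(5, n, replace = TRUE)  # ties half the time
    if (length(unique(x)) == 1) next
    expect_equal(kruskal_wallis(x, g)$statistic, brute_kruskal_H(x, g),
                 tolerance = 1e-12)
  }
})

test_that("with two groups and no ties H is a monotone transform of the
          rank-sum statistic", {
  set.seed(42)
  x <- rnorm(14)
  g <- rep(c("a", "b"), 7)
  W <- sum(rank(x)[g == "a"])  # rank sum of group a
  N <- 14; n1 <- 7; n2 <- 7
  H_from_W <- 12 / (N * (N + 1)) *
    (W^2 / n1 + (N * (N + 1) / 2 - W)^2 / n2) - 3 * (N + 1)
  expect_equal(kruskal_wallis(x, g)$statistic, H_from_W)
})

test_that("Pearson chi-square reproduces the morphology-table p-values", {
  fl <- pearson_chi_square(rbind(c(0, 1, 4), c(13, 6, 3)))
  expect_equal(fl$p_value, 0.007, tolerance = 0.1)
  expect_equal(round(fl$p_value, 3), 0.007)
  ns <- pearson_chi_square(rbind(c(8, 3, 0), c(5, 4, 7)))
  expect_equal(round(ns$p_value, 3), 0.028)

  # observed == expected
  flat <- pearson_chi_square(rbind(c(5, 5), c(5, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(pearson_chi_square(rbind(c(0, 0, 0), c(1, 2, 3))),
               "margin")
})

test_that("chi-square equals the brute-force (O-E)^2/E sum on random
          tables", {
  set.seed(43)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(2 * k, 5) + 1, 2, k)  # margins >= 1 guaranteed
    got <- pearson_chi_square(tab)
    expect_equal(got$statistic, brute_chisq(tab), tolerance = 1e-12)
    expect_equal(got$df, k - 1)
    expect_equal(got$p_value,
                 pchisq(brute_chisq(tab), k - 1, lower.tail = FALSE))
  }
})

test_that("Bonferroni scales, caps, and never decreases p-values", {
  expect_equal(bonferroni(0.028, m = 4), 0.112)
  expect_equal(bonferroni(0.007, m = 4), 0.028)
  expect_equal(bonferroni(c(0.5, 0.9), m = 2), c(1, 1))
  set.seed(44)
  p <- runif(20)
  expect_true(all(bonferroni(p, m = 7) >= p))
  expect_true(all(bonferroni(p, m = 7) <= 1))
  # agrees with p.adjust whenever the family is the whole vector
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
})

test_that("KS normality check matches the enumerated D statistic", {
  x <- as.numeric(1:20)
  got <- ks_normality(x)
  expect_equal(got$statistic, brute_ks_D(x))
  expect_true(got$approximate)

  # a correctly specified null at n = 500 is not rejected (fixed seed)
  set.seed(45)
  expect_gt(ks_normality(rnorm(500))$p_value, 0.05)

  # near-perfect normal quantiles give a tiny D
  q <- qnorm(ppoints(100))
  expect_lt(ks_normality(q)$statistic, 0.05)

  expect_error(ks_normality(rep(1, 10)), "zero variance")
})

test_that("group summaries compute per-group means and SDs", {
  toy <- data.frame(group = rep("A", 3), x = c(1, 2, 3),
                    excluded = FALSE)
  toy <- rbind(toy, data.frame(group = c("B", "B", "C", "C"),
                               x = c(5, 7, 2, 2), excluded = FALSE))
  s <- group_summary(toy, "x")
  expect_equal(s$mean, c(2, 6, 2))
  expect_equal(s$sd, c(1, sqrt(2), 0))
  expect_equal(s$n, c(3L, 2L, 2L))
})

test_that("the full battery on the reference cohort reproduces the
          published group statistics", {
  rc <- reference_cohort()
  st <- cohort_statistics(rc)
  # group means to the printed precision
  gm <- function(field) st$summaries$mean[st$summaries$field == field]
  expect_equal(round(gm("n_objects"), 1), c(23.2, 41.4, 33.6))
  # groups B and C round to the printed SMI means exactly; the group A
  # published value (2.97) was computed from unrounded per-sample SMIs,
  # so recomputing from the 2-decimal table lands at 2.977
  expect_equal(round(gm("mean_SMI")[2:3], 2), c(2.90, 3.03))
  expect_equal(gm("mean_SMI")[1], 2.97, tolerance = 0.01 / 2.97)
  expect_equal(round(gm("mean_V_1e5_um3")), c(106, 88, 56))
  expect_true(all(abs(gm("sd_SMI") - c(0.32, 0.32, 0.31)) <= 0.006))
  # chi-square p-values and the Bonferroni verdict
  expect_equal(round(st$chisq$p_value, 3), c(0.007, 0.539, 0.227, 0.028))
  expect_equal(st$chisq$significant, c(TRUE, FALSE, FALSE, FALSE))
})
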