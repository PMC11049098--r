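test_that("flow cross-tabulation counts pairs and tallies exclusions", {
  # identical classifications give a diagonal matrix
  f <- flow_from_assignments(c(1, 2, 3, 4, 4), c(1, 2, 3, 4, 4))
  expect_equal(f$counts, diag(c(1, 1, 1, 2)), ignore_attr = TRUE)
  expect_equal(f$excluded, 0)

  f <- flow_from_assignments(rep(1, 3), rep(4, 3))
  expect_equal(f$counts["NOVA1", "NOVA4"], 3L)
  expect_equal(sum(f$counts), 3L)

  f <- flow_from_assignments(c(1, 1, NA), c(4, "excluded", NA))
  expect_equal(f$excluded, 1)
  expect_equal(f$unclassified, 1)
  expect_equal(f$excluded_by_name[["NOVA1"]], 1L)
})

test_that("mismatched record sets are rejected", {
  nr <- classify_by_name(make_food_table("plain yogurt"))
  ir <- classify_by_name(make_food_table(c("plain yogurt", "rice")))
  expect_error(crosstab_flows(nr, ir), "same record_ids")
})

test_that("flow margins are conserved for random classifications", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    bn <- sample(1:4, n, replace = TRUE)
    bi <- pmax(bn, sample(1:4, n, replace = TRUE))  # only-upward flows
    f <- flow_from_assignments(bn, bi)
    expect_equal(unname(rowSums(f$counts)), tabulate(bn, 4))
    expect_equal(unname(colSums(f$counts)), tabulate(bi, 4))
    expect_equal(sum(f$counts), n)
  }
})

test_that("fold change is the margin ratio to one decimal", {
  f <- flow_from_assignments(c(rep(4, 10), rep(1, 20)),
                             c(rep(4, 25), rep(1, 5)))
  expect_equal(fold_change(f, 4), 2.5)
  ident <- flow_from_assignments(rep(4, 10), rep(4, 10))
  expect_equal(fold_change(ident, 4), 1.0)
  expect_warning(out <- fold_change(ident, 2), "zero")
  expect_true(is.na(out))
})

test_that("chi-square equals the hand formula, without continuity correction", {
  m <- matrix(c(10, 20, 20, 10), 2)
  res <- chi_square(m)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)  # E = 15 everywhere
  expect_equal(res$df, 1)

  expect_equal(chi_square(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(chi_square(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  set.seed(11)
  for (i in 1:50) {
    dims <- sample(2:4, 2, replace = TRUE)
    m <- matrix(sample(1:20, prod(dims), replace = TRUE), dims[1])
    res <- chi_square(m)
    expect_equal(res$statistic, hand_chisq(m), tolerance = 1e-10)
    expect_equal(res$df, (dims[1] - 1) * (dims[2] - 1))
  }
  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2)), "margins")
})

test_that("Kruskal-Wallis H matches the rank formula and degenerate cases", {
  d <- tibble::tibble(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(d, v, g)$statistic, 0, tolerance = 1e-10)

  # no ties: H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2, computed by hand
  d2 <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6),
                       g = rep(c("a", "b", "c"), each = 2))
  r <- rank(d2$v)
  rbar <- tapply(r, d2$g, mean)
  h_hand <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  res <- kruskal_wallis(d2, v, g)
  expect_equal(res$statistic, h_hand, tolerance = 1e-10)
  expect_equal(res$df, 2)

  expect_error(kruskal_wallis(tibble::tibble(v = 1:3, g = "a"), v, g),
               "2 groups")
})

test_that("a well-separated group drives the Kruskal-Wallis p below alpha", {
  d <- tibble::tibble(v = c(rnorm(30), rnorm(30) + 100),
                      g = rep(c("a", "b"), each = 30))
  expect_lt(kruskal_wallis(d, v, g)$p_value, 0.001)
})

test_that("pairwise Mann-Whitney matches brute-force U and exact enumeration", {
  d <- tibble::tibble(v = c(1, 2, 3, 4), g = rep(c("a", "b"), each = 2))
  res <- pairwise_mwu_bonferroni(d, v, g)
  expect_equal(res$statistic, 0)  # complete separation

  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(runif(n1, 0, 10), 1)
    y <- round(runif(n2, 0, 10), 1)
    d <- tibble::tibble(v = c(x, y), g = rep(c("a", "b"), c(n1, n2)))
    res <- pairwise_mwu_bonferroni(d, v, g)
    expect_equal(res$statistic, brute_u(x, y), info = i)
    if (!any(duplicated(c(x, y)))) {
      expect_equal(res$p_value, brute_mwu_p(x, y), tolerance = 1e-8, info = i)
    }
  }
})

test_that("Bonferroni adjustment multiplies by the number of pairs and caps at 1", {
  set.seed(9)
  d <- tibble::tibble(v = rnorm(30), g = rep(c("a", "b", "c"), 10))
  res <- pairwise_mwu_bonferroni(d, v, g)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 3))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("group summaries report median and type-7 quartiles, keeping empty groups", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5), g = "a")
  s <- summarize_groups(d, g, vars = "x")
  expect_equal(s$median, 3)

  d <- tibble::tibble(x = c(1, 2, 3, 4, 100), g = "a")
  expect_equal(summarize_groups(d, g, vars = "x")$median, 3)

  d <- tibble::tibble(x = c(1, 2, 3, 4), g = factor("a", levels = c("a", "b")))
  s <- summarize_groups(d, g, vars = "x")
  expect_equal(s$q1[s$group == "a"], 1.75)
  expect_equal(s$q3[s$group == "a"], 3.25)
  expect_equal(s$n[s$group == "b"], 0L)
  expect_true(is.na(s$median[s$group == "b"]))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3, na.rm = TRUE))
})

test_that("grade distributions give counts and one-decimal percentages per group", {
  d <- tibble::tibble(
    grade = factor(c("A", "A", "B", "C", "A"), levels = LETTERS[1:5]),
    g = c("x", "x", "x", "y", "y"))
  dist <- grade_distribution(d, g)
  expect_equal(dist$n[dist$group == "x" & dist$grade == "A"], 2L)
  expect_equal(dist$pct[dist$group == "x" & dist$grade == "A"], 66.7)
  # percentages in any group sum to 100 within rounding slack
  sums <- tapply(dist$pct, dist$group, sum)
  expect_true(all(abs(sums - 100) <= 0.2))

  all_a <- tibble::tibble(grade = factor("A", levels = LETTERS[1:5]),
                          g = "x")
  expect_equal(grade_distribution(all_a, g)$pct, c(100, 0, 0, 0, 0))
})
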