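test_that("omnibus normality statistic matches the reference implementation", {
  # frozen oracle values computed with an independent implementation of the
  # same omnibus K2 statistic (skewness + kurtosis normal approximations)
  r1 <- dagostino_pearson((1:20)^1.5)
  expect_equal(r1$statistic, 2.87971128, tolerance = 1e-7)
  expect_equal(r1$p_value, 0.23696196, tolerance = 1e-6)
  r2 <- dagostino_pearson(c(2.1, 1.9, 2.0, 2.2, 1.8, 2.05, 1.95, 2.15,
                            1.85, 2.0, 2.3, 1.7))
  expect_equal(r2$statistic, 0.03417451, tolerance = 1e-7)
  expect_equal(r2$p_value, 0.9830579, tolerance = 1e-6)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("Mann-Whitney agrees with exact enumeration for all n1, n2 <= 6", {
  set.seed(41)
  for (rep in 1:40) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2, 0.6), 1)
    got <- mann_whitney_u(x, y)
    # independent oracle: direct enumeration over all group assignments
    pooled <- c(x, y); rk <- rank(pooled)
    U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    U_obs <- min(U_obs, n1 * n2 - U_obs)
    sets <- combn(n1 + n2, n1)
    us <- numeric(ncol(sets))
    for (j in seq_len(ncol(sets))) {
      u <- sum(rk[sets[, j]]) - n1 * (n1 + 1) / 2
      us[j] <- min(u, n1 * n2 - u)
    }
    expect_equal(got$p_value, mean(us <= U_obs + 1e-9), tolerance = 1e-12)
  }
  # no ties: agree with the exact distribution in wilcox.test
  set.seed(42)
  for (rep in 1:20) {
    x <- rnorm(5); y <- rnorm(6, 1)
    got <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("textbook U cases come out right", {
  sep <- mann_whitney_u(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50))
  expect_equal(min(sep$U, 25 - sep$U), 0)
  expect_equal(sep$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
})

test_that("routing follows the normality gate", {
  set.seed(7)
  # clearly normal groups (n >= 8, omnibus passes) -> t-test
  a <- qnorm(seq(0.03, 0.97, length.out = 25))
  b <- a + 2
  r <- route_and_test(list(a = a, b = b))
  expect_identical(r$test_used, "t")
  expect_true(all(r$normality_p > 0.05))
  expect_lt(r$p_value, 1e-6)
  # heavy-tailed data -> Mann-Whitney
  x <- exp(qnorm(seq(0.01, 0.99, length.out = 40)))^2
  r2 <- route_and_test(list(a = x, b = x * 3))
  expect_identical(r2$test_used, "mann_whitney")
  # three normal groups -> ANOVA + Dunnett
  g3 <- list(a = a, b = a + 1, c = a - 1)
  r3 <- route_and_test(g3)
  expect_identical(r3$test_used, "anova_dunnett")
  expect_s3_class(r3$posthoc, "data.frame")
  expect_equal(nrow(r3$posthoc), 2)   # b-a and c-a
  # three skewed groups -> Kruskal-Wallis + Dunn
  r4 <- route_and_test(list(a = x, b = x * 2, c = x * 4))
  expect_identical(r4$test_used, "kruskal_wallis_dunn")
  expect_equal(nrow(r4$posthoc), 3)   # all pairs
  # small groups skip the normality test and are flagged
  r5 <- route_and_test(list(a = rnorm(5), b = rnorm(5)))
  expect_identical(r5$test_used, "mann_whitney")
  expect_match(r5$flags, "too_small")
  expect_true(all(is.na(r5$normality_p)))
  expect_error(route_and_test(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("routing is a pure function of normality p-values and group count", {
  set.seed(8)
  for (rep in 1:20) {
    gs <- lapply(seq_len(sample(2:4, 1)), function(i) {
      if (runif(1) < 0.5) rnorm(15) else exp(rnorm(15) * 1.5)
    })
    names(gs) <- paste0("g", seq_along(gs))
    r <- route_and_test(gs)
    normal <- all(vapply(gs, function(g) dagostino_pearson(g)$p_value,
                         numeric(1)) > 0.05)
    want <- if (normal) {
      if (length(gs) == 2) "t" else "anova_dunnett"
    } else {
      if (length(gs) == 2) "mann_whitney" else "kruskal_wallis_dunn"
    }
    expect_identical(r$test_used, want)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
  }
})

test_that("Kruskal-Wallis type-I error sits near the nominal level", {
  set.seed(1234)
  rej <- mean(vapply(1:1000, function(i) {
    kruskal.test(list(rnorm(10), rnorm(10), rnorm(10)))$p.value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("group summaries use the linear-interpolation quartile convention", {
  rec <- data.frame(position_class = c(rep("inner", 4), "outer"),
                    ln_ratio = c(1, 2, 3, 4, 2.5),
                    other = c(NA, NA, NA, NA, 1))
  s <- summarize_groups(rec, "position_class", "ln_ratio")
  inner <- s[s$group == "inner", ]
  expect_equal(inner$median, 2.5)
  expect_equal(inner$iqr, 1.5)
  expect_equal(inner$n, 4)
  outer <- s[s$group == "outer", ]
  expect_equal(outer$median, 2.5)
  expect_equal(outer$iqr, 0)
  expect_error(summarize_groups(rec, "position_class", "nope"),
               "unknown metric")
  expect_error(summarize_groups(rec, "nope", "ln_ratio"), "grouping")
  expect_warning(summarize_groups(rec, "position_class",
                                  c("ln_ratio", "other")), "dropped")
})

test_that("Dunn post hoc flags the separated group after Kruskal-Wallis", {
  x <- exp(qnorm(seq(0.01, 0.99, length.out = 20)))^2
  r <- route_and_test(list(a = x, b = x * 1.01, c = x * 50))
  expect_identical(r$test_used, "kruskal_wallis_dunn")
  ph <- r$posthoc
  ac <- ph$p_adjusted[(ph$group1 == "a" & ph$group2 == "c") |
                        (ph$group1 == "c" & ph$group2 == "a")]
  ab <- ph$p_adjusted[(ph$group1 == "a" & ph$group2 == "b") |
                        (ph$group1 == "b" & ph$group2 == "a")]
  expect_lt(ac, 0.01)
  expect_gt(ab, 0.1)
})
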