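test_that("exact one-tailed p-values match known small cases", {
  t <- mann_whitney(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(t$p, 0.05)
  expect_equal(t$U, 0)
  expect_equal(t$method, "exact")
  t2 <- mann_whitney(5, 1, "less")
  expect_equal(t2$p, 1)
  t3 <- mann_whitney(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(t3$p, 0.05)
})

test_that("the exact null agrees with base wilcox.test on tie-free data", {
  set.seed(1)
  for (k in 1:20) {
    a <- sample(1:1000, sample(2:6, 1))
    b <- sample(2000:3000, sample(2:6, 1)) / 7
    ours <- mann_whitney(a, b, "less")
    ref <- suppressWarnings(wilcox.test(a, b, alternative = "less", exact = TRUE))
    expect_equal(ours$p, unname(ref$p.value), info = k)
  }
})

test_that("tied data fall back to exact enumeration matching the bitmask oracle", {
  set.seed(2)
  for (k in 1:15) {
    a <- sample(1:4, sample(2:5, 1), replace = TRUE)
    b <- sample(2:5, sample(2:5, 1), replace = TRUE)
    ours <- mann_whitney(a, b, "less")
    expect_true(ours$method %in% c("exact-enumeration", "exact", "degenerate"))
    expect_equal(ours$p, mw_enum_p(a, b), info = k)
  }
})

test_that("identical constant samples give p = 1, never NaN", {
  t <- mann_whitney(rep(2, 5), rep(2, 7), "less")
  expect_equal(t$p, 1)
  t2 <- mann_whitney(rep(2, 50), rep(2, 70), "less")
  expect_equal(t2$p, 1)
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(3)
  a <- rnorm(60); b <- rnorm(80) + 0.5
  ours <- mann_whitney(a, b, "less")
  expect_equal(ours$method, "normal")
  ref <- wilcox.test(a, b, alternative = "less", exact = FALSE, correct = TRUE)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-8)
})

test_that("comparison matrices are anti-symmetric in their decisions", {
  set.seed(4)
  groups <- list(a = rnorm(30), b = rnorm(30) + 1, c = rnorm(30) + 2)
  m <- mann_whitney_matrix(groups, "less")
  expect_true(is.na(m$p["a", "a"]))
  for (i in names(groups)) for (j in names(groups)) {
    if (i == j) next
    expect_false(isTRUE(m$decision[i, j]) && isTRUE(m$decision[j, i]))
  }
  expect_true(m$decision["a", "b"])
  expect_false(m$decision["b", "a"])
})

test_that("presence-fitness summaries honour the occurrence threshold", {
  set.seed(5)
  n <- 1000
  tab <- planted_table(n, seed = 5)
  # force presence value 9 of Dist to occur exactly 199 times: excluded
  tab$Dist <- 0L
  tab$Dist[1:199] <- 9L
  ps <- presence_fitness_summary(tab, min_count = 200)
  dist_rows <- ps$summary[ps$summary$factor == "Dist", ]
  expect_equal(dist_rows$presence, 0)
  expect_equal(dist_rows$n, n - 199)
  expect_null(ps$comparisons$Dist)  # single retained value: nothing to compare
  # boundary: exactly 200 occurrences are kept
  tab$Dist[1:200] <- 9L
  ps2 <- presence_fitness_summary(tab, min_count = 200)
  expect_equal(sort(ps2$summary$presence[ps2$summary$factor == "Dist"]), c(0, 9))
})

test_that("presence-fitness quartiles match an independent tabulation", {
  tab <- planted_table(300, seed = 6)
  tab$Qual <- rep(c(-1L, 0L, 2L), each = 100)
  tab$fitness <- seq_len(300) / 3
  ps <- presence_fitness_summary(tab, min_count = 50)
  got <- ps$summary[ps$summary$factor == "Qual", ]
  for (v in c(-1, 0, 2)) {
    vals <- tab$fitness[tab$Qual == v]
    expect_equal(got$median[got$presence == v], unname(median(vals)))
    expect_equal(got$q1[got$presence == v], unname(quantile(vals, 0.25)))
    expect_equal(got$q3[got$presence == v], unname(quantile(vals, 0.75)))
  }
})

test_that("strategy comparison refuses tests on single-run distributions", {
  env <- generate_synthetic_environment(synthetic_env_spec(
    width = 10, height = 10, start_year = 800, end_year = 811,
    init_households = 5, seed = 3))
  expect_message(
    cmp <- compare_strategies(c("argmax[S_All](F_Qual)", "argmax[S_All](-F_Dist)"),
                              env, n_runs = 1, seed = 1),
    "refused")
  expect_null(cmp$tests)
  expect_equal(dim(cmp$rmse), c(1L, 2L))
})

test_that("comparing a strategy against itself does not reject the null", {
  env <- generate_synthetic_environment(synthetic_env_spec(
    width = 10, height = 10, start_year = 800, end_year = 811,
    init_households = 5, seed = 3))
  cmp <- compare_strategies(c(a = "argmax[S_All](F_Qual)",
                              b = "argmax[S_All](F_Qual)"),
                            env, n_runs = 8, seed = 2, baseline = "b")
  expect_false(cmp$tests$significant)
})
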