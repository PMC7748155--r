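test_that("fit_forest refuses underpowered tables and selects trees reproducibly", {
  tab <- planted_table(40, seed = 1)
  expect_error(fit_forest(tab), "50")
  tab <- planted_table(400, seed = 1)
  m1 <- fit_forest(tab, grid = c(20, 50), seed = 5)
  m2 <- fit_forest(tab, grid = c(20, 50), seed = 5)
  expect_equal(m1$n_trees, m2$n_trees)
  expect_equal(m1$test_r2, m2$test_r2)
  expect_equal(length(m1$train) + length(m1$test), 400)
  expect_equal(length(m1$train), floor(0.9 * 400))
})

test_that("a constant-fitness table is fit with zero test error", {
  tab <- planted_table(200, seed = 2, effect = c(Qual = 0), noise_sd = 0)
  tab$fitness <- 7.5
  m <- fit_forest(tab, grid = c(20), seed = 1)
  pred <- predict(m$forest, m$x[m$test, ], num.threads = 1)$predictions
  expect_true(all(abs(pred - 7.5) < 1e-9))
})

test_that("planted main effects are recovered with high held-out R2", {
  tab <- planted_table(5000, seed = 3)
  m <- fit_forest(tab, grid = c(100, 200), seed = 3)
  expect_gt(m$test_r2, 0.8)
  gi <- gini_importance(m)
  expect_equal(sum(gi), 1)
  expect_true(all(gi >= 0))
  expect_equal(names(which.max(gi)), "Qual")
  pi <- permutation_importance(m, repeats = 5, seed = 4)
  ord <- pi$factor[order(-pi$importance)]
  expect_equal(ord[1:3], c("Qual", "Soc", "Mig"))
})

test_that("permutation importance vanishes for irrelevant features and constant targets", {
  tab <- planted_table(600, seed = 5, effect = c(Qual = 0), noise_sd = 0)
  tab$fitness <- tab$Qual  # exact single-feature dependence
  m <- fit_forest(tab, grid = c(50), seed = 6)
  pi <- permutation_importance(m, repeats = 5, seed = 7)
  imp <- structure(pi$importance, names = pi$factor)
  expect_gt(imp[["Qual"]], 0)
  expect_true(all(abs(imp[setdiff(names(imp), "Qual")]) < 1e-2 * imp[["Qual"]]))
  tab$fitness <- 3
  mc <- fit_forest(tab, grid = c(50), seed = 6)
  pic <- permutation_importance(mc, repeats = 5, seed = 7)
  expect_true(all(abs(pic$importance) < 1e-9))
})

test_that("gini importance concentrates on the only informative feature", {
  tab <- planted_table(400, seed = 8, effect = c(Qual = 10), noise_sd = 0)
  for (f in setdiff(emdisc:::factor_names, "Qual")) tab[[f]] <- 0L
  m <- fit_forest(tab, grid = c(30), seed = 9)
  gi <- gini_importance(m)
  expect_equal(unname(gi[["Qual"]]), 1)
})

test_that("a single split attributes its mean change to the split feature", {
  # one informative feature, stumps only: contribution {Qual} = leaf - root mean
  tab <- planted_table(300, seed = 10, effect = c(Qual = 0), noise_sd = 0)
  for (f in setdiff(emdisc:::factor_names, "Qual")) tab[[f]] <- 0L
  tab$fitness <- ifelse(tab$Qual > 0, 20, 10)
  x <- tab[, emdisc:::factor_names]
  y <- tab$fitness
  rf <- ranger::ranger(x = x, y = y, num.trees = 1, mtry = 9, max.depth = 1,
                       min.node.size = 1, keep.inbag = TRUE, num.threads = 1,
                       seed = 11)
  model <- structure(list(forest = rf, x = x, y = y,
                          train = seq_len(nrow(x)), test = seq_len(nrow(x))),
                     class = "emd_forest")
  jc <- joint_contributions(model, newdata = x)
  expect_equal(jc$scores$subset, "Qual")
  # manual trace: bias is the inbag mean, each prediction reconstructs exactly
  inbag <- rf$inbag.counts[[1]]
  expect_equal(jc$bias, sum(inbag * y) / sum(inbag))
  pred <- predict(rf, x, num.threads = 1)$predictions
  expect_equal(jc$predictions, pred)
  routed_right <- which(pred > jc$bias)
  expect_true(all(abs((jc$predictions - jc$bias)[routed_right] -
                        (pred[routed_right] - jc$bias)) < 1e-12))
})

test_that("joint contributions conserve the forest prediction exactly", {
  tab <- planted_table(800, seed = 12, interaction = c("Qual", "Soc"))
  m <- fit_forest(tab, grid = c(60), seed = 13)
  jc <- joint_contributions(m)
  pred <- predict(m$forest, m$x[m$test, ], num.threads = 1)$predictions
  expect_lt(max(abs(jc$reconstruction - pred) / pmax(abs(pred), 1e-12)), 1e-9)
  expect_lt(jc$conservation_error, 1e-9)
  # scores are a normalized share of attributed mass
  expect_true(all(jc$scores$score >= 0))
  expect_lte(sum(jc$scores$score), 1 + 1e-12)
  expect_true(all(jc$scores$size <= 3))
})

test_that("a planted pairwise interaction surfaces among the top subsets", {
  tab <- planted_table(3000, seed = 14, effect = c(Qual = 8, Soc = 4),
                       interaction = c("Qual", "Soc"))
  m <- fit_forest(tab, grid = c(80), seed = 15)
  jc <- joint_contributions(m)
  expect_true("Qual+Soc" %in% jc$scores$subset[1:3])
})
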