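table1_strings <- function() table1_fixture()$rule

test_that("canonical parse/format round-trips on all shipped rules", {
  for (t in table1_strings()) {
    canon <- format_rule(parse_rule(t))
    expect_identical(format_rule(parse_rule(canon)), canon, info = t)
  }
  expect_identical(format_rule(parse_rule("argmax[S_All](F_Qual+F_Mig+F_Soc)")),
                   "argmax[S_All](F_Qual + F_Soc + F_Mig)")
})

test_that("unknown tokens are parse errors", {
  expect_error(parse_rule("argmax[S_All](F_Bogus)"), "F_Bogus|factor")
  expect_error(parse_rule("argmax[S_Everyone](F_Qual)"), "connectivity")
  expect_error(parse_rule("F_Qual + F_Soc"), "argmax")
  expect_error(parse_rule("argmax[S_All](0)"), "factor")
})

test_that("presence extraction matches the published rule coefficients", {
  p1 <- extract_presence(parse_rule("argmax[S_All](-F_Dist - F_Dry + 2*F_Mig)"))
  expect_equal(p1[["Dist"]], -1)
  expect_equal(p1[["Dry"]], -1)
  expect_equal(p1[["Mig"]], 2)
  expect_equal(sum(p1 != 0), 3)
  p2 <- extract_presence(parse_rule("argmax[S_All](F_Qual)"))
  expect_equal(as.integer(p2), c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  # nested subtraction: Soc - (Dist - Soc)
  tree <- emdisc:::node_op("sub", emdisc:::node_factor("Soc"),
                           emdisc:::node_op("sub", emdisc:::node_factor("Dist"),
                                            emdisc:::node_factor("Soc")))
  p3 <- extract_presence(rule_tree(tree))
  expect_equal(p3[["Soc"]], 2)
  expect_equal(p3[["Dist"]], -1)
})

test_that("presence equals the symbolic-expansion oracle on random trees", {
  for (s in 1:200) {
    r <- random_rule(s)
    expect_equal(as.numeric(extract_presence(r)),
                 unname(presence_by_expansion(r)), info = s)
  }
})

test_that("typing condition governs composition and random trees are well-typed", {
  expect_true(can_compose("Add", "F_Qual", 1))
  expect_true(can_compose("Sub", "Add", 2))
  expect_false(can_compose("F_Qual", "F_Soc", 1))  # terminals take no arguments
  for (s in 1:50) expect_true(type_check_rule(random_rule(s)))
  expect_error(rule_tree(list(kind = "op", op = "mul",
                              args = list(emdisc:::node_factor("Qual"),
                                          emdisc:::node_factor("Soc")))),
               "unknown node")
  expect_error(rule_tree(emdisc:::node_factor("Bogus")), "Bogus")
})

test_that("factor sub-scores are min-max normalized over the candidate set", {
  l <- tiny_landscape(width = 4, height = 4, years = 800:802)
  l$cells$quality <- rep(0.5, 16)
  cand_cells <- cell_index(c(0, 1, 2), c(3, 3, 3), 4)
  l$cells$quality[cand_cells] <- c(0.2, 0.5, 0.8)
  hh <- data.frame(id = 1L, parent_id = NA, age = 10, corn = 100,
                   farm_x = 0, farm_y = 0, dwell_x = 1, dwell_y = 0)
  ctx <- decision_context(l, hh, self_id = 1, year = 800)
  expect_equal(factor_subscore("Qual", cand_cells, ctx), c(0, 0.5, 1))
  # degenerate: identical raw values give the neutral 0.5
  same <- cell_index(c(0, 1), c(2, 2), 4)
  expect_equal(factor_subscore("Qual", same, ctx), c(0.5, 0.5))
})

test_that("the migration sub-score is binary on zone membership", {
  l <- tiny_landscape(width = 4, height = 2, years = 800:802)
  l$cells$zone <- ifelse(l$cells$x < 2, 0L, 1L)
  l$yields <- rbind(l$yields, transform(l$yields, zone = 1L))
  l <- landscape(l$cells, l$yields, l$water, l$target, 800, 802)
  hh <- data.frame(id = 1L, parent_id = NA, age = 10, corn = 100,
                   farm_x = 0, farm_y = 0, dwell_x = 1, dwell_y = 0)
  ctx <- decision_context(l, hh, self_id = 1, year = 800)
  cand <- cell_index(c(0, 2, 3), c(1, 1, 1), 4)
  expect_equal(factor_subscore("Mig", cand, ctx), c(0, 1, 1))
})

test_that("social presence counts households within the social radius", {
  l <- tiny_landscape(width = 12, height = 12, years = 800:802)
  hh <- data.frame(id = 1:4, parent_id = NA,
                   age = c(10, 12, 14, 16), corn = c(5, 9, 1, 3),
                   farm_x = c(0, 1, 2, 11), farm_y = c(0, 0, 0, 11),
                   dwell_x = c(1, 2, 1, 11), dwell_y = c(1, 1, 2, 10))
  ctx <- decision_context(l, hh, self_id = 1, year = 800)
  # plot A has households 2..4 nearby minus none, plot B (far corner) only #4
  a <- cell_index(3, 3, 12); b <- cell_index(8, 8, 12)
  s <- factor_subscore("Soc", c(a, b), ctx)
  expect_equal(s, c(1, 0))
})

test_that("argmax(-F_Dist) picks the nearest plot; forced ties break by (y, x)", {
  l <- tiny_landscape(width = 5, height = 1, years = 800:802)
  hh <- data.frame(id = 1L, parent_id = NA, age = 10, corn = 0,
                   farm_x = 0, farm_y = 0, dwell_x = 4, dwell_y = 0)
  ctx <- decision_context(l, hh, self_id = 1, year = 800)
  ctx$candidates <- cell_index(c(1, 2, 3), 0, 5)  # raw distances 1, 2, 3
  expect_equal(evaluate_rule(parse_rule("argmax[S_All](-F_Dist)"), ctx),
               cell_index(1, 0, 5))
  # all candidates in the decider's zone: every F_Mig score 0, tie-break wins
  expect_equal(evaluate_rule(parse_rule("argmax[S_All](F_Mig)"), ctx),
               cell_index(1, 0, 5))
})

test_that("evaluate_rule equals brute-force enumeration on a fixed context", {
  ctx <- fuzz_context(99)
  r <- parse_rule("argmax[S_All](F_Qual + F_Soc)")
  bf <- brute_force_scores(r, ctx)
  choice <- evaluate_rule(r, ctx)
  expect_equal(choice, bf$cand[which.max(bf$score)])
})

test_that("candidate subsets follow the connectivity configuration", {
  l <- tiny_landscape(width = 12, height = 12, years = 800:802)
  hh <- data.frame(id = 1:3, parent_id = c(NA, NA, NA),
                   age = c(10, 12, 14), corn = c(5, 9, 1),
                   farm_x = c(0, 6, 11), farm_y = c(0, 6, 11),
                   dwell_x = c(1, 6, 10), dwell_y = c(0, 7, 11))
  ctx <- decision_context(l, hh, self_id = 1, year = 800)
  expect_identical(candidate_subset("S_All", ctx), ctx$avail)
  # no living relatives: own knowledge only (radius 10 of own dwelling)
  fam <- candidate_subset("S_Fam", ctx)
  la <- ctx$la
  own <- ctx$avail[(la$xs[ctx$avail] - 1)^2 + (la$ys[ctx$avail] - 0)^2 <= 100]
  expect_identical(fam, sort(own))
  # top-2 by corn stock: households 2 (corn 9) and 1 (corn 5)
  perf <- candidate_subset("S_Perf", ctx, sim_options(perf_k = 2))
  centers <- cell_index(c(6, 1), c(7, 0), 12)
  expected <- sort(unique(unlist(lapply(centers, function(c0) {
    ctx$avail[(la$xs[ctx$avail] - la$xs[c0])^2 + (la$ys[ctx$avail] - la$ys[c0])^2 <= 100]
  }))))
  expect_identical(perf, expected)
})
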