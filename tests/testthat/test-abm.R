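one_household_state <- function(age = 5, corn_new = 0, corn_old = 0,
                                death_age = 200, farm = c(0, 1), dwell = c(0, 0)) {
  list(year = 800L, households = data.frame(
    id = 1L, parent_id = NA_integer_, grandparent_id = NA_integer_,
    age = age, corn_new = corn_new, corn_old = corn_old,
    death_age = death_age, fertility_end_age = 30, fertility = 0,
    farm_x = farm[1], farm_y = farm[2], dwell_x = dwell[1], dwell_y = dwell[2]),
    last_yield = NULL)
}

test_that("a noise-free year matches the hand trace exactly", {
  l <- tiny_landscape(width = 2, height = 2, yield = 1000, years = 800:803)
  p <- trace_params(need = 800, adjustment = 1, variance = 0)
  s1 <- step_year(one_household_state(), l, p, "argmax[S_All](-F_Dist)", seed = 1)
  h <- s1$households
  expect_equal(nrow(h), 1)
  expect_equal(h$corn_new, 200)  # 1000 harvested, 800 consumed from the new vintage
  expect_equal(h$corn_old, 0)
  expect_equal(h$age, 6)
  expect_equal(c(h$farm_x, h$farm_y), c(0, 1))      # no relocation: 1000 >= 800
  expect_equal(s1$last_yield[cell_index(0, 1, 2)], 1000)
  expect_equal(unname(attr(s1, "ledger")[c("harvested", "consumed", "after")]),
               c(1000, 800, 200))
  # second year: the 200 kg leftover is eaten first, as the older vintage
  s2 <- step_year(s1, l, p, "argmax[S_All](-F_Dist)", seed = 1)
  expect_equal(s2$households$corn_new, 400)  # 1000 - (800 - 200)
  expect_equal(s2$households$corn_old, 0)
})

test_that("maize older than two harvests is discarded", {
  l <- tiny_landscape(width = 2, height = 2, yield = 2000, years = 800:803)
  p <- trace_params(need = 500, adjustment = 1, variance = 0)
  s <- one_household_state()
  for (k in 1:3) s <- step_year(s, l, p, "argmax[S_All](-F_Dist)", seed = k)
  ledger <- attr(s, "ledger")
  # year 3 eats 500 of the 1000 kg two-year-old vintage and discards the rest
  expect_equal(unname(ledger["discarded"]), 500)
  expect_equal(s$households$corn_old, 2000)
  expect_equal(s$households$corn_new, 2000)
})

test_that("households beyond their death age are removed", {
  l <- tiny_landscape(width = 2, height = 2, yield = 1000, years = 800:802)
  p <- trace_params(death_age = 10)
  s <- step_year(one_household_state(age = 11, death_age = 10), l, p,
                 "argmax[S_All](-F_Dist)", seed = 1)
  expect_equal(nrow(s$households), 0)
  s0 <- step_year(s, l, p, "argmax[S_All](-F_Dist)", seed = 1)
  expect_equal(nrow(s0$households), 0)  # empty population is absorbing
})

test_that("a failing farm triggers strategy-driven relocation", {
  l <- tiny_landscape(width = 3, height = 3, yield = 1000, years = 800:802)
  l$cells$quality[cell_index(2, 2, 3)] <- 0  # the household's farm is barren
  p <- trace_params(need = 800, adjustment = 1, variance = 0)
  s <- step_year(one_household_state(farm = c(2, 2), dwell = c(0, 0)), l, p,
                 "argmax[S_All](-F_Dist)", seed = 1)
  h <- s$households
  expect_equal(nrow(h), 1)
  # nearest available plot to (2,2): (1,2) or (2,1) are tied at distance 1;
  # the (y,x) tie-break picks (2,1)
  expect_equal(c(h$farm_x, h$farm_y), c(2, 1))
})

test_that("run_simulation scores counts against the target series", {
  l <- tiny_landscape(width = 4, height = 4, yield = 1000, years = 800:802)
  l$target$households <- c(3L, 5L, 5L)
  p <- trace_params(need = 800, adjustment = 1, variance = 0)
  sim <- run_simulation(l, p, "argmax[S_All](-F_Dist)", seed = 1)
  expect_equal(unname(sim$counts), c(3L, 3L, 3L))  # no births, no deaths
  expect_equal(sim$rmse, sqrt(mean(c(0, 4, 4))))
  expect_true(all(sim$counts >= 0))
  expect_equal(as.integer(names(sim$counts)), 800:802)
})

test_that("corn mass balances within every step of a stochastic run", {
  env <- generate_synthetic_environment(synthetic_env_spec(
    width = 10, height = 10, start_year = 800, end_year = 819,
    init_households = 5, seed = 3))
  sim <- run_simulation(env, draw_params(seed = 4),
                        "argmax[S_All](F_Qual + F_Soc - F_Dist)", seed = 5)
  lb <- sim$ledgers
  resid <- lb[, "before"] + lb[, "harvested"] - lb[, "consumed"] -
    lb[, "discarded"] - lb[, "removed"] - lb[, "after"]
  scale <- pmax(lb[, "before"] + lb[, "harvested"], 1)
  expect_lt(max(abs(resid) / scale), 1e-9)
})

test_that("simulation runs are a pure function of seed, params and landscape", {
  env <- generate_synthetic_environment(synthetic_env_spec(
    width = 10, height = 10, start_year = 800, end_year = 819,
    init_households = 5, seed = 3))
  p <- draw_params(seed = 8)
  s1 <- run_simulation(env, p, "argmax[S_Neigh](F_Soc + F_HAge)", seed = 21)
  s2 <- run_simulation(env, p, "argmax[S_Neigh](F_Soc + F_HAge)", seed = 21)
  expect_identical(s1$counts, s2$counts)
})

test_that("span mismatch between init and landscape target is caught", {
  l <- tiny_landscape()
  l$target <- l$target[-2, ]
  expect_error(validate_landscape(l), "801")
})

test_that("incrementally maintained neighbourhood grids match brute-force recounts", {
  env <- generate_synthetic_environment(synthetic_env_spec(
    width = 12, height = 12, start_year = 800, end_year = 819,
    init_households = 6, seed = 9))
  bad <- 0L; checks <- 0L
  probe <- function(ctx) {
    la <- ctx$la
    g <- numeric(la$n)
    for (d in ctx$all_hh$dwell) {
      g <- g + ((la$xs - la$xs[d])^2 + (la$ys - la$ys[d])^2 <= 25)
    }
    if (max(abs(g - ctx$soc_grid)) > 1e-9) bad <<- bad + 1L
    w <- la$water
    act <- w[w$start_year <= ctx$year & w$end_year >= ctx$year, , drop = FALSE]
    wc <- numeric(la$n)
    for (j in seq_len(nrow(act))) {
      wc <- wc + ((la$xs - act$x[j])^2 + (la$ys - act$y[j])^2 <= 25)
    }
    if (max(abs(wc - ctx$water_cnt)) > 1e-9) bad <<- bad + 1L
    checks <<- checks + 1L
    evaluate_rule(parse_rule("argmax[S_All](F_Soc + F_Water)"), ctx)
  }
  run_simulation(env, draw_params(seed = 2), probe, seed = 3)
  expect_gt(checks, 20)
  expect_equal(bad, 0L)
})
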