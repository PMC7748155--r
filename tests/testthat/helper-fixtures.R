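# Fixtures and independent oracles, all built in code.

# small single-zone landscape: every cell quality `quality`, constant yield
tiny_landscape <- function(width = 3, height = 3, yield = 800, years = 800:802,
                           quality = 1, water_xy = c(0, 0), zone = 0L) {
  cells <- expand.grid(x = 0:(width - 1), y = 0:(height - 1))
  attr(cells, "out.attrs") <- NULL
  cells$zone <- zone
  cells$quality <- quality
  cells$water_body <- FALSE
  yields <- data.frame(zone = zone, year = years, baseline_yield = yield)
  water <- data.frame(x = water_xy[1], y = water_xy[2],
                      start_year = years[1], end_year = years[length(years)])
  target <- data.frame(year = years, households = 1L)
  landscape(cells, yields, water, target, years[1], years[length(years)])
}

# deterministic parameter set for hand-traced scenarios
trace_params <- function(need = 800, adjustment = 1, variance = 0,
                         fertility = 0, death_age = 200) {
  draw_params(list(
    water_source_distance = c(10, 10),
    min_death_age = c(death_age, death_age), death_age_span = c(0, 0),
    min_fertility = c(fertility, fertility), fertility_span = c(0, 0),
    min_fertility_ends_age = c(30, 30), fertility_ends_age_span = c(0, 0),
    base_nutrition_need = c(need, need),
    harvest_adjustment = c(adjustment, adjustment),
    harvest_variance = c(variance, variance),
    maize_gift_to_child = c(0.45, 0.45)
  ))
}

# the reduced synthetic testbed used for the planted-rule experiments
recovery_env <- function(rule, seed) {
  generate_synthetic_environment(synthetic_env_spec(
    width = 16, height = 16, quality_corr_length = 1,
    start_year = 800, end_year = 839, init_households = 10,
    water_density = 0.02, yield_mean_range = c(330, 500),
    yield_sd_frac = 0.2, rule = rule, seed = seed))
}

# random decision context over a random landscape with random households
fuzz_context <- function(seed) {
  set.seed(seed)
  w <- sample(4:8, 1); h <- sample(4:8, 1)
  nz <- sample(1:3, 1)
  years <- 800:802
  cells <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  cells$zone <- sample(0:(nz - 1), nrow(cells), replace = TRUE)
  cells$quality <- round(runif(nrow(cells)), 6)
  cells$water_body <- runif(nrow(cells)) < 0.1
  if (all(cells$water_body)) cells$water_body[1] <- FALSE
  yields <- expand.grid(zone = 0:(nz - 1), year = years)
  yields$baseline_yield <- round(runif(nrow(yields), 100, 1000), 3)
  nw <- sample(0:2, 1)
  water <- data.frame(x = sample(0:(w - 1), nw, replace = TRUE),
                      y = sample(0:(h - 1), nw, replace = TRUE),
                      start_year = rep(800L, nw), end_year = rep(802L, nw))
  target <- data.frame(year = years, households = 1L)
  l <- landscape(cells, yields, water, target, 800, 802)
  free <- which(!l$cells$water_body)
  nh <- sample(1:min(6, length(free)), 1)
  spots <- sample(free, min(2 * nh, length(free)))
  farms <- spots[seq_len(nh)]
  dwells <- if (length(spots) >= 2 * nh) spots[nh + seq_len(nh)] else farms
  hh <- data.frame(
    id = seq_len(nh),
    parent_id = c(NA, sample(c(NA, seq_len(nh - 1)), nh - 1, replace = TRUE))[seq_len(nh)],
    age = sample(0:40, nh, replace = TRUE),
    corn = round(runif(nh, 0, 500), 3),
    farm_x = cell_x(farms, w), farm_y = cell_y(farms, w),
    dwell_x = cell_x(dwells, w), dwell_y = cell_y(dwells, w)
  )
  ly <- numeric(w * h)
  touched <- sample(w * h, sample(0:5, 1))
  ly[touched] <- round(runif(length(touched), 0, 900), 3)
  decision_context(l, hh, self_id = sample(nh, 1), year = sample(years, 1),
                   last_yield = ly)
}

# scalar tree evaluation per candidate: the brute-force argmax oracle
eval_node_scalar <- function(node, subs, i) {
  if (node$kind == "factor") return(subs[[node$name]][i])
  a <- eval_node_scalar(node$args[[1]], subs, i)
  b <- eval_node_scalar(node$args[[2]], subs, i)
  if (node$op == "add") a + b else a - b
}

brute_force_scores <- function(rule, ctx, opts = sim_options()) {
  cand <- sort(candidate_subset(rule$connectivity, ctx, opts))
  if (length(cand) == 0) return(NULL)
  subs <- sapply(emdisc:::factor_names, function(f) factor_subscore(f, cand, ctx, opts),
                 simplify = FALSE)
  list(cand = cand,
       score = vapply(seq_along(cand), function(i) eval_node_scalar(rule$root, subs, i),
                      numeric(1)))
}

# independent presence oracle: evaluate the tree numerically at basis vectors
presence_by_expansion <- function(rule) {
  node <- if (inherits(rule, "emd_rule")) rule$root else rule
  fn <- emdisc:::factor_names
  out <- vapply(seq_along(fn), function(k) {
    subs <- lapply(fn, function(f) if (f == fn[k]) 1 else 0)
    names(subs) <- fn
    eval_node_scalar(node, subs, 1)
  }, numeric(1))
  names(out) <- fn
  out
}

# random well-typed rule tree for property tests
random_rule <- function(seed, max_depth = 6) {
  set.seed(seed)
  gen <- function(d) {
    if (d <= 0 || runif(1) < 0.4) {
      return(emdisc:::node_factor(sample(emdisc:::factor_names, 1)))
    }
    emdisc:::node_op(sample(c("add", "sub"), 1), gen(d - 1), gen(d - 1))
  }
  rule_tree(gen(sample(1:max_depth, 1)),
            sample(emdisc:::connectivity_names, 1))
}

# hard-coded nearest-available-plot strategy (full information)
nearest_plot_strategy <- function(ctx) {
  cand <- ctx$avail
  if (length(cand) == 0) return(NA_integer_)
  la <- ctx$la
  d2 <- (la$xs[cand] - la$xs[ctx$self$ref_farm])^2 +
    (la$ys[cand] - la$ys[ctx$self$ref_farm])^2
  cand[which.min(d2)]
}

# exhaustive Mann-Whitney null by bitmask enumeration of group assignments
mw_enum_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); n1 <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  us <- c()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(bitwShiftL(1, 0:(n - 1)), mask) > 0)
    if (length(idx) != n1) next
    us <- c(us, u_of(pool[idx], pool[-idx]))
  }
  mean(us <= u_obs + 1e-9)
}

# synthetic presence->fitness table with planted main effects
planted_table <- function(n, seed, effect = c(Qual = 30, Soc = -10, Mig = 5),
                          noise_sd = 5, interaction = NULL) {
  set.seed(seed)
  tab <- as.data.frame(matrix(sample(-2:4, n * 9, replace = TRUE), ncol = 9))
  names(tab) <- emdisc:::factor_names
  tab$connectivity <- "S_All"
  y <- rnorm(n, 0, noise_sd)
  for (f in names(effect)) y <- y + effect[[f]] * tab[[f]]
  if (!is.null(interaction)) {
    y <- y + 20 * (tab[[interaction[1]]] > 0 & tab[[interaction[2]]] > 0)
  }
  tab$fitness <- y
  tab$run <- 1L; tab$generation <- 0L
  tab
}
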