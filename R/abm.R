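# Annual-step household demographic simulator with a pluggable
# farm-plot-selection strategy.
#
# Step order within a year t: (1) harvest every farm; (2) consume the annual
# nutrition need, oldest vintage first, discarding maize older than two
# harvests; (3) remove households that outlived their death age; (4)
# households whose realized harvest fell short of the need relocate via the
# strategy (no admissible farm or dwelling => removal); (5) fertile
# households with at least one year's need in store may fission, the child
# receiving a fraction of the parent's stock and invoking the strategy for
# its own farm; (6) ages advance. Agent processing order is re-randomized
# every year from the run RNG.

# ---- internal state ---------------------------------------------------------

new_sim_state <- function(landscape, params, opts) {
  la <- landscape_arrays(landscape)
  e <- new.env(parent = emptyenv())
  e$la <- la; e$params <- params; e$opts <- opts
  e$year <- landscape$start_year
  e$id <- integer(0); e$parent <- integer(0); e$grand <- integer(0)
  e$age <- numeric(0); e$v1 <- numeric(0); e$v2 <- numeric(0)
  e$death_age <- numeric(0); e$fert_end <- numeric(0); e$fert <- numeric(0)
  e$farm <- integer(0); e$dwell <- integer(0)
  e$farms_occ <- rep(FALSE, la$n); e$dwell_cnt <- integer(la$n)
  e$last_yield <- numeric(la$n)
  e$next_id <- 1L
  e$water_sig <- ""
  r <- opts$social_radius
  g <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r))
  disk <- g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
  # per-cell neighbourhoods within the social radius, precomputed once
  e$disk_nb <- lapply(seq_len(la$n), function(cell) {
    nx <- la$xs[cell] + disk$dx; ny <- la$ys[cell] + disk$dy
    ok <- nx >= 0 & nx < la$width & ny >= 0 & ny < la$height
    as.integer(ny[ok]) * la$width + as.integer(nx[ok]) + 1L
  })
  e$soc_grid <- numeric(la$n) # households dwelling within social radius, per cell
  e
}

disk_cells <- function(st, cell) st$disk_nb[[cell]]

add_dwell <- function(st, cell) {
  st$dwell_cnt[cell] <- st$dwell_cnt[cell] + 1L
  i <- disk_cells(st, cell)
  st$soc_grid[i] <- st$soc_grid[i] + 1
  invisible()
}

rem_dwell <- function(st, cell) {
  st$dwell_cnt[cell] <- st$dwell_cnt[cell] - 1L
  i <- disk_cells(st, cell)
  st$soc_grid[i] <- st$soc_grid[i] - 1
  invisible()
}

update_water <- function(st) {
  w <- st$la$water
  act <- which(w$start_year <= st$year & w$end_year >= st$year)
  sig <- paste(act, collapse = ",")
  if (identical(sig, st$water_sig)) return(invisible())
  st$water_sig <- sig
  la <- st$la
  if (length(act) == 0) {
    st$water_dist <- rep(Inf, la$n)
  } else {
    d <- rep(Inf, la$n)
    for (j in act) {
      dj <- sqrt((la$xs - w$x[j])^2 + (la$ys - w$y[j])^2)
      d <- pmin(d, dj)
    }
    st$water_dist <- d
  }
  st$dwell_ok <- !la$water_body & st$water_dist <= st$params$water_source_distance
  st$dwell_cells <- which(st$dwell_ok)
  wc <- numeric(la$n)
  for (j in act) {
    src <- cell_index(w$x[j], w$y[j], la$width)
    i <- disk_cells(st, src)
    wc[i] <- wc[i] + 1
  }
  st$water_cnt <- wc # active water sources within social radius, per cell
  invisible()
}

shuffle <- function(x) if (length(x) <= 1) x else sample(x)

avail_cells <- function(st) {
  which(!st$farms_occ & st$dwell_cnt == 0L & !st$la$water_body)
}

make_ctx <- function(st, self) {
  others <- if (is.na(self$id)) seq_along(st$id) else which(st$id != self$id)
  list(
    la = st$la, year = st$year, yearcol = match(st$year, st$la$years),
    avail = avail_cells(st), last_yield = st$last_yield,
    soc_grid = st$soc_grid, water_cnt = st$water_cnt, dry_raw = st$dry_raw,
    hh = list(id = st$id[others], parent = st$parent[others],
              age = st$age[others], corn = st$v1[others] + st$v2[others],
              farm = st$farm[others], dwell = st$dwell[others]),
    all_hh = list(id = st$id, corn = st$v1 + st$v2, dwell = st$dwell),
    self = self
  )
}

choose_farm <- function(st, strategy, self) {
  ctx <- make_ctx(st, self)
  if (is.function(strategy)) return(strategy(ctx))
  cand <- candidate_subset(strategy$connectivity, ctx, st$opts)
  if (length(cand) == 0) return(NA_integer_)
  ctx$candidates <- cand
  evaluate_rule(strategy, ctx, st$opts)
}

site_dwelling <- function(st, farm_idx) {
  cand <- st$dwell_cells # non-water cells within reach of active water
  cells <- cand[!st$farms_occ[cand] & cand != farm_idx]
  if (length(cells) == 0) return(NA_integer_)
  la <- st$la
  d2 <- (la$xs[cells] - la$xs[farm_idx])^2 + (la$ys[cells] - la$ys[farm_idx])^2
  cells[which.min(d2)]
}

remove_rows <- function(st, rows) {
  if (length(rows) == 0) return(invisible())
  st$farms_occ[st$farm[rows]] <- FALSE
  for (d in st$dwell[rows]) rem_dwell(st, d)
  keep <- setdiff(seq_along(st$id), rows)
  for (f in c("id", "parent", "grand", "age", "v1", "v2", "death_age",
              "fert_end", "fert", "farm", "dwell")) {
    st[[f]] <- st[[f]][keep]
  }
  invisible()
}

add_household <- function(st, parent_row, farm_idx, dwell_idx, g1, g2) {
  p <- st$params
  st$id <- c(st$id, st$next_id)
  st$parent <- c(st$parent, if (is.null(parent_row)) NA_integer_ else st$id[parent_row])
  st$grand <- c(st$grand, if (is.null(parent_row)) NA_integer_ else st$parent[parent_row])
  st$age <- c(st$age, 0)
  st$v1 <- c(st$v1, g1); st$v2 <- c(st$v2, g2)
  st$death_age <- c(st$death_age, p$min_death_age + runif(1, 0, p$death_age_span))
  st$fert_end <- c(st$fert_end, p$min_fertility_ends_age + runif(1, 0, p$fertility_ends_age_span))
  st$fert <- c(st$fert, p$min_fertility + runif(1, 0, p$fertility_span))
  st$farm <- c(st$farm, farm_idx); st$farms_occ[farm_idx] <- TRUE
  st$dwell <- c(st$dwell, dwell_idx); add_dwell(st, dwell_idx)
  st$next_id <- st$next_id + 1L
  invisible()
}

init_population <- function(st, n) {
  update_water(st)
  la <- st$la
  avail <- avail_cells(st)
  ord <- avail[order(-la$quality[avail], avail)]
  placed <- 0L
  for (cell in ord) {
    if (placed >= n) break
    d <- site_dwelling(st, cell)
    if (is.na(d)) next
    add_household(st, NULL, cell, d, st$params$base_nutrition_need, 0)
    placed <- placed + 1L
  }
  st$age <- floor(runif(length(st$age), 0, st$opts$init_age_max + 1))
  invisible()
}

# one simulated year; returns the ledger of corn flows
sim_step <- function(st, strategy) {
  update_water(st)
  la0 <- st$la
  st$dry_raw <- -la0$yield_mat[cbind(la0$zone, match(st$year, la0$years))]
  p <- st$params
  ledger <- c(before = sum(st$v1 + st$v2), harvested = 0, consumed = 0,
              discarded = 0, removed = 0)
  nh <- length(st$id)
  if (nh > 0) {
    la <- st$la
    yearcol <- match(st$year, la$years)
    base <- la$yield_mat[cbind(la$zone[st$farm], yearcol)]
    eps <- rnorm(nh, 0, p$harvest_variance)
    h <- pmax(base * la$quality[st$farm] * p$harvest_adjustment * (1 + eps), 0)
    st$last_yield[st$farm] <- h
    ledger["harvested"] <- sum(h)
    need <- p$base_nutrition_need
    e2 <- pmin(st$v2, need)
    e1 <- pmin(st$v1, need - e2)
    eh <- pmin(h, need - e2 - e1)
    ledger["consumed"] <- sum(e2 + e1 + eh)
    ledger["discarded"] <- sum(st$v2 - e2)
    st$v2 <- st$v1 - e1
    st$v1 <- h - eh
    est <- h # realized harvest = estimate of next year's harvest
    names(est) <- st$id

    dead <- which(st$age > st$death_age)
    ledger["removed"] <- ledger["removed"] + sum(st$v1[dead] + st$v2[dead])
    remove_rows(st, dead)

    mover_ids <- intersect(as.integer(names(est)[est < need]), st$id)
    for (mid in shuffle(mover_ids)) {
      j <- match(mid, st$id)
      self <- list(id = mid, parent = st$parent[j], grandparent = st$grand[j],
                   ref_farm = st$farm[j], zone = st$la$zone[st$farm[j]],
                   age = st$age[j], corn = st$v1[j] + st$v2[j],
                   dwell = st$dwell[j], in_grid = TRUE)
      choice <- choose_farm(st, strategy, self)
      if (is.na(choice)) {
        ledger["removed"] <- ledger["removed"] + st$v1[j] + st$v2[j]
        remove_rows(st, j)
        next
      }
      st$farms_occ[st$farm[j]] <- FALSE # the failed farm is abandoned
      d <- site_dwelling(st, choice)
      if (is.na(d)) {
        ledger["removed"] <- ledger["removed"] + st$v1[j] + st$v2[j]
        remove_rows(st, j)
        next
      }
      st$farm[j] <- choice; st$farms_occ[choice] <- TRUE
      rem_dwell(st, st$dwell[j])
      st$dwell[j] <- d; add_dwell(st, d)
    }

    need1 <- p$base_nutrition_need
    elig <- st$id[st$age >= st$opts$fertility_start_age &
                    st$age < st$fert_end & st$v1 + st$v2 >= need1]
    for (pid in shuffle(elig)) {
      j <- match(pid, st$id)
      if (is.na(j)) next
      if (runif(1) >= st$fert[j]) next
      g1 <- p$maize_gift_to_child * st$v1[j]
      g2 <- p$maize_gift_to_child * st$v2[j]
      child <- list(id = NA_integer_, parent = pid, grandparent = st$parent[j],
                    ref_farm = st$farm[j], zone = st$la$zone[st$farm[j]],
                    age = 0, corn = g1 + g2, dwell = st$dwell[j], in_grid = FALSE)
      choice <- choose_farm(st, strategy, child)
      d <- if (is.na(choice)) NA_integer_ else site_dwelling(st, choice)
      st$v1[j] <- st$v1[j] - g1
      st$v2[j] <- st$v2[j] - g2
      if (is.na(choice) || is.na(d)) {
        # child could not establish itself; it is removed along with its gift
        ledger["removed"] <- ledger["removed"] + g1 + g2
      } else {
        add_household(st, j, choice, d, g1, g2)
      }
    }
    st$age <- st$age + 1
  }
  st$year <- st$year + 1L
  ledger["after"] <- sum(st$v1 + st$v2)
  ledger
}

# ---- public state conversion ------------------------------------------------

st_to_public <- function(st) {
  la <- st$la
  list(
    year = st$year,
    households = data.frame(
      id = st$id, parent_id = st$parent, grandparent_id = st$grand,
      age = st$age, corn_new = st$v1, corn_old = st$v2,
      death_age = st$death_age, fertility_end_age = st$fert_end,
      fertility = st$fert,
      farm_x = cell_x(st$farm, la$width), farm_y = cell_y(st$farm, la$width),
      dwell_x = cell_x(st$dwell, la$width), dwell_y = cell_y(st$dwell, la$width)
    ),
    last_yield = st$last_yield
  )
}

public_to_st <- function(state, landscape, params, opts) {
  st <- new_sim_state(landscape, params, opts)
  st$year <- state$year
  h <- state$households
  if (nrow(h) > 0) {
    st$id <- as.integer(h$id); st$parent <- as.integer(h$parent_id)
    st$grand <- as.integer(h$grandparent_id)
    st$age <- h$age; st$v1 <- h$corn_new; st$v2 <- h$corn_old
    st$death_age <- h$death_age; st$fert_end <- h$fertility_end_age
    st$fert <- h$fertility
    st$farm <- cell_index(h$farm_x, h$farm_y, st$la$width)
    st$dwell <- cell_index(h$dwell_x, h$dwell_y, st$la$width)
    st$farms_occ[st$farm] <- TRUE
    for (d in st$dwell) add_dwell(st, d)
    st$next_id <- max(st$id) + 1L
  }
  if (!is.null(state$last_yield)) st$last_yield <- state$last_yield
  st
}

#' Advance the simulation by one year
#'
#' Functional single-step interface over the simulator: applies harvest,
#' consumption, ageing-out, strategy-driven relocation and fission for the
#' state's current year and returns the state at the next year. The corn
#' ledger of the step (harvest inflow, consumption, vintage discard, corn of
#' removed households) is attached as attribute `"ledger"`; within one step
#' `before + harvested - consumed - discarded - removed == after` holds to
#' numerical precision.
#'
#' @param state List with `year`, a `households` data frame (see
#'   [run_simulation()] for the columns) and a `last_yield` vector.
#' @param landscape An [landscape()] object.
#' @param params An `emd_params` set, see [draw_params()].
#' @param strategy An `emd_rule`, a rule string, or `function(context)`
#'   returning a cell index.
#' @param opts See [sim_options()].
#' @param seed Optional seed for the step's randomness.
#' @return The successor state (same shape as `state`).
#' @export
step_year <- function(state, landscape, params, strategy, opts = sim_options(),
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(strategy)) strategy <- parse_rule(strategy)
  st <- public_to_st(state, landscape, params, opts)
  ledger <- sim_step(st, strategy)
  out <- st_to_public(st)
  attr(out, "ledger") <- ledger
  out
}

#' Run a full simulation and score it against the target series
#'
#' Places the initial population (the target series' first value by default)
#' on the highest-quality available plots with dwellings sited near water,
#' then iterates [step_year()] over the landscape span. The annual household
#' count is recorded at the start of each year, so the first recorded count
#' equals the initial population. Fitness is the root-mean-square error
#' between the simulated and target counts over all years of the span.
#'
#' @param landscape An [landscape()] object.
#' @param params An `emd_params` set ([draw_params()]).
#' @param strategy An `emd_rule`, a rule string in the canonical grammar, or
#'   a `function(context)` returning a cell index (`NA` = no admissible
#'   plot).
#' @param init_n Initial household count; defaults to the first value of the
#'   landscape's target series.
#' @param seed Optional integer seed covering every source of randomness in
#'   the run.
#' @param opts See [sim_options()].
#' @return Object of class `emd_sim`: list with `counts` (named integer
#'   vector over years), `rmse`, `ledgers` (per-year corn flows, a matrix),
#'   and the `params`/`seed`/`strategy` used.
#' @export
run_simulation <- function(landscape, params, strategy, init_n = NULL,
                           seed = NULL, opts = sim_options()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(strategy)) strategy <- parse_rule(strategy)
  if (inherits(strategy, "emd_rule")) attr(strategy, "presence") <- extract_presence(strategy)
  la_target <- landscape$target
  if (is.null(init_n)) init_n <- la_target$households[match(landscape$start_year, la_target$year)]
  st <- new_sim_state(landscape, params, opts)
  init_population(st, init_n)
  years <- landscape$start_year:landscape$end_year
  counts <- integer(length(years))
  ledgers <- matrix(NA_real_, nrow = length(years) - 1L, ncol = 6,
                    dimnames = list(NULL, c("before", "harvested", "consumed",
                                            "discarded", "removed", "after")))
  for (k in seq_along(years)) {
    counts[k] <- length(st$id)
    if (k < length(years)) ledgers[k, ] <- sim_step(st, strategy)[colnames(ledgers)]
  }
  names(counts) <- years
  target <- la_target$households[match(years, la_target$year)]
  structure(list(
    counts = counts, rmse = sqrt(mean((counts - target)^2)),
    ledgers = ledgers, params = params, seed = seed,
    strategy = if (is.function(strategy)) "<function>" else format_rule(strategy)
  ), class = "emd_sim")
}

#' @export
print.emd_sim <- function(x, ...) {
  cat("<emd_sim> ", length(x$counts), " years, final count ",
      x$counts[length(x$counts)], ", RMSE ", round(x$rmse, 3), "\n", sep = "")
  invisible(x)
}
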