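# Factor sub-scores and social connectivity candidate subsets.

#' Behaviour options for rule evaluation and the simulator
#'
#' @param neighbor_radius Radius (cells) within which plots are "known" to a
#'   household and within which other households count as neighbors.
#' @param perf_k Number of top households (by corn stock) whose knowledge is
#'   pooled under the `S_Perf` connectivity.
#' @param social_radius Radius (cells) used by the social presence, homophily
#'   and water-availability factors.
#' @param fertility_start_age Age (years) at which a household may fission.
#' @param dist_farther Orientation of the distance factor: `TRUE` (default)
#'   scores farther plots higher, so `argmax(-F_Dist)` is the classical
#'   nearest-available-plot strategy; `FALSE` flips the orientation.
#' @param init_age_max Upper bound (years) of the uniform initial-age draw at
#'   population setup.
#' @return Named list of options.
#' @export
sim_options <- function(neighbor_radius = 10, perf_k = 10, social_radius = 5,
                        fertility_start_age = 16, dist_farther = TRUE,
                        init_age_max = 25) {
  list(neighbor_radius = neighbor_radius, perf_k = perf_k,
       social_radius = social_radius, fertility_start_age = fertility_start_age,
       dist_farther = dist_farther, init_age_max = init_age_max)
}

minmax01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (!is.finite(lo) || hi - lo < 1e-12) return(rep(0.5, length(x)))
  (x - lo) / (hi - lo)
}

#' Build a decision context from explicit tables
#'
#' Assembles the state a deciding household sees when choosing a farm plot:
#' the landscape, the other households (positions, ages, corn stocks), the
#' occupancy-derived available plots, and the decider's own reference
#' location and attributes. The simulator builds equivalent contexts
#' internally; this constructor exists for direct rule evaluation and for
#' tests.
#'
#' @param landscape An [landscape()] object.
#' @param households `data.frame(id, parent_id, age, corn, farm_x, farm_y,
#'   dwell_x, dwell_y)`; `parent_id` may be `NA`. Farms and dwellings of
#'   these households define the occupancy.
#' @param self_id Id of the deciding household (must appear in
#'   `households`).
#' @param year Calendar year within the landscape span.
#' @param last_yield Optional numeric vector (length `width * height`) of
#'   last year's realized per-cell yield; defaults to all zero (never
#'   farmed).
#' @return A context list consumed by [evaluate_rule()],
#'   [candidate_subset()] and [factor_subscore()].
#' @export
decision_context <- function(landscape, households, self_id, year,
                             last_yield = NULL) {
  la <- landscape_arrays(landscape)
  h <- households
  farm <- cell_index(h$farm_x, h$farm_y, la$width)
  dwell <- cell_index(h$dwell_x, h$dwell_y, la$width)
  farms_occ <- rep(FALSE, la$n); farms_occ[farm] <- TRUE
  dwell_cnt <- integer(la$n)
  for (d in dwell) dwell_cnt[d] <- dwell_cnt[d] + 1L
  avail <- which(!farms_occ & dwell_cnt == 0L & !la$water_body)
  i <- match(self_id, h$id)
  if (is.na(i)) stop("self_id not found among households")
  grand <- h$parent_id[match(h$parent_id, h$id)]
  others <- setdiff(seq_len(nrow(h)), i)
  list(
    la = la, year = year, yearcol = match(year, la$years),
    avail = avail,
    last_yield = if (is.null(last_yield)) numeric(la$n) else last_yield,
    hh = list(id = h$id[others], parent = h$parent_id[others],
              age = h$age[others], corn = h$corn[others],
              farm = farm[others], dwell = dwell[others]),
    all_hh = list(id = h$id, corn = h$corn, dwell = dwell),
    self = list(id = h$id[i], parent = h$parent_id[i], grandparent = grand[i],
                ref_farm = farm[i], zone = la$zone[farm[i]],
                age = h$age[i], corn = h$corn[i], dwell = dwell[i],
                in_grid = TRUE)
  )
}

# available plots within radius r of each of `centers` (cell indices)
known_plots <- function(ctx, centers, r) {
  if (length(centers) == 0) return(integer(0))
  la <- ctx$la
  av <- ctx$avail
  d2 <- outer(la$xs[av], la$xs[centers], "-")^2 + outer(la$ys[av], la$ys[centers], "-")^2
  av[.rowSums(d2 <= r * r, length(av), length(centers)) > 0]
}

#' Candidate plots under a social connectivity configuration
#'
#' The connectivity fixes which available plots the deciding household can
#' compare: `S_All` pools complete knowledge of the landscape; `S_Fam` pools
#' the knowledge of the household itself, its parent, siblings and surviving
#' grandparent; `S_Neigh` pools the knowledge of households dwelling within
#' the neighbor radius of the decider; `S_Perf` pools the knowledge of the
#' `perf_k` households with the largest corn stocks. A household "knows" the
#' available plots within the neighbor radius of its dwelling.
#'
#' @param connectivity One of `"S_All"`, `"S_Fam"`, `"S_Neigh"`, `"S_Perf"`.
#' @param context A decision context ([decision_context()]).
#' @param opts See [sim_options()].
#' @return Ascending integer vector of candidate cell indices (possibly
#'   empty).
#' @export
candidate_subset <- function(connectivity, context, opts = sim_options()) {
  if (!connectivity %in% connectivity_names) {
    stop("unknown connectivity: ", connectivity)
  }
  ctx <- context
  if (connectivity == "S_All") return(ctx$avail)
  r <- opts$neighbor_radius
  hh <- ctx$hh
  centers <- if (connectivity == "S_Fam") {
    p <- ctx$self$parent; g <- ctx$self$grandparent
    fam <- (!is.na(p) & hh$id == p) |                          # parent
      (!is.na(p) & !is.na(hh$parent) & hh$parent == p) |       # siblings
      (!is.na(g) & hh$id == g)                                 # grandparent
    fam[is.na(fam)] <- FALSE
    c(ctx$self$dwell, hh$dwell[fam])
  } else if (connectivity == "S_Neigh") {
    la <- ctx$la
    dx <- la$xs[hh$dwell] - la$xs[ctx$self$dwell]
    dy <- la$ys[hh$dwell] - la$ys[ctx$self$dwell]
    c(ctx$self$dwell, hh$dwell[dx * dx + dy * dy <= r * r])
  } else { # S_Perf
    all <- ctx$all_hh
    top <- order(-all$corn, all$id)[seq_len(min(opts$perf_k, length(all$id)))]
    all$dwell[top]
  }
  # known_plots scans the ascending avail vector, so the result is sorted
  known_plots(ctx, unique(centers), r)
}

#' Factor sub-scores over a candidate set
#'
#' Each factor maps a raw per-plot statistic to a desirability sub-score via
#' min-max normalization over the candidate set, so every sub-score lies in
#' `[0, 1]`; when all candidates share the same raw value the sub-score is
#' the neutral 0.5. The migration factor is binary (1 for plots in a
#' different zone than the decider's current zone, 0 otherwise) and is not
#' normalized.
#'
#' Raw statistics: `Dist` Euclidean distance from the current farm (higher
#' sub-score = farther by default, see [sim_options()]); `Dry` dryness of the
#' plot's zone this year, measured as the negated baseline yield; `Qual`
#' soil quality; `Yield` last year's realized yield on the plot (0 if never
#' farmed); `Water` count of active water sources within the social radius;
#' `Soc` count of households dwelling within the social radius; `HAge` /
#' `HAgri` negated mean absolute difference between the decider's age / corn
#' stock and that of households within the social radius (plots with no
#' household in radius take the worst observed raw value).
#'
#' @param factor Factor name, with or without the `F_` prefix.
#' @param plots Integer vector of candidate cell indices (the normalization
#'   set).
#' @param context Decision context.
#' @param opts See [sim_options()].
#' @return Numeric vector of sub-scores in `[0, 1]`, one per plot.
#' @export
factor_subscore <- function(factor, plots, context, opts = sim_options()) {
  if (substr(factor, 1, 2) == "F_") factor <- substring(factor, 3)
  if (!factor %in% factor_names) stop("unknown factor: ", factor)
  ctx <- context; la <- ctx$la; cand <- plots
  cx <- la$xs[cand]; cy <- la$ys[cand]
  near_stat <- function(values, self_value) {
    # negated mean |attribute difference| to households within social radius
    if (length(ctx$hh$id) == 0) return(numeric(length(cand)))
    r2 <- opts$social_radius^2
    hx <- la$xs[ctx$hh$dwell]; hy <- la$ys[ctx$hh$dwell]
    within <- (outer(cx, hx, "-")^2 + outer(cy, hy, "-")^2 <= r2)
    cnt <- .rowSums(within, length(cand), length(hx))
    s <- as.vector(within %*% abs(values - self_value))
    raw <- -s / pmax(cnt, 1)
    none <- cnt == 0
    if (all(none)) return(numeric(length(cand)))
    raw[none] <- min(raw[!none])
    raw
  }
  raw <- switch(factor,
    Dist = {
      d <- sqrt((cx - la$xs[ctx$self$ref_farm])^2 + (cy - la$ys[ctx$self$ref_farm])^2)
      if (opts$dist_farther) d else -d
    },
    Dry = -la$yield_mat[cbind(la$zone[cand], ctx$yearcol)],
    Qual = la$quality[cand],
    Yield = ctx$last_yield[cand],
    Water = {
      if (!is.null(ctx$water_cnt)) ctx$water_cnt[cand] else {
        w <- ctx$la$water
        act <- w[w$start_year <= ctx$year & w$end_year >= ctx$year, , drop = FALSE]
        cnt <- numeric(length(cand))
        r2 <- opts$social_radius^2
        for (j in seq_len(nrow(act))) {
          dx <- cx - act$x[j]; dy <- cy - act$y[j]
          cnt <- cnt + (dx * dx + dy * dy <= r2)
        }
        cnt
      }
    },
    Soc = {
      if (!is.null(ctx$soc_grid)) {
        # grid counts every household's dwelling; discount the decider's own
        cnt <- ctx$soc_grid[cand]
        if (isTRUE(ctx$self$in_grid)) {
          dx <- cx - la$xs[ctx$self$dwell]; dy <- cy - la$ys[ctx$self$dwell]
          cnt <- cnt - (dx * dx + dy * dy <= opts$social_radius^2)
        }
        cnt
      } else {
        cnt <- numeric(length(cand))
        r2 <- opts$social_radius^2
        for (j in seq_along(ctx$hh$id)) {
          dx <- cx - la$xs[ctx$hh$dwell[j]]; dy <- cy - la$ys[ctx$hh$dwell[j]]
          cnt <- cnt + (dx * dx + dy * dy <= r2)
        }
        cnt
      }
    },
    HAge = near_stat(ctx$hh$age, ctx$self$age),
    HAgri = near_stat(ctx$hh$corn, ctx$self$corn),
    Mig = return(as.numeric(la$zone[cand] != ctx$self$zone))
  )
  minmax01(raw)
}
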