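# Strongly-typed genetic program over rule trees, evolving against
# simulator RMSE, and the exported factor-presence to fitness table.

#' Genetic program configuration
#'
#' Defaults follow the standard protocol of the discovery pipeline: runs of
#' 100 generations over populations of 50 trees with depths between 4 and
#' 10, initialized half-and-half, with the simulator parameters re-drawn for
#' every fitness evaluation from the +/-5 percent windows
#' ([default_param_ranges()]). Variation operators (tournament size 3,
#' subtree crossover 0.8, subtree-regrow mutation 0.2) are conventional
#' defaults, all overridable.
#'
#' @param population_size Individuals per generation.
#' @param generations Generations per run (0 = initial population only).
#' @param n_runs Independent GP runs; every run contributes its evaluations
#'   to the exported table.
#' @param min_depth,max_depth Tree depth bounds (edges) enforced at
#'   initialization and after every variation.
#' @param crossover_prob,mutation_prob Per-pair / per-individual variation
#'   probabilities.
#' @param tournament_size Selection tournament size.
#' @param connectivity_mut_prob Probability that a mutation also resamples
#'   the rule's connectivity configuration.
#' @param replicates Simulator replicates averaged per fitness evaluation
#'   (default 1, the published protocol; parameters are re-drawn per
#'   replicate).
#' @param param_ranges Parameter windows used by every fitness evaluation.
#' @param connectivities Connectivity configurations sampled at
#'   initialization and by connectivity mutation.
#' @param init_n Initial household count passed to the simulator (default:
#'   the landscape target's first value).
#' @param opts Behaviour options, see [sim_options()].
#' @return List of class `emd_gp_config`.
#' @export
gp_config <- function(population_size = 50, generations = 100, n_runs = 20,
                      min_depth = 4, max_depth = 10,
                      crossover_prob = 0.8, mutation_prob = 0.2,
                      tournament_size = 3, connectivity_mut_prob = 0.2,
                      replicates = 1,
                      param_ranges = default_param_ranges(),
                      connectivities = connectivity_names,
                      init_n = NULL, opts = sim_options()) {
  stopifnot(population_size >= 2, generations >= 0, n_runs >= 1,
            replicates >= 1,
            min_depth >= 0, min_depth <= max_depth,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = population_size, generations = generations,
                 n_runs = n_runs, min_depth = min_depth, max_depth = max_depth,
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 tournament_size = tournament_size,
                 connectivity_mut_prob = connectivity_mut_prob,
                 replicates = replicates,
                 param_ranges = param_ranges, connectivities = connectivities,
                 init_n = init_n, opts = opts),
            class = "emd_gp_config")
}

# ---- tree generation --------------------------------------------------------

random_terminal <- function() node_factor(sample(factor_names, 1))
random_op <- function(a, b) node_op(sample(c("add", "sub"), 1), a, b)

# full builder: every leaf at depth == height
gen_full <- function(height) {
  if (height <= 0) return(random_terminal())
  random_op(gen_full(height - 1), gen_full(height - 1))
}

# grow builder: operators forced until min_depth, terminals possible after;
# terminal probability = terminal share of the primitive set
gen_grow <- function(height, min_depth, depth = 0) {
  n_term <- length(factor_names)
  p_term <- n_term / (n_term + 2)
  if (depth >= height || (depth >= min_depth && runif(1) < p_term)) {
    return(random_terminal())
  }
  random_op(gen_grow(height, min_depth, depth + 1),
            gen_grow(height, min_depth, depth + 1))
}

#' Initialize a GP population (half-and-half)
#'
#' Half the trees are built with the full method (all leaves at the target
#' height) and half with the grow method (leaves allowed from the minimum
#' depth on), each at a target height drawn uniformly from
#' `[min_depth, max_depth]`; every tree is well-typed by construction and
#' its depth lies within the bounds.
#'
#' @param config An [gp_config()].
#' @param seed Optional seed.
#' @return List of `population_size` `emd_rule` objects.
#' @export
init_gp_population <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  heights <- config$min_depth:config$max_depth
  lapply(seq_len(config$population_size), function(i) {
    height <- heights[sample.int(length(heights), 1)]
    root <- if (i %% 2 == 0) gen_full(height) else gen_grow(height, config$min_depth)
    rule_tree(root, sample(config$connectivities, 1))
  })
}

# ---- variation --------------------------------------------------------------

# flatten node positions as path lists for uniform subtree pick
node_paths <- function(node, path = integer(0)) {
  if (node$kind == "factor") return(list(path))
  c(list(path),
    node_paths(node$args[[1]], c(path, 1L)),
    node_paths(node$args[[2]], c(path, 2L)))
}

get_node <- function(node, path) {
  for (k in path) node <- node$args[[k]]
  node
}

set_node <- function(node, path, sub) {
  if (length(path) == 0) return(sub)
  node$args[[path[1]]] <- set_node(node$args[[path[1]]], path[-1], sub)
  node
}

# typed subtree crossover; offspring exceeding max_depth are replaced by the
# corresponding parent (depth-bound bloat control)
crossover_rules <- function(a, b, config) {
  pa <- node_paths(a$root); pb <- node_paths(b$root)
  sa <- pa[[sample.int(length(pa), 1)]]
  sb <- pb[[sample.int(length(pb), 1)]]
  na <- get_node(a$root, sa); nb <- get_node(b$root, sb)
  ra <- set_node(a$root, sa, nb)
  rb <- set_node(b$root, sb, na)
  out_a <- if (depth_node(ra) <= config$max_depth) rule_tree(ra, a$connectivity) else a
  out_b <- if (depth_node(rb) <= config$max_depth) rule_tree(rb, b$connectivity) else b
  list(out_a, out_b)
}

# subtree-regrow mutation, optionally resampling the connectivity
mutate_rule <- function(r, config) {
  paths <- node_paths(r$root)
  p <- paths[[sample.int(length(paths), 1)]]
  room <- max(0, min(3, config$max_depth - length(p)))
  sub <- gen_grow(sample.int(room + 1, 1) - 1, 0)
  root <- set_node(r$root, p, sub)
  conn <- r$connectivity
  if (runif(1) < config$connectivity_mut_prob) conn <- sample(config$connectivities, 1)
  rule_tree(root, conn)
}

tournament_select <- function(fitness, k) {
  cand <- sample.int(length(fitness), k, replace = TRUE)
  cand[which.min(fitness[cand])]
}

# deterministic per-evaluation RNG stream: (seed, run, generation, index)
derive_seed <- function(seed, run, gen, idx) {
  as.integer((as.double(seed) + 7919 * run + 104729 * gen + 611953 * idx) %% 2147483647)
}

#' Evaluate the fitness of one rule
#'
#' Draws a fresh simulator parameter set from the configured windows, runs
#' one seeded simulation under the rule, and records the RMSE against the
#' landscape target together with the rule's presence vector.
#'
#' @param rule An `emd_rule` (or rule string).
#' @param landscape An [landscape()] object.
#' @param config An [gp_config()].
#' @param seed Integer seed for the parameter draw and the simulation.
#' @return List with `rule`, `presence`, `connectivity`, `fitness`, `params`
#'   and `seed`.
#' @export
evaluate_fitness <- function(rule, landscape, config = gp_config(), seed = NULL) {
  if (is.character(rule)) rule <- parse_rule(rule)
  reps <- config$replicates %||% 1
  rmse <- numeric(reps)
  params <- NULL
  for (k in seq_len(reps)) {
    rs <- if (is.null(seed)) NULL else seed + 2L * (k - 1L)
    params <- draw_params(config$param_ranges, seed = rs)
    sim <- run_simulation(landscape, params, rule, init_n = config$init_n,
                          seed = if (is.null(rs)) NULL else rs + 1L,
                          opts = config$opts)
    rmse[k] <- sim$rmse
  }
  list(rule = rule, presence = extract_presence(rule),
       connectivity = rule$connectivity, fitness = mean(rmse),
       params = params, seed = seed)
}

#' Run the genetic programming search
#'
#' Executes `n_runs` independent GP runs. Each run initializes a
#' half-and-half population, then loops: tournament selection, typed subtree
#' crossover, typed subtree-regrow mutation (depth bounds enforced,
#' violating offspring rejected in favour of their parents), and evaluation
#' of every individual with freshly drawn simulator parameters. A
#' hall-of-fame of size 1 tracks the best evaluation ever seen in the run.
#' Every evaluation performed is appended to the factor-scores table.
#'
#' @param config An [gp_config()].
#' @param landscape An [landscape()] object.
#' @param seed Integer seed; evaluation streams are derived per
#'   (seed, run, generation, index), making the search deterministic.
#' @param progress Print per-run progress to stderr.
#' @return List of class `emd_gp_result`: `best` (per-run list of best
#'   evaluations), and `table` (`data.frame` with the nine presence columns,
#'   `connectivity`, `fitness`, `run`, `generation`; one row per
#'   evaluation).
#' @export
evolve <- function(config, landscape, seed = 1, progress = FALSE) {
  stopifnot(inherits(config, "emd_gp_config"))
  n_rows <- config$n_runs * config$population_size * (config$generations + 1)
  pres <- matrix(0L, nrow = n_rows, ncol = length(factor_names),
                 dimnames = list(NULL, factor_names))
  conn <- character(n_rows); fit <- numeric(n_rows)
  run_col <- integer(n_rows); gen_col <- integer(n_rows)
  row <- 0L
  best <- vector("list", config$n_runs)

  for (run in seq_len(config$n_runs)) {
    set.seed(derive_seed(seed, run, 0, 0))
    pop <- init_gp_population(config)
    hof <- NULL
    for (gen in 0:config$generations) {
      if (gen > 0) {
        set.seed(derive_seed(seed, run, gen, 0))
        sel <- vapply(seq_len(config$population_size), function(i) {
          tournament_select(fitness, config$tournament_size)
        }, integer(1))
        offspring <- pop[sel]
        i <- 1
        while (i + 1 <= length(offspring)) {
          if (runif(1) < config$crossover_prob) {
            pair <- crossover_rules(offspring[[i]], offspring[[i + 1]], config)
            offspring[[i]] <- pair[[1]]; offspring[[i + 1]] <- pair[[2]]
          }
          i <- i + 2
        }
        for (i in seq_along(offspring)) {
          if (runif(1) < config$mutation_prob) {
            offspring[[i]] <- mutate_rule(offspring[[i]], config)
          }
        }
        pop <- offspring
      }
      fitness <- numeric(length(pop))
      for (i in seq_along(pop)) {
        stopifnot(rule_depth(pop[[i]]) <= config$max_depth)
        ev <- evaluate_fitness(pop[[i]], landscape, config,
                               seed = derive_seed(seed, run, gen, i))
        ev$run <- run; ev$generation <- gen
        fitness[i] <- ev$fitness
        row <- row + 1L
        pres[row, ] <- ev$presence
        conn[row] <- ev$connectivity; fit[row] <- ev$fitness
        run_col[row] <- run; gen_col[row] <- gen
        if (is.null(hof) || ev$fitness < hof$fitness) hof <- ev
      }
      if (progress) {
        message(sprintf("run %d gen %d: best %.3f (hof %.3f)", run, gen,
                        min(fitness), hof$fitness))
      }
    }
    best[[run]] <- hof
  }
  table <- data.frame(pres[seq_len(row), , drop = FALSE],
                      connectivity = conn[seq_len(row)], fitness = fit[seq_len(row)],
                      run = run_col[seq_len(row)], generation = gen_col[seq_len(row)],
                      stringsAsFactors = FALSE)
  structure(list(best = best, table = table), class = "emd_gp_result")
}

#' @export
print.emd_gp_result <- function(x, ...) {
  cat("<emd_gp_result> ", length(x$best), " runs, ", nrow(x$table),
      " evaluations\n", sep = "")
  for (i in seq_along(x$best)) {
    b <- x$best[[i]]
    cat(sprintf("  run %d: %s  (RMSE %.3f)\n", i, format_rule(b$rule), b$fitness))
  }
  invisible(x)
}

#' Write the factor-scores table and per-run best rules
#'
#' `factor_scores.csv` holds one row per fitness evaluation (presence
#' columns, connectivity, fitness, run, generation); `best_rules.json` holds
#' each run's best rule in the canonical grammar with its fitness.
#'
#' @param result An `emd_gp_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_gp_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$table, file.path(dir, "factor_scores.csv"), row.names = FALSE)
  best <- lapply(seq_along(result$best), function(i) {
    b <- result$best[[i]]
    list(run = i, rule = format_rule(b$rule), fitness = b$fitness)
  })
  jsonlite::write_json(best, file.path(dir, "best_rules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a factor-scores table written by [write_gp_result()]
#' @param path Path to `factor_scores.csv`.
#' @return The evaluations `data.frame`.
#' @export
read_factor_scores <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(factor_names, "connectivity", "fitness"), names(d))
  if (length(miss) > 0) stop("factor scores file missing column: ", miss[1])
  d
}
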