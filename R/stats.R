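# One-tailed Mann-Whitney U tests, comparison matrices, presence-fitness
# summaries, and the designed-strategy robustness comparison.

#' One-tailed Mann-Whitney U test
#'
#' Tests whether the values of group A lie stochastically below (or above)
#' those of group B. The U statistic counts pairs with `a > b` (ties count
#' one half), so small U supports "less". When the smaller group has at most
#' 8 observations the null distribution is exact: the distribution function
#' of U for tie-free data, full enumeration of group assignments otherwise
#' (falling back to the normal approximation if the enumeration would exceed
#' `max_enum` assignments). Larger samples use the normal approximation with
#' tie correction. Identical constant samples give p = 1.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative `"less"` (A below B) or `"greater"`.
#' @param max_enum Enumeration budget for the exact tied case.
#' @return List with `U` (pairs `a > b` + half-ties), `p`, `n_a`, `n_b`,
#'   `method`.
#' @export
mann_whitney <- function(a, b, alternative = c("less", "greater"),
                         max_enum = 500000) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (alternative == "greater") {
    out <- mann_whitney(b, a, "less", max_enum)
    return(list(U = length(a) * length(b) - out$U, p = out$p,
                n_a = length(a), n_b = length(b), method = out$method))
  }
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_stat <- function(ra) { # U for group with ranks ra out of pooled ranks
    sum(ra) - length(ra) * (length(ra) + 1) / 2
  }
  r <- rank(pool)
  U <- u_stat(r[seq_len(n1)])
  if (all(pool == pool[1])) {
    return(list(U = U, p = 1, n_a = n1, n_b = n2, method = "degenerate"))
  }
  ties <- any(duplicated(pool))
  if (min(n1, n2) <= 8) {
    if (!ties) {
      return(list(U = U, p = stats::pwilcox(U, n1, n2), n_a = n1, n_b = n2,
                  method = "exact"))
    }
    if (choose(n1 + n2, n1) <= max_enum) {
      sets <- combn(n1 + n2, n1)
      us <- apply(sets, 2, function(i) u_stat(r[i]))
      return(list(U = U, p = mean(us <= U + 1e-9), n_a = n1, n_b = n2,
                  method = "exact-enumeration"))
    }
  }
  # normal approximation with tie correction
  nt <- n1 + n2
  tie_tab <- table(pool)
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
  if (sig2 <= 0) return(list(U = U, p = 1, n_a = n1, n_b = n2, method = "degenerate"))
  z <- (U - mu + 0.5) / sqrt(sig2)
  list(U = U, p = stats::pnorm(z), n_a = n1, n_b = n2, method = "normal")
}

#' Pairwise one-tailed Mann-Whitney comparison matrix
#'
#' For every ordered pair of groups (A, B) tests the alternative that A's
#' values are stochastically less (or greater) than B's, at level `alpha`
#' per test (no multiple-testing correction by default, a Holm adjustment is
#' available). The decision matrix is anti-symmetric: accepting A < B
#' precludes accepting B < A.
#'
#' @param groups Named list of numeric vectors (>= 2 non-empty groups).
#' @param alternative `"less"` or `"greater"`, applied to each ordered pair.
#' @param alpha Significance level per test.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Object of class `emd_mw_matrix`: matrices `U`, `p` and logical
#'   `decision` (diagonal `NA`).
#' @export
mann_whitney_matrix <- function(groups, alternative = c("less", "greater"),
                                alpha = 0.05, adjust = c("none", "holm")) {
  alternative <- match.arg(alternative)
  adjust <- match.arg(adjust)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  U <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    t <- mann_whitney(groups[[i]], groups[[j]], alternative)
    U[i, j] <- t$U; p[i, j] <- t$p
  }
  if (adjust == "holm") {
    off <- !is.na(p)
    p[off] <- stats::p.adjust(p[off], method = "holm")
  }
  structure(list(U = U, p = p, decision = p < alpha, alpha = alpha,
                 alternative = alternative),
            class = "emd_mw_matrix")
}

#' @export
print.emd_mw_matrix <- function(x, ...) {
  cat("<emd_mw_matrix> alternative: row ", x$alternative, " column (alpha ",
      x$alpha, ")\np-values:\n", sep = "")
  print(signif(x$p, 3))
  invisible(x)
}

#' Fitness distributions by factor presence
#'
#' For each factor, summarizes the fitness distribution at every presence
#' value recorded in at least `min_count` rules, and runs the pairwise
#' presence comparison (alternative: fitness at presence A below fitness at
#' presence B) between the retained values.
#'
#' @param table Factor-scores `data.frame`.
#' @param min_count Minimum number of rules a presence value must appear in.
#' @param connectivity Connectivity filter (`NULL` keeps all rows).
#' @param alpha Level for the pairwise comparisons.
#' @return List with `summary` (`data.frame(factor, presence, n, q1, median,
#'   q3)`) and `comparisons` (per-factor [mann_whitney_matrix()] results,
#'   `NULL` when fewer than two presence values survive the filter).
#' @export
presence_fitness_summary <- function(table, min_count = 200,
                                     connectivity = "S_All", alpha = 0.05) {
  if (!is.null(connectivity)) table <- table[table$connectivity == connectivity, , drop = FALSE]
  rows <- list(); comparisons <- list()
  for (f in factor_names) {
    tab <- table(table[[f]])
    keep <- as.integer(names(tab)[tab >= min_count])
    if (length(keep) == 0) next
    groups <- lapply(keep, function(v) table$fitness[table[[f]] == v])
    names(groups) <- keep
    qs <- t(vapply(groups, quantile, numeric(3), probs = c(0.25, 0.5, 0.75)))
    rows[[f]] <- data.frame(factor = f, presence = keep,
                            n = as.integer(tab[as.character(keep)]),
                            q1 = qs[, 1], median = qs[, 2], q3 = qs[, 3],
                            row.names = NULL)
    comparisons[[f]] <- if (length(groups) >= 2) {
      mann_whitney_matrix(groups, "less", alpha)
    } else NULL
  }
  list(summary = if (length(rows) > 0) do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL,
       comparisons = comparisons)
}

#' Compare designed strategies against a baseline under randomized parameters
#'
#' Runs `n_runs` seeded simulations per strategy, re-drawing the simulator
#' parameters from the configured windows for every run, and tests each
#' non-baseline strategy against the baseline with a one-tailed Mann-Whitney
#' test (alternative: the designed strategy's RMSE is stochastically lower).
#'
#' @param strategies Character vector of rules in the canonical grammar
#'   (named, or names are taken from the rule strings).
#' @param landscape An [landscape()] object.
#' @param n_runs Simulations per strategy (>= 2 for the tests; with
#'   `n_runs = 1` the tests are refused with a message).
#' @param param_ranges Parameter windows, see [default_param_ranges()].
#' @param seed Integer seed.
#' @param baseline Name (or rule string) of the baseline strategy; defaults
#'   to the last element.
#' @param init_n,opts Passed to [run_simulation()].
#' @param alpha Level for the tests.
#' @return Object of class `emd_strategy_comparison`: `rmse` (runs x
#'   strategies matrix), `tests` (`data.frame(strategy, U, p, significant)`
#'   or `NULL`), `baseline`.
#' @export
compare_strategies <- function(strategies, landscape, n_runs = 100,
                               param_ranges = default_param_ranges(), seed = 1,
                               baseline = NULL, init_n = NULL,
                               opts = sim_options(), alpha = 0.05) {
  if (is.null(names(strategies))) names(strategies) <- strategies
  if (is.null(baseline)) baseline <- names(strategies)[length(strategies)]
  stopifnot(baseline %in% names(strategies), n_runs >= 1)
  rules <- lapply(strategies, parse_rule)
  rmse <- matrix(NA_real_, nrow = n_runs, ncol = length(strategies),
                 dimnames = list(NULL, names(strategies)))
  for (s in seq_along(rules)) {
    for (r in seq_len(n_runs)) {
      es <- derive_seed(seed, s, r, 0)
      params <- draw_params(param_ranges, seed = es)
      rmse[r, s] <- run_simulation(landscape, params, rules[[s]],
                                   init_n = init_n, seed = es + 1L,
                                   opts = opts)$rmse
    }
  }
  tests <- NULL
  if (n_runs < 2) {
    message("n_runs = 1: distributions of size 1, tests refused")
  } else {
    others <- setdiff(names(strategies), baseline)
    tests <- do.call(rbind, lapply(others, function(s) {
      t <- mann_whitney(rmse[, s], rmse[, baseline], "less")
      data.frame(strategy = s, U = t$U, p = t$p, significant = t$p < alpha,
                 row.names = NULL)
    }))
  }
  structure(list(rmse = rmse, tests = tests, baseline = baseline, alpha = alpha),
            class = "emd_strategy_comparison")
}

#' @export
print.emd_strategy_comparison <- function(x, ...) {
  cat("<emd_strategy_comparison> baseline: ", x$baseline, "\n", sep = "")
  med <- apply(x$rmse, 2, median)
  for (s in colnames(x$rmse)) cat(sprintf("  %-45s median RMSE %8.3f\n", s, med[s]))
  if (!is.null(x$tests)) {
    cat("one-tailed tests vs baseline (H1: lower RMSE):\n")
    print(x$tests)
  }
  invisible(x)
}
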