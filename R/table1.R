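# Shipped benchmark fixture: the best evolved farm-selection rule of each of
# the 20 published GP runs with its fitness, and a summary report over it.

#' Load the shipped best-rules-per-run fixture
#'
#' Twenty records of (run id, canonical rule string, best fitness) from the
#' published discovery experiment on the Long House Valley model. The
#' published literature benchmark for the original nearest-plot strategy
#' after parameter calibration is an RMSE of 733.6, which
#' [table1_report()] uses as its default threshold.
#'
#' @param path Optional path to an alternative fixture file with columns
#'   `run,rule,best_fitness`.
#' @return `data.frame(run, rule, best_fitness)`.
#' @export
table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_rules.csv", package = "emdisc",
                        mustWork = TRUE)
  }
  d <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("run", "rule", "best_fitness"), names(d))
  if (length(miss) > 0) stop("fixture missing column: ", miss[1])
  d
}

#' Summarize a best-rules fixture against a fitness benchmark
#'
#' Parses every rule, extracts its presence vector, counts the runs whose
#' best fitness lies strictly below the benchmark threshold, and tabulates
#' connectivity usage.
#'
#' @param fixture A [table1_fixture()] data frame.
#' @param threshold Fitness benchmark (default: the published calibrated
#'   RMSE of the original strategy, 733.6).
#' @return Object of class `emd_table1_report`: `n_rules`, `n_below`,
#'   `threshold`, `connectivity_counts` and the `presence` matrix (one row
#'   per run).
#' @export
table1_report <- function(fixture = table1_fixture(), threshold = 733.6) {
  rules <- lapply(seq_len(nrow(fixture)), function(i) {
    tryCatch(parse_rule(fixture$rule[i]),
             error = function(e) stop("fixture row ", i, " (run ", fixture$run[i],
                                      "): ", conditionMessage(e)))
  })
  presence <- t(vapply(rules, extract_presence, integer(length(factor_names))))
  rownames(presence) <- fixture$run
  conn <- vapply(rules, function(r) r$connectivity, character(1))
  structure(list(
    n_rules = nrow(fixture),
    n_below = sum(fixture$best_fitness < threshold),
    threshold = threshold,
    connectivity_counts = table(conn),
    presence = presence
  ), class = "emd_table1_report")
}

#' @export
print.emd_table1_report <- function(x, ...) {
  cat("<emd_table1_report> ", x$n_rules, " runs, ", x$n_below,
      " with best fitness below ", x$threshold, "\n", sep = "")
  print(x$connectivity_counts)
  invisible(x)
}
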