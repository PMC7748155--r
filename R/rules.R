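# Typed rule language: factor terminals, +/- operators, one connectivity
# configuration per rule; argmax evaluation and presence extraction.

factor_names <- c("Dist", "Dry", "Qual", "Yield", "Water", "Soc", "HAge", "HAgri", "Mig")
connectivity_names <- c("S_All", "S_Fam", "S_Neigh", "S_Perf")

#' Signatures of the rule-language primitives
#'
#' Every primitive carries a return type and parameter types; a primitive may
#' feed argument slot `k` of another only when its return type equals that
#' slot's parameter type. The nine factor terminals produce a normalized
#' desirability `score` in `[0, 1]` and the two operators combine scores, so
#' the language is closed under the typing condition; [type_check_rule()]
#' enforces it and randomly generated trees satisfy it by construction.
#'
#' @return `data.frame(name, kind, arity, return_type, arg_types)`; for
#'   operators `arg_types` is a comma-separated list.
#' @export
factor_signatures <- function() {
  rbind(
    data.frame(name = paste0("F_", factor_names), kind = "terminal", arity = 0L,
               return_type = "score", arg_types = "", stringsAsFactors = FALSE),
    data.frame(name = c("Add", "Sub"), kind = "operator", arity = 2L,
               return_type = "score", arg_types = "score,score", stringsAsFactors = FALSE)
  )
}

#' Can one primitive feed an argument slot of another?
#'
#' @param parent,child Rows of [factor_signatures()] (or names).
#' @param k Argument slot of `parent` (1-based).
#' @return `TRUE` iff the child's return type equals the type of slot `k`.
#' @export
can_compose <- function(parent, child, k = 1) {
  sig <- factor_signatures()
  if (is.character(parent)) parent <- sig[sig$name == parent, ]
  if (is.character(child)) child <- sig[sig$name == child, ]
  if (nrow(parent) == 0 || nrow(child) == 0) stop("unknown primitive")
  if (parent$arity < k) return(FALSE)
  args <- strsplit(parent$arg_types, ",")[[1]]
  identical(child$return_type, args[k])
}

node_factor <- function(name) list(kind = "factor", name = name)
node_op <- function(op, a, b) list(kind = "op", op = op, args = list(a, b))

#' Construct a rule tree
#'
#' @param root Expression node built from `Add`/`Sub` nodes over factor
#'   terminals (use [parse_rule()] for the text form).
#' @param connectivity One of `"S_All"`, `"S_Fam"`, `"S_Neigh"`, `"S_Perf"`:
#'   the social connectivity configuration fixing which candidate plots the
#'   deciding household knows about.
#' @return Object of class `emd_rule`.
#' @export
rule_tree <- function(root, connectivity = "S_All") {
  connectivity <- match.arg(connectivity, connectivity_names)
  r <- structure(list(connectivity = connectivity, root = root), class = "emd_rule")
  type_check_rule(r)
  r
}

check_node <- function(node) {
  if (node$kind == "factor") {
    if (!node$name %in% factor_names) stop("unknown factor terminal: ", node$name)
    return("score")
  }
  if (node$kind != "op" || !node$op %in% c("add", "sub")) stop("unknown node kind")
  if (length(node$args) != 2) stop("operator ", node$op, " expects 2 arguments")
  ts <- vapply(node$args, check_node, character(1))
  if (!all(ts == "score")) stop("ill-typed composition under ", node$op)
  "score"
}

#' Type-check a rule tree
#'
#' Verifies that every composition in the tree satisfies the typing
#' condition of the rule language and that the whole tree returns a `score`.
#'
#' @param rule An `emd_rule`.
#' @return `TRUE` invisibly; errors on an ill-typed tree.
#' @export
type_check_rule <- function(rule) {
  if (!rule$connectivity %in% connectivity_names) stop("unknown connectivity: ", rule$connectivity)
  if (check_node(rule$root) != "score") stop("rule must return a score")
  invisible(TRUE)
}

#' Depth of a rule tree (edges on the longest root-to-leaf path)
#' @param rule An `emd_rule` or a bare expression node.
#' @return Integer depth; a lone terminal has depth 0.
#' @export
rule_depth <- function(rule) {
  node <- if (inherits(rule, "emd_rule")) rule$root else rule
  depth_node(node)
}

depth_node <- function(node) {
  if (node$kind == "factor") return(0L)
  1L + max(vapply(node$args, depth_node, integer(1)))
}

count_nodes <- function(node) {
  if (node$kind == "factor") return(1L)
  1L + sum(vapply(node$args, count_nodes, integer(1)))
}

#' Extract the factor presence vector of a rule
#'
#' Presence is the signed integer coefficient of each factor in the expanded
#' linear form of the rule tree: a terminal contributes a unit vector, `Add`
#' adds and `Sub` subtracts its children's coefficient vectors. Presence is
#' the feature representation used by the importance pipeline.
#'
#' @param rule An `emd_rule` (or bare expression node).
#' @return Named integer vector over all nine factors (zeros included), with
#'   attribute `connectivity` when a full rule is given.
#' @export
extract_presence <- function(rule) {
  node <- if (inherits(rule, "emd_rule")) rule$root else rule
  p <- presence_node(node)
  p <- structure(as.integer(p), names = factor_names)
  if (inherits(rule, "emd_rule")) attr(p, "connectivity") <- rule$connectivity
  p
}

presence_node <- function(node) {
  if (node$kind == "factor") {
    p <- numeric(length(factor_names))
    p[match(node$name, factor_names)] <- 1
    return(p)
  }
  a <- presence_node(node$args[[1]])
  b <- presence_node(node$args[[2]])
  if (node$op == "add") a + b else a - b
}

# left-deep chain of Add over a list of nodes
chain_add <- function(nodes) {
  out <- nodes[[1]]
  for (n in nodes[-1]) out <- node_op("add", out, n)
  out
}

#' Parse a rule from its canonical text form
#'
#' Grammar: `argmax[S_X](<signed terms>)` where each term is `F_Name` or
#' `k*F_Name` with a positive integer `k`, joined by `+`/`-`; e.g.
#' `"argmax[S_All](F_Qual + 2*F_Mig - F_Dist)"`. The text is the linear form
#' of the rule; the parser rebuilds a tree whose presence vector equals the
#' written coefficients (a purely negative expression is represented as a
#' zero-presence subtree minus the negated terms, since the tree language has
#' no literals).
#'
#' @param text Rule string.
#' @return An `emd_rule`.
#' @export
parse_rule <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  m <- regmatches(s, regexec("^argmax\\[([A-Za-z_]+)\\]\\((.*)\\)$", s))[[1]]
  if (length(m) != 3) stop("rule does not match 'argmax[S_X](...)': ", text)
  conn <- m[2]
  if (!conn %in% connectivity_names) stop("unknown connectivity token: ", conn)
  body <- m[3]
  if (body == "" || body == "0") stop("rule body must contain at least one factor term: ", text)
  if (substr(body, 1, 1) != "-") body <- paste0("+", body)
  terms <- regmatches(body, gregexpr("[+-][^+-]+", body))[[1]]
  if (nchar(paste(terms, collapse = "")) != nchar(body)) stop("cannot parse rule body: ", text)
  pos <- list(); neg <- list()
  for (t in terms) {
    sign <- substr(t, 1, 1)
    tm <- regmatches(t, regexec("^[+-](([0-9]+)\\*)?F_([A-Za-z]+)$", t))[[1]]
    if (length(tm) != 4) stop("cannot parse term '", t, "' in rule: ", text)
    if (!tm[4] %in% factor_names) stop("unknown factor token: F_", tm[4])
    k <- if (tm[3] == "") 1L else as.integer(tm[3])
    if (k < 1) stop("coefficient must be a positive integer in term '", t, "'")
    leaves <- replicate(k, node_factor(tm[4]), simplify = FALSE)
    if (sign == "+") pos <- c(pos, leaves) else neg <- c(neg, leaves)
  }
  root <- if (length(neg) == 0) {
    chain_add(pos)
  } else if (length(pos) == 0) {
    # no positive part: subtract the negated terms from an identically-zero subtree
    z <- node_op("sub", neg[[1]], neg[[1]])
    node_op("sub", z, chain_add(neg))
  } else {
    node_op("sub", chain_add(pos), chain_add(neg))
  }
  rule_tree(root, conn)
}

#' Format a rule in canonical text form
#'
#' Serializes the linear expansion of the tree with factors in canonical
#' order, so `format_rule(parse_rule(t))` is the canonical spelling of `t`
#' and is a fixed point of parse/format. Tree shape beyond the linear form is
#' not preserved.
#'
#' @param rule An `emd_rule`.
#' @return Rule string in the canonical grammar.
#' @export
format_rule <- function(rule) {
  p <- extract_presence(rule)
  nz <- which(p != 0)
  if (length(nz) == 0) return(paste0("argmax[", rule$connectivity, "](0)"))
  parts <- character(0)
  for (i in nz) {
    k <- abs(p[i])
    term <- paste0(if (k > 1) paste0(k, "*") else "", "F_", factor_names[i])
    parts <- c(parts, if (p[i] > 0) paste0(" + ", term) else paste0(" - ", term))
  }
  body <- paste(parts, collapse = "")
  body <- sub("^ \\+ ", "", body)
  body <- sub("^ - ", "-", body)
  paste0("argmax[", rule$connectivity, "](", body, ")")
}

#' @export
print.emd_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' Evaluate a rule over a decision context and pick the best plot
#'
#' Computes the rule's utility for every candidate plot and returns the
#' argmax. The utility of the tree equals its linear expansion
#' `sum_f presence_f * subscore_f(plot)`, which is how it is computed; factor
#' sub-scores are min-max normalized over the candidate set by
#' [factor_subscore()]. Ties are broken deterministically in favour of the
#' lowest `(y, x)` coordinate.
#'
#' @param rule An `emd_rule`.
#' @param context A decision context from [decision_context()] (or one built
#'   by the simulator). If `context$candidates` is absent it is computed for
#'   `rule$connectivity` via [candidate_subset()].
#' @param opts Behaviour options, see [sim_options()].
#' @return Chosen cell index, or `NA_integer_` when the candidate set is
#'   empty.
#' @export
evaluate_rule <- function(rule, context, opts = sim_options()) {
  cand <- context$candidates
  if (is.null(cand)) cand <- candidate_subset(rule$connectivity, context, opts)
  if (length(cand) == 0) return(NA_integer_)
  if (is.unsorted(cand)) cand <- sort(cand)
  p <- attr(rule, "presence", exact = TRUE)
  if (is.null(p)) p <- extract_presence(rule)
  ctx <- fill_context_grids(context, opts)
  la <- ctx$la; self <- ctx$self
  select_plot_cpp(
    as.integer(cand), as.numeric(p),
    la$xs, la$ys, la$zone, la$quality,
    ctx$dry_raw, ctx$last_yield, ctx$water_cnt, ctx$soc_grid,
    la$xs[self$ref_farm], la$ys[self$ref_farm], self$zone,
    la$xs[self$dwell], la$ys[self$dwell],
    isTRUE(self$in_grid),
    as.numeric(self$age), as.numeric(self$corn),
    as.numeric(la$xs[ctx$hh$dwell]), as.numeric(la$ys[ctx$hh$dwell]),
    as.numeric(ctx$hh$age), as.numeric(ctx$hh$corn),
    opts$social_radius, opts$dist_farther
  )
}

# derive the per-cell dryness, water-count and social-presence grids for
# contexts that were not built by the simulator (which caches them)
fill_context_grids <- function(ctx, opts) {
  la <- ctx$la
  if (is.null(ctx$dry_raw)) {
    ctx$dry_raw <- -la$yield_mat[cbind(la$zone, ctx$yearcol)]
  }
  r2 <- opts$social_radius^2
  if (is.null(ctx$water_cnt)) {
    w <- la$water
    act <- w[w$start_year <= ctx$year & w$end_year >= ctx$year, , drop = FALSE]
    cnt <- numeric(la$n)
    for (j in seq_len(nrow(act))) {
      cnt <- cnt + ((la$xs - act$x[j])^2 + (la$ys - act$y[j])^2 <= r2)
    }
    ctx$water_cnt <- cnt
  }
  if (is.null(ctx$soc_grid)) {
    g <- numeric(la$n)
    for (d in ctx$all_hh$dwell) {
      g <- g + ((la$xs - la$xs[d])^2 + (la$ys - la$ys[d])^2 <= r2)
    }
    ctx$soc_grid <- g
  }
  ctx
}
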