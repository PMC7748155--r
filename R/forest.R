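# Random-forest regression of fitness on factor presence, with impurity,
# permutation and decision-path joint-contribution importance.

#' Fit a random forest of fitness on factor presence
#'
#' Regresses simulation RMSE on the nine presence coefficients. The table is
#' restricted to rules using the full-information (`S_All`) connectivity by
#' default, the tree count is searched over a grid between 10 and 1000, and
#' each candidate forest is trained on 90% of the rows and scored on the
#' held-out 10%; the forest with the best held-out R-squared is kept.
#'
#' @param table Factor-scores `data.frame` (nine presence columns plus
#'   `connectivity` and `fitness`), e.g. from [evolve()].
#' @param grid Integer vector of tree counts to try.
#' @param split Training fraction.
#' @param connectivity Connectivity filter; `NULL` keeps all rows.
#' @param seed Integer seed (split and forest growth).
#' @return Object of class `emd_forest`: the fitted `ranger` forest,
#'   `n_trees`, the grid search results, the split indices, the training
#'   data and the held-out `test_r2`.
#' @export
fit_forest <- function(table, grid = c(seq(10, 100, 10), seq(150, 1000, 50)),
                       split = 0.9, connectivity = "S_All", seed = 1) {
  if (!is.null(connectivity)) table <- table[table$connectivity == connectivity, , drop = FALSE]
  if (nrow(table) < 50) {
    stop("need at least 50 rows to fit the forest, got ", nrow(table),
         if (!is.null(connectivity)) paste0(" after the ", connectivity, " filter"))
  }
  if (any(!is.finite(table$fitness))) stop("non-finite fitness in table")
  x <- as.data.frame(table[, factor_names, drop = FALSE])
  y <- table$fitness
  set.seed(seed)
  n <- nrow(x)
  train <- sort(sample.int(n, floor(split * n)))
  test <- setdiff(seq_len(n), train)
  fit_one <- function(nt) {
    ranger::ranger(x = x[train, , drop = FALSE], y = y[train],
                   num.trees = nt, mtry = 3, min.node.size = 5,
                   importance = "impurity", keep.inbag = TRUE,
                   num.threads = 1, seed = seed)
  }
  score <- function(f) {
    pred <- predict(f, x[test, , drop = FALSE], num.threads = 1)$predictions
    1 - mean((pred - y[test])^2) / max(var(y[test]), .Machine$double.eps)
  }
  r2 <- numeric(length(grid))
  best <- NULL
  for (k in seq_along(grid)) {
    f <- fit_one(grid[k])
    r2[k] <- score(f)
    if (k == 1 || r2[k] > max(r2[seq_len(k - 1)])) best <- f
  }
  n_trees <- grid[which.max(r2)]
  structure(list(forest = best, n_trees = n_trees,
                 grid = data.frame(num_trees = grid, test_r2 = r2),
                 train = train, test = test,
                 x = x, y = y, test_r2 = max(r2), seed = seed),
            class = "emd_forest")
}

#' @export
print.emd_forest <- function(x, ...) {
  cat("<emd_forest> ", x$n_trees, " trees (grid ", min(x$grid$num_trees), "-",
      max(x$grid$num_trees), "), ", length(x$train), "/", length(x$test),
      " train/test, held-out R2 ", round(x$test_r2, 3), "\n", sep = "")
  invisible(x)
}

#' Impurity (gini) importance of the presence features
#'
#' Total decrease in node variance attributed to each feature across the
#' forest's splits, normalized to sum to one.
#'
#' @param model An [fit_forest()] object.
#' @return Named numeric vector over the nine factors (non-negative, sums
#'   to 1).
#' @export
gini_importance <- function(model) {
  imp <- model$forest$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  imp[factor_names]
}

#' Permutation importance of the presence features
#'
#' Mean increase in held-out squared error when one feature column of the
#' held-out split is shuffled, over independent repeats.
#'
#' @param model An [fit_forest()] object.
#' @param repeats Number of independent shuffles per feature (>= 2).
#' @param seed Integer seed.
#' @return `data.frame(factor, importance, sd)`; `importance` is the mean
#'   error increase.
#' @export
permutation_importance <- function(model, repeats = 10, seed = 1) {
  stopifnot(repeats >= 2)
  set.seed(seed)
  xt <- model$x[model$test, , drop = FALSE]
  yt <- model$y[model$test]
  base <- mean((predict(model$forest, xt, num.threads = 1)$predictions - yt)^2)
  out <- matrix(NA_real_, nrow = repeats, ncol = length(factor_names),
                dimnames = list(NULL, factor_names))
  for (r in seq_len(repeats)) {
    for (f in factor_names) {
      xp <- xt
      xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
      out[r, f] <- mean((predict(model$forest, xp, num.threads = 1)$predictions - yt)^2) - base
    }
  }
  data.frame(factor = factor_names, importance = colMeans(out),
             sd = apply(out, 2, sd), row.names = NULL)
}

# ---- decision-path joint contributions --------------------------------------

# Exact node means of one ranger tree, reconstructed by routing the inbag
# training rows; returns node-indexed vectors (1-based nodeIDs).
tree_node_means <- function(ti, x, y, inbag) {
  left <- ti$leftChild + 1L; right <- ti$rightChild + 1L
  svar <- ti$splitvarID + 1L; sval <- ti$splitval
  terminal <- ti$terminal
  rows <- which(inbag > 0)
  w <- inbag[rows]
  cur <- rep(1L, length(rows))
  alive <- rep(TRUE, length(rows))
  sw <- numeric(nrow(ti)); swy <- numeric(nrow(ti))
  # each row contributes once to every node on its root-to-leaf path
  while (any(alive)) {
    idx <- which(alive)
    acc <- rowsum(cbind(w[idx], w[idx] * y[rows[idx]]), cur[idx])
    ids <- as.integer(rownames(acc))
    sw[ids] <- sw[ids] + acc[, 1]
    swy[ids] <- swy[ids] + acc[, 2]
    at_leaf <- terminal[cur[idx]]
    alive[idx[at_leaf]] <- FALSE
    live <- idx[!at_leaf]
    if (length(live) > 0) {
      cl <- cur[live]
      go_left <- x[cbind(rows[live], svar[cl])] <= sval[cl]
      cur[live] <- ifelse(go_left, left[cl], right[cl])
    }
  }
  list(mean = ifelse(sw > 0, swy / sw, NA_real_), visited = sw > 0)
}

route_to_leaf <- function(ti, x) {
  left <- ti$leftChild + 1L; right <- ti$rightChild + 1L
  svar <- ti$splitvarID + 1L; sval <- ti$splitval
  terminal <- ti$terminal
  cur <- rep(1L, nrow(x))
  repeat {
    live <- which(!terminal[cur])
    if (length(live) == 0) break
    cl <- cur[live]
    go_left <- x[cbind(live, svar[cl])] <= sval[cl]
    cur[live] <- ifelse(go_left, left[cl], right[cl])
  }
  cur
}

#' Joint contributions of factor subsets along decision paths
#'
#' Decomposes every forest prediction along the root-to-leaf decision path
#' of each tree: at each split, the change in the node mean prediction is
#' attributed to the set of distinct features encountered on the path up to
#' and including that split. By construction the bias (root mean) plus the
#' sum of all attributed changes reconstructs the prediction exactly, for
#' every sample; the identity is checked internally. Attributed mass is
#' aggregated in absolute value per feature subset over all samples and
#' trees, and reported for subsets of up to `max_subset` features as a share
#' of the total attributed mass.
#'
#' @param model An [fit_forest()] object.
#' @param newdata Data frame of presence features to attribute over;
#'   defaults to the model's held-out split.
#' @param max_subset Largest reported subset size.
#' @return Object of class `emd_joint`: `scores`
#'   (`data.frame(subset, size, score, mass)`, sorted by score), `bias`,
#'   `predictions`, `reconstruction`, and `conservation_error` (largest
#'   relative reconstruction error over samples).
#' @export
joint_contributions <- function(model, newdata = NULL, max_subset = 3) {
  if (is.null(newdata)) newdata <- model$x[model$test, , drop = FALSE]
  xm <- as.matrix(newdata[, factor_names, drop = FALSE])
  xtrain <- as.matrix(model$x[model$train, factor_names, drop = FALSE])
  ytrain <- model$y[model$train]
  n <- nrow(xm)
  ntree <- model$forest$num.trees
  # feature subsets on a path are encoded as 9-bit masks over the factors
  nmask <- bitwShiftL(1L, length(factor_names)) - 1L
  contrib <- matrix(0, nrow = n, ncol = nmask) # column = subset mask
  preds <- numeric(n)
  bias <- 0
  for (t in seq_len(ntree)) {
    ti <- ranger::treeInfo(model$forest, t)
    nm <- tree_node_means(ti, xtrain, ytrain, model$forest$inbag.counts[[t]])$mean
    leaves <- route_to_leaf(ti, xm)
    preds <- preds + nm[leaves]
    bias <- bias + nm[1]
    parent <- integer(nrow(ti))
    ok <- !ti$terminal
    parent[ti$leftChild[ok] + 1L] <- which(ok)
    parent[ti$rightChild[ok] + 1L] <- which(ok)
    featbit <- bitwShiftL(1L, match(as.character(ti$splitvarName), factor_names) - 1L)
    by_leaf <- split(seq_len(n), leaves)
    for (leaf_chr in names(by_leaf)) {
      leaf <- as.integer(leaf_chr)
      ids <- by_leaf[[leaf_chr]]
      path <- leaf
      while (path[1] != 1L) path <- c(parent[path[1]], path)
      if (length(path) < 2) next
      mask <- 0L
      for (k in seq_len(length(path) - 1)) {
        mask <- bitwOr(mask, featbit[path[k]])
        delta <- nm[path[k + 1]] - nm[path[k]]
        if (delta != 0) contrib[ids, mask] <- contrib[ids, mask] + delta
      }
    }
  }
  preds <- preds / ntree
  bias <- bias / ntree
  contrib <- contrib / ntree
  used <- which(colSums(contrib != 0) > 0)
  reconstruction <- bias + rowSums(contrib[, used, drop = FALSE])
  cons_err <- max(abs(reconstruction - preds) / pmax(abs(preds), 1e-12))
  mask_names <- function(mask) {
    paste(factor_names[bitwAnd(bitwShiftL(1L, seq_along(factor_names) - 1L), mask) > 0],
          collapse = "+")
  }
  mass <- colSums(abs(contrib[, used, drop = FALSE]))
  total <- sum(mass)
  size <- vapply(used, function(mk) sum(bitwAnd(bitwShiftL(1L, 0:8), mk) > 0), integer(1))
  keep <- size <= max_subset
  scores <- data.frame(subset = vapply(used[keep], mask_names, character(1)),
                       size = size[keep],
                       score = if (total > 0) mass[keep] / total else 0 * mass[keep],
                       mass = mass[keep], row.names = NULL)
  scores <- scores[order(-scores$score), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(scores = scores, bias = bias, predictions = preds,
                 reconstruction = reconstruction, conservation_error = cons_err,
                 n_samples = n),
            class = "emd_joint")
}

#' @export
print.emd_joint <- function(x, ...) {
  cat("<emd_joint> ", x$n_samples, " samples, bias ", round(x$bias, 3),
      ", max relative reconstruction error ", signif(x$conservation_error, 3),
      "\n", sep = "")
  print(head(x$scores, 10))
  invisible(x)
}
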