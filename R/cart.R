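# Regression-tree engine: recursive partitioning of a continuous response
# (wean-to-finish ADG) on lesion-prevalence predictors, with a minimum-node
# stopping rule, weakest-link cost-complexity pruning, cross-validated
# selection of the complexity parameter, and per-split ANOVA.
#
# The fitted model is piecewise constant,
#   f(x) = sum_m c_m * I{x in R_m},
# where the leaf regions R_m come from axis-aligned binary splits chosen to
# minimise the summed within-child sum of squared errors, and c_m is the
# leaf mean.

node_sse <- function(y) sum(y^2) - sum(y)^2 / length(y)

#' Best axis-aligned split of one node
#'
#' Considers every predictor and every midpoint between consecutive distinct
#' predictor values, and returns the split minimising the summed
#' within-child SSE, subject to both children containing at least `min_leaf`
#' rows. Rows with `predictor < threshold` go left. Ties are broken towards
#' the lowest predictor (column order), then the lowest threshold, so the
#' result is deterministic.
#'
#' @param y Numeric response vector.
#' @param x `data.frame` of numeric predictors (same number of rows).
#' @param min_leaf Minimum rows in each child.
#' @return `NULL` if no admissible split reduces the SSE, otherwise a list
#'   with `var`, `threshold` and `sse_reduction`.
#' @export
best_split <- function(y, x, min_leaf = 10) {
  n <- length(y)
  if (n == 0L) stop("empty node")
  stopifnot(is.data.frame(x), nrow(x) == n)
  if (n < 2L * min_leaf) return(NULL)
  sse0 <- node_sse(y)
  tol <- 1e-10 * max(sse0, 1)
  best <- NULL
  for (j in seq_along(x)) {
    xv <- x[[j]]
    ord <- order(xv)
    xs <- xv[ord]; ys <- y[ord]
    cy <- cumsum(ys); cy2 <- cumsum(ys^2)
    i <- seq_len(n - 1L)
    ok <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & (n - i >= min_leaf)
    if (!any(ok)) next
    i <- i[ok]
    sse_l <- cy2[i] - cy[i]^2 / i
    sse_r <- (cy2[n] - cy2[i]) - (cy[n] - cy[i])^2 / (n - i)
    red <- sse0 - (sse_l + sse_r)
    k <- which.max(red)                    # first max = lowest threshold
    if (red[k] > tol && (is.null(best) || red[k] > best$sse_reduction)) {
      best <- list(var = names(x)[j],
                   threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2,
                   sse_reduction = red[k])
    }
  }
  best
}

new_cart_node <- function(id, y) {
  list(id = id, n = length(y), node_mean = mean(y), sse = node_sse(y),
       split_var = NA_character_, threshold = NA_real_,
       left = NULL, right = NULL)
}

grow_node <- function(y, x, min_leaf, min_split, id_env) {
  id_env$id <- id_env$id + 1L
  node <- new_cart_node(id_env$id, y)
  if (node$n < min_split) return(node)
  sp <- best_split(y, x, min_leaf)
  if (is.null(sp)) return(node)
  node$split_var <- sp$var
  node$threshold <- sp$threshold
  left <- x[[sp$var]] < sp$threshold
  node$left <- grow_node(y[left], x[left, , drop = FALSE],
                         min_leaf, min_split, id_env)
  node$right <- grow_node(y[!left], x[!left, , drop = FALSE],
                          min_leaf, min_split, id_env)
  node
}

#' Grow a regression tree
#'
#' Recursive top-down partitioning: earlier splits are never revisited.
#' Growth stops in a node when it has fewer than `min_split` rows or no
#' admissible split reduces the SSE. The default stopping rule requires 10
#' rows in every branch and leaf, i.e. `min_leaf = 10`, `min_split = 20`.
#' No complexity pre-pruning is applied while growing; use [cp_table()] and
#' [prune()] for size selection.
#'
#' @param cohort `data.frame` containing the response and predictor columns.
#' @param response Response column name (default `"adg"`).
#' @param predictors Predictor column names (default: the six
#'   lesion-prevalence columns).
#' @param min_leaf Minimum rows in any branch or leaf (default 10).
#' @param min_split Minimum rows required to attempt a split (default
#'   `2 * min_leaf`).
#' @return An object of class `cart_tree`.
#' @export
grow_tree <- function(cohort, response = "adg",
                      predictors = c("prev_pleurisy", "prev_ep_like",
                                     "prev_scars", "prev_abscess",
                                     "prev_pericarditis", "prev_milk_spots"),
                      min_leaf = 10, min_split = 2 * min_leaf) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  missing <- setdiff(c(response, predictors), names(cohort))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  y <- cohort[[response]]
  x <- cohort[predictors]
  if (anyNA(y) || anyNA(x)) stop("missing values are not supported")
  id_env <- new.env(); id_env$id <- 0L
  root <- grow_node(y, x, min_leaf, min_split, id_env)
  structure(list(root = root, response = response, predictors = predictors,
                 min_leaf = min_leaf, min_split = min_split,
                 n = length(y), sse_root = node_sse(y),
                 mean_root = mean(y)),
            class = "cart_tree")
}

is_leaf <- function(node) is.null(node$left)

count_leaves <- function(node) {
  if (is_leaf(node)) 1L
  else count_leaves(node$left) + count_leaves(node$right)
}

subtree_sse <- function(node) {
  if (is_leaf(node)) node$sse
  else subtree_sse(node$left) + subtree_sse(node$right)
}

#' Number of leaves of a fitted tree
#' @param tree A `cart_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) count_leaves(tree$root)

# Minimum weakest-link value g(t) = (sse(t) - sse(T_t)) / (|T_t| - 1)
# over internal nodes of a subtree.
min_link <- function(node) {
  if (is_leaf(node)) return(Inf)
  g <- (node$sse - subtree_sse(node)) / (count_leaves(node) - 1L)
  min(g, min_link(node$left), min_link(node$right))
}

collapse_at <- function(node, g_cut) {
  if (is_leaf(node)) return(node)
  g <- (node$sse - subtree_sse(node)) / (count_leaves(node) - 1L)
  if (g <= g_cut) {
    node$split_var <- NA_character_
    node$threshold <- NA_real_
    node$left <- NULL; node$right <- NULL
    return(node)
  }
  node$left <- collapse_at(node$left, g_cut)
  node$right <- collapse_at(node$right, g_cut)
  node
}

# Weakest-link pruning sequence: nested subtrees T_0 (full) > ... > T_K
# (root leaf) with thresholds alpha_0 = 0 < alpha_1 <= ... <= alpha_K; T_i
# minimises SSE + alpha*|T| for alpha in [alpha_i, alpha_{i+1}).
prune_sequence <- function(tree) {
  roots <- list(tree$root)
  alphas <- 0
  current <- tree$root
  while (!is_leaf(current)) {
    g <- min_link(current)
    current <- collapse_at(current, g + 1e-12 * max(g, 1))
    roots <- c(roots, list(current))
    alphas <- c(alphas, g)
  }
  alphas <- cummax(alphas)            # guard against numerical jitter
  list(alphas = alphas, roots = roots)
}

#' Cost-complexity pruning
#'
#' Returns the smallest subtree minimising `SSE + alpha * |T|` (weakest-link
#' pruning). `alpha = 0` returns the full tree; a sufficiently large `alpha`
#' collapses the tree to its root leaf (the overall mean).
#'
#' @param tree A `cart_tree`.
#' @param alpha Non-negative complexity penalty, in squared response units
#'   per leaf.
#' @return The pruned `cart_tree`.
#' @export
prune <- function(tree, alpha) {
  stopifnot(inherits(tree, "cart_tree"))
  if (alpha < 0) stop("alpha must be non-negative")
  seqs <- prune_sequence(tree)
  i <- max(which(seqs$alphas <= alpha))
  out <- tree
  out$root <- seqs$roots[[i]]
  out
}

#' Complexity table with cross-validated error
#'
#' Computes the weakest-link pruning sequence of a fitted tree and, for each
#' complexity value, the resubstitution relative error and the k-fold
#' cross-validated relative error (both normalised by the root SSE, so the
#' root-only row has relative error 1). Fold trees are grown with the same
#' stopping rule and pruned at the geometric mean of adjacent complexity
#' values before predicting the held-out fold. Fold assignment is a seeded
#' random permutation, so the table is deterministic given the seed.
#'
#' @param tree A `cart_tree` grown on `cohort`.
#' @param cohort The data the tree was grown on.
#' @param k_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return `data.frame` with columns `alpha`, `n_leaves`, `rel_error`,
#'   `xerror`, `xstd`, ordered from the root-only subtree (largest `alpha`)
#'   down to the full tree.
#' @export
cp_table <- function(tree, cohort, k_folds = 10, seed = 1L) {
  stopifnot(inherits(tree, "cart_tree"))
  n <- nrow(cohort)
  if (k_folds < 2 || k_folds > n) stop("k_folds must lie in [2, n]")
  seqs <- prune_sequence(tree)
  K <- length(seqs$alphas)
  # representative alpha for CV inside each interval [alpha_i, alpha_{i+1})
  if (K > 1L) {
    beta <- c(sqrt(seqs$alphas[-K] * seqs$alphas[-1]), Inf)
    beta[1] <- 0
  } else {
    beta <- Inf
  }
  y <- cohort[[tree$response]]
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))
  pred_err <- matrix(NA_real_, n, K)   # per-observation CV squared error
  for (f in seq_len(k_folds)) {
    test <- fold == f
    ft <- grow_tree(cohort[!test, , drop = FALSE], tree$response,
                    tree$predictors, tree$min_leaf, tree$min_split)
    fseq <- prune_sequence(ft)
    for (i in seq_len(K)) {
      j <- max(which(fseq$alphas <= beta[i]))
      yhat <- predict_node(fseq$roots[[j]], cohort[test, , drop = FALSE])
      pred_err[test, i] <- (y[test] - yhat)^2
    }
  }
  xerr <- colSums(pred_err) / tree$sse_root
  xstd <- apply(pred_err, 2, stats::sd) * sqrt(n) / tree$sse_root
  rel <- vapply(seqs$roots, subtree_sse, 0) / tree$sse_root
  nl <- vapply(seqs$roots, count_leaves, 0L)
  out <- data.frame(alpha = seqs$alphas, n_leaves = nl, rel_error = rel,
                    xerror = xerr, xstd = xstd)
  out <- out[rev(seq_len(K)), , drop = FALSE]   # root-only row first
  out <- out[!duplicated(out$alpha), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune a tree at the complexity value with least cross-validated error
#'
#' @param tree A `cart_tree`.
#' @param cp A complexity table from [cp_table()].
#' @return The pruned `cart_tree`. If several rows tie on `xerror`, the
#'   smallest subtree (largest `alpha`) is used.
#' @export
prune_min_xerror <- function(tree, cp) {
  i <- which(cp$xerror <= min(cp$xerror) + 1e-12)[1]  # table is root-first
  prune(tree, cp$alpha[i])
}

#' Grow, cross-validate and prune in one call
#'
#' Convenience wrapper: grows the tree, computes the complexity table and
#' prunes at the least-cross-validated-error complexity value.
#'
#' @inheritParams grow_tree
#' @inheritParams cp_table
#' @return List with elements `tree` (pruned `cart_tree`), `full` (unpruned),
#'   and `cp` (the complexity table).
#' @export
fit_lesion_tree <- function(cohort, response = "adg",
                            predictors = c("prev_pleurisy", "prev_ep_like",
                                           "prev_scars", "prev_abscess",
                                           "prev_pericarditis",
                                           "prev_milk_spots"),
                            min_leaf = 10, k_folds = 10, seed = 1L) {
  full <- grow_tree(cohort, response, predictors, min_leaf)
  cp <- cp_table(full, cohort, k_folds = k_folds, seed = seed)
  list(tree = prune_min_xerror(full, cp), full = full, cp = cp)
}

predict_node <- function(node, newdata) {
  if (is_leaf(node)) return(rep(node$node_mean, nrow(newdata)))
  left <- newdata[[node$split_var]] < node$threshold
  out <- numeric(nrow(newdata))
  if (any(left))
    out[left] <- predict_node(node$left, newdata[left, , drop = FALSE])
  if (any(!left))
    out[!left] <- predict_node(node$right, newdata[!left, , drop = FALSE])
  out
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  predict_node(object$root, newdata)
}

collect_nodes <- function(node, depth = 0L) {
  row <- data.frame(node_id = node$id, depth = depth, n = node$n,
                    node_mean = node$node_mean, sse = node$sse,
                    split_var = node$split_var, threshold = node$threshold,
                    leaf = is_leaf(node), stringsAsFactors = FALSE)
  if (is_leaf(node)) return(row)
  rbind(row, collect_nodes(node$left, depth + 1L),
        collect_nodes(node$right, depth + 1L))
}

#' Flat node table of a fitted tree
#'
#' Machine-readable dump: one row per node (preorder) with its size, mean,
#' SSE and, for internal nodes, the split variable and threshold.
#'
#' @param tree A `cart_tree`.
#' @return A `data.frame`.
#' @export
tree_nodes <- function(tree) collect_nodes(tree$root)

#' Leaf summary of a fitted tree
#' @param tree A `cart_tree`.
#' @return `data.frame` with one row per leaf: `node_id`, `n`, `node_mean`.
#' @export
cart_leaves <- function(tree) {
  nd <- tree_nodes(tree)
  nd[nd$leaf, c("node_id", "n", "node_mean")]
}

format_node <- function(node, indent = "") {
  if (is_leaf(node)) {
    sprintf("%sleaf: n=%d mean=%.1f\n", indent, node$n, node$node_mean)
  } else {
    paste0(sprintf("%s%s < %.4g (n=%d mean=%.1f)\n", indent, node$split_var,
                   node$threshold, node$n, node$node_mean),
           format_node(node$left, paste0(indent, "  ")),
           format_node(node$right, paste0(indent, "  ")))
  }
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("Regression tree: %s ~ %s (n=%d, %d leaves)\n", x$response,
              paste(x$predictors, collapse = " + "), x$n, n_leaves(x)))
  cat(format_node(x$root))
  invisible(x)
}

anova_between <- function(y, left) {
  n <- length(y)
  n1 <- sum(left); n2 <- n - n1
  m1 <- mean(y[left]); m2 <- mean(y[!left]); m <- mean(y)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- sum((y[left] - m1)^2) + sum((y[!left] - m2)^2)
  if (ssw <= 0) {
    f <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    f <- ssb / (ssw / (n - 2))
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  c(F = f, p = p)
}

anova_walk <- function(node, data, response) {
  if (is_leaf(node)) return(NULL)
  left <- data[[node$split_var]] < node$threshold
  fp <- anova_between(data[[response]], left)
  row <- data.frame(node_id = node$id, split_var = node$split_var,
                    threshold = node$threshold,
                    n_left = sum(left), n_right = sum(!left),
                    F = fp[["F"]], p = fp[["p"]],
                    significant = fp[["p"]] < 0.05,
                    stringsAsFactors = FALSE)
  rbind(row,
        anova_walk(node$left, data[left, , drop = FALSE], response),
        anova_walk(node$right, data[!left, , drop = FALSE], response))
}

#' One-way ANOVA between the two children of every split
#'
#' For each internal node, tests whether the response differs between the
#' two child partitions (one-way ANOVA on the binary grouping, equivalent to
#' a two-sample equal-variance t test, F = t^2). Significance is flagged at
#' the 0.05 level. A zero within-group variance with distinct means is
#' reported as `F = Inf`, `p = 0`.
#'
#' @param tree A fitted `cart_tree` with at least one split.
#' @param cohort The data to route through the tree (typically the data the
#'   tree was grown on).
#' @return `data.frame` with one row per split: split description, group
#'   sizes, `F`, `p`, `significant`.
#' @export
partition_anova <- function(tree, cohort) {
  stopifnot(inherits(tree, "cart_tree"))
  if (is_leaf(tree$root)) stop("tree has no splits")
  out <- anova_walk(tree$root, cohort, tree$response)
  rownames(out) <- NULL
  out
}
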