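make_instance <- function(n, k = 3, seed) {
  set.seed(seed)
  x <- as.data.frame(matrix(round(runif(n * k, 0, 40), 1), n, k))
  names(x) <- paste0("v", seq_len(k))
  y <- 700 + 40 * (x$v1 > 20) + rnorm(n, 0, 15)
  list(y = y, x = x)
}

test_that("best_split agrees with exhaustive enumeration", {
  for (seed in 1:15) {
    n <- sample(20:50, 1)
    inst <- make_instance(n, seed = seed)
    got <- best_split(inst$y, inst$x, min_leaf = 5)
    want <- oracle_best_split(inst$y, inst$x, min_leaf = 5)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$var, want$var)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$sse_reduction, want$sse_reduction, tolerance = 1e-9)
    }
  }
})

test_that("minimum node sizes are enforced", {
  inst <- make_instance(19, seed = 1)
  expect_null(best_split(inst$y, inst$x, min_leaf = 10))
  inst20 <- make_instance(20, seed = 2)
  sp <- best_split(inst20$y, inst20$x, min_leaf = 10)
  if (!is.null(sp)) {
    left <- inst20$x[[sp$var]] < sp$threshold
    expect_equal(sum(left), 10)
    expect_equal(sum(!left), 10)
  }
  co <- generate_cohort(seed = 1)
  tr <- grow_tree(co)
  nd <- tree_nodes(tr)
  expect_true(all(nd$n[nd$leaf] >= 10))
})

test_that("a constant response yields no split", {
  x <- data.frame(v1 = 1:40)
  expect_null(best_split(rep(5, 40), x, min_leaf = 5))
  co <- generate_cohort(seed = 1)
  co$adg <- 700
  expect_equal(n_leaves(grow_tree(co)), 1L)
})

test_that("grow_tree matches rpart as an independent oracle", {
  skip_if_not_installed("rpart")
  for (seed in c(1, 2, 3)) {
    co <- generate_cohort(seed = seed)
    tr <- grow_tree(co)
    rp <- rpart::rpart(
      adg ~ prev_pleurisy + prev_ep_like + prev_scars + prev_abscess +
        prev_pericarditis + prev_milk_spots,
      data = co, method = "anova",
      control = rpart::rpart.control(cp = 0, minsplit = 20, minbucket = 10,
                                     xval = 0, maxcompete = 0,
                                     maxsurrogate = 0))
    expect_equal(n_leaves(tr),
                 sum(rp$frame$var == "<leaf>"))
    expect_equal(unname(predict(tr, co)), unname(predict(rp, co)),
                 tolerance = 1e-9)
  }
})

test_that("training predictions are leaf means and reproduce the subtree SSE", {
  co <- generate_cohort(seed = 5)
  tr <- grow_tree(co)
  pred <- predict(tr, co)
  expect_equal(sum((co$adg - pred)^2),
               plucksim:::subtree_sse(tr$root), tolerance = 1e-9)
  leaves <- cart_leaves(tr)
  expect_true(all(pred %in% leaves$node_mean))
})

test_that("weakest-link pruning on a hand-computed example", {
  # 6 points, one predictor; full tree with min_leaf 1 has 3 leaves
  d <- data.frame(x = 1:6, y = c(0, 0, 10, 10, 30, 30))
  tr <- grow_tree(d, response = "y", predictors = "x",
                  min_leaf = 1, min_split = 2)
  expect_equal(n_leaves(tr), 3L)
  # root: mean 80/6, SSE 2800/3; split x < 4.5 leaves {0,0,10,10} (SSE 100)
  # and {30,30}; the inner split x < 2.5 zeroes the SSE. Weakest links:
  # inner node g = (100 - 0)/1 = 100, then root g = (2800/3 - 100)/1.
  seqs <- plucksim:::prune_sequence(tr)
  expect_equal(seqs$alphas, c(0, 100, 2500 / 3), tolerance = 1e-9)
  expect_equal(tr$root$threshold, 4.5)
  expect_equal(tr$root$left$threshold, 2.5)
  expect_equal(n_leaves(prune(tr, 0)), 3L)
  expect_equal(n_leaves(prune(tr, 99)), 3L)
  expect_equal(n_leaves(prune(tr, 101)), 2L)
  expect_equal(n_leaves(prune(tr, 1e9)), 1L)
  root_only <- prune(tr, 1e9)
  expect_equal(root_only$root$node_mean, mean(d$y))
})

test_that("pruning sequence is nested and prune is monotone in alpha", {
  co <- generate_cohort(seed = 3)
  tr <- grow_tree(co, min_leaf = 3, min_split = 6)
  seqs <- plucksim:::prune_sequence(tr)
  nl <- vapply(seqs$roots, plucksim:::count_leaves, 0L)
  expect_true(all(diff(nl) < 0))
  expect_equal(nl[length(nl)], 1L)
  expect_true(all(diff(seqs$alphas) >= 0))
  alphas <- sort(c(seqs$alphas, seqs$alphas + 1))
  sizes <- vapply(alphas, function(a) n_leaves(prune(tr, a)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("cp table is well-formed and deterministic in its seed", {
  co <- generate_cohort(seed = 2)
  tr <- grow_tree(co)
  cp <- cp_table(tr, co, seed = 7)
  expect_identical(cp, cp_table(tr, co, seed = 7))
  expect_equal(cp$n_leaves[1], 1L)          # root-only row first
  expect_equal(cp$rel_error[1], 1)
  expect_true(all(diff(cp$n_leaves) > 0))
  expect_true(all(diff(cp$rel_error) <= 1e-12))  # resubstitution error falls
  expect_true(all(cp$xstd >= 0))
  expect_equal(cp$n_leaves[nrow(cp)], n_leaves(tr))
  pruned <- prune_min_xerror(tr, cp)
  expect_true(n_leaves(pruned) <= n_leaves(tr))
})

test_that("partition ANOVA flags the engineered cluster structure", {
  co <- generate_cohort(seed = 1)
  fit <- fit_lesion_tree(co, seed = 1)
  an <- partition_anova(fit$tree, co)
  expect_true(all(c("split_var", "threshold", "F", "p") %in% names(an)))
  expect_true(all(an$p >= 0 & an$p <= 1))
  expect_true(all(an$F >= 0))
  expect_equal(an$significant, an$p < 0.05)
  # engineered signal: the root split must separate ADG levels sharply
  expect_lt(an$p[1], 0.05)
})

test_that("zero within-group variance is reported as infinite F", {
  d <- data.frame(x = c(1, 1, 2, 2), y = c(5, 5, 9, 9))
  tr <- grow_tree(d, "y", "x", min_leaf = 1, min_split = 2)
  an <- partition_anova(tr, d)
  expect_equal(an$F[1], Inf)
  expect_equal(an$p[1], 0)
})

test_that("malformed tree inputs are rejected", {
  co <- generate_cohort(seed = 1)
  expect_error(grow_tree(co[0, ]), "empty")
  expect_error(grow_tree(co, response = "nope"), "missing columns")
  co$adg[1] <- NA
  expect_error(grow_tree(co), "missing values")
})
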