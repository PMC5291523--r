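test_that("split importance follows the variance-decrease formula", {
  # zero-variance children: IV collapses to n * parent variance
  rec <- data.frame(n = 4, n1 = 2, n2 = 2, var_parent = 1,
                    var_child1 = 0, var_child2 = 0)
  expect_equal(split_importance(rec)$iv, 4)

  # constant parent: nothing to gain
  rec0 <- data.frame(n = 6, n1 = 3, n2 = 3, var_parent = 0,
                     var_child1 = 0, var_child2 = 0)
  expect_equal(split_importance(rec0)$iv, 0)

  # direct-arithmetic oracle for responses 1,2,3,4 split [1,2] | [3,4]
  y <- c(1, 2, 3, 4)
  pop_var <- function(v) mean((v - mean(v))^2)
  oracle <- 4 * pop_var(y) - 2 * pop_var(y[1:2]) - 2 * pop_var(y[3:4])
  rec2 <- data.frame(n = 4, n1 = 2, n2 = 2, var_parent = pop_var(y),
                     var_child1 = pop_var(y[1:2]), var_child2 = pop_var(y[3:4]))
  expect_equal(split_importance(rec2)$iv, oracle)
  expect_equal(oracle, 4) # sum of squared deviations 5 - 0.5 - 0.5

  expect_error(split_importance(data.frame(n = 4, n1 = 1, n2 = 2,
                                           var_parent = 1, var_child1 = 0,
                                           var_child2 = 0)),
               class = "bwerf_validation_error")
  expect_error(split_importance(data.frame(n = 2, n1 = 1, n2 = 1,
                                           var_parent = -1, var_child1 = 0,
                                           var_child2 = 0)),
               class = "bwerf_validation_error")
})

test_that("a fully grown tree interpolates its training data", {
  set.seed(10)
  X <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 2] * 2 + 1  # deterministic in one feature with distinct values
  tr <- grow_tree(X, y)
  expect_equal(predict(tr, X), y)

  # constant response: single leaf, no splits, no importance
  tr0 <- grow_tree(X, rep(3, 20))
  expect_equal(length(tr0$tree$n), 1L)
  expect_true(all(tr0$importance == 0))
  expect_equal(predict(tr0, X), rep(3, 20))
})

test_that("the root split matches exhaustive search over features and thresholds", {
  set.seed(77)
  for (case in 1:5) {
    X <- matrix(rnorm(6 * 2), 6, dimnames = list(NULL, c("f1", "f2")))
    y <- rnorm(6)
    tr <- grow_tree(X, y, mtry = 2)

    # brute-force oracle: every midpoint threshold on both features
    ssd <- function(v) sum((v - mean(v))^2)
    best <- list(iv = -Inf)
    for (f in 1:2) {
      xs <- sort(unique(X[, f]))
      for (i in seq_len(length(xs) - 1)) {
        thr <- (xs[i] + xs[i + 1]) / 2
        left <- X[, f] <= thr
        iv <- ssd(y) - ssd(y[left]) - ssd(y[!left])
        if (iv > best$iv) best <- list(iv = iv, f = f, thr = thr)
      }
    }
    expect_equal(tr$tree$feature[1], best$f)
    expect_equal(tr$tree$threshold[1], best$thr, tolerance = 1e-12)
    expect_equal(tr$tree$iv[1], best$iv, tolerance = 1e-10)
  }
})

test_that("forest fits are deterministic and respect degenerate features", {
  set.seed(3)
  X <- cbind(matrix(rnorm(40 * 4), 40), flat = rep(1, 40))
  colnames(X) <- c("a", "b", "c", "d", "flat")
  y <- X[, "a"] + rnorm(40, sd = 0.2)

  f1 <- fit_forest(X, y, ntree = 50, seed = 9)
  f2 <- fit_forest(X, y, ntree = 50, seed = 9)
  expect_identical(forest_importance(f1), forest_importance(f2))

  # a zero-variance column can never define a valid split
  expect_equal(unname(forest_importance(f1)["flat"]), 0)
  expect_true(all(forest_importance(f1) >= 0))

  # a different seed gives a different (but valid) fit
  f3 <- fit_forest(X, y, ntree = 50, seed = 10)
  expect_false(identical(forest_importance(f1), forest_importance(f3)))
})

test_that("per-tree importance conserves the total node-level variance decrease", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] - X[, 3] + rnorm(30, sd = 0.3)
  fit <- fit_forest(X, y, ntree = 10, seed = 4, keep_forest = TRUE)

  for (tr in fit$trees) {
    internal <- !is.na(tr$feature)
    total_iv <- sum(tr$iv[internal])
    per_feature <- tapply(tr$iv[internal], tr$feature[internal], sum)
    expect_equal(sum(per_feature), total_iv)
    # stored child counts are consistent
    expect_true(all(tr$n[internal] == tr$n1[internal] + tr$n2[internal]))
  }
  # forest importance is the mean over trees of per-tree sums
  per_tree <- sapply(fit$trees, function(tr) {
    v <- numeric(4)
    internal <- !is.na(tr$feature)
    for (i in which(internal)) v[tr$feature[i]] <- v[tr$feature[i]] + tr$iv[i]
    v
  })
  expect_equal(unname(forest_importance(fit)), rowMeans(per_tree))
})

test_that("re-traversal of stored trees reproduces the importance vector", {
  set.seed(8)
  X <- matrix(rnorm(25 * 5), 25, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * X[, 2] + rnorm(25, sd = 0.5)
  fit <- fit_forest(X, y, ntree = 15, seed = 2, keep_forest = TRUE)
  rt <- retrace_importance(fit, X, y)
  expect_equal(rt, forest_importance(fit), tolerance = 1e-12)
})

test_that("a strong linear signal earns the top importance across seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(rnorm(200 * 21), 200, dimnames = list(NULL, paste0("f", 1:21)))
    y <- 5 * X[, 1] + rnorm(200)
    imp <- forest_importance(fit_forest(X, y, ntree = 60, seed = s))
    if (names(which.max(imp)) == "f1") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("input validation rejects malformed forest problems", {
  X <- matrix(rnorm(10), 5, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_forest(X, rnorm(4)), class = "bwerf_validation_error")
  expect_error(fit_forest(X[1, , drop = FALSE], 1),
               class = "bwerf_validation_error")
  expect_error(fit_forest(X, c(1, 2, NA, 4, 5)),
               class = "bwerf_validation_error")
  expect_error(fit_forest(X, rnorm(5), mtry = 3),
               class = "bwerf_validation_error")
})
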