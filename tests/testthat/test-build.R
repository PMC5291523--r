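make_layer_problem <- function(seed = 1, n = 60, n_true = 3, n_decoy = 12) {
  set.seed(seed)
  tf_ids <- c(paste0("TF", seq_len(n_true)), paste0("D", seq_len(n_decoy)))
  X <- matrix(rnorm(n * length(tf_ids)), n, dimnames = list(NULL, tf_ids))
  targets <- sapply(1:2, function(j) {
    rowSums(X[, seq_len(n_true), drop = FALSE]) + rnorm(n, sd = 0.5)
  })
  colnames(targets) <- c("pgA", "pgB")
  list(expr = cbind(targets, X), pathway = c("pgA", "pgB"), pool = tf_ids,
       true_tfs = paste0("TF", seq_len(n_true)))
}

test_that("edge policies keep the intended pairs", {
  tab <- tibble::tibble(
    regulator = c("a", "b", "c", "d"),
    target = "g",
    importance = c(1, 2, 3, 4)
  )
  # quantile(0.5) over 1,2,3,4 is 2.5 (midpoint-interpolated): keep 3 and 4
  e <- assign_edges(tab, selected = c("a", "b", "c", "d"),
                    policy = "quantile", q = 0.5)
  expect_setequal(e$regulator, c("c", "d"))

  # all_positive drops exact zeros
  tab0 <- tab
  tab0$importance[1] <- 0
  e0 <- assign_edges(tab0, selected = tab0$regulator, policy = "all_positive")
  expect_false("a" %in% e0$regulator)

  # only selected regulators can carry edges
  e_sel <- assign_edges(tab, selected = "d", policy = "all_positive")
  expect_true(all(e_sel$regulator == "d"))

  expect_error(assign_edges(tab, selected = "zz"),
               class = "bwerf_validation_error")
})

test_that("fixed-count selection keeps the top unified importances", {
  prob <- make_layer_problem(seed = 2)
  res <- build_layer(prob$expr, prob$pathway, prob$pool,
                     selection = "fixed", n_select = 2, ntree = 30, seed = 4)
  expect_length(res$selected, 2)
  expect_equal(res$selected, res$unified$regulator[1:2])
  # the importance table covers the full pool x pathway grid
  expect_equal(nrow(res$table), length(prob$pool) * 2)
  # every edge regulator was selected
  expect_true(all(res$edges$regulator %in% res$selected))
})

test_that("a pool of one regulator is selected and linked per policy", {
  prob <- make_layer_problem(seed = 3, n_true = 1, n_decoy = 0)
  res <- build_layer(prob$expr, prob$pathway, "TF1", selection = "fixed",
                     n_select = 1, edge_policy = "all_positive", ntree = 20,
                     seed = 1)
  expect_equal(res$selected, "TF1")
  expect_setequal(res$edges$target, prob$pathway)
})

test_that("gmm selection recovers the true regulators on an easy layer", {
  prob <- make_layer_problem(seed = 5, n = 80, n_true = 3, n_decoy = 30)
  res <- build_layer(prob$expr, prob$pathway, prob$pool, selection = "gmm",
                     ntree = 60, seed = 6)
  # the top-mean component must contain every true TF (recovery), and the
  # selection must be a real cut, not the whole pool
  expect_true(all(prob$true_tfs %in% res$selected))
  expect_lt(length(res$selected), length(prob$pool) / 2)
  # the true TFs outrank every selected decoy
  expect_equal(res$unified$regulator[1:3], res$selected[1:3])
  expect_s3_class(res$gmm, "bw_gmm")
})

test_that("built networks satisfy the layer invariants and are reproducible", {
  h <- simulate_hierarchical(c(3, 4, 5), n_samples = 60, n_decoys = 8,
                             noise_scale = 0.4, seed = 9)
  net <- build_hgrn(h$expression, h$pathway, h$regulators, n_layers = 2,
                    selection = "fixed", n_select = 4, ntree = 30, seed = 11)
  expect_s3_class(net, "hgrn")
  expect_true(validate_hgrn(net, h$pathway))

  # no gene in two layers; every edge spans adjacent layers
  ids <- unlist(net$layers)
  expect_equal(anyDuplicated(ids), 0L)
  layer_of <- stats::setNames(rep(seq_along(net$layers) - 1L,
                                  lengths(net$layers)), ids)
  expect_true(all(layer_of[net$edges$regulator] ==
                    layer_of[net$edges$target] + 1L))

  # byte-identical edge list on a seeded rerun
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_edge_list(net$edges, p1)
  net2 <- build_hgrn(h$expression, h$pathway, h$regulators, n_layers = 2,
                     selection = "fixed", n_select = 4, ntree = 30, seed = 11)
  write_edge_list(net2$edges, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("n_layers = 1 yields a two-level network; small pools stop early", {
  prob <- make_layer_problem(seed = 12)
  net <- build_hgrn(prob$expr, prob$pathway, prob$pool, n_layers = 1,
                    selection = "fixed", n_select = 3, ntree = 25, seed = 2)
  expect_length(net$layers, 2)
  expect_true(all(net$edges$layer == 1L))

  # requesting more layers than the pool supports terminates with a warning
  expect_warning(
    net_deep <- build_hgrn(prob$expr, prob$pathway, c("TF1", "TF2"),
                           n_layers = 4, selection = "fixed", n_select = 2,
                           ntree = 25, seed = 2),
    "exhausted"
  )
  expect_lte(length(net_deep$layers), 3)
})

test_that("the single-pass baseline matches BWERF layer sizes by contract", {
  prob <- make_layer_problem(seed = 15)
  net <- build_hgrn(prob$expr, prob$pathway, prob$pool, n_layers = 1,
                    selection = "fixed", n_select = 3, ntree = 25, seed = 5)
  base <- build_genie3_baseline(prob$expr, prob$pathway, prob$pool,
                                match_to = net, ntree = 25, seed = 5)
  expect_equal(lengths(base$layers), lengths(net$layers))
  expect_true(isTRUE(base$params$baseline))
  expect_true(validate_hgrn(base, prob$pathway))

  # baseline per-gene scores equal one plain forest fit (no elimination)
  g <- prob$pathway[1]
  imp <- forest_importance(
    fit_forest(prob$expr[, prob$pool], prob$expr[, g], ntree = 25,
               seed = bwerf:::derive_seed(5, 1, 1, 1))
  )
  base_g <- base$tables[[1]] |> dplyr::filter(target == g)
  expect_equal(stats::setNames(base_g$importance, base_g$regulator),
               imp[base_g$regulator])
})

test_that("input validation catches overlapping pathway and pool", {
  prob <- make_layer_problem(seed = 20)
  expect_error(build_hgrn(prob$expr, prob$pathway,
                          c(prob$pathway[1], prob$pool), n_layers = 1),
               class = "bwerf_validation_error")
  expect_error(build_hgrn(prob$expr, character(), prob$pool, n_layers = 1),
               class = "bwerf_validation_error")
})

test_that("tidy and glance summarise a built network", {
  prob <- make_layer_problem(seed = 22)
  net <- build_hgrn(prob$expr, prob$pathway, prob$pool, n_layers = 1,
                    selection = "fixed", n_select = 2, ntree = 20, seed = 3)
  td <- tidy(net)
  expect_true(all(c("regulator", "target", "layer", "importance") %in%
                    names(td)))
  gl <- glance(net)
  expect_equal(gl$n_layers, 1L)
  expect_equal(gl$n_edges, nrow(net$edges))
})
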