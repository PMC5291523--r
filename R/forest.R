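#' Variance-reduction importance of a single split
#'
#' For a node that splits `n` samples with response variance `var_parent` into
#' children of sizes `n1`, `n2` and variances `var_child1`, `var_child2`, the
#' importance credited to the splitting variable is the decrease in variance
#'
#' \deqn{IV = n \delta_p - n_1 \delta_{c1} - n_2 \delta_{c2}}
#'
#' Variances are population variances (divide by the node count), so each term
#' is a sum of squared deviations and IV is exactly additive over the nodes of
#' a tree. Tiny negative values arising from floating point are clipped to 0.
#'
#' @param splits Data frame with columns `n`, `n1`, `n2`, `var_parent`,
#'   `var_child1`, `var_child2`, one row per split record.
#' @return The input as a tibble with an `iv` column appended.
#' @examples
#' split_importance(data.frame(
#'   n = 4, n1 = 2, n2 = 2, var_parent = 1, var_child1 = 0, var_child2 = 0
#' ))
#' @export
split_importance <- function(splits) {
  splits <- tibble::as_tibble(splits)
  needed <- c("n", "n1", "n2", "var_parent", "var_child1", "var_child2")
  missing_cols <- setdiff(needed, names(splits))
  if (length(missing_cols) > 0) {
    abort_bad_arg(paste0("`splits` lacks columns: ",
                         paste(missing_cols, collapse = ", ")))
  }
  if (any(splits$n != splits$n1 + splits$n2)) {
    abort_bad_arg("split record invalid: n must equal n1 + n2")
  }
  if (any(splits$n1 < 1) || any(splits$n2 < 1)) {
    abort_bad_arg("split record invalid: both children need at least 1 sample")
  }
  vars <- c(splits$var_parent, splits$var_child1, splits$var_child2)
  if (any(vars < 0)) {
    abort_bad_arg("split record invalid: variances must be nonnegative")
  }
  dplyr::mutate(
    splits,
    iv = pmax(0, .data$n * .data$var_parent -
                .data$n1 * .data$var_child1 - .data$n2 * .data$var_child2)
  )
}

default_mtry <- function(p) max(1L, floor(p / 3))

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    abort_bad_arg("`X` must be a numeric matrix or data frame (samples x features)")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    abort_bad_arg("`X` contains missing or non-finite values")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

#' Fit a regression random forest with variance-reduction importance
#'
#' Grows `ntree` fully grown regression trees, each on an independent bootstrap
#' sample drawn with replacement. At every node `mtry` candidate features are
#' sampled without replacement and the split minimising the summed child
#' variance is taken; thresholds are midpoints between consecutive distinct
#' feature values, and ties are broken towards the lowest feature index and
#' then the lowest threshold. Recursion stops when a node's responses are
#' identical or its predictor rows are indistinguishable. A feature's
#' importance in one tree is the sum of [split_importance()] over the nodes
#' that split on it; the forest importance is the mean over trees.
#'
#' The fit is a deterministic function of `(X, y, ntree, mtry, bootstrap_size,
#' seed)`.
#'
#' @param X Numeric matrix or data frame, samples in rows, candidate
#'   regulators (features) in columns.
#' @param y Numeric response, one value per sample.
#' @param ntree Number of trees (default 1000).
#' @param mtry Candidate features per node; default `max(1, floor(p/3))`.
#' @param bootstrap_size Bootstrap draws per tree; default `nrow(X)`.
#' @param seed Integer seed for the forest's random stream.
#' @param keep_forest Keep the full tree structures (inbag indices, split
#'   records) for auditing. Memory-heavy; intended for small problems.
#' @return An object of class `bw_forest` with elements `importance` (named
#'   numeric), `feature_ids`, `params`, and `trees` (when kept).
#' @seealso [retrace_importance()] to recompute importance from stored trees.
#' @export
fit_forest <- function(X, y, ntree = 1000, mtry = NULL, bootstrap_size = NULL,
                       seed = 1, keep_forest = FALSE) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort_bad_arg("`y` length must equal nrow(X)")
  if (anyNA(y) || any(!is.finite(y))) abort_bad_arg("`y` has non-finite values")
  if (n < 2) abort_bad_arg("need at least 2 samples to fit a forest")
  if (ntree < 1) abort_bad_arg("`ntree` must be >= 1")
  if (is.null(mtry)) mtry <- default_mtry(p)
  if (mtry < 1 || mtry > p) abort_bad_arg("`mtry` must be in [1, ncol(X)]")
  if (is.null(bootstrap_size)) bootstrap_size <- n
  if (bootstrap_size < 2) abort_bad_arg("`bootstrap_size` must be >= 2")

  fit <- cpp_fit_forest(X, y, as.integer(ntree), as.integer(mtry),
                        as.integer(bootstrap_size), TRUE, as.double(seed),
                        keep_forest)
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(X)
  structure(
    list(
      importance = imp,
      feature_ids = colnames(X),
      params = list(ntree = ntree, mtry = mtry,
                    bootstrap_size = bootstrap_size, seed = seed),
      trees = fit$trees
    ),
    class = "bw_forest"
  )
}

#' Grow one fully grown regression tree on the data as given
#'
#' Like a single forest tree but without bootstrap resampling: every sample is
#' used once. With `mtry = ncol(X)` (the default here) the split search is
#' exhaustive and deterministic.
#'
#' @inheritParams fit_forest
#' @return A `bw_tree` object: the tree's split records plus `importance`.
#' @export
grow_tree <- function(X, y, mtry = NULL, seed = 1) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2) abort_bad_arg("need at least 2 samples to grow a tree")
  if (length(y) != nrow(X)) abort_bad_arg("`y` length must equal nrow(X)")
  if (is.null(mtry)) mtry <- ncol(X)
  fit <- cpp_fit_forest(X, y, 1L, as.integer(mtry), nrow(X), FALSE,
                        as.double(seed), TRUE)
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(X)
  structure(
    list(tree = fit$trees[[1]], importance = imp, feature_ids = colnames(X)),
    class = "bw_tree"
  )
}

#' Predict from a single regression tree
#'
#' @param object A `bw_tree` from [grow_tree()].
#' @param newdata Matrix or data frame with the training feature columns.
#' @param ... Unused.
#' @return Numeric predictions, one per row of `newdata`.
#' @export
predict.bw_tree <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  tr <- object$tree
  vapply(seq_len(nrow(X)), function(i) {
    node <- 1L
    while (!is.na(tr$feature[node])) {
      node <- if (X[i, tr$feature[node]] <= tr$threshold[node]) {
        tr$left[node]
      } else {
        tr$right[node]
      }
    }
    tr$value[node]
  }, numeric(1))
}

#' Extract the per-feature importance vector of a fitted forest
#'
#' @param fit A `bw_forest`.
#' @return Named numeric vector, one nonnegative value per feature.
#' @export
forest_importance <- function(fit) {
  stopifnot(inherits(fit, "bw_forest"))
  fit$importance
}

#' @method tidy bw_forest
#' @export
tidy.bw_forest <- function(x, ...) {
  tibble::tibble(feature = x$feature_ids, importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature)
}

#' @export
print.bw_forest <- function(x, ...) {
  cat("Regression random forest:", x$params$ntree, "trees,",
      length(x$feature_ids), "features, mtry =", x$params$mtry, "\n")
  cat("Top features by variance-reduction importance:\n")
  print(head(tidy(x), 5))
  invisible(x)
}

#' Recompute forest importance by re-traversing stored trees
#'
#' Independent audit of the importance accounting: for every stored tree the
#' inbag samples are dropped through the recorded split thresholds, the
#' variance decrease at each internal node is recomputed from the actual
#' sample sets, summed per feature, and averaged over trees. No quantity from
#' the fit-time accumulation is reused.
#'
#' @param fit A `bw_forest` fitted with `keep_forest = TRUE`.
#' @param X,y The training data the forest was fitted on.
#' @return Named numeric importance vector on the same scale as
#'   [forest_importance()].
#' @export
retrace_importance <- function(fit, X, y) {
  stopifnot(inherits(fit, "bw_forest"))
  if (is.null(fit$trees)) {
    abort_bad_arg("forest was not fitted with keep_forest = TRUE")
  }
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  p <- length(fit$feature_ids)
  total <- numeric(p)
  ssd <- function(v) sum((v - mean(v))^2)
  for (tr in fit$trees) {
    imp <- numeric(p)
    recurse <- function(node, rows) {
      f <- tr$feature[node]
      if (is.na(f)) return(invisible(NULL))
      go_left <- X[rows, f] <= tr$threshold[node]
      left_rows <- rows[go_left]
      right_rows <- rows[!go_left]
      iv <- ssd(y[rows]) - ssd(y[left_rows]) - ssd(y[right_rows])
      imp[f] <<- imp[f] + max(0, iv)
      recurse(tr$left[node], left_rows)
      recurse(tr$right[node], right_rows)
    }
    recurse(1L, tr$inbag)
    total <- total + imp
  }
  out <- total / length(fit$trees)
  names(out) <- fit$feature_ids
  out
}
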