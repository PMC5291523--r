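#' Remove the least important fraction of regulators
#'
#' One round of backward elimination: regulators are ranked by importance and
#' the lowest `max(1, floor(rate * length(importance)))` are dropped. Ties at
#' the cutoff are resolved by removing the lexicographically larger gene ID
#' first, so a round is a deterministic function of its inputs.
#'
#' @param importance Named numeric vector of current importance values.
#' @param rate Fraction to remove per round, in (0, 1).
#' @return List with `retained` and `removed` character vectors (original
#'   order preserved within `retained`).
#' @export
eliminate_round <- function(importance, rate) {
  if (!(rate > 0 && rate < 1)) abort_bad_arg("`rate` must be in (0, 1)")
  ids <- names(importance)
  if (is.null(ids) || anyDuplicated(ids) > 0) {
    abort_bad_arg("`importance` must be named with unique gene IDs")
  }
  if (length(importance) < 2) {
    abort_bad_arg("elimination needs at least 2 regulators")
  }
  k <- max(1L, floor(rate * length(importance)))
  # removal order: importance ascending, larger ID first among ties
  ord <- order(importance, ids, decreasing = c(FALSE, TRUE), method = "radix")
  removed <- ids[ord[seq_len(k)]]
  list(retained = setdiff(ids, removed), removed = removed)
}

#' Backward-elimination random forest for one pathway gene
#'
#' Fits a random forest of the current regulator pool against one pathway
#' gene's expression, removes the least important fraction of regulators, and
#' refits on the survivors, repeating until a single regulator remains. A
#' regulator's final importance is its value in the last round in which it was
#' modelled, i.e. the round of its elimination (the last survivor keeps its
#' value from the final fitted round). That snapshot comes from the least
#' noise-contaminated model that still contained the regulator, which is what
#' lets moderate regulators surface above noise variables.
#'
#' Each round draws its forest seed from `derive_seed(seed, stream, round)`,
#' so per-gene runs are reproducible independently of execution order.
#'
#' @param X Expression of the current regulator pool (samples x regulators),
#'   matrix or data frame with column names.
#' @param y Expression profile of the pathway gene (one value per sample).
#' @param rate Elimination rate per round, in (0, 1); default 0.1.
#' @param ntree,mtry,bootstrap_size Forest parameters, see [fit_forest()].
#' @param seed Master seed.
#' @param stream Integer label of this regression's random stream (the
#'   pathway-gene index when called from [build_hgrn()]).
#' @return A `bw_elimination` object: `final` (tibble of feature, importance,
#'   round recorded), `trace` (tibble of round, feature, importance,
#'   eliminated flag), `n_rounds`.
#' @export
backward_eliminate <- function(X, y, rate = 0.1, ntree = 1000, mtry = NULL,
                               bootstrap_size = NULL, seed = 1, stream = 1) {
  X <- as_feature_matrix(X)
  if (ncol(X) < 1) abort_bad_arg("regulator pool is empty")
  pool <- colnames(X)
  final_imp <- stats::setNames(rep(NA_real_, length(pool)), pool)
  final_round <- stats::setNames(rep(NA_integer_, length(pool)), pool)
  trace <- vector("list", 0)
  round <- 0L

  repeat {
    round <- round + 1L
    fit <- fit_forest(X[, pool, drop = FALSE], y, ntree = ntree, mtry = mtry,
                      bootstrap_size = bootstrap_size,
                      seed = derive_seed(seed, stream, round))
    imp <- forest_importance(fit)
    final_imp[pool] <- imp[pool]
    final_round[pool] <- round
    if (length(pool) == 1) {
      trace[[round]] <- tibble::tibble(round = round, feature = pool,
                                       importance = unname(imp[pool]),
                                       eliminated = FALSE)
      break
    }
    step <- eliminate_round(imp, rate)
    trace[[round]] <- tibble::tibble(
      round = round, feature = pool,
      importance = unname(imp[pool]),
      eliminated = pool %in% step$removed
    )
    pool <- pool[pool %in% step$retained]
    if (length(pool) == 1) break
  }

  structure(
    list(
      final = tibble::tibble(feature = names(final_imp),
                             importance = unname(final_imp),
                             round = unname(final_round)) |>
        dplyr::arrange(dplyr::desc(.data$importance), .data$feature),
      trace = dplyr::bind_rows(trace),
      n_rounds = round,
      survivor = pool
    ),
    class = "bw_elimination"
  )
}

#' @method tidy bw_elimination
#' @export
tidy.bw_elimination <- function(x, ...) x$final

#' @method glance bw_elimination
#' @export
glance.bw_elimination <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$final), n_rounds = x$n_rounds,
                 survivor = x$survivor)
}

#' @export
print.bw_elimination <- function(x, ...) {
  cat("Backward elimination:", nrow(x$final), "regulators over", x$n_rounds,
      "rounds; survivor:", x$survivor, "\n")
  print(head(x$final, 5))
  invisible(x)
}

#' Aggregate per-gene importance into one unified value per regulator
#'
#' The unified importance of a regulator is the weighted sum over pathway
#' genes of its final backward-elimination importance:
#' `unified(t) = sum_j w_j * importance(t, gene_j)`. Default weights are all 1;
#' weights let known key pathway genes pull the selection towards their
#' regulators.
#'
#' @param table Long importance table: data frame with columns `regulator`,
#'   `target`, `importance` covering every (regulator, target) pair.
#' @param weights Named nonnegative weights over targets, or `NULL` for 1s.
#' @param normalize If `TRUE`, each target's importance vector is scaled to
#'   sum to 1 before weighting (sensitivity analysis; default off — raw values
#'   are aggregated).
#' @return Tibble with `regulator` and `importance` (unified), sorted
#'   decreasing.
#' @export
aggregate_importance <- function(table, weights = NULL, normalize = FALSE) {
  table <- tibble::as_tibble(table)
  needed <- c("regulator", "target", "importance")
  if (!all(needed %in% names(table))) {
    abort_bad_arg("`table` needs columns regulator, target, importance")
  }
  targets <- unique(table$target)
  regs <- unique(table$regulator)
  if (nrow(table) != length(targets) * length(regs) ||
      anyDuplicated(table[c("regulator", "target")]) > 0) {
    abort_bad_arg("`table` must contain each (regulator, target) pair exactly once")
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(targets)), targets)
  }
  if (is.null(names(weights)) || !setequal(names(weights), targets) ||
      length(weights) != length(targets)) {
    abort_bad_arg("`weights` must be named, one weight per target gene")
  }
  if (any(weights < 0) || !any(weights > 0)) {
    abort_bad_arg("weights must be nonnegative with at least one positive")
  }
  tab <- table
  if (normalize) {
    tab <- tab |>
      dplyr::group_by(.data$target) |>
      dplyr::mutate(importance = if (sum(.data$importance) > 0) {
        .data$importance / sum(.data$importance)
      } else {
        .data$importance
      }) |>
      dplyr::ungroup()
  }
  tab |>
    dplyr::mutate(w = unname(weights[.data$target])) |>
    dplyr::group_by(.data$regulator) |>
    dplyr::summarise(importance = sum(.data$w * .data$importance),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$regulator)
}
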