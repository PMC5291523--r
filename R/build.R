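#' Assign edges between selected regulators and the bottom-layer genes
#'
#' Every selected regulator is linked to the bottom genes for which its final
#' importance clears the edge policy. The `"quantile"` policy (default
#' q = 0.9) keeps the edge (t, g) when t's final importance for g is at or
#' above the q-quantile (midpoint-interpolated, R type 7) of *all* regulators'
#' final importance for g, which gives the sparse networks the layered view is
#' for; `"all_positive"` keeps every strictly positive importance.
#'
#' @param table Long importance table (`regulator`, `target`, `importance`).
#' @param selected Character vector of selected regulator IDs (subset of the
#'   table's regulators).
#' @param policy `"quantile"` or `"all_positive"`.
#' @param q Quantile level in (0, 1) for the quantile policy.
#' @param layer Layer index recorded on the emitted edges (regulator's layer).
#' @return Edge tibble: `regulator`, `target`, `layer`, `importance`.
#' @export
assign_edges <- function(table, selected, policy = c("quantile", "all_positive"),
                         q = 0.9, layer = 1L) {
  policy <- match.arg(policy)
  table <- tibble::as_tibble(table)
  if (!all(selected %in% table$regulator)) {
    abort_bad_arg("`selected` must be a subset of the table's regulators")
  }
  if (policy == "quantile" && !(q > 0 && q < 1)) {
    abort_bad_arg("`q` must be in (0, 1)")
  }
  kept <- table |>
    dplyr::group_by(.data$target) |>
    dplyr::mutate(.cut = if (policy == "quantile") {
      quantile(.data$importance, q, type = 7)
    } else {
      0
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$regulator %in% selected,
                  if (policy == "quantile") .data$importance >= .data$.cut
                  else .data$importance > 0)
  tibble::tibble(regulator = kept$regulator, target = kept$target,
                 layer = as.integer(layer), importance = kept$importance)
}

select_regulators <- function(unified, selection, n_select, pool_size, seed) {
  vals <- unified$importance
  if (selection == "fixed") {
    if (is.null(n_select)) abort_bad_arg("fixed selection needs `n_select`")
    m <- min(n_select, nrow(unified))
    return(list(selected = unified$regulator[seq_len(m)], gmm = NULL))
  }
  K <- 2
  if (length(vals) < 2 * K || var(vals) == 0) {
    m <- ceiling(sqrt(pool_size))
    warn(sprintf(
      "GMM selection degenerate (%d values); falling back to the top %d regulators",
      length(vals), m
    ))
    return(list(selected = unified$regulator[seq_len(min(m, nrow(unified)))],
                gmm = NULL))
  }
  gmm <- em_fit(vals, K = K, seed = seed)
  mask <- extract_top_component(vals, gmm)
  if (all(mask) || !any(mask)) {
    m <- ceiling(sqrt(pool_size))
    warn(sprintf(
      "GMM selection degenerate (selected %d of %d); falling back to the top %d",
      sum(mask), length(mask), m
    ))
    return(list(selected = unified$regulator[seq_len(min(m, nrow(unified)))],
                gmm = gmm))
  }
  if (sum(mask) > length(mask) / 2) {
    warn(sprintf(
      "GMM selected %d of %d regulators for one layer; implausibly dense layer",
      sum(mask), length(mask)
    ))
  }
  list(selected = unified$regulator[mask], gmm = gmm)
}

#' Infer one regulator layer above the current bottom genes
#'
#' Runs [backward_eliminate()] (or a single-pass forest in `baseline` mode)
#' for every bottom-layer gene against the full regulator pool, aggregates the
#' final importance values into one unified value per regulator
#' ([aggregate_importance()]), selects the layer's regulators — by Gaussian
#' mixture top-component extraction or a fixed count — and emits the layer's
#' edges under the edge policy.
#'
#' @param expr Samples x genes expression matrix containing all bottom and
#'   pool genes.
#' @param bottom Character vector of current bottom-layer gene IDs.
#' @param pool Candidate regulator IDs, disjoint from `bottom`.
#' @param weights Named nonnegative weights for `bottom` genes (default 1s).
#' @param selection `"gmm"` or `"fixed"`.
#' @param n_select Number kept under fixed selection.
#' @param edge_policy,edge_q See [assign_edges()].
#' @param rate,ntree,mtry Elimination and forest parameters.
#' @param seed Master seed.
#' @param layer Layer index for the emitted edges.
#' @param baseline Single-pass mode: one forest per bottom gene, no
#'   elimination (the GENIE3-style reference ranking).
#' @return List: `selected`, `table` (long importance tibble), `unified`,
#'   `edges`, `gmm` (fitted mixture or NULL).
#' @export
build_layer <- function(expr, bottom, pool, weights = NULL,
                        selection = c("gmm", "fixed"), n_select = NULL,
                        edge_policy = c("quantile", "all_positive"),
                        edge_q = 0.9, rate = 0.1, ntree = 1000, mtry = NULL,
                        seed = 1, layer = 1L, baseline = FALSE) {
  selection <- match.arg(selection)
  edge_policy <- match.arg(edge_policy)
  expr <- as_feature_matrix(expr)
  if (length(pool) < 1) abort_bad_arg("regulator pool is empty")
  if (length(intersect(bottom, pool)) > 0) {
    abort_bad_arg("`pool` must be disjoint from the bottom layer")
  }
  missing_ids <- setdiff(c(bottom, pool), colnames(expr))
  if (length(missing_ids) > 0) {
    abort_bad_arg(paste0("genes absent from expression matrix: ",
                         paste(head(missing_ids, 5), collapse = ", ")))
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(bottom)), bottom)

  Xp <- expr[, pool, drop = FALSE]
  table <- purrr::imap_dfr(stats::setNames(bottom, bottom), function(g, nm) {
    gi <- match(g, bottom)
    y <- expr[, g]
    if (baseline) {
      fit <- fit_forest(Xp, y, ntree = ntree, mtry = mtry,
                        seed = derive_seed(seed, layer, gi, 1))
      imp <- forest_importance(fit)
      tibble::tibble(regulator = names(imp), target = g,
                     importance = unname(imp), round = 1L)
    } else {
      el <- backward_eliminate(Xp, y, rate = rate, ntree = ntree, mtry = mtry,
                               seed = derive_seed(seed, layer),
                               stream = gi)
      tibble::tibble(regulator = el$final$feature, target = g,
                     importance = el$final$importance, round = el$final$round)
    }
  })

  unified <- aggregate_importance(table, weights)
  sel <- select_regulators(unified, selection, n_select, length(pool),
                           seed = derive_seed(seed, layer, 9001))
  edges <- assign_edges(table, sel$selected, policy = edge_policy, q = edge_q,
                        layer = layer)
  list(selected = sel$selected, table = table, unified = unified,
       edges = edges, gmm = sel$gmm)
}

new_hgrn <- function(layers, edges, tables, unified, gmms, params) {
  structure(
    list(layers = layers, edges = edges, tables = tables, unified = unified,
         gmms = gmms, params = params),
    class = "hgrn"
  )
}

#' Verify the structural invariants of a hierarchical network
#'
#' Layers must be pairwise disjoint, layer 0 must equal the input pathway set
#' when given, and every edge must run from a gene in layer i+1 to a gene in
#' layer i.
#'
#' @param hgrn An `hgrn`.
#' @param pathway Optional pathway IDs to check layer 0 against.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
validate_hgrn <- function(hgrn, pathway = NULL) {
  stopifnot(inherits(hgrn, "hgrn"))
  all_ids <- unlist(hgrn$layers)
  if (anyDuplicated(all_ids) > 0) abort_bad_arg("layers are not disjoint")
  if (!is.null(pathway) && !setequal(hgrn$layers[[1]], pathway)) {
    abort_bad_arg("layer 0 does not equal the input pathway set")
  }
  layer_of <- rep(seq_along(hgrn$layers) - 1L, lengths(hgrn$layers))
  names(layer_of) <- all_ids
  e <- hgrn$edges
  if (nrow(e) > 0) {
    lr <- layer_of[e$regulator]
    lt <- layer_of[e$target]
    if (any(is.na(lr)) || any(is.na(lt)) ||
        any(lr != lt + 1L) || any(lr != e$layer)) {
      abort_bad_arg("every edge must span adjacent layers (regulator one above target)")
    }
  }
  invisible(TRUE)
}

#' Build a multilayered hierarchical gene regulatory network
#'
#' Repeats [build_layer()] `n_layers` times: the regulators selected for a
#' layer are removed from the pool and become the new bottom layer (weights
#' reset to 1 — user weights apply to the pathway layer only), and the next
#' layer is inferred above them. Building stops early with a warning when the
#' pool empties or selection returns no regulators. With a fixed master seed
#' the whole build — including the serialised edge list — is reproducible
#' byte for byte.
#'
#' @inheritParams build_layer
#' @param pathway Bottom-layer (pathway) gene IDs.
#' @param pool Candidate regulator IDs, disjoint from the pathway.
#' @param n_layers Number of regulator layers to build above the pathway.
#' @return An `hgrn`: `layers` (gene IDs per layer, pathway first), `edges`
#'   (tibble regulator/target/layer/importance), per-layer importance
#'   `tables`, `unified` values and fitted `gmms`, plus `params`.
#' @export
build_hgrn <- function(expr, pathway, pool, weights = NULL, n_layers = 1,
                       selection = c("gmm", "fixed"), n_select = NULL,
                       edge_policy = c("quantile", "all_positive"),
                       edge_q = 0.9, rate = 0.1, ntree = 1000, mtry = NULL,
                       seed = 1) {
  selection <- match.arg(selection)
  edge_policy <- match.arg(edge_policy)
  if (length(pathway) < 1) abort_bad_arg("`pathway` must be non-empty")
  if (length(intersect(pathway, pool)) > 0) {
    abort_bad_arg("`pathway` and `pool` must be disjoint")
  }
  if (n_layers < 1) abort_bad_arg("`n_layers` must be >= 1")
  if (!is.null(weights) && is.null(names(weights))) {
    names(weights) <- pathway
  }

  layers <- list(pathway)
  bottom <- pathway
  w <- weights
  remaining <- pool
  edges <- list()
  tables <- list()
  unified <- list()
  gmms <- list()

  for (lv in seq_len(n_layers)) {
    if (length(remaining) == 0) {
      warn(sprintf("pool exhausted after %d layer(s); stopping early", lv - 1))
      break
    }
    res <- build_layer(expr, bottom, remaining, weights = w,
                       selection = selection, n_select = n_select,
                       edge_policy = edge_policy, edge_q = edge_q, rate = rate,
                       ntree = ntree, mtry = mtry, seed = seed, layer = lv)
    if (length(res$selected) == 0) {
      warn(sprintf("no regulators selected for layer %d; stopping early", lv))
      break
    }
    layers[[lv + 1]] <- res$selected
    edges[[lv]] <- res$edges
    tables[[lv]] <- res$table
    unified[[lv]] <- res$unified
    gmms[[lv]] <- res$gmm
    remaining <- setdiff(remaining, res$selected)
    bottom <- res$selected
    w <- NULL  # promoted layers carry unit weights
  }

  out <- new_hgrn(
    layers,
    if (length(edges) > 0) dplyr::bind_rows(edges) else
      tibble::tibble(regulator = character(), target = character(),
                     layer = integer(), importance = numeric()),
    tables, unified, gmms,
    params = list(n_layers = n_layers, selection = selection,
                  n_select = n_select, edge_policy = edge_policy,
                  edge_q = edge_q, rate = rate, ntree = ntree, mtry = mtry,
                  seed = seed, baseline = FALSE)
  )
  validate_hgrn(out, pathway)
  out
}

#' Single-pass baseline network with matched layer sizes
#'
#' The GENIE3-style reference: the identical layered pipeline but with one
#' forest fit per bottom gene and no backward elimination. The number of
#' regulators kept per layer is matched to a completed [build_hgrn()] run
#' (`match_to`) or fixed via `n_select`, so baseline and elimination networks
#' differ only in their rankings.
#'
#' @inheritParams build_hgrn
#' @param match_to An `hgrn` whose per-layer selected counts to reproduce, or
#'   `NULL` to use `n_select` throughout.
#' @return An `hgrn` with `params$baseline = TRUE`.
#' @export
build_genie3_baseline <- function(expr, pathway, pool, weights = NULL,
                                  n_layers = 1, match_to = NULL,
                                  n_select = NULL,
                                  edge_policy = c("quantile", "all_positive"),
                                  edge_q = 0.9, ntree = 1000, mtry = NULL,
                                  seed = 1) {
  edge_policy <- match.arg(edge_policy)
  if (length(pathway) < 1) abort_bad_arg("`pathway` must be non-empty")
  if (length(intersect(pathway, pool)) > 0) {
    abort_bad_arg("`pathway` and `pool` must be disjoint")
  }
  layer_counts <- if (!is.null(match_to)) {
    stopifnot(inherits(match_to, "hgrn"))
    lengths(match_to$layers)[-1]
  } else {
    if (is.null(n_select)) {
      abort_bad_arg("baseline needs `match_to` or `n_select`")
    }
    rep(n_select, n_layers)
  }
  if (!is.null(weights) && is.null(names(weights))) names(weights) <- pathway

  layers <- list(pathway)
  bottom <- pathway
  w <- weights
  remaining <- pool
  edges <- list()
  tables <- list()
  unified <- list()

  for (lv in seq_along(layer_counts)) {
    if (length(remaining) == 0) {
      warn(sprintf("pool exhausted after %d layer(s); stopping early", lv - 1))
      break
    }
    res <- build_layer(expr, bottom, remaining, weights = w,
                       selection = "fixed", n_select = layer_counts[lv],
                       edge_policy = edge_policy, edge_q = edge_q,
                       ntree = ntree, mtry = mtry, seed = seed, layer = lv,
                       baseline = TRUE)
    if (length(res$selected) == 0) {
      warn(sprintf("no regulators selected for layer %d; stopping early", lv))
      break
    }
    layers[[lv + 1]] <- res$selected
    edges[[lv]] <- res$edges
    tables[[lv]] <- res$table
    unified[[lv]] <- res$unified
    remaining <- setdiff(remaining, res$selected)
    bottom <- res$selected
    w <- NULL
  }

  out <- new_hgrn(
    layers,
    if (length(edges) > 0) dplyr::bind_rows(edges) else
      tibble::tibble(regulator = character(), target = character(),
                     layer = integer(), importance = numeric()),
    tables, unified, vector("list", length(layers) - 1),
    params = list(n_layers = length(layer_counts), selection = "fixed",
                  n_select = layer_counts, edge_policy = edge_policy,
                  edge_q = edge_q, rate = NA_real_, ntree = ntree, mtry = mtry,
                  seed = seed, baseline = TRUE)
  )
  validate_hgrn(out, pathway)
  out
}

#' @method tidy hgrn
#' @export
tidy.hgrn <- function(x, ...) {
  tibble::as_tibble(x$edges) |>
    dplyr::arrange(dplyr::desc(.data$layer), dplyr::desc(.data$importance),
                   .data$regulator, .data$target)
}

#' @method glance hgrn
#' @export
glance.hgrn <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$layers) - 1L,
    n_genes = length(unlist(x$layers)),
    n_edges = nrow(x$edges),
    baseline = isTRUE(x$params$baseline)
  )
}

#' @export
print.hgrn <- function(x, ...) {
  kind <- if (isTRUE(x$params$baseline)) "single-pass baseline" else
    "backward-elimination"
  cat(sprintf("Hierarchical GRN (%s): %d regulator layer(s), %d edges\n",
              kind, length(x$layers) - 1L, nrow(x$edges)))
  for (i in seq_along(x$layers)) {
    ids <- x$layers[[i]]
    shown <- paste(head(ids, 8), collapse = ", ")
    if (length(ids) > 8) shown <- paste0(shown, ", ...")
    cat(sprintf("  layer %d (%d genes): %s\n", i - 1L, length(ids), shown))
  }
  invisible(x)
}

#' @method autoplot hgrn
#' @export
autoplot.hgrn <- function(object, ...) {
  nodes <- tibble::tibble(
    name = unlist(object$layers),
    layer = rep(seq_along(object$layers) - 1L, lengths(object$layers))
  ) |>
    dplyr::group_by(.data$layer) |>
    dplyr::mutate(x = (dplyr::row_number() - 0.5) / dplyr::n()) |>
    dplyr::ungroup()
  edges <- object$edges |>
    dplyr::left_join(nodes, by = c("regulator" = "name")) |>
    dplyr::rename(x_from = "x", layer_from = "layer.y") |>
    dplyr::left_join(nodes, by = c("target" = "name")) |>
    dplyr::rename(x_to = "x", layer_to = "layer")
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_from, y = .data$layer_from, xend = .data$x_to,
                   yend = .data$layer_to, linewidth = .data$importance),
      colour = "grey60", alpha = 0.6
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 1.2))
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$layer),
                        size = 3, colour = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$layer,
                                    label = .data$name),
                       vjust = -1, size = 2.8) +
    ggplot2::scale_y_continuous(breaks = seq_along(object$layers) - 1L) +
    ggplot2::labs(x = NULL, y = "layer (0 = pathway)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
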