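#' Build the evaluation universe of candidate edges
#'
#' The implicit negatives of a network prediction are all regulator-target
#' pairs that could have been predicted. This helper enumerates
#' `regulators x targets`, excluding self-pairs.
#'
#' @param regulators,targets Character vectors of gene IDs.
#' @return Tibble with columns `regulator`, `target`.
#' @export
edge_universe <- function(regulators, targets) {
  tidyr::expand_grid(regulator = unique(regulators),
                     target = unique(targets)) |>
    dplyr::filter(.data$regulator != .data$target)
}

normalize_pairs <- function(df, what) {
  df <- tibble::as_tibble(df)
  if (!all(c("regulator", "target") %in% names(df))) {
    abort_bad_arg(paste0("`", what, "` needs columns regulator and target"))
  }
  df
}

pair_key <- function(df) paste(df$regulator, df$target, sep = "\r")

# join scores onto the universe (unscored pairs score 0) and flag gold pairs
scored_universe <- function(scores, gold, universe) {
  scores <- normalize_pairs(scores, "scores")
  gold <- normalize_pairs(gold, "gold")
  if (is.null(universe)) {
    universe <- dplyr::distinct(
      dplyr::bind_rows(scores[c("regulator", "target")],
                       gold[c("regulator", "target")])
    )
  }
  universe <- dplyr::distinct(normalize_pairs(universe, "universe"))
  if (!all(pair_key(gold) %in% pair_key(universe))) {
    abort_bad_arg("gold-standard pairs must be contained in the universe")
  }
  if (!("score" %in% names(scores))) {
    if ("importance" %in% names(scores)) {
      scores$score <- scores$importance
    } else {
      abort_bad_arg("`scores` needs a score (or importance) column")
    }
  }
  uk <- pair_key(universe)
  sk <- pair_key(scores)
  sc <- numeric(nrow(universe))
  hit <- match(uk, sk)
  sc[!is.na(hit)] <- scores$score[hit[!is.na(hit)]]
  universe$score <- sc
  universe$positive <- uk %in% pair_key(gold)
  universe
}

#' Confusion counts at a score threshold
#'
#' A pair is called positive when its score is at or above `threshold`;
#' universe pairs without a score rank last with score 0.
#'
#' @param scores Data frame with columns `regulator`, `target` and `score`
#'   (or `importance`).
#' @param gold Data frame of true edges (`regulator`, `target`); must be a
#'   subset of the universe.
#' @param universe All candidate pairs; `NULL` uses the union of scored and
#'   gold pairs.
#' @param threshold Score cutoff.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `p_total`, `f_total`.
#' @export
confusion_at_threshold <- function(scores, gold, universe = NULL, threshold) {
  u <- scored_universe(scores, gold, universe)
  called <- u$score >= threshold
  tibble::tibble(
    tp = sum(called & u$positive),
    fp = sum(called & !u$positive),
    fn = sum(!called & u$positive),
    tn = sum(!called & !u$positive),
    p_total = sum(u$positive),
    f_total = sum(!u$positive)
  )
}

sweep_counts <- function(u) {
  if (!any(u$positive)) abort_bad_arg("gold standard contains no positives")
  u <- u[order(-u$score, u$positive), ]
  thresholds <- sort(unique(u$score), decreasing = TRUE)
  cum_tp <- cumsum(u$positive)
  cum_fp <- cumsum(!u$positive)
  # index of the last pair included at each distinct threshold (ties grouped)
  last_at <- findInterval(-thresholds, sort(-u$score))
  tibble::tibble(
    threshold = thresholds,
    tp = cum_tp[last_at],
    fp = cum_fp[last_at],
    p_total = sum(u$positive),
    f_total = sum(!u$positive)
  )
}

curve_obj <- function(points, kind, counts) {
  structure(points, kind = kind, counts = counts,
            class = c("bw_curve", class(points)))
}

#' Precision-recall curve over score thresholds
#'
#' One point per distinct score value, descending, with ties grouped at a
#' single threshold (step semantics, no interpolation); anchored at recall 0
#' with the precision of the highest threshold. `precision = TP / (TP + FP)`,
#' `recall = TP / P_total`.
#'
#' @inheritParams confusion_at_threshold
#' @return A `bw_curve` tibble with columns `threshold`, `x` (recall),
#'   `y` (precision); the area is available via [trapz_area()].
#' @export
pr_curve <- function(scores, gold, universe = NULL) {
  u <- scored_universe(scores, gold, universe)
  if (sum(!u$positive) < 1) abort_bad_arg("universe contains no negatives")
  cts <- sweep_counts(u)
  pts <- tibble::tibble(
    threshold = c(Inf, cts$threshold),
    x = c(0, cts$tp / cts$p_total),
    y = c(cts$tp[1] / (cts$tp[1] + cts$fp[1]), cts$tp / (cts$tp + cts$fp))
  )
  curve_obj(pts, "PR", cts)
}

#' ROC curve over score thresholds
#'
#' `TPR = TP / P_total` against `FPR = FP / F_total`, one point per distinct
#' threshold plus the (0, 0) anchor; the lowest threshold includes every pair
#' and lands on (1, 1).
#'
#' @inheritParams confusion_at_threshold
#' @return A `bw_curve` tibble with columns `threshold`, `x` (FPR), `y` (TPR).
#' @export
roc_curve <- function(scores, gold, universe = NULL) {
  u <- scored_universe(scores, gold, universe)
  if (sum(!u$positive) < 1) abort_bad_arg("universe contains no negatives")
  cts <- sweep_counts(u)
  pts <- tibble::tibble(
    threshold = c(Inf, cts$threshold),
    x = c(0, cts$fp / cts$f_total),
    y = c(0, cts$tp / cts$p_total)
  )
  curve_obj(pts, "ROC", cts)
}

#' Area under an evaluation curve by the composite trapezoidal rule
#'
#' `sum_i (x_{i+1} - x_i) * (y_i + y_{i+1}) / 2` over the stored points with
#' x ascending. For ROC curves the stored FPR sequence must already be
#' non-decreasing.
#'
#' @param curve A `bw_curve` (or any data frame with `x` and `y`).
#' @return The area, a number between 0 and 1 for PR/ROC curves.
#' @export
trapz_area <- function(curve) {
  if (!all(c("x", "y") %in% names(curve))) {
    abort_bad_arg("`curve` needs x and y columns")
  }
  if (nrow(curve) < 2) abort_bad_arg("need at least 2 points")
  x <- curve$x
  y <- curve$y
  if (identical(attr(curve, "kind"), "ROC") && any(diff(x) < 0)) {
    abort_bad_arg("ROC x (FPR) must be non-decreasing")
  }
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Summarise a prediction against a gold standard
#'
#' @inheritParams confusion_at_threshold
#' @return One-row tibble: `aupr`, `auroc`, `p_total`, `f_total`.
#' @export
evaluate_edges <- function(scores, gold, universe = NULL) {
  pr <- pr_curve(scores, gold, universe)
  roc <- roc_curve(scores, gold, universe)
  cts <- attr(roc, "counts")
  tibble::tibble(
    aupr = trapz_area(pr),
    auroc = trapz_area(roc),
    p_total = cts$p_total[1],
    f_total = cts$f_total[1]
  )
}

#' @method autoplot bw_curve
#' @export
autoplot.bw_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  labs <- if (identical(kind, "PR")) {
    c("recall", "precision")
  } else {
    c("false positive rate", "true positive rate")
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = labs[1], y = labs[2],
      title = sprintf("%s curve (area %.3f)", kind, trapz_area(object))
    ) +
    ggplot2::theme_minimal()
  if (identical(kind, "ROC")) {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0,
                                  linetype = "dashed", colour = "grey60")
  }
  p
}
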