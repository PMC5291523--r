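# Small fixtures built in code; every test data set is derived from a seed.

# tiny expression matrix with named samples/genes
tiny_expr <- function(n = 6, genes = c("g1", "g2", "g3"), seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n * length(genes)), nrow = n,
              dimnames = list(paste0("s", seq_len(n)), genes))
  m
}

# scored pairs where all gold edges outrank all others (perfect ranking)
perfect_scores <- function(n_pos = 3, n_neg = 5) {
  tibble::tibble(
    regulator = paste0("r", seq_len(n_pos + n_neg)),
    target = "t",
    score = c(seq(2, 1.5, length.out = n_pos), seq(1, 0.5, length.out = n_neg))
  )
}

perfect_gold <- function(n_pos = 3) {
  tibble::tibble(regulator = paste0("r", seq_len(n_pos)), target = "t")
}

# independent brute-force PR/ROC sweep used as the curve oracle
brute_force_curves <- function(scores, gold, universe) {
  uk <- paste(universe$regulator, universe$target)
  sk <- paste(scores$regulator, scores$target)
  gk <- paste(gold$regulator, gold$target)
  s <- stats::setNames(rep(0, nrow(universe)), uk)
  s[sk[sk %in% uk]] <- scores$score[sk %in% uk]
  pos <- uk %in% gk
  p_total <- sum(pos)
  f_total <- sum(!pos)
  th <- sort(unique(s), decreasing = TRUE)
  pts <- t(vapply(th, function(t) {
    called <- s >= t
    tp <- sum(called & pos)
    fp <- sum(called & !pos)
    c(tp = tp, fp = fp)
  }, c(tp = 0, fp = 0)))
  list(
    pr = data.frame(x = c(0, pts[, "tp"] / p_total),
                    y = c(pts[1, "tp"] / (pts[1, "tp"] + pts[1, "fp"]),
                          pts[, "tp"] / (pts[, "tp"] + pts[, "fp"]))),
    roc = data.frame(x = c(0, pts[, "fp"] / f_total),
                     y = c(0, pts[, "tp"] / p_total))
  )
}

trapz_direct <- function(x, y) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  sum((x[-1] - x[-length(x)]) * (y[-1] + y[-length(y)]) / 2)
}
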