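test_that("one elimination round removes the floor(rate * n) lowest, at least one", {
  imp10 <- stats::setNames(10:1, paste0("t", 1:10))
  r <- eliminate_round(imp10, 0.1)
  expect_length(r$removed, 1)
  expect_equal(r$removed, "t10")  # the lowest

  imp5 <- stats::setNames(5:1, paste0("t", 1:5))
  r5 <- eliminate_round(imp5, 0.1)  # floor(0.5) = 0, but always remove >= 1
  expect_length(r5$removed, 1)

  # ties at the cutoff: the lexicographically larger ID goes first
  tied <- stats::setNames(c(1, 1, 5), c("aa", "ab", "zz"))
  expect_equal(eliminate_round(tied, 0.4)$removed, "ab")

  expect_error(eliminate_round(stats::setNames(1, "only"), 0.1),
               class = "bwerf_validation_error")
})

test_that("the survivor-count trajectory follows the removal recurrence", {
  # rate 0.5 from 10: 10 -> 5 -> 3 -> 2 -> 1, i.e. 4 elimination rounds
  n <- 10
  traj <- n
  while (n > 1) {
    n <- n - max(1, floor(0.5 * n))
    traj <- c(traj, n)
  }
  expect_equal(traj, c(10, 5, 3, 2, 1))

  set.seed(21)
  X <- matrix(rnorm(30 * 10), 30, dimnames = list(NULL, paste0("t", 1:10)))
  y <- X[, 1] + rnorm(30, sd = 0.5)
  el <- backward_eliminate(X, y, rate = 0.5, ntree = 25, seed = 1)
  counts <- el$trace |>
    dplyr::count(round) |>
    dplyr::pull(n)
  expect_equal(counts, c(10, 5, 3, 2))  # pools actually modelled
  expect_equal(el$n_rounds, 4)
})

test_that("elimination traces partition the pool and are reproducible", {
  set.seed(31)
  X <- matrix(rnorm(40 * 12), 40, dimnames = list(NULL, paste0("g", 1:12)))
  y <- 2 * X[, 3] + rnorm(40, sd = 0.4)

  el <- backward_eliminate(X, y, rate = 0.2, ntree = 30, seed = 5)
  eliminated <- el$trace$feature[el$trace$eliminated]
  expect_setequal(c(eliminated, el$survivor), colnames(X))
  expect_equal(length(eliminated) + 1, ncol(X))  # exact partition, no repeats

  # survivor counts strictly decrease round over round
  sizes <- el$trace |> dplyr::count(round) |> dplyr::pull(n)
  expect_true(all(diff(sizes) < 0))

  # same seed, identical result; the trace too
  el2 <- backward_eliminate(X, y, rate = 0.2, ntree = 30, seed = 5)
  expect_identical(el$final, el2$final)
  expect_identical(el$trace, el2$trace)

  # every feature's final importance comes from the round of its last model
  last_mod <- el$trace |>
    dplyr::group_by(feature) |>
    dplyr::summarise(round = max(round))
  expect_equal(
    dplyr::arrange(el$final[c("feature", "round")], feature),
    dplyr::arrange(last_mod, feature)
  )
})

test_that("a single-regulator pool skips elimination but is still scored", {
  set.seed(41)
  X <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "solo"))
  y <- X[, 1] + rnorm(20, sd = 0.2)
  el <- backward_eliminate(X, y, ntree = 20, seed = 2)
  expect_equal(el$n_rounds, 1)
  expect_equal(el$survivor, "solo")
  expect_gt(el$final$importance, 0)
  expect_false(any(el$trace$eliminated))
})

test_that("aggregation is the weighted sum over pathway genes", {
  tab <- tibble::tibble(
    regulator = rep(c("t"), 2),
    target = c("g1", "g2"),
    importance = c(2.0, 3.0)
  )
  expect_equal(aggregate_importance(tab)$importance, 5.0)
  expect_equal(
    aggregate_importance(tab, c(g1 = 1, g2 = 0))$importance, 2.0)
  expect_equal(
    aggregate_importance(tab, c(g1 = 2, g2 = 0.5))$importance, 5.5)

  # linearity: scaling all weights scales every unified value
  tab2 <- tidyr::expand_grid(regulator = c("a", "b"), target = c("g1", "g2")) |>
    dplyr::mutate(importance = c(1, 2, 3, 4))
  u1 <- aggregate_importance(tab2, c(g1 = 1, g2 = 2))
  u3 <- aggregate_importance(tab2, c(g1 = 3, g2 = 6))
  expect_equal(u3$importance, 3 * u1$importance)

  expect_error(aggregate_importance(tab, c(g1 = 1)),
               class = "bwerf_validation_error")
  expect_error(aggregate_importance(tab, c(g1 = -1, g2 = 1)),
               class = "bwerf_validation_error")
  expect_error(aggregate_importance(tab[c(1, 1), ]),
               class = "bwerf_validation_error")
})

test_that("elimination lifts true regulators above noise on a toys-style problem", {
  # scaled-down single-target design: 6 true TFs, 50 noise TFs, n = 100
  hits <- 0
  for (s in 1:10) {
    toys <- simulate_toys(n_noise = 50, seed = 300 + s)
    X <- toys$expression[, toys$regulators]
    y <- toys$expression[, "y"]
    el <- backward_eliminate(X, y, rate = 0.1, ntree = 200, seed = s)
    strong <- paste0("X", 4:6)
    noise_imp <- el$final$importance[!(el$final$feature %in% paste0("X", 1:6))]
    strong_imp <- el$final$importance[el$final$feature %in% strong]
    if (all(strong_imp > max(noise_imp))) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
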