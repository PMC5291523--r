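#' One-dimensional Gaussian mixture fitted by expectation-maximization
#'
#' The unified importance values coming out of backward elimination are
#' treated as i.i.d. draws from a K-component Gaussian mixture
#' `g(x) = sum_k alpha_k N(x; mu_k, sigma2_k)`: a broad low-mean background of
#' non-regulators and a high-mean component of genuine regulators. [em_fit()]
#' estimates the parameters, [extract_top_component()] keeps the points whose
#' posterior is maximal for the component with the largest mean.
#'
#' @name bw_gmm
NULL

new_bw_gmm <- function(alpha, mu, sigma2, loglik = NA_real_, n_iter = NA_integer_,
                       converged = NA, loglik_trace = numeric()) {
  structure(
    list(K = length(alpha), alpha = alpha, mu = mu, sigma2 = sigma2,
         loglik = loglik, n_iter = n_iter, converged = converged,
         loglik_trace = loglik_trace),
    class = "bw_gmm"
  )
}

validate_gmm <- function(model) {
  if (!inherits(model, "bw_gmm")) abort_bad_arg("`model` must be a bw_gmm")
  if (model$K < 2) abort_bad_arg("mixture needs K > 1 components")
  if (any(model$alpha <= 0) || abs(sum(model$alpha) - 1) > 1e-8) {
    abort_bad_arg("mixing proportions must be positive and sum to 1")
  }
  if (any(model$sigma2 <= 0)) abort_bad_arg("variances must be positive")
  invisible(model)
}

# log of component-weighted densities, N x K
log_weighted_dens <- function(x, model) {
  vapply(seq_len(model$K), function(k) {
    log(model$alpha[k]) + dnorm(x, model$mu[k], sqrt(model$sigma2[k]), log = TRUE)
  }, numeric(length(x)))
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' E-step: posterior membership weights
#'
#' Computes `w_ik = alpha_k phi_k(x_i) / sum_k alpha_k phi_k(x_i)` for every
#' point and component, in log space so that points far in the tails never
#' divide zero by zero. Each row of the result sums to 1.
#'
#' @param x Numeric vector of N importance values.
#' @param model A `bw_gmm` (current parameter values).
#' @return N x K matrix of membership weights.
#' @export
e_step <- function(x, model) {
  validate_gmm(model)
  if (length(x) < 1) abort_bad_arg("`x` must be non-empty")
  ld <- log_weighted_dens(x, model)
  if (length(x) == 1) ld <- matrix(ld, nrow = 1)
  w <- exp(ld - logsumexp_rows(ld))
  w / rowSums(w)
}

#' M-step: re-estimate mixture parameters from membership weights
#'
#' Given membership weights, applies the closed-form updates
#' `alpha_k = N_k / N`, `mu_k = sum_i w_ik x_i / N_k`,
#' `sigma2_k = sum_i w_ik (x_i - mu_k)^2 / N_k` with `N_k = sum_i w_ik`.
#' Variances are floored at `var_floor` so tied importance values cannot
#' collapse a component to a point mass.
#'
#' @param x Numeric vector of N values.
#' @param weights N x K membership matrix with rows summing to 1.
#' @param var_floor Lower bound for component variances; default
#'   `1e-8 * var(x)` (or 1e-12 when x is constant).
#' @return A `bw_gmm` with the updated parameters.
#' @export
m_step <- function(x, weights, var_floor = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != length(x)) abort_bad_arg("weights rows must match length(x)")
  if (any(abs(rowSums(weights) - 1) > 1e-8)) {
    abort_bad_arg("membership weight rows must sum to 1")
  }
  if (is.null(var_floor)) {
    gv <- if (length(x) > 1) var(x) else 0
    var_floor <- max(1e-8 * gv, 1e-12)
  }
  nk <- colSums(weights)
  alpha <- nk / length(x)
  mu <- colSums(weights * x) / nk
  sigma2 <- vapply(seq_along(nk), function(k) {
    sum(weights[, k] * (x - mu[k])^2) / nk[k]
  }, numeric(1))
  new_bw_gmm(alpha, mu, pmax(sigma2, var_floor))
}

# deterministic uniforms on (0,1) from a Lehmer stream; keeps the restart
# jitters independent of R's global RNG state
hash_unif <- function(seed, n) {
  h <- (as.double(seed) %% 2147483646) + 1
  vapply(seq_len(n), function(i) {
    h <<- (h * 48271) %% 2147483647
    h / 2147483647
  }, numeric(1))
}

em_init <- function(x, K, jitter_sd = 0, seed = 1) {
  # component k seeded at the (k - 0.5)/K quantile; equal weights,
  # shared global variance
  mu <- unname(quantile(x, (seq_len(K) - 0.5) / K, type = 7))
  if (jitter_sd > 0) {
    mu <- mu + jitter_sd * (2 * hash_unif(seed, K) - 1)
  }
  gv <- max(var(x), 1e-12)
  new_bw_gmm(rep(1 / K, K), mu, rep(gv, K))
}

em_run <- function(x, model, tol, max_iter, var_floor) {
  ll_trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    ld <- log_weighted_dens(x, model)
    ll <- sum(logsumexp_rows(ld))
    ll_trace <- c(ll_trace, ll)
    w <- exp(ld - logsumexp_rows(ld))
    w <- w / rowSums(w)
    nk <- colSums(w)
    if (any(nk < 1e-10)) {
      # empty component: re-seed it at the point the model explains worst
      worst <- which.min(logsumexp_rows(ld))
      k_empty <- which(nk < 1e-10)[1]
      model$mu[k_empty] <- x[worst]
      model$sigma2[k_empty] <- max(var(x), var_floor)
      model$alpha <- rep(1 / model$K, model$K)
      next
    }
    model <- m_step(x, w, var_floor = var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  model$loglik <- ll_trace[length(ll_trace)]
  model$n_iter <- iter
  model$converged <- converged
  model$loglik_trace <- ll_trace
  model
}

#' Fit a K-component Gaussian mixture by EM
#'
#' Alternates [e_step()] and [m_step()] until the log-likelihood changes by
#' less than `tol`, starting from a quantile-based initialisation plus
#' `restarts` randomly jittered restarts; the fit with the best log-likelihood
#' wins. The log-likelihood is non-decreasing along any single run (the EM
#' guarantee), which [glance()] exposes via the trace.
#'
#' @param x Numeric vector of importance values, length N >= 2K.
#' @param K Number of components (> 1); default 2, background vs regulators.
#' @param tol Convergence tolerance on the log-likelihood; default 1e-8.
#' @param max_iter Iteration cap per run; default 500.
#' @param restarts Number of jittered restarts beyond the quantile start.
#' @param seed Seed for the restart jitters.
#' @return A fitted `bw_gmm`.
#' @export
em_fit <- function(x, K = 2, tol = 1e-8, max_iter = 500, restarts = 5, seed = 1) {
  x <- as.numeric(x)
  if (K < 2) abort_bad_arg("`K` must be > 1")
  if (length(x) < 2 * K) {
    abort_bad_arg("need at least 2K points to fit a K-component mixture")
  }
  gv <- max(var(x), 1e-12)
  var_floor <- max(1e-8 * gv, 1e-300)
  sdx <- sqrt(gv)
  best <- NULL
  for (r in 0:restarts) {
    init <- em_init(x, K, jitter_sd = if (r == 0) 0 else 0.5 * sdx,
                    seed = derive_seed(seed, r))
    fit <- em_run(x, init, tol = tol, max_iter = max_iter, var_floor = var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' Select the points belonging to the top-mean component
#'
#' Runs an E-step under the fitted model and flags the points whose largest
#' membership weight lies on the component with the largest mean — the
#' putative regulators. Ties (in means or in responsibilities) resolve to the
#' lower component index.
#'
#' @param x Numeric vector the model was fitted to.
#' @param model A fitted `bw_gmm`.
#' @return Logical mask over `x`.
#' @export
extract_top_component <- function(x, model) {
  w <- e_step(x, model)
  top <- which(model$mu == max(model$mu))[1]
  assign_k <- apply(w, 1, which.max)  # which.max takes the first on ties
  assign_k == top
}

#' @method tidy bw_gmm
#' @export
tidy.bw_gmm <- function(x, ...) {
  tibble::tibble(component = seq_len(x$K), alpha = x$alpha, mu = x$mu,
                 sigma2 = x$sigma2)
}

#' @method glance bw_gmm
#' @export
glance.bw_gmm <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged)
}

#' @export
print.bw_gmm <- function(x, ...) {
  cat("Gaussian mixture (K =", x$K, "), log-likelihood",
      format(x$loglik, digits = 6), "\n")
  print(tidy(x))
  invisible(x)
}

#' @method autoplot bw_gmm
#' @export
autoplot.bw_gmm <- function(object, x = NULL, ...) {
  pars <- tidy(object)
  p <- ggplot2::ggplot()
  if (!is.null(x)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = x),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 50, fill = "grey80", colour = "grey50"
    )
    grid <- seq(min(x), max(x), length.out = 400)
  } else {
    lo <- min(pars$mu - 4 * sqrt(pars$sigma2))
    hi <- max(pars$mu + 4 * sqrt(pars$sigma2))
    grid <- seq(lo, hi, length.out = 400)
  }
  dens <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble::tibble(component = factor(k), x = grid,
                   density = pars$alpha[k] *
                     dnorm(grid, pars$mu[k], sqrt(pars$sigma2[k])))
  })
  p +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "unified importance", y = "density",
                  colour = "component") +
    ggplot2::theme_minimal()
}
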