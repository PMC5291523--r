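#' Simulate the "toys" benchmark: one pathway gene, six true regulators
#'
#' Generates the classic single-target benchmark for regulator ranking: a
#' pathway gene `y` driven additively by six true TFs among a sea of
#' independent noise TFs. The defaults reproduce the study design —
#' `X_i ~ N(1, 1)` for the weak block (i = 1..3), `X_i ~ N(3, 1)` for the
#' strong block (i = 4..6), `X_i ~ N(0, 1)` for 1000 noise TFs,
#' `y = X_1 + ... + X_6 + z` with `z ~ N(0, 0.1)`, and 100 samples. The weak
#' block contributes the same unit coefficient but from a lower baseline, so
#' it is the part most easily drowned by noise variables.
#'
#' The second parameter of every normal law is read as a **variance**
#' (`N(1, 1)`, `N(3, 1)` are indistinguishable under either convention; for
#' `z ~ N(0, 0.1)` set `noise_scale_is_sd = TRUE` to switch).
#'
#' @param n_samples Number of samples (default 100).
#' @param n_weak,n_strong Sizes of the weak (mean 1) and strong (mean 3) true
#'   regulator blocks; defaults 3 and 3.
#' @param n_noise Number of mean-0 noise TFs (default 1000).
#' @param noise_scale Second parameter of the response noise law `z`
#'   (default 0.1).
#' @param noise_scale_is_sd Interpret `noise_scale` as a standard deviation
#'   instead of a variance.
#' @param seed Integer seed; the generator is exactly reproducible from it.
#' @return List with `expression` (samples x (1 + TFs) matrix; first column
#'   `y`), `pathway` (`"y"`), `regulators` (all TF IDs), `truth` (tibble of
#'   true edges), and `config`.
#' @export
simulate_toys <- function(n_samples = 100, n_weak = 3, n_strong = 3,
                          n_noise = 1000, noise_scale = 0.1,
                          noise_scale_is_sd = FALSE, seed = 1) {
  stopifnot(n_samples >= 2, n_weak >= 0, n_strong >= 0, n_noise >= 0,
            noise_scale > 0)
  rng <- local_rng(derive_seed(seed, 7001))
  on.exit(rng())
  n_tf <- n_weak + n_strong + n_noise
  X <- matrix(rnorm(n_samples * n_tf), nrow = n_samples)
  if (n_weak > 0) X[, seq_len(n_weak)] <- X[, seq_len(n_weak)] + 1
  if (n_strong > 0) X[, n_weak + seq_len(n_strong)] <- X[, n_weak + seq_len(n_strong)] + 3
  colnames(X) <- paste0("X", seq_len(n_tf))
  z_sd <- if (noise_scale_is_sd) noise_scale else sqrt(noise_scale)
  n_true <- n_weak + n_strong
  y <- rowSums(X[, seq_len(n_true), drop = FALSE]) + rnorm(n_samples, sd = z_sd)

  expr <- cbind(y = y, X)
  rownames(expr) <- paste0("S", seq_len(n_samples))
  truth <- tibble::tibble(
    regulator = colnames(X)[seq_len(n_true)],
    target = "y",
    layer = 1L
  )
  list(
    expression = expr,
    pathway = "y",
    regulators = colnames(X),
    truth = truth,
    config = list(n_samples = n_samples, n_weak = n_weak, n_strong = n_strong,
                  n_noise = n_noise, noise_scale = noise_scale,
                  noise_scale_is_sd = noise_scale_is_sd, seed = seed)
  )
}

# run code under a private R RNG state; returns a restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed %% 2147483647)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Append noise regulators to an expression matrix
#'
#' Emulates the in-silico validation design of spiking a TF pool with
#' uninformative profiles before network inference. `"gaussian"` appends
#' standard-normal columns; `"permuted"` (the default) appends sample-permuted
#' copies of randomly chosen existing columns, which destroys any association
#' with the targets while preserving each profile's marginal distribution —
#' the closest analogue of drawing real non-regulator genes from the same
#' expression data set.
#'
#' @param expr Samples x genes numeric matrix with column names.
#' @param count Number of noise columns to append.
#' @param mode `"permuted"` or `"gaussian"`.
#' @param prefix Name prefix for the appended columns.
#' @param seed Integer seed.
#' @return The matrix with `count` extra columns `prefix1..prefixcount`.
#' @export
add_noise_genes <- function(expr, count, mode = c("permuted", "gaussian"),
                            prefix = "noise", seed = 1) {
  mode <- match.arg(mode)
  if (count < 0) abort_bad_arg("`count` must be >= 0")
  if (count == 0) return(expr)
  if (mode == "permuted" && ncol(expr) == 0) {
    abort_bad_arg("permuted mode needs at least one existing column")
  }
  rng <- local_rng(derive_seed(seed, 7002))
  on.exit(rng())
  n <- nrow(expr)
  noise <- if (mode == "gaussian") {
    matrix(rnorm(n * count), nrow = n)
  } else {
    src <- sample.int(ncol(expr), count, replace = TRUE)
    vapply(src, function(j) expr[sample.int(n), j], numeric(n))
  }
  colnames(noise) <- paste0(prefix, seq_len(count))
  cbind(expr, noise)
}

#' Simulate a multilayered hierarchical regulatory network
#'
#' Ground-truth generator for recovery experiments on the layered builder.
#' Top-layer regulators are independent standard normals; every variable in a
#' lower layer is a positive-coefficient linear combination of 1-3 randomly
#' chosen parents in the layer immediately above, plus Gaussian noise. Decoy
#' TFs are independent standard normals with no descendants, so the generating
#' edge set is the exact gold standard for evaluation.
#'
#' @param layer_sizes Integer vector of layer sizes from the top layer down to
#'   the bottom (pathway) layer; at least 2 layers.
#' @param n_samples Number of samples (default 200).
#' @param n_decoys Number of decoy TFs appended to the regulator pool
#'   (default 100).
#' @param coeff_range Range of the uniform positive regulatory coefficients.
#' @param noise_scale Standard deviation of the additive noise on each
#'   regulated variable (default 1.5, putting per-target model fits in the
#'   realistic microarray regime of R^2 ~ 0.3-0.6 rather than at ceiling);
#'   0 gives the exactly reproducible noiseless limit.
#' @param max_parents Maximum number of parents per regulated variable.
#' @param seed Integer seed.
#' @return List with `expression` (samples x all variables), `pathway`
#'   (bottom-layer IDs), `regulators` (upper-layer IDs plus decoys), `truth`
#'   (tibble regulator/target/layer/coefficient; `layer` is the regulator's
#'   layer counted from the bottom layer = 0), and `layers` (IDs per layer,
#'   bottom first).
#' @export
simulate_hierarchical <- function(layer_sizes, n_samples = 200, n_decoys = 100,
                                  coeff_range = c(0.5, 1.5), noise_scale = 1.5,
                                  max_parents = 3, seed = 1) {
  if (length(layer_sizes) < 2) abort_bad_arg("need at least 2 layers")
  if (any(layer_sizes < 1)) abort_bad_arg("all layer sizes must be >= 1")
  rng <- local_rng(derive_seed(seed, 7003))
  on.exit(rng())

  n_layers <- length(layer_sizes)
  # layer index from the bottom: bottom layer 0, top layer n_layers - 1
  layer_of <- rev(seq_len(n_layers) - 1L)
  ids <- lapply(seq_len(n_layers), function(i) {
    lv <- layer_of[i]
    if (lv == 0) paste0("T", seq_len(layer_sizes[i]))
    else paste0("L", lv, "_", seq_len(layer_sizes[i]))
  })

  cols <- list()
  truth <- list()
  top <- matrix(rnorm(n_samples * layer_sizes[1]), nrow = n_samples)
  colnames(top) <- ids[[1]]
  cols[[1]] <- top
  for (i in 2:n_layers) {
    above <- cols[[i - 1]]
    mat <- matrix(0, nrow = n_samples, ncol = layer_sizes[i])
    colnames(mat) <- ids[[i]]
    for (j in seq_len(layer_sizes[i])) {
      k <- sample.int(min(max_parents, ncol(above)), 1)
      parents <- sample.int(ncol(above), k)
      coefs <- runif(k, coeff_range[1], coeff_range[2])
      mat[, j] <- above[, parents, drop = FALSE] %*% coefs +
        rnorm(n_samples, sd = noise_scale)
      truth[[length(truth) + 1]] <- tibble::tibble(
        regulator = colnames(above)[parents],
        target = ids[[i]][j],
        layer = layer_of[i] + 1L,
        coefficient = coefs
      )
    }
    cols[[i]] <- mat
  }

  expr <- do.call(cbind, cols)
  decoys <- NULL
  if (n_decoys > 0) {
    decoys <- matrix(rnorm(n_samples * n_decoys), nrow = n_samples)
    colnames(decoys) <- paste0("N", seq_len(n_decoys))
    expr <- cbind(expr, decoys)
  }
  rownames(expr) <- paste0("S", seq_len(n_samples))

  pathway <- ids[[n_layers]]
  regulators <- c(unlist(ids[-n_layers]), colnames(decoys))
  list(
    expression = expr,
    pathway = pathway,
    regulators = regulators,
    truth = dplyr::bind_rows(truth),
    layers = rev(ids),  # bottom first
    config = list(layer_sizes = layer_sizes, n_samples = n_samples,
                  n_decoys = n_decoys, coeff_range = coeff_range,
                  noise_scale = noise_scale, max_parents = max_parents,
                  seed = seed)
  )
}
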