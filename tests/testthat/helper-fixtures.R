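# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# small in-memory synthetic dataset: 4 classes x 12 images at 32 px
fixture_small_dataset <- function() {
  if (is.null(.fixtures$small)) {
    counts <- stats::setNames(rep(12L, 4L), cultivar_presets()$cultivar[c(1, 3, 6, 10)])
    man <- generate_leaf_dataset(counts, seed = 404, size = 32, keep_images = TRUE)
    man$class_id <- as.integer(factor(man$class_id))
    .fixtures$small <- man
  }
  .fixtures$small
}

# random ft tensor helper
rand_ft <- function(H, W, C, N, seed = 1) {
  set.seed(seed)
  ft(matrix(stats::rnorm(H * W * N * C), H * W * N, C), H, W, N)
}

# numerical gradient of a scalar function
num_grad <- function(fn, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# engine internals used across tests
eng_fwd <- vitileaf:::eng_fwd
eng_bwd <- vitileaf:::eng_bwd
eng_params <- vitileaf:::eng_params
eng_set <- vitileaf:::eng_set
ft <- vitileaf:::ft
ft_like <- vitileaf:::ft_like
as_ft <- vitileaf:::as_ft
ft_to_array <- vitileaf:::ft_to_array
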