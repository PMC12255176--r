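# Independent oracles and small fixture builders used across the suite.

# O(N^4) direct-DFT power spectrum (brute force; only for tiny images)
brute_power_spectrum <- function(y) {
  n <- nrow(y); m <- ncol(y)
  p <- matrix(0, n, m)
  for (u in 0:(n - 1)) for (v in 0:(m - 1)) {
    acc <- 0 + 0i
    for (r in 0:(n - 1)) for (c in 0:(m - 1))
      acc <- acc + y[r + 1, c + 1] * exp(-2i * pi * (u * r / n + v * c / m))
    p[u + 1, v + 1] <- Mod(acc)^2
  }
  p
}

# naive WAIC from first principles (plain loops, no log-sum-exp tricks)
naive_waic <- function(loglik) {
  n <- ncol(loglik)
  lppd <- 0; p <- 0; pw <- numeric(n)
  for (i in seq_len(n)) {
    li <- log(mean(exp(loglik[, i])))
    vi <- var(loglik[, i])
    lppd <- lppd + li; p <- p + vi
    pw[i] <- li - vi
  }
  list(elpd = lppd - p, p_waic = p, se = sqrt(n * var(pw)))
}

# loglik matrix whose WAIC elpd is exactly `target` (constant draws)
constant_waic <- function(target, n_points = 4, draws = 10) {
  waic(matrix(target / n_points, draws, n_points))
}

# tiny deterministic RGB test image with structure in every channel
toy_image <- function(n = 16, seed = 1) {
  with_seed(seed, {
    img <- array(runif(n * n * 3, 0.2, 0.8), c(n, n, 3))
    img[seq_len(n / 2), , 1] <- img[seq_len(n / 2), , 1] + 0.15
    clamp01(img)
  })
}

# small synthetic stimulus set, half scenes half textures
stimulus_set <- function(n_per_type, size = 64, seed0 = 100) {
  imgs <- list()
  for (k in seq_len(n_per_type)) {
    imgs[[sprintf("scene%02d", k)]] <- generate_scene_image(size, seed0 + k)
    imgs[[sprintf("texture%02d", k)]] <- generate_texture_image(size, seed0 + 500 + k)
  }
  imgs
}

# quick small trial table for model-contract tests
tiny_trials <- function(seed = 5) {
  simulate_experiment(observer_truth(grains = c(1, 5)), participants = 3,
                      images_per_type = 3, reaches = c(1, 3, 8),
                      trials_per_cell = 2, seed = seed)
}
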