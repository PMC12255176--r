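# Synthetic stimuli and simulated observers: texture-like and scene-like
# image generators separable in the (CE, SC) plane, and odd-one-out trial
# simulation from the generative psychometric model.

#' Generate a texture-like image
#'
#' Stationary band-pass-filtered Gaussian noise, amplitude-modulated by a
#' smooth log-normal envelope and kept at low overall contrast, with mild
#' chromatic modulation: a stand-in for texture-heavy photographic
#' content. The low contrast keeps the fitted Weibull scale (CE) small
#' and the heavy-tailed envelope keeps the fitted shape (SC) small, so
#' the population sits in the low-CE/low-SC corner of the statistic
#' plane, clearly below the scene population.
#'
#' @param size Side length in pixels (default 128).
#' @param seed Integer seed.
#' @param band_sigma Smoothing scale of the noise carrier in px
#'   (default 3).
#' @param contrast Amplitude of the luminance modulation (default 0.05).
#' @param envelope Log-amplitude SD of the multiplicative envelope
#'   (default 1.2).
#' @return `size x size x 3` array in `[0, 1]`.
#' @export
generate_texture_image <- function(size = 128, seed = 1, band_sigma = 3,
                                   contrast = 0.05, envelope = 1.2) {
  with_seed(seed, {
    base <- gaussian_blur(matrix(rnorm(size^2), size, size), band_sigma)
    base <- base - gaussian_blur(base, 4 * band_sigma)   # band-pass
    env <- gaussian_blur(matrix(rnorm(size^2), size, size), 8)
    base <- base * exp(envelope * env / sd(env))
    base <- base / sd(base) * contrast
    chroma <- gaussian_blur(matrix(rnorm(size^2), size, size), 2 * band_sigma)
    chroma <- chroma / sd(chroma) * contrast / 3
    img <- array(0, c(size, size, 3))
    img[, , 1] <- 0.5 + base + chroma
    img[, , 2] <- 0.5 + base
    img[, , 3] <- 0.5 + base - chroma
    clamp01(img)
  })
}

#' Generate a scene-like image
#'
#' Composition of 5 to 15 random filled polygons and ellipses with sharp
#' boundaries and heterogeneous contrasts over a smooth background, plus
#' a fine low-amplitude luminance grain everywhere: a stand-in for
#' object/scene photographs. The strong heterogeneous edges push the
#' fitted Weibull scale (CE) up, and the grain gives the contrast
#' distribution a solid floor that keeps the fitted shape (SC) high, so
#' the population sits in the high-CE/high-SC corner of the statistic
#' plane. Deterministic per seed.
#'
#' @param size Side length in pixels (default 128).
#' @param seed Integer seed.
#' @param n_shapes Range of shape counts (default `c(5, 15)`).
#' @param grain_sd Amplitude of the fine luminance grain (default 0.04).
#' @return `size x size x 3` array in `[0, 1]`.
#' @export
generate_scene_image <- function(size = 128, seed = 1, n_shapes = c(5, 15),
                                 grain_sd = 0.04) {
  with_seed(seed, {
    xs <- matrix(rep(seq_len(size), each = size), size, size)   # column coord
    ys <- matrix(rep(seq_len(size), times = size), size, size)  # row coord
    bg <- gaussian_blur(matrix(rnorm(size^2), size, size), size / 8)
    bg <- 0.5 + bg / sd(bg) * 0.08
    img <- array(0, c(size, size, 3))
    for (ch in 1:3) img[, , ch] <- bg
    n <- sample(seq(n_shapes[1], n_shapes[2]), 1)
    for (s in seq_len(n)) {
      cx <- runif(1, 0.1, 0.9) * size; cy <- runif(1, 0.1, 0.9) * size
      col <- runif(3, 0.02, 0.98)
      if (runif(1) < 0.5) {                       # ellipse
        a <- runif(1, 0.05, 0.25) * size; b <- runif(1, 0.05, 0.25) * size
        th <- runif(1, 0, pi)
        u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
        v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
        mask <- (u / a)^2 + (v / b)^2 <= 1
      } else {                                    # convex polygon (triangle)
        px <- cx + runif(3, -0.25, 0.25) * size
        py <- cy + runif(3, -0.25, 0.25) * size
        mask <- matrix(TRUE, size, size)
        for (e in 1:3) {
          j <- e %% 3 + 1
          cross <- (px[j] - px[e]) * (ys - py[e]) - (py[j] - py[e]) * (xs - px[e])
          ocross <- (px[j] - px[e]) * (py[(j %% 3) + 1] - py[e]) -
            (py[j] - py[e]) * (px[(j %% 3) + 1] - px[e])
          mask <- mask & (cross * ocross >= 0)
        }
      }
      for (ch in 1:3) { pl <- img[, , ch]; pl[mask] <- col[ch]; img[, , ch] <- pl }
    }
    fine <- gaussian_blur(matrix(rnorm(size^2), size, size), 0.8)
    fine <- fine / sd(fine) * grain_sd
    for (ch in 1:3) img[, , ch] <- img[, , ch] + fine
    clamp01(img)
  })
}

#' Default ground-truth observer parameters
#'
#' Condition-wise Weibull thresholds and widths plus random-effect scales
#' for simulating odd-one-out data. Scene thresholds increase with grain;
#' texture thresholds sit `texture_shift` higher on the log-reach axis
#' (harder), mirroring the qualitative structure of distortion-visibility
#' data. Offset SDs default to 0.2; participant lapse rates are drawn
#' from Beta(1,10) truncated to `[0, 0.2]`.
#'
#' @param grains Grain levels (default `c(1, 3, 5, 7, 10)`).
#' @param texture_shift Added to texture thresholds on the log-reach axis
#'   (default 1).
#' @param m_scene Scene thresholds per grain (default `0.4 + 0.12 *
#'   seq_along(grains)`).
#' @param w Common width (default 1.5).
#' @param sd_participant,sd_image Offset SDs (default 0.2).
#' @return List of class `"observer_truth"` with a `conditions` data
#'   frame (`image_type`, `grain`, `m`, `w`) and the offset SDs.
#' @export
observer_truth <- function(grains = c(1, 3, 5, 7, 10), texture_shift = 1,
                           m_scene = 0.4 + 0.12 * seq_along(grains),
                           w = 1.5, sd_participant = 0.2, sd_image = 0.2) {
  cond <- rbind(
    data.frame(image_type = "scene", grain = grains, m = m_scene, w = w),
    data.frame(image_type = "texture", grain = grains,
               m = m_scene + texture_shift, w = w))
  structure(list(conditions = cond, sd_participant = sd_participant,
                 sd_image = sd_image), class = "observer_truth")
}

#' Simulate an odd-one-out experiment from the generative Weibull model
#'
#' Draws participant and image offsets (zero-mean normals), participant
#' lapse rates (Beta(1,10) truncated to `[0, 0.2]`), computes the success
#' probability `S(x) = gamma + (1 - gamma - lambda) * F(x)` for every
#' trial of the design, and samples Bernoulli correctness.
#'
#' @param truth An [observer_truth()] object.
#' @param participants Number of participants (default 6).
#' @param images_per_type Images per image type (default 10).
#' @param reaches Reach levels (default `c(1, 2, 3, 4, 8)`).
#' @param trials_per_cell Trials per participant x image x grain x reach
#'   cell (default 2).
#' @param gamma Chance level (default 1/3).
#' @param seed Integer seed.
#' @return Trial table (data frame) with the true generating parameters
#'   attached as attribute `"truth_effects"`.
#' @export
simulate_experiment <- function(truth = observer_truth(), participants = 6,
                                images_per_type = 10,
                                reaches = c(1, 2, 3, 4, 8),
                                trials_per_cell = 2, gamma = 1 / 3, seed = 1) {
  stopifnot(inherits(truth, "observer_truth"), all(reaches > 0))
  with_seed(seed, {
    cond <- truth$conditions
    pids <- sprintf("p%02d", seq_len(participants))
    iids <- c(sprintf("scene%02d", seq_len(images_per_type)),
              sprintf("texture%02d", seq_len(images_per_type)))
    itype <- rep(c("scene", "texture"), each = images_per_type)
    dmp <- rnorm(participants, 0, truth$sd_participant)
    dwp <- rnorm(participants, 0, truth$sd_participant)
    dmi <- rnorm(length(iids), 0, truth$sd_image)
    dwi <- rnorm(length(iids), 0, truth$sd_image)
    lam <- numeric(participants)
    for (j in seq_len(participants)) {
      repeat { l <- stats::rbeta(1, 1, 10); if (l <= 0.2) break }
      lam[j] <- l
    }
    grid <- expand.grid(p = seq_len(participants), i = seq_along(iids),
                        ci = seq_len(nrow(cond)), reach = reaches,
                        rep = seq_len(trials_per_cell))
    grid <- grid[itype[grid$i] == cond$image_type[grid$ci], ]
    m <- cond$m[grid$ci] + dmp[grid$p] + dmi[grid$i]
    w <- pmax(cond$w[grid$ci] + dwp[grid$p] + dwi[grid$i], 1e-3)
    pr <- gamma + (1 - gamma - lam[grid$p]) * weibull_F(grid$reach, m, w)
    out <- data.frame(participant_id = pids[grid$p],
                      image_id = iids[grid$i],
                      image_type = cond$image_type[grid$ci],
                      grain = cond$grain[grid$ci],
                      reach = grid$reach,
                      correct = rbinom(nrow(grid), 1, pr),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "truth_effects") <- list(conditions = cond, dmp = dmp, dwp = dwp,
                                       dmi = dmi, dwi = dwi, lambda = lam,
                                       gamma = gamma)
    out
  })
}

#' Simulate trials whose difficulty is driven by a metric
#'
#' Correctness is generated from the metric-based probit model
#' `S(x) = gamma + (1 - gamma) * pnorm(b0_p + b1_p * x)` on the supplied
#' (already transformed) metric values, with participant weights drawn
#' around the population truth.
#'
#' @param series Data frame `(image_id, grain, reach, value)`; `value`
#'   should already be on the transformed (z-score) scale.
#' @param participants Number of participants (default 6).
#' @param trials_per_row Trials per participant per series row
#'   (default 2).
#' @param b0,b1 Population-truth regression weights (defaults 0.3 and 1).
#' @param sd_b Participant SD of both weights (default 0.2).
#' @param gamma Chance level (default 1/3).
#' @param seed Integer seed.
#' @param image_type Optional vector (recycled) labelling each series row
#'   (default `"scene"`; only used to satisfy the trial-table schema).
#' @return Trial table joining back to `series` by
#'   `(image_id, grain, reach)`.
#' @export
simulate_metric_experiment <- function(series, participants = 6,
                                       trials_per_row = 2, b0 = 0.3, b1 = 1,
                                       sd_b = 0.2, gamma = 1 / 3, seed = 1,
                                       image_type = "scene") {
  stopifnot(all(c("image_id", "grain", "reach", "value") %in% names(series)))
  with_seed(seed, {
    pids <- sprintf("p%02d", seq_len(participants))
    b0p <- rnorm(participants, b0, sd_b)
    b1p <- rnorm(participants, b1, sd_b)
    grid <- expand.grid(p = seq_len(participants), r = seq_len(nrow(series)),
                        rep = seq_len(trials_per_row))
    pr <- regression_prob(series$value[grid$r], b0p[grid$p], b1p[grid$p], gamma)
    out <- data.frame(participant_id = pids[grid$p],
                      image_id = series$image_id[grid$r],
                      image_type = rep_len(image_type, nrow(series))[grid$r],
                      grain = series$grain[grid$r],
                      reach = series$reach[grid$r],
                      correct = rbinom(nrow(grid), 1, pr),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "truth_effects") <- list(b0 = b0, b1 = b1, b0p = b0p, b1p = b1p,
                                       gamma = gamma)
    out
  })
}
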