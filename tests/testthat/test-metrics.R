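test_that("mse matches hand-computed values and distance axioms", {
  img <- toy_image(8)
  expect_identical(mse(img, img), 0)
  expect_equal(mse(array(0, c(4, 4, 3)), array(1, c(4, 4, 3))), 1)
  # 2x2 pair differing by 0.5 in one channel of one pixel: 0.25 / 12
  a <- array(0, c(2, 2, 3)); b <- a; b[1, 1, 2] <- 0.5
  expect_equal(mse(a, b), 0.25 / 12)
  expect_equal(mse(a, b), mse(b, a))
  expect_error(mse(toy_image(8), toy_image(9)), "differ")
})

test_that("opponent means follow the channel arithmetic", {
  gray <- array(0.4, c(6, 6, 3))
  expect_equal(opponent_means(gray), c(rg = 0, yb = 0))
  red <- array(0, c(6, 6, 3)); red[, , 1] <- 1
  expect_equal(unname(opponent_means(red)["rg"]), 1)
  blue <- array(0, c(6, 6, 3)); blue[, , 3] <- 1
  expect_equal(unname(opponent_means(blue)["yb"]), -1)
})

test_that("spectrum distance matches the brute-force DFT oracle and shift invariance", {
  img <- toy_image(8, 3)
  expect_identical(power_spectrum_distance(img, img), 0)
  shifted <- img[c(4:8, 1:3), c(7:8, 1:6), ]
  expect_equal(power_spectrum_distance(img, shifted), 0, tolerance = 1e-8)
  b <- toy_image(8, 4)
  ya <- luminance(img); yb <- luminance(b)
  pa <- brute_power_spectrum(ya); pb <- brute_power_spectrum(yb)
  pa[1, 1] <- 0; pb[1, 1] <- 0
  expect_equal(power_spectrum_distance(img, b), sum(abs(pa - pb)),
               tolerance = 1e-8)
  expect_equal(power_spectrum_distance(img, b), power_spectrum_distance(b, img))
})

test_that("radial spectrum slope recovers flat and 1/f^2 spectra", {
  fs_white <- mean(vapply(1:20, function(s) with_seed(s, {
    fourier_slope_intercept(matrix(runif(512^2), 512, 512))["fs"]
  }), numeric(1)))
  expect_lt(abs(fs_white), 0.05)
  # synthesize noise with power exactly proportional to f^-2
  pink <- with_seed(9, {
    n <- 256
    fy <- ((seq_len(n) - 1 + n %/% 2) %% n - n %/% 2)
    r <- sqrt(outer(fy^2, fy^2, "+")); r[1, 1] <- 1
    ph <- fft(matrix(rnorm(n^2), n, n))
    Re(fft((ph / Mod(ph)) / r, inverse = TRUE) / n^2)
  })
  fs_pink <- fourier_slope_intercept(pink)["fs"]
  expect_lt(abs(fs_pink - (-2)), 0.1)
  # doubling contrast: intercept + log10(4), slope unchanged
  y <- luminance(generate_texture_image(64, 5))
  y2 <- mean(y) + 2 * (y - mean(y))
  f1 <- fourier_slope_intercept(y); f2 <- fourier_slope_intercept(y2)
  expect_equal(unname(f2["fi"] - f1["fi"]), log10(4), tolerance = 1e-9)
  expect_equal(unname(f2["fs"]), unname(f1["fs"]), tolerance = 1e-9)
})

test_that("lgn distance is a Euclidean metric on (CE, SC)", {
  expect_identical(lgn_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(lgn_distance(c(0, 1), c(3, 5)), 5)
  expect_equal(lgn_distance(c(0.2, 1), c(1, 3)), lgn_distance(c(1, 3), c(0.2, 1)))
})

test_that("texture-statistic vectors are deterministic with fixed length and blocks", {
  img <- generate_texture_image(64, 8)
  v1 <- ps_statistics(img, 3, 4, 7)
  v2 <- ps_statistics(img, 3, 4, 7)
  expect_identical(v1, v2)
  v3 <- ps_statistics(generate_scene_image(64, 9), 3, 4, 7)
  expect_identical(length(v1), length(v3))
  expect_identical(names(v1), names(v3))
  # marginal pixel block is orientation blind: 90-degree rotation
  y <- luminance(img); rot <- t(y)[ncol(y):1, ]
  m1 <- ps_statistics(y, 3, 4, 7)[1:6]
  m2 <- ps_statistics(rot, 3, 4, 7)[1:6]
  expect_equal(m1, m2, tolerance = 1e-10)
  expect_error(ps_statistics(img, 4, 4, 9), "too small")
})

test_that("texture-statistic distances behave at equality and anti-parallel", {
  v <- ps_statistics(generate_texture_image(64, 10), 3, 4, 7)
  expect_equal(ps_distance(v, v, "euclidean"), 0)
  expect_equal(ps_distance(v, v, "cosine"), 0, tolerance = 1e-12)
  expect_equal(ps_distance(c(1, 2, 3), c(-1, -2, -3), "cosine"), -2)
  expect_equal(ps_distance(c(0, 3), c(4, 0), "euclidean"), 5)
  expect_error(ps_distance(1:3, 1:4), "length")
})

test_that("jod shift, normalized variant, and difficulty transform contracts", {
  expect_equal(jod_adapter(10), 0)
  expect_equal(jod_adapter(8), -2)
  expect_equal(normalized_variant(2, 4), 0.5)
  expect_equal(normalized_variant(0, 3), 0)
  expect_error(normalized_variant(1, 0), "undefined")
  v <- c(0.5, 2, 9, 0.1, 4)
  z <- difficulty_transform(v)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_identical(order(v), order(z))   # monotone for positive inputs
  expect_error(difficulty_transform(rep(2, 10)), "degenerate")
  expect_error(metric_spec("mse", normalized = TRUE), "no normalized")
  expect_error(metric_spec("nope"), "unknown")
  expect_identical(metric_spec("ce_diff", TRUE)$normalized, TRUE)
})

test_that("battery produces one row per design cell with zeros at reach 0", {
  imgs <- stimulus_set(2, size = 64, seed0 = 40)
  bat <- compute_battery(imgs, grains = c(2, 5), reaches = c(0, 3),
                         metrics = c("mse", "rg_mean", "spectrum_manhattan",
                                     "ps_cosine"))
  # 4 images x 2 grains x 2 reaches x (4 direct + 2 normalized variants)
  expect_identical(nrow(bat), 4L * 2L * 2L * 6L)
  key <- paste(bat$image_id, bat$grain, bat$reach, bat$metric, bat$normalized)
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(is.finite(bat$value)))
  at0 <- bat[bat$reach == 0, ]
  expect_true(all(abs(at0$value) < 1e-12))
})

test_that("mse is insensitive to grain but grows with reach", {
  imgs <- stimulus_set(5, size = 64, seed0 = 60)
  grains <- c(1, 3, 5, 10); reaches <- c(1, 2, 3, 4, 8)
  vals <- expand.grid(img = names(imgs), grain = grains, reach = reaches,
                      stringsAsFactors = FALSE)
  # matched seeds across grains: the same field realization rescaled
  vals$mse <- vapply(seq_len(nrow(vals)), function(j) {
    im <- imgs[[vals$img[j]]]
    mse(im, eidolon_distort(im, eidolon_params(vals$grain[j], vals$reach[j],
                                               seed = match(vals$img[j], names(imgs)))))
  }, numeric(1))
  # statistically invariant to grain at fixed reach
  kw <- stats::kruskal.test(mse ~ factor(grain), data = vals[vals$reach == 3, ])
  expect_gt(kw$p.value, 0.01)
  # non-decreasing mean |mse| in reach at fixed grain
  m <- tapply(abs(vals$mse[vals$grain == 5]), vals$reach[vals$grain == 5], mean)
  expect_true(all(diff(m[as.character(reaches)]) >= 0))
})
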