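test_that("local contrast map responds to edges and is linear in contrast", {
  const <- array(0.5, c(16, 16, 3))
  expect_true(all(local_contrast_map(const) == 0))
  # vertical step edge: strongest response at the edge, decaying away
  y <- matrix(0.2, 32, 32); y[, 17:32] <- 0.8
  cm <- local_contrast_map(y, sigma = 1.5)
  peak <- which.max(cm[16, ])
  expect_true(peak %in% 16:17)
  expect_true(cm[16, 4] < cm[16, 12] && cm[16, 12] < cm[16, peak])
  # doubling contrast about the mean doubles the map
  y2 <- 0.5 + 2 * (y - 0.5)
  expect_equal(local_contrast_map(y2, 1.5), 2 * cm, tolerance = 1e-12)
  expect_error(local_contrast_map(y, sigma = 0), "positive")
})

test_that("Weibull MLE recovers known parameters", {
  x <- with_seed(42, rweibull(1e5, shape = 1.5, scale = 2))
  fit <- weibull_contrast_fit(x)
  expect_gt(fit["scale"], 1.96); expect_lt(fit["scale"], 2.04)
  expect_gt(fit["shape"], 1.47); expect_lt(fit["shape"], 1.53)
  # exponential is the shape = 1 special case
  e <- with_seed(43, rexp(1e5, rate = 0.5))
  fe <- weibull_contrast_fit(e)
  expect_gt(fe["shape"], 0.98); expect_lt(fe["shape"], 1.02)
  expect_error(weibull_contrast_fit(rep(0.3, 100)), "degenerate")
  expect_error(weibull_contrast_fit(matrix(0, 5, 5)), "degenerate")
})

test_that("Weibull MLE agrees with an independent fitting routine", {
  x <- with_seed(7, rweibull(5000, shape = 0.8, scale = 0.1))
  fit <- weibull_contrast_fit(x)
  ref <- suppressWarnings(MASS::fitdistr(x, "weibull"))$estimate
  expect_equal(unname(fit["shape"]), unname(ref["shape"]), tolerance = 1e-3)
  expect_equal(unname(fit["scale"]), unname(ref["scale"]), tolerance = 1e-3)
})

test_that("CE/SC are deterministic, rotation invariant, and scale with contrast", {
  img <- generate_scene_image(64, 3)
  a <- compute_ce_sc(img); b <- compute_ce_sc(img)
  expect_identical(a, b)
  rot <- array(0, dim(img))
  for (ch in 1:3) rot[, , ch] <- t(img[, , ch])[dim(img)[2]:1, ]
  expect_equal(compute_ce_sc(rot), a, tolerance = 1e-6)
  # contrast scaling (pre-clipping): CE doubles, SC unchanged
  y <- luminance(img); y2 <- mean(y) + 2 * (y - mean(y))
  s1 <- compute_ce_sc(y); s2 <- compute_ce_sc(y2)
  expect_equal(unname(s2["ce"] / s1["ce"]), 2, tolerance = 1e-6)
  expect_equal(unname(s2["sc"]), unname(s1["sc"]), tolerance = 1e-6)
  expect_error(compute_ce_sc(array(0.5, c(32, 32, 3))), "degenerate")
})

test_that("scene and texture populations order correctly in (CE, SC)", {
  imgs <- stimulus_set(25, size = 64, seed0 = 900)
  st <- t(vapply(imgs, compute_ce_sc, numeric(2)))
  scene <- grepl("^scene", rownames(st))
  expect_gt(mean(st[scene, "ce"]), mean(st[!scene, "ce"]))
  expect_gt(mean(st[scene, "sc"]), mean(st[!scene, "sc"]))
})

test_that("linear classifier separates separable clusters and is at chance on noise", {
  pts <- rbind(cbind(rnorm(50, 0, 0.1), rnorm(50, 0, 0.1)),
               cbind(rnorm(50, 3, 0.1), rnorm(50, 3, 0.1)))
  pts <- with_seed(1, pts)
  lab <- rep(c("texture", "scene"), each = 50)
  bd <- train_scene_texture_classifier(pts, lab)
  expect_equal(bd$accuracy, 1.0)
  expect_identical(classify(pts, bd), lab)
  # flipping the boundary flips every label
  bd2 <- bd; bd2$w <- -bd$w; bd2$b <- -bd$b
  off <- abs(drop(pts %*% bd$w) + bd$b) > 1e-9
  expect_true(all(classify(pts, bd)[off] != classify(pts, bd2)[off]))
  # a point exactly on the boundary is a scene by the tie rule
  hand <- structure(list(w = c(1, -1), b = 0), class = "linear_boundary")
  expect_identical(classify(matrix(c(0.5, 0.5), 1), hand), "scene")
  # permuted labels: in-sample accuracy compatible with chance
  perm <- with_seed(2, {
    p2 <- cbind(rnorm(1000), rnorm(1000))
    l2 <- sample(rep(c("scene", "texture"), 500))
    train_scene_texture_classifier(p2, l2)$accuracy
  })
  expect_lt(abs(perm - 0.5), 0.05)
  expect_error(train_scene_texture_classifier(pts, rep("scene", 100)), "two classes")
})
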