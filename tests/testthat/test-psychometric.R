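test_that("Weibull function hits its landmarks", {
  m <- 0.7; w <- 1.3
  expect_equal(weibull_F(exp(m), m, w), 0.5)
  expect_lt(weibull_F(1e-8, m, w), 1e-6)
  expect_gt(weibull_F(1e6, m, w), 1 - 1e-6)
  # c makes w the exact 0.05-0.95 quantile span on the log axis (the
  # function is asymmetric about m, so the landmarks are not m +/- w/2)
  q <- function(alpha) {
    z <- (log(-log(1 - alpha)) - log(-log(0.5))) / weibull_c()
    m + z * w
  }
  expect_equal(weibull_F(exp(q(0.95)), m, w), 0.95, tolerance = 1e-12)
  expect_equal(weibull_F(exp(q(0.05)), m, w), 0.05, tolerance = 1e-12)
  expect_equal(q(0.95) - q(0.05), w, tolerance = 1e-12)
  expect_error(weibull_F(-1, m, w), "positive")
  expect_error(weibull_F(2, m, w = 0), "positive")
  # strictly increasing until floating-point saturation
  xs <- exp(seq(-3, 1.5, length.out = 50))
  expect_true(all(diff(weibull_F(xs, m, w)) > 0))
})

test_that("success probability is chance- and lapse-bounded", {
  expect_equal(success_prob(exp(0.5), 0.5, 1, lambda = 0, gamma = 1 / 3), 2 / 3)
  expect_equal(success_prob(1e-9, 2, 1, lambda = 0.15, gamma = 1 / 3), 1 / 3,
               tolerance = 1e-6)
  expect_equal(success_prob(1e9, 0, 1, lambda = 0.1, gamma = 1 / 3), 0.9,
               tolerance = 1e-6)
  xs <- exp(seq(-4, 4, length.out = 60))
  p <- success_prob(xs, 0.3, 1.2, lambda = 0.05)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 1 / 3 & p <= 0.95))
  expect_error(success_prob(1, 0, 1, lambda = 0.5), "lambda")
})

test_that("trial-table validation catches schema problems", {
  tr <- tiny_trials()
  bad <- tr; bad$image_type[1] <- "face"
  expect_error(fit_oracle(bad), "image_type")
  bad2 <- tr[, -6]
  expect_error(fit_oracle(bad2), "lacks columns")
  bad3 <- tr; bad3$reach[2] <- 0
  expect_error(fit_oracle(bad3), "positive")
})

test_that("oracle fit returns draws, loglik, and is seed-reproducible", {
  tr <- tiny_trials()
  f1 <- fit_oracle(tr, chains = 1, warmup = 100, samples = 100, seed = 4)
  expect_s3_class(f1, "oracle_fit")
  expect_identical(nrow(f1$loglik), 100L)
  expect_identical(ncol(f1$loglik), nrow(tr))
  expect_true(all(is.finite(f1$loglik)))
  # lapse draws respect the truncation
  lam <- f1$draws[, grep("^lam\\[", colnames(f1$draws))]
  expect_true(all(lam >= 0 & lam <= 0.2))
  f2 <- fit_oracle(tr, chains = 1, warmup = 100, samples = 100, seed = 4)
  expect_identical(f1$draws, f2$draws)
  expect_identical(coef(f1)$condition, f1$cond_labels)
  s <- summary(f1)
  expect_true(all(c("mean", "hpdi_lo", "hpdi_hi") %in% names(s$table)))
  p <- predict(f1, data.frame(reach = c(1, 8), condition = "scene:1"))
  expect_true(all(p >= 1 / 3 & p <= 1) && p[2] > p[1])
})

test_that("hpdi is the narrowest interval with the requested mass", {
  z <- with_seed(10, rnorm(1e5))
  h <- hpdi(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  expect_identical(hpdi(rep(3.2, 50)), c(3.2, 3.2))
  e <- with_seed(11, rexp(1e5))
  he <- hpdi(e, 0.9)
  expect_lt(he[1], 0.01)   # density is monotone: interval starts at 0
  # at least the requested mass is inside
  expect_gte(mean(z >= h[1] & z <= h[2]), 0.95)
})

test_that("threshold contrast flags and degenerate cases", {
  tr <- tiny_trials()
  f <- fit_oracle(tr, chains = 1, warmup = 150, samples = 150, seed = 2)
  same <- threshold_contrast(f, "scene:1", "scene:1")
  expect_true(all(same$draws == 0))
  expect_identical(same$hpdi, c(0, 0))
  expect_false(same$credible)
  expect_error(threshold_contrast(f, "scene:1", "scene:2"), "unknown")
})
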