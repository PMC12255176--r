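test_that("image generators are deterministic, bounded, and distinct", {
  t1 <- generate_texture_image(48, 1); t1b <- generate_texture_image(48, 1)
  t2 <- generate_texture_image(48, 2)
  expect_identical(t1, t1b)
  expect_gt(mean(abs(t1 - t2)), 0)
  expect_true(all(t1 >= 0 & t1 <= 1))
  s1 <- generate_scene_image(48, 1)
  expect_identical(s1, generate_scene_image(48, 1))
  expect_true(all(s1 >= 0 & s1 <= 1))
  # scenes contain at least one strong luminance step
  y <- luminance(generate_scene_image(64, 12))
  steps <- max(abs(diff(y)), abs(t(diff(t(y)))))
  expect_gt(steps, 0.3)
})

test_that("simulated accuracy respects floor, ceiling, and chance", {
  # ceiling: thresholds far below the measured reaches
  hi <- observer_truth(grains = c(1, 5), m_scene = c(-10, -10))
  tr <- simulate_experiment(hi, participants = 4, images_per_type = 4,
                            trials_per_cell = 3, seed = 2)
  lam_max <- max(attr(tr, "truth_effects")$lambda)
  se3 <- 3 * sqrt(0.25 / nrow(tr))
  expect_gte(mean(tr$correct), 1 - lam_max - se3)
  # floor: thresholds far above -> chance performance
  lo <- observer_truth(grains = c(1, 5), m_scene = c(30, 30))
  tr2 <- simulate_experiment(lo, participants = 4, images_per_type = 4,
                             trials_per_cell = 3, seed = 3)
  expect_lt(abs(mean(tr2$correct) - 1 / 3), 3 * sqrt(2 / 9 / nrow(tr2)) + 0.01)
  # pooled accuracy strictly between chance and 1 at default truth
  tr3 <- simulate_experiment(seed = 4)
  expect_gt(mean(tr3$correct), 1 / 3)
  expect_lt(mean(tr3$correct), 1)
  expect_identical(tr3, simulate_experiment(seed = 4))
})

test_that("trial tables have the full factorial structure", {
  tr <- simulate_experiment(observer_truth(grains = c(1, 3)), participants = 3,
                            images_per_type = 2, reaches = c(1, 4),
                            trials_per_cell = 2, seed = 9)
  # participants x images x own-type grains x reaches x trials
  expect_identical(nrow(tr), 3L * 4L * 2L * 2L * 2L)
  expect_true(all(table(tr$participant_id) == nrow(tr) / 3))
  expect_true(all(tr$image_type[grepl("^scene", tr$image_id)] == "scene"))
})

test_that("metric-driven simulation responds to the slope", {
  ser <- data.frame(image_id = sprintf("im%d", 1:40), grain = 1,
                    reach = rep(c(1, 2, 4, 8), 10),
                    value = with_seed(5, sort(rnorm(40))))
  flat <- simulate_metric_experiment(ser, participants = 8, trials_per_row = 8,
                                     b0 = 0.3, b1 = 0, sd_b = 0, seed = 6)
  expect_lt(abs(mean(flat$correct) - regression_prob(0, 0.3, 0)),
            3 * sqrt(0.25 / nrow(flat)))
  steep <- simulate_metric_experiment(ser, participants = 8, trials_per_row = 8,
                                      b1 = 2, seed = 7)
  acc <- tapply(steep$correct, findInterval(ser$value[match(steep$image_id, ser$image_id)],
                                            quantile(ser$value, c(0.25, 0.75))), mean)
  expect_true(acc[1] < acc[2] && acc[2] < acc[3])
  expect_identical(steep, simulate_metric_experiment(ser, participants = 8,
                                                     trials_per_row = 8,
                                                     b1 = 2, seed = 7))
})

test_that("participant exclusion is strict at the threshold", {
  tr <- data.frame(participant_id = rep(c("a", "b", "c"), each = 10),
                   correct = c(rep(1, 10),                    # 100%
                               rep(c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0), 1), # 60%
                               rep(c(1, 0, 0, 0, 0), 2)))     # 20%
  out <- exclude_participants(tr, 0.60)
  expect_identical(out$excluded, "c")
  expect_true(all(c("a", "b") %in% out$trials$participant_id))
  # a guessing participant among high performers is excluded
  good <- simulate_experiment(observer_truth(grains = c(1, 5),
                                             m_scene = c(-5, -5)),
                              participants = 3, images_per_type = 4,
                              trials_per_cell = 2, seed = 12)
  guess <- good[good$participant_id == "p01", ]
  guess$participant_id <- "p99"
  guess$correct <- with_seed(13, rbinom(nrow(guess), 1, 1 / 3))
  out2 <- exclude_participants(rbind(good, guess), 0.60)
  expect_identical(out2$excluded, "p99")
})
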