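test_that("config validation rejects degenerate settings", {
  expect_error(synthetic_config(rest_duration = 0), "durations")
  expect_error(synthetic_config(task_duration = -1), "durations")
  expect_error(synthetic_config(fs = 0), "fs")
  expect_error(synthetic_config(effect_bad = -0.1), "effect")
  expect_error(synthetic_config(n_bad = 1, n_good = 0), "2 subjects")
  expect_error(synthetic_config(score_params = list(bad = c(mean = 5, sd = -1),
                                                    good = c(mean = 20, sd = 7))),
               "score_params")
})

test_that("generation is deterministic and seed-sensitive", {
  cfg <- synthetic_config(n_bad = 1, n_good = 1, rest_duration = 2,
                          task_duration = 2, fs = 250, seed = 3)
  prof <- list(subject_id = "S01", skill = 0.5, group = "BAD")
  a <- generate_subject_recording(prof, "task", cfg, seed = 10)
  b <- generate_subject_recording(prof, "task", cfg, seed = 10)
  expect_identical(a$data, b$data)
  c2 <- generate_subject_recording(prof, "task", cfg, seed = 11)
  expect_false(identical(a$data, c2$data))

  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  cfg2 <- synthetic_config(n_bad = 1, n_good = 1, rest_duration = 2,
                           task_duration = 2, fs = 250, seed = 4)
  expect_false(identical(co1$recordings[[1]]$data,
                         generate_cohort(cfg2)$recordings[[1]]$data))
})

test_that("cohort counting: one rest and one task recording per subject", {
  cfg <- synthetic_config(n_bad = 1, n_good = 1, rest_duration = 1,
                          task_duration = 1, fs = 100, seed = 1)
  co <- generate_cohort(cfg)
  expect_length(co$recordings, 4L)
  expect_equal(nrow(co$manifest), 2L)
  expect_setequal(vapply(co$recordings, `[[`, "", "condition"),
                  c("rest", "task"))
  expect_equal(ncol(co$recordings[[1]]$data), 100L)
})

test_that("zero effect multipliers give equal expected rest/task power", {
  cfg <- synthetic_config(n_bad = 1, n_good = 1, rest_duration = 30,
                          task_duration = 30, fs = 250,
                          effect_bad = 0, effect_good = 0,
                          alpha_task_factor = 1, seed = 21)
  prof <- list(subject_id = "S01", skill = 0, group = "BAD")
  rest <- generate_subject_recording(prof, "rest", cfg, seed = 5)
  task <- generate_subject_recording(prof, "task", cfg, seed = 6)
  pr <- rowMeans(rest$data^2); pt <- rowMeans(task$data^2)
  # Monte-Carlo tolerance at 30 s: pink-noise power estimates wobble a few %
  expect_lt(max(abs(pt - pr) / pr), 0.25)
  expect_lt(abs(mean(pt) - mean(pr)) / mean(pr), 0.1)
})

test_that("task power over frontal channels matches the closed-form scaling", {
  cfg <- synthetic_config(n_bad = 1, n_good = 1, rest_duration = 40,
                          task_duration = 40, fs = 250,
                          effect_bad = 2, seed = 31)
  prof <- list(subject_id = "S01", skill = 0, group = "BAD")
  rest <- generate_subject_recording(prof, "rest", cfg, seed = 7)
  task <- generate_subject_recording(prof, "task", cfg, seed = 8)
  exp_ratio <- expected_channel_power(prof, "task", cfg) /
    expected_channel_power(prof, "rest", cfg)
  frontal <- c("Fp1", "Fp2", "F3", "F4", "Fz")
  got <- rowMeans(task$data[frontal, ]^2) / rowMeans(rest$data[frontal, ]^2)
  # theta amplitude x3 on frontal sites: expected ratio well above 2
  expect_true(all(exp_ratio[frontal] > 2))
  expect_lt(max(abs(got - exp_ratio[frontal]) / exp_ratio[frontal]), 0.2)
  expect_gt(mean(rowMeans(task$data[frontal, ]^2)),
            mean(rowMeans(rest$data[frontal, ]^2)))
})

test_that("expected task-minus-rest power is monotone in the effect multiplier", {
  prof <- list(subject_id = "S01", skill = 0.3, group = "BAD")
  diffs <- vapply(c(0, 0.5, 1, 2, 4), function(e) {
    cfg <- synthetic_config(effect_bad = e, seed = 1)
    mean(expected_channel_power(prof, "task", cfg) -
           expected_channel_power(prof, "rest", cfg))
  }, numeric(1))
  expect_true(all(diff(diffs) >= 0))
})

test_that("realized group scores emulate the stated cohort statistics", {
  # 200 seeded cohorts with near-empty recordings (scores are what matters)
  means <- sapply(1:200, function(s) {
    cfg <- synthetic_config(rest_duration = 0.05, task_duration = 0.05,
                            fs = 200, seed = 5000 + s)
    m <- generate_cohort(cfg)$manifest
    c(bad = mean(m$X[m$group == "BAD"]), good = mean(m$X[m$group == "GOOD"]))
  })
  expect_lt(abs(mean(means["bad", ]) - 6.2), 0.5)
  expect_lt(abs(mean(means["good", ]) - 21.99), 1.0)
})

test_that("scores are positive, rounded to 2 decimals, labels follow the threshold", {
  cfg <- synthetic_config(rest_duration = 0.05, task_duration = 0.05,
                          fs = 200, seed = 99)
  m <- generate_cohort(cfg)$manifest
  expect_true(all(m$X > 0))
  expect_equal(m$X, round(m$X, 2))
  expect_identical(m$group, ifelse(m$X <= 10, "BAD", "GOOD"))
  expect_identical(m$subject_id, sort(m$subject_id))
})
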