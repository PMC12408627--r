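test_that("cohorts are byte-identical under a fixed seed", {
  cfg <- generator_config(n_subjects = 3, test_retest = TRUE,
                          motion_probability = 0.3, seed = 1)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- generator_config(n_subjects = 3, seed = 2)
  expect_false(identical(generate_cohort(cfg)[[1]]$region_tacs[[1]]$activity,
                         generate_cohort(cfg2)[[1]]$region_tacs[[1]]$activity))
})

test_that("noiseless TACs equal the forward model and refit to the true VT", {
  cfg <- generator_config(n_subjects = 2, noise_cv = 0,
                          motion_probability = 0, seed = 2)
  for (subj in generate_cohort(cfg)) {
    p <- subj$true_params[[1]]
    rebuilt <- forward_tac(p$model_id, p, subj$true_input,
                           subj$region_tacs[[1]]$schedule)
    expect_equal(subj$region_tacs[[1]]$activity, rebuilt$activity,
                 tolerance = 1e-12)
    fit <- fit_compartment_model(subj$region_tacs[[1]], subj$true_input,
                                 "1T2k")
    expect_equal(fit$vt, p$VT, tolerance = 0.005)
  }
})

test_that("generated parent fractions and plasma ratio are calibrated", {
  cfg <- generator_config(n_subjects = 100, seed = 3)
  cohort <- generate_cohort(cfg)
  pf30 <- vapply(cohort, function(s) {
    s$blood$parent_fraction[s$blood$time_min == 30]
  }, numeric(1))
  pf59 <- vapply(cohort, function(s) {
    s$blood$parent_fraction[s$blood$time_min == 59]
  }, numeric(1))
  expect_lt(abs(mean(pf30) - 0.80), 0.02)
  # 0.72 is the 60-min value; the last draw is at 59 min
  expect_lt(abs(mean(pf59) - 0.72), 0.02)
  ratio <- unlist(lapply(cohort, function(s) s$blood$plasma / s$blood$whole_blood))
  expect_lt(abs(mean(ratio) - 0.8), 0.05)
})

test_that("frame noise scales to the configured CV at the last frame", {
  cfg <- generator_config(n_subjects = 1, noise_cv = 0, seed = 4)
  subj <- generate_cohort(cfg)[[1]]
  clean <- subj$region_tacs[[1]]$activity
  dur <- subj$region_tacs[[1]]$schedule$dur_s
  set.seed(99)
  reps <- replicate(1000, add_frame_noise(clean, dur, 0.05))
  n <- length(clean)
  emp_cv <- sd(reps[n, ]) / mean(reps[n, ])
  expect_lt(abs(emp_cv - 0.05) / 0.05, 0.15)
  # SD profile follows sqrt(activity/duration) up to the common scale,
  # on frames untouched by the non-negativity clamp
  sds <- apply(reps, 1, sd)
  expected <- sqrt(clean / dur)
  unclamped <- apply(reps, 1, min) > 0
  ratio <- sds[unclamped] / expected[unclamped]
  expect_gte(sum(unclamped), 5)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.25)
})

test_that("true parameters respect the fitting bounds", {
  cfg <- generator_config(n_subjects = 10, model_id = "2T4k",
                          regions = default_region_table(), seed = 5,
                          test_retest = TRUE)
  for (subj in generate_cohort(cfg)) {
    for (p in subj$true_params) {
      expect_lte(p$K1, 0.7)
      expect_lte(p$Vb, 0.7)
      expect_lte(p$VT, 40)
      if (!is.null(p$k3)) expect_lte(p$k3, 0.8)
    }
  }
})

test_that("retest sessions perturb K1 and VT on the log scale", {
  cfg <- generator_config(n_subjects = 40, test_retest = TRUE,
                          retest_log_sd = 0.1, seed = 6)
  cohort <- generate_cohort(cfg)
  te <- Filter(function(s) s$session == "test", cohort)
  re <- Filter(function(s) s$session == "retest", cohort)
  lr <- mapply(function(a, b) {
    log(b$true_params[[1]]$VT / a$true_params[[1]]$VT)
  }, te, re)
  expect_lt(abs(mean(lr)), 0.05)
  expect_lt(abs(sd(lr) - 0.1) / 0.1, 0.35)
})

test_that("motion artifacts modify only the requested frames", {
  sch <- sch60()
  tac <- new_tac(sch, seq(19, 1))
  hit <- add_motion_artifact(tac, 10, 0.5)
  expect_equal(hit$activity[10], tac$activity[10] * 0.5)
  expect_equal(hit$activity[-10], tac$activity[-10])
  expect_equal(tac$activity[10], 10)  # original untouched
  sustained <- add_motion_artifact(tac, 15, 0.4, sustained = TRUE)
  expect_equal(sustained$activity[15:19], tac$activity[15:19] * 0.6)
  # identity limit
  tiny <- add_motion_artifact(tac, 10, 1e-12)
  expect_equal(tiny$activity, tac$activity, tolerance = 1e-9)
  expect_error(add_motion_artifact(tac, 25, 0.5), "out of range")
  expect_error(add_motion_artifact(tac, 5, 1.5), "\\(0, 1\\)")
})

test_that("generator configuration errors name the offending field", {
  expect_error(generator_config(vt_range = c(17, 7)), "vt_range")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
  expect_error(generator_config(motion_probability = 1.5),
               "motion_probability")
  expect_error(generator_config(sample_times_min = c(5, 5, 10)),
               "sample_times_min")
  expect_error(generator_config(sample_times_min = c(5, 70)),
               "sample_times_min")
  expect_error(generator_config(regions = data.frame(region = "a")),
               "regions")
})
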