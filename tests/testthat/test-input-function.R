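test_that("IDIF scale factor is 1 when the image matches the whole-blood model", {
  input <- make_input()
  sch <- sch60()
  img <- new_tac(sch, frame_average_matrix(sch, length(input$time_min)) %*%
                   input$wb, region = "aorta")
  s <- samples_from_input(input)
  fit <- fit_blood_curves(s)
  pf <- fit_parent_fraction(s)
  idif <- build_idif(img, fit$whole_blood, fit$plasma, pf)
  expect_equal(idif$scale, 1.0, tolerance = 0.01)
})

test_that("reconstructed metabolite-corrected plasma matches truth on noiseless subjects", {
  cfg <- generator_config(n_subjects = 3, noise_cv = 0, seed = 11)
  for (subj in generate_cohort(cfg)) {
    fit <- fit_blood_curves(subj$blood)
    pf <- fit_parent_fraction(subj$blood)
    idif <- build_idif(subj$image_blood_tac, fit$whole_blood, fit$plasma, pf)
    tt <- seq(0, 60, by = 1 / 60)
    truth <- if_eval(subj$true_input, tt)
    rec <- if_eval(idif, tt)
    expect_lt(sqrt(mean((rec - truth)^2)) / sqrt(mean(truth^2)), 0.03)
  }
})

test_that("disabling both corrections reduces the input to whole blood", {
  input <- make_input(plasma_ratio = 1, pf = FALSE)
  s <- samples_from_input(input)
  fit <- fit_blood_curves(s)
  pf1 <- parent_fraction_model(a = 0, b = 1, c = 10)  # pf == 1 everywhere
  sch <- sch60()
  img <- new_tac(sch, frame_average_matrix(sch, length(input$time_min)) %*%
                   input$wb, region = "aorta")
  idif <- build_idif(img, fit$whole_blood, fit$plasma, pf1)
  expect_equal(idif$plasma_mc, idif$wb, tolerance = 0.02)
})

test_that("IDIF is continuous at the junction and ordered pointwise", {
  cfg <- generator_config(n_subjects = 1, noise_cv = 0, seed = 12)
  subj <- generate_cohort(cfg)[[1]]
  fit <- fit_blood_curves(subj$blood)
  pf <- fit_parent_fraction(subj$blood)
  idif <- build_idif(subj$image_blood_tac, fit$whole_blood, fit$plasma, pf)
  # relative step across the 5-min junction below 1%
  v_lo <- if_eval(idif, 5 - 1 / 60, "wb")
  v_hi <- if_eval(idif, 5 + 1 / 60, "wb")
  expect_lt(abs(v_hi - v_lo) / v_hi, 0.01)
  # metabolite-corrected plasma <= plasma pointwise (pf <= 1)
  expect_true(all(idif$plasma_mc <= idif$plasma + 1e-9))
})

test_that("IDIF errors on inadequate early coverage or degenerate scale", {
  input <- make_input()
  s <- samples_from_input(input)
  fit <- fit_blood_curves(s)
  pf <- fit_parent_fraction(s)
  late_only <- frame_schedule(rep(600, 6))
  img <- new_tac(late_only, rep(1, 6), region = "aorta")
  expect_error(build_idif(img, fit$whole_blood, fit$plasma, pf),
               ">= 5 frames")
  sch <- sch60()
  img0 <- new_tac(sch, rep(0, 19), region = "aorta")
  expect_error(build_idif(img0, fit$whole_blood, fit$plasma, pf), "scale")
})

test_that("VT from the reconstructed IDIF matches VT from the true input", {
  cfg <- generator_config(n_subjects = 10, noise_cv = 0, seed = 13)
  cohort <- generate_cohort(cfg)
  for (subj in cohort) {
    fit <- fit_blood_curves(subj$blood)
    pf <- fit_parent_fraction(subj$blood)
    idif <- build_idif(subj$image_blood_tac, fit$whole_blood, fit$plasma, pf)
    tac <- subj$region_tacs[[1]]
    vt_true_input <- fit_compartment_model(tac, subj$true_input, "1T2k")$vt
    vt_idif <- fit_compartment_model(tac, idif, "1T2k")$vt
    expect_lt(abs(vt_idif - vt_true_input) / vt_true_input, 0.05)
  }
})

test_that("delay estimation recovers null, positive and negative shifts", {
  input <- make_input()
  sch <- sch60()
  p <- list(K1 = 0.3, k2 = 0.02, Vb = 0.05)
  tac0 <- forward_tac("1T2k", p, input, sch)
  expect_lte(abs(estimate_delay(input, tac0)), 1)
  tac_p <- forward_tac("1T2k", p, input, sch, delay_s = 10)
  expect_lte(abs(estimate_delay(input, tac_p) - 10), 2)
  tac_m <- forward_tac("1T2k", p, input, sch, delay_s = -10)
  expect_lte(abs(estimate_delay(input, tac_m) + 10), 2)
})

test_that("a flat early TAC warns and returns zero delay", {
  input <- make_input()
  sch <- sch60()
  tac <- new_tac(sch, rep(5, 19))
  expect_warning(d <- estimate_delay(input, tac), "flat")
  expect_equal(d, 0)
})
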