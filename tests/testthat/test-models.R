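test_that("blood-only limit: Vb = 1 returns the frame-averaged blood curve", {
  input <- make_input()
  sch <- sch60()
  tac <- forward_tac("1T2k", list(K1 = 0.3, k2 = 0.02, Vb = 1), input, sch)
  wb_frames <- as.vector(
    frame_average_matrix(sch, length(input$time_min)) %*% input$wb)
  expect_equal(tac$activity, wb_frames, tolerance = 1e-8)
})

test_that("constant input drives 1T2k tissue to the equilibrium VT level", {
  span <- 400
  tt <- seq(0, span, by = 1 / 60)
  C <- 2
  input <- input_function(tt, rep(C, length(tt)), rep(C, length(tt)),
                          rep(C, length(tt)))
  sch <- frame_schedule(rep(1200, 20))  # 400 min
  tac <- forward_tac("1T2k", list(K1 = 0.3, k2 = 0.02, Vb = 0), input, sch)
  expect_equal(tac$activity[20], 15 * C, tolerance = 0.01)
})

test_that("analytic convolution agrees with a stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  input <- make_input()
  sch <- sch60()
  tt <- seq(0, 60, by = 1 / 60)
  cp <- if_eval(input, tt)
  cp_fun <- stats::approxfun(tt, cp, rule = 2)
  ode_tac <- function(model_id, p) {
    deriv <- function(t, y, parms) {
      if (model_id == "1T2k") {
        list(p$K1 * cp_fun(t) - p$k2 * y[1])
      } else {
        k4 <- if (model_id == "2T3k") 0 else p$k4
        d1 <- p$K1 * cp_fun(t) - (p$k2 + p$k3) * y[1] + k4 * y[2]
        d2 <- p$k3 * y[1] - k4 * y[2]
        list(c(d1, d2))
      }
    }
    y0 <- if (model_id == "1T2k") 0 else c(0, 0)
    sol <- deSolve::lsoda(y0, tt, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    ct <- if (model_id == "1T2k") sol[, 2] else sol[, 2] + sol[, 3]
    meas <- (1 - p$Vb) * ct + p$Vb * if_eval(input, tt, "wb")
    as.vector(frame_average_matrix(sch, length(tt)) %*% meas)
  }
  set.seed(101)
  for (i in 1:5) {
    model_id <- sample(c("1T2k", "2T3k", "2T4k"), 1)
    p <- list(K1 = runif(1, 0.1, 0.6), k2 = runif(1, 0.02, 0.3),
              k3 = runif(1, 0.01, 0.5), k4 = runif(1, 0.01, 0.3),
              Vb = runif(1, 0, 0.3))
    analytic <- forward_tac(model_id, p, input, sch)$activity
    oracle <- ode_tac(model_id, p)
    expect_lt(max(abs(analytic - oracle)), 0.001 * max(analytic))
  }
})

test_that("noiseless 1T2k TAC is identified to within 0.5%", {
  input <- make_input()
  sch <- sch60()
  truth <- list(K1 = 0.3, k2 = 0.02, Vb = 0.05)
  tac <- forward_tac("1T2k", truth, input, sch)
  fit <- fit_compartment_model(tac, input, "1T2k")
  expect_true(fit$converged)
  expect_equal(fit$vt, 15, tolerance = 0.005)
  expect_equal(fit$params$K1, truth$K1, tolerance = 0.005)
  expect_equal(fit$params$Vb, truth$Vb, tolerance = 0.01)
})

test_that("2T4k fit of a k3 = 0 TAC collapses to the one-tissue VT", {
  input <- make_input()
  sch <- sch60()
  tac <- forward_tac("2T4k", list(K1 = 0.3, k2 = 0.02, k3 = 0, k4 = 0.05,
                                  Vb = 0.04), input, sch)
  fit <- fit_compartment_model(tac, input, "2T4k")
  expect_equal(fit$vt, 15, tolerance = 0.01)
})

test_that("AIC arithmetic follows the Gaussian-RSS closed form", {
  expect_equal(compute_aic(2, 19, 3) - compute_aic(2, 19, 5), -4)
  expect_equal(compute_aic(1, 19, 3) - compute_aic(2, 19, 3), -19 * log(2))
  expect_warning(a <- compute_aic(0, 19, 3), "zero")
  expect_identical(a, -Inf)
  expect_error(compute_aic(1, 3, 3), "more frames")
})

test_that("fitted 2T4k RSS never exceeds fitted 1T2k RSS (nesting)", {
  input <- make_input()
  sch <- sch60()
  base <- forward_tac("1T2k", list(K1 = 0.3, k2 = 0.02, Vb = 0.05), input, sch)
  set.seed(21)
  for (i in 1:8) {
    tac <- base
    tac$activity <- pmax(base$activity * (1 + rnorm(19, 0, 0.03)), 0)
    f1 <- fit_compartment_model(tac, input, "1T2k")
    f4 <- fit_compartment_model(tac, input, "2T4k")
    expect_lte(f4$rss, f1$rss * (1 + 1e-6))
  }
})

test_that("rate constants and VT are invariant to global amplitude rescaling", {
  input <- make_input()
  sch <- sch60()
  tac <- forward_tac("1T2k", list(K1 = 0.3, k2 = 0.02, Vb = 0.05), input, sch)
  set.seed(31)
  tac$activity <- pmax(tac$activity * (1 + rnorm(19, 0, 0.02)), 0)
  f <- fit_compartment_model(tac, input, "1T2k")
  c_fac <- 7.3
  tac2 <- tac; tac2$activity <- tac$activity * c_fac
  input2 <- input
  input2$wb <- input$wb * c_fac
  input2$plasma <- input$plasma * c_fac
  input2$plasma_mc <- input$plasma_mc * c_fac
  f2 <- fit_compartment_model(tac2, input2, "1T2k")
  expect_equal(f2$params$K1, f$params$K1, tolerance = 1e-4)
  expect_equal(f2$params$k2, f$params$k2, tolerance = 1e-4)
  expect_equal(f2$vt, f$vt, tolerance = 1e-4)
})

test_that("uncorrected-input variant ranks subjects like the corrected model", {
  # shared parent fraction across subjects: the whole-blood variant's VT must
  # be a monotone transform of the metabolite-corrected VT
  input <- make_input()
  sch <- sch60()
  vts <- seq(6, 18, length.out = 6)
  vt_std <- vt_wb <- numeric(length(vts))
  for (i in seq_along(vts)) {
    p <- list(K1 = 0.3, k2 = 0.3 / vts[i], Vb = 0.05)
    tac <- forward_tac("1T2k", p, input, sch)
    vt_std[i] <- fit_compartment_model(tac, input, "1T2k")$vt
    vt_wb[i] <- fit_compartment_model(tac, input, "1T2k_WB")$vt
  }
  expect_equal(cor(vt_std, vt_wb, method = "spearman"), 1)
  # uncorrected plasma exceeds parent plasma, so VT_WB < VT
  expect_true(all(vt_wb < vt_std))
})

test_that("fitting rejects degenerate inputs", {
  input <- make_input()
  sch <- sch60()
  expect_error(fit_compartment_model(new_tac(sch, rep(0, 19)), input, "1T2k"),
               "all-zero")
  short_input <- make_input(span_min = 30)
  tac <- new_tac(sch, rep(1, 19))
  expect_error(fit_compartment_model(tac, short_input, "1T2k"), "span")
  expect_error(forward_tac("2T4k", list(K1 = 0.3, k2 = 0.1, k3 = 0.1, k4 = 0,
                                        Vb = 0), input, sch), "k4 > 0")
})
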