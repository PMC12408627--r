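# Plasma-input compartment models with a fractional blood-volume term.
#
# Tissue impulse response functions (t in minutes, K1 in mL.cm^-3.min^-1,
# k2..k4 in min^-1):
#   1T2k: IRF(t) = K1 exp(-k2 t)
#   2T:   IRF(t) = (K1/(a2 - a1)) [(k3 + k4 - a1) exp(-a1 t)
#                                  + (a2 - k3 - k4) exp(-a2 t)]
#         with a1,2 = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)) / 2.
# The irreversible 2T3k model is the k4 = 0 special case (a1 = 0).
# Measured signal: (1 - Vb) * (IRF (x) Cp_mc) + Vb * C_wb, frame-averaged.

MODEL_IDS <- c("1T2k", "2T3k", "2T4k", "1T2k_WB")

model_n_params <- function(model_id) {
  switch(model_id, "1T2k" = 3L, "1T2k_WB" = 3L, "2T3k" = 4L, "2T4k" = 5L,
         stop(sprintf("unknown model id '%s'", model_id)))
}

# Convolution of x (on a regular grid, step dt) with exp(-lambda t), by the
# trapezoid rule, computed recursively via stats::filter (O(n), exact for
# piecewise-linear x up to the trapezoid discretisation).
conv_exp <- function(x, lambda, dt) {
  n <- length(x)
  e <- exp(-lambda * dt)
  z <- numeric(n)
  z[-1] <- dt * (x[-1] + e * x[-n]) / 2
  as.numeric(stats::filter(z, e, method = "recursive"))
}

# Precompute the frame-averaging operator for a schedule on a regular grid:
# a dense (n_frames x n_grid) matrix of trapezoid weights, so that frame
# averages are a single matrix-vector product inside fitting loops.
frame_average_matrix <- function(schedule, n_grid, dt_s = 1) {
  W <- matrix(0, nrow(schedule), n_grid)
  i0 <- round(schedule$start_s / dt_s) + 1L
  i1 <- round((schedule$start_s + schedule$dur_s) / dt_s) + 1L
  for (f in seq_len(nrow(schedule))) {
    idx <- i0[f]:i1[f]
    w <- rep(1, length(idx)); w[c(1, length(idx))] <- 0.5
    W[f, idx] <- w * dt_s / schedule$dur_s[f]
  }
  W
}

# Tissue concentration on the grid for a given model and parameters.
tissue_grid <- function(model_id, params, cp, dt) {
  K1 <- params$K1
  if (model_id %in% c("1T2k", "1T2k_WB")) {
    return(K1 * conv_exp(cp, params$k2, dt))
  }
  k2 <- params$k2; k3 <- params$k3
  k4 <- if (model_id == "2T3k") 0 else params$k4
  s <- k2 + k3 + k4
  disc <- max(s^2 - 4 * k2 * k4, 0)
  root <- sqrt(disc)
  a1 <- (s - root) / 2
  a2 <- (s + root) / 2
  if (a2 - a1 < 1e-10) a2 <- a1 + 1e-10  # repeated-root guard
  c1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
  c2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
  c1 * conv_exp(cp, a1, dt) + c2 * conv_exp(cp, a2, dt)
}

# Frame averages of a grid curve. The 1-s grid aligns with the integer-second
# frame boundaries; averages use the trapezoid rule within each frame.
frame_average <- function(y, schedule, dt_s = 1) {
  cum <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * dt_s))
  i0 <- round(schedule$start_s / dt_s) + 1L
  i1 <- round((schedule$start_s + schedule$dur_s) / dt_s) + 1L
  (cum[i1] - cum[i0]) / schedule$dur_s
}

input_curve_for <- function(model_id, wb_input = FALSE) {
  if (model_id == "1T2k_WB") {
    if (wb_input) "wb" else "plasma"
  } else {
    "plasma_mc"
  }
}

#' Forward-simulate a regional TAC from a compartment model
#'
#' Convolves the analytic tissue impulse response with the metabolite-
#' corrected plasma input on a 1-second grid, adds the fractional
#' blood-volume contribution, and averages over the acquisition frames.
#'
#' @param model_id one of `"1T2k"`, `"2T3k"`, `"2T4k"`, `"1T2k_WB"` (the
#'   latter uses the non-metabolite-corrected input, see `wb_input`).
#' @param params a list with `K1` (mL.cm^-3.min^-1), `k2`, `k3`, `k4`
#'   (min^-1, as required by the model) and `Vb` (fraction in [0, 1]).
#' @param input an [input_function()].
#' @param schedule a [frame_schedule()].
#' @param delay_s input delay in seconds (overrides the input's stored delay).
#' @param wb_input for `1T2k_WB` only: use whole blood instead of uncorrected
#'   plasma as the input curve.
#' @param region,session,subject labels passed to the returned TAC.
#' @return A [new_tac()] with the model-predicted frame activities.
#' @export
forward_tac <- function(model_id, params, input, schedule, delay_s = NULL,
                        wb_input = FALSE, region = "region", session = "test",
                        subject = "sim") {
  model_id <- match.arg(model_id, MODEL_IDS)
  schedule <- assert_frame_schedule(schedule)
  span <- schedule_span_min(schedule)
  if (max(input$time_min) < span - 1e-9) {
    stop("input function span is shorter than the frame schedule")
  }
  if (is.null(params$Vb)) params$Vb <- 0
  check_params_physical(model_id, params)
  dt <- 1 / 60
  tt <- seq(0, span, by = dt)
  cp <- if_eval(input, tt, curve = input_curve_for(model_id, wb_input),
                delay_s = delay_s)
  wb <- if_eval(input, tt, curve = "wb", delay_s = delay_s)
  ct <- tissue_grid(model_id, params, cp, dt)
  meas <- (1 - params$Vb) * ct + params$Vb * wb
  new_tac(schedule, frame_average(meas, schedule), region = region,
          session = session, subject = subject)
}

# Physical validity for forward simulation (the fitting bounds — K1 <= 0.7,
# k3 <= 0.8, Vb <= 0.7, VT <= 40 — constrain estimation, not simulation).
check_params_physical <- function(model_id, params) {
  if (params$K1 < 0) stop("K1 must be >= 0")
  if (params$Vb < 0 || params$Vb > 1) stop("Vb must lie in [0, 1]")
  if (params$k2 < 0) stop("k2 must be >= 0")
  if (model_id %in% c("2T3k", "2T4k")) {
    if (is.null(params$k3)) stop("k3 required for two-tissue models")
    if (params$k3 < 0) stop("k3 must be >= 0")
  }
  if (model_id == "2T4k") {
    if (is.null(params$k4) || params$k4 <= 0) {
      stop("2T4k requires k4 > 0 (use model_id '2T3k' for the irreversible model)")
    }
  }
  invisible(TRUE)
}

macro_vt <- function(model_id, params) {
  switch(model_id,
         "1T2k" = , "1T2k_WB" = if (params$k2 > 0) params$K1 / params$k2 else Inf,
         "2T4k" = if (params$k2 > 0 && params$k4 > 0)
           (params$K1 / params$k2) * (1 + params$k3 / params$k4) else Inf,
         "2T3k" = NA_real_)
}

macro_ki <- function(model_id, params) {
  if (model_id != "2T3k") return(NA_real_)
  params$K1 * params$k3 / (params$k2 + params$k3)
}

#' Akaike information criterion for a kinetic fit
#'
#' Gaussian residual form: `AIC = n log(RSS / n) + 2 p`, where `p` counts
#' all fitted parameters including the blood-volume fraction.
#'
#' @param rss residual sum of squares (weighted), > 0.
#' @param n number of frames used.
#' @param p number of fitted parameters.
#' @export
compute_aic <- function(rss, n, p) {
  if (n <= p) stop("need more frames than parameters for AIC")
  if (rss < 0) stop("RSS must be >= 0")
  if (rss == 0) {
    warning("RSS is exactly zero; returning -Inf AIC")
    return(-Inf)
  }
  n * log(rss / n) + 2 * p
}

# Frame weights proportional to duration / activity, floor-clamped at 5% of
# the peak activity, normalised to mean 1 (standard PET count weighting).
frame_weights <- function(tac) {
  act <- pmax(tac$activity, 0.05 * max(tac$activity))
  w <- tac$schedule$dur_s / act
  w / mean(w)
}

#' Fit a compartment model to a regional TAC
#'
#' Bounded weighted nonlinear least squares (weights proportional to frame
#' duration over activity, floor-clamped), multi-start with the best-RSS
#' winner. Parameter bounds follow the physiological boundaries: all lower
#' bounds 0, K1 <= 0.7 mL.cm^-3.min^-1, k3 <= 0.8 min^-1, Vb <= 0.7, and
#' implied VT <= 40 (for the one-tissue models via the reparameterisation
#' k2 = K1/40 + s with s >= 0; for 2T4k via a smooth penalty).
#'
#' @inheritParams forward_tac
#' @param tac the measured [new_tac()].
#' @param n_starts number of multi-start initialisations (default 3).
#' @return An object of class `kinetic_fit`: list with `model_id`, `params`
#'   (K1, k2, k3, k4, Vb, delay_s), `vt`, `ki`, `rss` (weighted), `aic`,
#'   `n_frames`, `converged`.
#' @export
fit_compartment_model <- function(tac, input, model_id, delay_s = NULL,
                                  wb_input = FALSE, n_starts = 3) {
  model_id <- match.arg(model_id, MODEL_IDS)
  stopifnot(inherits(tac, "tac"), inherits(input, "input_function"))
  if (all(tac$activity == 0)) stop("all-zero TAC cannot be fitted")
  schedule <- tac$schedule
  span <- schedule_span_min(schedule)
  if (max(input$time_min) < span - 1e-9) {
    stop("input function span is shorter than the TAC")
  }
  dt <- 1 / 60
  tt <- seq(0, span, by = dt)
  cp <- if_eval(input, tt, curve = input_curve_for(model_id, wb_input),
                delay_s = delay_s)
  wb <- if_eval(input, tt, curve = "wb", delay_s = delay_s)
  w <- frame_weights(tac)
  obs <- tac$activity
  W <- frame_average_matrix(schedule, length(tt))
  wb_frames <- as.vector(W %*% wb)

  # parameter vectors by model:
  #   1T2k:  (K1, s, Vb)            with k2 = K1/40 + s  (VT <= 40 exactly)
  #   2T3k:  (K1, k2, k3, Vb)
  #   2T4k:  (K1, k2, k3, k4, Vb)   VT <= 40 via smooth penalty
  unpack <- function(p) {
    switch(model_id,
      "1T2k" = , "1T2k_WB" =
        list(K1 = p[1], k2 = p[1] / 40 + p[2], Vb = p[3]),
      "2T3k" = list(K1 = p[1], k2 = p[2], k3 = p[3], Vb = p[4]),
      "2T4k" = list(K1 = p[1], k2 = p[2], k3 = p[3], k4 = p[4], Vb = p[5]))
  }
  sw <- sqrt(w)
  pen_scale <- max(obs)
  residuals_fn <- function(p) {
    pars <- unpack(p)
    ct <- tissue_grid(model_id, pars, cp, dt)
    pred <- (1 - pars$Vb) * as.vector(W %*% ct) + pars$Vb * wb_frames
    r <- sw * (obs - pred)
    if (model_id == "2T4k") {
      # fixed-length residual vector: zero below the bound, smooth above
      vt <- macro_vt(model_id, pars)
      excess <- if (is.finite(vt)) max(vt - 40, 0) else 1e6
      r <- c(r, pen_scale * excess)
    }
    r
  }
  rss_fn <- function(p) {
    pars <- unpack(p)
    ct <- tissue_grid(model_id, pars, cp, dt)
    pred <- (1 - pars$Vb) * as.vector(W %*% ct) + pars$Vb * wb_frames
    sum(w * (obs - pred)^2)
  }
  bounds <- switch(model_id,
    "1T2k" = , "1T2k_WB" = list(lower = c(1e-6, 0, 0), upper = c(0.7, 5, 0.7)),
    "2T3k" = list(lower = c(1e-6, 1e-6, 0, 0), upper = c(0.7, 5, 0.8, 0.7)),
    "2T4k" = list(lower = c(1e-6, 1e-6, 0, 1e-4, 0),
                  upper = c(0.7, 5, 0.8, 2, 0.7)))
  # multi-start at fractions of the upper bounds (rate starts kept in a
  # physiological range rather than scaled to the wide k2/k4 boxes)
  fracs <- c(0.1, 0.3, 0.5)[seq_len(n_starts)]
  starts <- lapply(fracs, function(f) {
    switch(model_id,
      "1T2k" = , "1T2k_WB" = c(0.7 * f, 0.2 * f, 0.1 * f),
      "2T3k" = c(0.7 * f, 0.4 * f, 0.8 * f, 0.1 * f),
      "2T4k" = c(0.7 * f, 0.4 * f, 0.8 * f, 0.2 * f, 0.1 * f))
  })
  if (model_id %in% c("2T3k", "2T4k")) {
    # nested start: the one-tissue solution with k3 = 0 reproduces the 1T2k
    # impulse response exactly, so the two-tissue fit can only improve on it
    f1 <- tryCatch(
      fit_compartment_model(tac, input, "1T2k", delay_s = delay_s,
                            n_starts = n_starts),
      error = function(e) NULL)
    if (!is.null(f1) && !is.null(f1$params)) {
      starts <- c(starts, list(
        if (model_id == "2T3k") {
          c(f1$params$K1, f1$params$k2, 0, f1$params$Vb)
        } else {
          c(f1$params$K1, f1$params$k2, 0, 0.05, f1$params$Vb)
        }))
    }
  }
  best <- NULL
  best_obj <- Inf
  converged <- FALSE
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = bounds$lower,
                         upper = bounds$upper, fn = residuals_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(residuals_fn(fit$par)^2)
    if (obj < best_obj) {
      best <- fit
      best_obj <- obj
      converged <- fit$info %in% 1:4
    }
  }
  if (is.null(best)) {
    return(structure(list(model_id = model_id, params = NULL, vt = NA_real_,
                          ki = NA_real_, rss = NA_real_, aic = NA_real_,
                          n_frames = length(obs), converged = FALSE),
                     class = "kinetic_fit"))
  }
  pars <- unpack(best$par)
  pars$delay_s <- if (is.null(delay_s)) input$delay_s else delay_s
  n <- length(obs)
  p_n <- model_n_params(model_id)
  rss <- rss_fn(best$par)
  aic <- if (rss > 0) n * log(rss / n) + 2 * p_n else -Inf
  structure(list(model_id = model_id, params = pars,
                 vt = macro_vt(model_id, pars),
                 ki = macro_ki(model_id, pars),
                 rss = rss, aic = aic, n_frames = n, converged = converged),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s: VT = %.3g, Ki = %.3g, RSS = %.4g, AIC = %.2f%s\n",
              x$model_id, x$vt, x$ki, x$rss, x$aic,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  if (!is.null(x$params)) {
    p <- x$params
    cat(sprintf("  K1 = %.4f, k2 = %.4f%s%s, Vb = %.3f\n", p$K1, p$k2,
                if (!is.null(p$k3)) sprintf(", k3 = %.4f", p$k3) else "",
                if (!is.null(p$k4)) sprintf(", k4 = %.4f", p$k4) else "",
                p$Vb))
  }
  invisible(x)
}
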