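#' Metabolite-corrected plasma input function
#'
#' An input function bundles the three continuous blood curves evaluated on a
#' regular 1-second grid: whole blood, total plasma, and metabolite-corrected
#' plasma (plasma times parent fraction), plus a per-region delay in seconds.
#' Build one from fitted analytic models with [input_from_models()] or from
#' an image-derived early blood-pool curve with [build_idif()].
#'
#' @param time_min grid times in minutes (regular, starting at 0).
#' @param wb,plasma,plasma_mc activity concentration (kBq/mL) on the grid.
#' @param delay_s time shift in seconds applied when evaluating (a positive
#'   delay means the blood curves reach the tissue late).
#' @param scale scale factor applied to the image-derived segment (NA when
#'   not applicable).
#' @param models optional list of the underlying analytic models.
#' @export
input_function <- function(time_min, wb, plasma, plasma_mc, delay_s = 0,
                           scale = NA_real_, models = NULL) {
  n <- length(time_min)
  stopifnot(length(wb) == n, length(plasma) == n, length(plasma_mc) == n)
  if (any(!is.finite(wb)) || any(!is.finite(plasma)) || any(!is.finite(plasma_mc))) {
    stop("input-function curves must be finite")
  }
  if (any(plasma_mc < -1e-9)) stop("metabolite-corrected plasma must be >= 0")
  structure(list(time_min = as.numeric(time_min), wb = as.numeric(wb),
                 plasma = as.numeric(plasma), plasma_mc = as.numeric(plasma_mc),
                 delay_s = delay_s, scale = scale, models = models),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "<input_function> span %.1f min, delay %+.0f s, peak plasma_mc %.2f kBq/mL\n",
    max(x$time_min), x$delay_s, max(x$plasma_mc)))
  invisible(x)
}

#' Evaluate an input function
#'
#' Linear interpolation on the stored grid; times before injection evaluate
#' to zero. The stored `delay_s` is applied unless overridden.
#'
#' @param input an [input_function()].
#' @param t_min evaluation times (minutes).
#' @param curve one of `"plasma_mc"`, `"plasma"`, `"wb"`.
#' @param delay_s override for the stored delay (seconds).
#' @export
if_eval <- function(input, t_min,
                    curve = c("plasma_mc", "plasma", "wb"),
                    delay_s = NULL) {
  curve <- match.arg(curve)
  d <- if (is.null(delay_s)) input$delay_s else delay_s
  tt <- as.numeric(t_min) - d / 60
  y <- stats::approx(input$time_min, input[[curve]], xout = pmax(tt, 0),
                     rule = 2)$y
  y[tt < 0] <- 0
  y
}

#' Build an input function from analytic blood models
#'
#' Evaluates a whole-blood curve, plasma curve and parent-fraction model on a
#' regular grid. Used for ground-truth inputs of synthetic subjects and for
#' sample-only (image-free) input functions.
#'
#' @param wb_model,plasma_model [blood_curve()] models.
#' @param pf_model a [parent_fraction_model()]; `NULL` means no metabolite
#'   correction (parent fraction 1 everywhere).
#' @param span_min grid span (minutes).
#' @param dt_s grid step (seconds); the package convention is 1 s.
#' @export
input_from_models <- function(wb_model, plasma_model, pf_model = NULL,
                              span_min = 60, dt_s = 1) {
  tt <- seq(0, span_min, by = dt_s / 60)
  wb <- eval_blood_curve(wb_model, tt)
  pl <- eval_blood_curve(plasma_model, tt)
  pf <- if (is.null(pf_model)) rep(1, length(tt)) else eval_parent_fraction(pf_model, tt)
  input_function(tt, wb, pl, pl * pf,
                 models = list(whole_blood = wb_model, plasma = plasma_model,
                               parent_fraction = pf_model))
}

# Fit a rise + multi-exponential blood model to the early image frames,
# accounting for frame averaging (long early frames otherwise bias the sharp
# bolus peak). Model order 3; nls.lm with bounds and two starts.
fit_early_blood_model <- function(image_blood_tac, junction_min) {
  sch <- image_blood_tac$schedule
  early <- which(sch$start_s + sch$dur_s <= junction_min * 60 + 1e-9)
  sub <- sch[early, , drop = FALSE]
  class(sub) <- c("frame_schedule", "data.frame")
  y <- image_blood_tac$activity[early]
  tt <- seq(0, junction_min, by = 1 / 60)
  W <- frame_average_matrix(sub, length(tt))
  resid_fn <- function(p) {
    bc <- blood_curve(p[2:4], p[5:7], t_peak = p[1],
                      span_min = junction_min)
    y - as.vector(W %*% eval_blood_curve(bc, tt))
  }
  ymax <- max(y)
  lower <- c(0.05, rep(0, 3), rep(1e-4, 3))
  upper <- c(2.5, rep(ymax * 20 + 1e-9, 3), c(20, 5, 1))
  starts <- list(c(0.75, ymax * c(1.5, 0.4, 0.1), c(3.5, 0.3, 0.01)),
                 c(1.2, ymax * c(1.0, 0.6, 0.2), c(6, 0.8, 0.05)))
  best <- NULL; best_obj <- Inf
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(resid_fn(fit$par)^2)
    if (obj < best_obj) { best <- fit; best_obj <- obj }
  }
  if (is.null(best)) stop("early blood-pool model failed to converge")
  p <- best$par
  blood_curve(p[2:4], p[5:7], t_peak = p[1], span_min = junction_min)
}

#' Image-derived input function (IDIF)
#'
#' Combines the early image-derived blood-pool curve with sample-based
#' analytic models: before `junction_min` the peak segment is a rise +
#' multi-exponential model fitted to the early image frames through the
#' frame-averaging operator, multiplied by a single constant scale factor
#' that matches the fitted whole-blood activity at the junction; from the
#' junction onwards the fitted sample curves are used. Plasma is derived via
#' the plasma-to-whole-blood ratio of the fitted curves, and metabolite-
#' corrected plasma via the parent-fraction model. The result is continuous
#' at the junction by construction.
#'
#' @param image_blood_tac a [new_tac()] from the blood-pool (ascending aorta)
#'   region, covering 0 to `junction_min` with at least 5 frames.
#' @param wb_model,plasma_model fitted [blood_curve()] models (see
#'   [fit_blood_curves()]).
#' @param pf_model fitted [parent_fraction_model()].
#' @param junction_min junction time (minutes); default 5.
#' @param span_min output grid span (minutes).
#' @return An [input_function()] with the `scale` field set.
#' @export
build_idif <- function(image_blood_tac, wb_model, plasma_model, pf_model,
                       junction_min = 5, span_min = 60) {
  stopifnot(inherits(image_blood_tac, "tac"))
  mids <- tac_midpoints_min(image_blood_tac)
  early <- sum(mids <= junction_min)
  span_img <- schedule_span_min(image_blood_tac$schedule)
  if (early < 5L || span_img < junction_min) {
    stop(sprintf(
      "image blood TAC must cover 0-%g min with >= 5 frames (has %d early frames, span %.1f min)",
      junction_min, early, span_img))
  }
  tt <- seq(0, span_min, by = 1 / 60)
  wb_fit <- eval_blood_curve(wb_model, tt)
  pl_fit <- eval_blood_curve(plasma_model, tt)
  pf <- eval_parent_fraction(pf_model, tt)

  early_model <- fit_early_blood_model(image_blood_tac, junction_min)
  wb_j <- eval_blood_curve(wb_model, junction_min)
  img_j <- eval_blood_curve(early_model, junction_min)
  if (wb_j <= 0) stop("fitted whole-blood activity at the junction is zero; cannot scale")
  if (img_j <= 0) stop("image-derived activity at the junction is zero; cannot scale")
  scale <- wb_j / img_j

  wb <- wb_fit
  pre <- tt < junction_min
  wb[pre] <- scale * eval_blood_curve(early_model, tt[pre])
  # plasma via the ratio of the fitted curves (guarded at early times where
  # the fitted decay models extrapolate)
  ratio <- ifelse(wb_fit > 0, pl_fit / wb_fit, 1)
  pl <- wb * ratio
  input_function(tt, wb, pl, pl * pf, scale = scale,
                 models = list(whole_blood = wb_model, plasma = plasma_model,
                               parent_fraction = pf_model))
}

#' Estimate the input-to-tissue delay for one region
#'
#' Grid search over integer-second shifts: the shift whose delayed input
#' minimises the one-tissue-model (1T2k) weighted residual sum of squares on
#' the target TAC is returned. Requires at least 3 frames in the first two
#' minutes; a flat early TAC yields a warning and delay 0.
#'
#' @param input an [input_function()] (its stored delay is ignored).
#' @param tac the regional [new_tac()].
#' @param range_s search range in seconds (default -30..+30).
#' @param step_s search step (seconds).
#' @return The estimated delay in seconds.
#' @export
estimate_delay <- function(input, tac, range_s = c(-30, 30), step_s = 1) {
  mids <- tac_midpoints_min(tac)
  early <- which(mids <= 2)
  if (length(early) < 3L) stop("TAC needs >= 3 frames within the first 2 min")
  if (max(tac$activity[early]) - min(tac$activity[early]) <= 1e-9) {
    warning("flat early TAC; returning delay 0")
    return(0)
  }
  shifts <- seq(range_s[1], range_s[2], by = step_s)
  rss <- vapply(shifts, function(d) {
    fit <- fit_compartment_model(tac, input, "1T2k", delay_s = d, n_starts = 1)
    fit$rss
  }, numeric(1))
  shifts[which.min(rss)]
}
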