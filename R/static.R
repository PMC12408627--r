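# Simplified static uptake measures: SUV and target-to-blood ratios.

#' Standardized uptake value over a time window
#'
#' Time-weighted mean activity over the window (kBq/mL) normalised by
#' injected dose per body weight. With tissue density taken as 1 g/mL the
#' normalisation reduces to `SUV = C[kBq/mL] * weight[kg] / dose[MBq]`, so
#' uniform unit uptake of the whole injected dose per kg gives SUV = 1.
#'
#' @param tac a [new_tac()].
#' @param injected_dose_mbq injected activity, MBq (> 0).
#' @param body_weight_kg body weight, kg (> 0).
#' @param window_min `c(start, end)` in minutes, within the TAC span.
#' @return SUV (dimensionless).
#' @export
compute_suv <- function(tac, injected_dose_mbq, body_weight_kg,
                        window_min = c(30, 60)) {
  if (injected_dose_mbq <= 0) stop("`injected_dose_mbq` must be > 0")
  if (body_weight_kg <= 0) stop("`body_weight_kg` must be > 0")
  mean_act <- tac_window_mean(tac, window_min)
  mean_act * body_weight_kg / injected_dose_mbq
}

#' Target-to-blood ratio over a time window
#'
#' Ratio of the time-weighted mean tissue activity to the time-weighted mean
#' of the selected blood curve over the same window. `mode = "WB"` uses whole
#' blood (TBR-WB); `mode = "PP"` uses metabolite-corrected plasma (TBR-PP).
#' Blood denominators are evaluated from the continuous fitted curves.
#'
#' @inheritParams compute_suv
#' @param input an [input_function()].
#' @param mode `"WB"` or `"PP"`.
#' @return TBR (dimensionless).
#' @export
compute_tbr <- function(tac, input, window_min = c(30, 60),
                        mode = c("WB", "PP")) {
  mode <- match.arg(mode)
  if (max(input$time_min) < window_min[2] - 1e-9) {
    stop("input function does not cover the window")
  }
  mean_tissue <- tac_window_mean(tac, window_min)
  tt <- seq(window_min[1], window_min[2], by = 1 / 60)
  blood <- if_eval(input, tt, curve = if (mode == "WB") "wb" else "plasma_mc")
  mean_blood <- trapz(tt, blood) / diff(window_min)
  if (mean_blood <= 0) stop("blood activity integrates to zero over the window")
  mean_tissue / mean_blood
}
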