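# Shared fixtures, built in code.

# Ground-truth style input function: rise + tri-exponential whole blood,
# plasma at 0.8 x whole blood, default Hill parent fraction.
make_input <- function(span_min = 60, plasma_ratio = 0.8, pf = TRUE) {
  wb <- blood_curve(c(30, 8, 2), c(3.5, 0.3, 0.01), t_peak = 0.75,
                    span_min = span_min)
  pl <- blood_curve(wb$A * plasma_ratio, wb$lambda, t_peak = wb$t_peak,
                    span_min = span_min)
  input_from_models(wb, pl,
                    if (pf) default_parent_fraction_model() else NULL,
                    span_min = span_min)
}

# The 19-frame protocol schedule with the final frame extended to 60 min.
sch60 <- function() frame_schedule(extend_last = TRUE)

# Finer late framing (protocol early frames, then 2-min frames), used where
# the graphical methods need several late points.
fine_schedule <- function(end_min = 56) {
  early <- default_frame_durations()[1:12]
  n_late <- floor((end_min * 60 - sum(early)) / 120)
  frame_schedule(c(early, rep(120, n_late)))
}

# Venous samples drawn (noiselessly) from an input function's models.
samples_from_input <- function(input, times = c(5, 10, 15, 30, 35, 40, 59)) {
  blood_samples(times,
                eval_blood_curve(input$models$whole_blood, times),
                eval_blood_curve(input$models$plasma, times),
                if (is.null(input$models$parent_fraction)) 1 else
                  eval_parent_fraction(input$models$parent_fraction, times))
}
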