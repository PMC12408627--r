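# Synthetic subjects with known ground truth: tri-exponential-like blood
# curves peaking within 2 min, plasma at a fixed fraction of whole blood,
# a Hill-type parent fraction reaching ~0.80 at 30 min and ~0.72 at 60 min,
# TACs from 1T2k/2T4k kinetics with frame-dependent Gaussian noise, optional
# motion artifacts, and a controllable test-retest variance structure.

#' Default Hill parent-fraction parameters
#'
#' Calibrated so pf(30 min) = 0.80 and pf(60 min) = 0.72 exactly:
#' asymptotic metabolite fraction a = 0.35, slope b = log(3)/log(2), and
#' half-time c = 30 * (3/4)^(1/b) minutes.
#' @export
default_parent_fraction_model <- function() {
  b <- log(3) / log(2)
  parent_fraction_model(a = 0.35, b = b, c = 30 * (3 / 4)^(1 / b))
}

# Whole-blood shape in SUV units: linear rise to the peak at 0.75 min, then
# a tri-exponential decay. Amplitude is converted to kBq/mL per subject via
# dose/weight. Fractions/rates give a curve dropping ~30x from peak to the
# 30-60 min plateau, as seen for short-lived TSPO ligands.
wb_shape_suv <- function(peak_suv = 5.5) {
  blood_curve(A = peak_suv * c(0.75, 0.20, 0.05),
              lambda = c(3.5, 0.30, 0.010), t_peak = 0.75)
}

#' Configuration for the synthetic-subject generator
#'
#' @param n_subjects number of subjects.
#' @param model_id kinetic model generating the tissue curves: `"1T2k"` or
#'   `"2T4k"`.
#' @param vt_range range of true volumes of distribution (used when no
#'   `regions` table is given).
#' @param k1_range range of true K1 values (mL.cm^-3.min^-1).
#' @param vb_range range of true fractional blood volumes.
#' @param noise_cv fractional coefficient of variation of the frame noise at
#'   the last frame (>= 0).
#' @param retest_log_sd between-session log-scale SD applied to true K1 and
#'   VT for retest sessions.
#' @param motion_probability probability that a regional TAC receives a
#'   motion artifact (single-frame signal drop), in [0, 1].
#' @param seed integer RNG seed; the cohort is deterministic given the seed.
#' @param schedule a [frame_schedule()]; the default extends the final frame
#'   of the 19-frame protocol so the span closes the 60-min scan.
#' @param sample_times_min venous sampling times (minutes), strictly
#'   increasing and within the scan duration.
#' @param test_retest logical; also generate a retest session per subject.
#' @param regions optional data.frame with columns `region`, `condition`
#'   (`"target"`/`"unaffected"`), `vt_mean`, `vt_sd`; when given, true VT is
#'   drawn from a truncated normal per region instead of `vt_range`.
#' @param plasma_ratio plasma-to-whole-blood activity ratio (default 0.8).
#' @param wb_peak_suv whole-blood peak amplitude in SUV units.
#' @param dose_mbq_mean,dose_mbq_sd injected dose distribution (MBq).
#' @param weight_kg_mean,weight_kg_sd body-weight distribution (kg).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 14,
                             model_id = "1T2k",
                             vt_range = c(7, 17),
                             k1_range = c(0.15, 0.45),
                             vb_range = c(0.03, 0.08),
                             noise_cv = 0.03,
                             retest_log_sd = 0.1,
                             motion_probability = 0,
                             seed = 1L,
                             schedule = frame_schedule(extend_last = TRUE),
                             sample_times_min = c(5, 10, 15, 30, 35, 40, 59),
                             test_retest = FALSE,
                             regions = NULL,
                             plasma_ratio = 0.8,
                             wb_peak_suv = 5.5,
                             dose_mbq_mean = 370, dose_mbq_sd = 22,
                             weight_kg_mean = 75, weight_kg_sd = 10) {
  chk_range <- function(r, nm, lo = -Inf, hi = Inf) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      stop(sprintf("invalid `%s`: must be an ordered pair within [%g, %g]",
                   nm, lo, hi))
    }
  }
  if (n_subjects < 1L) stop("invalid `n_subjects`: must be >= 1")
  model_id <- match.arg(model_id, c("1T2k", "2T4k"))
  chk_range(vt_range, "vt_range", 0, 40)
  chk_range(k1_range, "k1_range", 0, 0.7)
  chk_range(vb_range, "vb_range", 0, 0.7)
  if (noise_cv < 0) stop("invalid `noise_cv`: must be >= 0")
  if (retest_log_sd < 0) stop("invalid `retest_log_sd`: must be >= 0")
  if (motion_probability < 0 || motion_probability > 1) {
    stop("invalid `motion_probability`: must lie in [0, 1]")
  }
  schedule <- assert_frame_schedule(schedule)
  if (any(diff(sample_times_min) <= 0)) {
    stop("invalid `sample_times_min`: must be strictly increasing")
  }
  if (max(sample_times_min) > 60) {
    stop("invalid `sample_times_min`: must lie within the 60-min scan")
  }
  if (!is.null(regions)) {
    need <- c("region", "condition", "vt_mean", "vt_sd")
    if (!is.data.frame(regions) || !all(need %in% names(regions))) {
      stop("invalid `regions`: need columns region, condition, vt_mean, vt_sd")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), model_id = model_id,
                 vt_range = vt_range, k1_range = k1_range,
                 vb_range = vb_range, noise_cv = noise_cv,
                 retest_log_sd = retest_log_sd,
                 motion_probability = motion_probability,
                 seed = as.integer(seed), schedule = schedule,
                 sample_times_min = sample_times_min,
                 test_retest = test_retest, regions = regions,
                 plasma_ratio = plasma_ratio, wb_peak_suv = wb_peak_suv,
                 dose_mbq_mean = dose_mbq_mean, dose_mbq_sd = dose_mbq_sd,
                 weight_kg_mean = weight_kg_mean, weight_kg_sd = weight_kg_sd),
            class = "generator_config")
}

#' Reference region table with target/unaffected cohort moments
#'
#' Neuroforaminal and spinal-cord target and unaffected regions with
#' one-tissue VT means (SD) of 15.00 (6.09), 8.80 (3.51), 13.52 (6.24) and
#' 7.41 (4.05).
#' @export
default_region_table <- function() {
  data.frame(
    region = c("neuroforamina", "neuroforamina", "spinal_cord", "spinal_cord"),
    condition = c("target", "unaffected", "target", "unaffected"),
    vt_mean = c(15.00, 8.80, 13.52, 7.41),
    vt_sd = c(6.09, 3.51, 6.24, 4.05))
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Frame-dependent Gaussian noise: SD_i proportional to sqrt(activity/duration),
# normalised so SD at the last frame equals noise_cv * activity(last frame).
add_frame_noise <- function(activity, dur_s, noise_cv) {
  if (noise_cv == 0) return(activity)
  n <- length(activity)
  ref <- max(activity[n], 1e-12) / dur_s[n]
  sd_i <- noise_cv * activity[n] * sqrt(pmax(activity, 0) / dur_s / ref)
  pmax(activity + stats::rnorm(n, 0, sd_i), 0)
}

draw_region_params <- function(config, vt) {
  K1 <- stats::runif(1, config$k1_range[1], config$k1_range[2])
  Vb <- stats::runif(1, config$vb_range[1], config$vb_range[2])
  if (config$model_id == "1T2k") {
    list(model_id = "1T2k", K1 = K1, k2 = K1 / vt, Vb = Vb, VT = vt)
  } else {
    k3 <- stats::runif(1, 0.02, 0.10)
    k4 <- stats::runif(1, 0.02, 0.05)
    list(model_id = "2T4k", K1 = K1, k2 = (K1 / vt) * (1 + k3 / k4),
         k3 = k3, k4 = k4, Vb = Vb, VT = vt)
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic given `config$seed`. Each subject carries its true kinetic
#' parameters, ground-truth input function, discrete venous samples, an
#' image-derived blood-pool TAC (aorta surrogate) and noisy regional TACs;
#' with `test_retest = TRUE` a second session with lognormally perturbed
#' K1 and VT is added.
#'
#' @param config a [generator_config()].
#' @return A list of `synthetic_subject` objects.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  span <- max(60, schedule_span_min(config$schedule))
  regions <- if (is.null(config$regions)) {
    data.frame(region = "region1", condition = "target",
               vt_mean = NA_real_, vt_sd = NA_real_)
  } else {
    config$regions
  }
  sessions <- if (config$test_retest) c("test", "retest") else "test"
  cohort <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", i)
    dose <- max(stats::rnorm(1, config$dose_mbq_mean, config$dose_mbq_sd), 50)
    weight <- max(stats::rnorm(1, config$weight_kg_mean, config$weight_kg_sd), 40)
    # base truth per region (shared across sessions, then perturbed)
    base <- list()
    for (r in seq_len(nrow(regions))) {
      vt <- if (is.null(config$regions)) {
        stats::runif(1, config$vt_range[1], config$vt_range[2])
      } else {
        rnorm_trunc(1, regions$vt_mean[r], regions$vt_sd[r], 1.5, 38)
      }
      base[[paste(regions$region[r], regions$condition[r], sep = "_")]] <-
        draw_region_params(config, vt)
    }
    for (sess in sessions) {
      # per-session blood model: amplitude in kBq/mL from dose/weight, mild
      # biological jitter on the amplitude and the metabolite asymptote
      amp_jit <- exp(stats::rnorm(1, 0, 0.10))
      suv_to_kbq <- dose / weight
      shape <- wb_shape_suv(config$wb_peak_suv)
      wb_model <- blood_curve(shape$A * suv_to_kbq * amp_jit, shape$lambda,
                              t_peak = shape$t_peak, span_min = span)
      pl_model <- blood_curve(wb_model$A * config$plasma_ratio,
                              wb_model$lambda, t_peak = wb_model$t_peak,
                              span_min = span)
      pf_base <- default_parent_fraction_model()
      pf_model <- parent_fraction_model(
        min(max(pf_base$a + stats::rnorm(1, 0, 0.01), 0), 1),
        pf_base$b, pf_base$c)
      true_input <- input_from_models(wb_model, pl_model, pf_model,
                                      span_min = span)
      blood <- blood_samples(
        config$sample_times_min,
        eval_blood_curve(wb_model, config$sample_times_min),
        eval_blood_curve(pl_model, config$sample_times_min),
        eval_parent_fraction(pf_model, config$sample_times_min))
      wb_frames <- frame_average(true_input$wb, config$schedule)
      image_blood_tac <- new_tac(
        config$schedule,
        add_frame_noise(wb_frames, config$schedule$dur_s, config$noise_cv),
        region = "aorta", session = sess, subject = sid)

      true_params <- base
      if (sess == "retest" && config$retest_log_sd > 0) {
        for (nm in names(true_params)) {
          p <- true_params[[nm]]
          p$K1 <- min(p$K1 * exp(stats::rnorm(1, 0, config$retest_log_sd)), 0.7)
          p$VT <- min(p$VT * exp(stats::rnorm(1, 0, config$retest_log_sd)), 38)
          p$k2 <- if (p$model_id == "1T2k") p$K1 / p$VT else
            (p$K1 / p$VT) * (1 + p$k3 / p$k4)
          true_params[[nm]] <- p
        }
      }
      region_tacs <- list()
      motion_frames <- list()
      for (nm in names(true_params)) {
        p <- true_params[[nm]]
        clean <- forward_tac(p$model_id, p, true_input, config$schedule,
                             region = nm, session = sess, subject = sid)
        noisy <- clean
        noisy$activity <- add_frame_noise(clean$activity,
                                          config$schedule$dur_s,
                                          config$noise_cv)
        if (config$motion_probability > 0 &&
            stats::runif(1) < config$motion_probability) {
          late <- which(tac_midpoints_min(noisy) > 10)
          fr <- late[sample.int(length(late), 1)]
          noisy <- add_motion_artifact(noisy, fr,
                                       stats::runif(1, 0.35, 0.6))
          motion_frames[[nm]] <- fr
        }
        region_tacs[[nm]] <- noisy
      }
      cohort[[length(cohort) + 1L]] <- structure(
        list(subject_id = sid, session = sess, true_params = true_params,
             blood = blood, image_blood_tac = image_blood_tac,
             region_tacs = region_tacs, true_input = true_input,
             injected_dose_mbq = dose, body_weight_kg = weight,
             motion_frames = motion_frames),
        class = "synthetic_subject")
    }
  }
  cohort
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s (%s): %d region TAC(s), dose %.0f MBq, %.0f kg\n",
              x$subject_id, x$session, length(x$region_tacs),
              x$injected_dose_mbq, x$body_weight_kg))
  invisible(x)
}

#' Inject a motion-like signal drop into a TAC
#'
#' Returns a copy of the TAC with the activity at `frame_index` (and, when
#' `sustained = TRUE`, all subsequent frames) multiplied by
#' `1 - drop_fraction`. The input TAC is unmodified.
#'
#' @param tac a [new_tac()].
#' @param frame_index frame to perturb.
#' @param drop_fraction fraction of signal lost, in (0, 1).
#' @param sustained apply the drop to all subsequent frames as well.
#' @export
add_motion_artifact <- function(tac, frame_index, drop_fraction,
                                sustained = FALSE) {
  stopifnot(inherits(tac, "tac"))
  n <- length(tac$activity)
  if (frame_index < 1L || frame_index > n) {
    stop(sprintf("frame_index %d out of range 1..%d", frame_index, n))
  }
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop("`drop_fraction` must lie in (0, 1)")
  }
  idx <- if (sustained) frame_index:n else frame_index
  tac$activity[idx] <- tac$activity[idx] * (1 - drop_fraction)
  tac
}
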