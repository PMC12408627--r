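#' Discrete venous blood samples
#'
#' Container for the manual venous samples drawn during the scan: sample
#' times (minutes post-injection), whole-blood and plasma activity
#' concentrations (kBq/mL) and the plasma parent fraction (fraction of
#' plasma activity attributable to intact tracer, in [0, 1]).
#'
#' @param time_min sample times in minutes, strictly increasing.
#' @param whole_blood whole-blood activity concentration, kBq/mL.
#' @param plasma plasma activity concentration, kBq/mL.
#' @param parent_fraction plasma parent fraction in [0, 1] (may be `NA` if
#'   only the activity curves are needed).
#' @return An object of class `blood_samples` (a data.frame).
#' @export
blood_samples <- function(time_min, whole_blood, plasma,
                          parent_fraction = NA_real_) {
  n <- length(time_min)
  if (n < 1L) stop("at least one blood sample is required")
  if (any(diff(time_min) <= 0)) stop("`time_min` must be strictly increasing")
  if (any(!is.finite(whole_blood)) || any(!is.finite(plasma))) {
    stop("blood activities must be finite")
  }
  if (any(whole_blood < 0) || any(plasma < 0)) {
    stop("blood activities must be non-negative")
  }
  pf <- rep_len(as.numeric(parent_fraction), n)
  if (any(!is.na(pf) & (pf < 0 | pf > 1))) {
    stop("`parent_fraction` must lie in [0, 1]")
  }
  out <- data.frame(time_min = as.numeric(time_min),
                    whole_blood = as.numeric(whole_blood),
                    plasma = as.numeric(plasma),
                    parent_fraction = pf)
  class(out) <- c("blood_samples", "data.frame")
  out
}

#' Read and write blood sample CSVs
#'
#' Columns: `time_min`, `whole_blood_kbq_ml`, `plasma_kbq_ml`,
#' `parent_fraction` (plus optional `subject`, `session`).
#'
#' @param samples a `blood_samples` object.
#' @param path file path.
#' @param subject,session optional labels written alongside the samples.
#' @export
write_blood_csv <- function(samples, path, subject = "s01", session = "test") {
  df <- data.frame(time_min = samples$time_min,
                   whole_blood_kbq_ml = samples$whole_blood,
                   plasma_kbq_ml = samples$plasma,
                   parent_fraction = samples$parent_fraction,
                   subject = subject, session = session)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blood_csv
#' @export
read_blood_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "whole_blood_kbq_ml", "plasma_kbq_ml",
            "parent_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("blood file '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  }
  if (is.null(df$subject)) df$subject <- "s01"
  if (is.null(df$session)) df$session <- "test"
  key <- interaction(df$subject, df$session, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_min), ]
    blood_samples(d$time_min, d$whole_blood_kbq_ml, d$plasma_kbq_ml,
                  d$parent_fraction)
  })
}

# ---------------------------------------------------------------------------
# Blood curve model: optional linear rise from (0, 0) to a peak at t_peak,
# followed by a sum of 1-3 decaying exponentials. Fitted sample curves use
# t_peak = 0 (pure multi-exponential decay); the synthetic generator uses the
# rise + tri-exponential form.

#' Multi-exponential blood curve model
#'
#' `blood_curve()` builds the model; `eval_blood_curve()` evaluates it at
#' arbitrary times (minutes). For `t < t_peak` the curve rises linearly from
#' zero; for `t >= t_peak` it is `sum(A * exp(-lambda * (t - t_peak)))`.
#'
#' @param A non-negative exponential amplitudes (kBq/mL), 1-3 terms.
#' @param lambda non-negative decay rates (1/min), same length as `A`.
#' @param t_peak time of the peak (minutes); 0 for a pure decay model.
#' @param span_min valid time span (minutes).
#' @export
blood_curve <- function(A, lambda, t_peak = 0, span_min = 60) {
  if (length(A) != length(lambda) || length(A) < 1L || length(A) > 3L) {
    stop("`A` and `lambda` must have equal length between 1 and 3")
  }
  if (any(A < 0) || any(lambda < 0)) stop("amplitudes and rates must be >= 0")
  if (t_peak < 0) stop("`t_peak` must be >= 0")
  structure(list(A = as.numeric(A), lambda = as.numeric(lambda),
                 t_peak = t_peak, span_min = span_min),
            class = "blood_curve")
}

#' @rdname blood_curve
#' @param model a `blood_curve`.
#' @param t_min evaluation times, minutes.
#' @export
eval_blood_curve <- function(model, t_min) {
  stopifnot(inherits(model, "blood_curve"))
  t_min <- as.numeric(t_min)
  peak_val <- sum(model$A)
  y <- numeric(length(t_min))
  post <- t_min >= model$t_peak
  if (any(post)) {
    td <- outer(t_min[post] - model$t_peak, model$lambda, function(t, l) exp(-l * t))
    y[post] <- as.vector(td %*% model$A)
  }
  if (any(!post)) {
    # linear rise from injection to peak
    y[!post] <- peak_val * pmax(t_min[!post], 0) / model$t_peak
  }
  y
}

#' @export
print.blood_curve <- function(x, ...) {
  cat(sprintf("<blood_curve> %d exp term(s), peak %.2f kBq/mL at %.2f min\n",
              length(x$A), sum(x$A), x$t_peak))
  invisible(x)
}

# Fit sum of k decaying exponentials to (t, y) by bounded least squares,
# multi-start over log-spaced rate initialisations.
fit_multiexp <- function(t, y, k) {
  obj <- function(p) {
    A <- p[seq_len(k)]
    l <- p[k + seq_len(k)]
    pred <- as.vector(outer(t, l, function(tt, ll) exp(-ll * tt)) %*% A)
    sum((y - pred)^2)
  }
  ymax <- max(y)
  lower <- rep(0, 2 * k)
  upper <- c(rep(ymax * 10 + 1e-9, k), rep(10, k))
  starts <- list(
    c(rep(ymax / k, k), seq(0.01, 0.5, length.out = k)),
    c(rep(ymax / k, k), seq(0.005, 0.1, length.out = k)),
    c(rep(ymax / (2 * k), k), seq(0.02, 1, length.out = k))
  )
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::nlminb(p0, obj, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("multi-exponential fit failed to converge")
  list(A = best$par[seq_len(k)], lambda = best$par[k + seq_len(k)],
       rss = best$objective)
}

#' Fit multi-exponential curves to discrete blood samples
#'
#' Fits the decaying segment of the whole-blood and plasma sample series
#' separately with a sum of 1-3 exponentials; the model order is chosen by
#' lowest AIC (Gaussian residual form, ties broken toward fewer terms).
#'
#' @param samples a [blood_samples()] series with at least 4 samples.
#' @param span_min valid span recorded on the returned models (minutes).
#' @return A list with elements `whole_blood` and `plasma`
#'   (each a [blood_curve()]) and `residuals` (per-curve RSS and order).
#' @export
fit_blood_curves <- function(samples, span_min = 60) {
  stopifnot(inherits(samples, "blood_samples"))
  if (nrow(samples) < 4L) {
    stop("at least 4 blood samples are required to fit the blood curves")
  }
  fit_one <- function(y) {
    n <- length(y)
    # floor the RSS so noiseless fits don't let extra terms win on log(0)
    rss_floor <- n * (1e-6 * max(y, 1e-12))^2
    cands <- lapply(1:3, function(k) {
      if (2 * k >= n) return(NULL)
      f <- fit_multiexp(samples$time_min, y, k)
      f$k <- k
      f$aic <- n * log(max(f$rss, rss_floor) / n) + 2 * (2 * k)
      f
    })
    cands <- Filter(Negate(is.null), cands)
    aics <- vapply(cands, `[[`, numeric(1), "aic")
    cands[[which.min(round(aics, 6))]]  # which.min takes first on ties
  }
  fw <- fit_one(samples$whole_blood)
  fp <- fit_one(samples$plasma)
  list(whole_blood = blood_curve(fw$A, fw$lambda, t_peak = 0, span_min = span_min),
       plasma = blood_curve(fp$A, fp$lambda, t_peak = 0, span_min = span_min),
       residuals = data.frame(curve = c("whole_blood", "plasma"),
                              n_terms = c(fw$k, fp$k),
                              rss = c(fw$rss, fp$rss)))
}

# ---------------------------------------------------------------------------
# Parent fraction: Hill-type model pf(t) = 1 - a * t^b / (t^b + c^b).
# pf(0) = 1 by construction, monotone non-increasing, asymptote 1 - a.

#' Hill-type plasma parent-fraction model
#'
#' `parent_fraction_model()` constructs the model
#' `pf(t) = 1 - a * t^b / (t^b + c^b)`; `eval_parent_fraction()` evaluates it.
#' `pf(0) = 1` and the curve decreases monotonically to the asymptote `1 - a`.
#'
#' @param a asymptotic metabolite fraction in [0, 1].
#' @param b Hill slope, > 0.
#' @param c half-time parameter in minutes, > 0.
#' @export
parent_fraction_model <- function(a, b, c) {
  if (a < 0 || a > 1) stop("`a` must lie in [0, 1]")
  if (b <= 0) stop("`b` must be > 0")
  if (c <= 0) stop("`c` must be > 0")
  structure(list(a = a, b = b, c = c), class = "parent_fraction_model")
}

#' @rdname parent_fraction_model
#' @param model a `parent_fraction_model`.
#' @param t_min times in minutes, >= 0.
#' @export
eval_parent_fraction <- function(model, t_min) {
  stopifnot(inherits(model, "parent_fraction_model"))
  t_min <- pmax(as.numeric(t_min), 0)
  tb <- t_min^model$b
  1 - model$a * tb / (tb + model$c^model$b)
}

#' Fit the Hill parent-fraction model to discrete samples
#'
#' Bounded least squares with `pf(0) = 1` enforced by the functional form.
#'
#' @param samples a [blood_samples()] series with at least 3 non-missing
#'   parent fractions.
#' @return A [parent_fraction_model()].
#' @export
fit_parent_fraction <- function(samples) {
  stopifnot(inherits(samples, "blood_samples"))
  ok <- !is.na(samples$parent_fraction)
  if (sum(ok) < 3L) {
    stop("at least 3 parent-fraction samples are required")
  }
  t <- samples$time_min[ok]
  pf <- samples$parent_fraction[ok]
  if (any(pf < 0 | pf > 1)) stop("parent fractions must lie in [0, 1]")
  obj <- function(p) {
    m <- parent_fraction_model(p[1], p[2], p[3])
    sum((pf - eval_parent_fraction(m, t))^2)
  }
  lower <- c(0, 0.05, 0.5)
  upper <- c(1, 10, 500)
  starts <- list(c(0.3, 1.5, 25), c(0.5, 1, 10), c(0.2, 3, 60))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::nlminb(p0, obj, lower = lower, upper = upper,
                    control = list(iter.max = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("parent-fraction fit failed to converge")
  parent_fraction_model(best$par[1], best$par[2], best$par[3])
}
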