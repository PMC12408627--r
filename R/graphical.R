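# Logan and Patlak graphical analyses with plasma input.

graphical_prepare <- function(tac, input, t_star_min) {
  stopifnot(inherits(tac, "tac"), inherits(input, "input_function"))
  span <- schedule_span_min(tac$schedule)
  if (span <= t_star_min) stop("TAC does not extend beyond t*")
  dt <- 1 / 60
  tt <- seq(0, span, by = dt)
  cp <- if_eval(input, tt, curve = "plasma_mc")
  ct <- tac_interp(tac, tt)
  cum_cp <- c(0, cumsum((cp[-1] + cp[-length(cp)]) / 2 * dt))
  cum_ct <- c(0, cumsum((ct[-1] + ct[-length(ct)]) / 2 * dt))
  mids <- tac_midpoints_min(tac)
  idx <- pmin(round(mids / dt) + 1L, length(tt))
  # frames included by midpoint >= t*; when coarse late framing leaves fewer
  # than 3 such frames, widen to every frame extending beyond t*
  use <- mids >= t_star_min
  if (sum(use) < 3L) {
    ends <- (tac$schedule$start_s + tac$schedule$dur_s) / 60
    use <- ends > t_star_min
  }
  list(mids = mids, use = use,
       ct_mid = tac$activity, cp_mid = cp[idx],
       int_cp = cum_cp[idx], int_ct = cum_ct[idx])
}

graphical_ols <- function(x, y, method, t_star_min) {
  n <- length(x)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(method = method, t_star_min = t_star_min,
                 slope = unname(slope), intercept = unname(intercept),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = n),
            class = "graphical_fit")
}

#' @export
print.graphical_fit <- function(x, ...) {
  cat(sprintf("<graphical_fit> %s (t* = %g min): slope %.4g, R^2 %.4f, %d points\n",
              x$method, x$t_star_min, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Logan graphical analysis (volume of distribution)
#'
#' Ordinary least squares on the Logan linearisation
#' `int_0^t C_T / C_T(t)` versus `int_0^t C_p / C_T(t)` (metabolite-corrected
#' plasma input) over frames whose midpoints lie at or beyond `t_star_min`.
#' The slope estimates VT for reversible kinetics. Integrals are computed by
#' the trapezoid rule on the 1-second grid.
#'
#' @param tac a [new_tac()].
#' @param input an [input_function()].
#' @param t_star_min start of the linear segment (minutes), default 30.
#' @return A `graphical_fit` with the slope reported as VT.
#' @export
logan_vt <- function(tac, input, t_star_min = 30) {
  g <- graphical_prepare(tac, input, t_star_min)
  use <- g$use & g$ct_mid > 0
  if (sum(use) < 3L) stop("fewer than 3 usable frames past t*")
  x <- g$int_cp[use] / g$ct_mid[use]
  y <- g$int_ct[use] / g$ct_mid[use]
  graphical_ols(x, y, "Logan", t_star_min)
}

#' Patlak graphical analysis (net influx rate)
#'
#' OLS of `C_T(t) / C_p(t)` versus `int_0^t C_p / C_p(t)` past `t_star_min`;
#' the slope estimates the net influx rate Ki for irreversible kinetics.
#'
#' @inheritParams logan_vt
#' @return A `graphical_fit` with the slope reported as Ki (1/min).
#' @export
patlak_ki <- function(tac, input, t_star_min = 30) {
  g <- graphical_prepare(tac, input, t_star_min)
  use <- g$use & g$cp_mid > 0
  if (sum(use) < 3L) stop("fewer than 3 usable frames past t*")
  x <- g$int_cp[use] / g$cp_mid[use]
  y <- g$ct_mid[use] / g$cp_mid[use]
  graphical_ols(x, y, "Patlak", t_star_min)
}
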