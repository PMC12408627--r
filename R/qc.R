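# Model-selection tallies and quality-control rules.

QC_REASONS <- c("vt_median_rule", "motion", "missing_input")

#' Tally AIC model preference across regions
#'
#' For each region the model with the lowest AIC wins; ties are broken toward
#' the model with fewer parameters. Returns per-region winners plus cohort
#' percentages per model and for the reversible (1T2k/2T4k) versus
#' irreversible (2T3k) classes.
#'
#' @param fits a data.frame with columns `region` (one row per region x
#'   model), `model_id`, `aic` — or a list of `kinetic_fit` objects plus a
#'   parallel `region` vector.
#' @param region region identifiers when `fits` is a list of fits.
#' @return A list with `winners` (data.frame region/model_id/aic),
#'   `percent_by_model` (named percentages) and `percent_reversible`.
#' @export
tally_model_preference <- function(fits, region = NULL) {
  if (!is.data.frame(fits)) {
    stopifnot(!is.null(region), length(region) == length(fits))
    fits <- data.frame(
      region = region,
      model_id = vapply(fits, `[[`, character(1), "model_id"),
      aic = vapply(fits, `[[`, numeric(1), "aic"))
  }
  stopifnot(all(c("region", "model_id", "aic") %in% names(fits)))
  models <- intersect(MODEL_IDS, unique(fits$model_id))
  winners <- lapply(split(fits, fits$region), function(d) {
    if (!all(models %in% d$model_id) || any(!is.finite(d$aic))) {
      warning(sprintf("region '%s' lacks a finite AIC for every model; excluded",
                      d$region[1]))
      return(NULL)
    }
    # tie-break toward fewer parameters: order by AIC then parameter count
    np <- vapply(d$model_id, model_n_params, integer(1))
    d[order(d$aic, np), ][1, c("region", "model_id", "aic")]
  })
  winners <- do.call(rbind, Filter(Negate(is.null), winners))
  if (is.null(winners) || nrow(winners) == 0L) stop("no region had a complete set of fits")
  tab <- table(factor(winners$model_id, levels = models))
  pct <- 100 * as.numeric(tab) / nrow(winners)
  names(pct) <- names(tab)
  rev_pct <- sum(pct[names(pct) %in% c("1T2k", "2T4k", "1T2k_WB")])
  list(winners = winners, percent_by_model = pct,
       percent_reversible = rev_pct)
}

#' Flag a VT estimate as an outlier against the regional group median
#'
#' A fit is flagged when its VT exceeds the group median VT for the same
#' anatomical region by more than 50% (strict inequality, one-sided upward).
#'
#' @param vt estimated VT.
#' @param group_median_vt group median VT for the region, > 0.
#' @return Logical flag.
#' @export
flag_vt_outlier <- function(vt, group_median_vt) {
  if (any(group_median_vt <= 0)) stop("group median VT must be > 0")
  vt > 1.5 * group_median_vt
}

#' Detect motion-like signal drops in a TAC
#'
#' Flags non-physiological patterns typical of patient motion: a late frame
#' (midpoint beyond `late_min`) whose activity falls by more than
#' `drop_thresh` relative to the previous frame while the following frame
#' recovers by more than `recovery_thresh`, or any sustained late drop larger
#' than `sustained_thresh`. TACs with fewer than 8 frames return unflagged
#' with a warning.
#'
#' @param tac a [new_tac()].
#' @param late_min only frames with midpoint beyond this (minutes) are tested.
#' @param drop_thresh relative single-frame drop threshold (default 0.30).
#' @param recovery_thresh relative recovery threshold for the next frame
#'   (default 0.15).
#' @param sustained_thresh relative drop flagged regardless of recovery
#'   (default 0.40).
#' @return A list with `flag` (logical) and `frames` (indices of offending
#'   frames, empty when unflagged).
#' @export
detect_motion <- function(tac, late_min = 10, drop_thresh = 0.30,
                          recovery_thresh = 0.15, sustained_thresh = 0.40) {
  stopifnot(inherits(tac, "tac"))
  n <- length(tac$activity)
  if (n < 8L) {
    warning("TAC has fewer than 8 frames; motion detection skipped")
    return(list(flag = FALSE, frames = integer(0)))
  }
  mids <- tac_midpoints_min(tac)
  act <- tac$activity
  offending <- integer(0)
  for (i in which(mids > late_min)) {
    if (i < 2L) next
    prev <- act[i - 1]
    if (prev <= 0) next
    drop <- (prev - act[i]) / prev
    if (drop > sustained_thresh) {
      offending <- c(offending, i)
    } else if (drop > drop_thresh && i < n && act[i] > 0) {
      recovery <- (act[i + 1] - act[i]) / act[i]
      if (recovery > recovery_thresh) offending <- c(offending, i)
    }
  }
  list(flag = length(offending) > 0L, frames = offending)
}
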