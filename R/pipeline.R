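# End-to-end orchestration: simulate (or load) -> input function -> kinetic
# fits -> graphical & static metrics -> QC -> reliability reports.

#' Pipeline run configuration
#'
#' @param generator a [generator_config()]; ignored when `paths` is given.
#' @param paths optional named list of input files (`tac`, `blood`, `meta`)
#'   for [load_study()]; `NULL` enables the synthetic generator.
#' @param models compartment models to fit (subset of
#'   `c("1T2k", "2T3k", "2T4k", "1T2k_WB")`).
#' @param windows list of uptake windows in minutes (default 20-50, 30-60).
#' @param t_star_min Logan/Patlak linear-segment start (minutes).
#' @param reliability_threshold minimum acceptable ICC(2,1) (default 0.76).
#' @param use_idif reconstruct the image-derived input function from samples
#'   plus the blood-pool TAC (`TRUE`, the study procedure) or use the
#'   ground-truth input when available (`FALSE`; synthetic cohorts only).
#' @param estimate_delays grid-search a per-region input delay before
#'   fitting (slower; default `FALSE` as the generator introduces no delay).
#' @param fit_logan,fit_patlak compute the graphical analyses.
#' @param seed seed forwarded to the generator.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(regions = default_region_table()),
                       paths = NULL,
                       models = c("1T2k", "2T3k", "2T4k"),
                       windows = list(c(20, 50), c(30, 60)),
                       t_star_min = 30,
                       reliability_threshold = 0.76,
                       use_idif = TRUE,
                       estimate_delays = FALSE,
                       fit_logan = TRUE,
                       fit_patlak = FALSE,
                       seed = NULL) {
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  span <- schedule_span_min(generator$schedule)
  for (w in windows) {
    if (length(w) != 2L || w[1] >= w[2] || w[1] < 0 || w[2] > span + 1e-9) {
      stop(sprintf("window [%g, %g] outside the scan span [0, %g] min",
                   w[1], w[2], span))
    }
  }
  if (reliability_threshold <= 0 || reliability_threshold > 1) {
    stop("`reliability_threshold` must lie in (0, 1]")
  }
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  structure(list(generator = generator, paths = paths, models = models,
                 windows = windows, t_star_min = t_star_min,
                 reliability_threshold = reliability_threshold,
                 use_idif = use_idif, estimate_delays = estimate_delays,
                 fit_logan = fit_logan, fit_patlak = fit_patlak),
            class = "run_config")
}

#' Load and validate a study from tabular files
#'
#' `paths` names three CSV files: `tac` (TAC table, see [read_tac_csv()];
#' the blood-pool curve carries region label `"aorta"`), `blood`
#' (venous samples, see [read_blood_csv()]) and `meta` (columns `subject`,
#' `session`, `injected_dose_mbq`, `body_weight_kg`). Subjects without blood
#' data are retained and excluded later with reason `missing_input`.
#'
#' @param paths named list or character vector with elements `tac`, `blood`,
#'   `meta`.
#' @return A list of subject-session records shaped like the generator's
#'   output (minus ground truth).
#' @export
load_study <- function(paths) {
  need <- c("tac", "blood", "meta")
  if (!all(need %in% names(paths))) {
    stop("`paths` must name 'tac', 'blood' and 'meta' files")
  }
  for (p in unlist(paths[need])) {
    if (!file.exists(p)) stop(sprintf("input file '%s' does not exist", p))
  }
  tacs <- read_tac_csv(paths[["tac"]])
  bloods <- read_blood_csv(paths[["blood"]])
  meta <- utils::read.csv(paths[["meta"]], stringsAsFactors = FALSE)
  mneed <- c("subject", "session", "injected_dose_mbq", "body_weight_kg")
  miss <- setdiff(mneed, names(meta))
  if (length(miss)) {
    stop(sprintf("meta file '%s' is missing column(s): %s",
                 paths[["meta"]], paste(miss, collapse = ", ")))
  }
  bad <- which(meta$injected_dose_mbq <= 0 | meta$body_weight_kg <= 0)
  if (length(bad)) {
    stop(sprintf("meta file '%s': non-positive dose or weight at row %d",
                 paths[["meta"]], bad[1]))
  }
  subjects <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject[i]; sess <- meta$session[i]
    mine <- Filter(function(x) x$subject == sid && x$session == sess, tacs)
    if (!length(mine)) next
    aorta <- Filter(function(x) x$region == "aorta", mine)
    region_tacs <- Filter(function(x) x$region != "aorta", mine)
    names(region_tacs) <- vapply(region_tacs, `[[`, character(1), "region")
    blood <- bloods[[paste(sid, sess, sep = ".")]]
    subjects[[length(subjects) + 1L]] <- structure(
      list(subject_id = sid, session = sess, true_params = NULL,
           blood = blood,
           image_blood_tac = if (length(aorta)) aorta[[1]] else NULL,
           region_tacs = region_tacs, true_input = NULL,
           injected_dose_mbq = meta$injected_dose_mbq[i],
           body_weight_kg = meta$body_weight_kg[i],
           motion_frames = list()),
      class = "synthetic_subject")
  }
  if (!length(subjects)) stop("no subject in the meta table has TAC data")
  subjects
}

subject_input <- function(subj, use_idif, log) {
  if (is.null(subj$blood) ||
      (use_idif && is.null(subj$image_blood_tac))) {
    return(list(input = NULL, log = c(log, sprintf(
      "%s/%s: missing blood or blood-pool data; excluded (missing_input)",
      subj$subject_id, subj$session))))
  }
  if (!use_idif && !is.null(subj$true_input)) {
    return(list(input = subj$true_input, log = log))
  }
  curves <- fit_blood_curves(subj$blood)
  pf <- fit_parent_fraction(subj$blood)
  input <- build_idif(subj$image_blood_tac, curves$whole_blood,
                      curves$plasma, pf)
  list(input = input, log = c(log, sprintf(
    "%s/%s: IDIF built (scale %.3f)", subj$subject_id, subj$session,
    input$scale)))
}

#' Run the full quantification pipeline
#'
#' Executes simulate/load -> input function -> per-region QC and kinetic,
#' graphical and static metrics -> model-preference tally -> VT-outlier
#' flagging -> target-vs-unaffected and test-retest reports. Deterministic
#' given the generator seed. Stage failures exclude the record with a reason
#' and the run continues.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result` with elements `study_table`
#'   (one row per subject x region x condition x session), `table_regions`
#'   (target-vs-unaffected report), `table_reliability` (test-retest report,
#'   when retest sessions exist), `preference` (AIC tally, when >= 2 models
#'   were fitted), `qc` (exclusion/flag table) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  subjects <- if (!is.null(config$paths)) {
    load_study(config$paths)
  } else {
    generate_cohort(config$generator)
  }
  if (!length(subjects)) stop("empty cohort")
  log <- c(log, sprintf("cohort: %d subject-session records", length(subjects)))

  rows <- list(); qc_rows <- list(); pref_rows <- list()
  for (subj in subjects) {
    si <- subject_input(subj, config$use_idif, log)
    log <- si$log
    if (is.null(si$input)) {
      for (nm in names(subj$region_tacs)) {
        qc_rows[[length(qc_rows) + 1L]] <- data.frame(
          subject = subj$subject_id, session = subj$session, region_key = nm,
          reason = "missing_input")
      }
      next
    }
    input <- si$input
    for (nm in names(subj$region_tacs)) {
      tac <- subj$region_tacs[[nm]]
      parts <- strsplit(nm, "_(?=[^_]+$)", perl = TRUE)[[1]]
      region <- parts[1]
      condition <- if (length(parts) == 2L) parts[2] else "target"
      mot <- detect_motion(tac)
      if (mot$flag) {
        qc_rows[[length(qc_rows) + 1L]] <- data.frame(
          subject = subj$subject_id, session = subj$session, region_key = nm,
          reason = "motion")
        log <- c(log, sprintf("%s/%s/%s: motion artifact at frame(s) %s; excluded",
                              subj$subject_id, subj$session, nm,
                              paste(mot$frames, collapse = ",")))
        next
      }
      delay <- if (config$estimate_delays) {
        estimate_delay(input, tac)
      } else {
        0
      }
      row <- list(subject = subj$subject_id, region = region,
                  condition = condition, session = subj$session,
                  delay_s = delay)
      for (m in config$models) {
        fit <- tryCatch(
          fit_compartment_model(tac, input, m, delay_s = delay),
          error = function(e) NULL)
        if (is.null(fit)) {
          log <- c(log, sprintf("%s/%s/%s: %s fit failed",
                                subj$subject_id, subj$session, nm, m))
          next
        }
        key <- tolower(m)
        row[[paste0("vt_", key)]] <- fit$vt
        row[[paste0("ki_", key)]] <- fit$ki
        row[[paste0("aic_", key)]] <- fit$aic
        pref_rows[[length(pref_rows) + 1L]] <- data.frame(
          region = paste(subj$subject_id, subj$session, nm, sep = "/"),
          model_id = m, aic = fit$aic)
      }
      if (config$fit_logan) {
        row$vt_logan <- tryCatch(
          logan_vt(tac, input, config$t_star_min)$slope,
          error = function(e) NA_real_)
      }
      if (config$fit_patlak) {
        row$ki_patlak <- tryCatch(
          patlak_ki(tac, input, config$t_star_min)$slope,
          error = function(e) NA_real_)
      }
      for (w in config$windows) {
        tag <- sprintf("%d_%d", w[1], w[2])
        row[[paste0("suv_", tag)]] <- compute_suv(
          tac, subj$injected_dose_mbq, subj$body_weight_kg, w)
        row[[paste0("tbr_wb_", tag)]] <- compute_tbr(tac, input, w, "WB")
        row[[paste0("tbr_pp_", tag)]] <- compute_tbr(tac, input, w, "PP")
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  if (!length(rows)) stop("all records were excluded; empty study table")
  study <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else
    data.frame(subject = character(0), session = character(0),
               region_key = character(0), reason = character(0))

  # VT-median outlier rule on the primary model, per region x condition
  primary <- paste0("vt_", tolower(config$models[1]))
  if (primary %in% names(study)) {
    study$vt_outlier <- FALSE
    for (key in unique(paste(study$region, study$condition))) {
      sel <- paste(study$region, study$condition) == key &
        is.finite(study[[primary]])
      if (sum(sel) >= 3L) {
        med <- stats::median(study[[primary]][sel])
        if (med > 0) {
          study$vt_outlier[sel] <- flag_vt_outlier(study[[primary]][sel], med)
        }
      }
    }
    flagged <- which(study$vt_outlier)
    for (i in flagged) {
      qc <- rbind(qc, data.frame(
        subject = study$subject[i], session = study$session[i],
        region_key = paste(study$region[i], study$condition[i], sep = "_"),
        reason = "vt_median_rule"))
    }
  }

  preference <- if (length(config$models) >= 2L && length(pref_rows)) {
    tally_model_preference(do.call(rbind, pref_rows))
  } else {
    NULL
  }
  table_regions <- region_difference_report(study, config)
  table_reliability <- if (any(study$session == "retest")) {
    reliability_report(study, config)
  } else {
    NULL
  }
  structure(list(study_table = study, table_regions = table_regions,
                 table_reliability = table_reliability,
                 preference = preference, qc = qc, log = log),
            class = "pipeline_result")
}

metric_columns <- function(study) {
  cand <- names(study)[grepl("^(vt_|ki_|suv_|tbr_)", names(study))]
  cand <- cand[cand != "vt_outlier"]
  cand[vapply(cand, function(x) is.numeric(study[[x]]), logical(1))]
}

# Target-vs-unaffected paired report (test session), one row per metric and
# region with mean (SD) per condition, paired mean difference (SE) and p.
region_difference_report <- function(study, config) {
  test <- study[study$session == "test", ]
  out <- list()
  for (reg in unique(test$region)) {
    d <- test[test$region == reg, ]
    if (!all(c("target", "unaffected") %in% d$condition)) next
    tg <- d[d$condition == "target", ]
    un <- d[d$condition == "unaffected", ]
    common <- intersect(tg$subject, un$subject)
    if (length(common) < 2L) next
    tg <- tg[match(common, tg$subject), ]
    un <- un[match(common, un$subject), ]
    for (mcol in metric_columns(study)) {
      x <- tg[[mcol]]; y <- un[[mcol]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 2L) next
      pd <- paired_region_difference(x[ok], y[ok])
      out[[length(out) + 1L]] <- data.frame(
        region = reg, metric = mcol, n = pd$n,
        target_mean = mean(x[ok]), target_sd = stats::sd(x[ok]),
        unaffected_mean = mean(y[ok]), unaffected_sd = stats::sd(y[ok]),
        mean_diff = pd$mean_diff, se = pd$se, p = pd$p)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Test-retest reliability report on target regions, one row per metric and
# region: session moments, difference moments, r, ICC (CI), SEM (pooled SD),
# SDD, Bland-Altman limits of agreement.
reliability_report <- function(study, config) {
  tgt <- study[study$condition == "target", ]
  out <- list()
  for (reg in unique(tgt$region)) {
    d <- tgt[tgt$region == reg, ]
    te <- d[d$session == "test", ]
    re <- d[d$session == "retest", ]
    common <- intersect(te$subject, re$subject)
    if (length(common) < 3L) next
    te <- te[match(common, te$subject), ]
    re <- re[match(common, re$subject), ]
    for (mcol in metric_columns(study)) {
      x <- te[[mcol]]; y <- re[[mcol]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L) next
      x <- x[ok]; y <- y[ok]
      icc <- tryCatch(icc_2_1(x, y), error = function(e) NULL)
      if (is.null(icc)) next
      ba <- bland_altman(x, y)
      pooled_sd <- sqrt((stats::var(x) + stats::var(y)) / 2)
      ss <- sem_sdd(pooled_sd, icc$icc)
      r <- tryCatch(correlate(x, y)$r, error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        region = reg, metric = mcol, n = length(x),
        test_mean = mean(x), test_sd = stats::sd(x),
        retest_mean = mean(y), retest_sd = stats::sd(y),
        mean_diff = ba$mean_diff, sd_diff = ba$sd_diff, r = r,
        icc = icc$icc, icc_lower = icc$ci[["lower"]],
        icc_upper = icc$ci[["upper"]],
        sem = ss$sem, sdd = ss$sdd,
        loa_lower = ba$loa[["lower"]], loa_upper = ba$loa[["upper"]],
        category = icc_category(icc$icc),
        reliable = icc$icc >= config$reliability_threshold)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d study rows, %d QC exclusions/flags\n",
              nrow(x$study_table), nrow(x$qc)))
  if (!is.null(x$preference)) {
    cat(sprintf("  reversible models preferred in %.0f%% of regions\n",
                x$preference$percent_reversible))
  }
  invisible(x)
}

#' Write the pipeline reports as CSV files
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_reports <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$study_table, file.path(dir, "study_table.csv"),
                   row.names = FALSE)
  if (!is.null(result$table_regions)) {
    utils::write.csv(result$table_regions,
                     file.path(dir, "region_differences.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$table_reliability)) {
    utils::write.csv(result$table_reliability,
                     file.path(dir, "reliability.csv"), row.names = FALSE)
  }
  utils::write.csv(result$qc, file.path(dir, "qc.csv"), row.names = FALSE)
  writeLines(result$log, file.path(dir, "run.log"))
  invisible(dir)
}
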