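# Per-stride/per-cycle metric assembly and subject x trial summaries — the
# analysis units for the trial statistics (each variable's per-subject mean
# and standard deviation).

#' Compute the full per-unit gait metric table of a recording
#'
#' Runs stride detection, integrated pressure and cyclogram analysis on a
#' footfall recording (after pass normalization) and stacks the results in
#' one tidy table, one row per measurement unit (stride, footfall or gait
#' cycle) per metric.
#'
#' @param footfalls footfall-level sample table (footfall CSV dialect).
#' @return tidy data.frame: subject_id, group, trial, unit_id, metric,
#'   value, flag.
#' @examples
#' sub <- draw_subjects(2, seed = 1)[1, ]
#' tr <- simulate_trial(sub, "GaitBaseline", duration_s = 30, seed = 2)
#' m <- gait_metrics(tr$footfalls)
#' table(m$metric)
#' @export
gait_metrics <- function(footfalls) {
  footfalls <- normalize_passes(footfalls)
  grp <- unique(footfalls[, c("subject_id", "group")])
  strides <- detect_strides(footfalls)
  press <- footfall_pressures(footfalls)
  cycles <- cycle_metrics(footfalls)

  long <- function(df, metric, value, unit, flag = NULL) {
    if (nrow(df) == 0L) return(NULL)
    data.frame(subject_id = df$subject_id, trial = df$trial,
               unit_id = unit, metric = metric, value = value,
               flag = if (is.null(flag)) "ok" else flag,
               stringsAsFactors = FALSE)
  }
  su <- function(df) paste(df$pass_id, df$lead_footfall_id, sep = ".")
  pieces <- list(
    long(strides, "stride_length", strides$stride_length, su(strides)),
    long(strides, "stride_velocity", strides$stride_velocity, su(strides)),
    long(strides, "single_support_time", strides$single_support_time,
         su(strides), strides$flag),
    long(press, "integrated_pressure", press$integrated_pressure,
         paste(press$pass_id, press$footfall_id, sep = ".")),
    long(cycles, "cisp_ap_pct", cycles$cisp_ap_pct,
         paste(cycles$pass_id, cycles$cycle_index, cycles$foot, sep = "."),
         cycles$flag),
    long(cycles, "cisp_ml_pct", cycles$cisp_ml_pct,
         paste(cycles$pass_id, cycles$cycle_index, cycles$foot, sep = "."),
         cycles$flag)
  )
  if (nrow(cycles)) {
    effs <- rbind(
      data.frame(subject_id = cycles$subject_id, trial = cycles$trial,
                 unit_id = paste(cycles$pass_id, cycles$cycle_index, "L",
                                 sep = "."),
                 metric = "ss_cop_efficiency",
                 value = cycles$ss_cop_efficiency_L,
                 flag = ifelse(is.na(cycles$ss_cop_efficiency_L),
                               "missing", "ok"),
                 stringsAsFactors = FALSE),
      data.frame(subject_id = cycles$subject_id, trial = cycles$trial,
                 unit_id = paste(cycles$pass_id, cycles$cycle_index, "R",
                                 sep = "."),
                 metric = "ss_cop_efficiency",
                 value = cycles$ss_cop_efficiency_R,
                 flag = ifelse(is.na(cycles$ss_cop_efficiency_R),
                               "missing", "ok"),
                 stringsAsFactors = FALSE)
    )
    pieces <- c(pieces, list(effs))
  }
  res <- do.call(rbind, pieces)
  res$flag[is.na(res$value)] <- ifelse(res$flag[is.na(res$value)] == "ok",
                                       "missing", res$flag[is.na(res$value)])
  res <- merge(res, grp, by = "subject_id", sort = FALSE)
  res[, c("subject_id", "group", "trial", "unit_id", "metric", "value",
          "flag")]
}

#' Summarize per-unit metrics to subject x trial means and SDs
#'
#' Sample mean and sample (n-1) standard deviation per (subject, trial,
#' metric) cell, the analysis units of the trial statistics. Units with a
#' non-\code{"ok"} flag or missing values are excluded; exclusion counts
#' are reported. Cells with fewer than \code{min_units} valid units are
#' flagged \code{"low_n"}; empty cells are absent (with a warning).
#'
#' @param metrics tidy metric table from \code{\link{gait_metrics}} (or a
#'   data.frame with subject_id, group, trial, metric, value and optional
#'   flag).
#' @param min_units minimum valid units for an unflagged cell. Default 10.
#' @return data.frame: subject_id, group, trial, metric, mean, sd,
#'   n_units, n_excluded, flag.
#' @export
summarize_trials <- function(metrics, min_units = 10L) {
  if (is.null(metrics$flag)) metrics$flag <- "ok"
  key <- interaction(metrics$subject_id, metrics$trial, metrics$metric,
                     drop = TRUE)
  idx <- split(seq_len(nrow(metrics)), key)
  rows <- lapply(idx, function(ii) {
    v <- metrics$value[ii]
    ok <- metrics$flag[ii] == "ok" & !is.na(v)
    v <- v[ok]
    if (!length(v)) return(NULL)
    data.frame(
      subject_id = metrics$subject_id[ii[1]],
      group = metrics$group[ii[1]],
      trial = metrics$trial[ii[1]],
      metric = metrics$metric[ii[1]],
      mean = mean(v),
      sd = if (length(v) >= 2L) sd(v) else NA_real_,
      n_units = length(v),
      n_excluded = sum(!ok),
      flag = if (length(v) < min_units) "low_n" else "ok",
      stringsAsFactors = FALSE
    )
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0L) {
    warning(dropped, " empty (subject, trial, metric) cells omitted",
            call. = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
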