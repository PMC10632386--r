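# Full statistical battery over a cohort's summaries: the two mixed-ANOVA
# trial pairs per gait metric (mean and per-subject SD), the EG-vs-CG
# training comparison, and the clinical Day1/Day2 ANOVAs.

#' Run the complete trial statistics over summary tables
#'
#' Applies the decision procedure across the board, as in the trial
#' report: for every gait metric and for both the per-subject mean and the
#' per-subject SD ("variability"), a mixed ANOVA on the Gait pair
#' (GaitBaseline vs GaitPost) and on the Test pair (TestPre vs TestPost),
#' plus the independent t / Mann-Whitney U comparison of the Training
#' trial between groups; and, when clinical scores are supplied, a mixed
#' ANOVA per instrument on Day 1 vs Day 2.
#'
#' @param summaries subject-by-trial summary table from
#'   \code{\link{summarize_trials}} (or summary-fidelity
#'   \code{\link{simulate_cohort}} output).
#' @param clinical optional tidy clinical score table (subject_id, group,
#'   session, instrument, score).
#' @param alpha significance level.
#' @return object of class \code{pbt_stats}: data.frame with columns
#'   comparison, metric, statistic (mean/sd/score), effect,
#'   statistic_kind, statistic_value, df1, df2, p, stars, transform.
#' @export
trial_statistics <- function(summaries, clinical = NULL, alpha = 0.05) {
  rows <- vector("list", 0)
  add <- function(comparison, metric, statistic, effect, kind, value,
                  df1, df2, p, transform) {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, metric = metric, statistic = statistic,
      effect = effect, statistic_kind = kind, statistic_value = value,
      df1 = df1, df2 = df2, p = p, stars = significance_stars(p),
      transform = transform, stringsAsFactors = FALSE
    )
  }
  pairs <- list(Gait = c("GaitBaseline", "GaitPost"),
                Test = c("TestPre", "TestPost"))
  for (met in intersect(gait_metrics_names(), unique(summaries$metric))) {
    sm <- summaries[summaries$metric == met, , drop = FALSE]
    for (stat in c("mean", "sd")) {
      if (is.null(sm[[stat]])) next
      for (cmp in names(pairs)) {
        d <- sm[sm$trial %in% pairs[[cmp]], , drop = FALSE]
        if (length(unique(d$trial)) < 2L) next
        fit <- tryCatch(
          mixed_anova(d, value = stat, condition = "trial", alpha = alpha),
          error = function(e) NULL
        )
        if (is.null(fit)) next
        for (i in seq_len(nrow(fit$table))) {
          add(cmp, met, stat, fit$table$effect[i], "F",
              fit$table$statistic[i], fit$table$df1[i], fit$table$df2[i],
              fit$table$p[i], fit$transform)
        }
      }
      tr <- sm[sm$trial == "Training", , drop = FALSE]
      if (nrow(tr) >= 4L && length(unique(tr$group)) == 2L) {
        ht <- tryCatch(
          compare_training(tr[[stat]][tr$group == "EG"],
                           tr[[stat]][tr$group == "CG"], alpha = alpha),
          error = function(e) NULL
        )
        if (!is.null(ht)) {
          add("Training", met, stat, "two_sample", ht$statistic_kind,
              unname(ht$statistic),
              if (!is.null(ht$parameter)) unname(ht$parameter) else NA_real_,
              NA_real_, ht$p.value, "none")
        }
      }
    }
  }
  if (!is.null(clinical)) {
    for (ins in unique(clinical$instrument)) {
      d <- clinical[clinical$instrument == ins, , drop = FALSE]
      fit <- tryCatch(
        mixed_anova(d, value = "score", condition = "session",
                    alpha = alpha),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      for (i in seq_len(nrow(fit$table))) {
        add("Day", ins, "score", fit$table$effect[i], "F",
            fit$table$statistic[i], fit$table$df1[i], fit$table$df2[i],
            fit$table$p[i], fit$transform)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("pbt_stats", "data.frame")
  res
}

#' @export
print.pbt_stats <- function(x, ...) {
  df <- as.data.frame(x)
  df$statistic_value <- signif(df$statistic_value, 4)
  df$p <- signif(df$p, 3)
  cat("Trial statistics (", nrow(df), " tests)\n", sep = "")
  sig <- df[df$p < 0.05 & !is.na(df$p), , drop = FALSE]
  print(df, row.names = FALSE)
  if (nrow(sig)) {
    cat("\nSignificant at 0.05: ",
        paste(unique(paste(sig$comparison, sig$metric, sig$effect,
                           sep = "/")), collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}
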