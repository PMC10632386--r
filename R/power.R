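# Monte-Carlo calibration and power for the interaction test of the
# decision procedure, run over summary-fidelity null or effect cohorts.

#' Monte-Carlo rejection rate of the mixed-ANOVA interaction test
#'
#' Simulates replicate two-group cohorts at the summary fidelity (the
#' per-subject trial-mean model of \code{\link{simulate_cohort}}), runs
#' the full decision procedure (assumption checks, log-transform rule,
#' mixed ANOVA) on the chosen metric for a pair of conditions, and reports
#' how often the group-by-condition interaction is declared significant.
#' With \code{d = 0} this estimates the procedure's type-I error; with an
#' injected interaction effect it estimates power.
#'
#' @param n_rep number of replicate cohorts.
#' @param n_per_group subjects per group. Default 20.
#' @param d standardized interaction effect size injected on
#'   \code{metric} (Cohen's d on the subject-summary scale); 0 for a null
#'   cohort.
#' @param metric gait metric targeted. Default \code{"ss_cop_efficiency"}.
#' @param trials condition pair. Default \code{c("TestPre", "TestPost")}.
#' @param seed master seed; each replicate uses its own substream.
#' @param alpha significance level. Default 0.05.
#' @return list: \code{rate} (rejection proportion), \code{rejections},
#'   \code{n_rep}, \code{alpha}, \code{d}.
#' @examples
#' mc_interaction_rate(20, n_per_group = 10, d = 0, seed = 1)$rate
#' @export
mc_interaction_rate <- function(n_rep, n_per_group = 20L, d = 0,
                                metric = "ss_cop_efficiency",
                                trials = c("TestPre", "TestPost"),
                                seed = 1L, alpha = 0.05) {
  stopifnot(metric %in% gait_metrics_names(), length(trials) == 2L)
  mm <- .metric_model()
  row <- mm[mm$metric == metric, ]
  s_tot <- sqrt(row$sd_between^2 + row$sd_within^2)
  n <- 2L * n_per_group
  grp <- rep(c("EG", "CG"), each = n_per_group)
  rej <- 0L
  for (r in seq_len(n_rep)) {
    set.seed(substream_seed(seed, r))
    b <- rnorm(n, 0, row$sd_between)
    y1 <- row$mean + b + rnorm(n, 0, row$sd_within)
    y2 <- row$mean + b + rnorm(n, 0, row$sd_within) +
      ifelse(grp == "EG", d * s_tot, 0)
    dat <- data.frame(
      subject_id = rep(seq_len(n), 2),
      group = rep(grp, 2),
      trial = rep(trials, each = n),
      mean = c(y1, y2),
      stringsAsFactors = FALSE
    )
    fit <- mixed_anova(dat, value = "mean", condition = "trial",
                       alpha = alpha)
    p_int <- fit$table$p[fit$table$effect == "interaction"]
    if (!is.na(p_int) && p_int < alpha) rej <- rej + 1L
  }
  list(rate = rej / n_rep, rejections = rej, n_rep = n_rep,
       alpha = alpha, d = d)
}
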