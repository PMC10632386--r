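# Cohort-level simulation: injectable effects, recordings or summary-level
# fidelity, clinical score tables, ground-truth log.

# Summary-level generating model per gait metric: cohort mean, between- and
# within-subject SDs of the per-subject trial mean, and the typical
# stride-to-stride SD within a trial (the "variability" analysed per
# person).
.metric_model <- function() {
  read.table(header = TRUE, text = "
metric               mean  sd_between sd_within sd_unit
stride_length        110    10        5         5
stride_velocity      110    12        5         6
single_support_time  0.78   0.07      0.03      0.04
integrated_pressure  320    60        20        25
cisp_ap_pct          50     5         3         6
cisp_ml_pct          0      3         2         5
ss_cop_efficiency    98.9   0.65      0.45      1.0
", stringsAsFactors = FALSE)
}

#' Specify an injectable group/session effect
#'
#' Describes a shift of a metric's generating parameters used to plant a
#' known signal in synthetic cohorts, expressed as a standardized effect
#' size (Cohen's d on the per-subject summary scale, i.e. in units of the
#' total between + within SD of subject-trial means).
#'
#' @param metric one of the seven gait metrics
#'   (\code{\link{gait_metrics_names}}) or a clinical instrument name
#'   (\code{\link{clinical_instruments}}).
#' @param type \code{"interaction"} (EG shifted at the second condition
#'   only), \code{"group_main"} (EG shifted at both conditions) or
#'   \code{"session_main"} (everyone shifted at the second condition).
#' @param d standardized effect size (finite; sign gives direction).
#' @param applies_to character pair of condition labels the effect spans,
#'   e.g. \code{c("TestPre", "TestPost")} or \code{c("Day1", "Day2")}.
#' @return object of class \code{pbt_effect}.
#' @export
effect_spec <- function(metric,
                        type = c("interaction", "group_main", "session_main"),
                        d,
                        applies_to = c("TestPre", "TestPost")) {
  type <- match.arg(type)
  valid <- c(gait_metrics_names(), clinical_instruments()$instrument)
  if (!metric %in% valid) {
    stop("unknown metric/instrument: ", metric, call. = FALSE)
  }
  if (!is.finite(d)) stop("effect size d must be finite", call. = FALSE)
  if (length(applies_to) != 2L) {
    stop("applies_to must name a pair of conditions", call. = FALSE)
  }
  structure(list(metric = metric, type = type, d = d,
                 applies_to = as.character(applies_to)),
            class = "pbt_effect")
}

.validate_effects <- function(effects) {
  if (inherits(effects, "pbt_effect")) effects <- list(effects)
  if (length(effects) == 0L) return(list())
  if (!all(vapply(effects, inherits, TRUE, "pbt_effect"))) {
    stop("effects must be a list of effect_spec() objects", call. = FALSE)
  }
  key <- vapply(effects, function(e) paste(e$metric, e$type), "")
  if (anyDuplicated(key)) {
    stop("contradictory effects: more than one spec targets ",
         key[duplicated(key)][1], call. = FALSE)
  }
  effects
}

# shift (same units as the metric) a spec applies to one cell
.effect_shift <- function(e, group, condition_index, sd_total) {
  on2 <- condition_index == 2L
  hit <- switch(e$type,
    interaction = group == "EG" && on2,
    group_main = group == "EG",
    session_main = on2
  )
  if (hit) e$d * sd_total else 0
}

#' Simulate a full two-group five-trial cohort
#'
#' Generates a balanced EG/CG cohort walking the five-trial perturbation
#' protocol, at one of two fidelities. \code{"recordings"} produces
#' footfall-level COP recordings for every subject and trial (plus
#' perturbation schedules) through \code{\link{simulate_trial}};
#' \code{"summary"} draws the per-subject, per-trial metric summaries
#' directly from the same cohort-level model (between-subject +
#' within-subject normal components), which is the fidelity used for
#' large Monte-Carlo calibration and power studies. Both fidelities share
#' the ground-truth log needed to verify injected effects.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param protocol a \code{\link{pbt_protocol}}.
#' @param effects list of \code{\link{effect_spec}} objects (or empty).
#' @param seed integer master seed; expanded into per-subject, per-trial
#'   substreams.
#' @param fidelity \code{"recordings"} or \code{"summary"}.
#' @param duration_s optional duration override (seconds) applied to every
#'   trial, used to scale simulations down; \code{NULL} uses protocol
#'   durations.
#' @param trials subset of trial labels to simulate (default all five).
#' @return object of class \code{pbt_cohort}: list with \code{subjects},
#'   \code{footfalls} (recordings fidelity), \code{summaries} (summary
#'   fidelity), \code{clinical}, \code{schedules}, \code{truth} (data.frame
#'   ground-truth log), and the call metadata.
#' @examples
#' coh <- simulate_cohort(3, seed = 1, fidelity = "summary")
#' table(coh$subjects$group)
#' @export
simulate_cohort <- function(n_per_group,
                            protocol = pbt_protocol(),
                            effects = list(),
                            seed = 1L,
                            fidelity = c("recordings", "summary"),
                            duration_s = NULL,
                            trials = trial_labels()) {
  fidelity <- match.arg(fidelity)
  effects <- .validate_effects(effects)
  trials <- match.arg(trials, trial_labels(), several.ok = TRUE)
  subjects <- draw_subjects(n_per_group, seed = seed)
  gait_eff <- Filter(function(e) e$metric %in% gait_metrics_names(), effects)
  clin_eff <- Filter(function(e) !e$metric %in% gait_metrics_names(), effects)

  if (fidelity == "summary") {
    summaries <- .simulate_summary(subjects, trials, gait_eff, seed)
    footfalls <- NULL
    schedules <- NULL
    truth <- attr(summaries, "truth")
  } else {
    out <- .simulate_recordings(subjects, trials, gait_eff, protocol,
                                duration_s, seed)
    footfalls <- out$footfalls
    schedules <- out$schedules
    truth <- out$truth
    summaries <- NULL
  }
  clinical <- generate_clinical_scores(subjects, clin_eff,
                                       seed = substream_seed(seed, 999983L))
  structure(
    list(subjects = subjects, footfalls = footfalls, summaries = summaries,
         clinical = clinical, schedules = schedules, truth = truth,
         effects = effects, protocol = protocol, seed = seed,
         fidelity = fidelity, trials = trials),
    class = "pbt_cohort"
  )
}

#' @export
print.pbt_cohort <- function(x, ...) {
  cat(sprintf("PBT cohort: %d subjects (%d EG / %d CG), %s fidelity\n",
              nrow(x$subjects), sum(x$subjects$group == "EG"),
              sum(x$subjects$group == "CG"), x$fidelity))
  cat("  trials:", paste(x$trials, collapse = ", "), "\n")
  if (length(x$effects)) {
    for (e in x$effects) {
      cat(sprintf("  injected %s effect d = %g on %s (%s -> %s)\n",
                  e$type, e$d, e$metric, e$applies_to[1], e$applies_to[2]))
    }
  }
  invisible(x)
}

# summary-level fidelity: subject-trial metric means and SDs drawn from the
# cohort model, with effect shifts applied to the generating means
.simulate_summary <- function(subjects, trials, effects, seed) {
  set.seed(substream_seed(seed, 1L))
  mm <- .metric_model()
  n <- nrow(subjects)
  rows <- vector("list", nrow(mm))
  truth_rows <- vector("list", 0)
  for (m in seq_len(nrow(mm))) {
    mu <- mm$mean[m]; sb <- mm$sd_between[m]; sw <- mm$sd_within[m]
    s_tot <- sqrt(sb^2 + sw^2)
    b <- rnorm(n, 0, sb)
    eff_m <- Filter(function(e) e$metric == mm$metric[m], effects)
    per_trial <- lapply(seq_along(trials), function(ti) {
      lab <- trials[ti]
      shift <- vapply(seq_len(n), function(i) {
        s <- 0
        for (e in eff_m) {
          ci <- match(lab, e$applies_to)
          if (!is.na(ci)) {
            s <- s + .effect_shift(e, subjects$group[i], ci, s_tot)
          }
        }
        s
      }, 0)
      means <- mu + b + shift + rnorm(n, 0, sw)
      sds <- mm$sd_unit[m] * sqrt(rchisq(n, df = 30) / 30)
      data.frame(subject_id = subjects$subject_id, group = subjects$group,
                 trial = lab, metric = mm$metric[m],
                 mean = means, sd = sds, n_units = 100L,
                 truth_mean = mu + b + shift,
                 stringsAsFactors = FALSE)
    })
    rows[[m]] <- do.call(rbind, per_trial)
  }
  out <- do.call(rbind, rows)
  truth <- out[, c("subject_id", "group", "trial", "metric", "truth_mean")]
  out$truth_mean <- NULL
  attr(out, "truth") <- truth
  out
}

# recordings fidelity: full COP simulation per subject x trial, applying
# effect shifts to the generating subject parameters that control each
# metric
.simulate_recordings <- function(subjects, trials, effects, protocol,
                                 duration_s, seed) {
  param_for <- c(stride_length = "mean_stride_length",
                 stride_velocity = "mean_stride_velocity",
                 single_support_time = "single_support_mean",
                 ss_cop_efficiency = "cop_waviness")
  bad <- setdiff(vapply(effects, `[[`, "", "metric"), names(param_for))
  if (length(bad)) {
    stop("recordings fidelity has no generating parameter for: ",
         paste(bad, collapse = ", "), "; use fidelity = \"summary\"",
         call. = FALSE)
  }
  mm <- .metric_model()
  ff_l <- vector("list", 0)
  truth_l <- vector("list", 0)
  schedules <- list()
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects[i, ]
    for (ti in seq_along(trials)) {
      lab <- trials[ti]
      sub_i <- sub
      for (e in effects) {
        ci <- match(lab, e$applies_to)
        if (is.na(ci)) next
        s_tot <- sqrt(sum(unlist(
          mm[mm$metric == e$metric, c("sd_between", "sd_within")]
        )^2))
        shift <- .effect_shift(e, sub$group, ci, s_tot)
        if (shift == 0) next
        p <- param_for[[e$metric]]
        if (e$metric == "ss_cop_efficiency") {
          # efficiency falls as waviness grows: map a d-unit efficiency
          # shift onto a multiplicative waviness change (sign flipped)
          sub_i[[p]] <- max(0, sub_i[[p]] * (1 - shift / 1.3))
        } else {
          sub_i[[p]] <- sub_i[[p]] + shift
        }
      }
      sseed <- substream_seed(seed, i, ti)
      dur <- if (is.null(duration_s)) {
        60 * unname(protocol$trial_durations_min[lab])
      } else {
        duration_s
      }
      sch <- perturbation_schedule(dur, protocol, lab, sub$group,
                                   sub$body_weight, seed = sseed)
      tr <- simulate_trial(sub_i, lab, schedule = sch, protocol = protocol,
                           duration_s = dur, seed = sseed + 1L)
      ff_l[[length(ff_l) + 1L]] <- tr$footfalls
      schedules[[paste(sub$subject_id, lab, sep = ":")]] <- sch
      truth_l[[length(truth_l) + 1L]] <- as.data.frame(
        tr$truth[c("subject_id", "group", "trial", "stride_length",
                   "stride_velocity", "single_support_time",
                   "integrated_pressure", "cop_waviness", "n_footfalls",
                   "n_pulses")],
        stringsAsFactors = FALSE
      )
    }
  }
  list(footfalls = do.call(rbind, ff_l),
       truth = do.call(rbind, truth_l),
       schedules = schedules)
}

#' Generate clinical score tables for a cohort
#'
#' Draws Day 1 / Day 2 scores for the balance, falls-confidence and
#' cognitive instruments in \code{\link{clinical_instruments}}. Scores are
#' a subject random effect plus session noise (and any injected effects),
#' clamped to each instrument's closed range after effect injection.
#'
#' @param subjects subject table from \code{\link{draw_subjects}}.
#' @param effects list of \code{\link{effect_spec}} targeting instruments;
#'   \code{applies_to} should be \code{c("Day1", "Day2")}.
#' @param seed integer seed.
#' @param noise_scale multiplier on all random components (0 gives the
#'   degenerate zero-variance generator: identical Day 1 and Day 2 scores).
#' @return tidy data.frame: subject_id, group, session, instrument, score.
#' @export
generate_clinical_scores <- function(subjects, effects = list(), seed = 1L,
                                     noise_scale = 1) {
  effects <- .validate_effects(effects)
  bad <- Filter(function(e) !e$metric %in% clinical_instruments()$instrument,
                effects)
  if (length(bad)) {
    stop("unknown instrument: ", bad[[1]]$metric, call. = FALSE)
  }
  set.seed(as.integer(seed))
  inst <- clinical_instruments()
  n <- nrow(subjects)
  sessions <- c("Day1", "Day2")
  out <- vector("list", nrow(inst))
  for (m in seq_len(nrow(inst))) {
    b <- noise_scale * rnorm(n, 0, inst$sd[m] * sqrt(0.7))
    eff_m <- Filter(function(e) e$metric == inst$instrument[m], effects)
    per_sess <- lapply(seq_along(sessions), function(si) {
      shift <- vapply(seq_len(n), function(i) {
        s <- 0
        for (e in eff_m) {
          ci <- match(sessions[si], e$applies_to)
          if (!is.na(ci)) s <- s + .effect_shift(e, subjects$group[i], ci,
                                                 inst$sd[m])
        }
        s
      }, 0)
      raw <- inst$mean[m] + b + shift +
        noise_scale * rnorm(n, 0, inst$sd[m] * sqrt(0.3))
      data.frame(subject_id = subjects$subject_id, group = subjects$group,
                 session = sessions[si], instrument = inst$instrument[m],
                 score = pmin(pmax(raw, inst$min[m]), inst$max[m]),
                 stringsAsFactors = FALSE)
    })
    out[[m]] <- do.call(rbind, per_sess)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
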