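#' Five-trial perturbation protocol configuration
#'
#' Builds the configuration object describing the overground
#' perturbation-based balance training (PBT) protocol: five walking trials
#' (Gait Baseline, Test Pre, Training, Test Post, Gait Post), square-pulse
#' pelvic perturbations of ~10% body weight and 100 ms width, and the
#' random inter-pulse spacing used to prevent anticipation.
#'
#' @param trial_durations_min named numeric vector of walking durations in
#'   minutes, one per trial label. Defaults to 5 min for every trial except
#'   Training (10 min), the protocol used in the study design this package
#'   emulates.
#' @param force_fraction_bw pulse magnitude as a fraction of body weight
#'   (dimensionless, in (0, 1)). Default 0.10.
#' @param pulse_width_s square-pulse width in seconds. Default 0.100.
#' @param min_gap_s,max_gap_s bounds of the uniform distribution for random
#'   inter-pulse onset gaps, seconds. Defaults 3 and 8.
#' @param sampling_hz COP sampling rate of the simulated walkway, Hz.
#' @param walkway_length_cm usable walkway length per pass, cm.
#' @param alpha significance level used downstream. Default 0.05.
#'
#' @return An object of class \code{pbt_protocol}: a validated list with the
#'   above fields plus \code{trial_labels}.
#' @examples
#' p <- pbt_protocol()
#' p$trial_labels
#' @export
pbt_protocol <- function(trial_durations_min = c(
                           GaitBaseline = 5, TestPre = 5, Training = 10,
                           TestPost = 5, GaitPost = 5
                         ),
                         force_fraction_bw = 0.10,
                         pulse_width_s = 0.100,
                         min_gap_s = 3,
                         max_gap_s = 8,
                         sampling_hz = 50,
                         walkway_length_cm = 500,
                         alpha = 0.05) {
  labs <- trial_labels()
  if (!setequal(names(trial_durations_min), labs) ||
      length(trial_durations_min) != 5L) {
    stop("trial_durations_min must name exactly the 5 trials: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  trial_durations_min <- trial_durations_min[labs]
  if (any(trial_durations_min <= 0)) {
    stop("trial durations must be positive", call. = FALSE)
  }
  if (trial_durations_min["Training"] <= max(trial_durations_min[labs != "Training"])) {
    stop("Training must be the longest trial", call. = FALSE)
  }
  if (!(force_fraction_bw > 0 && force_fraction_bw < 1)) {
    stop("force_fraction_bw must lie in (0, 1)", call. = FALSE)
  }
  if (pulse_width_s <= 0) stop("pulse_width_s must be positive", call. = FALSE)
  if (!(min_gap_s < max_gap_s)) {
    stop("min_gap_s must be strictly less than max_gap_s", call. = FALSE)
  }
  if (min_gap_s < pulse_width_s) {
    stop("min_gap_s must be at least the pulse width (pulses must not overlap)",
         call. = FALSE)
  }
  if (sampling_hz <= 0 || walkway_length_cm <= 0) {
    stop("sampling_hz and walkway_length_cm must be positive", call. = FALSE)
  }
  structure(
    list(
      trial_labels = labs,
      trial_durations_min = trial_durations_min,
      force_fraction_bw = force_fraction_bw,
      pulse_width_s = pulse_width_s,
      min_gap_s = min_gap_s,
      max_gap_s = max_gap_s,
      sampling_hz = sampling_hz,
      walkway_length_cm = walkway_length_cm,
      alpha = alpha
    ),
    class = "pbt_protocol"
  )
}

#' @export
print.pbt_protocol <- function(x, ...) {
  cat("PBT five-trial protocol\n")
  cat("  trials (min):",
      paste(sprintf("%s=%g", x$trial_labels, x$trial_durations_min),
            collapse = ", "), "\n")
  cat(sprintf("  pulses: %.0f ms square wave, %.0f%% BW, gaps U[%g, %g] s\n",
              1000 * x$pulse_width_s, 100 * x$force_fraction_bw,
              x$min_gap_s, x$max_gap_s))
  cat(sprintf("  walkway: %g cm, COP sampled at %g Hz\n",
              x$walkway_length_cm, x$sampling_hz))
  invisible(x)
}

#' Ordered trial labels of the five-trial protocol
#' @return character vector of the 5 trial labels in protocol order.
#' @export
trial_labels <- function() {
  c("GaitBaseline", "TestPre", "Training", "TestPost", "GaitPost")
}

#' Gait metric names produced by the pipeline
#' @return character vector of the seven per-trial gait metrics.
#' @export
gait_metrics_names <- function() {
  c("stride_length", "stride_velocity", "single_support_time",
    "integrated_pressure", "cisp_ap_pct", "cisp_ml_pct",
    "ss_cop_efficiency")
}

# standard gravity, m/s^2, for %BW -> Newton conversion
GRAVITY <- 9.81

#' Clinical instrument registry
#'
#' Score ranges (and cohort-typical means/SDs used by the synthetic
#' generator) for the balance, falls-confidence and cognitive instruments
#' administered on Day 1 and Day 2. Ranges are the instruments' published
#' scales: BBS 0-56, SPPB 0-12, FES-I 16-64, 4-Stage Balance stances 0-10 s,
#' MOCA 0-30; timed cognitive tests are bounded below by 0.
#'
#' @return data.frame with columns \code{instrument}, \code{min},
#'   \code{max}, \code{mean}, \code{sd} (generator defaults on the
#'   instrument scale) and \code{higher_better}.
#' @export
clinical_instruments <- function() {
  df <- read.table(header = TRUE, text = "
instrument           min  max  mean  sd   higher_better
BBS                  0    56   48    3    TRUE
SPPB                 0    12   11.9  0.4  TRUE
FES_I                16   64   38    9    FALSE
FourStage_SideBySide 0    10   10    0.2  TRUE
FourStage_SemiTandem 0    10   9.8   0.5  TRUE
FourStage_Tandem     0    10   8.7   1.9  TRUE
FourStage_OneFoot    0    10   5.0   2.8  TRUE
MOCA                 0    30   28    1.5  TRUE
SDMT_60              0    110  28    9    TRUE
SDMT_90              0    110  44    11   TRUE
SDMT_C               0    600  192   48   FALSE
TMT_A                0    300  43    21   FALSE
TMT_B                0    400  98    43   FALSE
", stringsAsFactors = FALSE)
  df
}
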