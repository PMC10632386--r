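# Cohort parameter draws and perturbation schedules for the synthetic
# five-trial protocol.

# Deterministic 32-bit substream seed so per-subject / per-trial pieces are
# reproducible from one global seed.
substream_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) + 7919 * i + 104729 * j) %% 2147483647)
}

#' Draw synthetic subject parameters for a two-group cohort
#'
#' Subjects are randomized 1:1 to an experimental group (EG, perturbation
#' training) and a control group (CG). Anthropometrics and gait parameters
#' are drawn from distributions typical of community-dwelling older adults
#' (body weight 72 +/- 17 kg; stride length ~110 cm; stride velocity
#' ~110 cm/s).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param seed integer seed.
#' @return data.frame of per-subject generating parameters, one row per
#'   subject: \code{subject_id}, \code{group}, \code{body_weight} (kg),
#'   \code{mean_stride_length} / \code{stride_length_sd} (cm),
#'   \code{mean_stride_velocity} (cm/s), \code{single_support_mean} (s),
#'   \code{step_width} (cm), \code{cop_waviness} (cm, lateral meander
#'   amplitude of single-stance COP), \code{perturbation_susceptibility}
#'   (cm/N, lateral COP deflection per Newton of pulse force).
#' @export
draw_subjects <- function(n_per_group, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  set.seed(substream_seed(seed, 0L))
  n <- 2L * n_per_group
  clamp <- function(x, lo, hi = Inf) pmin(pmax(x, lo), hi)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("EG", "CG"), each = n_per_group),
    body_weight = clamp(rnorm(n, 72, 17), 45, 140),
    mean_stride_length = clamp(rnorm(n, 110, 10), 70),
    stride_length_sd = clamp(rnorm(n, 5, 1), 1),
    mean_stride_velocity = clamp(rnorm(n, 110, 12), 60),
    single_support_mean = clamp(rnorm(n, 0.78, 0.06), 0.5, 1.0),
    step_width = clamp(rnorm(n, 10, 2), 4),
    cop_waviness = clamp(rnorm(n, 0.15, 0.05), 0.02),
    perturbation_susceptibility = clamp(rnorm(n, 0.02, 0.005), 0.002),
    stringsAsFactors = FALSE
  )
}

perturbation_directions <- function() {
  c("left", "right", "left-up", "left-down", "right-up", "right-down")
}

#' Generate a random perturbation schedule for one trial
#'
#' Square force pulses (width \code{protocol$pulse_width_s}, magnitude
#' \code{force_fraction_bw} x body weight x g) at random inter-onset gaps
#' drawn uniformly in \code{[min_gap_s, max_gap_s]} so the timing cannot be
#' anticipated. Between pulses the commanded force is exactly 0 N. Trial
#' semantics follow the protocol: the two Test trials deliver lateral
#' (left/right) pulses to both groups; Training delivers diagonal
#' (lateral + vertical) pulses to the EG only and none to the CG; the two
#' Gait trials are unperturbed.
#'
#' @param duration_s trial duration, seconds (> 0).
#' @param protocol a \code{\link{pbt_protocol}}.
#' @param trial_label one of \code{\link{trial_labels}()}.
#' @param group \code{"EG"} or \code{"CG"}.
#' @param body_weight subject body weight, kg.
#' @param seed optional integer seed; \code{NULL} uses the current RNG
#'   state.
#' @return data.frame with columns \code{onset_time} (s), \code{width} (s),
#'   \code{magnitude} (N), \code{direction}; zero rows for unperturbed
#'   trials.
#' @examples
#' p <- pbt_protocol()
#' sch <- perturbation_schedule(300, p, "TestPre", "EG", 70, seed = 1)
#' all(sch$width == 0.1)
#' @export
perturbation_schedule <- function(duration_s, protocol, trial_label, group,
                                  body_weight, seed = NULL) {
  stopifnot(inherits(protocol, "pbt_protocol"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  trial_label <- match.arg(trial_label, trial_labels())
  group <- match.arg(group, c("EG", "CG"))
  if (body_weight <= 0) stop("body_weight must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  empty <- data.frame(onset_time = numeric(0), width = numeric(0),
                      magnitude = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  dirs <- switch(trial_label,
    TestPre = ,
    TestPost = c("left", "right"),
    Training = if (group == "EG") {
      c("left-up", "left-down", "right-up", "right-down")
    } else {
      NULL # CG trains with cables attached but no pulses
    },
    NULL # Gait trials are unperturbed
  )
  if (is.null(dirs)) return(empty)

  width <- protocol$pulse_width_s
  mag <- protocol$force_fraction_bw * body_weight * GRAVITY
  onsets <- numeric(0)
  t <- runif(1, protocol$min_gap_s, protocol$max_gap_s)
  while (t + width <= duration_s) {
    onsets <- c(onsets, t)
    t <- t + runif(1, protocol$min_gap_s, protocol$max_gap_s)
  }
  if (length(onsets) == 0L) {
    warning("gap bounds admit no pulses within the trial duration",
            call. = FALSE)
    return(empty)
  }
  data.frame(
    onset_time = onsets,
    width = width,
    magnitude = mag,
    direction = sample(dirs, length(onsets), replace = TRUE),
    stringsAsFactors = FALSE
  )
}
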