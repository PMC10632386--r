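# Footfall/COP recording simulator for one subject x trial.
#
# Gait model: alternating L/R heel strikes advance along the walkway in
# passes (back and forth); step lengths are i.i.d. normal so that
# successive-ipsilateral-heel-strike distances have the subject's stride
# SD; step timing follows the subject's mean stride velocity with a small
# timing jitter. During stance the COP advances heel-to-toe along the
# footprint with a smooth lateral meander whose amplitude is the subject's
# cop_waviness. A force pulse overlapping a stance adds a lateral COP
# deflection magnitude x susceptibility in the pulse's direction, held for
# the pulse width and decaying exponentially afterwards (time constant
# 0.3 s); vertical pulse components scale the pressure curve during the
# pulse only.

PERT_DECAY_TAU <- 0.3 # s, first-order decay of the lateral COP deflection

# lateral / vertical signed components of a pulse direction label
.dir_components <- function(direction) {
  lat <- ifelse(grepl("right", direction), 1, -1)
  vert <- ifelse(grepl("-up", direction), 1,
                 ifelse(grepl("-down", direction), -1, 0))
  list(lat = lat, vert = vert)
}

# deflection response at times tt for pulses in schedule (lateral, cm) and
# pressure multiplier (dimensionless)
.pulse_response <- function(tt, schedule, susceptibility, force_fraction) {
  defl <- numeric(length(tt))
  mult <- rep(1, length(tt))
  if (is.null(schedule) || nrow(schedule) == 0L) {
    return(list(defl = defl, mult = mult))
  }
  comp <- .dir_components(schedule$direction)
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset_time[i]
    off <- on + schedule$width[i]
    amp <- schedule$magnitude[i] * susceptibility * comp$lat[i]
    inside <- tt >= on & tt < off
    after <- tt >= off
    defl[inside] <- defl[inside] + amp
    defl[after] <- defl[after] + amp * exp(-(tt[after] - off) / PERT_DECAY_TAU)
    if (comp$vert[i] != 0) {
      mult[inside] <- mult[inside] * (1 - comp$vert[i] * force_fraction)
    }
  }
  list(defl = defl, mult = mult)
}

#' Simulate one walking trial as a footfall-level COP recording
#'
#' Generates the per-sample COP positions and pressures of every footfall
#' of one subject walking one trial of the five-trial protocol, optionally
#' under a perturbation schedule, together with the generating ground truth
#' for parameter-recovery checks.
#'
#' @param subject one row of \code{\link{draw_subjects}} (data.frame or
#'   list).
#' @param trial_label one of \code{\link{trial_labels}()}.
#' @param schedule perturbation schedule from
#'   \code{\link{perturbation_schedule}}, or \code{NULL} for none.
#' @param protocol a \code{\link{pbt_protocol}}.
#' @param duration_s walking duration in seconds; default taken from the
#'   protocol for \code{trial_label}.
#' @param seed optional integer seed (reproducible recordings).
#' @param step_time_jitter_s SD of step-timing noise, s.
#' @param step_placement_sd_cm SD of lateral foot-placement noise, cm.
#' @param ss_jitter_s SD of double-support timing noise, s.
#' @param cop_excursion_cm heel-to-toe COP progression per stance, cm.
#' @param turn_time_s time consumed by each end-of-walkway turn, s.
#' @return list of class \code{pbt_trial}: \code{footfalls} (data.frame in
#'   the footfall CSV dialect: subject_id, group, trial, pass_id,
#'   footfall_id, foot, sample_t_s, cop_x_cm, cop_y_cm, pressure),
#'   \code{truth} (generating parameters actually used), and
#'   \code{schedule}.
#' @examples
#' sub <- draw_subjects(2, seed = 1)[1, ]
#' tr <- simulate_trial(sub, "GaitBaseline", duration_s = 30, seed = 2)
#' head(tr$footfalls)
#' @export
simulate_trial <- function(subject, trial_label, schedule = NULL,
                           protocol = pbt_protocol(), duration_s = NULL,
                           seed = NULL,
                           step_time_jitter_s = 0.01,
                           step_placement_sd_cm = 0.7,
                           ss_jitter_s = 0.01,
                           cop_excursion_cm = 18,
                           turn_time_s = 2) {
  subject <- as.list(subject)
  trial_label <- match.arg(trial_label, trial_labels())
  if (is.null(duration_s)) {
    duration_s <- 60 * unname(protocol$trial_durations_min[trial_label])
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  mu_step <- subject$mean_stride_length / 2
  sd_step <- subject$stride_length_sd / sqrt(2)
  v <- subject$mean_stride_velocity
  ss <- subject$single_support_mean
  L <- protocol$walkway_length_cm
  fs <- protocol$sampling_hz

  if (duration_s < 2.5 * subject$mean_stride_length / v) {
    stop("duration too short for one full stride", call. = FALSE)
  }

  # --- heel strike sequence over passes -------------------------------
  cap <- ceiling(duration_s / (mu_step / v)) + 8L
  h_t <- y <- x <- numeric(cap)
  pass <- integer(cap)
  foot <- character(cap)
  t <- 0.5
  y_abs <- 0
  dir <- 1L
  pid <- 1L
  k <- 0L
  side <- -1L # first strike with the left foot
  while (t <= duration_s && k < cap) {
    step_len <- max(10, rnorm(1, mu_step, sd_step))
    tau <- max(0.15, step_len / v + rnorm(1, 0, step_time_jitter_s))
    y_next <- y_abs + dir * step_len
    if (y_next < 0 || y_next > L) { # turn at the end of the walkway
      pid <- pid + 1L
      dir <- -dir
      y_abs <- if (dir > 0) 0 else L
      y_next <- y_abs + dir * step_len
      t <- t + turn_time_s
      if (t > duration_s) break
    }
    k <- k + 1L
    h_t[k] <- t + tau
    y[k] <- y_next
    x[k] <- dir * side * subject$step_width / 2 +
      rnorm(1, 0, step_placement_sd_cm)
    pass[k] <- pid
    foot[k] <- if (side < 0) "L" else "R"
    t <- t + tau
    y_abs <- y_next
    side <- -side
  }
  n <- k
  if (n < 4L) stop("duration too short for one full stride", call. = FALSE)
  h_t <- h_t[1:n]; y <- y[1:n]; x <- x[1:n]
  pass <- pass[1:n]; foot <- foot[1:n]

  # toe-off: footfall k lifts ds after the strike of footfall k+1, where ds
  # is chosen so each single-stance phase lasts ss/2 on average
  to_t <- numeric(n)
  nominal_stance <- subject$mean_stride_length / v - ss / 2
  for (k in seq_len(n)) {
    if (k + 2L <= n && pass[k + 1L] == pass[k] && pass[k + 2L] == pass[k]) {
      tau_next <- h_t[k + 2L] - h_t[k + 1L]
      ds <- max(0.02, tau_next - ss / 2 + rnorm(1, 0, ss_jitter_s))
      to_t[k] <- h_t[k + 1L] + ds
    } else {
      to_t[k] <- h_t[k] + max(0.3, nominal_stance)
    }
  }
  keep <- to_t <= duration_s + 2
  h_t <- h_t[keep]; to_t <- to_t[keep]; y <- y[keep]; x <- x[keep]
  pass <- pass[keep]; foot <- foot[keep]
  n <- length(h_t)

  # --- per-footfall COP samples ---------------------------------------
  pass_dir <- ifelse(pass %% 2L == 1L, 1, -1)
  w <- subject$cop_waviness
  P0 <- subject$body_weight
  ts_l <- xs_l <- ys_l <- ps_l <- vector("list", n)
  for (k in seq_len(n)) {
    stance <- to_t[k] - h_t[k]
    ns <- max(4L, ceiling(stance * fs) + 1L)
    tt <- seq(h_t[k], to_t[k], length.out = ns)
    u <- (tt - h_t[k]) / stance
    ph1 <- runif(1, 0, 2 * pi)
    ph2 <- runif(1, 0, 2 * pi)
    meander <- w * (sin(2 * pi * 3 * u + ph1) - sin(ph1) +
                      0.5 * (sin(2 * pi * 5 * u + ph2) - sin(ph2)))
    resp <- .pulse_response(tt, schedule, subject$perturbation_susceptibility,
                            protocol$force_fraction_bw)
    ts_l[[k]] <- tt
    xs_l[[k]] <- x[k] + meander + pass_dir[k] * resp$defl
    ys_l[[k]] <- y[k] + pass_dir[k] * cop_excursion_cm * u
    ps_l[[k]] <- pmax(0, P0 * sin(pi * u) * resp$mult)
  }
  lens <- lengths(ts_l)
  footfalls <- data.frame(
    subject_id = rep(subject$subject_id, sum(lens)),
    group = rep(subject$group, sum(lens)),
    trial = rep(trial_label, sum(lens)),
    pass_id = rep(pass, lens),
    footfall_id = rep(seq_len(n), lens),
    foot = rep(foot, lens),
    sample_t_s = unlist(ts_l),
    cop_x_cm = unlist(xs_l),
    cop_y_cm = unlist(ys_l),
    pressure = unlist(ps_l),
    stringsAsFactors = FALSE
  )

  truth <- list(
    subject_id = subject$subject_id,
    group = subject$group,
    trial = trial_label,
    stride_length = subject$mean_stride_length,
    stride_velocity = subject$mean_stride_velocity,
    single_support_time = subject$single_support_mean,
    integrated_pressure = 2 / pi * P0 * mean(to_t - h_t),
    cop_waviness = w,
    n_footfalls = n,
    n_pulses = if (is.null(schedule)) 0L else nrow(schedule)
  )
  structure(list(footfalls = footfalls, truth = truth, schedule = schedule),
            class = "pbt_trial")
}

#' @export
print.pbt_trial <- function(x, ...) {
  cat(sprintf("PBT trial recording: %s / %s, %d footfalls, %d pulses\n",
              x$truth$subject_id, x$truth$trial, x$truth$n_footfalls,
              x$truth$n_pulses))
  invisible(x)
}
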