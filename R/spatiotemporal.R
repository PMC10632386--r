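# Spatiotemporal gait parameters from footfall-segmented COP recordings:
# stride detection, single support time, integrated pressure, stride
# velocity. Lengths in cm, times in s.

# Collapse a footfall-level sample table to one row per footfall, with
# validation. Heel-strike position is by definition the first COP sample
# of the footfall (walkway exports carry no anatomical landmarks).
footfall_table <- function(footfalls) {
  req <- c("subject_id", "trial", "pass_id", "footfall_id", "foot",
           "sample_t_s", "cop_x_cm", "cop_y_cm", "pressure")
  miss <- setdiff(req, names(footfalls))
  if (length(miss)) {
    stop("footfall table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(footfalls$pressure < 0)) {
    stop("negative pressure sample", call. = FALSE)
  }
  key <- interaction(footfalls$subject_id, footfalls$trial,
                     footfalls$pass_id, footfalls$footfall_id, drop = TRUE)
  idx <- split(seq_len(nrow(footfalls)), key)
  bad <- vapply(idx, function(ii) {
    is.unsorted(footfalls$sample_t_s[ii], strictly = TRUE)
  }, TRUE)
  if (any(bad)) {
    stop("samples within a footfall must be strictly increasing in time ",
         "(footfall ", names(idx)[which(bad)[1]], ")", call. = FALSE)
  }
  first <- vapply(idx, `[`, 0L, 1L)
  last <- vapply(idx, function(ii) ii[length(ii)], 0L)
  ft <- data.frame(
    subject_id = footfalls$subject_id[first],
    trial = footfalls$trial[first],
    pass_id = footfalls$pass_id[first],
    footfall_id = footfalls$footfall_id[first],
    foot = footfalls$foot[first],
    heel_strike_t = footfalls$sample_t_s[first],
    toe_off_t = footfalls$sample_t_s[last],
    heel_x = footfalls$cop_x_cm[first],
    heel_y = footfalls$cop_y_cm[first],
    stringsAsFactors = FALSE
  )
  ft[order(ft$subject_id, ft$trial, ft$pass_id, ft$heel_strike_t), ,
     drop = FALSE]
}

.check_alternation <- function(feet, where) {
  if (length(feet) >= 2 && any(feet[-1] == feet[-length(feet)])) {
    stop("feet do not alternate within pass ", where, call. = FALSE)
  }
}

#' Detect strides from a footfall recording
#'
#' A stride spans two successive ipsilateral heel strikes within one
#' walkway pass (strides never cross passes; turns are excluded). Stride
#' length is the Euclidean distance between the two heel-strike positions,
#' a heel strike being the first COP sample of its footfall. Stride
#' velocity is stride length over stride duration; single support time is
#' the total time within the stride during which exactly one foot is in
#' contact with the ground.
#'
#' @param footfalls footfall-level sample table (footfall CSV dialect; see
#'   \code{\link{read_footfalls}}).
#' @return data.frame with one row per stride: subject_id, trial, pass_id,
#'   foot, lead_footfall_id, stride_length (cm), stride_duration (s),
#'   stride_velocity (cm/s), single_support_time (s, NA when the
#'   contralateral contact data are missing) and \code{flag}
#'   (\code{"ok"} / \code{"missing_contra"}).
#' @examples
#' sub <- draw_subjects(2, seed = 1)[1, ]
#' tr <- simulate_trial(sub, "GaitBaseline", duration_s = 30, seed = 2)
#' s <- detect_strides(tr$footfalls)
#' head(s)
#' @export
detect_strides <- function(footfalls) {
  ft <- footfall_table(footfalls)
  out <- vector("list", 0)
  for (key in split(seq_len(nrow(ft)),
                    interaction(ft$subject_id, ft$trial, ft$pass_id,
                                drop = TRUE))) {
    p <- ft[key, , drop = FALSE]
    .check_alternation(p$foot, paste(p$subject_id[1], p$trial[1],
                                     p$pass_id[1]))
    for (f in c("L", "R")) {
      ii <- which(p$foot == f)
      if (length(ii) < 2L) next
      for (j in seq_len(length(ii) - 1L)) {
        a <- ii[j]; b <- ii[j + 1L]
        len <- sqrt((p$heel_x[b] - p$heel_x[a])^2 +
                      (p$heel_y[b] - p$heel_y[a])^2)
        dur <- p$heel_strike_t[b] - p$heel_strike_t[a]
        contra <- p[p$foot != f, c("heel_strike_t", "toe_off_t"),
                    drop = FALSE]
        overl <- contra[contra$toe_off_t > p$heel_strike_t[a] &
                          contra$heel_strike_t < p$heel_strike_t[b], ,
                        drop = FALSE]
        # the stride's leading double support is unobservable unless a
        # contralateral contact is already on the ground at stride start
        covered <- any(overl$heel_strike_t <= p$heel_strike_t[a] &
                         overl$toe_off_t > p$heel_strike_t[a])
        sst <- if (covered) {
          single_support_time(
            p$heel_strike_t[a], p$heel_strike_t[b],
            rbind(
              data.frame(start = p$heel_strike_t[a],
                         end = p$toe_off_t[a]),
              data.frame(start = overl$heel_strike_t,
                         end = overl$toe_off_t)
            )
          )
        } else {
          NA_real_
        }
        out[[length(out) + 1L]] <- data.frame(
          subject_id = p$subject_id[1], trial = p$trial[1],
          pass_id = p$pass_id[1], foot = f,
          lead_footfall_id = p$footfall_id[a],
          stride_length = len, stride_duration = dur,
          stride_velocity = len / dur,
          single_support_time = sst,
          flag = if (is.na(sst)) "missing_contra" else "ok",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(0), trial = character(0),
                      pass_id = integer(0), foot = character(0),
                      lead_footfall_id = integer(0),
                      stride_length = numeric(0),
                      stride_duration = numeric(0),
                      stride_velocity = numeric(0),
                      single_support_time = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single support time within a stride
#'
#' Total time within \code{[stride_start, stride_end]} during which exactly
#' one of the supplied foot-contact intervals covers the instant.
#'
#' @param stride_start,stride_end stride span, seconds.
#' @param contacts data.frame with columns \code{start}, \code{end}: all
#'   foot-contact intervals overlapping the stride (both feet).
#' @return time in seconds.
#' @examples
#' # L on [0, 0.7], R on [0.6, 1.3], stride span [0, 1.1]:
#' single_support_time(0, 1.1, data.frame(start = c(0, 0.6),
#'                                        end = c(0.7, 1.3)))
#' @export
single_support_time <- function(stride_start, stride_end, contacts) {
  stopifnot(stride_end > stride_start)
  if (is.null(contacts) || nrow(contacts) == 0L) return(NA_real_)
  s <- pmax(contacts$start, stride_start)
  e <- pmin(contacts$end, stride_end)
  ok <- e > s
  s <- s[ok]; e <- e[ok]
  if (!length(s)) return(0)
  pts <- sort(unique(c(s, e, stride_start, stride_end)))
  tot <- 0
  for (i in seq_len(length(pts) - 1L)) {
    mid <- (pts[i] + pts[i + 1L]) / 2
    if (sum(s <= mid & e > mid) == 1L) tot <- tot + pts[i + 1L] - pts[i]
  }
  tot
}

#' Integrated pressure of a footfall
#'
#' Area under the pressure-vs-time curve over the footfall's contact,
#' by the trapezoidal rule on the samples as recorded (no resampling).
#'
#' @param t sample times, strictly increasing, seconds.
#' @param pressure pressure samples, instrument units, >= 0.
#' @return area in instrument-units x seconds.
#' @examples
#' integrated_pressure(seq(0, 0.8, 0.1), rep(10, 9)) # 8.0
#' @export
integrated_pressure <- function(t, pressure) {
  if (length(t) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (any(pressure < 0)) stop("negative pressure sample", call. = FALSE)
  sum(diff(t) * (pressure[-1] + pressure[-length(pressure)]) / 2)
}

#' Stride velocity
#'
#' Average velocity of a stride: stride length over stride duration.
#'
#' @param stride_length cm.
#' @param stride_duration s, > 0.
#' @return cm/s.
#' @export
stride_velocity <- function(stride_length, stride_duration) {
  if (any(stride_duration <= 0)) {
    stop("stride_duration must be positive", call. = FALSE)
  }
  stride_length / stride_duration
}

# per-footfall integrated pressure table
footfall_pressures <- function(footfalls) {
  key <- interaction(footfalls$subject_id, footfalls$trial,
                     footfalls$pass_id, footfalls$footfall_id, drop = TRUE)
  idx <- split(seq_len(nrow(footfalls)), key)
  rows <- lapply(idx, function(ii) {
    data.frame(
      subject_id = footfalls$subject_id[ii[1]],
      trial = footfalls$trial[ii[1]],
      pass_id = footfalls$pass_id[ii[1]],
      footfall_id = footfalls$footfall_id[ii[1]],
      integrated_pressure = integrated_pressure(footfalls$sample_t_s[ii],
                                                footfalls$pressure[ii]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
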