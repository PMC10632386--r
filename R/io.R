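# Footfall CSV dialect, clinical/summary tables, ground-truth log.
# Coordinates: cm in the walkway frame, y = forward progression after pass
# normalization, x = subject's right; times in s from trial start; comma
# separation, '.' decimal.

FOOTFALL_COLUMNS <- c("subject_id", "group", "trial", "pass_id",
                      "footfall_id", "foot", "sample_t_s", "cop_x_cm",
                      "cop_y_cm", "pressure")

#' Normalize walkway passes to a common forward axis
#'
#' Subjects walk back and forth; each pass is rigidly rotated so that its
#' net heel-strike displacement (first to last footfall) points along +y.
#' The map is exactly idempotent: re-normalizing normalized data is the
#' identity.
#'
#' @param footfalls footfall-level sample table.
#' @return the table with \code{cop_x_cm}, \code{cop_y_cm} rotated per
#'   pass.
#' @export
normalize_passes <- function(footfalls) {
  key <- interaction(footfalls$subject_id, footfalls$trial,
                     footfalls$pass_id, drop = TRUE)
  for (ii in split(seq_len(nrow(footfalls)), key)) {
    ids <- footfalls$footfall_id[ii]
    first_ff <- ii[ids == min(ids)][1]
    # use the last heel strike of the SAME foot so the direction estimate
    # carries no lateral left/right offset
    same <- ii[footfalls$foot[ii] == footfalls$foot[first_ff]]
    last_ff <- same[footfalls$footfall_id[same] ==
                      max(footfalls$footfall_id[same])][1]
    if (footfalls$footfall_id[last_ff] == footfalls$footfall_id[first_ff]) {
      last_ff <- ii[ids == max(ids)][1]
    }
    dx <- footfalls$cop_x_cm[last_ff] - footfalls$cop_x_cm[first_ff]
    dy <- footfalls$cop_y_cm[last_ff] - footfalls$cop_y_cm[first_ff]
    if (dx == 0 && dy == 0) next
    a <- pi / 2 - atan2(dy, dx) # rotate net displacement onto +y
    if (a == 0) next
    x <- footfalls$cop_x_cm[ii]; y <- footfalls$cop_y_cm[ii]
    footfalls$cop_x_cm[ii] <- cos(a) * x - sin(a) * y
    footfalls$cop_y_cm[ii] <- sin(a) * x + cos(a) * y
  }
  footfalls
}

#' Write / read footfall recordings in the package's CSV dialect
#'
#' One row per COP sample, grouped by footfall and time-sorted within;
#' exact header \code{subject_id, group, trial, pass_id, footfall_id,
#' foot, sample_t_s, cop_x_cm, cop_y_cm, pressure}. The reader validates
#' the schema (naming the offending row on failure): known trial labels,
#' L/R feet, non-negative pressures, strictly increasing sample times
#' within each footfall — violations are hard errors, never silently
#' reordered.
#'
#' @param footfalls footfall sample table.
#' @param path file path.
#' @param normalize rotate passes to the common forward axis after
#'   reading (see \code{\link{normalize_passes}}). Default TRUE; use FALSE
#'   to obtain the file's values verbatim.
#' @return \code{read_footfalls}: the validated data.frame (zero rows for
#'   an empty file with a valid header).
#' @export
write_footfalls <- function(footfalls, path) {
  stopifnot(identical(names(footfalls), FOOTFALL_COLUMNS))
  write.csv(footfalls, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_footfalls
#' @export
read_footfalls <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, FOOTFALL_COLUMNS)) {
    stop("footfall CSV header mismatch; expected exactly: ",
         paste(FOOTFALL_COLUMNS, collapse = ","), call. = FALSE)
  }
  ff <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject_id = "character",
                                group = "character", trial = "character",
                                pass_id = "integer",
                                footfall_id = "integer",
                                foot = "character", sample_t_s = "numeric",
                                cop_x_cm = "numeric", cop_y_cm = "numeric",
                                pressure = "numeric"))
  if (!identical(names(ff), FOOTFALL_COLUMNS)) {
    stop("footfall CSV header mismatch; expected exactly: ",
         paste(FOOTFALL_COLUMNS, collapse = ","), call. = FALSE)
  }
  if (nrow(ff) == 0L) return(ff)
  bad <- which(!ff$trial %in% trial_labels())
  if (length(bad)) {
    stop("unknown trial label '", ff$trial[bad[1]], "' at data row ",
         bad[1], call. = FALSE)
  }
  bad <- which(!ff$foot %in% c("L", "R"))
  if (length(bad)) {
    stop("foot must be L or R at data row ", bad[1], call. = FALSE)
  }
  bad <- which(ff$pressure < 0)
  if (length(bad)) {
    stop("negative pressure at data row ", bad[1], call. = FALSE)
  }
  key <- interaction(ff$subject_id, ff$trial, ff$pass_id, ff$footfall_id,
                     drop = TRUE)
  for (ii in split(seq_len(nrow(ff)), key)) {
    dt <- diff(ff$sample_t_s[ii])
    if (any(dt <= 0)) {
      stop("sample times not strictly increasing within footfall at data ",
           "row ", ii[which(dt <= 0)[1] + 1L], call. = FALSE)
    }
  }
  if (normalize) ff <- normalize_passes(ff)
  ff
}

#' Write / read the ground-truth log as a key-value text file
#'
#' One line per (subject, trial, parameter): \code{subject:trial:param=value}.
#'
#' @param truth ground-truth data.frame from \code{\link{simulate_cohort}}.
#' @param path file path.
#' @return \code{read_truth_log}: the reconstructed data.frame.
#' @export
write_truth_log <- function(truth, path) {
  keys <- c("subject_id", "group", "trial")
  pars <- setdiff(names(truth), keys)
  lines <- character(0)
  for (i in seq_len(nrow(truth))) {
    lines <- c(lines, sprintf("%s:%s:%s:%s=%.15g",
                              truth$subject_id[i], truth$group[i],
                              truth$trial[i], pars,
                              as.numeric(unlist(truth[i, pars]))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth_log
#' @export
read_truth_log <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "[:=]")
  df <- data.frame(
    subject_id = vapply(parts, `[`, "", 1L),
    group = vapply(parts, `[`, "", 2L),
    trial = vapply(parts, `[`, "", 3L),
    param = vapply(parts, `[`, "", 4L),
    value = as.numeric(vapply(parts, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  wide <- reshape(df, idvar = c("subject_id", "group", "trial"),
                  timevar = "param", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
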