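# COP butterfly cyclograms per gait cycle, the cyclogram self-intersection
# point (CISP), and single-stance COP path efficiency.
#
# A gait cycle spans two successive ipsilateral heel strikes. The net COP
# over the cycle is the pressure-weighted combination of the feet in
# contact; plotted ML against AP after removing the forward-progression
# trend it traces the familiar butterfly whose two double-support strokes
# cross near the middle — that crossing is the CISP, and its AP/ML position
# (as a percentage of the cyclogram extents) indexes gait symmetry.

#' Build a COP cyclogram trajectory for one gait cycle
#'
#' Re-expresses the merged cycle COP in the cyclogram frame: the AP
#' coordinate has the linear forward-progression trend (OLS of AP on time)
#' removed and is anchored at the cycle's leading heel strike; the ML
#' coordinate is centred on the cycle midline. Phases are carried through.
#'
#' @param cycle_cop data.frame for one gait cycle with columns \code{t}
#'   (s, increasing), \code{x_ml} (cm), \code{y_ap} (cm) and \code{phase}
#'   (\code{"single_stance_L"}, \code{"single_stance_R"},
#'   \code{"double_support"}).
#' @return data.frame of class \code{cyclogram_trajectory} with columns
#'   \code{x_ml_rel}, \code{y_ap_rel}, \code{t}, \code{phase} and attribute
#'   \code{has_double_support}.
#' @export
build_cyclogram <- function(cycle_cop) {
  req <- c("t", "x_ml", "y_ap", "phase")
  if (!all(req %in% names(cycle_cop))) {
    stop("cycle_cop needs columns t, x_ml, y_ap, phase", call. = FALSE)
  }
  if (is.unsorted(cycle_cop$t)) {
    stop("cycle samples must be time-ordered", call. = FALSE)
  }
  t0 <- cycle_cop$t[1]
  tc <- cycle_cop$t - t0
  fit <- lm.fit(cbind(1, tc), cycle_cop$y_ap)
  y_rel <- fit$residuals - fit$residuals[1]
  x_rel <- cycle_cop$x_ml - mean(cycle_cop$x_ml)
  traj <- data.frame(x_ml_rel = x_rel, y_ap_rel = y_rel, t = cycle_cop$t,
                     phase = cycle_cop$phase, stringsAsFactors = FALSE)
  attr(traj, "has_double_support") <- any(cycle_cop$phase == "double_support")
  class(traj) <- c("cyclogram_trajectory", "data.frame")
  traj
}

# intersection of segment (p1,p2) with (p3,p4); returns c(x, y, s) with s
# the parameter along (p1,p2), or NULL
.seg_intersect <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  rx <- x2 - x1; ry <- y2 - y1
  sx <- x4 - x3; sy <- y4 - y3
  denom <- rx * sy - ry * sx
  if (abs(denom) < 1e-14) return(NULL)
  tt <- ((x3 - x1) * sy - (y3 - y1) * sx) / denom
  uu <- ((x3 - x1) * ry - (y3 - y1) * rx) / denom
  if (tt < 0 || tt > 1 || uu < 0 || uu > 1) return(NULL)
  c(x1 + tt * rx, y1 + tt * ry, tt)
}

#' Locate the cyclogram intersection point (CISP)
#'
#' Finds the self-intersection of the piecewise-linear cyclogram path.
#' Candidate crossings are intersections of non-adjacent segment pairs;
#' when several exist the one nearest the cyclogram's AP midpoint is taken
#' (ties broken by the earliest along the path). The AP position is
#' expressed as a percentage of the cyclogram's AP extent and the ML
#' position as a signed percentage of half the ML extent about the
#' midline.
#'
#' @param traj a \code{\link{build_cyclogram}} trajectory (or data.frame
#'   with \code{x_ml_rel}, \code{y_ap_rel}).
#' @return list: \code{point} (named x/y, cm, cyclogram frame),
#'   \code{cisp_ap_pct}, \code{cisp_ml_pct}, \code{n_crossings},
#'   \code{flag} (\code{"ok"} or \code{"no_crossing"}, with the percentage
#'   fields NA when no crossing exists).
#' @examples
#' # symmetric X: two straight legs crossing at (0, 2)
#' traj <- data.frame(x_ml_rel = c(-2, 2, 2, -2), y_ap_rel = c(0, 4, 0, 4),
#'                    t = 1:4, phase = "double_support")
#' find_cisp(traj)$cisp_ap_pct # 50
#' @export
find_cisp <- function(traj) {
  x <- traj$x_ml_rel
  y <- traj$y_ap_rel
  n <- length(x) - 1L # segments
  none <- list(point = c(x = NA_real_, y = NA_real_),
               cisp_ap_pct = NA_real_, cisp_ml_pct = NA_real_,
               n_crossings = 0L, flag = "no_crossing")
  if (n < 3L) return(none)
  # bounding-box prefilter over non-adjacent pairs
  xlo <- pmin(x[-(n + 1L)], x[-1L]); xhi <- pmax(x[-(n + 1L)], x[-1L])
  ylo <- pmin(y[-(n + 1L)], y[-1L]); yhi <- pmax(y[-(n + 1L)], y[-1L])
  cand <- which(outer(seq_len(n), seq_len(n),
                      function(i, j) j > i + 1L) &
                  outer(xlo, xhi, `<=`) & outer(xhi, xlo, `>=`) &
                  outer(ylo, yhi, `<=`) & outer(yhi, ylo, `>=`),
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(none)
  hits <- matrix(numeric(0), ncol = 4) # x, y, seg index, param
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    p <- .seg_intersect(x[i], y[i], x[i + 1L], y[i + 1L],
                        x[j], y[j], x[j + 1L], y[j + 1L])
    if (!is.null(p)) hits <- rbind(hits, c(p[1], p[2], i, p[3]))
  }
  if (nrow(hits) == 0L) return(none)
  ymin <- min(y); ymax <- max(y)
  xmin <- min(x); xmax <- max(x)
  mid_ap <- (ymin + ymax) / 2
  d <- abs(hits[, 2] - mid_ap)
  best <- which(d <= min(d) + 1e-12)
  if (length(best) > 1L) { # tie: earliest along the path
    ord <- order(hits[best, 3], hits[best, 4])
    best <- best[ord[1L]]
  }
  px <- as.numeric(hits[best, 1]); py <- as.numeric(hits[best, 2])
  ap_ext <- ymax - ymin
  ml_half <- (xmax - xmin) / 2
  list(
    point = c(x = px, y = py),
    cisp_ap_pct = if (ap_ext > 0) 100 * (py - ymin) / ap_ext else NA_real_,
    cisp_ml_pct = if (ml_half > 0) {
      100 * (px - (xmin + xmax) / 2) / ml_half
    } else {
      NA_real_
    },
    n_crossings = nrow(hits),
    flag = "ok"
  )
}

#' Single-stance COP path efficiency
#'
#' Percentage ratio of the straight chord from the first to the last point
#' of a single-stance COP segment to the actual distance the COP travels
#' along it, in the horizontal plane. 100% means the COP follows the chord
#' exactly; deviations lower the ratio (triangle inequality bounds it in
#' (0, 100]).
#'
#' @param x,y COP coordinates of the single-stance segment, cm.
#' @return efficiency in percent.
#' @examples
#' u <- seq(0, 1, length.out = 50)
#' ss_cop_efficiency(20 * u, rep(0, 50)) # straight chord: 100
#' @export
ss_cop_efficiency <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y)) {
    stop("need >= 2 paired samples", call. = FALSE)
  }
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  if (path <= 0) stop("zero path length", call. = FALSE)
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  100 * chord / path
}

# ---- cycle assembly -----------------------------------------------------

# merged (pressure-weighted) COP over a time window from the involved
# footfalls of one pass
.merge_cop <- function(samples, ft, t_lo, t_hi) {
  inv <- ft[ft$toe_off_t > t_lo & ft$heel_strike_t < t_hi, , drop = FALSE]
  if (nrow(inv) < 2L) return(NULL)
  tt <- sort(unique(samples$sample_t_s[samples$sample_t_s >= t_lo &
                                         samples$sample_t_s <= t_hi]))
  if (length(tt) < 4L) return(NULL)
  wx <- wy <- wsum <- numeric(length(tt))
  nactive <- integer(length(tt))
  active_foot <- character(length(tt))
  for (k in seq_len(nrow(inv))) {
    ss <- samples[samples$footfall_id == inv$footfall_id[k] &
                    samples$pass_id == inv$pass_id[k], , drop = FALSE]
    act <- tt >= inv$heel_strike_t[k] & tt <= inv$toe_off_t[k]
    if (!any(act)) next
    xi <- approx(ss$sample_t_s, ss$cop_x_cm, tt[act], rule = 2)$y
    yi <- approx(ss$sample_t_s, ss$cop_y_cm, tt[act], rule = 2)$y
    pi_ <- pmax(approx(ss$sample_t_s, ss$pressure, tt[act], rule = 2)$y, 0)
    w <- pi_ + 1e-9 # keep the weighted mean defined at zero-load instants
    wx[act] <- wx[act] + w * xi
    wy[act] <- wy[act] + w * yi
    wsum[act] <- wsum[act] + w
    nactive[act] <- nactive[act] + 1L
    active_foot[act] <- ifelse(nactive[act] == 1L, inv$foot[k], "")
  }
  ok <- wsum > 0
  phase <- ifelse(nactive >= 2L, "double_support",
                  ifelse(active_foot == "L", "single_stance_L",
                         "single_stance_R"))
  data.frame(t = tt[ok], x_ml = wx[ok] / wsum[ok], y_ap = wy[ok] / wsum[ok],
             phase = phase[ok], stringsAsFactors = FALSE)[nactive[ok] > 0L, ]
}

#' Per-cycle cyclogram metrics for a recording
#'
#' Segments a (pass-normalized) footfall recording into gait cycles, builds
#' the COP cyclogram of each cycle, locates the CISP and computes each
#' foot's single-stance COP path efficiency. Cycles whose cyclogram has no
#' self-crossing carry NA CISP values and flag \code{"no_crossing"}; they
#' are excluded from summaries (counts reported via the flag column).
#'
#' @param footfalls footfall-level sample table, pass-normalized (see
#'   \code{\link{normalize_passes}}).
#' @return data.frame: subject_id, trial, pass_id, cycle_index,
#'   cisp_ap_pct, cisp_ml_pct, ss_cop_efficiency_L, ss_cop_efficiency_R,
#'   n_crossings, flag.
#' @export
cycle_metrics <- function(footfalls) {
  ft_all <- footfall_table(footfalls)
  out <- vector("list", 0)
  groups <- split(seq_len(nrow(ft_all)),
                  interaction(ft_all$subject_id, ft_all$trial,
                              ft_all$pass_id, drop = TRUE))
  for (gi in groups) {
    ft <- ft_all[gi, , drop = FALSE]
    if (nrow(ft) < 3L) next
    samp <- footfalls[footfalls$subject_id == ft$subject_id[1] &
                        footfalls$trial == ft$trial[1] &
                        footfalls$pass_id == ft$pass_id[1], , drop = FALSE]
    cyc <- 0L
    for (f in c("L", "R")) {
      ii <- which(ft$foot == f)
      if (length(ii) < 2L) next
      for (j in seq_len(length(ii) - 1L)) {
        a <- ii[j]; b <- ii[j + 1L]
        cyc <- cyc + 1L
        mcop <- .merge_cop(samp, ft, ft$heel_strike_t[a], ft$heel_strike_t[b])
        eff <- c(L = NA_real_, R = NA_real_)
        # single-stance segment per involved foot: its own samples while no
        # other foot is in contact
        for (k in seq_len(nrow(ft))) {
          if (ft$heel_strike_t[k] >= ft$heel_strike_t[b] ||
              ft$toe_off_t[k] <= ft$heel_strike_t[a]) next
          others <- ft[-k, , drop = FALSE]
          ss <- samp[samp$footfall_id == ft$footfall_id[k], , drop = FALSE]
          solo <- vapply(ss$sample_t_s, function(tm) {
            tm >= ft$heel_strike_t[a] && tm <= ft$heel_strike_t[b] &&
              !any(others$heel_strike_t <= tm & others$toe_off_t > tm)
          }, TRUE)
          if (sum(solo) >= 2L && is.na(eff[ft$foot[k]])) {
            pth <- sum(sqrt(diff(ss$cop_x_cm[solo])^2 +
                              diff(ss$cop_y_cm[solo])^2))
            if (pth > 0) {
              eff[ft$foot[k]] <- ss_cop_efficiency(ss$cop_x_cm[solo],
                                                   ss$cop_y_cm[solo])
            }
          }
        }
        if (is.null(mcop)) next
        traj <- build_cyclogram(mcop)
        ci <- find_cisp(traj)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = ft$subject_id[1], trial = ft$trial[1],
          pass_id = ft$pass_id[1], cycle_index = cyc, foot = f,
          cisp_ap_pct = ci$cisp_ap_pct, cisp_ml_pct = ci$cisp_ml_pct,
          ss_cop_efficiency_L = unname(eff["L"]),
          ss_cop_efficiency_R = unname(eff["R"]),
          n_crossings = ci$n_crossings, flag = ci$flag,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(0), trial = character(0),
                      pass_id = integer(0), cycle_index = integer(0),
                      foot = character(0), cisp_ap_pct = numeric(0),
                      cisp_ml_pct = numeric(0),
                      ss_cop_efficiency_L = numeric(0),
                      ss_cop_efficiency_R = numeric(0),
                      n_crossings = integer(0), flag = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
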