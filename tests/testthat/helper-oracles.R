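# Independent oracles and small fixtures used across the suite.

# plain-loop arc length (oracle for the vectorized path length inside
# ss_cop_efficiency)
loop_path_length <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L)) {
    s <- s + sqrt((x[i + 1L] - x[i])^2 + (y[i + 1L] - y[i])^2)
  }
  s
}

loop_efficiency <- function(x, y) {
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  100 * chord / loop_path_length(x, y)
}

# brute-force all-segment-pairs self-intersection with the same decision
# rule as find_cisp (nearest AP midpoint, ties earliest along the path),
# written as naive loops with its own intersection algebra
brute_force_cisp <- function(x, y) {
  n <- length(x) - 1L
  hits <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L) next
      d1x <- x[i + 1L] - x[i]; d1y <- y[i + 1L] - y[i]
      d2x <- x[j + 1L] - x[j]; d2y <- y[j + 1L] - y[j]
      den <- d1x * d2y - d1y * d2x
      if (abs(den) < 1e-14) next
      tt <- ((x[j] - x[i]) * d2y - (y[j] - y[i]) * d2x) / den
      uu <- ((x[j] - x[i]) * d1y - (y[j] - y[i]) * d1x) / den
      if (tt >= 0 && tt <= 1 && uu >= 0 && uu <= 1) {
        hits[[length(hits) + 1L]] <- c(x[i] + tt * d1x, y[i] + tt * d1y,
                                       i, tt)
      }
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  mid <- (min(y) + max(y)) / 2
  d <- abs(h[, 2] - mid)
  best <- which(d <= min(d) + 1e-12)
  if (length(best) > 1L) best <- best[order(h[best, 3], h[best, 4])][1L]
  list(point = h[best, 1:2], n = nrow(h))
}

# random wavy closed-ish trajectory that usually self-intersects
random_cyclogram <- function(n = 30L) {
  tt <- seq(0, 1, length.out = n)
  a <- runif(3, 0.5, 2)
  x <- a[1] * sin(2 * pi * tt + runif(1, 0, 2 * pi)) + 0.3 * rnorm(n)
  y <- a[2] * cos(4 * pi * tt + runif(1, 0, 2 * pi)) +
    a[3] * tt + 0.3 * rnorm(n)
  data.frame(x_ml_rel = x, y_ap_rel = y, t = tt, phase = "double_support",
             stringsAsFactors = FALSE)
}

# counts favourable (x > y) pairs directly (oracle for the rank-based U)
brute_force_u <- function(x, y) {
  u1 <- 0
  for (xi in x) for (yi in y) {
    u1 <- u1 + (xi > yi) + 0.5 * (xi == yi)
  }
  c(U1 = u1, U2 = length(x) * length(y) - u1)
}

# one fast synthetic subject and recording for metric tests
quick_subject <- function(seed = 1L, ...) {
  sub <- draw_subjects(2, seed = seed)[1, ]
  dots <- list(...)
  for (k in names(dots)) sub[[k]] <- dots[[k]]
  sub
}

quick_trial <- function(duration_s = 40, seed = 2L, subject = quick_subject(),
                        ...) {
  simulate_trial(subject, "GaitBaseline", duration_s = duration_s,
                 seed = seed, ...)
}

# balanced long-format two-condition dataset
random_mixed_design <- function(n_per_group = 10L, delta_eg = 0, sd = 5) {
  n <- 2L * n_per_group
  g <- rep(c("EG", "CG"), each = n_per_group)
  b <- rnorm(n, 0, sd)
  y1 <- 100 + b + rnorm(n, 0, sd / 2)
  y2 <- 100 + b + rnorm(n, 0, sd / 2) + ifelse(g == "EG", delta_eg, 0)
  data.frame(subject_id = rep(sprintf("s%03d", 1:n), 2),
             group = rep(g, 2),
             trial = rep(c("TestPre", "TestPost"), each = n),
             mean = c(y1, y2), stringsAsFactors = FALSE)
}
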