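# The trial's statistical decision procedure: assumption checks with the
# log-transform rule, two-factor mixed-design ANOVA (group between,
# session/trial within), independent t / Mann-Whitney U comparison of the
# training trials, and the baseline descriptive table.

#' Significance stars
#'
#' @param p p-value(s).
#' @return "***" for p < 0.001, "**" for p < 0.01, "*" for p < 0.05,
#'   otherwise "".
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Check distributional assumptions before the mixed ANOVA
#'
#' Normality by Shapiro-Wilk on the cell-mean residuals, homoscedasticity
#' by Levene's test across groups, and sphericity (trivially satisfied
#' with two within-subject levels). The transform rule follows the trial's
#' procedure: if homoscedasticity and sphericity hold but normality fails,
#' a natural log transform is indicated — provided all values are
#' positive, otherwise the transform is skipped and flagged.
#'
#' @param value numeric observations.
#' @param group between-subject factor (two levels).
#' @param condition within-subject factor (two levels).
#' @param alpha significance level for the assumption tests. Default 0.05.
#' @return object of class \code{assumption_report}: normal /
#'   homoscedastic / spherical logicals with p-values,
#'   \code{transform_applied} (\code{"none"} or \code{"natural_log"}) and
#'   \code{transform_skipped} (TRUE when indicated but data were not all
#'   positive).
#' @export
check_assumptions <- function(value, group, condition = NULL, alpha = 0.05) {
  stopifnot(length(value) == length(group))
  cells <- if (is.null(condition)) {
    factor(group)
  } else {
    interaction(group, condition, drop = TRUE)
  }
  if (any(table(cells) < 3L)) {
    stop("need >= 3 observations per cell", call. = FALSE)
  }
  resid <- value - ave(value, cells)
  sw <- if (length(unique(round(resid, 12))) > 1L) {
    shapiro.test(resid)
  } else {
    list(p.value = 1) # degenerate constant residuals
  }
  lev_p <- tryCatch({
    lt <- car::leveneTest(value ~ factor(group))
    lt[["Pr(>F)"]][1]
  }, error = function(e) 1)
  if (is.na(lev_p)) lev_p <- 1
  normal <- sw$p.value >= alpha
  homosc <- lev_p >= alpha
  n_within <- if (is.null(condition)) 1L else length(unique(condition))
  spherical <- n_within <= 2L # undefined below 3 levels, hence satisfied
  indicated <- homosc && spherical && !normal
  positive <- all(value > 0)
  structure(
    list(normal = normal, normal_p = unname(sw$p.value),
         homoscedastic = homosc, homoscedastic_p = unname(lev_p),
         spherical = spherical, spherical_p = NA_real_,
         transform_applied = if (indicated && positive) "natural_log"
                             else "none",
         transform_skipped = indicated && !positive,
         alpha = alpha),
    class = "assumption_report"
  )
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Assumption checks (alpha =", x$alpha, ")\n")
  cat(sprintf("  normality (Shapiro-Wilk):      %s (p = %.4g)\n",
              ifelse(x$normal, "met", "violated"), x$normal_p))
  cat(sprintf("  homoscedasticity (Levene):     %s (p = %.4g)\n",
              ifelse(x$homoscedastic, "met", "violated"),
              x$homoscedastic_p))
  cat(sprintf("  sphericity:                    %s\n",
              ifelse(x$spherical, "met (2 within-levels)", "violated")))
  cat("  transform:", x$transform_applied,
      if (x$transform_skipped) "(indicated but skipped: non-positive values)",
      "\n")
  invisible(x)
}

# ---- mixed-design ANOVA -------------------------------------------------

#' Two-factor mixed-design ANOVA
#'
#' Fits the trial's mixed analysis of variance: one between-subject factor
#' (group: EG/CG) and one within-subject factor with two levels (session
#' or trial pair), one value per subject per condition. Sums of squares
#' are computed from the subject mean/difference decomposition; with two
#' within-levels the interaction F equals the squared pooled two-sample t
#' on per-subject difference scores. Effects whose sum of squares is zero
#' (e.g. constant data) report F = 0. Subjects missing a condition are
#' excluded listwise (count reported).
#'
#' By default the assumption checks run first and the natural-log
#' transform is applied when the procedure indicates it (homoscedastic and
#' spherical but non-normal, all values positive).
#'
#' @param data data.frame in long form.
#' @param value,subject,group,condition column names in \code{data}.
#' @param transform \code{"auto"} (decision rule), \code{"none"} or
#'   \code{"log"}.
#' @param alpha significance level for assumption checks / stars.
#' @return object of class \code{mixed_anova} with components
#'   \code{table} (effect, df1, df2, F, p, stars), \code{assumptions},
#'   \code{transform}, \code{n} (subjects per group), \code{n_excluded},
#'   and \code{condition_levels}.
#' @examples
#' d <- data.frame(subject = rep(1:10, 2), group = rep(rep(c("EG", "CG"),
#'   each = 5), 2), condition = rep(c("pre", "post"), each = 10),
#'   value = rnorm(20, 100, 5))
#' fit <- mixed_anova(d, value = "value", subject = "subject")
#' fit
#' @export
mixed_anova <- function(data, value = "mean", subject = "subject_id",
                        group = "group", condition = "trial",
                        transform = c("auto", "none", "log"),
                        alpha = 0.05) {
  transform <- match.arg(transform)
  v <- data[[value]]; s <- as.character(data[[subject]])
  g <- as.character(data[[group]]); cnd <- as.character(data[[condition]])
  ok <- !is.na(v)
  v <- v[ok]; s <- s[ok]; g <- g[ok]; cnd <- cnd[ok]
  lev <- sort(unique(cnd))
  if (length(lev) != 2L) {
    stop("condition must have exactly 2 levels, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  # order the pair by protocol position when the labels are protocol trials
  known <- c(trial_labels(), "Day1", "Day2")
  if (all(lev %in% known)) lev <- known[sort(match(lev, known))]

  wide <- reshape_pair(v, s, g, cnd, lev)
  n_excluded <- attr(wide, "n_excluded")
  if (nrow(wide) < 4L) stop("too few complete subjects", call. = FALSE)

  report <- tryCatch(
    check_assumptions(c(wide$y1, wide$y2),
                      rep(wide$group, 2),
                      rep(lev, each = nrow(wide)), alpha = alpha),
    error = function(e) NULL # cells too small to test: fit untransformed
  )
  applied <- "none"
  if (transform == "log" ||
      (transform == "auto" && !is.null(report) &&
         report$transform_applied == "natural_log")) {
    if (all(c(wide$y1, wide$y2) > 0)) {
      wide$y1 <- log(wide$y1); wide$y2 <- log(wide$y2)
      applied <- "natural_log"
    }
  }

  tab <- .mixed_anova_ss(wide$y1, wide$y2, wide$group)
  tab$stars <- significance_stars(tab$p)
  structure(
    list(table = tab, assumptions = report, transform = applied,
         n = table(wide$group), n_excluded = n_excluded,
         condition_levels = lev, alpha = alpha,
         data = wide),
    class = "mixed_anova"
  )
}

# long -> wide pair with listwise exclusion
reshape_pair <- function(v, s, g, cnd, lev) {
  sub <- unique(s)
  y1 <- y2 <- rep(NA_real_, length(sub))
  gr <- rep(NA_character_, length(sub))
  for (i in seq_along(sub)) {
    ii <- s == sub[i]
    gr[i] <- g[ii][1]
    a <- v[ii & cnd == lev[1]]
    b <- v[ii & cnd == lev[2]]
    if (length(a) == 1L) y1[i] <- a
    if (length(b) == 1L) y2[i] <- b
  }
  complete <- !is.na(y1) & !is.na(y2)
  out <- data.frame(subject = sub[complete], group = gr[complete],
                    y1 = y1[complete], y2 = y2[complete],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!complete)
  out
}

# sums of squares for the 2 (between) x 2 (within) mixed design
.mixed_anova_ss <- function(y1, y2, group) {
  group <- as.character(group)
  gl <- unique(group)
  N <- length(y1)
  m <- (y1 + y2) / 2
  d <- y2 - y1
  ni <- tapply(rep(1, N), group, sum)[gl]
  mi <- tapply(m, group, mean)[gl]
  di <- tapply(d, group, mean)[gl]
  mbar <- mean(m)
  dbar <- mean(d)
  ss_group <- 2 * sum(ni * (mi - mbar)^2)
  ss_subj <- 2 * sum((m - mi[group])^2)
  ss_sess <- N * dbar^2 / 2
  ss_int <- sum(ni * (di - dbar)^2) / 2
  ss_werr <- sum((d - di[group])^2) / 2
  dfb <- c(length(gl) - 1L, N - length(gl))
  dfw <- c(1L, length(gl) - 1L, N - length(gl))
  f_of <- function(ss_eff, df1, ss_err, df2) {
    if (ss_eff <= 1e-12 * max(1, ss_eff + ss_err)) return(c(0, 1))
    if (ss_err <= 0) return(c(Inf, 0))
    f <- (ss_eff / df1) / (ss_err / df2)
    c(f, pf(f, df1, df2, lower.tail = FALSE))
  }
  fg <- f_of(ss_group, dfb[1], ss_subj, dfb[2])
  fs <- f_of(ss_sess, dfw[1], ss_werr, dfw[3])
  fi <- f_of(ss_int, dfw[2], ss_werr, dfw[3])
  data.frame(
    effect = c("group_main", "trial_main", "interaction"),
    statistic_kind = "F",
    statistic = c(fg[1], fs[1], fi[1]),
    df1 = c(dfb[1], dfw[1], dfw[2]),
    df2 = c(dfb[2], dfw[3], dfw[3]),
    p = c(fg[2], fs[2], fi[2]),
    stringsAsFactors = FALSE
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Two-factor mixed ANOVA: group (between) x condition (%s vs %s)\n",
              x$condition_levels[1], x$condition_levels[2]))
  cat(sprintf("  subjects: %s; %d excluded (missing a condition); transform: %s\n",
              paste(sprintf("%s n=%d", names(x$n), as.integer(x$n)),
                    collapse = ", "),
              x$n_excluded, x$transform))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-12s F(%d,%d) = %-8.4g p = %-8.4g %s\n",
                tab$effect[i], tab$df1[i], tab$df2[i], tab$statistic[i],
                tab$p[i], tab$stars[i]))
  }
  invisible(x)
}

#' @export
summary.mixed_anova <- function(object, ...) {
  out <- object$table
  out$transform <- object$transform
  out
}

#' @export
coef.mixed_anova <- function(object, ...) {
  w <- object$data
  gl <- sort(unique(w$group))
  means <- c(tapply(w$y1, w$group, mean)[gl], tapply(w$y2, w$group, mean)[gl])
  names(means) <- c(paste(gl, object$condition_levels[1], sep = ":"),
                    paste(gl, object$condition_levels[2], sep = ":"))
  means
}

# ---- training-trial comparison -----------------------------------------

#' Mann-Whitney U statistic (midranks for ties)
#'
#' Computes U as \eqn{\min(U_1, U_2)} with \eqn{U_1 + U_2 = n_1 n_2},
#' where \eqn{U_1} counts pairs (x, y) with x > y plus half the ties.
#'
#' @param x,y numeric samples.
#' @return named vector: \code{U}, \code{U1}, \code{U2}.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # complete separation: U = 0
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  c(U = min(u1, u2), U1 = u1, U2 = u2)
}

#' Compare EG and CG training-trial values
#'
#' Branches on the assumption checks as in the trial's procedure: an
#' independent (pooled) two-sample t-test when normality and
#' homoscedasticity hold; otherwise a Mann-Whitney U test (midranks,
#' two-sided p from the rank-sum distribution).
#'
#' @param eg,cg numeric values for the experimental and control groups
#'   (>= 2 each).
#' @param alpha significance level for the assumption branch.
#' @return an object of class \code{htest} augmented with
#'   \code{assumptions} (the \code{\link{check_assumptions}} report),
#'   \code{statistic_kind} (\code{"t"} or \code{"U"}) and \code{stars}.
#' @export
compare_training <- function(eg, cg, alpha = 0.05) {
  eg <- eg[!is.na(eg)]; cg <- cg[!is.na(cg)]
  if (length(eg) < 2L || length(cg) < 2L) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  pooled <- c(eg, cg)
  if (diff(range(pooled)) == 0) {
    stop("all-constant data: no comparison possible", call. = FALSE)
  }
  rep_ <- if (min(length(eg), length(cg)) >= 3L) {
    check_assumptions(pooled,
                      rep(c("EG", "CG"), c(length(eg), length(cg))),
                      alpha = alpha)
  } else {
    NULL # too few values to test normality: fall back to the rank test
  }
  if (!is.null(rep_) && rep_$normal && rep_$homoscedastic) {
    ht <- t.test(eg, cg, var.equal = TRUE)
    ht$statistic_kind <- "t"
  } else {
    u <- mann_whitney_u(eg, cg)
    wt <- suppressWarnings(wilcox.test(eg, cg, exact = FALSE,
                                       correct = TRUE))
    ht <- wt
    ht$statistic <- c(U = unname(u["U"]))
    ht$method <- "Mann-Whitney U test (midranks, two-sided)"
    ht$statistic_kind <- "U"
  }
  ht$assumptions <- rep_
  ht$stars <- significance_stars(ht$p.value)
  ht
}

# ---- baseline descriptive table ----------------------------------------

#' Baseline (Day 1) descriptive comparison of the two groups
#'
#' Builds the mean +/- SD / n (%) descriptive table and between-group
#' p-values for the Day 1 baseline data: continuous variables get a
#' two-sample t-test (or, with \code{as_printed = TRUE}, a paired t-test
#' pairing by row order — the test named in some trial reports even though
#' the groups are independent), categorical variables a Pearson chi-squared
#' test without continuity correction.
#'
#' @param data data.frame with columns \code{subject_id}, \code{group}
#'   (EG/CG), \code{variable}, \code{value}; numeric-valued variables are
#'   treated as continuous, others as categorical.
#' @param as_printed use a paired t-test (pairing by row order) for
#'   continuous variables. Default FALSE (independent two-sample t).
#' @return object of class \code{baseline_table}: data.frame with
#'   variable, type, EG, CG, statistic_kind, statistic, p, stars, flag
#'   (\code{"low_expected"} when a chi-squared expected cell count is
#'   below 1).
#' @export
baseline_table <- function(data, as_printed = FALSE) {
  stopifnot(all(c("subject_id", "group", "variable", "value") %in%
                  names(data)))
  rows <- lapply(split(data, data$variable), function(d) {
    eg <- d$value[d$group == "EG"]
    cg <- d$value[d$group == "CG"]
    num <- suppressWarnings(as.numeric(d$value))
    continuous <- !anyNA(num)
    if (continuous) {
      eg <- as.numeric(eg); cg <- as.numeric(cg)
      fmt <- function(v) sprintf("%.3g (± %.2g)", mean(v), sd(v))
      if (diff(range(c(eg, cg))) == 0) {
        st <- 0; p <- 1
      } else if (as_printed) {
        k <- min(length(eg), length(cg))
        dif <- eg[seq_len(k)] - cg[seq_len(k)]
        if (sd(dif) == 0) {
          st <- 0; p <- 1 # identical pairs: no evidence either way
        } else {
          ht <- t.test(eg[seq_len(k)], cg[seq_len(k)], paired = TRUE)
          st <- unname(ht$statistic); p <- ht$p.value
        }
      } else {
        ht <- t.test(eg, cg, var.equal = TRUE)
        st <- unname(ht$statistic); p <- ht$p.value
      }
      data.frame(variable = d$variable[1], type = "continuous",
                 EG = fmt(eg), CG = fmt(cg), statistic_kind = "t",
                 statistic = st, p = p, flag = "ok",
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(d$group, c("EG", "CG")), d$value)
      fmt <- function(g) {
        lv <- colnames(tab)[which.max(colSums(tab))]
        sprintf("%d (%.0f%%)", tab[g, lv], 100 * tab[g, lv] / sum(tab[g, ]))
      }
      if (ncol(tab) < 2L) {
        st <- 0; p <- 1; flag <- "ok"
      } else {
        ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
        st <- unname(ht$statistic); p <- ht$p.value
        flag <- if (any(ht$expected < 1)) "low_expected" else "ok"
      }
      data.frame(variable = d$variable[1], type = "categorical",
                 EG = fmt("EG"), CG = fmt("CG"), statistic_kind = "chi2",
                 statistic = st, p = p, flag = flag,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$stars <- significance_stars(res$p)
  class(res) <- c("baseline_table", "data.frame")
  res
}

#' @export
print.baseline_table <- function(x, ...) {
  cat("Baseline (Day 1) group comparison\n")
  df <- as.data.frame(x)
  df$p <- signif(df$p, 3)
  df$statistic <- signif(df$statistic, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
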