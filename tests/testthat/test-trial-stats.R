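# Assumption checks, mixed ANOVA, training comparison, baseline table.

test_that("sphericity is always satisfied with two within-levels", {
  set.seed(1)
  rep_ <- check_assumptions(rnorm(40), rep(c("EG", "CG"), 20),
                            rep(c("a", "b"), each = 20))
  expect_true(rep_$spherical)
})

test_that("the transform rule fires on log-normal data and not on normal data", {
  set.seed(2)
  hits <- 0L
  for (r in 1:40) {
    v <- exp(rnorm(60, 0, 0.8))
    g <- rep(c("EG", "CG"), 30)
    cnd <- rep(c("a", "b"), each = 30)
    rep_ <- check_assumptions(v, g, cnd)
    if (rep_$transform_applied == "natural_log") hits <- hits + 1L
  }
  expect_gt(hits / 40, 0.5) # log-normal cells: transform in the majority
  # idempotence: already-normal data get no transform, repeatedly
  set.seed(3)
  v <- rnorm(60, 100, 5)
  g <- rep(c("EG", "CG"), 30)
  cnd <- rep(c("a", "b"), each = 30)
  r1 <- check_assumptions(v, g, cnd)
  expect_identical(r1$transform_applied, "none")
  d <- data.frame(subject_id = rep(1:30, 2), group = rep(g[1:30], 2),
                  trial = cnd, mean = v)
  fit <- mixed_anova(d)
  expect_identical(fit$transform, "none")
})

test_that("normality checks are calibrated on normal cells", {
  set.seed(4)
  hits <- 0L
  n_rep <- 300L
  for (r in seq_len(n_rep)) {
    v <- rnorm(48)
    rep_ <- check_assumptions(v, rep(c("EG", "CG"), 24),
                              rep(c("a", "b"), each = 24))
    if (rep_$normal) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.90) # ~95% under the null
  expect_lt(hits / n_rep, 0.99)
})

test_that("mixed ANOVA matches aov and the difference-score t identity", {
  set.seed(5)
  for (r in 1:20) {
    d <- random_mixed_design(sample(5:12, 1))
    fit <- mixed_anova(d, transform = "none")
    tab <- fit$table
    # independent cross-check: aov error strata
    d$trial <- factor(d$trial, c("TestPre", "TestPost"))
    a <- summary(aov(mean ~ group * trial + Error(subject_id / trial),
                     data = d))
    ab <- a[["Error: subject_id"]][[1]]
    aw <- a[["Error: subject_id:trial"]][[1]]
    expect_equal(tab$statistic[tab$effect == "group_main"],
                 ab["group", "F value"], tolerance = 1e-10)
    expect_equal(tab$statistic[tab$effect == "trial_main"],
                 aw["trial", "F value"], tolerance = 1e-10)
    expect_equal(tab$statistic[tab$effect == "interaction"],
                 aw["group:trial", "F value"], tolerance = 1e-10)
    # interaction F = squared pooled t on difference scores
    w <- copgait:::reshape_pair(d$mean, d$subject_id, d$group,
                                as.character(d$trial),
                                c("TestPre", "TestPost"))
    tt <- t.test((w$y2 - w$y1)[w$group == "EG"],
                 (w$y2 - w$y1)[w$group == "CG"], var.equal = TRUE)
    expect_equal(tab$statistic[tab$effect == "interaction"],
                 unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("constant data give all-zero F and subjects missing a condition drop", {
  d <- random_mixed_design(6)
  d$mean <- 42
  fit <- mixed_anova(d, transform = "none")
  expect_equal(fit$table$statistic, c(0, 0, 0))
  expect_equal(fit$table$p, c(1, 1, 1))
  d2 <- random_mixed_design(6)
  d2 <- d2[-3, ] # one subject loses a condition
  fit2 <- mixed_anova(d2, transform = "none")
  expect_identical(fit2$n_excluded, 1L)
  expect_identical(sum(as.integer(fit2$n)), 11L)
})

test_that("stars follow the three printed thresholds", {
  expect_identical(significance_stars(c(0.0005, 0.005, 0.04, 0.06, NA)),
                   c("***", "**", "*", "", ""))
})

test_that("Mann-Whitney U is min(U1, U2) with U1 + U2 = n1 n2", {
  expect_equal(unname(mann_whitney_u(c(1, 2), c(3, 4))["U"]), 0)
  set.seed(6)
  for (r in 1:50) {
    x <- rnorm(sample(5:20, 1))
    y <- rnorm(sample(5:20, 1))
    if (r %% 3 == 0) x <- round(x, 1) # force some ties -> midranks
    u <- mann_whitney_u(x, y)
    bf <- brute_force_u(x, y)
    expect_equal(unname(u["U1"]), unname(bf["U1"]))
    expect_equal(unname(u["U"]), min(bf))
    expect_equal(unname(u["U1"] + u["U2"]), length(x) * length(y))
  }
})

test_that("the training comparison branches on the assumptions", {
  set.seed(7)
  eg <- rnorm(20, 10, 2); cg <- rnorm(20, 11, 2)
  ht <- compare_training(eg, cg)
  expect_identical(ht$statistic_kind, "t")
  expect_equal(ht$p.value, t.test(eg, cg, var.equal = TRUE)$p.value)
  # heavy-tailed data fall back to the U test
  set.seed(8)
  eg2 <- exp(rnorm(20, 0, 1.5)); cg2 <- exp(rnorm(20, 0.3, 1.5))
  ht2 <- compare_training(eg2, cg2)
  expect_identical(ht2$statistic_kind, "U")
  expect_equal(unname(ht2$statistic),
               unname(mann_whitney_u(eg2, cg2)["U"]))
  expect_error(compare_training(rep(3, 10), rep(3, 10)), "constant")
  expect_error(compare_training(1, c(2, 3)), ">= 2")
})

test_that("the baseline table reproduces the chi-squared and t cases", {
  mk <- function(values, variable) {
    data.frame(subject_id = sprintf("s%02d", seq_along(values)),
               group = rep(c("EG", "CG"), each = length(values) / 2),
               variable = variable, value = values,
               stringsAsFactors = FALSE)
  }
  # identical 15/5 proportions: chi2 = 0, p = 1
  cat1 <- mk(c(rep(c("F", "M"), c(15, 5)), rep(c("F", "M"), c(15, 5))),
             "sex")
  bt <- baseline_table(cat1)
  expect_equal(bt$statistic, 0)
  expect_equal(bt$p, 1)
  expect_identical(bt$EG, "15 (75%)")
  # 2x2 counts 17/3 vs 18/2 against the hand-computed Pearson formula
  cat2 <- mk(c(rep(c("no", "yes"), c(17, 3)), rep(c("no", "yes"), c(18, 2))),
             "fallrisk")
  o <- matrix(c(17, 3, 18, 2), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(baseline_table(cat2)$statistic, sum((o - e)^2 / e),
               tolerance = 1e-12)
  # identical continuous samples: p = 1
  cont <- mk(rep(c(61, 72, 58, 80, 65), 2), "age")
  bt3 <- baseline_table(cont)
  expect_identical(bt3$statistic_kind, "t")
  expect_equal(bt3$p, 1, tolerance = 1e-10)
  # as-printed paired mode pairs by row order
  bt4 <- baseline_table(cont, as_printed = TRUE)
  expect_equal(bt4$p, 1, tolerance = 1e-10)
})

test_that("the full battery reports the injected interaction", {
  eff <- effect_spec("ss_cop_efficiency", "interaction", -1.5,
                     c("TestPre", "TestPost"))
  coh <- simulate_cohort(20, seed = 9, fidelity = "summary",
                         effects = list(eff))
  res <- trial_statistics(coh$summaries, coh$clinical)
  row <- res[res$metric == "ss_cop_efficiency" & res$comparison == "Test" &
               res$effect == "interaction" & res$statistic == "mean", ]
  expect_identical(nrow(row), 1L)
  expect_lt(row$p, 0.05)
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
})
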