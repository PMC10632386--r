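# Cyclogram construction, CISP location, single-stance COP efficiency.

test_that("straight-chord samples are exactly 100% efficient", {
  u <- seq(0, 1, length.out = 50)
  expect_identical(ss_cop_efficiency(3 + 20 * u, -2 + 5 * u), 100)
})

test_that("a semicircular arc is 2/pi efficient", {
  th <- seq(0, pi, length.out = 2000)
  eff <- ss_cop_efficiency(5 * cos(th), 5 * sin(th))
  expect_equal(eff, 200 / pi, tolerance = 1e-5)
})

test_that("efficiency matches the loop arc-length oracle and its bounds", {
  set.seed(11)
  for (r in 1:200) {
    n <- sample(3:60, 1)
    x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
    got <- ss_cop_efficiency(x, y)
    expect_equal(got, loop_efficiency(x, y), tolerance = 1e-9)
    expect_gt(got, 0)
    expect_lte(got, 100 + 1e-12)
  }
  expect_error(ss_cop_efficiency(1, 1), "2 paired")
  expect_error(ss_cop_efficiency(c(1, 1), c(2, 2)), "zero path")
})

test_that("efficiency and CISP percentages are rigid-motion and scale invariant", {
  set.seed(21)
  x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
  e0 <- ss_cop_efficiency(x, y)
  th <- 1.1
  xr <- cos(th) * x - sin(th) * y + 7
  yr <- sin(th) * x + cos(th) * y - 3
  expect_equal(ss_cop_efficiency(xr, yr), e0, tolerance = 1e-10)
  expect_equal(ss_cop_efficiency(3.7 * x, 3.7 * y), e0, tolerance = 1e-10)

  traj <- random_cyclogram(40)
  ci <- find_cisp(traj)
  sc <- traj
  sc$x_ml_rel <- 2.5 * sc$x_ml_rel
  sc$y_ap_rel <- 2.5 * sc$y_ap_rel
  ci_sc <- find_cisp(sc)
  expect_equal(ci_sc$cisp_ap_pct, ci$cisp_ap_pct, tolerance = 1e-10)
  expect_equal(ci_sc$cisp_ml_pct, ci$cisp_ml_pct, tolerance = 1e-10)
})

test_that("the symmetric X-crossing sits mid-extent on the midline", {
  traj <- data.frame(x_ml_rel = c(-2, 2, 2, -2), y_ap_rel = c(0, 4, 0, 4),
                     t = 1:4, phase = "double_support",
                     stringsAsFactors = FALSE)
  ci <- find_cisp(traj)
  expect_equal(unname(ci$point), c(0, 2))
  expect_equal(ci$cisp_ap_pct, 50)
  expect_equal(ci$cisp_ml_pct, 0)
})

test_that("find_cisp agrees with the brute-force all-pairs oracle", {
  set.seed(31)
  n_checked <- 0L
  for (r in 1:150) {
    traj <- random_cyclogram(sample(15:40, 1))
    got <- find_cisp(traj)
    exp_ <- brute_force_cisp(traj$x_ml_rel, traj$y_ap_rel)
    if (is.null(exp_)) {
      expect_identical(got$flag, "no_crossing")
    } else {
      n_checked <- n_checked + 1L
      expect_equal(unname(got$point), unname(exp_$point),
                   tolerance = 1e-9)
      expect_identical(got$n_crossings, exp_$n)
    }
  }
  expect_gt(n_checked, 80) # most random cyclograms do cross
})

test_that("build_cyclogram anchors, detrends and is translation invariant", {
  tr <- quick_trial(duration_s = 25)
  ff <- normalize_passes(tr$footfalls)
  samp <- ff[ff$pass_id == 1, ]
  ft <- copgait:::footfall_table(samp)
  mcop <- copgait:::.merge_cop(samp, ft, ft$heel_strike_t[1],
                               ft$heel_strike_t[3])
  traj <- build_cyclogram(mcop)
  expect_equal(traj$y_ap_rel[1], 0) # anchored at the leading heel strike
  expect_setequal(unique(traj$phase),
                  c("single_stance_L", "single_stance_R", "double_support"))
  shifted <- mcop
  shifted$x_ml <- shifted$x_ml + 40
  shifted$y_ap <- shifted$y_ap - 17
  traj2 <- build_cyclogram(shifted)
  expect_equal(traj2$x_ml_rel, traj$x_ml_rel, tolerance = 1e-10)
  expect_equal(traj2$y_ap_rel, traj$y_ap_rel, tolerance = 1e-10)
})

test_that("zero-meander gait gives constant-x single stance and 100% efficiency", {
  sub <- quick_subject(cop_waviness = 0, perturbation_susceptibility = 0)
  tr <- simulate_trial(sub, "GaitBaseline", duration_s = 30, seed = 9,
                       step_placement_sd_cm = 0)
  ff <- normalize_passes(tr$footfalls)
  cm <- cycle_metrics(ff)
  effs <- c(cm$ss_cop_efficiency_L, cm$ss_cop_efficiency_R)
  expect_true(all(abs(effs[!is.na(effs)] - 100) < 1e-9))
  samp <- ff[ff$pass_id == 1, ]
  ft <- copgait:::footfall_table(samp)
  mcop <- copgait:::.merge_cop(samp, ft, ft$heel_strike_t[1],
                               ft$heel_strike_t[3])
  traj <- build_cyclogram(mcop)
  for (ph in c("single_stance_L", "single_stance_R")) {
    xs <- traj$x_ml_rel[traj$phase == ph]
    if (length(xs) > 1) expect_lt(diff(range(xs)), 1e-9)
  }
})

test_that("mean efficiency decreases as COP waviness grows", {
  effs <- vapply(c(0.05, 0.2, 0.45), function(w) {
    tr <- simulate_trial(quick_subject(cop_waviness = w), "GaitBaseline",
                         duration_s = 40, seed = 12)
    cm <- cycle_metrics(normalize_passes(tr$footfalls))
    mean(c(cm$ss_cop_efficiency_L, cm$ss_cop_efficiency_R), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(effs) < 0))
})

test_that("a lateral step-width bias shifts the CISP ML percentage monotonically", {
  ml_means <- vapply(c(0, 2, 4), function(bias) {
    sub <- quick_subject()
    tr <- simulate_trial(sub, "GaitBaseline", duration_s = 60, seed = 15,
                         step_placement_sd_cm = 0)
    ff <- tr$footfalls
    # widen right steps: move every R footfall bias cm further right
    ff$cop_x_cm <- ff$cop_x_cm +
      ifelse(ff$foot == "R", bias, 0) * ifelse(ff$pass_id %% 2 == 1, 1, -1)
    cm <- cycle_metrics(normalize_passes(ff))
    mean(cm$cisp_ml_pct, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(ml_means) < 0) || all(diff(ml_means) > 0))
})

test_that("per-cycle metric count equals the number of complete cycles", {
  tr <- quick_trial(duration_s = 30)
  cm <- cycle_metrics(normalize_passes(tr$footfalls))
  s <- detect_strides(tr$footfalls)
  expect_identical(nrow(cm), nrow(s)) # one cycle per stride
  expect_true(all(is.na(cm$cisp_ap_pct[cm$flag == "no_crossing"])))
})
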