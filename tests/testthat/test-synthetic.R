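# Synthetic protocol generator: schedules, recordings, cohorts, clinical
# scores.

test_that("perturbation schedules follow the protocol semantics", {
  p <- pbt_protocol()
  # CG training and both unperturbed gait trials get no pulses
  expect_identical(nrow(perturbation_schedule(600, p, "Training", "CG", 70,
                                              seed = 1)), 0L)
  expect_identical(nrow(perturbation_schedule(300, p, "GaitBaseline", "EG",
                                              70, seed = 1)), 0L)
  # test trials: lateral only, fixed width, magnitude = 0.10 * m * g
  sch <- perturbation_schedule(300, p, "TestPre", "EG", 70, seed = 1)
  expect_gt(nrow(sch), 10)
  expect_true(all(sch$width == 0.100))
  expect_true(all(sch$direction %in% c("left", "right")))
  expect_true(all(abs(sch$magnitude - 68.67) < 1e-9))
  # EG training: diagonal directions
  tr <- perturbation_schedule(600, p, "Training", "EG", 70, seed = 1)
  expect_true(all(tr$direction %in% c("left-up", "left-down", "right-up",
                                      "right-down")))
})

test_that("schedules are reproducible, non-overlapping, gap-bounded", {
  p <- pbt_protocol()
  a <- perturbation_schedule(300, p, "TestPost", "CG", 80, seed = 11)
  b <- perturbation_schedule(300, p, "TestPost", "CG", 80, seed = 11)
  expect_identical(a, b)
  gaps <- diff(a$onset_time)
  expect_true(all(gaps >= a$width[1])) # no overlap
  expect_true(all(gaps >= p$min_gap_s - 1e-12 &
                    gaps <= p$max_gap_s + 1e-12))
  expect_true(all(a$onset_time + a$width <= 300))
  expect_error(perturbation_schedule(-5, p, "TestPre", "EG", 70),
               "positive")
  expect_warning(
    out <- perturbation_schedule(2, p, "TestPre", "EG", 70, seed = 1),
    "no pulses"
  )
  expect_identical(nrow(out), 0L)
})

test_that("zero-waviness unperturbed gait yields exactly collinear COP", {
  sub <- quick_subject(cop_waviness = 0, perturbation_susceptibility = 0)
  tr <- simulate_trial(sub, "GaitBaseline", duration_s = 30, seed = 5,
                       step_placement_sd_cm = 0)
  for (ii in split(seq_len(nrow(tr$footfalls)),
                   tr$footfalls$footfall_id)) {
    expect_lt(diff(range(tr$footfalls$cop_x_cm[ii])), 1e-12)
  }
})

test_that("recordings are byte-identical under a fixed seed", {
  sub <- quick_subject()
  a <- simulate_trial(sub, "TestPre", duration_s = 30, seed = 7)
  b <- simulate_trial(sub, "TestPre", duration_s = 30, seed = 7)
  expect_identical(a$footfalls, b$footfalls)
  expect_error(simulate_trial(sub, "TestPre", duration_s = 1),
               "too short")
})

test_that("stride parameters are recovered from the ground truth log", {
  sub <- quick_subject()
  tr <- simulate_trial(sub, "GaitBaseline", duration_s = 90, seed = 3)
  s <- detect_strides(tr$footfalls)
  ok <- s$flag == "ok"
  expect_gte(nrow(s), 60)
  se <- function(v) sd(v) / sqrt(length(v))
  expect_lt(abs(mean(s$stride_length) - tr$truth$stride_length),
            2 * se(s$stride_length))
  expect_lt(abs(mean(s$stride_velocity) - tr$truth$stride_velocity),
            2 * se(s$stride_velocity))
  expect_lt(abs(mean(s$single_support_time[ok]) -
                  tr$truth$single_support_time),
            2 * se(s$single_support_time[ok]))
})

test_that("cohorts are balanced and reject contradictory effects", {
  coh <- simulate_cohort(20, seed = 1, fidelity = "summary")
  expect_identical(nrow(coh$subjects), 40L)
  expect_identical(as.vector(table(coh$subjects$group)[c("EG", "CG")]),
                   c(20L, 20L))
  expect_error(
    simulate_cohort(3, seed = 1, fidelity = "summary",
                    effects = list(
                      effect_spec("stride_length", "interaction", 1),
                      effect_spec("stride_length", "interaction", -1)
                    )),
    "contradictory"
  )
  # null configuration: EG and CG generating means identical in the truth
  tr <- coh$truth
  for (m in unique(tr$metric)) {
    mt <- tr[tr$metric == m & tr$trial == "TestPre", ]
    expect_lt(abs(mean(mt$truth_mean[mt$group == "EG"]) -
                    mean(mt$truth_mean[mt$group == "CG"])),
              5 * sd(mt$truth_mean) / sqrt(10))
  }
})

test_that("injected effects show up in the ground-truth log", {
  eff <- effect_spec("ss_cop_efficiency", "interaction", -1.5,
                     c("TestPre", "TestPost"))
  coh <- simulate_cohort(10, seed = 2, fidelity = "summary",
                         effects = list(eff))
  tr <- coh$truth[coh$truth$metric == "ss_cop_efficiency", ]
  shift <- function(g) {
    mean(tr$truth_mean[tr$group == g & tr$trial == "TestPost"]) -
      mean(tr$truth_mean[tr$group == g & tr$trial == "TestPre"])
  }
  expect_lt(shift("EG"), -0.5) # EG pushed down at TestPost
  expect_lt(abs(shift("CG")), 0.5)
})

test_that("clinical scores respect instrument ranges", {
  subs <- draw_subjects(20, seed = 4)
  sc <- generate_clinical_scores(subs, seed = 4)
  inst <- clinical_instruments()
  for (m in inst$instrument) {
    v <- sc$score[sc$instrument == m]
    expect_true(all(v >= inst$min[inst$instrument == m] &
                      v <= inst$max[inst$instrument == m]))
  }
  bbs <- sc$score[sc$instrument == "BBS"]
  expect_true(all(bbs >= 0 & bbs <= 56))
  fes <- sc$score[sc$instrument == "FES_I"]
  expect_true(all(fes >= 16 & fes <= 64))
  expect_identical(sort(unique(sc$session)), c("Day1", "Day2"))
  # degenerate zero-variance generator: Day 1 equals Day 2
  sc0 <- generate_clinical_scores(subs, seed = 4, noise_scale = 0)
  d1 <- sc0[sc0$session == "Day1", c("subject_id", "instrument", "score")]
  d2 <- sc0[sc0$session == "Day2", c("subject_id", "instrument", "score")]
  expect_equal(d1$score, d2$score)
  expect_error(
    generate_clinical_scores(subs, list(effect_spec("BBS", "interaction",
                                                    1, c("Day1", "Day2")))),
    NA
  )
  expect_error(effect_spec("NotAScale", "interaction", 1), "unknown")
})
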