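test_that("participant profiles match the target population moments", {
  pr <- simulate_participants(10000, seed = 1)
  expect_lt(abs(mean(pr$rspan) - 9.42), 0.1)
  expect_lt(abs(mean(pr$vocab) - 13.0), 0.1)
  expect_lt(abs(mean(pr$pta_db) - 6.88), 0.15)
  expect_true(all(pr$rspan >= 0 & pr$rspan <= 15))
  expect_true(all(pr$vocab >= 0 & pr$vocab <= 20))
  expect_true(all(pr$pause_tendency > 0))
  # unit-median multiplier
  expect_lt(abs(median(pr$pause_tendency) - 1), 0.03)

  expect_identical(simulate_participants(50, seed = 3),
                   simulate_participants(50, seed = 3))
  expect_error(simulate_participants(0), ">= 1")
})

test_that("cell expectations follow the stated linear construction", {
  # hand-computed single cell at atten = 1:
  # base 40, clear, self-paced, high-pred, main level
  cal1 <- effect_calibration(interaction_atten = 1)
  ex1 <- cell_expectations(cal1)
  cell <- ex1$expected_pct[ex1$level == "main" & ex1$predictability == "high" &
                           ex1$format == "selfpaced" & ex1$clarity == "clear"]
  expect_equal(cell, 40 + 4.78 + 6.83 + 7.85 + (5.61 + 9.78))
  # reference cell anchors at base_pct for any attenuation
  for (a in c(1, 0.55, 0.3)) {
    ex <- cell_expectations(effect_calibration(interaction_atten = a))
    ref <- ex$expected_pct[ex$level == "detail" & ex$predictability == "low" &
                           ex$format == "continuous" & ex$clarity == "vocoded"]
    expect_equal(ref, 40)
  }
})

test_that("marginal contrasts equal the calibration deltas symbolically", {
  # analytic expectation: unweighted means over the 24 design cells
  cal <- effect_calibration()
  ex <- cell_expectations(cal)
  contrast <- function(var, a, b)
    mean(ex$expected_pct[ex[[var]] == a]) - mean(ex$expected_pct[ex[[var]] == b])
  expect_equal(contrast("predictability", "high", "low"), cal$d_pred)
  expect_equal(contrast("level", "main", "mid"), cal$d_main_mid)
  expect_equal(contrast("level", "mid", "detail"), cal$d_mid_detail)
  expect_equal(contrast("format", "selfpaced", "continuous"), cal$d_format)
  expect_equal(contrast("clarity", "clear", "vocoded"), cal$d_clarity)
})

test_that("hierarchy-slope attenuation equals the calibration ratio", {
  for (a in c(1, 0.7, 0.55, 0.3)) {
    ex <- cell_expectations(effect_calibration(interaction_atten = a))
    slope <- function(pred) {
      m <- tapply(ex$expected_pct[ex$predictability == pred],
                  ex$level[ex$predictability == pred], mean)
      (m[["main"]] - m[["detail"]]) / 2
    }
    expect_equal(slope("low") / slope("high"), a, tolerance = 1e-12)
    if (a < 1) expect_lt(slope("low"), slope("high"))
  }
})

test_that("infeasible calibrations are refused before sampling", {
  expect_error(effect_calibration(base_pct = 90), "infeasible")
  expect_error(effect_calibration(base_pct = -10), "infeasible")
  expect_error(effect_calibration(interaction_atten = 0), "interaction_atten")
  expect_error(effect_calibration(sd_item = -1), "SDs")
})

test_that("the packaged default calibration file matches the defaults", {
  cal <- read_calibration(
    system.file("extdata", "paper_defaults.json", package = "vocrecall"))
  expect_equal(cal, effect_calibration())
  tmp <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, tmp)
  expect_equal(read_calibration(tmp), cal)
})

test_that("zero effects with zero SDs leave only binomial variation", {
  cal0 <- effect_calibration(base_pct = 50, d_pred = 0, d_main_mid = 0,
                             d_mid_detail = 0, d_format = 0, d_clarity = 0,
                             interaction_atten = 1, sd_participant = 0,
                             sd_item = 0, sd_item_slope = 0,
                             rspan_loading = 0, pause_loading_between = 0,
                             pause_loading_within = 0)
  expect_true(all(cell_expectations(cal0)$expected_pct == 50))
  plan <- build_design(24, default_passages(), seed = 1)
  parts <- simulate_participants(24, seed = 2)
  tr <- simulate_recall(plan, parts, cal0, seed = 3)
  expect_true(all(tr$n_recalled <= tr$n_props))
  # overall proportion near 0.5 within 4 binomial SEs
  n_tot <- sum(tr$n_props)
  se <- sqrt(0.25 / n_tot)
  expect_lt(abs(sum(tr$n_recalled) / n_tot - 0.5), 4 * se)
})

test_that("recall simulation is seed-deterministic end-to-end", {
  s1 <- simulate_study(seed = 11)
  s2 <- simulate_study(seed = 11)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$pauses, s2$pauses)
  s3 <- simulate_study(seed = 12)
  expect_false(identical(s1$trials$n_recalled, s3$trials$n_recalled))
})

test_that("pause generator matches its lognormal moments when iid", {
  # sdlog 0 for participant and passage components -> pauses iid lognormal
  parts <- simulate_participants(264, seed = 1, pause_sdlog = 0)
  plan <- build_design(264, default_passages(), seed = 2)
  pp <- simulate_pauses(plan, parts, seed = 3, within_sdlog = 0)
  p <- pp$pause_s[1:10000]
  expect_lt(abs(mean(p) - 2.43), 0.1)   # ~3.7 iid SEs
  expect_lt(abs(sd(p) - 2.71), 0.35)
  expect_true(all(p > 0))
  expect_identical(pp, simulate_pauses(plan, parts, seed = 3,
                                       within_sdlog = 0))
})

test_that("pauses exist only for self-paced trials and require them", {
  sim <- simulate_study(seed = 4)
  sp_keys <- unique(paste(sim$plan$participant, sim$plan$passage)[
    sim$plan$format == "selfpaced"])
  expect_setequal(unique(paste(sim$pauses$participant, sim$pauses$passage)),
                  sp_keys)
  cont_only <- sim$plan[sim$plan$format == "continuous", ]
  class(cont_only) <- class(sim$plan)
  expect_error(simulate_pauses(cont_only, sim$participants, seed = 1),
               "self-paced")
})

test_that("zero pause-recall coupling yields no association", {
  cal0 <- effect_calibration(pause_loading_between = 0,
                             pause_loading_within = 0)
  rs <- vapply(1:10, function(s) {
    sim <- simulate_study(calibration = cal0, seed = 2000 + s)
    mp <- tapply(sim$pauses$pause_s, sim$pauses$participant, mean)
    mr <- tapply(sim$trials$proportion, sim$trials$participant, mean)
    cor(mp[names(mr)], mr)
  }, numeric(1))
  # mean correlation ~ 0 within 3 SEs (SE ~ 0.07 for 10 reps of n = 24)
  expect_lt(abs(mean(rs)), 0.21)
})
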