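# deterministic, noise-free table: proportions set to the expected cell means
noise_free_table <- function(calibration = effect_calibration(), n = 8) {
  plan <- build_design(n, default_passages(), seed = 1)
  ex <- cell_expectations(calibration)
  mu <- setNames(ex$expected_pct, paste(ex$level, ex$predictability,
                                        ex$format, ex$clarity))
  rows <- plan[rep(seq_len(nrow(plan)), each = 3), ]
  rows$level <- rep(c("detail", "mid", "main"), nrow(plan))
  rows$n_props <- 100L
  rows$proportion <- mu[paste(rows$level, rows$predictability, rows$format,
                              rows$clarity)] / 100
  rows$n_recalled <- rows$proportion * 100
  rownames(rows) <- NULL
  class(rows) <- c("cell_table", "data.frame")
  rows
}

test_that("on noise-free data the mixed model reproduces the cell means", {
  tab <- noise_free_table()
  m <- fit_recall_model(tab, model_spec(
    interactions = "hierarchy:predictability"))
  # fixed effects fully explain the generating surface: fitted == observed
  expect_lt(max(abs(fitted(m) - 100 * tab$proportion)), 1e-6)
  # fixed-effect contrasts agree with plain cell-mean contrasts
  expect_equal(unname(coef(m)["predictabilityhigh"] +
                 mean(c(0, coef(m)[["levelmid:predictabilityhigh"]],
                        coef(m)[["levelmain:predictabilityhigh"]]))),
               7.85, tolerance = 1e-6)
  expect_equal(marginal_effect(tab, "predictability", n_boot = 0)$estimate,
               7.85, tolerance = 1e-9)
})

test_that("model refits are deterministic and flag convergence diagnostics", {
  sim <- simulate_study(seed = 21)
  m1 <- fit_recall_model(sim$trials)
  m2 <- fit_recall_model(sim$trials)
  expect_equal(as.numeric(logLik(m1)), as.numeric(logLik(m2)))
  expect_type(m1$converged, "logical")
  expect_s4_class(m1$fit, "lmerMod")
  # ML, not REML
  expect_false(lme4::isREML(m1$fit))
  expect_error(fit_recall_model(sim$trials[sim$trials$participant == "P01", ]),
               "non-degenerate")
})

test_that("LRT df bookkeeping matches the per-predictor null-model scheme", {
  sim <- simulate_study(seed = 5)
  spec <- model_spec(interactions = "hierarchy:predictability")
  # main effect removed together with its retained interaction
  expect_equal(lrt(sim$trials, spec, "hierarchy")$df, 4L)
  expect_equal(lrt(sim$trials, spec, "predictability")$df, 3L)
  expect_equal(lrt(sim$trials, spec, "hierarchy:predictability")$df, 2L)
  expect_equal(lrt(sim$trials, spec, "format")$df, 1L)
  expect_error(lrt(sim$trials, model_spec(), "hierarchy:format"), "not in")
})

test_that("nested log-likelihoods are ordered and chisq is non-negative", {
  sim <- simulate_study(seed = 6)
  spec <- model_spec(interactions = "hierarchy:predictability")
  for (pred in c("hierarchy", "predictability", "format", "clarity",
                 "hierarchy:predictability")) {
    t <- lrt(sim$trials, spec, pred)
    expect_gte(t$chisq, 0)
    expect_true(t$p >= 0 && t$p <= 1)
  }
})

test_that("reverse selection returns main-effects specs unchanged", {
  sim <- simulate_study(seed = 7)
  rs <- reverse_select(sim$trials, model_spec())
  expect_equal(rs$spec$interactions, character(0))
  expect_equal(rs$spec$fixed, c("hierarchy", "predictability", "format",
                                "clarity"))
  expect_equal(nrow(rs$steps), 0L)
})

test_that("reverse selection excludes interactions absent from the truth", {
  # no interactions generated (atten = 1): false retentions should be rare
  cal <- effect_calibration(interaction_atten = 1)
  n_kept <- vapply(1:20, function(s)
    length(reverse_select(simulate_study(calibration = cal,
                                         seed = 300 + s)$trials
                          )$spec$interactions), numeric(1))
  # majority of replicates exclude everything; total false retentions
  # bounded as a Binomial(120, 0.05) tail
  expect_gte(sum(n_kept == 0), 10)
  expect_lte(sum(n_kept), 12)
})

test_that("reverse selection retains a generated hierarchy interaction", {
  # strong attenuation: retention in a clear majority
  strong <- vapply(1:20, function(s)
    "hierarchy:predictability" %in%
      reverse_select(simulate_study(
        calibration = effect_calibration(interaction_atten = 0.3),
        seed = 200 + s)$trials)$spec$interactions, logical(1))
  expect_gte(sum(strong), 12)
  # default attenuation: retention well above the ~5% chance rate
  default <- vapply(1:40, function(s)
    "hierarchy:predictability" %in%
      reverse_select(simulate_study(seed = 100 + s)$trials
                     )$spec$interactions, logical(1))
  expect_gte(sum(default), 8)
})

test_that("marginal effects compute unweighted cell-mean contrasts", {
  # identical proportions everywhere -> 0
  plan <- build_design(8, default_passages(), seed = 1)
  rows <- plan[rep(seq_len(nrow(plan)), each = 3), ]
  rows$level <- rep(c("detail", "mid", "main"), nrow(plan))
  flat <- manual_cell_table(data.frame(rows, proportion = 0.4))
  expect_equal(marginal_effect(flat, "clarity", n_boot = 0)$estimate, 0)
  expect_equal(hierarchy_slope(flat), 0)

  # hand table: two participants, proportions 0.5/0.5 (low) vs 0.6/0.7 (high)
  hand <- manual_cell_table(data.frame(
    participant = c("a", "b", "a", "b"),
    passage = c("x", "x", "y", "y"),
    format = "continuous", clarity = "clear",
    predictability = c("low", "low", "high", "high"),
    level = "mid", n_props = 10L,
    proportion = c(0.5, 0.5, 0.6, 0.7)))
  expect_warning(
    est <- marginal_effect(hand, "predictability", n_boot = 0)$estimate,
    "unbalanced")
  expect_equal(est, 15)
})

test_that("hierarchy_slope is the (main - detail)/2 linear contrast", {
  plan <- build_design(8, default_passages(), seed = 1)
  rows <- plan[rep(seq_len(nrow(plan)), each = 3), ]
  rows$level <- rep(c("detail", "mid", "main"), nrow(plan))
  prof <- manual_cell_table(data.frame(
    rows, proportion = c(0.3, 0.4, 0.5)[match(rows$level,
                                              c("detail", "mid", "main"))]))
  expect_equal(hierarchy_slope(prof), 10)
  expect_equal(hierarchy_slope(prof, predictability = "low"), 10)
  no_main <- prof[prof$level != "main", ]
  class(no_main) <- class(prof)
  expect_error(hierarchy_slope(no_main), "three hierarchy levels")
})

test_that("bootstrap CIs are seeded and bracket the estimate", {
  sim <- simulate_study(seed = 8)
  e1 <- marginal_effect(sim$trials, "format", n_boot = 60, seed = 9)
  e2 <- marginal_effect(sim$trials, "format", n_boot = 60, seed = 9)
  expect_equal(e1$ci, e2$ci)
  expect_true(e1$ci[1] < e1$estimate && e1$estimate < e1$ci[2])
})

test_that("pause analyses detect the generated couplings", {
  # between-participant association significant in a clear majority
  res <- vapply(1:25, function(s) {
    sim <- simulate_study(seed = 900 + s)
    pa <- pause_analyses(sim$trials, sim$pauses)
    c(pa$between$p < 0.05, pa$within$slope > 0, pa$between$df2)
  }, numeric(3))
  expect_gte(sum(res[1, ]), 14)
  expect_gte(sum(res[2, ]), 16)        # positive within-passage slope
  expect_equal(unique(res[3, ]), 22)   # F(1, n - 2) with n = 24
})

test_that("pause analyses validate degenerate input", {
  sim <- simulate_study(seed = 31)
  few <- sim$trials[sim$trials$participant %in% c("P01", "P02"), ]
  class(few) <- class(sim$trials)
  expect_error(pause_analyses(few, sim$pauses), ">= 3 participants")
  flatp <- sim$pauses
  flatp$pause_s <- 2
  expect_error(pause_analyses(sim$trials, flatp), "degenerate")
})

test_that("covariate predictors are tested by 1-df LRTs with validation", {
  sim <- simulate_study(seed = 32)
  res <- covariate_predictors(sim$trials, sim$participants)
  expect_equal(res$covariate, c("rspan", "vocab", "pta_db"))
  expect_true(all(res$df == 1L))
  expect_true(all(res$chisq >= 0))
  bad <- sim$participants
  bad$rspan <- 7L
  expect_error(covariate_predictors(sim$trials, bad, "rspan"), "variance")
  expect_error(covariate_predictors(sim$trials, sim$participants, "nope"),
               "missing covariate")
})

test_that("the R-span covariate is detected at its default loading", {
  sig <- vapply(1:30, function(s) {
    sim <- simulate_study(seed = 3000 + s)
    covariate_predictors(sim$trials, sim$participants, "rspan")$p < 0.05
  }, logical(1))
  expect_gte(sum(sig), 14)
})
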