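#' Pause-duration analyses
#'
#' The two pause/recall relations examined in self-paced listening:
#' \describe{
#'   \item{between}{Do participants who tend to pause longer between
#'     segments recall more overall? Ordinary least-squares regression of
#'     each participant's mean recall percentage on their mean pause
#'     duration; F with (1, n - 2) df.}
#'   \item{within}{Does pausing longer while self-pacing a particular
#'     passage go with better recall of that passage? Mixed model of
#'     passage-level recall on the within-participant-centered passage mean
#'     pause with participant random intercepts, tested by likelihood-ratio
#'     against the no-pause null (chi-square, 1 df).}
#' }
#'
#' @param trials a `cell_table` of recall outcomes.
#' @param pauses a pause table from [simulate_pauses()] (columns
#'   `participant`, `passage`, `pause_s`).
#' @param alpha significance level used only for the printed summary.
#' @return An object of class `pause_analysis`: list with elements
#'   `between` (`slope`, `F`, `df1`, `df2`, `p`) and `within` (an
#'   `lrt_result`-like list).
#' @export
pause_analyses <- function(trials, pauses, alpha = 0.05) {
  stopifnot(is.data.frame(trials), is.data.frame(pauses))
  if (!all(c("participant", "passage", "pause_s") %in% names(pauses)))
    stop2("'pauses' needs columns participant, passage, pause_s")
  sp <- trials[trials$format == "selfpaced", , drop = FALSE]
  if (nrow(sp) == 0) stop2("no self-paced trials present")

  # between participants: overall mean recall vs mean pause
  p_pause <- tapply(pauses$pause_s, pauses$participant, mean)
  p_recall <- tapply(100 * trials$proportion, trials$participant, mean)
  common <- intersect(names(p_pause), names(p_recall))
  if (length(common) < 3) stop2("need >= 3 participants with pauses")
  x <- p_pause[common]; y <- p_recall[common]
  if (var(x) == 0)
    stop2("degenerate regressor: pause durations are constant across participants")
  fit <- lm(y ~ x)
  fs <- summary(fit)$fstatistic
  between <- list(slope = unname(coef(fit)[2]), F = unname(fs[1]),
                  df1 = unname(fs[2]), df2 = unname(fs[3]),
                  p = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))

  # within participants: passage-level recall vs centered passage mean pause
  pp_recall <- aggregate(proportion ~ participant + passage, data = sp,
                         FUN = mean)
  pp_recall$pct <- 100 * pp_recall$proportion
  pp_pause <- aggregate(pause_s ~ participant + passage, data = pauses,
                        FUN = mean)
  m <- merge(pp_recall, pp_pause, by = c("participant", "passage"))
  pm <- tapply(m$pause_s, m$participant, mean)
  m$pause_c <- m$pause_s - pm[m$participant]
  if (var(m$pause_c) == 0)
    stop2("degenerate regressor: no within-participant pause variation")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  f1 <- suppressWarnings(lme4::lmer(pct ~ pause_c + (1 | participant),
                                    data = m, REML = FALSE, control = ctrl))
  f0 <- suppressWarnings(lme4::lmer(pct ~ 1 + (1 | participant),
                                    data = m, REML = FALSE, control = ctrl))
  chisq <- max(0, 2 * (as.numeric(logLik(f1)) - as.numeric(logLik(f0))))
  within <- structure(list(predictor = "passage mean pause", chisq = chisq,
                           df = 1L,
                           p = pchisq(chisq, 1, lower.tail = FALSE),
                           slope = unname(lme4::fixef(f1)["pause_c"])),
                      class = "lrt_result")
  structure(list(between = between, within = within, alpha = alpha),
            class = "pause_analysis")
}

#' @export
print.pause_analysis <- function(x, ...) {
  b <- x$between
  cat(sprintf("Between participants: F(%d, %d) = %.2f, p = %.4g (slope %.2f pp/s)\n",
              b$df1, b$df2, b$F, b$p, b$slope))
  w <- x$within
  cat(sprintf("Within participants:  chisq(%d) = %.2f, p = %.4g (slope %.2f pp/s)\n",
              w$df, w$chisq, w$p, w$slope))
  invisible(x)
}

#' Covariate predictors of overall recall
#'
#' Adds each participant covariate (R-span working-memory score, vocabulary,
#' hearing acuity) to the recall model as a standardized continuous fixed
#' effect and tests it by likelihood ratio against the model without it
#' (1 df each).
#'
#' @param table a `cell_table`.
#' @param participants a [simulate_participants()]-style data.frame.
#' @param covariates columns of `participants` to test (default `rspan`,
#'   `vocab`, `pta_db`).
#' @param spec the final [model_spec()] the covariates are added to.
#' @return A data.frame with one row per covariate: `covariate`, `chisq`,
#'   `df`, `p`.
#' @export
covariate_predictors <- function(table, participants,
                                 covariates = c("rspan", "vocab", "pta_db"),
                                 spec = model_spec(
                                   interactions = "hierarchy:predictability")) {
  stopifnot(is.data.frame(participants))
  missing_cols <- setdiff(covariates, names(participants))
  if (length(missing_cols))
    stop2("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  null_fit <- fit_recall_model(table, spec)
  res <- lapply(covariates, function(cv) {
    vals <- participants[[cv]][match(table$participant,
                                     participants$participant)]
    if (anyNA(vals)) stop2("covariate '", cv, "' missing for some participants")
    if (sd(vals) == 0) stop2("covariate '", cv, "' has no variance")
    tab <- table
    tab$cov_z <- (vals - mean(vals)) / sd(vals)
    full_fit <- fit_recall_model(tab, spec, extra_fixed = "cov_z")
    t <- lrt_from_fits(full_fit, null_fit, cv)
    data.frame(covariate = cv, chisq = t$chisq, df = t$df, p = t$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
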