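CANON_MAIN <- c("hierarchy", "predictability", "format", "clarity")
TERM_VAR <- c(hierarchy = "level", predictability = "predictability",
              format = "format", clarity = "clarity")

canon_term <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (!all(parts %in% CANON_MAIN))
    stop2("unknown predictor component in '", term, "'; known: ",
          paste(CANON_MAIN, collapse = ", "))
  paste(parts[order(match(parts, CANON_MAIN))], collapse = ":")
}

#' Mixed-model specification for the recall analysis
#'
#' Fixed effects are named by the design factors (`"hierarchy"`,
#' `"predictability"`, `"format"`, `"clarity"`) and interactions by
#' colon-joined names (e.g. `"hierarchy:predictability"`). The random
#' structure follows the study's analysis: random intercepts for
#' participants and items (passages), with the slope of the semantic
#' hierarchy allowed to vary by items.
#'
#' @param fixed main-effect terms (default all four factors).
#' @param interactions interaction terms (default none).
#' @param item_hierarchy_slope keep the by-item hierarchy random slope
#'   (default `TRUE`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed = CANON_MAIN, interactions = character(),
                       item_hierarchy_slope = TRUE) {
  fixed <- vapply(fixed, canon_term, character(1), USE.NAMES = FALSE)
  if (any(grepl(":", fixed))) stop2("'fixed' must contain main effects only")
  interactions <- vapply(interactions, canon_term, character(1),
                         USE.NAMES = FALSE)
  for (int in interactions) {
    parts <- strsplit(int, ":")[[1]]
    if (!all(parts %in% fixed))
      stop2("interaction '", int, "' involves a main effect not in the model")
  }
  structure(list(fixed = fixed, interactions = unique(interactions),
                 item_hierarchy_slope = isTRUE(item_hierarchy_slope)),
            class = "model_spec")
}

#' Full starting specification for reverse selection
#'
#' All four main effects plus every two-way interaction among them; the
#' four-way interaction (with its nested three-way terms) can be added as an
#' optional check.
#' @param four_way include the four-way interaction term (default `FALSE`).
#' @return A [model_spec()].
#' @export
full_model_spec <- function(four_way = FALSE) {
  two_way <- combn(CANON_MAIN, 2, paste, collapse = ":")
  ints <- if (four_way)
    c(two_way, combn(CANON_MAIN, 3, paste, collapse = ":"),
      paste(CANON_MAIN, collapse = ":"))
  else two_way
  model_spec(interactions = ints)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec: ", paste(c(x$fixed, x$interactions), collapse = " + "),
      "\n  random: (1 | participant) + (1",
      if (x$item_hierarchy_slope) " + hierarchy slope" else "",
      " | passage)\n", sep = "")
  invisible(x)
}

spec_terms <- function(spec) c(spec$fixed, spec$interactions)

# cell table -> modelling frame with canonical factor codings
prepare_model_data <- function(table) {
  need <- c("participant", "passage", "format", "clarity", "predictability",
            "level", "proportion")
  if (!all(need %in% names(table)))
    stop2("cell table must have columns ", paste(need, collapse = ", "))
  d <- as.data.frame(table)
  d$level <- factor(d$level, levels = c("detail", "mid", "main"))
  d$predictability <- factor(d$predictability, levels = c("low", "high"))
  d$format <- factor(d$format, levels = c("continuous", "selfpaced"))
  d$clarity <- factor(d$clarity, levels = c("vocoded", "clear"))
  if (anyNA(d$level) || anyNA(d$predictability) || anyNA(d$format) ||
      anyNA(d$clarity))
    stop2("unrecognized factor levels in cell table")
  d$pct <- 100 * d$proportion
  d$hier_score <- c(-1, 0, 1)[as.integer(d$level)]
  d
}

spec_formula <- function(spec, extra_fixed = character()) {
  fx <- vapply(spec_terms(spec), function(tm) {
    paste(TERM_VAR[strsplit(tm, ":")[[1]]], collapse = ":")
  }, character(1))
  fx <- c(fx, extra_fixed)
  if (length(fx) == 0) fx <- "1"
  rnd <- if (spec$item_hierarchy_slope)
    "(1 | participant) + (1 + hier_score | passage)"
  else "(1 | participant) + (1 | passage)"
  as.formula(paste("pct ~", paste(fx, collapse = " + "), "+", rnd))
}

#' Fit the linear mixed-effects recall model
#'
#' Fits recall percentage per participant x passage x level cell with the
#' spec's fixed effects and the study's random structure (participant and
#' item intercepts, by-item hierarchy slope), by maximum likelihood (not
#' REML) so that nested models can be compared with likelihood-ratio tests.
#' Treatment coding is used with reference levels detail / low / continuous
#' / vocoded. Convergence problems are never silent: messages are collected
#' in the returned object and flagged by `print()`; if the by-item slope
#' makes the fit fail outright it is dropped with a warning and the
#' simplification recorded.
#'
#' @param table a `cell_table` (from [simulate_recall()] or
#'   [aggregate_scores()]) with at least 2 participants and 2 passages.
#' @param spec a [model_spec()].
#' @param extra_fixed character vector of additional fixed-effect column
#'   names already present in `table` (used for covariate tests).
#' @return An object of class `recall_lmm` with elements `fit` (the lme4
#'   fit), `spec`, `formula`, `logLik`, `fixef`, `converged`, `messages`.
#' @examples
#' sim <- simulate_study(seed = 1)
#' m <- fit_recall_model(sim$trials,
#'        model_spec(interactions = "hierarchy:predictability"))
#' coef(m)
#' @export
fit_recall_model <- function(table, spec = model_spec(),
                             extra_fixed = character()) {
  d <- prepare_model_data(table)
  if (length(unique(d$participant)) < 2 || length(unique(d$passage)) < 2)
    stop2("non-degenerate data required: >= 2 participants and >= 2 passages")
  form <- spec_formula(spec, extra_fixed)
  msgs <- character()
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(form, data = d, REML = FALSE, control = ctrl),
             error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error") && spec$item_hierarchy_slope) {
    warning("by-item hierarchy slope dropped: ", conditionMessage(fit),
            call. = FALSE)
    msgs <- c(msgs, paste("random-slope fit failed, refit without it:",
                          conditionMessage(fit)))
    spec2 <- spec; spec2$item_hierarchy_slope <- FALSE
    return(fit_recall_model_inner(d, spec2, extra_fixed, msgs))
  }
  if (inherits(fit, "error")) stop2("model fit failed: ", conditionMessage(fit))
  conv_ok <- length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  structure(list(fit = fit, spec = spec, formula = form,
                 logLik = logLik(fit), fixef = lme4::fixef(fit),
                 converged = conv_ok && !length(msgs), messages = msgs,
                 n_obs = nrow(d)),
            class = "recall_lmm")
}

fit_recall_model_inner <- function(d, spec, extra_fixed, msgs) {
  form <- spec_formula(spec, extra_fixed)
  fit <- lme4::lmer(form, data = d, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  structure(list(fit = fit, spec = spec, formula = form,
                 logLik = logLik(fit), fixef = lme4::fixef(fit),
                 converged = FALSE, messages = msgs, n_obs = nrow(d)),
            class = "recall_lmm")
}

#' @export
print.recall_lmm <- function(x, ...) {
  cat("Linear mixed-effects recall model (ML fit)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  log-likelihood %.2f on %d obs; %s\n", as.numeric(x$logLik),
              x$n_obs,
              if (x$converged) "converged" else "CONVERGENCE FLAGGED"))
  if (length(x$messages))
    cat("  diagnostics:", paste(x$messages, collapse = "; "), "\n")
  print(round(x$fixef, 3))
  invisible(x)
}

#' @export
summary.recall_lmm <- function(object, ...) {
  s <- summary(object$fit)
  if (!object$converged)
    cat("NOTE: convergence flagged;",
        paste(object$messages, collapse = "; "), "\n")
  s
}

#' @export
coef.recall_lmm <- function(object, ...) object$fixef

#' @export
logLik.recall_lmm <- function(object, ...) object$logLik

#' @export
fitted.recall_lmm <- function(object, ...) fitted(object$fit)

#' @export
residuals.recall_lmm <- function(object, ...) residuals(object$fit)

null_spec_for <- function(spec, predictor) {
  predictor <- canon_term(predictor)
  if (!(predictor %in% spec_terms(spec)))
    stop2("predictor '", predictor, "' is not in the model spec")
  ns <- spec
  if (grepl(":", predictor)) {
    ns$interactions <- setdiff(ns$interactions, predictor)
  } else {
    # testing a main effect removes the effect and its retained interactions
    # together (df bookkeeping of the per-predictor null-model comparisons)
    ns$fixed <- setdiff(ns$fixed, predictor)
    keep <- !vapply(ns$interactions, function(i)
      predictor %in% strsplit(i, ":")[[1]], logical(1))
    ns$interactions <- ns$interactions[keep]
  }
  ns
}

#' Likelihood-ratio test of one predictor against the final model
#'
#' Compares the ML fit of `spec` to a null model with `predictor` removed.
#' Removing a main effect also removes its retained interactions, so e.g.
#' testing the semantic hierarchy in a final model containing the
#' hierarchy-by-predictability interaction gives df = 4, and testing
#' predictability gives df = 3. The statistic is
#' `chisq = 2 (logLik_full - logLik_null)` with df the difference in
#' parameter counts.
#'
#' @param table a `cell_table`.
#' @param spec the final [model_spec()].
#' @param predictor a term of `spec`.
#' @return A list of class `lrt_result`: `predictor`, `chisq`, `df`, `p`.
#' @export
lrt <- function(table, spec, predictor) {
  full <- fit_recall_model(table, spec)
  null <- fit_recall_model(table, null_spec_for(spec, predictor))
  lrt_from_fits(full, null, canon_term(predictor))
}

lrt_from_fits <- function(full, null, predictor) {
  chisq <- max(0, 2 * (as.numeric(full$logLik) - as.numeric(null$logLik)))
  df <- attr(full$logLik, "df") - attr(null$logLik, "df")
  if (df < 1) stop2("null model is not nested with fewer parameters")
  structure(list(predictor = predictor, chisq = chisq, df = as.integer(df),
                 p = pchisq(chisq, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s: chisq(%d) = %.3f, p = %.4g\n",
              x$predictor, x$df, x$chisq, x$p))
  invisible(x)
}

#' Reverse selection of the final model
#'
#' Backwards model reduction as used for the recall analysis: starting from
#' a full specification, the least-significant non-significant interaction
#' term (by drop-one likelihood-ratio test at `alpha`) is removed and the
#' model refit, until every retained interaction is significant or only
#' main effects remain. Main effects are never removed. The removal order
#' and every step's LRT are logged in the result.
#'
#' @param table a `cell_table`.
#' @param full_spec starting [model_spec()] (default [full_model_spec()]:
#'   all two-way interactions).
#' @param alpha significance threshold (default 0.05).
#' @return An object of class `reverse_selection`: `spec` (final
#'   [model_spec()]) and `steps` (data.frame log with columns `term`,
#'   `chisq`, `df`, `p`, `action`).
#' @export
reverse_select <- function(table, full_spec = full_model_spec(),
                           alpha = 0.05) {
  spec <- full_spec
  steps <- list()
  repeat {
    if (length(spec$interactions) == 0) break
    full <- fit_recall_model(table, spec)
    tests <- lapply(spec$interactions, function(tm)
      lrt_from_fits(full, fit_recall_model(table, null_spec_for(spec, tm)), tm))
    p <- vapply(tests, `[[`, numeric(1), "p")
    if (all(p < alpha)) {
      for (t in tests)
        steps[[length(steps) + 1L]] <-
          data.frame(term = t$predictor, chisq = t$chisq, df = t$df, p = t$p,
                     action = "retained", stringsAsFactors = FALSE)
      break
    }
    drop_i <- which.max(p)
    t <- tests[[drop_i]]
    steps[[length(steps) + 1L]] <-
      data.frame(term = t$predictor, chisq = t$chisq, df = t$df, p = t$p,
                 action = "removed", stringsAsFactors = FALSE)
    spec <- null_spec_for(spec, t$predictor)
  }
  structure(list(spec = spec,
                 steps = if (length(steps)) do.call(rbind, steps)
                         else data.frame(term = character(), chisq = numeric(),
                                         df = integer(), p = numeric(),
                                         action = character())),
            class = "reverse_selection")
}

#' @export
print.reverse_selection <- function(x, ...) {
  cat("Reverse selection\n  final: ",
      paste(c(x$spec$fixed, x$spec$interactions), collapse = " + "), "\n",
      sep = "")
  if (nrow(x$steps)) {
    cat("  steps:\n")
    print(transform(x$steps, chisq = round(chisq, 3), p = signif(p, 3)),
          row.names = FALSE)
  }
  invisible(x)
}
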