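#' Generating calibration for the synthetic recall data
#'
#' Fixed- and random-effect parameters of the linear-probability generative
#' model, on the percentage scale. The five effect deltas default to the
#' study's reported marginal contrasts in percentage points; by construction
#' of [cell_expectations()] each marginal contrast of the generated data
#' equals its delta exactly in expectation.
#'
#' The hierarchy-by-predictability interaction is parameterized as the
#' attenuation `interaction_atten` in (0, 1]: the ratio of the expected
#' hierarchy slope under low versus high predictability (1 = no
#' interaction). It enters the cell means as a double-centered term so that
#' no marginal contrast is contaminated (see the methods vignette).
#'
#' Values not reported by the study (`base_pct`, `interaction_atten`, the
#' random-effect SDs, the loadings, `n_props_per_level`) are invented,
#' documented defaults.
#'
#' @param base_pct baseline recall percent for the reference cell (detail
#'   level, low predictability, vocoded, continuous). Default 40.
#' @param d_pred high-vs-low predictability contrast in percentage points
#'   (default 7.85).
#' @param d_main_mid main-ideas-vs-mid-level contrast (default 9.78).
#' @param d_mid_detail mid-level-vs-detail contrast (default 5.61).
#' @param d_format self-paced-vs-continuous contrast (default 6.83).
#' @param d_clarity clear-vs-vocoded contrast (default 4.78).
#' @param interaction_atten hierarchy-slope attenuation under low
#'   predictability, in (0, 1] (default 0.55).
#' @param sd_participant,sd_item,sd_item_slope,sd_resid random-effect SDs in
#'   percentage points (participant intercept, item intercept, item-by-level
#'   slope, residual; defaults 8, 5, 2, 0).
#' @param rspan_loading correlation-scale loading of the participant
#'   intercept on the standardized R-span score (default 0.5).
#' @param pause_loading_between,pause_loading_within couplings of pauses with
#'   recall: between-participant loading of the participant intercept on the
#'   pause-tendency latent (default 0.6), and within-participant
#'   percentage-point effect (per SD of the passage-level pause latent,
#'   scaled by `sd_participant`) of pausing longer on a passage (default 0.3).
#' @param n_props_per_level named vector of proposition counts per level
#'   (default main 10, mid 15, detail 20).
#' @return An object of class `effect_calibration`. Errors if the implied
#'   cell means leave \[0, 100\].
#' @export
effect_calibration <- function(base_pct = 40, d_pred = 7.85,
                               d_main_mid = 9.78, d_mid_detail = 5.61,
                               d_format = 6.83, d_clarity = 4.78,
                               interaction_atten = 0.55,
                               sd_participant = 8, sd_item = 5,
                               sd_item_slope = 2, sd_resid = 0,
                               rspan_loading = 0.5,
                               pause_loading_between = 0.6,
                               pause_loading_within = 0.3,
                               n_props_per_level = c(main = 10L, mid = 15L,
                                                     detail = 20L)) {
  if (interaction_atten <= 0 || interaction_atten > 1)
    stop2("'interaction_atten' must be in (0, 1]")
  sds <- c(sd_participant, sd_item, sd_item_slope, sd_resid)
  if (any(sds < 0)) stop2("random-effect SDs must be >= 0")
  if (rspan_loading^2 + pause_loading_between^2 > 1)
    stop2("rspan_loading^2 + pause_loading_between^2 must be <= 1")
  if (!all(c("main", "mid", "detail") %in% names(n_props_per_level)))
    stop2("'n_props_per_level' needs named entries main, mid, detail")
  cal <- structure(list(base_pct = base_pct, d_pred = d_pred,
                        d_main_mid = d_main_mid, d_mid_detail = d_mid_detail,
                        d_format = d_format, d_clarity = d_clarity,
                        interaction_atten = interaction_atten,
                        sd_participant = sd_participant, sd_item = sd_item,
                        sd_item_slope = sd_item_slope, sd_resid = sd_resid,
                        rspan_loading = rspan_loading,
                        pause_loading_between = pause_loading_between,
                        pause_loading_within = pause_loading_within,
                        n_props_per_level = n_props_per_level),
                   class = "effect_calibration")
  ex <- cell_expectations(cal)
  if (any(ex$expected_pct < 0 | ex$expected_pct > 100))
    stop2("infeasible calibration: implied cell means outside [0, 100] ",
          "(range ", signif(min(ex$expected_pct), 4), " to ",
          signif(max(ex$expected_pct), 4), ")")
  cal
}

#' @export
print.effect_calibration <- function(x, ...) {
  cat("Effect calibration (percentage-point scale)\n")
  cat(sprintf("  base %.2f | pred %.2f | main-mid %.2f | mid-detail %.2f | format %.2f | clarity %.2f\n",
              x$base_pct, x$d_pred, x$d_main_mid, x$d_mid_detail,
              x$d_format, x$d_clarity))
  cat(sprintf("  hierarchy-slope attenuation (low/high) %.2f\n",
              x$interaction_atten))
  cat(sprintf("  SDs: participant %.1f, item %.1f, item slope %.1f, resid %.1f\n",
              x$sd_participant, x$sd_item, x$sd_item_slope, x$sd_resid))
  invisible(x)
}

#' Expected cell means implied by a calibration
#'
#' The deterministic part of the generative model, over the 24 design cells
#' (3 levels x 2 predictability x 2 format x 2 clarity):
#' \deqn{\mu = b + c(level) + d_p [high] + d_f [selfpaced] + d_c [clear]
#'       \pm \kappa\, g(level)}
#' where `c(level)` is (0, d_mid_detail, d_mid_detail + d_main_mid) for
#' detail/mid/main, `g` is `c` centered over levels,
#' `kappa = (1 - atten) / (1 + atten)`, and the sign is + for high and - for
#' low predictability. The double-centering makes every marginal contrast
#' equal its delta exactly while the low/high hierarchy-slope ratio equals
#' `atten`; at `atten = 1` the term vanishes.
#'
#' @param calibration an [effect_calibration()] (the constructor calls this
#'   for its feasibility check, so the argument may also be an unclassed
#'   list with the same fields).
#' @return A 24-row data.frame: `level`, `predictability`, `format`,
#'   `clarity`, `expected_pct`.
#' @export
cell_expectations <- function(calibration) {
  cal <- calibration
  lev <- c("detail", "mid", "main")
  contrib <- c(detail = 0, mid = cal$d_mid_detail,
               main = cal$d_mid_detail + cal$d_main_mid)
  g <- contrib - mean(contrib)
  kappa <- (1 - cal$interaction_atten) / (1 + cal$interaction_atten)
  # anchor so the reference cell (detail, low, continuous, vocoded) = base_pct
  base_adj <- cal$base_pct - kappa * mean(contrib)
  grid <- expand.grid(level = lev, predictability = c("low", "high"),
                      format = c("continuous", "selfpaced"),
                      clarity = c("vocoded", "clear"),
                      stringsAsFactors = FALSE)
  sgn <- ifelse(grid$predictability == "high", 1, -1)
  grid$expected_pct <- base_adj + contrib[grid$level] +
    cal$d_pred * (grid$predictability == "high") +
    cal$d_format * (grid$format == "selfpaced") +
    cal$d_clarity * (grid$clarity == "clear") +
    sgn * kappa * g[grid$level]
  rownames(grid) <- NULL
  grid
}

#' Write / read a calibration as JSON
#'
#' The packaged default calibration ships as
#' `system.file("extdata", "paper_defaults.json", package = "vocrecall")`.
#' @param calibration an [effect_calibration()].
#' @param path JSON file path.
#' @return `read_calibration()` returns an [effect_calibration()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "effect_calibration"))
  x <- unclass(calibration)
  x$n_props_per_level <- as.list(x$n_props_per_level)  # keep level names
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::fromJSON(path)
  np <- unlist(j$n_props_per_level)
  do.call(effect_calibration,
          c(j[setdiff(names(j), "n_props_per_level")],
            list(n_props_per_level = np)))
}
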