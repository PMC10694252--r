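design_cell_means <- function(d) {
  # unweighted means per design cell (over participants and passages),
  # then contrasts average over cells so every factor combination counts once
  aggregate(pct ~ level + predictability + format + clarity, data = d,
            FUN = mean)
}

#' Marginal effect of a design factor, in percentage points
#'
#' Difference of unweighted cell-mean recall percentages between two levels
#' of a factor, averaged over all other design factors: the scale on which
#' the study reports its effects (e.g. 7.85 percentage points for high vs.
#' low predictability). A participant-level bootstrap provides the
#' confidence interval.
#'
#' @param table a `cell_table`.
#' @param factor one of `"predictability"`, `"format"`, `"clarity"`,
#'   `"hierarchy"`.
#' @param levels length-2 character vector `c(a, b)` for the contrast
#'   `a - b`; defaults to high-low, selfpaced-continuous, clear-vocoded; for
#'   `"hierarchy"` it must be supplied (e.g. `c("main", "mid")`).
#' @param n_boot bootstrap replicates for the CI (default 200; 0 skips it).
#' @param seed seed for the bootstrap resampling.
#' @param ci_level CI coverage (default 0.95).
#' @return An object of class `marginal_effect`: `contrast`, `estimate`
#'   (percentage points), `ci` (or `NULL`).
#' @examples
#' sim <- simulate_study(seed = 1)
#' marginal_effect(sim$trials, "predictability", n_boot = 50, seed = 2)
#' @export
marginal_effect <- function(table, factor = c("predictability", "format",
                                              "clarity", "hierarchy"),
                            levels = NULL, n_boot = 200, seed = NULL,
                            ci_level = 0.95) {
  factor <- match.arg(factor)
  defaults <- list(predictability = c("high", "low"),
                   format = c("selfpaced", "continuous"),
                   clarity = c("clear", "vocoded"))
  if (is.null(levels)) {
    if (factor == "hierarchy")
      stop2("supply 'levels' for the hierarchy contrast, e.g. c(\"main\", \"mid\")")
    levels <- defaults[[factor]]
  }
  if (length(levels) != 2) stop2("'levels' must name two factor levels")
  var <- if (factor == "hierarchy") "level" else factor
  d <- prepare_model_data(table)
  if (!all(levels %in% as.character(d[[var]])))
    stop2("both contrast levels must be present in the data")
  full_cells <- 3 * 2 * 2 * 2
  est_fun <- function(dd) {
    cells <- design_cell_means(dd)
    m <- tapply(cells$pct, as.character(cells[[var]]), mean)
    unname(m[levels[1]] - m[levels[2]])
  }
  cells <- design_cell_means(d)
  if (nrow(cells) < full_cells)
    warning("unbalanced design: ", full_cells - nrow(cells),
            " empty design cells; using available-cell means", call. = FALSE)
  est <- est_fun(d)
  ci <- NULL
  if (n_boot > 0) {
    parts <- unique(d$participant)
    rows_of <- split(seq_len(nrow(d)), d$participant)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      take <- sample(parts, length(parts), replace = TRUE)
      est_fun(d[unlist(rows_of[take]), ])
    }, numeric(1)))
    a <- (1 - ci_level) / 2
    ci <- unname(quantile(boots, c(a, 1 - a), na.rm = TRUE))
  }
  structure(list(contrast = paste0(factor, ": ", levels[1], " - ", levels[2]),
                 estimate = est, ci = ci, n_boot = n_boot),
            class = "marginal_effect")
}

#' @export
print.marginal_effect <- function(x, ...) {
  cat(sprintf("Marginal effect [%s]: %.2f percentage points", x$contrast,
              x$estimate))
  if (!is.null(x$ci))
    cat(sprintf(" (CI %.2f to %.2f, %d bootstrap reps)", x$ci[1], x$ci[2],
                x$n_boot))
  cat("\n")
  invisible(x)
}

#' Semantic-hierarchy slope on cell-mean percentages
#'
#' The linear contrast `(main - detail) / 2` over level means (level spacing
#' -1, 0, +1), computed from unweighted design-cell means within the
#' requested condition subset; a shallower slope indicates an attenuated
#' levels effect. Model-agnostic by design: no mixed-model coefficients are
#' involved.
#'
#' @param table a `cell_table`.
#' @param predictability,format,clarity optional filters (`"high"`,
#'   `"selfpaced"`, ...); `NULL` keeps all.
#' @return Slope in percentage points per hierarchy level.
#' @export
hierarchy_slope <- function(table, predictability = NULL, format = NULL,
                            clarity = NULL) {
  d <- prepare_model_data(table)
  if (!is.null(predictability)) d <- d[d$predictability %in% predictability, ]
  if (!is.null(format)) d <- d[d$format %in% format, ]
  if (!is.null(clarity)) d <- d[d$clarity %in% clarity, ]
  if (!all(c("detail", "mid", "main") %in% as.character(d$level)))
    stop2("all three hierarchy levels must be present in the filtered cells")
  cells <- design_cell_means(d)
  m <- tapply(cells$pct, as.character(cells$level), mean)
  unname((m["main"] - m["detail"]) / 2)
}
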