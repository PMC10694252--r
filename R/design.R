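#' Build the counterbalanced within-subject design
#'
#' Assigns each participant all eight passages, two per presentation-format
#' by speech-clarity cell (continuous/self-paced crossed with
#' clear/vocoded), with one high- and one low-predictability passage in each
#' cell. Across every balanced block of 8 participants each passage appears
#' in each cell exactly twice, so by the end of a multiple-of-8 run every
#' passage has been heard equally often in every condition.
#'
#' Construction: a canonical 8-row cell-rotation matrix (a Latin-square
#' rotation of the four cells over the four passages of each predictability
#' class, crossed so the high and low rotations decouple across rows). The
#' seed permutes only the participant-to-row assignment within each block,
#' which preserves balance exactly.
#'
#' @param n_participants number of participants; a multiple of 8 keeps the
#'   across-participant balance exact (otherwise a warning is issued).
#' @param passages list of 8 [passage()] objects (or a data.frame with
#'   columns `id` and `predictability_class`), 4 high- and 4 low-
#'   predictability.
#' @param seed integer seed for the row permutation; `NULL` for the
#'   canonical order.
#' @return A data.frame of class `design_plan` with columns `participant`,
#'   `passage`, `format` (`"continuous"`/`"selfpaced"`), `clarity`
#'   (`"clear"`/`"vocoded"`) and `predictability` (`"high"`/`"low"`).
#' @examples
#' plan <- build_design(8, default_passages(), seed = 1)
#' table(plan$passage, paste(plan$format, plan$clarity))
#' @export
build_design <- function(n_participants, passages, seed = NULL) {
  if (is.data.frame(passages)) {
    ids <- as.character(passages$id)
    pclass <- as.character(passages$predictability_class)
  } else {
    ids <- vapply(passages, function(p) p$id, character(1))
    pclass <- vapply(passages, function(p) p$predictability_class, character(1))
  }
  if (length(ids) != 8L) stop2("exactly 8 passages are required")
  if (anyDuplicated(ids)) stop2("passage ids must be unique")
  if (sum(pclass == "high") != 4L || sum(pclass == "low") != 4L)
    stop2("need 4 high- and 4 low-predictability passages")
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L)
    stop2("'n_participants' must be >= 1")
  if (n_participants %% 8L != 0L)
    warning("n_participants is not a multiple of 8; ",
            "across-participant passage balance will be approximate",
            call. = FALSE)

  cells <- data.frame(
    format  = rep(c("continuous", "selfpaced"), each = 2),
    clarity = rep(c("clear", "vocoded"), times = 2),
    stringsAsFactors = FALSE)
  hi_ids <- ids[pclass == "high"]
  lo_ids <- ids[pclass == "low"]

  # canonical 8-row rotation: row r sends high passage i to cell (i + r) mod 4
  # and low passage i to cell (i + r + floor(r/4)) mod 4; over the 8 rows each
  # passage hits each cell exactly twice
  row_assign <- function(r) {
    hi_cell <- (seq_len(4) - 1 + r) %% 4 + 1
    lo_cell <- (seq_len(4) - 1 + r + r %/% 4) %% 4 + 1
    data.frame(passage = c(hi_ids, lo_ids),
               predictability = rep(c("high", "low"), each = 4),
               cell = c(hi_cell, lo_cell),
               stringsAsFactors = FALSE)
  }

  n_blocks <- ceiling(n_participants / 8L)
  block_seeds <- if (is.null(seed)) NULL else derive_seeds(seed, n_blocks)
  plan <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    blk <- (p - 1L) %/% 8L
    pos <- (p - 1L) %% 8L + 1L
    rows <- if (is.null(block_seeds)) 0:7
            else with_seed(block_seeds[blk + 1L], sample(0:7))
    a <- row_assign(rows[pos])
    a$participant <- sprintf("P%02d", p)
    a$format <- cells$format[a$cell]
    a$clarity <- cells$clarity[a$cell]
    plan[[p]] <- a[, c("participant", "passage", "format", "clarity",
                       "predictability")]
  }
  out <- do.call(rbind, plan)
  rownames(out) <- NULL
  class(out) <- c("design_plan", "data.frame")
  out
}

#' Default synthetic passage set
#'
#' Eight stub passages (4 high-, 4 low-predictability) used by the
#' synthetic-data generator in place of the copyrighted experimental
#' recordings. Segment counts per passage are {10, 10, 11, 11} for the high
#' set and {10, 11, 11, 11} for the low set, emulating the roughly 10.5
#' segments per passage of the real stimuli; only the pause generator uses
#' them. These are synthetic stand-ins, not the experiment's materials.
#'
#' @return A data.frame with columns `id`, `predictability_class`,
#'   `mean_cloze` and `n_segments`.
#' @export
default_passages <- function() {
  data.frame(
    id = c(paste0("hp", 1:4), paste0("lp", 1:4)),
    predictability_class = rep(c("high", "low"), each = 4),
    mean_cloze = rep(c(0.67, 0.51), each = 4),
    n_segments = c(10L, 10L, 11L, 11L, 10L, 11L, 11L, 11L),
    stringsAsFactors = FALSE)
}
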