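#' Simulate participant profiles
#'
#' Draws covariate profiles matching the study sample: R-span (working
#' memory) as a rounded normal censored to \[0, 15\] with mean 9.42 and SD
#' 2.98; Shipley vocabulary as a rounded normal censored to \[0, 20\] with
#' mean 13.0 and SD 1.8; better-ear pure-tone average as normal
#' (6.88, 4.12) dB HL; and a lognormal pause-tendency multiplier with unit
#' median. Censoring (rather than rejection) at the range bounds keeps the
#' R-span mean within sampling error of 9.42.
#'
#' @param n number of participants (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param rspan_mean,rspan_sd,vocab_mean,vocab_sd,pta_mean,pta_sd population
#'   moments (defaults are the study sample's).
#' @param pause_sdlog log-scale SD of the pause-tendency multiplier
#'   (default 0.35, the between-participant share of the pause-duration
#'   log-variance).
#' @return A data.frame of class `participant_profiles` with columns
#'   `participant`, `rspan`, `vocab`, `pta_db`, `pause_tendency`; the
#'   `pause_sdlog` used is attached as an attribute.
#' @export
simulate_participants <- function(n, seed = NULL,
                                  rspan_mean = 9.42, rspan_sd = 2.98,
                                  vocab_mean = 13.0, vocab_sd = 1.8,
                                  pta_mean = 6.88, pta_sd = 4.12,
                                  pause_sdlog = 0.35) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop2("'n' must be >= 1")
  with_seed(seed, {
    rspan <- clamp(round(rnorm(n, rspan_mean, rspan_sd)), 0, 15)
    vocab <- clamp(round(rnorm(n, vocab_mean, vocab_sd)), 0, 20)
    pta <- rnorm(n, pta_mean, pta_sd)
    z_pause <- rnorm(n)
    out <- data.frame(participant = sprintf("P%02d", seq_len(n)),
                      rspan = as.integer(rspan), vocab = as.integer(vocab),
                      pta_db = pta,
                      pause_tendency = exp(pause_sdlog * z_pause),
                      stringsAsFactors = FALSE)
    attr(out, "pause_sdlog") <- pause_sdlog
    class(out) <- c("participant_profiles", "data.frame")
    out
  })
}

#' Simulate proposition-recall outcomes for a design plan
#'
#' Linear-probability generative model on the percentage scale. For each
#' participant x passage x level cell the expected recall percentage is the
#' [cell_expectations()] value plus a participant intercept, an item
#' intercept, an item-by-level slope deviation, a within-participant pause
#' coupling term (self-paced trials only), and optional residual noise; the
#' recalled-proposition count is binomial with that probability.
#'
#' The participant intercept is built from three standard-normal sources
#' with the calibration's loadings: the standardized R-span score, the
#' pause-tendency latent (so participants who tend to pause longer also tend
#' to recall more), and an independent residual. Self-paced trials
#' additionally receive a per-passage latent shared with the pause
#' generator, coupling longer pausing on a passage to better recall on that
#' passage; the latents are stored in the `"pause_latent"` attribute for
#' [simulate_pauses()].
#'
#' @param plan a [build_design()] plan.
#' @param participants a [simulate_participants()] data.frame covering every
#'   participant in the plan.
#' @param calibration an [effect_calibration()].
#' @param seed integer seed.
#' @return A `cell_table` data.frame (one row per participant x passage x
#'   level) with attributes `pause_latent` (participant, passage, z) and
#'   `calibration`.
#' @export
simulate_recall <- function(plan, participants,
                            calibration = effect_calibration(),
                            seed = NULL) {
  stopifnot(inherits(plan, "design_plan"),
            is.data.frame(participants),
            inherits(calibration, "effect_calibration"))
  cal <- calibration
  if (!all(plan$participant %in% participants$participant))
    stop2("participants table does not cover the plan")
  ex <- cell_expectations(cal)
  key <- function(l, p, f, c) paste(l, p, f, c, sep = "\r")
  mu <- setNames(ex$expected_pct,
                 key(ex$level, ex$predictability, ex$format, ex$clarity))
  with_seed(seed, {
    pid <- participants$participant
    np <- length(pid)
    z_r <- if (sd(participants$rspan) > 0)
      (participants$rspan - mean(participants$rspan)) / sd(participants$rspan)
      else rep(0, np)
    psl <- attr(participants, "pause_sdlog") %||% 0
    z_p <- if (psl > 0) log(participants$pause_tendency) / psl else rep(0, np)
    lr <- cal$rspan_loading; lp <- cal$pause_loading_between
    resid_load <- sqrt(max(0, 1 - lr^2 - lp^2))
    u_part <- setNames(cal$sd_participant *
                         (lr * z_r + lp * z_p + resid_load * rnorm(np)), pid)
    items <- unique(plan$passage)
    u_item <- setNames(rnorm(length(items), 0, cal$sd_item), items)
    u_slope <- setNames(rnorm(length(items), 0, cal$sd_item_slope), items)

    # per-(participant, passage) pause latent, self-paced trials only
    sp <- unique(plan[plan$format == "selfpaced", c("participant", "passage")])
    sp$z <- if (nrow(sp)) rnorm(nrow(sp)) else numeric()
    zmap <- setNames(sp$z, paste(sp$participant, sp$passage, sep = "\r"))

    lev <- c("detail", "mid", "main")
    hs <- c(detail = -1, mid = 0, main = 1)
    rows <- plan[rep(seq_len(nrow(plan)), each = 3L), ]
    rows$level <- rep(lev, times = nrow(plan))
    zw <- zmap[paste(rows$participant, rows$passage, sep = "\r")]
    zw[is.na(zw) | rows$format != "selfpaced"] <- 0
    p_pct <- mu[key(rows$level, rows$predictability, rows$format, rows$clarity)] +
      u_part[rows$participant] + u_item[rows$passage] +
      u_slope[rows$passage] * hs[rows$level] +
      cal$pause_loading_within * cal$sd_participant * zw +
      (if (cal$sd_resid > 0) rnorm(nrow(rows), 0, cal$sd_resid) else 0)
    p <- clamp(p_pct, 0, 100) / 100
    n_props <- cal$n_props_per_level[rows$level]
    n_rec <- rbinom(nrow(rows), n_props, p)
    out <- data.frame(participant = rows$participant, passage = rows$passage,
                      format = rows$format, clarity = rows$clarity,
                      predictability = rows$predictability, level = rows$level,
                      n_props = as.integer(n_props),
                      n_recalled = as.integer(n_rec),
                      proportion = n_rec / n_props,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("cell_table", "data.frame")
    attr(out, "pause_latent") <- sp
    attr(out, "calibration") <- cal
    out
  })
}

#' Simulate inter-segment pause durations
#'
#' Lognormal pauses for the self-paced trials, moment-matched so the
#' marginal distribution has mean `mean_s` (default 2.43 s) and SD `sd_s`
#' (default 2.71 s) exactly. The total log-scale variance is decomposed into
#' a between-participant component (the profile's pause tendency), a
#' between-passage-within-participant component, and a within-passage
#' segment component. The passage-level latent is shared with
#' [simulate_recall()] (its `"pause_latent"` attribute) so that pausing
#' longer on a passage accompanies better recall on it; speech clarity does
#' not enter the pause model at all, matching its observed insensitivity to
#' stimulus clarity.
#'
#' @param plan a [build_design()] plan with self-paced trials.
#' @param participants a [simulate_participants()] data.frame.
#' @param recall optional result of [simulate_recall()]; if supplied its
#'   pause latents are reused, otherwise fresh latents are drawn.
#' @param seed integer seed.
#' @param mean_s,sd_s target marginal mean and SD in seconds.
#' @param within_sdlog between-passage-within-participant log-scale SD
#'   (default 0.25).
#' @param n_segments named vector passage -> segment count; defaults to the
#'   [default_passages()] counts, or 11 for unknown passages. A passage with
#'   k segments yields k - 1 inter-segment pauses.
#' @return A data.frame with columns `participant`, `passage`,
#'   `segment_index`, `pause_s`.
#' @export
simulate_pauses <- function(plan, participants, recall = NULL, seed = NULL,
                            mean_s = 2.43, sd_s = 2.71, within_sdlog = 0.25,
                            n_segments = NULL) {
  stopifnot(inherits(plan, "design_plan"), is.data.frame(participants))
  sp <- plan[plan$format == "selfpaced", , drop = FALSE]
  if (nrow(sp) == 0) stop2("plan contains no self-paced trials")
  if (is.null(n_segments)) {
    dp <- default_passages()
    n_segments <- setNames(dp$n_segments, dp$id)
  }
  total_var <- log(1 + (sd_s / mean_s)^2)
  between_sdlog <- attr(participants, "pause_sdlog") %||% 0
  seg_var <- total_var - between_sdlog^2 - within_sdlog^2
  if (seg_var <= 0)
    stop2("between/within log-SDs exceed the total implied by mean_s, sd_s")
  mu0 <- log(mean_s) - total_var / 2
  b <- setNames(log(participants$pause_tendency), participants$participant)

  latent <- if (!is.null(recall)) attr(recall, "pause_latent") else NULL
  with_seed(seed, {
    keys <- unique(sp[, c("participant", "passage")])
    if (is.null(latent)) {
      latent <- keys
      latent$z <- rnorm(nrow(latent))
    }
    zmap <- setNames(latent$z, paste(latent$participant, latent$passage,
                                     sep = "\r"))
    res <- lapply(seq_len(nrow(keys)), function(i) {
      part <- keys$participant[i]; pass <- keys$passage[i]
      nseg <- unname(n_segments[pass]); if (is.na(nseg)) nseg <- 11L
      k <- max(1L, nseg - 1L)
      zw <- zmap[[paste(part, pass, sep = "\r")]] %||% 0
      if (is.na(zw)) zw <- 0
      data.frame(participant = part, passage = pass, segment_index = seq_len(k),
                 pause_s = exp(mu0 + b[[part]] + within_sdlog * zw +
                               sqrt(seg_var) * rnorm(k)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper chaining [simulate_participants()], [build_design()],
#' [simulate_recall()] and [simulate_pauses()] with sub-seeds derived from
#' one master seed.
#'
#' @param n_participants number of participants (default 24, the study's
#'   sample size).
#' @param passages passage set (default [default_passages()]).
#' @param calibration an [effect_calibration()].
#' @param seed master integer seed.
#' @return An object of class `simulated_dataset`: a list with `trials`
#'   (cell table), `pauses`, `participants`, `plan`, and `truth` (the
#'   generating calibration).
#' @examples
#' sim <- simulate_study(seed = 1)
#' head(sim$trials)
#' @export
simulate_study <- function(n_participants = 24, passages = default_passages(),
                           calibration = effect_calibration(), seed = NULL) {
  seeds <- if (is.null(seed)) rep(list(NULL), 4) else as.list(derive_seeds(seed, 4))
  participants <- simulate_participants(n_participants, seed = seeds[[1]])
  plan <- build_design(n_participants, passages, seed = seeds[[2]])
  trials <- simulate_recall(plan, participants, calibration, seed = seeds[[3]])
  n_seg <- if (is.data.frame(passages) && "n_segments" %in% names(passages))
    setNames(passages$n_segments, passages$id) else NULL
  pauses <- simulate_pauses(plan, participants, recall = trials,
                            seed = seeds[[4]], n_segments = n_seg)
  structure(list(trials = trials, pauses = pauses,
                 participants = participants, plan = plan,
                 truth = calibration),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset: %d participants, %d trials rows, %d pauses>\n",
              nrow(x$participants), nrow(x$trials), nrow(x$pauses)))
  invisible(x)
}

#' Write a simulated dataset to CSV/JSON files
#'
#' Emits `trials.csv`, `pauses.csv`, `participants.csv` and `truth.json`
#' (the generating calibration, for parameter-recovery tests).
#' @param dataset a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(dataset$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(dataset$pauses, file.path(dir, "pauses.csv"), row.names = FALSE)
  write.csv(dataset$participants, file.path(dir, "participants.csv"),
            row.names = FALSE)
  write_calibration(dataset$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
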