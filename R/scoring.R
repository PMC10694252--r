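#' Built-in suffix-stripping lemmatizer
#'
#' A small deterministic heuristic used to canonicalize transcript and
#' proposition lemmas: strips regular plural "-s"/"-es"/"-ies" and the verbal
#' suffixes "-ed"/"-ing" (undoubling a doubled final consonant). It does not
#' restore dropped final "e" ("making" -> "mak"): irregular or e-dropping
#' forms should be covered through the proposition bank's synonym sets. It is
#' swappable via the `lemmatizer` argument of [score_transcript()].
#'
#' @param tokens character vector of lower-case tokens.
#' @return Character vector of lemmas.
#' @examples
#' lemmatize(c("sailed", "storms", "running", "cities"))
#' @export
lemmatize <- function(tokens) {
  vapply(tolower(tokens), function(w) {
    if (nchar(w) > 4 && grepl("ies$", w)) {
      w <- sub("ies$", "y", w)
    } else if (nchar(w) > 3 && grepl("(s|x|z|ch|sh)es$", w)) {
      w <- sub("es$", "", w)
    } else if (nchar(w) > 3 && grepl("[^s]s$", w)) {
      w <- sub("s$", "", w)
    }
    for (suf in c("ing", "ed")) {
      if (nchar(w) > nchar(suf) + 2 && grepl(paste0(suf, "$"), w)) {
        st <- sub(paste0(suf, "$"), "", w)
        # undouble a doubled final consonant: "running" -> "run"
        n <- nchar(st)
        if (n >= 2 && substr(st, n, n) == substr(st, n - 1, n - 1) &&
            !grepl("[aeiou]$", st))
          st <- substr(st, 1, n - 1)
        if (nchar(st) >= 3) w <- st
        break
      }
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

#' Propositional representation of a passage
#'
#' Propositions are predicate-argument units of text meaning; a proposition
#' may take other propositions as arguments, and this nesting induces the
#' semantic hierarchy: topic-bearing root propositions are *main ideas*,
#' propositions taking a main proposition as an argument are *mid-level*,
#' and the rest are *details*.
#'
#' @param passage_id passage identifier.
#' @param propositions list of propositions, each a list with elements `id`
#'   (string), `predicate` (lemma) and `args` (non-empty character vector of
#'   atomic lemmas and/or other proposition ids).
#' @param roots character vector of topic-bearing proposition ids (the main
#'   ideas); non-empty, subset of the proposition ids.
#' @param synonyms named list: lemma -> character vector of acceptable
#'   substitute lemmas ("close synonyms" earn full credit in scoring). An
#'   explicit lexicon, not automatic: synonym judgment was human work.
#' @return An object of class `proposition_bank` (levels unassigned; see
#'   [assign_levels()]).
#' @export
proposition_bank <- function(passage_id, propositions, roots,
                             synonyms = list()) {
  if (length(propositions) == 0) stop2("empty proposition bank")
  ids <- vapply(propositions, function(p) as.character(p$id), character(1))
  if (anyDuplicated(ids)) stop2("duplicate proposition ids")
  for (p in propositions) {
    if (length(p$args) == 0) stop2("proposition ", p$id, " has no arguments")
    if (is.null(p$predicate) || !nzchar(p$predicate))
      stop2("proposition ", p$id, " has no predicate")
  }
  roots <- as.character(roots)
  if (length(roots) == 0) stop2("'roots' must be non-empty")
  if (!all(roots %in% ids)) stop2("roots must be proposition ids")
  bank <- structure(list(passage_id = as.character(passage_id),
                         propositions = propositions, roots = roots,
                         synonyms = synonyms, levels = NULL),
                    class = "proposition_bank")
  check_acyclic(bank)
  bank
}

# reference graph (prop -> prop args) must be a DAG
check_acyclic <- function(bank) {
  ids <- vapply(bank$propositions, function(p) as.character(p$id), character(1))
  adj <- lapply(bank$propositions, function(p)
    intersect(as.character(p$args), ids))
  names(adj) <- ids
  state <- setNames(rep(0L, length(ids)), ids)  # 0 new, 1 in stack, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) stop2("cycle detected in proposition references at ", v)
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w)
    state[[v]] <<- 2L
  }
  for (v in ids) visit(v)
  invisible(bank)
}

#' Assign hierarchy levels to a proposition bank
#'
#' Applies the three-level rule: a proposition is *main* if it is a flagged
#' root; *mid* if (not main and) it takes any main proposition as an
#' argument; *detail* otherwise. Referencing both a main and a lower
#' proposition still yields mid (referencing any main takes precedence).
#' Every proposition receives exactly one level.
#'
#' @param bank a [proposition_bank()].
#' @return The bank with a named `levels` vector (`"main"`, `"mid"`,
#'   `"detail"`).
#' @export
assign_levels <- function(bank) {
  stopifnot(inherits(bank, "proposition_bank"))
  check_acyclic(bank)
  ids <- vapply(bank$propositions, function(p) as.character(p$id), character(1))
  lev <- setNames(rep("detail", length(ids)), ids)
  lev[bank$roots] <- "main"
  for (p in bank$propositions) {
    id <- as.character(p$id)
    if (lev[[id]] == "main") next
    if (any(as.character(p$args) %in% bank$roots)) lev[[id]] <- "mid"
  }
  bank$levels <- lev
  bank
}

#' Read a proposition bank from JSON
#'
#' Schema: `{passage_id, roots, synonyms: {lemma: [alts]},
#' propositions: [{id, predicate, args}]}`.
#' @param path JSON file path.
#' @return A level-assigned [proposition_bank()].
#' @export
read_proposition_bank <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  syn <- lapply(j$synonyms %||% list(), function(s) as.character(unlist(s)))
  props <- lapply(j$propositions, function(p)
    list(id = p$id, predicate = p$predicate,
         args = as.character(unlist(p$args))))
  assign_levels(proposition_bank(j$passage_id, props,
                                 as.character(unlist(j$roots)), syn))
}

#' Score a free-recall transcript against a proposition bank
#'
#' Binary, synonym-tolerant credit: a proposition is recalled iff its
#' predicate lemma and all of its atomic-argument lemmas appear in the
#' lemmatized transcript, each matched directly or via the bank's synonym
#' sets. No half credit. Propositional arguments impose no extra lexical
#' requirement beyond their own independent scoring. Matching is
#' bag-of-lemmas over the whole transcript: free recall is scored for
#' content, not order.
#'
#' @param transcript a character string of recall text, or a token vector.
#' @param bank a [proposition_bank()]; levels are assigned on the fly if
#'   missing.
#' @param lemmatizer function mapping a token vector to lemmas (default
#'   [lemmatize()]).
#' @return A data.frame of class `recall_score` with one row per level
#'   (`detail`, `mid`, `main`): `n_total`, `n_recalled` and `pct`.
#' @examples
#' bank <- read_proposition_bank(
#'   system.file("extdata", "toy_bank.json", package = "vocrecall"))
#' score_transcript("the captain sailed the sea", bank)
#' @export
score_transcript <- function(transcript, bank, lemmatizer = lemmatize) {
  stopifnot(inherits(bank, "proposition_bank"))
  if (is.null(bank$levels)) bank <- assign_levels(bank)
  if (length(bank$propositions) == 0) stop2("empty proposition bank")
  tokens <- if (length(transcript) == 1L) tokenize_words(transcript)
            else tolower(as.character(transcript))
  have <- unique(lemmatizer(tokens))
  syn <- bank$synonyms
  matched <- function(lemma) {
    if (lemma %in% have) return(TRUE)
    alts <- syn[[lemma]]
    !is.null(alts) && any(alts %in% have)
  }
  ids <- vapply(bank$propositions, function(p) as.character(p$id), character(1))
  lev_order <- c("detail", "mid", "main")
  n_total <- setNames(integer(3), lev_order)
  n_rec <- setNames(integer(3), lev_order)
  for (p in bank$propositions) {
    lv <- bank$levels[[as.character(p$id)]]
    n_total[lv] <- n_total[lv] + 1L
    atoms <- setdiff(as.character(p$args), ids)
    need <- c(as.character(p$predicate), atoms)
    if (all(vapply(need, matched, logical(1))))
      n_rec[lv] <- n_rec[lv] + 1L
  }
  out <- data.frame(level = lev_order, n_total = as.integer(n_total),
                    n_recalled = as.integer(n_rec),
                    pct = ifelse(n_total > 0, 100 * n_rec / n_total, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("recall_score", "data.frame")
  out
}

#' Assemble per-cell recall proportions from scores and a design plan
#'
#' Joins per-(participant, passage) recall scores with the counterbalanced
#' plan into the long cell table the analysis stage consumes: one row per
#' participant x passage x hierarchy level.
#'
#' @param scores a data.frame with columns `participant`, `passage`, `level`,
#'   `n_total`, `n_recalled` (e.g. stacked [score_transcript()] results).
#' @param plan a [build_design()] plan.
#' @return A data.frame of class `cell_table` with columns `participant`,
#'   `passage`, `format`, `clarity`, `predictability`, `level`, `n_props`,
#'   `n_recalled`, `proportion`.
#' @export
aggregate_scores <- function(scores, plan) {
  stopifnot(is.data.frame(scores), inherits(plan, "design_plan"))
  need <- c("participant", "passage", "level", "n_total", "n_recalled")
  if (!all(need %in% names(scores)))
    stop2("'scores' must have columns ", paste(need, collapse = ", "))
  key_plan <- paste(plan$participant, plan$passage, sep = "\r")
  key_sc <- unique(paste(scores$participant, scores$passage, sep = "\r"))
  missing <- setdiff(key_plan, key_sc)
  if (length(missing))
    stop2("missing scores for plan cells: ",
          paste(gsub("\r", ":", missing), collapse = ", "))
  m <- merge(plan, scores, by = c("participant", "passage"))
  out <- data.frame(participant = m$participant, passage = m$passage,
                    format = m$format, clarity = m$clarity,
                    predictability = m$predictability, level = m$level,
                    n_props = m$n_total, n_recalled = m$n_recalled,
                    proportion = ifelse(m$n_total > 0,
                                        m$n_recalled / m$n_total, NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant, out$passage, match(out$level,
               c("detail", "mid", "main"))), ]
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}
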