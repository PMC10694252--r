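#' Tokenize passage text into words
#'
#' Lower-cases, strips punctuation (keeping internal apostrophes), and splits
#' on whitespace.
#' @param text a character string.
#' @return Character vector of word tokens.
#' @export
tokenize_words <- function(text) {
  stopifnot(is.character(text))
  text <- tolower(paste(text, collapse = " "))
  text <- gsub("[^a-z0-9' ]+", " ", text)
  text <- gsub("(^|\\s)'+|'+(\\s|$)", " ", text)  # strip quoting apostrophes
  toks <- strsplit(trimws(gsub("\\s+", " ", text)), " ")[[1]]
  toks[nzchar(toks)]
}

#' Discourse passage
#'
#' A stimulus passage: its word tokens and its inter-word predictability
#' class. Cloze predictability (the fraction of norming respondents supplying
#' a deleted word) summarizes the contextual constraint of the passage; the
#' experiment's low- and high-predictability sets average 0.51 and 0.67.
#'
#' @param id passage identifier.
#' @param text passage text (tokenized internally) or `NULL` if `words` given.
#' @param predictability_class `"high"` or `"low"`.
#' @param mean_cloze mean inter-word cloze probability in \[0, 1\].
#' @param words pre-tokenized word vector (alternative to `text`).
#' @return An object of class `passage`.
#' @export
passage <- function(id, text = NULL, predictability_class = c("high", "low"),
                    mean_cloze = NA_real_, words = NULL) {
  predictability_class <- match.arg(predictability_class)
  if (is.null(words)) {
    if (is.null(text)) stop2("supply 'text' or 'words'")
    words <- tokenize_words(text)
  }
  if (length(words) == 0) stop2("passage has no words")
  if (!is.na(mean_cloze) && (mean_cloze < 0 || mean_cloze > 1))
    stop2("'mean_cloze' must be in [0, 1]")
  structure(list(id = as.character(id), words = words,
                 predictability_class = predictability_class,
                 mean_cloze = mean_cloze),
            class = "passage")
}

#' Segment a passage at annotated boundaries
#'
#' Splits the word sequence for self-paced presentation. Boundary indices are
#' 0-based: a boundary at index `k` means "interrupt before word k", so legal
#' boundaries lie strictly between 0 and `length(words)`. Segmentation is
#' lossless: concatenating the segments reproduces the word list.
#'
#' @param passage a [passage()].
#' @param boundaries strictly ascending integer vector of 0-based word
#'   indices in `(0, length(words))`; empty for a single segment.
#' @return An object of class `segmented_passage` with elements `passage_id`,
#'   `boundaries` and `segments` (list of word vectors).
#' @export
segment_passage <- function(passage, boundaries = integer()) {
  stopifnot(inherits(passage, "passage"))
  n <- length(passage$words)
  boundaries <- as.integer(boundaries)
  if (length(boundaries)) {
    if (any(is.na(boundaries))) stop2("boundaries must be integers")
    if (any(boundaries <= 0 | boundaries >= n))
      stop2("boundaries must lie strictly inside (0, ", n, ")")
    if (any(diff(boundaries) <= 0))
      stop2("boundaries must be strictly ascending (no duplicates)")
  }
  cuts <- c(0L, boundaries, n)
  segments <- lapply(seq_len(length(cuts) - 1L), function(i)
    passage$words[(cuts[i] + 1L):cuts[i + 1L]])
  structure(list(passage_id = passage$id, boundaries = boundaries,
                 segments = segments),
            class = "segmented_passage")
}

#' Segment statistics for a set of segmented passages
#'
#' @param segmented a non-empty list of [segment_passage()] results.
#' @return A list with `mean_segments_per_passage` and `mean_words_per_segment`
#'   (total words over total segments).
#' @export
segment_stats <- function(segmented) {
  if (!is.list(segmented) || length(segmented) == 0)
    stop2("'segmented' must be a non-empty list")
  n_seg <- vapply(segmented, function(s) length(s$segments), numeric(1))
  n_words <- vapply(segmented, function(s)
    sum(lengths(s$segments)), numeric(1))
  list(mean_segments_per_passage = mean(n_seg),
       mean_words_per_segment = sum(n_words) / sum(n_seg))
}

#' Heuristic boundary suggestion for fixture passages
#'
#' A convenience for generating test fixtures only: splits after
#' sentence-final punctuation and after commas followed by a coordinating
#' conjunction. This is a crude orthographic heuristic, not the linguistic
#' "major clause and sentence boundary" annotation real stimuli require,
#' which is human work supplied as input.
#'
#' @param text passage text including punctuation.
#' @return 0-based boundary indices into the [tokenize_words()] token list.
#' @export
suggest_boundaries <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- strsplit(trimws(gsub("\\s+", " ", text)), " ")[[1]]
  conj <- c("and", "but", "or", "so", "because", "while", "when")
  word_i <- 0L
  bounds <- integer()
  for (k in seq_along(raw)) {
    tok <- raw[k]
    has_word <- grepl("[a-zA-Z0-9]", tok)
    if (has_word) word_i <- word_i + 1L
    if (word_i == 0L) next
    nxt <- if (k < length(raw)) tolower(gsub("[^a-z]", "", tolower(raw[k + 1]))) else ""
    cut <- grepl("[.!?]$", tok) || (grepl(",$", tok) && nxt %in% conj)
    if (cut && k < length(raw)) bounds <- c(bounds, word_i)
  }
  n <- word_i
  unique(bounds[bounds > 0 & bounds < n])
}

#' Read passages from a JSON file
#'
#' Expected schema per entry: `{id, text, predictability_class, mean_cloze,
#' boundaries}` (boundaries optional).
#' @param path JSON file path.
#' @return A list of [passage()] objects; any boundaries are attached as the
#'   `"boundaries"` attribute of each passage.
#' @export
read_passages <- function(path) {
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(entries, function(e) {
    p <- passage(e$id, text = e$text,
                 predictability_class = e$predictability_class,
                 mean_cloze = e$mean_cloze %||% NA_real_)
    attr(p, "boundaries") <- as.integer(unlist(e$boundaries %||% integer()))
    p
  })
}
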