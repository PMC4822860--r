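#' Construct a single annotated recording
#'
#' A recording is an ordered sequence of phrase events: a phrase-type label
#' plus start and end times in seconds. Events must be supplied in
#' non-decreasing start-time order with `end > start` and non-empty labels.
#'
#' @param labels character vector of phrase-type codes (e.g. `"ai"`).
#' @param start,end numeric vectors of phrase boundary times in seconds.
#'   When omitted, synthetic times are generated at one phrase per second.
#' @param individual_id identifier of the singing individual.
#' @param recorded_at recording timestamp (`POSIXct`, or anything coercible
#'   via [as.POSIXct()]); used to order recordings chronologically.
#' @param source recording identifier, typically the annotation file name.
#' @return an object of class `song_recording`.
#' @export
song_recording <- function(labels, start = NULL, end = NULL,
                           individual_id = "unknown", recorded_at = NA,
                           source = NA_character_) {
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(start)) start <- as.numeric(seq_len(n) - 1L)
  if (is.null(end)) end <- start + 0.5
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0L) {
    if (any(!nzchar(labels))) stop("empty phrase labels are not allowed")
    if (any(end <= start)) stop("phrase end times must exceed start times")
    if (is.unsorted(start)) stop("phrase events must be ordered by start time")
  }
  if (!inherits(recorded_at, "POSIXct") && !is.na(recorded_at[1L])) {
    recorded_at <- as.POSIXct(recorded_at, tz = "UTC")
  }
  structure(
    list(labels = labels, start = as.numeric(start), end = as.numeric(end),
         individual_id = individual_id, recorded_at = recorded_at,
         source = source),
    class = "song_recording"
  )
}

#' @export
print.song_recording <- function(x, ...) {
  cat("Recording", x$source, "of", x$individual_id, "-", length(x$labels),
      "phrases,", length(unique(x$labels)), "types\n")
  invisible(x)
}

#' @export
length.song_recording <- function(x) length(x$labels)

#' Assemble a per-individual corpus of recordings
#'
#' Orders recordings chronologically (by `recorded_at`, falling back to the
#' lexicographic order of `source` when timestamps are missing) and records
#' the vocabulary: the union of phrase-type labels observed, i.e. the
#' individual's observed repertoire.
#'
#' @param recordings list of [song_recording()] objects.
#' @param individual_id identifier; defaults to the first recording's.
#' @return an object of class `song_corpus` with elements `individual_id`,
#'   `recordings` and `vocabulary` (sorted).
#' @export
song_corpus <- function(recordings, individual_id = NULL) {
  stopifnot(length(recordings) >= 1L,
            all(vapply(recordings, inherits, logical(1L), "song_recording")))
  if (is.null(individual_id)) individual_id <- recordings[[1L]]$individual_id
  ts <- vapply(recordings, function(r) {
    if (inherits(r$recorded_at, "POSIXct")) as.numeric(r$recorded_at) else NA_real_
  }, numeric(1L))
  src <- vapply(recordings, function(r) r$source %||% NA_character_, character(1L))
  ord <- order(ts, src, na.last = TRUE)
  recordings <- recordings[ord]
  vocab <- sort(unique(unlist(lapply(recordings, function(r) r$labels))))
  structure(
    list(individual_id = individual_id, recordings = recordings,
         vocabulary = vocab),
    class = "song_corpus"
  )
}

#' @export
print.song_corpus <- function(x, ...) {
  cat("Song corpus for individual", x$individual_id, "\n")
  cat("  recordings:", length(x$recordings), "\n")
  cat("  phrases:   ", corpus_size(x), "\n")
  cat("  repertoire:", length(x$vocabulary), "phrase types\n")
  invisible(x)
}

#' @export
summary.song_corpus <- function(object, ...) {
  lens <- recording_lengths(object)
  out <- list(individual_id = object$individual_id,
              n_recordings = length(object$recordings),
              n_phrases = sum(lens),
              repertoire_size = length(object$vocabulary),
              recording_lengths = lens)
  class(out) <- "summary.song_corpus"
  out
}

#' @export
print.summary.song_corpus <- function(x, ...) {
  cat("Individual      :", x$individual_id, "\n")
  cat("Recordings      :", x$n_recordings, "\n")
  cat("Phrases recorded:", x$n_phrases, "\n")
  cat("Repertoire size :", x$repertoire_size, "\n")
  cat("Recording lengths:", paste(x$recording_lengths, collapse = ", "), "\n")
  invisible(x)
}

#' Total number of phrases in a corpus
#' @param corpus a `song_corpus`.
#' @return integer phrase count.
#' @export
corpus_size <- function(corpus) {
  sum(vapply(corpus$recordings, function(r) length(r$labels), integer(1L)))
}

#' Per-recording phrase counts
#' @param corpus a `song_corpus`.
#' @return named integer vector (names are recording sources).
#' @export
recording_lengths <- function(corpus) {
  out <- vapply(corpus$recordings, function(r) length(r$labels), integer(1L))
  names(out) <- recording_ids(corpus)
  out
}

recording_ids <- function(corpus) {
  vapply(seq_along(corpus$recordings), function(i) {
    s <- corpus$recordings[[i]]$source
    if (is.na(s) || !nzchar(s)) paste0("recording_", i) else s
  }, character(1L))
}

#' Drop recordings with too few phrases
#'
#' Short recordings carry little sequential information; following standard
#' practice for this kind of corpus, recordings with fewer than `min_phrases`
#' phrases are discarded and the vocabulary is recomputed from the remainder.
#'
#' @param corpus a `song_corpus`.
#' @param min_phrases minimum number of phrases a recording must contain
#'   (default 50).
#' @return a filtered `song_corpus` (possibly with zero recordings, in which
#'   case an empty corpus of the same individual is returned).
#' @export
filter_short_recordings <- function(corpus, min_phrases = 50L) {
  stopifnot(inherits(corpus, "song_corpus"), min_phrases >= 1L)
  keep <- vapply(corpus$recordings, function(r) length(r$labels) >= min_phrases,
                 logical(1L))
  if (!any(keep)) {
    out <- corpus
    out$recordings <- list()
    out$vocabulary <- character(0L)
    return(out)
  }
  song_corpus(corpus$recordings[keep], corpus$individual_id)
}

#' Chronological train/test split of a corpus
#'
#' Concatenates recordings in chronological order, finds the phrase at
#' position `ceiling(total / 2)`, and assigns the recording containing it plus
#' all preceding recordings to the training set; the remainder form the
#' testing set. Recordings are never split in two. If the midpoint falls in
#' the final recording the split would leave the testing set empty; in that
#' case the final recording is moved to the testing side with a warning.
#'
#' @param corpus a `song_corpus` with at least two recordings.
#' @return an object of class `split_spec`: a list with `train` and `test`
#'   character vectors of recording identifiers.
#' @export
train_test_split <- function(corpus) {
  stopifnot(inherits(corpus, "song_corpus"))
  ids <- recording_ids(corpus)
  if (length(ids) < 2L) stop("cannot split a corpus with fewer than 2 recordings")
  lens <- recording_lengths(corpus)
  total <- sum(lens)
  midpoint <- ceiling(total / 2)
  cum <- cumsum(lens)
  i_mid <- which(cum >= midpoint)[1L]
  if (i_mid >= length(ids)) {
    warning("midpoint falls in the final recording; moving it to the testing set")
    i_mid <- length(ids) - 1L
  }
  split_spec(train = ids[seq_len(i_mid)], test = ids[(i_mid + 1L):length(ids)])
}

#' Construct a train/test split specification
#' @param train,test disjoint character vectors of recording identifiers.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(train, test) {
  if (length(intersect(train, test)) > 0L) stop("train and test sets overlap")
  structure(list(train = train, test = test), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat("Split:", length(x$train), "training /", length(x$test),
      "testing recordings\n")
  invisible(x)
}

#' Leave-one-recording-out cross-validation folds
#'
#' One fold per recording: fold `i` holds out recording `i` for evaluation
#' and trains on all others.
#'
#' @param corpus a `song_corpus` with at least two recordings.
#' @return a list of [split_spec()] objects.
#' @export
loocv_folds <- function(corpus) {
  ids <- recording_ids(corpus)
  if (length(ids) < 2L) stop("LOOCV requires at least 2 recordings")
  lapply(seq_along(ids), function(i) split_spec(train = ids[-i], test = ids[i]))
}

#' Subset a corpus by recording identifiers
#'
#' @param corpus a `song_corpus`.
#' @param ids character vector of recording identifiers (as in
#'   [recording_lengths()] names).
#' @return a `song_corpus` containing only the named recordings. The
#'   vocabulary is recomputed. Returns an empty corpus when `ids` is empty.
#' @export
corpus_subset <- function(corpus, ids) {
  all_ids <- recording_ids(corpus)
  missing <- setdiff(ids, all_ids)
  if (length(missing) > 0L) {
    stop("unknown recording identifiers: ", paste(missing, collapse = ", "))
  }
  keep <- all_ids %in% ids
  if (!any(keep)) {
    out <- corpus
    out$recordings <- list()
    out$vocabulary <- character(0L)
    return(out)
  }
  song_corpus(corpus$recordings[keep], corpus$individual_id)
}

# Integer-encoded label sequences for all recordings, w.r.t. a vocabulary.
corpus_int_seqs <- function(corpus, vocabulary) {
  lapply(corpus$recordings, function(r) encode_labels(r$labels, vocabulary))
}
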