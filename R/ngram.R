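# N-gram and recurrence-interval distributions and their L1 comparison: the
# currency in which simulated and observed sequences are compared.

# ---- fast integer-coded internals ------------------------------------------

# Relative frequencies of N-grams (numeric base-C keys), within recordings.
ngram_freq_int <- function(seqs, N, C) {
  keys <- numeric(0)
  for (x in seqs) {
    L <- length(x)
    if (L < N) next
    k <- x[1:(L - N + 1L)] - 1
    if (N > 1L) for (j in 2:N) k <- k * C + (x[j:(L - N + j)] - 1)
    keys <- c(keys, k)
  }
  if (length(keys) == 0L) return(list(keys = numeric(0), freq = numeric(0)))
  sorted <- if (C^N < .Machine$integer.max) {
    sort.int(as.integer(keys), method = "radix")
  } else {
    sort(keys)
  }
  r <- rle(as.numeric(sorted))
  list(keys = r$values, freq = r$lengths / length(keys))
}

# Recurrence intervals: intervening-phrase counts between consecutive
# occurrences of the same type, within recordings; adjacent repeat = 0.
recurrence_freq_int <- function(seqs) {
  gaps <- integer(0)
  for (x in seqs) {
    if (length(x) < 2L) next
    for (posn in split(seq_along(x), x)) {
      if (length(posn) >= 2L) gaps <- c(gaps, diff(posn) - 1L)
    }
  }
  if (length(gaps) == 0L) return(list(keys = numeric(0), freq = numeric(0)))
  r <- rle(sort(as.numeric(gaps)))
  list(keys = r$values, freq = r$lengths / length(gaps))
}

# L1 distance between two key/frequency tables over the union of keys.
l1_int <- function(a, b) {
  if (length(a$keys) == 0L && length(b$keys) == 0L) return(0)
  keys <- sort(unique(c(a$keys, b$keys)))
  fa <- numeric(length(keys)); fa[match(a$keys, keys)] <- a$freq
  fb <- numeric(length(keys)); fb[match(b$keys, keys)] <- b$freq
  sum(abs(fa - fb))
}

# ---- public distribution objects -------------------------------------------

new_seq_distribution <- function(kind, parameter, table) {
  structure(list(kind = kind, parameter = parameter, table = table),
            class = "seq_distribution")
}

#' @export
print.seq_distribution <- function(x, ...) {
  what <- if (x$kind == "ngram") paste0(x$parameter, "-gram") else
    "recurrence-interval"
  cat(what, "distribution over", length(x$table), "keys\n")
  invisible(x)
}

#' N-gram distribution of a corpus
#'
#' Relative frequencies of all length-`N` phrase subsequences, counted within
#' recordings only (N-grams never span recording boundaries) and normalized by
#' the total N-gram count so the entries sum to one.
#'
#' @param corpus a [song_corpus()].
#' @param N subsequence length, 1 to 7.
#' @return a `seq_distribution` whose `table` is a named numeric vector;
#'   multi-phrase keys join labels with a space.
#' @export
ngram_distribution <- function(corpus, N) {
  stopifnot(inherits(corpus, "song_corpus"), N >= 1L, N <= 7L)
  vocab <- corpus$vocabulary
  C <- length(vocab)
  f <- ngram_freq_int(corpus_int_seqs(corpus, vocab), N, C)
  if (length(f$keys) == 0L) {
    stop("no recording of length >= ", N, " in the corpus")
  }
  labs <- vapply(f$keys, function(code) {
    context_label(decode_code(code + 1, N, C), vocab)
  }, character(1L))
  new_seq_distribution("ngram", as.integer(N), stats::setNames(f$freq, labs))
}

#' Recurrence-interval distribution of a corpus
#'
#' The recurrence interval is the number of intervening phrases between two
#' consecutive occurrences of the same phrase type within a recording (an
#' immediate repeat scores 0). Frequencies are normalized over all recorded
#' intervals; types occurring once contribute nothing.
#'
#' @param corpus a [song_corpus()].
#' @return a `seq_distribution` keyed by interval length.
#' @export
recurrence_distribution <- function(corpus) {
  stopifnot(inherits(corpus, "song_corpus"))
  vocab <- corpus$vocabulary
  f <- recurrence_freq_int(corpus_int_seqs(corpus, vocab))
  new_seq_distribution("recurrence", NA_integer_,
                       stats::setNames(f$freq, format(f$keys, scientific = FALSE,
                                                      trim = TRUE)))
}

#' L1 distance between two distributions
#'
#' The sum of absolute frequency differences over the union of keys (a key
#' absent from one distribution contributes its full frequency). Since both
#' inputs sum to one the distance lies in `[0, 2]`: 0 for identical
#' distributions, 2 for disjoint support.
#'
#' @param d1,d2 `seq_distribution` objects of the same kind and parameter.
#' @return a number in `[0, 2]`.
#' @export
l1_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "seq_distribution"), inherits(d2, "seq_distribution"))
  if (!identical(d1$kind, d2$kind) ||
      !identical(is.na(d1$parameter), is.na(d2$parameter)) ||
      (!is.na(d1$parameter) && d1$parameter != d2$parameter)) {
    stop("distributions of different kind or parameter are not comparable")
  }
  keys <- union(names(d1$table), names(d2$table))
  f1 <- d1$table[keys]; f1[is.na(f1)] <- 0
  f2 <- d2$table[keys]; f2[is.na(f2)] <- 0
  sum(abs(f1 - f2))
}

# ---- model assessment -------------------------------------------------------

#' Compare simulated corpora with held-out data by L1 distance
#'
#' For each N-gram size and for recurrence intervals, computes the baseline
#' L1 distance between the training and testing sets and, per candidate
#' model, the mean over replicate simulations of the L1 distance between the
#' simulated corpus and the testing set. A model whose simulations sit at the
#' training baseline reproduces the testing set about as well as the training
#' data themselves do.
#'
#' @param training,testing the two sides of a chronological split.
#' @param simulations named list: model name -> list of simulated corpora
#'   (see [replicate_simulations()]).
#' @param N_range N-gram sizes to evaluate (default 1 to 7).
#' @param include_recurrence also compare recurrence-interval distributions.
#' @return a data frame with columns `individual`, `metric` (`"1"`..`"7"` or
#'   `"RI"`), `model`, `mean_l1`, `sd_l1`, `baseline_l1`, `n_reps`.
#' @export
assess_models <- function(training, testing, simulations, N_range = 1:7,
                          include_recurrence = TRUE) {
  stopifnot(length(simulations) >= 1L,
            all(vapply(simulations, length, integer(1L)) >= 1L))
  vocab <- sort(unique(c(training$vocabulary, testing$vocabulary)))
  C <- length(vocab)
  test_seqs <- corpus_int_seqs(testing, vocab)
  train_seqs <- corpus_int_seqs(training, vocab)
  metrics <- c(as.character(N_range), if (include_recurrence) "RI")
  ref <- lapply(metrics, function(m) {
    if (m == "RI") recurrence_freq_int(test_seqs)
    else ngram_freq_int(test_seqs, as.integer(m), C)
  })
  names(ref) <- metrics
  base <- vapply(metrics, function(m) {
    d <- if (m == "RI") recurrence_freq_int(train_seqs)
         else ngram_freq_int(train_seqs, as.integer(m), C)
    l1_int(d, ref[[m]])
  }, numeric(1L))
  out <- list()
  for (model_name in names(simulations)) {
    reps <- simulations[[model_name]]
    l1 <- matrix(NA_real_, nrow = length(reps), ncol = length(metrics),
                 dimnames = list(NULL, metrics))
    for (r in seq_along(reps)) {
      sim_seqs <- corpus_int_seqs(reps[[r]], vocab)
      for (m in metrics) {
        d <- if (m == "RI") recurrence_freq_int(sim_seqs)
             else ngram_freq_int(sim_seqs, as.integer(m), C)
        l1[r, m] <- l1_int(d, ref[[m]])
      }
    }
    out[[model_name]] <- data.frame(
      individual = training$individual_id, metric = metrics,
      model = model_name, mean_l1 = colMeans(l1),
      sd_l1 = apply(l1, 2L, stats::sd), baseline_l1 = unname(base),
      n_reps = length(reps), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Across-individual divergence tests for an assessment table
#'
#' For each metric and model, a one-tailed paired t-test across individuals
#' of the mean simulation L1 against the training baseline (alternative: the
#' simulations lie further from the testing set than the training set does).
#'
#' @param assessment row-bound [assess_models()] tables from several
#'   individuals.
#' @return a data frame with columns `metric`, `model`, `t`, `df`, `p`.
#' @export
assess_ttests <- function(assessment) {
  combos <- unique(assessment[, c("metric", "model")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- assessment$metric == combos$metric[i] &
      assessment$model == combos$model[i]
    a <- assessment[sel, ]
    tt <- stats::t.test(a$mean_l1, a$baseline_l1, paired = TRUE,
                        alternative = "greater")
    data.frame(metric = combos$metric[i], model = combos$model[i],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
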