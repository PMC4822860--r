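# Next-phrase prediction: each model predicts the modal phrase type of its
# conditional distribution for the immediately preceding context.

#' Predict the most likely next phrase type
#'
#' Returns the argmax of the model's conditional distribution for the given
#' context: the unconditional mode for a zero-order model, the deepest
#' included state for an interpolated model. Unseen contexts resolve through
#' the smoothing backoff chain; ties break to the lexicographically first
#' label.
#'
#' @param model a [markov_model()], [smooth_markov()] model, or
#'   [forward_selection()] model.
#' @param context character vector of preceding phrase labels (may be empty).
#' @return a single phrase-type label.
#' @export
predict_next <- function(model, context = character(0L)) {
  UseMethod("predict_next")
}

#' @export
predict_next.markov_model <- function(model, context = character(0L)) {
  predict_next(smooth_markov(model), context)
}

#' @export
predict_next.smoothed_markov <- function(model, context = character(0L)) {
  d <- smoothed_dist(model, context)
  names(d)[which.max(d)]
}

#' @export
predict_next.interpolated_markov <- function(model, context = character(0L)) {
  context <- as.character(context %||% character(0L))
  n <- length(context)
  syms <- encode_labels(context, model$vocabulary)
  C <- model$C
  level <- 0L
  code <- 1
  if (n >= 2L) {
    c2 <- (syms[n - 1L] - 1) * C + syms[n]
    if (c2 %in% model$included2) { level <- 2L; code <- c2 }
  }
  if (level == 0L && n >= 1L && syms[n] %in% model$included1) {
    level <- 1L; code <- syms[n]
  }
  d <- cond_dist_sm(model$sm, level, code)
  model$vocabulary[which.max(d)]
}

#' @export
predict.markov_model <- function(object, context = character(0L), ...) {
  predict_next(object, context)
}

#' @export
predict.smoothed_markov <- function(object, context = character(0L), ...) {
  predict_next(object, context)
}

#' @export
predict.interpolated_markov <- function(object, context = character(0L), ...) {
  predict_next(object, context)
}

# Vectorised predictions (integer symbols) for all scored positions.
predicted_symbols <- function(model, pos) {
  UseMethod("predicted_symbols")
}

#' @export
predicted_symbols.smoothed_markov <- function(model, pos) {
  level <- min(model$order, 2L)
  codes <- switch(as.character(level), "0" = rep.int(1, pos$n),
                  "1" = pos$c1, "2" = pos$c2)
  out <- integer(pos$n)
  for (grp in split(seq_len(pos$n), codes)) {
    out[grp] <- which.max(cond_dist_sm(model, level, codes[grp[1L]]))
  }
  out
}

#' @export
predicted_symbols.markov_model <- function(model, pos) {
  predicted_symbols(smooth_markov(model), pos)
}

#' @export
predicted_symbols.interpolated_markov <- function(model, pos) {
  lvl2 <- pos$c2 %in% model$included2
  lvl1 <- !lvl2 & (pos$c1 %in% model$included1)
  codes <- ifelse(lvl2, pos$c2, ifelse(lvl1, pos$c1, 0))
  levels <- ifelse(lvl2, 2L, ifelse(lvl1, 1L, 0L))
  out <- integer(pos$n)
  for (grp in split(seq_len(pos$n), paste0(levels, ":", codes))) {
    i <- grp[1L]
    code <- if (levels[i] == 0L) 1 else codes[i]
    out[grp] <- which.max(cond_dist_sm(model$sm, levels[i], code))
  }
  out
}

# Shared preparation: positions of a testing corpus w.r.t. a model vocabulary
# (extended when the testing set contains novel labels).
prediction_setup <- function(model, testing, skip) {
  model <- if (inherits(model, "interpolated_markov")) {
    extend_interpolated(model, testing$vocabulary)
  } else if (inherits(model, "smoothed_markov")) {
    ensure_vocabulary(model, testing$vocabulary)
  } else {
    smooth_markov(model, vocabulary = testing$vocabulary)
  }
  pos <- scored_positions(testing, if (inherits(model, "interpolated_markov"))
    model$vocabulary else model$vocabulary, skip)
  list(model = model, pos = pos)
}

#' Next-phrase prediction accuracy
#'
#' The percentage of scored positions (the first two phrases of each
#' recording are excluded, mirroring likelihood scoring) where the model's
#' predicted phrase type equals the observed one.
#'
#' @param model a model accepted by [predict_next()].
#' @param testing a [song_corpus()].
#' @param skip initial phrases per recording excluded from scoring.
#' @return accuracy in percent, with attribute `"n_phrases"`.
#' @export
prediction_accuracy <- function(model, testing, skip = 2L) {
  ps <- prediction_setup(model, testing, skip)
  if (ps$pos$n == 0L) stop("no scorable phrases")
  hits <- predicted_symbols(ps$model, ps$pos) == ps$pos$nxt
  structure(100 * mean(hits), n_phrases = ps$pos$n)
}

#' Accuracy restricted to positions where models disagree
#'
#' Restricts scoring to positions where not all models make the same
#' prediction; small overall accuracy differences between similar models are
#' concentrated (and therefore easier to see) on this restriction set.
#'
#' @param models named list of two or more models.
#' @param testing a [song_corpus()].
#' @param skip initial phrases per recording excluded from scoring.
#' @return a list with `n_disagreements`, `n_total` and `accuracy` (named
#'   percent vector over the restriction set; `NaN` when the models never
#'   disagree).
#' @export
disagreement_accuracy <- function(models, testing, skip = 2L) {
  stopifnot(length(models) >= 2L)
  preds <- NULL
  obs <- NULL
  labels <- list()
  for (nm in names(models)) {
    ps <- prediction_setup(models[[nm]], testing, skip)
    vocab <- if (inherits(ps$model, "interpolated_markov")) ps$model$vocabulary
             else ps$model$vocabulary
    labels[[nm]] <- vocab[predicted_symbols(ps$model, ps$pos)]
    obs <- vocab[ps$pos$nxt]
  }
  preds <- do.call(cbind, labels)
  differ <- apply(preds, 1L, function(r) length(unique(r)) > 1L)
  acc <- vapply(colnames(preds), function(nm) {
    100 * mean(preds[differ, nm] == obs[differ])
  }, numeric(1L))
  list(n_disagreements = sum(differ), n_total = length(obs), accuracy = acc)
}

#' Prediction accuracy stratified by inter-phrase interval
#'
#' Assigns every scored position to a time bin by the silence gap between the
#' previous phrase's end and the current phrase's start (set `gap = "onset"`
#' for onset-to-onset intervals) and reports per-bin accuracy and counts.
#' Non-positive gaps are clamped into the first bin; the last bin is open
#' above.
#'
#' @param model a model accepted by [predict_next()].
#' @param testing a [song_corpus()] whose recordings carry phrase times.
#' @param bin_edges increasing numeric vector of bin boundaries in seconds;
#'   defaults to one-second bins 0-10 with a final `> 10 s` bin.
#' @param gap `"silence"` (previous end to current start) or `"onset"`
#'   (onset to onset).
#' @param skip initial phrases per recording excluded from scoring.
#' @return a data frame with columns `bin_low`, `bin_high`, `accuracy`
#'   (percent; `NA` for empty bins) and `n`.
#' @export
rate_stratified_accuracy <- function(model, testing, bin_edges = 0:10,
                                     gap = c("silence", "onset"), skip = 2L) {
  gap <- match.arg(gap)
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  ps <- prediction_setup(model, testing, skip)
  pos <- ps$pos
  if (pos$n == 0L) stop("no scorable phrases")
  hits <- predicted_symbols(ps$model, pos) == pos$nxt
  gaps <- numeric(pos$n)
  for (i in seq_len(pos$n)) {
    r <- testing$recordings[[pos$rec[i]]]
    m <- pos$pos[i]
    gaps[i] <- if (gap == "silence") r$start[m] - r$end[m - 1L]
               else r$start[m] - r$start[m - 1L]
  }
  breaks <- c(bin_edges, Inf)
  bin <- pmax(findInterval(gaps, breaks), 1L)   # clamp non-positive gaps
  nbin <- length(bin_edges)
  out <- data.frame(bin_low = bin_edges,
                    bin_high = c(bin_edges[-1L], Inf),
                    accuracy = NA_real_, n = 0L)
  for (b in seq_len(nbin)) {
    sel <- bin == b
    out$n[b] <- sum(sel)
    if (any(sel)) out$accuracy[b] <- 100 * mean(hits[sel])
  }
  out
}
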