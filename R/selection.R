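#' Per-phrase negative log-likelihood of held-out sequences
#'
#' Scores a testing corpus under a model parametrized on training data:
#' \eqn{-\ln L = -\ln \prod_m P(x_m | \mathrm{model})}, accumulated with
#' Witten-Bell/backoff smoothing so every observation has positive
#' probability, then divided by the number of scored phrases. The first two
#' phrases of each recording are conditioning-only and are not scored (the
#' second-order model needs two preceding phrases); recordings of length two
#' or less contribute nothing.
#'
#' @param model a [markov_model()] (smoothed on the fly), a
#'   [smooth_markov()] model, or an interpolated model from
#'   [forward_selection()].
#' @param testing a non-empty [song_corpus()].
#' @param skip number of initial phrases per recording excluded from scoring
#'   (default 2).
#' @return the average per-phrase negative log-likelihood (natural log), with
#'   attribute `"n_phrases"` giving the number of scored phrases.
#' @export
sequence_nll <- function(model, testing, skip = 2L) {
  UseMethod("sequence_nll")
}

#' @export
sequence_nll.markov_model <- function(model, testing, skip = 2L) {
  sm <- smooth_markov(model, vocabulary = testing$vocabulary)
  sequence_nll(sm, testing, skip)
}

#' @export
sequence_nll.smoothed_markov <- function(model, testing, skip = 2L) {
  sm <- ensure_vocabulary(model, testing$vocabulary)
  pos <- scored_positions(testing, sm$vocabulary, skip)
  if (pos$n == 0L) stop("no scorable phrases: all recordings have length <= ", skip)
  lp <- level_logprobs(sm, pos, min(sm$order, 2L))
  structure(-sum(lp) / pos$n, n_phrases = pos$n)
}

ensure_vocabulary <- function(sm, vocabulary) {
  if (all(vocabulary %in% sm$vocabulary)) return(sm)
  smooth_markov(sm$base, vocabulary = unique(c(sm$vocabulary, vocabulary)))
}

#' @export
sequence_nll.interpolated_markov <- function(model, testing, skip = 2L) {
  ipm <- extend_interpolated(model, testing$vocabulary)
  pos <- scored_positions(testing, ipm$sm$vocabulary, skip)
  if (pos$n == 0L) stop("no scorable phrases: all recordings have length <= ", skip)
  lp <- interp_logprobs(ipm, pos)
  structure(-sum(lp) / pos$n, n_phrases = pos$n)
}

# Deepest-match log-probabilities under an interpolated model.
interp_logprobs <- function(ipm, pos) {
  lvl2 <- pos$c2 %in% ipm$included2
  lvl1 <- !lvl2 & (pos$c1 %in% ipm$included1)
  lvl0 <- !lvl2 & !lvl1
  lp <- numeric(pos$n)
  sub_level <- function(sel, level) {
    if (!any(sel)) return()
    sp <- list(nxt = pos$nxt[sel], c1 = pos$c1[sel], c2 = pos$c2[sel],
               n = sum(sel))
    lp[sel] <<- level_logprobs(ipm$sm, sp, level)
  }
  sub_level(lvl2, 2L)
  sub_level(lvl1, 1L)
  sub_level(lvl0, 0L)
  lp
}

#' Greedy forward selection of a mixed-order ("interpolated") Markov model
#'
#' Starting from the zero-order model, repeatedly adds the state (a
#' first-order context, or a second-order context whose first-order parent is
#' already included) that most reduces the training-set negative
#' log-likelihood, recording the testing-set negative log-likelihood after
#' each addition, until every observed second-order state has been added. The
#' returned model is the one at the testing-set minimum and may combine
#' zero-order, first-order and second-order states: a context ending in an
#' included pair uses the second-order conditional, otherwise an included
#' ultimate type uses the first-order conditional, otherwise the zero-order
#' fallback (deepest match wins). Candidate scoring uses the same
#' Witten-Bell/backoff smoothing as final evaluation, so states are not
#' rewarded for assigning zero probability to unseen events.
#'
#' Because each level's smoothed conditionals are fixed, a state's gain is the
#' summed log-probability change over exactly the positions whose deepest
#' match it becomes; gains are therefore additive and the greedy argmax is
#' computed from precomputed per-position level log-probabilities. Ties break
#' lexicographically by context label.
#'
#' @param training,testing non-empty [song_corpus()] objects.
#' @param skip initial phrases per recording excluded from scoring.
#' @return an object of class `interpolated_markov` with elements
#'   `included_first` / `included_second` (label vectors), `trace` (a data
#'   frame: one row per step with the state added and the training/testing
#'   per-phrase NLL), and `chosen_step` (0 = the zero-order model).
#' @export
forward_selection <- function(training, testing, skip = 2L) {
  stopifnot(inherits(training, "song_corpus"), inherits(testing, "song_corpus"))
  base <- markov_model(training, 2L)
  sm <- smooth_markov(base, vocabulary = testing$vocabulary)
  C <- sm$C
  tr <- scored_positions(training, sm$vocabulary, skip)
  te <- scored_positions(testing, sm$vocabulary, skip)
  if (tr$n == 0L || te$n == 0L) stop("training and testing must both contain recordings longer than ", skip, " phrases")
  lp_tr <- lapply(0:2, function(k) level_logprobs(sm, tr, k))
  lp_te <- lapply(0:2, function(k) level_logprobs(sm, te, k))

  # candidate states = contexts observed in training counts
  cand1 <- as.integer(sm$counts[[2L]]$ctx)            # symbols
  cand2 <- sm$counts[[3L]]$ctx                        # pair codes
  sum_by <- function(delta, codes, cand) {
    s <- vapply(split(delta, codes), sum, numeric(1L))
    out <- stats::setNames(numeric(length(cand)), format(cand, scientific = FALSE))
    hit <- intersect(names(s), names(out))
    out[hit] <- s[hit]
    out
  }
  g1_tr <- sum_by(lp_tr[[2L]] - lp_tr[[1L]], format(tr$c1, scientific = FALSE), cand1)
  g2_tr <- sum_by(lp_tr[[3L]] - lp_tr[[2L]], format(tr$c2, scientific = FALSE), cand2)
  g1_te <- sum_by(lp_te[[2L]] - lp_te[[1L]], format(te$c1, scientific = FALSE), cand1)
  g2_te <- sum_by(lp_te[[3L]] - lp_te[[2L]], format(te$c2, scientific = FALSE), cand2)

  lab1 <- sm$vocabulary[cand1]
  lab2 <- vapply(cand2, function(code) {
    context_label(decode_code(code, 2L, C), sm$vocabulary)
  }, character(1L))
  parent2 <- as.integer(((cand2 - 1) %% C) + 1)

  n1 <- length(cand1); n2 <- length(cand2)
  gains <- c(unname(g1_tr), unname(g2_tr))
  deltas_te <- c(unname(g1_te), unname(g2_te))
  labels <- c(lab1, lab2)
  orders <- c(rep(1L, n1), rep(2L, n2))
  added <- logical(n1 + n2)
  admissible <- c(rep(TRUE, n1), rep(FALSE, n2))

  tl_tr <- sum(lp_tr[[1L]])   # running total train log-likelihood
  tl_te <- sum(lp_te[[1L]])
  steps <- list()
  steps[[1L]] <- data.frame(step = 0L, state = NA_character_, order = 0L,
                            train_nll = -tl_tr / tr$n, test_nll = -tl_te / te$n,
                            stringsAsFactors = FALSE)
  done <- function() {
    if (n2 > 0L) all(added[(n1 + 1L):(n1 + n2)]) else all(added)
  }
  step <- 0L
  while (!done()) {
    avail <- admissible & !added
    if (!any(avail)) break
    g <- gains
    g[!avail] <- -Inf
    pick <- which.max(g)   # first maximum = lexicographic tie-break within order
    # exact ties across the two blocks: prefer the lexicographically first label
    ties <- which(avail & gains == gains[pick])
    if (length(ties) > 1L) pick <- ties[order(labels[ties])][1L]
    added[pick] <- TRUE
    if (orders[pick] == 1L) {
      admissible[n1 + which(parent2 == cand1[pick])] <- TRUE
    }
    tl_tr <- tl_tr + gains[pick]
    tl_te <- tl_te + deltas_te[pick]
    step <- step + 1L
    steps[[step + 1L]] <- data.frame(step = step, state = labels[pick],
                                     order = orders[pick],
                                     train_nll = -tl_tr / tr$n,
                                     test_nll = -tl_te / te$n,
                                     stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, steps)
  chosen <- which.min(trace$test_nll) - 1L
  sel <- trace$step >= 1L & trace$step <= chosen
  inc1 <- sort(trace$state[sel & trace$order == 1L])
  inc2 <- sort(trace$state[sel & trace$order == 2L])
  new_interpolated(base, sm, inc1, inc2, trace, chosen)
}

new_interpolated <- function(base, sm, inc1_labels, inc2_labels, trace, chosen) {
  C <- sm$C
  inc1 <- match(inc1_labels, sm$vocabulary)
  inc2 <- vapply(strsplit(inc2_labels, " ", fixed = TRUE), function(p) {
    context_code(match(p, sm$vocabulary), C)
  }, numeric(1L))
  structure(
    list(vocabulary = sm$vocabulary, C = C, base = base, sm = sm,
         included_first = inc1_labels, included_second = inc2_labels,
         included1 = sort(inc1), included2 = sort(inc2),
         trace = trace, chosen_step = chosen),
    class = "interpolated_markov"
  )
}

# Rebuild an interpolated model against an extended vocabulary.
extend_interpolated <- function(ipm, vocabulary) {
  if (all(vocabulary %in% ipm$vocabulary)) return(ipm)
  sm <- smooth_markov(ipm$base, vocabulary = unique(c(ipm$vocabulary, vocabulary)))
  new_interpolated(ipm$base, sm, ipm$included_first, ipm$included_second,
                   ipm$trace, ipm$chosen_step)
}

#' Re-estimate an interpolated model's probabilities on new training data
#'
#' Keeps the selected state set fixed and re-parametrizes all conditional
#' distributions from `training` (used by the LOOCV paradigm, where
#' re-selecting states per fold would leak the held-out recording into
#' selection).
#'
#' @param ipm an `interpolated_markov` model.
#' @param training a [song_corpus()] whose vocabulary is contained in the
#'   model's.
#' @return an `interpolated_markov` with refreshed probabilities.
#' @export
refit_interpolated <- function(ipm, training) {
  base <- markov_model(training, 2L)
  vocab <- unique(c(ipm$vocabulary, training$vocabulary))
  sm <- smooth_markov(base, vocabulary = vocab)
  new_interpolated(base, sm, ipm$included_first, ipm$included_second,
                   ipm$trace, ipm$chosen_step)
}

#' @export
print.interpolated_markov <- function(x, ...) {
  cat("Interpolated Markov model (forward selection)\n")
  cat("  vocabulary:", x$C, "phrase types\n")
  cat("  states: zero-order fallback +", length(x$included_first),
      "first-order +", length(x$included_second), "second-order\n")
  cat("  chosen at step", x$chosen_step, "of", max(x$trace$step),
      "(test NLL", format(min(x$trace$test_nll), digits = 4), ")\n")
  invisible(x)
}

#' @export
summary.interpolated_markov <- function(object, ...) {
  props <- classify_states(object)
  out <- list(model = object, proportions = props)
  class(out) <- "summary.interpolated_markov"
  out
}

#' @export
print.summary.interpolated_markov <- function(x, ...) {
  print(x$model)
  cat("\nRepertoire structure (proportion of phrase types):\n")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Selection trace plot
#'
#' Training and testing per-phrase NLL against the number of added states,
#' with the chosen model marked.
#'
#' @param x an `interpolated_markov`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.interpolated_markov <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$step, tr$train_nll, type = "l", lty = 2,
                 xlab = "states added", ylab = "negative log-likelihood per phrase",
                 ylim = range(c(tr$train_nll, tr$test_nll)), ...)
  graphics::lines(tr$step, tr$test_nll, lty = 1)
  graphics::points(x$chosen_step, tr$test_nll[x$chosen_step + 1L], pch = 19)
  graphics::legend("topright", legend = c("training", "testing"), lty = c(2, 1),
                   bty = "n")
  invisible(x)
}

#' Classify phrase types by the model order that conditions on them
#'
#' A phrase type shows second-order properties when some included
#' second-order context has it as ultimate symbol; otherwise first-order
#' properties when its first-order state is included; otherwise it is grouped
#' in the zero-order fallback.
#'
#' @param ipm an `interpolated_markov` model.
#' @return named numeric vector of proportions `c(zero, first, second)`
#'   summing to 1 over the vocabulary.
#' @export
classify_states <- function(ipm) {
  stopifnot(inherits(ipm, "interpolated_markov"))
  C <- ipm$C
  second <- unique(as.integer(((ipm$included2 - 1) %% C) + 1))
  first <- setdiff(ipm$included1, second)
  n2 <- length(second); n1 <- length(first)
  c(zero = (C - n1 - n2) / C, first = n1 / C, second = n2 / C)
}

#' Evaluate all candidate models on one corpus
#'
#' Runs the full likelihood and predictability comparison: zero-, first-,
#' second-order and interpolated models under both the chronological
#' train-test paradigm and leave-one-recording-out cross-validation. The
#' interpolated model's state set is selected once on the train-test split;
#' per LOOCV fold only its probabilities are re-estimated. Sample size is the
#' number of training phrases (train-test) or the corpus total minus the mean
#' recording length (LOOCV).
#'
#' @param corpus a [song_corpus()] with at least two recordings.
#' @param paradigms subset of `c("train-test", "loocv")`.
#' @param skip initial phrases per recording excluded from scoring.
#' @return a data frame of class `model_evaluation` with one row per paradigm
#'   and columns `L0, L1, L2, LInt` (per-phrase NLL) and `P0, P1, P2, PInt`
#'   (prediction accuracy, percent).
#' @export
evaluate_all <- function(corpus, paradigms = c("train-test", "loocv"),
                         skip = 2L) {
  paradigms <- match.arg(paradigms, c("train-test", "loocv"), several.ok = TRUE)
  split <- train_test_split(corpus)
  training <- corpus_subset(corpus, split$train)
  testing <- corpus_subset(corpus, split$test)
  ipm <- forward_selection(training, testing, skip)
  vocab <- ipm$vocabulary
  rows <- list()
  if ("train-test" %in% paradigms) {
    base <- markov_model(training, 2L)
    sms <- lapply(0:2, function(k) smooth_markov(truncate_model(base, k), vocab))
    nll <- vapply(sms, function(s) as.numeric(sequence_nll(s, testing, skip)),
                  numeric(1L))
    nll <- c(nll, as.numeric(sequence_nll(ipm, testing, skip)))
    acc <- vapply(c(sms, list(ipm)), function(mdl) {
      prediction_accuracy(mdl, testing, skip)
    }, numeric(1L))
    rows[["train-test"]] <- data.frame(
      individual = corpus$individual_id, paradigm = "train-test",
      sample_size = corpus_size(training),
      L0 = nll[1L], L1 = nll[2L], L2 = nll[3L], LInt = nll[4L],
      P0 = acc[1L], P1 = acc[2L], P2 = acc[3L], PInt = acc[4L],
      stringsAsFactors = FALSE)
  }
  if ("loocv" %in% paradigms) {
    folds <- loocv_folds(corpus)
    tot_ll <- numeric(4L); tot_hits <- numeric(4L); tot_n <- 0L
    for (fold in folds) {
      ftr <- corpus_subset(corpus, fold$train)
      fte <- corpus_subset(corpus, fold$test)
      if (max(recording_lengths(fte)) <= skip) next
      base <- markov_model(ftr, 2L)
      sms <- lapply(0:2, function(k) smooth_markov(truncate_model(base, k), vocab))
      models <- c(sms, list(refit_interpolated(ipm, ftr)))
      for (j in seq_along(models)) {
        nll <- sequence_nll(models[[j]], fte, skip)
        n <- attr(nll, "n_phrases")
        tot_ll[j] <- tot_ll[j] + as.numeric(nll) * n
        tot_hits[j] <- tot_hits[j] + prediction_accuracy(models[[j]], fte, skip) / 100 * n
      }
      tot_n <- tot_n + attr(sequence_nll(models[[1L]], fte, skip), "n_phrases")
    }
    rows[["loocv"]] <- data.frame(
      individual = corpus$individual_id, paradigm = "loocv",
      sample_size = round(corpus_size(corpus) -
                            mean(recording_lengths(corpus))),
      L0 = tot_ll[1L] / tot_n, L1 = tot_ll[2L] / tot_n,
      L2 = tot_ll[3L] / tot_n, LInt = tot_ll[4L] / tot_n,
      P0 = tot_hits[1L] / tot_n * 100, P1 = tot_hits[2L] / tot_n * 100,
      P2 = tot_hits[3L] / tot_n * 100, PInt = tot_hits[4L] / tot_n * 100,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "interpolated") <- ipm
  class(out) <- c("model_evaluation", class(out))
  out
}

# View of a fitted model at a lower order (count tables are fitted directly
# at every order, so truncation is exact, not a marginalization).
truncate_model <- function(model, k) {
  stopifnot(k <= model$order)
  out <- model
  out$order <- as.integer(k)
  out$counts <- model$counts[seq_len(k + 1L)]
  out
}
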