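#' Fit maximum-likelihood Markov models to a song corpus
#'
#' Estimates unsmoothed transition counts of a given order from the phrase
#' sequences of a corpus. A zero-order model holds unigram frequencies
#' \eqn{P_i = n_i / N}; a first-order model holds \eqn{P(j|i) = n_{ij} /
#' n_{i\bullet}}; a second-order model holds \eqn{P(k|ij) = n_{ijk} /
#' n_{ij\bullet}}; order 3 is available for dependency screening. Counts are
#' accumulated within recordings only: an (k+1)-gram is counted only when it
#' lies entirely inside one recording, so a context total \eqn{n_{i\bullet}}
#' can be slightly less than the unigram count \eqn{n_i} when type `i` ends a
#' recording. The fitted object also carries the directly fitted count tables
#' of every lower order, which the smoothing backoff chain and the simulator
#' use.
#'
#' @param corpus a [song_corpus()] with at least one recording.
#' @param order Markov order, one of 0, 1, 2, 3.
#' @return an object of class `markov_model` with elements `order`,
#'   `vocabulary`, `counts` (one count table per order `0..order`),
#'   `n_events`, `n_recordings` and `individual_id`.
#' @seealso [smooth_markov()], [simulate.markov_model()], [sequence_nll()]
#' @export
#' @examples
#' corp <- song_corpus(list(song_recording(c("a", "b", "a", "b", "a"))))
#' m <- markov_model(corp, order = 1)
#' mle_prob(m, "a", "b")  # 1: "a" is always followed by "b"
markov_model <- function(corpus, order = 1L) {
  stopifnot(inherits(corpus, "song_corpus"))
  if (!order %in% 0:3) stop("order must be 0, 1, 2 or 3")
  if (length(corpus$recordings) == 0L || corpus_size(corpus) == 0L) {
    stop("cannot fit a model to an empty corpus")
  }
  vocab <- corpus$vocabulary
  C <- length(vocab)
  seqs <- corpus_int_seqs(corpus, vocab)
  counts <- lapply(0:order, function(k) fit_count_table(seqs, k, C))
  structure(
    list(order = as.integer(order), vocabulary = vocab, C = C,
         counts = counts, n_events = sum(lengths(seqs)),
         n_recordings = length(seqs),
         individual_id = corpus$individual_id),
    class = "markov_model"
  )
}

# One order-k count table in compressed sparse row layout over context codes.
fit_count_table <- function(seqs, k, C) {
  ctx_all <- numeric(0); nxt_all <- integer(0)
  for (x in seqs) {
    rc <- rolling_codes(x, k, C)
    ctx_all <- c(ctx_all, rc$ctx)
    nxt_all <- c(nxt_all, rc$nxt)
  }
  if (length(ctx_all) == 0L) {
    return(list(order = k, ctx = numeric(0), ptr = 1L, nxt = integer(0),
                cnt = integer(0), N = integer(0), T = integer(0)))
  }
  full <- (ctx_all - 1) * C + (nxt_all - 1)
  o <- order(full)
  r <- rle(full[o])
  codes <- r$values
  cnt <- r$lengths
  ctx <- floor(codes / C) + 1
  nxt <- as.integer(codes %% C) + 1L
  # group by context
  cr <- rle(ctx)
  uctx <- cr$values
  len <- cr$lengths
  ptr <- c(1L, cumsum(len) + 1L)
  Nn <- as.integer(vapply(seq_along(uctx), function(i) {
    sum(cnt[ptr[i]:(ptr[i + 1L] - 1L)])
  }, numeric(1L)))
  list(order = k, ctx = uctx, ptr = as.integer(ptr), nxt = nxt,
       cnt = as.integer(cnt), N = Nn, T = as.integer(len))
}

# Locate a context code in a count table; 0 when unseen.
ctx_index <- function(tab, code) {
  if (length(tab$ctx) == 0L) return(0L)
  i <- findInterval(code, tab$ctx)
  if (i >= 1L && tab$ctx[i] == code) i else 0L
}

# Seen next-symbols and counts for a context (by table row index).
ctx_rows <- function(tab, i) {
  idx <- tab$ptr[i]:(tab$ptr[i + 1L] - 1L)
  list(nxt = tab$nxt[idx], cnt = tab$cnt[idx])
}

#' Maximum-likelihood transition probability
#'
#' Returns `count(context, next) / total(context)` from the fitted counts of
#' order `length(context)`. Unseen next-types in a seen context have
#' probability 0; a context never observed in training is an error (callers
#' needing positive probabilities should use [smooth_markov()]).
#'
#' @param model a [markov_model()].
#' @param context character vector of preceding phrase labels (length 0 to
#'   `model$order`); `NULL` or `character(0)` addresses the zero-order table.
#' @param next_label the candidate next phrase label.
#' @return a probability.
#' @export
mle_prob <- function(model, context, next_label) {
  stopifnot(inherits(model, "markov_model"))
  context <- as.character(context %||% character(0L))
  k <- length(context)
  if (k > model$order) stop("context longer than model order")
  syms <- encode_labels(context, model$vocabulary)
  j <- match(next_label, model$vocabulary)
  if (is.na(j)) return(0)
  tab <- model$counts[[k + 1L]]
  i <- ctx_index(tab, context_code(syms, model$C))
  if (i == 0L) {
    stop("unknown context: ", context_label(syms, model$vocabulary),
         call. = FALSE)
  }
  rows <- ctx_rows(tab, i)
  hit <- match(j, rows$nxt)
  if (is.na(hit)) 0 else rows$cnt[hit] / tab$N[i]
}

#' Observed next-type counts for one context
#'
#' @param model a [markov_model()].
#' @param context character vector of preceding labels (length 0 to
#'   `model$order`).
#' @return named integer vector of next-type counts (empty when the context
#'   was never observed).
#' @export
context_counts <- function(model, context = character(0L)) {
  context <- as.character(context %||% character(0L))
  k <- length(context)
  if (k > model$order) stop("context longer than model order")
  syms <- encode_labels(context, model$vocabulary)
  tab <- model$counts[[k + 1L]]
  i <- ctx_index(tab, context_code(syms, model$C))
  if (i == 0L) return(stats::setNames(integer(0L), character(0L)))
  rows <- ctx_rows(tab, i)
  stats::setNames(rows$cnt, model$vocabulary[rows$nxt])
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Order-", x$order, " Markov model (maximum likelihood)\n", sep = "")
  cat("  individual:", x$individual_id, "\n")
  cat("  vocabulary:", x$C, "phrase types;", x$n_events, "phrases in",
      x$n_recordings, "recordings\n")
  tab <- x$counts[[x$order + 1L]]
  cat("  observed order-", x$order, " contexts: ", length(tab$ctx), "\n", sep = "")
  invisible(x)
}

#' @export
summary.markov_model <- function(object, ...) {
  per_order <- lapply(object$counts, function(tab) {
    data.frame(order = tab$order, contexts = length(tab$ctx),
               grams = sum(tab$cnt))
  })
  out <- list(model = object, tables = do.call(rbind, per_order))
  class(out) <- "summary.markov_model"
  out
}

#' @export
print.summary.markov_model <- function(x, ...) {
  print(x$model)
  cat("\nCount tables:\n")
  print(x$tables, row.names = FALSE)
  invisible(x)
}

#' Transition probabilities of a fitted model
#'
#' For the model's top order, returns the sparse table of observed contexts,
#' next types and maximum-likelihood probabilities. For `order <= 1` models a
#' dense `C x C` (or `1 x C`) matrix is available via `matrix = TRUE`.
#'
#' @param object a [markov_model()].
#' @param matrix return a dense probability matrix (rows = contexts) rather
#'   than a long data frame; only for order 0 or 1.
#' @param ... unused.
#' @return a data frame with columns `context`, `next_type`, `count`, `prob`,
#'   or a matrix.
#' @export
coef.markov_model <- function(object, matrix = FALSE, ...) {
  tab <- object$counts[[object$order + 1L]]
  k <- object$order
  ctx_labels <- vapply(tab$ctx, function(code) {
    context_label(decode_code(code, k, object$C), object$vocabulary)
  }, character(1L))
  rows <- rep(seq_along(tab$ctx), tab$T)
  df <- data.frame(
    context = ctx_labels[rows],
    next_type = object$vocabulary[tab$nxt],
    count = tab$cnt,
    prob = tab$cnt / tab$N[rows],
    stringsAsFactors = FALSE
  )
  if (!matrix) return(df)
  if (k > 1L) stop("dense matrix output is only supported for order <= 1")
  m <- matrix(0, nrow = length(tab$ctx), ncol = object$C,
              dimnames = list(ctx_labels, object$vocabulary))
  m[cbind(rows, tab$nxt)] <- df$prob
  m
}

#' Serialize a fitted model to JSON
#'
#' Writes `{order, vocabulary, tables: [{order, contexts: [{context,
#' next_counts}]}]}` covering every stored order, so a model can be exchanged
#' or re-loaded without the original corpus.
#'
#' @param model a [markov_model()].
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_markov_json <- function(model, path = NULL) {
  tables <- lapply(model$counts, function(tab) {
    contexts <- lapply(seq_along(tab$ctx), function(i) {
      rows <- ctx_rows(tab, i)
      list(context = as.list(model$vocabulary[decode_code(tab$ctx[i], tab$order,
                                                          model$C)]),
           next_counts = as.list(stats::setNames(rows$cnt,
                                                 model$vocabulary[rows$nxt])))
    })
    list(order = tab$order, contexts = contexts)
  })
  doc <- list(order = model$order, vocabulary = as.list(model$vocabulary),
              individual_id = model$individual_id,
              n_events = model$n_events, n_recordings = model$n_recordings,
              tables = tables)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Re-load a model serialized with [write_markov_json()]
#'
#' @param path JSON file path (or a JSON string).
#' @return a [markov_model()].
#' @export
read_markov_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  vocab <- unlist(doc$vocabulary)
  C <- length(vocab)
  counts <- lapply(doc$tables, function(tb) {
    k <- tb$order
    ctxs <- vapply(tb$contexts, function(cx) {
      context_code(match(unlist(cx$context), vocab), C)
    }, numeric(1L))
    o <- order(ctxs)
    items <- tb$contexts[o]
    nxt <- integer(0); cnt <- integer(0); Tt <- integer(0); Nn <- integer(0)
    for (cx in items) {
      nc <- unlist(cx$next_counts)
      j <- match(names(nc), vocab)
      oj <- order(j)
      nxt <- c(nxt, j[oj]); cnt <- c(cnt, as.integer(nc[oj]))
      Tt <- c(Tt, length(nc)); Nn <- c(Nn, sum(nc))
    }
    list(order = k, ctx = ctxs[o], ptr = as.integer(c(1L, cumsum(Tt) + 1L)),
         nxt = nxt, cnt = cnt, N = as.integer(Nn), T = Tt)
  })
  structure(
    list(order = as.integer(doc$order), vocabulary = vocab, C = C,
         counts = counts, n_events = doc$n_events,
         n_recordings = doc$n_recordings,
         individual_id = doc$individual_id %||% "unknown"),
    class = "markov_model"
  )
}
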