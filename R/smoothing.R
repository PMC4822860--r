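#' Witten-Bell discounting with recursive backoff
#'
#' Converts a maximum-likelihood [markov_model()] into a smoothed model that
#' assigns a strictly positive probability to every phrase type in every
#' context. In a context with `N` observations and `T` distinct observed
#' continuations, each observed probability is discounted by the factor
#' `N / (N + T)` and the reserved mass `T / (N + T)` is redistributed over the
#' unobserved types in proportion to their probabilities under the
#' next-lower-order smoothed model (Katz-style backoff), so each context
#' normalizes exactly. The chain runs order `k`, `k - 1`, ..., 0, and
#' terminates in a uniform distribution over the vocabulary. Two boundary
#' conventions: a context in which every vocabulary type has been observed is
#' left at its maximum-likelihood estimate (there is no unseen set to fund),
#' and a context never observed at all backs off entirely to the lower order.
#'
#' @param model a [markov_model()] fitted on training data.
#' @param vocabulary optional vocabulary superset. Supplying the union of the
#'   training and testing vocabularies lets held-out symbols that never
#'   occurred in training be scored (they are "unseen" at every level and end
#'   at the uniform terminal distribution, keeping likelihoods finite).
#' @return an object of class `smoothed_markov`.
#' @export
#' @examples
#' corp <- song_corpus(list(song_recording(c("b", "b", "b", "c", "a"))))
#' sm <- smooth_markov(markov_model(corp, order = 1))
#' backoff_prob(sm, "b", "b")  # discounted: (2/3) * (3/5)
smooth_markov <- function(model, vocabulary = NULL) {
  stopifnot(inherits(model, "markov_model"))
  if (length(model$vocabulary) == 0L) stop("empty vocabulary")
  vocab <- sort(unique(c(model$vocabulary, vocabulary)))
  m <- if (identical(vocab, model$vocabulary)) {
    model
  } else {
    recode_model(model, vocab)
  }
  structure(
    list(order = m$order, vocabulary = vocab, C = length(vocab),
         counts = m$counts, base = model,
         memo = new.env(parent = emptyenv())),
    class = "smoothed_markov"
  )
}

# Re-express count tables against an extended (super-)vocabulary.
recode_model <- function(model, vocab) {
  map <- match(model$vocabulary, vocab)
  C2 <- length(vocab)
  counts <- lapply(model$counts, function(tab) {
    k <- tab$order
    if (length(tab$ctx) == 0L) return(list(order = k, ctx = numeric(0),
                                           ptr = 1L, nxt = integer(0),
                                           cnt = integer(0), N = integer(0),
                                           T = integer(0)))
    ctx2 <- vapply(tab$ctx, function(code) {
      context_code(map[decode_code(code, k, model$C)], C2)
    }, numeric(1L))
    o <- order(ctx2)
    nxt <- integer(0); cnt <- integer(0)
    for (i in o) {
      rows <- ctx_rows(tab, i)
      oj <- order(map[rows$nxt])
      nxt <- c(nxt, map[rows$nxt][oj])
      cnt <- c(cnt, rows$cnt[oj])
    }
    list(order = k, ctx = ctx2[o],
         ptr = as.integer(c(1L, cumsum(tab$T[o]) + 1L)),
         nxt = nxt, cnt = cnt, N = tab$N[o], T = tab$T[o])
  })
  list(order = model$order, counts = counts, C = C2)
}

#' @export
print.smoothed_markov <- function(x, ...) {
  cat("Witten-Bell smoothed order-", x$order, " Markov model\n", sep = "")
  cat("  vocabulary:", x$C, "phrase types\n")
  invisible(x)
}

# Full smoothed conditional distribution over the vocabulary for a context
# given by its order level (k) and base-C code; memoized per context.
cond_dist_sm <- function(sm, level, code) {
  key <- paste0(level, ":", format(code, scientific = FALSE))
  hit <- sm$memo[[key]]
  if (!is.null(hit)) return(hit)
  C <- sm$C
  lower <- if (level == 0L) {
    rep.int(1 / C, C)
  } else {
    suffix <- ((code - 1) %% C^(level - 1L)) + 1
    cond_dist_sm(sm, level - 1L, suffix)
  }
  tab <- sm$counts[[level + 1L]]
  i <- ctx_index(tab, code)
  p <- if (i == 0L) {
    lower
  } else {
    rows <- ctx_rows(tab, i)
    N <- tab$N[i]; Tt <- tab$T[i]
    if (Tt == C) {
      v <- numeric(C)
      v[rows$nxt] <- rows$cnt / N
      v
    } else {
      v <- numeric(C)
      v[rows$nxt] <- rows$cnt / (N + Tt)
      unseen <- v == 0
      v[unseen] <- lower[unseen] * (Tt / (N + Tt)) / sum(lower[unseen])
      v
    }
  }
  assign(key, p, envir = sm$memo)
  p
}

#' Smoothed conditional distribution for a context
#'
#' @param sm a [smooth_markov()] model.
#' @param context character vector of preceding labels. Contexts longer than
#'   the model order are truncated to their suffix; shorter contexts address
#'   the corresponding lower-order level directly.
#' @return named numeric vector of probabilities over the vocabulary (sums
#'   to 1; all entries positive).
#' @export
smoothed_dist <- function(sm, context = character(0L)) {
  stopifnot(inherits(sm, "smoothed_markov"))
  context <- as.character(context %||% character(0L))
  if (length(context) > sm$order) {
    context <- if (sm$order == 0L) character(0L) else
      context[(length(context) - sm$order + 1L):length(context)]
  }
  syms <- encode_labels(context, sm$vocabulary)
  p <- cond_dist_sm(sm, length(context), context_code(syms, sm$C))
  stats::setNames(p, sm$vocabulary)
}

#' Backoff probability of one transition
#'
#' @param sm a [smooth_markov()] model.
#' @param context character vector of preceding labels (see
#'   [smoothed_dist()]).
#' @param next_label candidate next phrase label; must be in the model
#'   vocabulary.
#' @return a strictly positive probability.
#' @export
backoff_prob <- function(sm, context, next_label) {
  j <- match(next_label, sm$vocabulary)
  if (is.na(j)) stop("label outside vocabulary: ", next_label, call. = FALSE)
  unname(smoothed_dist(sm, context)[j])
}

# ---- vectorised scoring machinery -----------------------------------------

# Scored positions of a corpus under the usual evaluation convention: the
# first `skip` phrases of each recording are conditioning-only. Returns
# integer next symbols plus the level-1 and level-2 context codes per
# position (level-2 codes are NA where unavailable).
scored_positions <- function(corpus, vocabulary, skip = 2L) {
  C <- length(vocabulary)
  nxt <- integer(0); c1 <- numeric(0); c2 <- numeric(0)
  rec <- integer(0); pos <- integer(0)
  for (ri in seq_along(corpus$recordings)) {
    x <- encode_labels(corpus$recordings[[ri]]$labels, vocabulary)
    L <- length(x)
    if (L <= skip) next
    m <- (skip + 1L):L
    nxt <- c(nxt, x[m])
    c1 <- c(c1, x[m - 1L])
    c2 <- c(c2, if (skip >= 2L) (x[m - 2L] - 1) * C + x[m - 1L] else rep(NA_real_, length(m)))
    rec <- c(rec, rep.int(ri, length(m)))
    pos <- c(pos, m)
  }
  list(nxt = nxt, c1 = c1, c2 = c2, rec = rec, pos = pos, n = length(nxt))
}

# log P(next | context at `level`) for every scored position, under sm.
level_logprobs <- function(sm, positions, level) {
  n <- positions$n
  out <- numeric(n)
  codes <- switch(as.character(level),
                  "0" = rep.int(1, n),
                  "1" = positions$c1,
                  "2" = positions$c2,
                  stop("unsupported level"))
  for (grp in split(seq_len(n), codes)) {
    d <- cond_dist_sm(sm, level, codes[grp[1L]])
    out[grp] <- log(d[positions$nxt[grp]])
  }
  out
}
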