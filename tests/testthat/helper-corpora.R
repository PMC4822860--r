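# Shared fixtures: tiny corpora built in code, plus an independent reference
# implementation of Witten-Bell discounting with Katz-style backoff, written
# as naive label-matching loops so it shares no machinery with the package.

rec <- function(labels, start = NULL, end = NULL, id = "bird1",
                at = NA, src = NA_character_) {
  song_recording(labels, start, end, individual_id = id, recorded_at = at,
                 source = src)
}

corpus_of <- function(..., id = "bird1") {
  seqs <- list(...)
  recs <- lapply(seq_along(seqs), function(i) {
    rec(seqs[[i]], id = id, at = as.POSIXct("2013-05-01", tz = "UTC") +
          i * 86400, src = paste0("r", i))
  })
  song_corpus(recs, id)
}

random_corpus <- function(n_rec, len, vocab, seed, id = "bird1") {
  set.seed(seed)
  do.call(corpus_of, c(lapply(seq_len(n_rec), function(i) {
    sample(vocab, len, replace = TRUE)
  }), list(id = id)))
}

# Reference Witten-Bell/backoff probability: P(nxt | context) under counts
# taken from `seqs` (list of character vectors), over `vocab`.
ref_backoff_prob <- function(seqs, vocab, context, nxt) {
  C <- length(vocab)
  k <- length(context)
  lower <- function(w) {
    if (k == 0L) 1 / C else ref_backoff_prob(seqs, vocab, context[-1L], w)
  }
  counts <- stats::setNames(numeric(C), vocab)
  for (x in seqs) {
    if (length(x) <= k) next
    for (m in (k + 1L):length(x)) {
      if (k == 0L || all(x[(m - k):(m - 1L)] == context)) {
        counts[x[m]] <- counts[x[m]] + 1
      }
    }
  }
  N <- sum(counts)
  T <- sum(counts > 0)
  if (N == 0) return(lower(nxt))
  if (counts[nxt] > 0) {
    if (T == C) return(unname(counts[nxt] / N))
    return(unname(counts[nxt] / (N + T)))
  }
  unseen <- vocab[counts == 0]
  lw <- vapply(unseen, lower, numeric(1L))
  (T / (N + T)) * lower(nxt) / sum(lw)
}

# All label tuples of a given length over a vocabulary.
all_contexts <- function(vocab, k) {
  if (k == 0L) return(list(character(0L)))
  grid <- do.call(expand.grid, c(rep(list(vocab), k),
                                 list(stringsAsFactors = FALSE)))
  lapply(seq_len(nrow(grid)), function(i) rev(unlist(grid[i, ], use.names = FALSE)))
}
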