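# Sequence simulation from unsmoothed fitted models. A simulation preserves
# the template corpus's file structure: one simulated recording per template
# recording with the same length, the first k phrases copied verbatim
# (k = model order), and subsequent phrases drawn from the maximum-likelihood
# conditional of the running context. Phrase times and recording metadata are
# copied from the template.

# Per-level count tables with within-row cumulative probabilities, in the
# flat layout the compiled sampler consumes.
build_sampler <- function(model) {
  lapply(0:model$order, function(k) {
    tab <- model$counts[[k + 1L]]
    cum <- numeric(length(tab$nxt))
    for (i in seq_along(tab$ctx)) {
      idx <- tab$ptr[i]:(tab$ptr[i + 1L] - 1L)
      cum[idx] <- cumsum(tab$cnt[idx] / tab$N[i])
    }
    list(ctx = as.numeric(tab$ctx), ptr = tab$ptr, nxt = tab$nxt, cum = cum)
  })
}

# Simulate one recording's symbol sequence. Dead-end contexts (observed only
# at a recording end, hence without outgoing counts) back off to the next
# shorter context; the order-0 table always resolves.
sim_symbols <- function(samplers, k, C, template_ints) {
  .sim_chain(as.integer(template_ints), as.integer(k), as.integer(C), samplers)
}

sim_corpus_once <- function(model, template, samplers, seed) {
  set.seed(seed)
  C <- model$C
  k <- model$order
  recs <- lapply(template$recordings, function(r) {
    x <- encode_labels(r$labels, model$vocabulary)
    y <- sim_symbols(samplers, k, C, x)
    out <- r
    out$labels <- model$vocabulary[y]
    out
  })
  song_corpus(recs, template$individual_id)
}

#' Simulate a corpus from a fitted model
#'
#' @param model an unsmoothed [markov_model()]; its top-order
#'   maximum-likelihood conditionals drive the simulation.
#' @param template a [song_corpus()] supplying the file structure, recording
#'   lengths, initial phrases and phrase times. Template labels must belong to
#'   the model vocabulary (always true when the model was fitted on the
#'   template). Recordings shorter than the model order are copied verbatim.
#' @param seed integer seed; the same seed reproduces the same corpus.
#' @return a simulated [song_corpus()].
#' @export
simulate_corpus <- function(model, template, seed = 1L) {
  stopifnot(inherits(model, "markov_model"), inherits(template, "song_corpus"))
  sim_corpus_once(model, template, build_sampler(model), seed)
}

#' Independent replicate simulations
#'
#' Runs [simulate_corpus()] `n_reps` times with per-replicate seeds derived
#' deterministically from the master seed, so replicates are independent yet
#' the whole batch is reproducible from one number.
#'
#' @param model an unsmoothed [markov_model()].
#' @param template template [song_corpus()].
#' @param n_reps number of replicates (the full protocols of this kind of
#'   analysis use 1000 for model assessment and 100 for homogeneity testing).
#' @param seed master integer seed.
#' @return a list of `n_reps` simulated corpora.
#' @export
replicate_simulations <- function(model, template, n_reps, seed = 1L) {
  stopifnot(n_reps >= 1L)
  samplers <- build_sampler(model)
  lapply(seq_len(n_reps), function(i) {
    sim_corpus_once(model, template, samplers, child_seed(seed, i))
  })
}

#' @rdname simulate_corpus
#' @param object a [markov_model()] (S3 method for [stats::simulate()]).
#' @param nsim number of replicate corpora.
#' @param ... unused.
#' @return for the `simulate` method, a list of `nsim` corpora.
#' @export
simulate.markov_model <- function(object, nsim = 1L, seed = 1L,
                                  template = NULL, ...) {
  if (is.null(template)) stop("a template corpus is required")
  replicate_simulations(object, template, nsim, seed)
}
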