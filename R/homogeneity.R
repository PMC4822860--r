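#' Simulation-based test of time homogeneity
#'
#' Asks whether the divergence between a corpus's chronological training and
#' testing halves exceeds what a time-homogeneous process would produce. A
#' second-order Markov model is fitted (unsmoothed) on the entire corpus and
#' the full corpus is simulated `n_sims` times; each simulated corpus is
#' divided into simulated-training and simulated-testing sets by the same
#' file assignment as the observed split, and the L1 distance between the two
#' is computed for each N-gram size. The observed training/testing L1 is then
#' expressed as a z-score against the simulated distribution; positive z
#' means the observed halves differ more than time homogeneity predicts.
#'
#' @param corpus a [song_corpus()].
#' @param split a [split_spec()]; default the chronological
#'   [train_test_split()].
#' @param n_sims number of simulated corpora (default 100).
#' @param N_range N-gram sizes (default 1 to 7).
#' @param seed master integer seed.
#' @param order generator order (default 2).
#' @return a data frame of class `homogeneity_test` with one row per N:
#'   `individual`, `N`, `observed_l1`, `sim_mean`, `sim_sd`, `z`, `n_sims`.
#' @export
homogeneity_test <- function(corpus, split = NULL, n_sims = 100L,
                             N_range = 1:7, seed = 1L, order = 2L) {
  stopifnot(inherits(corpus, "song_corpus"))
  if (is.null(split)) split <- train_test_split(corpus)
  stopifnot(inherits(split, "split_spec"))
  vocab <- corpus$vocabulary
  C <- length(vocab)
  ids <- recording_ids(corpus)
  in_train <- ids %in% split$train
  model <- markov_model(corpus, order)
  samplers <- build_sampler(model)
  seqs <- corpus_int_seqs(corpus, vocab)

  split_l1 <- function(sqs) {
    tr <- sqs[in_train]; te <- sqs[!in_train]
    vapply(N_range, function(N) {
      l1_int(ngram_freq_int(tr, N, C), ngram_freq_int(te, N, C))
    }, numeric(1L))
  }
  observed <- split_l1(seqs)
  sims <- matrix(NA_real_, nrow = n_sims, ncol = length(N_range))
  for (r in seq_len(n_sims)) {
    set.seed(child_seed(seed, r))
    sim_seqs <- lapply(seqs, function(x) sim_symbols(samplers, order, C, x))
    sims[r, ] <- split_l1(sim_seqs)
  }
  mu <- colMeans(sims)
  sdv <- apply(sims, 2L, stats::sd)
  if (any(sdv == 0)) {
    stop("simulated L1 distances show no variability; increase n_sims or corpus size")
  }
  out <- data.frame(individual = corpus$individual_id, N = N_range,
                    observed_l1 = observed, sim_mean = mu, sim_sd = sdv,
                    z = (observed - mu) / sdv, n_sims = n_sims,
                    stringsAsFactors = FALSE)
  class(out) <- c("homogeneity_test", class(out))
  out
}

#' @export
print.homogeneity_test <- function(x, ...) {
  cat("Time-homogeneity test for", x$individual[1L], "(", x$n_sims[1L],
      "simulations )\n")
  print(data.frame(N = x$N, observed = round(x$observed_l1, 4),
                   expected = round(x$sim_mean, 4), z = round(x$z, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Observed vs simulated L1 distances per N-gram size
#'
#' @param x a `homogeneity_test` result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.homogeneity_test <- function(x, ...) {
  graphics::plot(x$N, x$observed_l1, pch = 19, xlab = "N-gram size",
                 ylab = "L1 distance",
                 ylim = range(c(x$observed_l1, x$sim_mean - 2 * x$sim_sd,
                                x$sim_mean + 2 * x$sim_sd)), ...)
  graphics::points(x$N, x$sim_mean, pch = 1)
  graphics::segments(x$N, x$sim_mean - 2 * x$sim_sd,
                     x$N, x$sim_mean + 2 * x$sim_sd)
  graphics::legend("topleft", pch = c(19, 1),
                   legend = c("observed", "time-homogeneous (mean +/- 2 SD)"),
                   bty = "n")
  invisible(x)
}

#' Population-level homogeneity summary
#'
#' Combines per-individual [homogeneity_test()] results: at each N-gram size,
#' a one-sample t-test of the individuals' z-scores against zero (one-sided,
#' alternative mean z > 0, since time inhomogeneity inflates the observed
#' train/test divergence).
#'
#' @param results a list of `homogeneity_test` data frames or their row-bound
#'   combination.
#' @return a data frame with columns `N`, `n_individuals`, `mean_z`, `t`,
#'   `df`, `p` and `signif` (`""`, `"*"` for p < 0.05, `"**"` for p < 0.01).
#' @export
homogeneity_summary <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  all <- do.call(rbind, lapply(results, as.data.frame))
  rows <- lapply(sort(unique(all$N)), function(N) {
    z <- all$z[all$N == N]
    tt <- stats::t.test(z, mu = 0, alternative = "greater")
    data.frame(N = N, n_individuals = length(z), mean_z = mean(z),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               signif = if (tt$p.value < 0.01) "**"
                        else if (tt$p.value < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
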