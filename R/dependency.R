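#' Screen for second- or third-order dependencies with Fisher's exact tests
#'
#' For `order = 2`: for each phrase type, the two penultimate-phrase contexts
#' with the most observations are compared. Under a first-order process the
#' next-phrase distribution depends only on the ultimate type, so the two
#' rows of the resulting `2 x K` contingency table (columns: the union of
#' next types observed after either context) should be homogeneous; an exact
#' test of independence screens for a genuine second-order dependency. For
#' `order = 3` the shared suffix is the penultimate+ultimate bigram and the
#' antepenultimate type varies. Targets observed with a single extended
#' context are skipped. Significance is reported both at 0.05 and at the
#' Bonferroni-corrected threshold `0.05 / n`, with `n` the number of tests
#' performed for this corpus and order.
#'
#' The exact engine is Fisher's test (network algorithm); tables whose total
#' count exceeds `max_exact_total` or with more than `max_exact_cols` columns
#' fall back to a Chi-square test of independence (with large counts exact
#' p-values become impractical). Each result records which engine ran.
#'
#' @param corpus a [song_corpus()]; the complete corpus is used (no split).
#' @param order 2 or 3.
#' @param min_context_n optional minimum observation count a context needs to
#'   enter the comparison (default 0: none, for sensitivity analyses only).
#' @param max_exact_total,max_exact_cols work bounds for the exact engine.
#' @return a data frame of class `dependency_tests` with one row per test:
#'   `individual`, `order`, `target`, `context_a`, `context_b`, `n_a`, `n_b`,
#'   `n_cols`, `engine`, `p`, `sig_05`, `sig_bonferroni`, `n_comparisons`.
#'   The contingency tables are attached as attribute `"tables"`.
#' @export
higher_order_tests <- function(corpus, order = 2L, min_context_n = 0L,
                               max_exact_total = 500L, max_exact_cols = 12L) {
  stopifnot(inherits(corpus, "song_corpus"), order %in% c(2L, 3L))
  model <- markov_model(corpus, order)
  C <- model$C
  tab <- model$counts[[order + 1L]]
  if (length(tab$ctx) == 0L) return(empty_dependency_tests())
  suffix <- ((tab$ctx - 1) %% C^(order - 1L)) + 1
  keep <- tab$N >= min_context_n
  rows <- list()
  tables <- list()
  for (grp in split(which(keep), suffix[keep])) {
    if (length(grp) < 2L) next
    # two contexts with most observations; ties broken lexicographically
    grp <- grp[order(-tab$N[grp], tab$ctx[grp])]
    a <- grp[1L]; b <- grp[2L]
    ra <- ctx_rows(tab, a); rb <- ctx_rows(tab, b)
    cols <- sort(unique(c(ra$nxt, rb$nxt)))
    m <- matrix(0L, nrow = 2L, ncol = length(cols),
                dimnames = list(
                  c(context_label(decode_code(tab$ctx[a], order, C),
                                  model$vocabulary),
                    context_label(decode_code(tab$ctx[b], order, C),
                                  model$vocabulary)),
                  model$vocabulary[cols]))
    m[1L, match(ra$nxt, cols)] <- ra$cnt
    m[2L, match(rb$nxt, cols)] <- rb$cnt
    use_exact <- sum(m) <= max_exact_total && ncol(m) <= max_exact_cols
    res <- run_independence_test(m, use_exact)
    tgt_syms <- decode_code(((tab$ctx[a] - 1) %% C^(order - 1L)) + 1,
                            order - 1L, C)
    rows[[length(rows) + 1L]] <- data.frame(
      individual = corpus$individual_id, order = order,
      target = context_label(tgt_syms, model$vocabulary),
      context_a = rownames(m)[1L], context_b = rownames(m)[2L],
      n_a = sum(m[1L, ]), n_b = sum(m[2L, ]), n_cols = ncol(m),
      engine = res$engine, p = res$p, stringsAsFactors = FALSE)
    tables[[length(tables) + 1L]] <- m
  }
  if (length(rows) == 0L) return(empty_dependency_tests())
  out <- do.call(rbind, rows)
  n <- nrow(out)
  out$sig_05 <- out$p < 0.05
  out$sig_bonferroni <- out$p < 0.05 / n
  out$n_comparisons <- n
  attr(out, "tables") <- tables
  class(out) <- c("dependency_tests", class(out))
  out
}

empty_dependency_tests <- function() {
  out <- data.frame(individual = character(0), order = integer(0),
                    target = character(0), context_a = character(0),
                    context_b = character(0), n_a = integer(0),
                    n_b = integer(0), n_cols = integer(0),
                    engine = character(0), p = numeric(0),
                    sig_05 = logical(0), sig_bonferroni = logical(0),
                    n_comparisons = integer(0), stringsAsFactors = FALSE)
  attr(out, "tables") <- list()
  class(out) <- c("dependency_tests", class(out))
  out
}

run_independence_test <- function(m, use_exact, mc_B = 10000L) {
  if (ncol(m) < 2L || any(rowSums(m) == 0L)) {
    # both contexts share one next type (or one row is empty): no signal
    return(list(p = 1, engine = "fisher"))
  }
  if (use_exact) {
    p <- tryCatch(stats::fisher.test(m)$p.value, error = function(e) NULL)
    if (!is.null(p)) return(list(p = p, engine = "fisher"))
  }
  # Chi-square fallback with a Monte-Carlo null: many columns of these tables
  # hold only a handful of counts, where the asymptotic reference
  # distribution is anticonservative. The simulated null is seeded from the
  # table itself so results are deterministic, and the caller's RNG state is
  # left untouched.
  seed_state <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(seed_state)) {
      assign(".Random.seed", seed_state, envir = globalenv())
    }
  })
  set.seed(as.integer((sum(m) * 131 + sum(m * seq_along(m)) ) %% 2147483629))
  p <- suppressWarnings(
    stats::chisq.test(m, simulate.p.value = TRUE, B = mc_B)$p.value)
  if (is.na(p)) p <- 1 # degenerate table (a zero margin): no evidence
  list(p = p, engine = "chi-square")
}

#' @export
summary.dependency_tests <- function(object, ...) {
  if (nrow(object) == 0L) {
    out <- data.frame(individual = character(0), order = integer(0),
                      n_comparisons = integer(0), n_sig_05 = integer(0),
                      n_sig_bonferroni = integer(0))
  } else {
    out <- data.frame(individual = object$individual[1L],
                      order = object$order[1L],
                      n_comparisons = nrow(object),
                      n_sig_05 = sum(object$sig_05),
                      n_sig_bonferroni = sum(object$sig_bonferroni),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("summary.dependency_tests", class(out))
  out
}

#' @export
print.dependency_tests <- function(x, ...) {
  cat("Higher-order dependency screen (order ", if (nrow(x)) x$order[1L] else "?",
      "): ", nrow(x), " comparisons, ", sum(x$sig_05), " at p<0.05, ",
      sum(x$sig_bonferroni), " Bonferroni-significant\n", sep = "")
  invisible(x)
}

#' Null calibration of the dependency screen
#'
#' Simulates the complete corpus once from a Markov model one order below the
#' screen (a first-order generator for the second-order screen, a
#' second-order generator for the third-order screen), fitted on the complete
#' corpus, and runs the same screen on the simulated data. Under this null the
#' screen is expected to produce no Bonferroni-significant results.
#'
#' @param corpus a [song_corpus()].
#' @param order screen order, 2 or 3.
#' @param seed integer seed for the simulation.
#' @param ... passed to [higher_order_tests()].
#' @return a `dependency_tests` data frame for the simulated corpus.
#' @export
null_calibration <- function(corpus, order = 2L, seed = 1L, ...) {
  stopifnot(order %in% c(2L, 3L))
  gen <- markov_model(corpus, order - 1L)
  sim <- simulate_corpus(gen, corpus, seed)
  higher_order_tests(sim, order, ...)
}
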