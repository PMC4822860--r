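test_that("a uniform zero-order model scores ln(C) per phrase", {
  training <- corpus_of(rep(c("a", "b", "c", "d"), 25))
  m0 <- markov_model(training, 0L)
  testing <- corpus_of(c("d", "c", "a", "b", "a", "d", "c", "b"))
  nll <- sequence_nll(m0, testing)
  expect_equal(as.numeric(nll), log(4), tolerance = 1e-12)
  expect_equal(attr(nll, "n_phrases"), 6L)   # first two phrases skipped
})

test_that("a near-deterministic chain scores near zero", {
  training <- corpus_of(rep(c("a", "b"), 50))
  m1 <- markov_model(training, 1L)
  testing <- corpus_of(rep(c("a", "b"), 20))
  expect_lt(as.numeric(sequence_nll(m1, testing)), 0.2)
})

test_that("recordings shorter than the skip contribute nothing", {
  training <- corpus_of(rep(c("a", "b"), 10))
  m <- markov_model(training, 1L)
  expect_error(sequence_nll(m, corpus_of(c("a", "b"))), "no scorable")
  nll <- sequence_nll(m, corpus_of(c("a", "b"), c("a", "b", "a")))
  expect_equal(attr(nll, "n_phrases"), 1L)
})

test_that("greedy choice at step one matches exhaustive candidate search", {
  cp <- random_corpus(4, 40, c("a", "b", "c"), seed = 81)
  sp <- train_test_split(cp)
  training <- corpus_subset(cp, sp$train)
  testing <- corpus_subset(cp, sp$test)
  fs <- forward_selection(training, testing)
  # brute force: score every single-first-order-state model on the training
  # set via the public scoring path
  sm <- smooth_markov(markov_model(training, 2L),
                      vocabulary = testing$vocabulary)
  nll_with_state <- function(state) {
    total <- 0; n <- 0
    for (r in training$recordings) {
      x <- r$labels
      if (length(x) <= 2L) next
      for (m in 3:length(x)) {
        ctx <- if (x[m - 1L] == state) x[m - 1L] else character(0L)
        total <- total - log(backoff_prob(sm, ctx, x[m]))
        n <- n + 1L
      }
    }
    total / n
  }
  cands <- sort(unique(unlist(lapply(training$recordings, function(r) {
    r$labels[-length(r$labels)]
  }))))
  brute <- vapply(cands, nll_with_state, numeric(1L))
  expect_equal(fs$trace$state[2L], names(brute)[which.min(brute)])
  expect_equal(fs$trace$train_nll[2L], min(brute), tolerance = 1e-10)
})

test_that("the selection trace is coherent and the chosen model optimal", {
  spec <- ground_truth_spec(repertoire_size = 15, sparsity = 4, seed = 82)
  gt <- make_ground_truth(spec)
  cp <- simulate_ground_truth(gt, rep(500L, 6), seed = 83)
  sp <- train_test_split(cp)
  training <- corpus_subset(cp, sp$train)
  testing <- corpus_subset(cp, sp$test)
  fs <- forward_selection(training, testing)
  tr <- fs$trace
  # train NLL is non-increasing up to the chosen step
  expect_true(all(diff(tr$train_nll[seq_len(fs$chosen_step + 1L)]) <= 1e-9))
  # chosen test NLL is the trace minimum, hence <= both endpoints
  expect_equal(min(tr$test_nll), tr$test_nll[fs$chosen_step + 1L])
  expect_lte(tr$test_nll[fs$chosen_step + 1L], tr$test_nll[1L])
  expect_lte(tr$test_nll[fs$chosen_step + 1L], tr$test_nll[nrow(tr)])
  # every included second-order state has its parent included
  parents <- vapply(strsplit(fs$included_second, " ", fixed = TRUE),
                    `[`, character(1L), 2L)
  expect_true(all(parents %in% fs$included_first))
  # the model's own NLL equals the trace value at the chosen step
  expect_equal(as.numeric(sequence_nll(fs, testing)),
               tr$test_nll[fs$chosen_step + 1L], tolerance = 1e-10)
})

test_that("interpolated scoring follows deepest-match semantics", {
  cp <- random_corpus(3, 50, c("a", "b", "c"), seed = 84)
  sp <- train_test_split(cp)
  training <- corpus_subset(cp, sp$train)
  testing <- corpus_subset(cp, sp$test)
  fs <- forward_selection(training, testing)
  sm <- fs$sm
  manual <- 0; n <- 0
  for (r in testing$recordings) {
    x <- r$labels
    if (length(x) <= 2L) next
    for (m in 3:length(x)) {
      pair <- paste(x[m - 2L], x[m - 1L])
      ctx <- if (pair %in% fs$included_second) c(x[m - 2L], x[m - 1L])
             else if (x[m - 1L] %in% fs$included_first) x[m - 1L]
             else character(0L)
      manual <- manual - log(backoff_prob(sm, ctx, x[m]))
      n <- n + 1L
    }
  }
  expect_equal(as.numeric(sequence_nll(fs, testing)), manual / n,
               tolerance = 1e-12)
})

test_that("state classification covers the trivial structures", {
  cp <- random_corpus(2, 30, c("a", "b", "c"), seed = 85)
  base <- markov_model(cp, 2L)
  sm <- smooth_markov(base)
  tr <- data.frame(step = 0L, state = NA_character_, order = 0L,
                   train_nll = 1, test_nll = 1)
  empty <- vireosyntax:::new_interpolated(base, sm, character(0L),
                                          character(0L), tr, 0L)
  expect_equal(classify_states(empty), c(zero = 1, first = 0, second = 0))
  allfirst <- vireosyntax:::new_interpolated(base, sm, c("a", "b", "c"),
                                             character(0L), tr, 3L)
  expect_equal(classify_states(allfirst), c(zero = 0, first = 1, second = 0))
  mixed <- vireosyntax:::new_interpolated(base, sm, c("a", "b"), "a b", tr, 3L)
  expect_equal(classify_states(mixed),
               c(zero = 1 / 3, first = 1 / 3, second = 1 / 3))
})

test_that("evaluate_all produces both paradigms with sane orderings", {
  spec <- ground_truth_spec(repertoire_size = 12, frac_second_order = 0,
                            frac_zero_order = 1, sparsity = 4, seed = 86)
  gt <- make_ground_truth(spec)   # i.i.d. (zero-order) truth
  cp <- simulate_ground_truth(gt, rep(800L, 6), seed = 87)
  ev <- evaluate_all(cp)
  expect_setequal(ev$paradigm, c("train-test", "loocv"))
  expect_true(all(c("L0", "L1", "L2", "LInt", "P0", "P1", "P2", "PInt")
                  %in% names(ev)))
  tt <- ev[ev$paradigm == "train-test", ]
  # no spurious structural gain on structureless data
  expect_lt(abs(tt$L1 - tt$L0), 0.05)
  expect_lt(abs(tt$LInt - tt$L0), 0.05)
  expect_equal(tt$sample_size,
               corpus_size(corpus_subset(cp, train_test_split(cp)$train)))
})
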