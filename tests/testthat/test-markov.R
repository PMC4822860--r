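test_that("first-order counts match a hand count, with terminal-phrase deficit", {
  m <- markov_model(corpus_of(c("a", "b", "a", "b", "a")), 1L)
  expect_equal(context_counts(m, "a"), c(b = 2L))
  expect_equal(context_counts(m, "b"), c(a = 2L))
  # n_a. = 2 (a is followed twice) although n_a = 3: "a" ends the recording
  expect_equal(sum(context_counts(m, "a")), 2L)
  expect_equal(unname(context_counts(m)["a"]), 3L)
  expect_equal(mle_prob(m, "a", "b"), 1)
  expect_equal(mle_prob(m, "a", "a"), 0)
})

test_that("transitions never span recording boundaries", {
  m <- markov_model(corpus_of(c("a", "b"), c("b", "a")), 1L)
  expect_equal(context_counts(m, "a"), c(b = 1L))
  expect_equal(context_counts(m, "b"), c(a = 1L))
  expect_false("b" %in% names(context_counts(m, "b")))
})

test_that("zero-order counts are plain frequencies", {
  m <- markov_model(corpus_of(c("a", "a", "b")), 0L)
  expect_equal(context_counts(m), c(a = 2L, b = 1L))
  expect_equal(mle_prob(m, NULL, "a"), 2 / 3)
})

test_that("unknown contexts error; seen contexts normalize", {
  cp <- random_corpus(2, 40, c("a", "b", "c"), seed = 3)
  m <- markov_model(cp, 2L)
  expect_error(mle_prob(markov_model(corpus_of(c("a", "b", "a")), 1L), "c", "a"),
               "labels outside vocabulary")
  for (k in 0:2) {
    mk <- markov_model(cp, k)
    for (ctx in all_contexts(cp$vocabulary, k)) {
      counts <- context_counts(mk, ctx)
      if (length(counts) == 0L) next
      total <- sum(vapply(cp$vocabulary, function(w) mle_prob(mk, ctx, w),
                          numeric(1L)))
      expect_equal(total, 1)
    }
  }
})

test_that("gram totals and cross-order consistency hold on random corpora", {
  for (seed in 1:3) {
    cp <- random_corpus(3, 25 + seed * 7, c("a", "b", "c", "d"), seed = seed)
    lens <- recording_lengths(cp)
    for (k in 0:3) {
      m <- markov_model(cp, k)
      tab <- m$counts[[k + 1L]]
      expect_equal(sum(tab$cnt), sum(pmax(0L, lens - k)))
    }
    # marginalizing order-2 counts over the penultimate symbol reproduces
    # order-1 counts restricted to trigram-covered positions
    m2 <- markov_model(cp, 2L)
    marg <- stats::setNames(numeric(0L), character(0L))
    for (ctx in all_contexts(cp$vocabulary, 2L)) {
      counts <- context_counts(m2, ctx)
      for (w in names(counts)) {
        key <- paste(ctx[2L], w)
        marg[key] <- (if (key %in% names(marg)) marg[key] else 0) + counts[w]
      }
    }
    direct <- stats::setNames(numeric(0L), character(0L))
    for (r in cp$recordings) {
      x <- r$labels
      if (length(x) < 3L) next
      for (m in 3:length(x)) {
        key <- paste(x[m - 1L], x[m])
        direct[key] <- (if (key %in% names(direct)) direct[key] else 0) + 1
      }
    }
    expect_equal(marg[sort(names(marg))], direct[sort(names(direct))])
  }
})

test_that("JSON serialization round-trips counts and probabilities", {
  cp <- random_corpus(2, 30, c("ai", "en", "ds"), seed = 9)
  m <- markov_model(cp, 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_markov_json(m, path)
  m2 <- read_markov_json(path)
  expect_equal(m2$order, m$order)
  expect_equal(m2$vocabulary, m$vocabulary)
  for (k in 0:2) {
    for (ctx in all_contexts(m$vocabulary, k)) {
      expect_equal(context_counts(m2, ctx), context_counts(m, ctx))
    }
  }
})

test_that("coef returns per-context probability tables", {
  m <- markov_model(corpus_of(c("a", "b", "a", "c", "a", "b")), 1L)
  df <- coef(m)
  sums <- tapply(df$prob, df$context, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  mat <- coef(m, matrix = TRUE)
  expect_equal(unname(rowSums(mat)[rownames(mat) == "a"]), 1)
})
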