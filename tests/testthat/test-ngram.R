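test_that("n-gram distributions match hand counts", {
  cp <- corpus_of(c("a", "b", "a", "b"))
  d2 <- ngram_distribution(cp, 2L)
  expect_equal(sort(d2$table), sort(c("a b" = 2 / 3, "b a" = 1 / 3)))
  d1 <- ngram_distribution(corpus_of(c("a", "a", "b")), 1L)
  expect_equal(sort(d1$table), sort(c(a = 2 / 3, b = 1 / 3)))
  expect_error(ngram_distribution(corpus_of(c("a", "b")), 5L), "length >= 5")
})

test_that("n-grams never span recording boundaries and always normalize", {
  cp <- corpus_of(c("a", "b"), c("b", "c"))
  d <- ngram_distribution(cp, 2L)
  expect_false("b b" %in% names(d$table))
  for (seed in 1:3) {
    rcp <- random_corpus(3, 15, c("a", "b", "c"), seed = 50 + seed)
    for (N in 1:4) expect_equal(sum(ngram_distribution(rcp, N)$table), 1)
  }
})

test_that("L1 distance attains its bounds and is a metric", {
  cp1 <- corpus_of(c("a", "a", "b", "b"))
  expect_equal(l1_distance(ngram_distribution(cp1, 1L),
                           ngram_distribution(cp1, 1L)), 0)
  cp2 <- corpus_of(c("c", "d", "c", "d"))
  expect_equal(l1_distance(ngram_distribution(cp1, 1L),
                           ngram_distribution(cp2, 1L)), 2)
  # {a: .5, b: .5} vs {a: 1}
  d1 <- ngram_distribution(corpus_of(c("a", "b")), 1L)
  d2 <- ngram_distribution(corpus_of(c("a", "a")), 1L)
  expect_equal(l1_distance(d1, d2), 1)
  expect_error(l1_distance(d1, ngram_distribution(cp1, 2L)), "not comparable")
  # metric properties on random corpora
  for (seed in 1:5) {
    a <- ngram_distribution(random_corpus(1, 20, letters[1:4], seed), 2L)
    b <- ngram_distribution(random_corpus(1, 20, letters[1:4], seed + 100), 2L)
    c3 <- ngram_distribution(random_corpus(1, 20, letters[1:4], seed + 200), 2L)
    expect_equal(l1_distance(a, b), l1_distance(b, a))
    expect_lte(l1_distance(a, c3), l1_distance(a, b) + l1_distance(b, c3) + 1e-12)
    expect_gte(l1_distance(a, b), 0)
  }
})

test_that("recurrence intervals count intervening phrases between repeats", {
  d <- recurrence_distribution(corpus_of(c("a", "b", "a")))
  expect_equal(d$table, c("1" = 1))
  expect_equal(recurrence_distribution(corpus_of(c("a", "a")))$table, c("0" = 1))
  expect_length(recurrence_distribution(corpus_of(c("a", "b", "c")))$table, 0L)
  # consecutive occurrences only: a at 1, 3, 4 -> intervals 1 and 0
  d2 <- recurrence_distribution(corpus_of(c("a", "b", "a", "a")))
  expect_equal(sort(d2$table), sort(c("0" = 0.5, "1" = 0.5)))
})

test_that("model assessment compares simulations to the testing baseline", {
  spec <- ground_truth_spec(repertoire_size = 12, frac_second_order = 0,
                            sparsity = 4, seed = 61)
  gt <- make_ground_truth(spec)
  cp <- simulate_ground_truth(gt, rep(400L, 6), seed = 62)
  sp <- train_test_split(cp)
  training <- corpus_subset(cp, sp$train)
  testing <- corpus_subset(cp, sp$test)
  sims <- list(
    "order-0" = replicate_simulations(markov_model(training, 0L), training,
                                      20, seed = 63),
    "order-1" = replicate_simulations(markov_model(training, 1L), training,
                                      20, seed = 64))
  tab <- assess_models(training, testing, sims, N_range = 1:3)
  expect_setequal(unique(tab$metric), c("1", "2", "3", "RI"))
  # zero-order simulations of first-order truth diverge at N = 2 ...
  z2 <- tab[tab$model == "order-0" & tab$metric == "2", ]
  expect_gt(z2$mean_l1, z2$baseline_l1)
  # ... and more at higher N than at N = 1
  z1 <- tab[tab$model == "order-0" & tab$metric == "1", ]
  expect_gte(z2$mean_l1, z1$mean_l1)
  # training compared with itself is at distance zero
  expect_equal(l1_distance(ngram_distribution(training, 1L),
                           ngram_distribution(training, 1L)), 0)
  expect_error(assess_models(training, testing, list()), "length")
})
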