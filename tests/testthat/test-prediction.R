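test_that("zero-order models always predict the modal type", {
  training <- corpus_of(c(rep("b", 6), rep("a", 4)))
  m0 <- markov_model(training, 0L)
  expect_equal(predict_next(m0), "b")
  expect_equal(predict_next(m0, c("a", "a")), "b")   # context ignored
  expect_equal(predict(m0, "a"), "b")
})

test_that("first-order models condition on the previous phrase, ties break
           lexicographically", {
  m <- markov_model(corpus_of(c("a", "b", "a", "b")), 1L)
  expect_equal(predict_next(smooth_markov(m), "a"), "b")
  # from "c": a twice, b twice, c once -> tie between a and b -> "a"
  tie <- corpus_of(c("c", "a", "c", "b", "c", "a", "c", "b", "c", "c"))
  mt <- smooth_markov(markov_model(tie, 1L))
  d <- smoothed_dist(mt, "c")
  expect_equal(unname(d["a"]), unname(d["b"]))
  expect_equal(predict_next(mt, "c"), "a")
})

test_that("prediction accuracy is exact on a deterministic chain and
           converges to the modal frequency on i.i.d. data", {
  training <- corpus_of(rep(c("a", "b"), 30))
  m <- markov_model(training, 1L)
  testing <- corpus_of(rep(c("a", "b"), 10))
  expect_equal(as.numeric(prediction_accuracy(m, testing)), 100)
  # i.i.d. with modal frequency 0.4
  set.seed(91)
  p <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  iid <- corpus_of(sample(names(p), 1e4, replace = TRUE, prob = p))
  m0 <- markov_model(iid, 0L)
  test_iid <- corpus_of(sample(names(p), 1e4, replace = TRUE, prob = p))
  expect_lt(abs(as.numeric(prediction_accuracy(m0, test_iid)) - 40), 2)
})

test_that("disagreement restriction recombines to the overall accuracy", {
  spec <- ground_truth_spec(repertoire_size = 12, sparsity = 4, seed = 92)
  gt <- make_ground_truth(spec)
  cp <- simulate_ground_truth(gt, rep(400L, 6), seed = 93)
  sp <- train_test_split(cp)
  training <- corpus_subset(cp, sp$train)
  testing <- corpus_subset(cp, sp$test)
  models <- list(m0 = smooth_markov(markov_model(training, 0L),
                                    testing$vocabulary),
                 m1 = smooth_markov(markov_model(training, 1L),
                                    testing$vocabulary),
                 m2 = smooth_markov(markov_model(training, 2L),
                                    testing$vocabulary))
  da <- disagreement_accuracy(models, testing)
  expect_gt(da$n_disagreements, 0L)
  overall <- vapply(models, function(m) {
    as.numeric(prediction_accuracy(m, testing))
  }, numeric(1L))
  # agreement-set accuracy is common to all models; recombination identity
  n <- da$n_total; nd <- da$n_disagreements
  agree_hits <- overall * n / 100 - da$accuracy * nd / 100
  expect_equal(max(agree_hits) - min(agree_hits), 0, tolerance = 1e-9)
  # identical models never disagree
  same <- disagreement_accuracy(list(a = models$m1, b = models$m1), testing)
  expect_equal(same$n_disagreements, 0L)
})

test_that("a single open bin reproduces overall accuracy and counts partition", {
  spec <- ground_truth_spec(repertoire_size = 10, sparsity = 4, seed = 94)
  gt <- make_ground_truth(spec)
  cp <- simulate_ground_truth(gt, rep(300L, 4), seed = 95)
  sp <- train_test_split(cp)
  training <- corpus_subset(cp, sp$train)
  testing <- corpus_subset(cp, sp$test)
  m1 <- smooth_markov(markov_model(training, 1L), testing$vocabulary)
  one <- rate_stratified_accuracy(m1, testing, bin_edges = 0)
  expect_equal(one$accuracy, as.numeric(prediction_accuracy(m1, testing)))
  many <- rate_stratified_accuracy(m1, testing)
  expect_equal(sum(many$n), attr(prediction_accuracy(m1, testing), "n_phrases"))
})

test_that("accuracy declines across long gaps when the generator resets there", {
  spec <- ground_truth_spec(repertoire_size = 10, sparsity = 3,
                            timing = list(p_long = 0.25), seed = 96)
  gt <- make_ground_truth(spec)
  cp <- simulate_ground_truth(gt, rep(600L, 6), seed = 97)
  sp <- train_test_split(cp)
  training <- corpus_subset(cp, sp$train)
  testing <- corpus_subset(cp, sp$test)
  m1 <- smooth_markov(markov_model(training, 1L), testing$vocabulary)
  acc <- rate_stratified_accuracy(m1, testing, bin_edges = c(0, 8))
  expect_gt(acc$n[2L], 10L)
  expect_gt(acc$accuracy[1L], acc$accuracy[2L])
})
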