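test_that("recording construction enforces event invariants", {
  expect_error(song_recording(c("a", ""), c(0, 1), c(0.5, 1.5)), "empty")
  expect_error(song_recording("a", 1, 1), "exceed")
  expect_error(song_recording(c("a", "b"), c(1, 0), c(1.5, 0.5)), "ordered")
  r <- song_recording(character(0))
  expect_equal(length(r), 0L)
})

test_that("corpora order recordings chronologically with source fallback", {
  r1 <- rec(c("a", "b"), at = "2013-06-01", src = "late")
  r2 <- rec(c("b", "a"), at = "2013-05-01", src = "early")
  cp <- song_corpus(list(r1, r2))
  expect_equal(cp$recordings[[1L]]$source, "early")
  expect_equal(cp$vocabulary, c("a", "b"))
  # missing timestamps: lexicographic source order
  r3 <- rec("a", src = "b_file")
  r4 <- rec("b", src = "a_file")
  cp2 <- song_corpus(list(r3, r4))
  expect_equal(cp2$recordings[[1L]]$source, "a_file")
})

test_that("short-recording filter keeps exactly the threshold and above", {
  cp <- corpus_of(rep("a", 49), rep("a", 50), rep("a", 51))
  kept <- filter_short_recordings(cp)
  expect_equal(unname(recording_lengths(kept)), c(50L, 51L))
  # identity when nothing is short
  expect_equal(recording_lengths(filter_short_recordings(kept)),
               recording_lengths(kept))
  # may return an empty corpus
  empty <- filter_short_recordings(cp, min_phrases = 100L)
  expect_equal(length(empty$recordings), 0L)
  expect_equal(empty$vocabulary, character(0L))
})

test_that("chronological split follows the midpoint-recording rule", {
  cp <- corpus_of(rep("a", 60), rep("b", 60), rep("c", 60))
  sp <- train_test_split(cp)   # midpoint phrase 90 falls in recording 2
  expect_equal(sp$train, c("r1", "r2"))
  expect_equal(sp$test, "r3")

  cp2 <- corpus_of(rep("a", 100), rep("b", 10))
  sp2 <- train_test_split(cp2)
  expect_equal(sp2$train, "r1")
  expect_equal(sp2$test, "r2")

  # degenerate: midpoint in final recording -> moved to test with a warning
  cp3 <- corpus_of(rep("a", 10), rep("b", 100))
  expect_warning(sp3 <- train_test_split(cp3), "final recording")
  expect_equal(sp3$train, "r1")
  expect_equal(sp3$test, "r2")

  expect_error(train_test_split(corpus_of(rep("a", 5))), "fewer than 2")
})

test_that("splits preserve phrase counts and filtering is idempotent", {
  cp <- random_corpus(5, 80, c("a", "b", "c"), seed = 1)
  sp <- train_test_split(cp)
  tr <- corpus_subset(cp, sp$train)
  te <- corpus_subset(cp, sp$test)
  expect_equal(corpus_size(tr) + corpus_size(te), corpus_size(cp))
  # filter -> split again gives the same assignment
  sp2 <- train_test_split(filter_short_recordings(cp, 10L))
  expect_equal(sp2$train, sp$train)
})

test_that("LOOCV folds partition the corpus", {
  cp <- random_corpus(3, 30, c("a", "b"), seed = 2)
  folds <- loocv_folds(cp)
  expect_length(folds, 3L)
  test_ids <- vapply(folds, function(f) f$test, character(1L))
  expect_setequal(test_ids, names(recording_lengths(cp)))
  for (f in folds) {
    expect_length(f$train, 2L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  expect_error(loocv_folds(corpus_of(rep("a", 5))), "at least 2")
})

test_that("corpus_subset validates identifiers and recomputes vocabulary", {
  cp <- corpus_of(c("a", "b"), c("c", "c"))
  expect_error(corpus_subset(cp, "nope"), "unknown recording")
  sub <- corpus_subset(cp, "r2")
  expect_equal(sub$vocabulary, "c")
  expect_equal(length(corpus_subset(cp, character(0L))$recordings), 0L)
})
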