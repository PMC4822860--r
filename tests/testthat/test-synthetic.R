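test_that("ground-truth specs validate their parameters", {
  expect_error(ground_truth_spec(repertoire_size = 10, sparsity = 20),
               "out-degree")
  expect_error(ground_truth_spec(frac_second_order = 0.8,
                                 frac_zero_order = 0.5))
  expect_error(ground_truth_spec(separation = 0.3))
  spec <- ground_truth_spec()
  expect_equal(spec$repertoire_size, 50L)
  expect_equal(spec$frac_second_order, 0.4)
  expect_equal(spec$frac_zero_order, 0.08)
})

test_that("model construction is deterministic in the seed", {
  s1 <- make_ground_truth(ground_truth_spec(repertoire_size = 20, seed = 8))
  s2 <- make_ground_truth(ground_truth_spec(repertoire_size = 20, seed = 8))
  s3 <- make_ground_truth(ground_truth_spec(repertoire_size = 20, seed = 9))
  expect_identical(s1$q, s2$q)
  expect_identical(s1$planted, s2$planted)
  expect_false(identical(s1$q, s3$q))
})

test_that("construction guarantees hold: separation, roles, fallback sharing", {
  spec <- ground_truth_spec()
  gt <- make_ground_truth(spec)
  # planted contexts exist with guaranteed separation
  expect_gte(nrow(gt$planted_table), ceiling(0.4 * 50 * 0.5))
  expect_true(all(gt$planted_table$separation >= spec$separation - 1e-9))
  # every planted conditional sums to one
  expect_true(all(abs(vapply(gt$planted, sum, numeric(1L)) - 1) < 1e-9))
  # zero-order types share the fallback distribution exactly
  for (i in which(gt$roles == "zero")) {
    expect_equal(unname(gt$q[i, ]), gt$p0)
  }
  # role fractions follow the spec
  expect_equal(sum(gt$roles == "second"), round(0.4 * 50))
  expect_equal(sum(gt$roles == "zero"), round(0.08 * 50))
  # a purely first-order spec plants nothing
  gt1 <- make_ground_truth(ground_truth_spec(frac_second_order = 0, seed = 3))
  expect_length(gt1$planted, 0L)
})

test_that("order-1 fits on a long corpus recover the true conditionals", {
  spec <- ground_truth_spec(repertoire_size = 20, frac_second_order = 0,
                            sparsity = 3, timing = list(p_long = 0),
                            seed = 111)
  gt <- make_ground_truth(spec)
  cp <- simulate_ground_truth(gt, rep(12500L, 8), seed = 112)  # 1e5 phrases
  m1 <- markov_model(cp, 1L)
  l1_at <- function(min_n) {
    worst <- 0
    for (lab in intersect(gt$vocabulary, cp$vocabulary)) {
      counts <- context_counts(m1, lab)
      if (sum(counts) < min_n) next
      fitted <- stats::setNames(numeric(20L), gt$vocabulary)
      fitted[names(counts)] <- counts / sum(counts)
      worst <- max(worst, sum(abs(fitted - gt$q[lab, ])))
    }
    worst
  }
  # sampling error of an out-degree-5 multinomial row is about 0.05 at
  # n = 500, so consistency is asserted at a tolerance that scales with n
  expect_lt(l1_at(500L), 0.12)
  expect_lt(l1_at(2000L), 0.05)
})

test_that("generated studies mirror the emulated corpus shape", {
  study <- generate_study(ground_truth_spec(seed = 121), n_individuals = 4L)
  expect_length(study$corpora, 4L)
  for (id in names(study$corpora)) {
    cp <- study$corpora[[id]]
    expect_gte(length(cp$vocabulary), 44L)
    expect_lte(length(cp$vocabulary), 60L)
    expect_true(all(cp$vocabulary %in% study$truth[[id]]$vocabulary))
    expect_true(all(recording_lengths(cp) >= 50L))
    # recurrence intervals are biased low: median well under repertoire size
    d <- recurrence_distribution(cp)
    keys <- as.numeric(names(d$table))
    med <- keys[which(cumsum(d$table) >= 0.5)[1L]]
    expect_lt(med, length(cp$vocabulary) / 2)
  }
  # timing: modal inter-onset interval near two seconds, with a long tail
  r <- study$corpora[[1L]]$recordings[[1L]]
  ioi <- diff(r$start)
  expect_gt(stats::median(ioi), 1.2)
  expect_lt(stats::median(ioi), 3.5)
  expect_gt(max(ioi), 10)
})

test_that("deliberately short recordings exercise the length filter", {
  study <- generate_study(ground_truth_spec(repertoire_size = 15, seed = 122),
                          n_individuals = 1L, repertoire_range = NULL,
                          n_recordings_range = c(5L, 5L), n_short = 2L)
  cp <- study$corpora[[1L]]
  expect_equal(sum(recording_lengths(cp) < 50L), 2L)
  kept <- filter_short_recordings(cp)
  expect_equal(length(kept$recordings), length(cp$recordings) - 2L)
})

test_that("study generation writes a readable corpus directory", {
  dir <- withr::local_tempdir()
  generate_study(ground_truth_spec(repertoire_size = 10, seed = 123),
                 n_individuals = 2L, repertoire_range = NULL,
                 n_recordings_range = c(3L, 3L), length_meanlog = log(60),
                 length_sdlog = 0.1, dir = dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_corpus(dir)
  expect_length(back, 2L)
  expect_equal(unname(vapply(back, function(cp) length(cp$recordings),
                             integer(1L))), c(3L, 3L))
})

test_that("recording-level tilts and partial drift perturb without breaking
           the generative contract", {
  spec <- ground_truth_spec(repertoire_size = 10, sparsity = 3,
                            recording_effect = 0.8, seed = 131)
  gt <- make_ground_truth(spec)
  cp <- simulate_ground_truth(gt, rep(400L, 4), seed = 132)
  cp2 <- simulate_ground_truth(gt, rep(400L, 4), seed = 132)
  expect_identical(lapply(cp$recordings, `[[`, "labels"),
                   lapply(cp2$recordings, `[[`, "labels"))
  # tilts shift per-recording type frequencies more than i.i.d. noise would
  freqs <- vapply(cp$recordings, function(r) {
    as.numeric(table(factor(r$labels, levels = gt$vocabulary))) / 400
  }, numeric(10L))
  expect_gt(mean(apply(freqs, 1L, stats::sd)), 0)
  # blending two truths interpolates conditionals
  t2 <- vireosyntax:::regenerate_conditionals(gt, 999)
  mix <- vireosyntax:::blend_ground_truth(gt, t2, 0.25)
  expect_equal(unname(mix$q), unname(0.75 * gt$q + 0.25 * t2$q))
  expect_true(all(abs(rowSums(mix$q) - 1) < 1e-9))
  expect_true(all(abs(vapply(mix$planted, sum, numeric(1L)) - 1) < 1e-9))
  # a drifted study still yields valid corpora
  study <- generate_study(ground_truth_spec(repertoire_size = 10, sparsity = 3,
                                            seed = 133),
                          n_individuals = 1L, repertoire_range = NULL,
                          n_recordings_range = c(4L, 4L),
                          length_meanlog = log(120), length_sdlog = 0.1,
                          drift = 0.3)
  expect_equal(length(study$corpora[[1L]]$recordings), 4L)
})
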