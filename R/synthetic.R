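# Synthetic ground-truth corpora. The generator emulates the statistical
# structure of a wild vireo song study - per-individual repertoires of a few
# dozen two-letter phrase types drawn from a larger population inventory,
# sparse transition structure that favours low recurrence intervals, a
# mixture of zero-, first- and second-order phrase types, and phrase timing
# with a modal inter-onset interval near two seconds plus occasional long
# silences - so that every pipeline stage can be validated against known
# truth without any field recordings.

#' Specification of a synthetic ground truth
#'
#' @param repertoire_size number of phrase types in the individual's
#'   repertoire (default 50, typical of the emulated study).
#' @param frac_second_order fraction of types given genuinely second-order
#'   contexts (default 0.4).
#' @param frac_zero_order fraction of types sharing the zero-order fallback
#'   distribution (default 0.08). The remainder get distinct first-order
#'   conditionals.
#' @param sparsity mean out-degree of a conditional distribution (default 5):
#'   small out-degrees concentrate singing on small subsets of the repertoire,
#'   as in the emulated species, and keep the second-order model's smoothing
#'   overhead moderate at study-scale corpora.
#' @param recurrence_bias geometric decay (in (0, 1)) of successor weight with
#'   repertoire "distance" from the current type; values near 1 spread
#'   successors evenly, small values cluster them, biasing the song toward
#'   low recurrence intervals (default 0.55).
#' @param separation guaranteed L1 distance between the two planted
#'   conditionals of each second-order type (default 1.6; must be at least
#'   0.5). The default comes from a simulation-based power analysis: at
#'   50000-phrase corpora the planted signal must also outweigh the
#'   second-order model's discounting overhead (about 0.05 nats per phrase)
#'   so that the model-comparison orderings the generator is designed to
#'   produce are guaranteed by construction, not left to chance.
#' @param timing list of timing parameters: lognormal phrase duration
#'   (`dur_meanlog`, `dur_sdlog`, modal duration about 0.8 s), lognormal
#'   short gap (`gap_meanlog`, `gap_sdlog`, modal silence about 1 s, so the
#'   modal inter-onset interval is about 2 s), long-gap probability `p_long`
#'   and offset `long_gap_min`, and `reset_on_long`: whether the phrase after
#'   a long silence is drawn from the fallback distribution (a bout restart)
#'   rather than from the running context.
#' @param recording_effect standard deviation of a per-recording
#'   log-normal tilt applied to every conditional distribution (default 0:
#'   none). Positive values emulate recording-level context effects - the
#'   way field recordings made in different social situations are enriched
#'   for different phrases and transitions - which make a corpus's halves
#'   differ by more than sampling noise even when the underlying syntax is
#'   stable.
#' @param recording_lengths default per-recording phrase counts used by
#'   [simulate_ground_truth()] when none are supplied.
#' @param seed integer seed governing model construction.
#' @return an object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(repertoire_size = 50L, frac_second_order = 0.4,
                              frac_zero_order = 0.08, sparsity = 5,
                              recurrence_bias = 0.55, separation = 1.6,
                              timing = list(), recording_effect = 0,
                              recording_lengths = NULL, seed = 1L) {
  stopifnot(repertoire_size >= 2L,
            frac_second_order >= 0, frac_zero_order >= 0,
            frac_second_order + frac_zero_order <= 1,
            recurrence_bias > 0, recurrence_bias < 1,
            separation >= 0.5, separation <= 2, recording_effect >= 0)
  if (sparsity > repertoire_size) {
    stop("sparsity (mean out-degree) cannot exceed the repertoire size")
  }
  tdef <- list(dur_meanlog = log(0.9), dur_sdlog = 0.35,
               gap_meanlog = log(1.3), gap_sdlog = 0.5,
               p_long = 0.08, long_gap_min = 10, reset_on_long = TRUE)
  tdef[names(timing)] <- timing
  structure(
    list(repertoire_size = as.integer(repertoire_size),
         frac_second_order = frac_second_order,
         frac_zero_order = frac_zero_order,
         sparsity = sparsity, recurrence_bias = recurrence_bias,
         separation = separation, timing = tdef,
         recording_effect = recording_effect,
         recording_lengths = recording_lengths, seed = as.integer(seed)),
    class = "ground_truth_spec"
  )
}

# The 126-label population inventory of two-letter phrase-type codes.
population_inventory <- function() {
  paste0(rep(letters, each = 26L), rep(letters, times = 26L))[1:126]
}

#' Build a labelled mixed-order generative model
#'
#' Constructs the generator a [ground_truth_spec()] describes. Zero-order
#' types share the fallback distribution; first-order types get distinct
#' sparse conditionals whose successors cluster near the current type
#' (producing low recurrence intervals); each second-order type `i` gets two
#' planted contexts `(h1, i)`, `(h2, i)` whose conditionals are mixtures
#' `(1 - w) q_i + w u_A` and `(1 - w) q_i + w u_B` with `A`, `B` disjoint
#' halves of the support of `q_i`, so their L1 separation is exactly
#' `w * 2 = separation` by construction. The two predecessors `h1`, `h2` are
#' guaranteed substantial transition probability into `i`, so the planted
#' contexts accumulate observations. True state labels are retained for
#' recovery scoring.
#'
#' @param spec a [ground_truth_spec()].
#' @return an object of class `ground_truth` with elements `vocabulary`,
#'   `roles` (named `"zero"`/`"first"`/`"second"`), `p0`, `q` (row-stochastic
#'   matrix), `planted` (named list of planted conditionals, names are
#'   `"h i"` context labels) and `spec`.
#' @export
make_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  set.seed(spec$seed)
  C <- spec$repertoire_size
  vocab <- sort(sample(population_inventory(), C))
  n_second <- round(spec$frac_second_order * C)
  n_zero <- round(spec$frac_zero_order * C)
  roles <- rep("first", C)
  idx <- sample.int(C)
  roles[idx[seq_len(n_second)]] <- "second"
  if (n_zero > 0L) roles[idx[n_second + seq_len(n_zero)]] <- "zero"
  names(roles) <- vocab

  p0 <- stats::rgamma(C, shape = 2)
  p0 <- p0 / sum(p0)

  ring_dist <- function(i, j) pmin(abs(i - j), C - abs(i - j))
  q <- matrix(0, C, C, dimnames = list(vocab, vocab))
  for (i in seq_len(C)) {
    if (roles[i] == "zero") {
      q[i, ] <- p0
      next
    }
    d <- max(2L, min(C, stats::rpois(1L, spec$sparsity - 2) + 2L))
    w <- spec$recurrence_bias^ring_dist(i, seq_len(C))
    w[i] <- w[i] * 0.15   # repeats of the same type are uncommon
    support <- sample.int(C, d, prob = w)
    pr <- stats::rgamma(d, shape = 1.5)
    q[i, support] <- pr / sum(pr)
  }
  # every type must be reachable: give orphans a foothold in one conditional
  orphan <- which(colSums(q) == 0 & p0 < 1e-8)
  for (j in orphan) {
    i <- sample(which(roles != "zero"), 1L)
    q[i, ] <- q[i, ] * 0.95
    q[i, j] <- q[i, j] + 0.05
  }

  # Stationary distribution of the first-order backbone: hosts for planted
  # second-order contexts are chosen by how often they are actually visited,
  # so every planted context accumulates observations in corpora of realistic
  # length (the construction must guarantee detectable signal).
  pi_st <- p0
  for (it in 1:60) pi_st <- as.numeric(pi_st %*% q)
  boost_for <- function(h) {
    # expected visits to h in a ~5e4-phrase corpus times this probability
    # should give the planted context a few hundred observations
    min(0.45, max(0.15, 250 / (5e4 * max(pi_st[h], 1e-6))))
  }
  host_pool <- setdiff(which(roles != "zero"), integer(0))
  host_pool <- host_pool[order(pi_st[host_pool], decreasing = TRUE)]
  host_used <- integer(0)
  planted <- list()
  planted_meta <- list()
  for (i in which(roles == "second")) {
    avail <- setdiff(host_pool, c(host_used, i))
    if (length(avail) < 2L) avail <- setdiff(host_pool, i)  # reuse if exhausted
    hs <- avail[1:2]
    host_used <- c(host_used, hs)
    for (h in hs) {
      target <- boost_for(h)
      if (q[h, i] < target) {
        q[h, ] <- q[h, ] * (1 - (target - q[h, i]) / max(1 - q[h, i], 1e-9))
        q[h, i] <- 1 - sum(q[h, -i])
      }
    }
    base <- q[i, ]
    support <- which(base > 0)
    if (length(support) < 2L) { # degenerate: widen the support minimally
      extra <- setdiff(seq_len(C), support)[1:2]
      base[extra] <- 0.05
      base <- base / sum(base)
      support <- which(base > 0)
      q[i, ] <- base
    }
    half <- support[order(base[support], decreasing = TRUE)]
    A <- half[seq(1L, length(half), by = 2L)]
    B <- half[seq(2L, length(half), by = 2L)]
    uA <- numeric(C); uA[A] <- base[A] / sum(base[A])
    uB <- numeric(C); uB[B] <- base[B] / sum(base[B])
    wgt <- spec$separation / 2
    d1 <- (1 - wgt) * base + wgt * uA
    d2 <- (1 - wgt) * base + wgt * uB
    k1 <- paste(vocab[hs[1L]], vocab[i])
    k2 <- paste(vocab[hs[2L]], vocab[i])
    planted[[k1]] <- d1
    planted[[k2]] <- d2
    planted_meta[[length(planted_meta) + 1L]] <- data.frame(
      type = vocab[i], context_a = k1, context_b = k2,
      separation = sum(abs(d1 - d2)), stringsAsFactors = FALSE)
  }
  structure(
    list(vocabulary = vocab, C = C, roles = roles, p0 = p0, q = q,
         planted = planted,
         planted_table = if (length(planted_meta)) do.call(rbind, planted_meta)
                         else data.frame(type = character(0)),
         spec = spec),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground-truth generator\n")
  cat("  repertoire:", x$C, "types (",
      sum(x$roles == "zero"), "zero-order,",
      sum(x$roles == "first"), "first-order,",
      sum(x$roles == "second"), "second-order )\n")
  cat("  planted second-order contexts:", length(x$planted), "\n")
  invisible(x)
}

# Regenerate all conditional distributions (same vocabulary and roles) -
# a different syntax for the same repertoire, used to plant time
# inhomogeneity.
regenerate_conditionals <- function(truth, seed) {
  spec2 <- truth$spec
  spec2$seed <- as.integer(seed)
  t2 <- make_ground_truth(spec2)
  # keep this repertoire's labels and roles, adopt the new tables
  old_vocab <- t2$vocabulary
  t2$vocabulary <- truth$vocabulary
  dimnames(t2$q) <- list(truth$vocabulary, truth$vocabulary)
  names(t2$roles) <- truth$vocabulary
  relabel <- function(k) {
    parts <- match(strsplit(k, " ", fixed = TRUE)[[1L]], old_vocab)
    paste(truth$vocabulary[parts], collapse = " ")
  }
  names(t2$planted) <- vapply(names(t2$planted), relabel, character(1L))
  t2
}

# Convex blend of two ground truths sharing a vocabulary: conditionals (and
# planted tables, over the union of planted contexts) are mixed with weight d
# on the second truth. Used to plant gradual syntax drift.
blend_ground_truth <- function(t1, t2, d) {
  stopifnot(identical(t1$vocabulary, t2$vocabulary), d >= 0, d <= 1)
  out <- t1
  out$p0 <- (1 - d) * t1$p0 + d * t2$p0
  out$q <- (1 - d) * t1$q + d * t2$q
  row_of <- function(truth, k) {
    hit <- truth$planted[[k]]
    if (!is.null(hit)) return(hit)
    i <- strsplit(k, " ", fixed = TRUE)[[1L]][2L]
    truth$q[i, ]
  }
  keys <- union(names(t1$planted), names(t2$planted))
  out$planted <- stats::setNames(lapply(keys, function(k) {
    (1 - d) * row_of(t1, k) + d * row_of(t2, k)
  }), keys)
  out
}

#' Simulate timed recordings from a ground-truth model
#'
#' The first phrase of a recording is drawn from the fallback distribution,
#' the second from the first-order conditional, and subsequent phrases from
#' the planted second-order conditional when the running context matches one,
#' otherwise from the first-order conditional. Phrase durations and gaps are
#' drawn from the spec's timing model; when a long gap occurs and
#' `reset_on_long` is set, the following phrase is drawn from the fallback
#' distribution (a bout restart), which makes upcoming phrases genuinely less
#' predictable across long silences.
#'
#' @param truth a [make_ground_truth()] model.
#' @param recording_lengths integer vector of phrase counts, one per
#'   recording.
#' @param seed integer seed.
#' @param individual_id,start_date recording metadata (one recording per day).
#' @return a [song_corpus()].
#' @export
simulate_ground_truth <- function(truth, recording_lengths = NULL, seed = 1L,
                                  individual_id = "synthetic",
                                  start_date = as.POSIXct("2013-04-25",
                                                          tz = "UTC")) {
  stopifnot(inherits(truth, "ground_truth"))
  lengths <- recording_lengths %||% truth$spec$recording_lengths %||%
    rep(200L, 8L)
  set.seed(seed)
  C <- truth$C
  tm <- truth$spec$timing
  lambda <- truth$spec$recording_effect %||% 0
  pl_code <- vapply(names(truth$planted), function(k) {
    parts <- match(strsplit(k, " ", fixed = TRUE)[[1L]], truth$vocabulary)
    (parts[1L] - 1) * C + parts[2L]
  }, numeric(1L))
  draw <- function(cum, u) min(findInterval(u, cum) + 1L, C)
  recs <- vector("list", length(lengths))
  for (rj in seq_along(lengths)) {
    L <- lengths[rj]
    # recording-level context effect: a shared multiplicative tilt on the
    # successor probabilities of every conditional in this recording
    tilt <- if (lambda > 0) exp(stats::rnorm(C, 0, lambda)) else rep(1, C)
    retilt <- function(p) { v <- p * tilt; v / sum(v) }
    cumq <- t(apply(truth$q, 1L, function(p) cumsum(retilt(p))))
    cum0 <- cumsum(retilt(truth$p0))
    pl_cum <- new.env(parent = emptyenv())
    for (j in seq_along(pl_code)) {
      assign(format(pl_code[j], scientific = FALSE),
             cumsum(retilt(truth$planted[[j]])), envir = pl_cum)
    }
    u <- stats::runif(L)
    gaps_long <- stats::runif(L) < tm$p_long
    gap <- stats::rlnorm(L, tm$gap_meanlog, tm$gap_sdlog)
    gap[gaps_long] <- tm$long_gap_min + stats::rexp(sum(gaps_long), 1 / 20)
    dur <- stats::rlnorm(L, tm$dur_meanlog, tm$dur_sdlog)
    x <- integer(L)
    for (m in seq_len(L)) {
      reset <- m > 1L && gaps_long[m] && tm$reset_on_long
      x[m] <- if (m == 1L || reset) {
        draw(cum0, u[m])
      } else if (m == 2L) {
        draw(cumq[x[1L], ], u[m])
      } else {
        code <- format((x[m - 2L] - 1) * C + x[m - 1L], scientific = FALSE)
        pc <- pl_cum[[code]]
        if (is.null(pc)) draw(cumq[x[m - 1L], ], u[m]) else draw(pc, u[m])
      }
    }
    start <- cumsum(c(0, dur[-L] + gap[-1L]))
    recs[[rj]] <- song_recording(
      labels = truth$vocabulary[x], start = start, end = start + dur,
      individual_id = individual_id,
      recorded_at = start_date + (rj - 1L) * 86400,
      source = sprintf("%s_rec%03d", individual_id, rj))
  }
  song_corpus(recs, individual_id)
}

#' Generate a full synthetic study
#'
#' One independent ground-truth model and recording corpus per individual,
#' mirroring the shape of the emulated field study: per-individual repertoire
#' sizes drawn from `repertoire_range`, a handful to a few dozen recordings
#' per individual, and right-skewed recording lengths of at least 50 phrases
#' (deliberately shorter recordings can be planted to exercise filtering).
#'
#' @param spec a [ground_truth_spec()]; its `repertoire_size` is overridden
#'   per individual when `repertoire_range` is given.
#' @param n_individuals number of individuals (default 14).
#' @param seed master seed (default the spec seed).
#' @param repertoire_range integer range of per-individual repertoire sizes;
#'   `NULL` keeps `spec$repertoire_size` for everyone.
#' @param n_recordings_range integer range of recordings per individual.
#' @param length_meanlog,length_sdlog lognormal recording-length parameters
#'   (lengths are clamped to `[50, 10000]` phrases).
#' @param n_short number of deliberately short (< 50 phrases) recordings to
#'   plant per individual.
#' @param inhomogeneous when `TRUE`, each individual's syntax switches to a
#'   regenerated set of conditionals halfway through its recordings (a
#'   planted violation of time homogeneity; equivalent to `drift = 1`).
#' @param drift degree in `[0, 1]` of a milder halfway syntax change: the
#'   second half of the recordings uses conditionals blended `drift` of the
#'   way toward a regenerated syntax. Small values emulate the modest
#'   within-study drift that field corpora of this kind display.
#' @param dir when given, writes TextGrids, `metadata.csv` and a
#'   `truth.json` record there via [write_corpus()].
#' @return a list with `corpora` (named list of [song_corpus()]), `truth`
#'   (named list of [make_ground_truth()] objects) and `seed`.
#' @export
generate_study <- function(spec = ground_truth_spec(), n_individuals = 14L,
                           seed = NULL, repertoire_range = c(44L, 60L),
                           n_recordings_range = c(5L, 20L),
                           length_meanlog = log(250), length_sdlog = 0.6,
                           n_short = 0L, inhomogeneous = FALSE, drift = 0,
                           dir = NULL) {
  stopifnot(inherits(spec, "ground_truth_spec"), n_individuals >= 1L)
  seed <- seed %||% spec$seed
  corpora <- list()
  truths <- list()
  for (b in seq_len(n_individuals)) {
    s_b <- child_seed(seed, b)
    set.seed(s_b)
    id <- sprintf("SYN%02d", b)
    spec_b <- spec
    if (!is.null(repertoire_range)) {
      spec_b$repertoire_size <- as.integer(
        resample(repertoire_range[1L]:repertoire_range[2L]))
    }
    spec_b$seed <- child_seed(s_b, 1L)
    truth <- make_ground_truth(spec_b)
    n_rec <- resample(n_recordings_range[1L]:n_recordings_range[2L])
    lens <- pmin(pmax(round(stats::rlnorm(n_rec, length_meanlog,
                                          length_sdlog)), 50L), 10000L)
    if (n_short > 0L) {
      lens <- c(lens, sample(5:49, n_short, replace = TRUE))
      lens <- sample(lens)   # shuffle short ones into the schedule
    }
    d <- if (inhomogeneous) 1 else drift
    if (d > 0) {
      if (length(lens) < 2L) stop("a halfway syntax switch needs >= 2 recordings")
      truth2 <- blend_ground_truth(truth,
                                   regenerate_conditionals(truth,
                                                           child_seed(s_b, 3L)),
                                   d)
      cut <- ceiling(length(lens) / 2)
      c1 <- simulate_ground_truth(truth, lens[seq_len(cut)],
                                  seed = child_seed(s_b, 2L),
                                  individual_id = id)
      c2 <- simulate_ground_truth(truth2, lens[(cut + 1L):length(lens)],
                                  seed = child_seed(s_b, 4L),
                                  individual_id = id,
                                  start_date = as.POSIXct("2013-04-25",
                                                          tz = "UTC") +
                                    cut * 86400)
      recs <- c(c1$recordings, c2$recordings)
      for (j in seq_along(recs)) {
        recs[[j]]$source <- sprintf("%s_rec%03d", id, j)
      }
      corpora[[id]] <- song_corpus(recs, id)
    } else {
      corpora[[id]] <- simulate_ground_truth(truth, lens,
                                             seed = child_seed(s_b, 2L),
                                             individual_id = id)
    }
    truths[[id]] <- truth
  }
  out <- list(corpora = corpora, truth = truths, seed = seed)
  if (!is.null(dir)) {
    write_corpus(corpora, dir)
    truth_doc <- lapply(truths, function(t) {
      list(vocabulary = as.list(t$vocabulary),
           roles = as.list(t$roles),
           planted_contexts = as.list(names(t$planted)),
           seed = t$spec$seed)
    })
    writeLines(jsonlite::toJSON(truth_doc, auto_unbox = TRUE, digits = NA),
               file.path(dir, "truth.json"))
  }
  out
}
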