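#' Run the full syntax analysis pipeline
#'
#' Orchestrates every stage over a set of per-individual corpora: ingest (or
#' synthesize), filter short recordings, split chronologically, simulate and
#' assess candidate models by L1 distance, screen for higher-order
#' dependencies, evaluate model likelihoods and predictability, and test time
#' homogeneity. All stochastic stages derive their seeds from the single
#' master seed in the config, so a rerun with the same config reproduces the
#' same outputs byte for byte.
#'
#' @param config a named list, or the path of a YAML file holding one, with
#'   fields: `corpus_dir` (a directory readable by [read_corpus()]) or
#'   `synthetic` (a list of [ground_truth_spec()] arguments plus optional
#'   `n_individuals`); `out_dir` (required); `seed` (default 1);
#'   `n_range` (default 1:7); `assess_reps` (simulation replicates per model
#'   for the L1 assessment, default 100); `homogeneity_sims` (default 100);
#'   `min_phrases` (default 50); `paradigms` (default both); `stages`
#'   (subset of `c("assess", "dependencies", "likelihood", "prediction",
#'   "homogeneity")`).
#' @return (invisibly) a named list of the result tables, which are also
#'   written to `out_dir` as CSV files together with `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  n_range <- config$n_range %||% 1:7
  stopifnot(all(n_range >= 1L), all(n_range <= 7L))
  assess_reps <- config$assess_reps %||% 100L
  homo_sims <- config$homogeneity_sims %||% 100L
  min_phrases <- config$min_phrases %||% 50L
  paradigms <- config$paradigms %||% c("train-test", "loocv")
  stages <- config$stages %||% c("assess", "dependencies", "likelihood",
                                 "prediction", "homogeneity")
  log_msg <- function(...) message("[pipeline] ", ...)

  corpora <- if (!is.null(config$corpus_dir)) {
    log_msg("reading corpora from ", config$corpus_dir)
    read_corpus(config$corpus_dir, tier_name = config$tier_name %||% "phrases")
  } else if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    gs_names <- c("n_individuals", "repertoire_range", "n_recordings_range",
                  "length_meanlog", "length_sdlog", "n_short", "inhomogeneous")
    gs_args <- syn[names(syn) %in% gs_names]
    # an explicit repertoire_size fixes every individual's repertoire unless
    # a range is also requested
    if (!is.null(syn$repertoire_size) && is.null(syn$repertoire_range)) {
      gs_args["repertoire_range"] <- list(NULL)
    }
    spec_args <- syn[!names(syn) %in% gs_names]
    spec <- do.call(ground_truth_spec, c(spec_args, list(seed = seed)))
    log_msg("generating synthetic study: ",
            gs_args$n_individuals %||% 14L, " individuals")
    do.call(generate_study, c(list(spec = spec, seed = seed), gs_args))$corpora
  } else {
    stop("config must provide corpus_dir or synthetic")
  }

  corpora <- lapply(corpora, filter_short_recordings, min_phrases = min_phrases)
  corpora <- Filter(function(cp) length(cp$recordings) >= 2L, corpora)
  if (length(corpora) == 0L) stop("no corpus with >= 2 recordings after filtering")
  log_msg(length(corpora), " corpora, ",
          sum(vapply(corpora, corpus_size, integer(1L))), " phrases total")

  results <- list()
  assess_rows <- list(); dep_rows <- list(); eval_rows <- list()
  pred_rows <- list(); homo_rows <- list()
  for (id in names(corpora)) {
    corpus <- corpora[[id]]
    split <- train_test_split(corpus)
    training <- corpus_subset(corpus, split$train)
    testing <- corpus_subset(corpus, split$test)
    s_id <- child_seed(seed, match(id, names(corpora)))
    if ("assess" %in% stages) {
      log_msg(id, ": assessing models with ", assess_reps, " simulations each")
      sims <- lapply(stats::setNames(0:2, paste0("order-", 0:2)), function(k) {
        replicate_simulations(markov_model(training, k), training,
                              assess_reps, child_seed(s_id, 10L + k))
      })
      assess_rows[[id]] <- assess_models(training, testing, sims, n_range)
    }
    if ("dependencies" %in% stages) {
      log_msg(id, ": dependency screens")
      dep_rows[[id]] <- rbind(summary(higher_order_tests(corpus, 2L)),
                              summary(higher_order_tests(corpus, 3L)))
    }
    if ("likelihood" %in% stages || "prediction" %in% stages) {
      log_msg(id, ": likelihood and predictability evaluation")
      ev <- evaluate_all(corpus, paradigms = paradigms)
      eval_rows[[id]] <- as.data.frame(ev)
      if ("prediction" %in% stages) {
        ipm <- attr(ev, "interpolated")
        pred_rows[[id]] <- cbind(individual = id,
                                 rate_stratified_accuracy(ipm, testing))
      }
    }
    if ("homogeneity" %in% stages) {
      log_msg(id, ": homogeneity test with ", homo_sims, " simulations")
      homo_rows[[id]] <- homogeneity_test(corpus, split, n_sims = homo_sims,
                                          N_range = n_range,
                                          seed = child_seed(s_id, 20L))
    }
  }
  write_out <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    log_msg("wrote ", path)
    df
  }
  if (length(assess_rows)) {
    results$assessment <- write_out(do.call(rbind, assess_rows), "assessment.csv")
    results$assessment_tests <- write_out(assess_ttests(results$assessment),
                                          "assessment_ttests.csv")
  }
  if (length(dep_rows)) {
    results$dependencies <- write_out(do.call(rbind, dep_rows),
                                      "dependencies.csv")
  }
  if (length(eval_rows)) {
    results$evaluation <- write_out(do.call(rbind, eval_rows), "evaluation.csv")
  }
  if (length(pred_rows)) {
    results$rate_accuracy <- write_out(do.call(rbind, pred_rows),
                                       "rate_accuracy.csv")
  }
  if (length(homo_rows)) {
    results$homogeneity <- write_out(do.call(rbind, lapply(homo_rows,
                                                           as.data.frame)),
                                     "homogeneity.csv")
    results$homogeneity_summary <- write_out(homogeneity_summary(homo_rows),
                                             "homogeneity_summary.csv")
  }
  manifest <- list(
    seed = seed, n_range = as.list(n_range), assess_reps = assess_reps,
    homogeneity_sims = homo_sims, min_phrases = min_phrases,
    stages = as.list(stages), paradigms = as.list(paradigms),
    individuals = as.list(names(corpora)),
    package_version = as.character(utils::packageVersion("vireosyntax")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(results)
}
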