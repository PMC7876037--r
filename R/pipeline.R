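# End-to-end experiment: cohort -> features -> (ranking) -> single and
# undersampling-ensemble models -> metrics, over repeated stratified 80/20
# holdout splits. Keyword vocabulary and embedding model are fitted on the
# training split of each repetition (leakage mode "train_only") or on the
# full cohort (mode "all", the whole-corpus variant).

FEATURE_FAMILIES <- c("statistics", "keyword", "embedding")

#' Configure a termination-prediction experiment
#'
#' @param records list of `trial_record` objects (e.g. a selected cohort or
#'   `generate_cohort(spec)$records`).
#' @param labels binary labels (1 = terminated), aligned with `records`.
#' @param families feature families to assemble, subset of
#'   `c("statistics", "keyword", "embedding")`.
#' @param learners base-learner families to evaluate, subset of [LEARNERS].
#' @param rounds undersampling rounds per ensemble, default 10.
#' @param repetitions number of random holdout repetitions, default 5.
#' @param test_fraction held-out fraction, default 0.2.
#' @param seed master seed.
#' @param leakage_mode `"train_only"` (fit text models on the training
#'   split; default) or `"all"` (fit on the full cohort).
#' @param keyword_max_terms keyword vocabulary cap, default 500.
#' @param embedding list of embedding settings: `d`, `window`, `min_count`,
#'   `epochs`, `negative`, `infer_epochs`.
#' @param learner_params named list of per-learner parameter overrides,
#'   e.g. `list(neural_network = list(size = 20))`.
#' @param threshold classification threshold, default 0.5.
#' @return A validated `experiment_config`.
#' @export
experiment_config <- function(records, labels,
                              families = FEATURE_FAMILIES,
                              learners = "logistic_regression",
                              rounds = 10L, repetitions = 5L,
                              test_fraction = 0.2, seed = 1L,
                              leakage_mode = c("train_only", "all"),
                              keyword_max_terms = 500L,
                              embedding = list(),
                              learner_params = list(),
                              threshold = 0.5) {
  stopifnot(length(records) == length(labels),
            all(families %in% FEATURE_FAMILIES), length(families) >= 1,
            all(learners %in% LEARNERS),
            repetitions >= 1, rounds >= 1,
            test_fraction > 0, test_fraction < 1)
  emb_defaults <- list(d = 100L, window = 5L, min_count = 2L, epochs = 20L,
                       negative = 5L, infer_epochs = 50L)
  emb <- utils::modifyList(emb_defaults, embedding)
  structure(list(records = records, labels = as.integer(labels),
                 families = families, learners = learners,
                 rounds = as.integer(rounds),
                 repetitions = as.integer(repetitions),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 leakage_mode = match.arg(leakage_mode),
                 keyword_max_terms = as.integer(keyword_max_terms),
                 embedding = emb, learner_params = learner_params,
                 threshold = threshold),
            class = "experiment_config")
}

#' Assemble the feature matrix for a set of trials
#'
#' Binds the requested family blocks: the 40 statistics features, the
#' TF-IDF keyword block against a fitted vocabulary, and the inferred
#' embedding block. At the defaults (500-term vocabulary, d = 100) the full
#' assembly has 640 columns.
#'
#' @param records list of `trial_record` objects.
#' @param families families to include.
#' @param kw_vocab fitted [fit_keyword_vocabulary()] (required for the
#'   keyword family).
#' @param emb_model fitted [fit_doc_embedding()] (required for the
#'   embedding family).
#' @param infer_epochs inference epochs for the embedding block.
#' @return Numeric matrix with named columns and no missing values.
#' @export
assemble_features <- function(records, families = FEATURE_FAMILIES,
                              kw_vocab = NULL, emb_model = NULL,
                              infer_epochs = 50L) {
  blocks <- list()
  if ("statistics" %in% families) {
    blocks$statistics <- extract_statistics_matrix(records)
  }
  if ("keyword" %in% families) {
    if (is.null(kw_vocab)) stop("keyword family requires a fitted vocabulary",
                                call. = FALSE)
    tok <- lapply(records, function(r) tokenize_keywords(r$keywords_field))
    blocks$keyword <- keyword_matrix(tok, kw_vocab)
  }
  if ("embedding" %in% families) {
    if (is.null(emb_model)) stop("embedding family requires a fitted model",
                                 call. = FALSE)
    desc <- vapply(records, function(r) {
      if (is_missing_text(r$detailed_description)) "" else r$detailed_description
    }, character(1))
    blocks$embedding <- suppressMessages(
      infer_doc_matrix(emb_model, desc, epochs = infer_epochs))
  }
  out <- do.call(cbind, blocks[FEATURE_FAMILIES[FEATURE_FAMILIES %in% names(blocks)]])
  stopifnot(!anyNA(out))
  out
}

stratified_split <- function(labels, test_fraction, seed) {
  with_seed(seed, {
    test <- integer(0)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      n_test <- max(1L, round(length(idx) * test_fraction))
      test <- c(test, sample(idx, n_test))
    }
    sort(test)
  })
}

#' Run a full termination-prediction experiment
#'
#' For each repetition: draw a stratified holdout split, fit the keyword
#' vocabulary and embedding model according to the leakage mode, assemble
#' train and test matrices, and train every requested learner both as a
#' single no-sampling model and as a random-undersampling ensemble.
#' Metrics are computed on the held-out split; ensembles are compared to
#' their single counterparts with the corrected resampled t-test across
#' repetitions.
#'
#' @param config an [experiment_config()].
#' @return An `experiment_report`: `results` (one row per repetition x
#'   learner x model type), `summary` (means over repetitions),
#'   `comparisons` (corrected resampled t-tests, ensemble minus single, per
#'   learner and metric), `feature_columns` and the `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  records <- config$records
  labels <- config$labels
  n <- length(records)
  rows <- list()
  feature_columns <- NULL

  for (rep in seq_len(config$repetitions)) {
    rep_seed <- config$seed + rep
    test_idx <- stratified_split(labels, config$test_fraction, rep_seed)
    train_idx <- setdiff(seq_len(n), test_idx)
    fit_idx <- if (config$leakage_mode == "all") seq_len(n) else train_idx

    kw_vocab <- NULL
    if ("keyword" %in% config$families) {
      tok <- lapply(records[fit_idx], function(r) tokenize_keywords(r$keywords_field))
      kw_vocab <- fit_keyword_vocabulary(tok, config$keyword_max_terms)
    }
    emb_model <- NULL
    if ("embedding" %in% config$families) {
      desc <- vapply(records[fit_idx], function(r) {
        if (is_missing_text(r$detailed_description)) "" else r$detailed_description
      }, character(1))
      emb <- config$embedding
      emb_model <- fit_doc_embedding(desc, d = emb$d, seed = rep_seed,
                                     window = emb$window,
                                     min_count = emb$min_count,
                                     epochs = emb$epochs,
                                     negative = emb$negative)
    }
    X <- assemble_features(records, config$families, kw_vocab, emb_model,
                           infer_epochs = config$embedding$infer_epochs)
    feature_columns <- colnames(X)
    Xtr <- X[train_idx, , drop = FALSE]
    Xte <- X[test_idx, , drop = FALSE]
    ytr <- labels[train_idx]
    yte <- labels[test_idx]

    for (learner in config$learners) {
      params <- config$learner_params[[learner]] %||% list()
      single <- fit_base(Xtr, ytr, learner, seed = rep_seed, params = params)
      ens <- fit_ensemble(Xtr, ytr, learner, rounds = config$rounds,
                          seed = rep_seed, params = params)
      for (kind in c("single", "ensemble")) {
        scores <- if (kind == "single") predict_base(single, Xte) else
          ensemble_score(ens, Xte)
        m <- compute_metrics(yte, scores, config$threshold)
        rows[[length(rows) + 1]] <- data.frame(
          repetition = rep, learner = learner, model = kind,
          accuracy = m$accuracy, balanced_accuracy = m$balanced_accuracy,
          f1 = m$f1, auc = m$auc, stringsAsFactors = FALSE)
      }
    }
  }

  results <- do.call(rbind, rows)
  metrics <- c("accuracy", "balanced_accuracy", "f1", "auc")
  summary <- stats::aggregate(results[metrics],
                              by = results[c("learner", "model")], FUN = mean)

  comparisons <- list()
  if (config$repetitions >= 2) {
    n_test <- length(stratified_split(labels, config$test_fraction,
                                      config$seed + 1))
    n_train <- n - n_test
    for (learner in config$learners) {
      for (metric in metrics) {
        e <- results[results$learner == learner & results$model == "ensemble",
                     metric]
        s <- results[results$learner == learner & results$model == "single",
                     metric]
        tt <- corrected_resampled_ttest(e - s, n_train, n_test)
        comparisons[[length(comparisons) + 1]] <- data.frame(
          learner = learner, metric = metric, mean_diff = mean(e - s),
          t = tt$t, p = tt$p, stringsAsFactors = FALSE)
      }
    }
    comparisons <- do.call(rbind, comparisons)
    comparisons$p_holm <- holm_bonferroni(comparisons$p)
  }

  structure(list(results = results, summary = summary,
                 comparisons = comparisons,
                 feature_columns = feature_columns, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Termination-prediction experiment:",
      length(x$config$records), "trials,",
      length(x$feature_columns), "features,",
      x$config$repetitions, "repetitions\n")
  cat("Feature families:", paste(x$config$families, collapse = ", "), "\n\n")
  cat("Mean metrics over repetitions (percent):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (is.data.frame(x$comparisons)) {
    cat("\nEnsemble vs single (corrected resampled t-test):\n")
    print(x$comparisons, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
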