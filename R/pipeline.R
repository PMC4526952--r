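# End-to-end driver: simulate -> analytics -> rater adjudication ->
# features -> semi-supervised training -> cross-validation -> corpus-wide
# classification -> threshold retrieval, with every artifact written as CSV
# or JSON under one output directory and every stochastic stage seeded from
# one global seed.

#' Configuration for the end-to-end pipeline
#'
#' Desk-scale defaults: a 20-day synthetic stream with one five-fold spike,
#' three simulated raters, a reduced vocabulary and a small network so a
#' full run (and its byte-identical repeat) completes in minutes.
#'
#' @param generator a [generator_config()] for the corpus.
#' @param n_raters simulated raters (default 3).
#' @param rater_agreement per-rater probability of reporting the true
#'   category (default 0.8).
#' @param n_sample_for_labeling tweets sampled for manual-style rating.
#' @param n_unlabeled tweets sampled as unlabeled pretraining examples.
#' @param hidden_sizes hidden layer sizes (default c(60, 60, 30)).
#' @param pretrain a [pretrain_config()].
#' @param finetune a [finetune_config()].
#' @param per_class_top,overall_top vocabulary construction caps.
#' @param cv_k cross-validation folds (default 10).
#' @param retrieve_category,retrieve_thresholds retrieval report settings.
#' @param seed global seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(
                              n_days = 20L, base_rate = 60,
                              spike_days = data.frame(day = 10L, multiplier = 5)),
                            n_raters = 3L, rater_agreement = 0.8,
                            n_sample_for_labeling = 400L,
                            n_unlabeled = 2000L,
                            hidden_sizes = c(60L, 60L, 30L),
                            pretrain = pretrain_config(epochs_per_layer = 2L),
                            finetune = finetune_config(epochs = 5L),
                            per_class_top = 20L, overall_top = 300L,
                            cv_k = 10L,
                            retrieve_category = "Misuse",
                            retrieve_thresholds = seq(0.3, 0.8, by = 0.1),
                            seed = 1L) {
  structure(list(generator = generator, n_raters = n_raters,
                 rater_agreement = rater_agreement,
                 n_sample_for_labeling = n_sample_for_labeling,
                 n_unlabeled = n_unlabeled, hidden_sizes = hidden_sizes,
                 pretrain = pretrain, finetune = finetune,
                 per_class_top = per_class_top, overall_top = overall_top,
                 cv_k = cv_k, retrieve_category = retrieve_category,
                 retrieve_thresholds = retrieve_thresholds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_report_csv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = TRUE)
}

#' Run the full pipeline and write every report
#'
#' Executes simulate, analytics, rater adjudication, featurization,
#' semi-supervised training, cross-validation, corpus-wide classification
#' and threshold retrieval. All artifacts land in `out_dir`; a repeat run
#' with the same config produces byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with the in-memory results: `corpus`, `kappa`,
#'   `labeled`, `cv`, `assignments`, `retrieval_counts`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  seed <- cfg$seed
  scheme <- cfg$generator$scheme

  # 1. simulate
  gen <- generate_corpus(cfg$generator)
  store <- gen$store
  write_tweets_jsonl(store, file.path(out_dir, "corpus.jsonl"))
  write_report_csv(gen$truth, out_dir, "truth.csv")

  # 2. corpus analytics
  series <- daily_counts(store)
  write_report_csv(series, out_dir, "daily_counts.csv")
  spikes <- zscore_spikes(series)
  write_report_csv(spikes$days, out_dir, "spikes.csv")
  ht <- hashtag_stats(store)
  write_report_csv(ht$table, out_dir, "hashtags.csv")
  uc <- user_concentration(store)
  write_report_csv(uc$per_user, out_dir, "users.csv")
  rs <- retweet_summary(store)
  write_report_csv(rs$tallies, out_dir, "retweets.csv")

  # 3. simulated raters, kappa, adjudication
  sample_ids <- withr::with_seed(seed + 2L, {
    sample(gen$truth$tweet_id, min(cfg$n_sample_for_labeling, nrow(gen$truth)))
  })
  truth_sample <- gen$truth[match(sort(sample_ids), gen$truth$tweet_id), ]
  votes <- generate_rater_table(truth_sample, cfg$n_raters,
                                cfg$rater_agreement, seed = seed + 3L,
                                scheme = scheme)
  write_report_csv(votes, out_dir, "votes.csv")
  kappa <- fleiss_kappa(votes, scheme)
  adj <- adjudicate(votes, scheme = scheme)
  write_report_csv(adj$labels, out_dir, "labels.csv")
  write_report_csv(tibble::tibble(tweet_id = adj$dropped), out_dir, "dropped.csv")

  # 4. features
  lab_idx <- match(adj$labels$tweet_id, store$id)
  vocab <- build_vocabulary(store$text[lab_idx], adj$labels$category,
                            store$text, scheme = scheme,
                            per_class_top = cfg$per_class_top,
                            overall_top = cfg$overall_top)
  fspec <- feature_spec(vocab)
  write_feature_spec(fspec, file.path(out_dir, "feature_spec.json"))
  X_lab <- featurize_tweets(store[lab_idx, ], fspec)
  unlab_idx <- withr::with_seed(seed + 4L, {
    sort(sample.int(nrow(store), min(cfg$n_unlabeled, nrow(store))))
  })
  X_unlab <- featurize_tweets(store[unlab_idx, ], fspec)

  # 5. pretrain once on unlabeled data; fine-tune a final model on all labels
  sizes <- c(fspec$total_dim, cfg$hidden_sizes, length(scheme))
  pre_cfg <- cfg$pretrain
  pre_cfg$seed <- seed + 5L
  pretrained <- pretrain_dbn(X_unlab, sizes, pre_cfg, scheme)
  fin_cfg <- cfg$finetune
  fin_cfg$seed <- seed + 6L
  final_model <- finetune_dbn(pretrained, X_lab, adj$labels$category, fin_cfg)
  save_dbn(final_model, file.path(out_dir, "model.json"))

  # 6. cross-validation (fine-tune from the shared pretrained weights)
  folds <- stratified_folds(adj$labels$category, k = cfg$cv_k, seed = seed + 7L)
  trainer <- function(X_tr, y_tr) {
    m <- finetune_dbn(pretrained, X_tr, y_tr, fin_cfg)
    function(X_new) predict_scores(m, X_new)
  }
  cv <- cross_validate(X_lab, adj$labels$category, folds, trainer, scheme)
  write_report_csv(cv$per_fold, out_dir, "cv_report.csv")
  write_report_csv(cv$per_class, out_dir, "per_class.csv")
  write_report_csv(as.data.frame.matrix(cv$confusion), out_dir, "confusion.csv")

  # 7. classify the whole corpus
  X_all <- featurize_tweets(store, fspec)
  scores <- predict_scores(final_model, X_all)
  assignments <- assign_categories(scores, scheme)
  scores_df <- tibble::as_tibble(as.data.frame(scores))
  scores_df <- dplyr::bind_cols(tibble::tibble(tweet_id = store$id), scores_df,
                                tibble::tibble(assigned_category = assignments))
  write_report_csv(scores_df, out_dir, "scores.csv")
  write_report_csv(category_frequencies(assignments, scheme), out_dir,
                   "category_freq.csv")

  # 8. threshold retrieval
  retrieval_counts <- tibble::tibble(
    threshold = cfg$retrieve_thresholds,
    n_retrieved = vapply(cfg$retrieve_thresholds, function(t) {
      nrow(retrieve_tweets(scores, cfg$retrieve_category, t, scheme))
    }, numeric(1L))
  )
  write_report_csv(retrieval_counts, out_dir, "retrieval_counts.csv")

  summary <- list(
    seed = seed, n_tweets = nrow(store), kappa = kappa,
    n_labeled = nrow(adj$labels), n_dropped = length(adj$dropped),
    cv_accuracy = cv$accuracy, top2_accuracy = cv$top2_accuracy,
    retweet_fraction = rs$fraction, heavy_user_share = uc$heavy_user_share,
    n_spike_days = nrow(spikes$flagged)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(corpus = gen, kappa = kappa, labeled = adj, cv = cv,
                 assignments = assignments,
                 retrieval_counts = retrieval_counts))
}
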