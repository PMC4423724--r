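# Comparison methods: majority-class under-sampling, inverse-frequency class
# weighting, and traditional self-training (no significance querying).

#' Under-sample the majority class
#'
#' Keeps every non-majority instance and a uniform random sample of the
#' majority class so that the non-majority:majority count ratio equals
#' `ratio` (e.g. `ratio = 1/4` keeps four majority instances per positive).
#' Surviving rows are unchanged and keep their original order.
#'
#' @param ds labeled [svm_dataset].
#' @param ratio fraction in (0, 1]: (non-majority total) : (majority kept).
#' @param majority_class majority class name (default `"Negative"`).
#' @param seed integer seed.
#' @return The under-sampled [svm_dataset].
#' @examples
#' fx <- edge_detection_fixture(scale = 0.001, seed = 1)
#' class_counts(undersample(fx$train, 1 / 4, seed = 1))
#' @export
undersample <- function(ds, ratio, majority_class = "Negative", seed = 0L) {
  if (!is_labeled(ds)) stopf("undersample() needs a labeled dataset")
  if (ratio <= 0 || ratio > 1) stopf("ratio must be in (0, 1]")
  maj_code <- ds$label_map$code[match(majority_class, ds$label_map$name)]
  if (is.na(maj_code)) stopf("majority class '%s' not in label map", majority_class)
  maj_idx <- which(ds$labels == maj_code)
  other_idx <- which(ds$labels != maj_code)
  n_keep <- min(length(maj_idx), as.integer(round(length(other_idx) / ratio)))
  kept <- with_seed(seed, sample(maj_idx, n_keep))
  ds[sort(c(other_idx, kept))]
}

#' Inverse-frequency class weights
#'
#' `weight_c = N_total / (n_classes * count_c)`: each class's weight is
#' inversely proportional to its frequency, normalized so the average
#' instance keeps unit weight (minority classes receive larger weights).
#' Scale-invariant in the counts.
#'
#' @param counts named non-negative integer vector of per-class counts
#'   (e.g. from [class_counts()]); all counts must be >= 1.
#' @return Named numeric vector of weights, suitable for
#'   [train_ovr()]'s `class_weights`.
#' @examples
#' inverse_frequency_weights(c(A = 10, B = 90))
#' @export
inverse_frequency_weights <- function(counts) {
  if (any(counts < 1)) stopf("all class counts must be >= 1")
  w <- sum(counts) / (length(counts) * counts)
  stats::setNames(as.numeric(w), names(counts))
}

#' Traditional self-training
#'
#' The classical self-training loop: each round the current task model labels
#' the entire pool (no significance querying), the confidence filter keeps
#' the confidently labeled subset, the training set grows and the model is
#' retrained. Shares the selection strategies, stopping rules and history
#' format with [run_stss()], so a comparison between the two isolates the
#' significance-querying step.
#'
#' @param train labeled [svm_dataset].
#' @param pool [svm_dataset] (unlabeled for the usual self-labeling setting).
#' @param config an [stss_config()].
#' @param dev optional labeled dev set tracked per iteration.
#' @param model optional starting [ovr_model][train_ovr].
#' @return An `stss_history` with `method = "self_train"`.
#' @export
self_train <- function(train, pool, config, dev = NULL, model = NULL) {
  with_seed(config$seed, {
    svm1 <- model %||% train_ovr(train, C = config$C1, seed = config$seed,
                                 sv_tolerance = config$sv_tolerance)
    history <- new_history(config, method = "self_train")
    history <- record_iteration(history, svm1, train, pool, dev,
                                stats = NULL, iteration = 0L)
    empty_streak <- 0L
    it <- 0L
    while (it < config$max_iter && nrow(pool$features) > 0L) {
      it <- it + 1L
      U <- seq_len(nrow(pool$features))
      lab <- pool_labels_for(svm1, pool, U, config$mode)
      keep <- confidence_filter(U, lab$confidences, config$strategy)
      stats <- list(n_significant = NA_integer_, n_queried = length(U),
                    n_selected = length(keep),
                    added_per_class = integer(0),
                    pool_remaining = nrow(pool$features))
      if (length(keep)) {
        keep_lab <- lab$labels[match(keep, U)]
        added <- svm_dataset(pool$features[keep, , drop = FALSE],
                             labels = keep_lab, label_map = train$label_map)
        cc <- table(factor(keep_lab, levels = train$label_map$code))
        stats$added_per_class <- stats::setNames(as.integer(cc), train$label_map$name)
        train <- dataset_bind(train, added)
        if (config$remove_selected_from_pool) {
          pool <- pool[setdiff(U, keep)]
        }
        stats$pool_remaining <- nrow(pool$features)
        svm1 <- retrain_like(svm1, train, config)
      }
      history <- record_iteration(history, svm1, train, pool, dev,
                                  stats = stats, iteration = it)
      log_round(it, stats)
      if (length(keep) == 0L) {
        # with a deterministic strategy and nothing changed, the next round
        # is provably identical -- stop now; random draws get a second try
        if (config$strategy$kind != "random") break
        empty_streak <- empty_streak + 1L
        if (empty_streak >= 2L) break
      } else {
        empty_streak <- 0L
      }
    }
    history$final_train <- train
    history$final_pool <- pool
    history
  })
}
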