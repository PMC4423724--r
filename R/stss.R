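# The STSS round: significance-set construction, significance-model training,
# pool querying, confidence filtering, augmentation — and the iterated loop.
#
# One round, given a task model (SVM_1) and a pool:
#   1. relabel the training set: support vectors -> significant (1), rest -> 0;
#   2. train the significance model (SVM_2) on that binary view;
#   3. query the pool for instances SVM_2 classifies significant (the set U);
#   4. label U: true pool labels (labeled-pool mode, Phase I) or SVM_1
#      predictions (self-label mode, Phase II);
#   5. keep the confidently labeled subset L_c per the selection strategy;
#   6. augment the training set with L_c and retrain SVM_1.

#' Selection strategy for confidence filtering
#'
#' The four instance-selection rules applied to the queried significant set:
#' keep the `k` highest-confidence examples (`top_k`); keep the top fraction
#' `p` (`top_pct`, a flexible threshold — the count tracks the current pool);
#' keep everything with confidence at or above `tau` (`threshold`); or keep
#' `k` uniformly random examples (`random`).
#'
#' @param kind one of `"top_k"`, `"top_pct"`, `"threshold"`, `"random"`.
#' @param k positive count (`top_k`, `random`).
#' @param p fraction in (0, 1] (`top_pct`); the selected count is
#'   `ceiling(p * n)`, so a non-empty candidate set always yields a selection.
#' @param tau confidence threshold in \[0, 1\] (`threshold`).
#' @return An object of class `selection_strategy`.
#' @export
selection_strategy <- function(kind = c("top_pct", "top_k", "threshold", "random"),
                               k = NULL, p = NULL, tau = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    top_k = {
      if (is.null(k) || k < 1) stopf("top_k needs k >= 1")
      if (!is.null(p) || !is.null(tau)) stopf("top_k takes only k")
    },
    top_pct = {
      p <- p %||% 0.10
      if (p <= 0 || p > 1) stopf("top_pct needs p in (0, 1]")
      if (!is.null(k) || !is.null(tau)) stopf("top_pct takes only p")
    },
    threshold = {
      if (is.null(tau) || tau < 0 || tau > 1) stopf("threshold needs tau in [0, 1]")
      if (!is.null(k) || !is.null(p)) stopf("threshold takes only tau")
    },
    random = {
      if (is.null(k) || k < 1) stopf("random needs k >= 1")
      if (!is.null(p) || !is.null(tau)) stopf("random takes only k")
    })
  structure(list(kind = kind, k = if (!is.null(k)) as.integer(k), p = p, tau = tau),
            class = "selection_strategy")
}

#' @exportS3Method base::print
print.selection_strategy <- function(x, ...) {
  par <- switch(x$kind, top_k = sprintf("k = %d", x$k),
                top_pct = sprintf("p = %g", x$p),
                threshold = sprintf("tau = %g", x$tau),
                random = sprintf("k = %d", x$k))
  cat(sprintf("<selection strategy: %s (%s)>\n", x$kind, par))
  invisible(x)
}

#' STSS configuration
#'
#' @param C1,C2 regularization strengths of the task model (SVM_1) and the
#'   significance model (SVM_2).
#' @param sv_tolerance margin slack for support-vector identification.
#' @param strategy a [selection_strategy()]; default: top 10 percent.
#' @param max_iter maximum number of STSS rounds (>= 0).
#' @param mode `"labeled_pool"` (pool instances carry true labels — Phase I)
#'   or `"self_label"` (the task model labels them — Phase II).
#' @param remove_selected_from_pool consume selected instances (default TRUE).
#' @param majority_class name of the designated majority class balanced
#'   against in Phase I (default `"Negative"`).
#' @param seed master seed for all randomness.
#' @return An object of class `stss_config`.
#' @export
stss_config <- function(C1 = 1, C2 = 1, sv_tolerance = 1e-3,
                        strategy = selection_strategy("top_pct", p = 0.10),
                        max_iter = 10L,
                        mode = c("self_label", "labeled_pool"),
                        remove_selected_from_pool = TRUE,
                        majority_class = "Negative",
                        seed = 0L) {
  mode <- match.arg(mode)
  if (C1 <= 0 || C2 <= 0) stopf("C1 and C2 must be positive")
  if (max_iter < 0) stopf("max_iter must be >= 0")
  stopifnot(inherits(strategy, "selection_strategy"))
  structure(list(C1 = C1, C2 = C2, sv_tolerance = sv_tolerance,
                 strategy = strategy, max_iter = as.integer(max_iter),
                 mode = mode,
                 remove_selected_from_pool = isTRUE(remove_selected_from_pool),
                 majority_class = majority_class, seed = as.integer(seed)),
            class = "stss_config")
}

#' Build the significance training set
#'
#' Relabels the training data into the binary significance view: instances in
#' the model's support-vector set get significance label 1, all others 0.
#' Original class labels are untouched.
#'
#' @param train labeled [svm_dataset].
#' @param model the task model: an [ovr_model][train_ovr] (the union of
#'   per-class SV sets is used) or a single binary component.
#' @return An object of class `significance_set`: the source dataset plus a
#'   0/1 `significant` vector.
#' @export
build_significance_set <- function(train, model) {
  sv <- if (inherits(model, "ovr_model")) {
    support_union(model, train)
  } else {
    support_indices(model, train)
  }
  sig <- integer(nrow(train$features))
  sig[sv] <- 1L
  structure(list(source = train, significant = sig), class = "significance_set")
}

#' @exportS3Method base::print
print.significance_set <- function(x, ...) {
  cat(sprintf("<significance set: %d instances, %d significant / %d non-significant>\n",
              length(x$significant), sum(x$significant), sum(!x$significant)))
  invisible(x)
}

#' Train the significance model
#'
#' A binary linear SVM separating significant (support-vector) from
#' non-significant training examples, with Platt calibration.
#'
#' @param S a [build_significance_set()] result.
#' @param C2 regularization strength.
#' @param solver_tolerance libsvm termination tolerance.
#' @return A binary linear model whose positive class is "significant".
#' @export
train_significance_model <- function(S, C2 = 1, solver_tolerance = 1e-3) {
  n1 <- sum(S$significant == 1L)
  n0 <- sum(S$significant == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop(errorCondition(
      sprintf(paste0("degenerate significance set: %d significant, %d ",
                     "non-significant (the significance model needs both)"),
              n1, n0),
      class = c("stss_degenerate_significance", "error")))
  }
  fit_binary_linear(S$source$features, S$significant == 1L, C = C2,
                    solver_tolerance = solver_tolerance, pos_code = 1L)
}

#' Query the significant subset of a pool
#'
#' @param svm2 the significance model ([train_significance_model()]).
#' @param pool an [svm_dataset] (labeled or not).
#' @return Integer indices of pool instances classified significant
#'   (decision value > 0). Empty pool gives an empty set.
#' @export
query_significant <- function(svm2, pool) {
  X <- as_feature_matrix(pool)
  if (nrow(X) == 0L) return(integer(0))
  which(binary_decision(svm2, X) > 0)
}

#' Confidence-based instance filtering
#'
#' Applies a [selection_strategy()] to candidate indices with one confidence
#' score each. Ranking ties are broken in favor of the lower candidate index.
#'
#' @param candidates integer candidate indices (e.g. the queried set U).
#' @param confidences numeric vector in (0, 1), one per candidate.
#' @param strategy a [selection_strategy()].
#' @return The accepted subset of `candidates` (the set L_c), in index order.
#' @export
confidence_filter <- function(candidates, confidences, strategy) {
  stopifnot(inherits(strategy, "selection_strategy"))
  n <- length(candidates)
  if (length(confidences) != n) {
    stopf("need one confidence per candidate (%d vs %d)", length(confidences), n)
  }
  if (n == 0L) return(integer(0))
  take_top <- function(k) {
    k <- min(k, n)
    if (k == 0L) return(integer(0))
    ord <- order(-confidences, candidates)
    sort(candidates[ord[seq_len(k)]])
  }
  switch(strategy$kind,
    top_k = take_top(strategy$k),
    top_pct = take_top(as.integer(ceiling(strategy$p * n))),
    threshold = candidates[confidences >= strategy$tau],
    random = sort(candidates[sample.int(n, min(strategy$k, n))])
  )
}

#' Constant significance model
#'
#' A degenerate significance model classifying every instance as significant
#' (or none, with `significant = FALSE`). With the all-significant stub, the
#' STSS loop reduces exactly to traditional self-training; useful for
#' controlled comparisons.
#'
#' @param n_features feature-space width.
#' @param significant direction of the constant decision.
#' @return A binary linear model with zero weights and bias +1 / -1.
#' @export
constant_significance_model <- function(n_features, significant = TRUE) {
  structure(
    list(weights = numeric(n_features), bias = if (significant) 1 else -1,
         calibration = c(A = -1, B = 0), C = 1,
         class_weight_pos = 1, class_weight_neg = 1,
         sv_tolerance = 1e-3, pos_code = 1L,
         n_features = as.integer(n_features)),
    class = "binary_linear_model"
  )
}

# Labels used when augmenting: truth in labeled_pool mode, model predictions
# (restricted to the queried indices) in self_label mode.
pool_labels_for <- function(svm1, pool, idx, mode) {
  if (mode == "labeled_pool") {
    if (!is_labeled(pool)) {
      stopf("labeled_pool mode needs a pool with true labels")
    }
    list(labels = pool$labels[idx],
         confidences = predict_with_confidence(svm1, pool$features[idx, , drop = FALSE])$confidences)
  } else {
    pr <- predict_with_confidence(svm1, pool$features[idx, , drop = FALSE])
    list(labels = pr$labels, confidences = pr$confidences)
  }
}

#' One STSS round
#'
#' Executes the full round (see the package vignette): significance set from
#' the current task model, significance model, pool query, labeling,
#' confidence filtering, augmentation, retraining. If the query comes back
#' empty the inputs are returned unchanged with `stats$n_queried = 0`.
#'
#' @param train labeled [svm_dataset].
#' @param pool [svm_dataset]; must carry labels in labeled-pool mode.
#' @param svm1 the current task [ovr_model][train_ovr].
#' @param config an [stss_config()].
#' @param sig_model optional pre-built significance model, overriding the
#'   round's own construction (used for controlled comparisons).
#' @param sig_set optional pre-built significance set for this round,
#'   overriding [build_significance_set()] (used when the task model's
#'   support vectors are defined with respect to data other than `train`,
#'   e.g. the assembled Phase-I model whose components were fitted on
#'   per-class subsets).
#' @return List with `train`, `pool`, `model` (the retrained task model) and
#'   `stats` (`n_significant`, `n_queried`, `n_selected`, `added_per_class`,
#'   `pool_remaining`).
#' @export
stss_round <- function(train, pool, svm1, config, sig_model = NULL,
                       sig_set = NULL) {
  if (ncol(train$features) != ncol(pool$features)) {
    stopf("train and pool widths differ")
  }
  S <- sig_set %||% build_significance_set(train, svm1)
  svm2 <- sig_model %||% train_significance_model(S, C2 = config$C2)
  U <- query_significant(svm2, pool)
  stats <- list(n_significant = sum(S$significant), n_queried = length(U),
                n_selected = 0L, added_per_class = integer(0),
                pool_remaining = nrow(pool$features),
                queried_idx = U, selected_idx = integer(0))
  if (length(U) == 0L) {
    return(list(train = train, pool = pool, model = svm1, stats = stats))
  }
  lab <- pool_labels_for(svm1, pool, U, config$mode)
  keep <- confidence_filter(U, lab$confidences, config$strategy)
  stats$n_selected <- length(keep)
  stats$selected_idx <- keep
  if (length(keep) == 0L) {
    return(list(train = train, pool = pool, model = svm1, stats = stats))
  }
  keep_lab <- lab$labels[match(keep, U)]
  added <- svm_dataset(pool$features[keep, , drop = FALSE], labels = keep_lab,
                       label_map = train$label_map,
                       instance_ids = if (!is.null(pool$instance_ids)) pool$instance_ids[keep])
  cc <- table(factor(keep_lab, levels = train$label_map$code))
  stats$added_per_class <- stats::setNames(as.integer(cc), train$label_map$name)
  train2 <- dataset_bind(train, added)
  pool2 <- if (config$remove_selected_from_pool) {
    pool[setdiff(seq_len(nrow(pool$features)), keep)]
  } else {
    pool
  }
  stats$pool_remaining <- nrow(pool2$features)
  svm1b <- retrain_like(svm1, train2, config)
  list(train = train2, pool = pool2, model = svm1b, stats = stats)
}

# Retrain the task model on an augmented training set, preserving its
# structural settings (C, fallback class, tolerances).
retrain_like <- function(svm1, train, config) {
  train_ovr(train, C = config$C1, sv_tolerance = config$sv_tolerance,
            seed = config$seed, default_class = svm1$default_class)
}

#' Run the STSS loop
#'
#' Iterates [stss_round()] starting from a task model trained on `train`
#' (or from `model` if supplied) until `max_iter` rounds are done, the pool is
#' exhausted, or the selection comes back empty twice in a row. Every
#' intermediate task model is stored.
#'
#' @param train labeled [svm_dataset].
#' @param pool [svm_dataset] (labeled in labeled-pool mode).
#' @param config an [stss_config()].
#' @param dev optional labeled [svm_dataset]; per-iteration macro-averaged
#'   metrics on it are recorded in the history.
#' @param model optional starting [ovr_model][train_ovr]; default is a fresh
#'   fit on `train`.
#' @param sig_model optional fixed significance model passed to every round
#'   (see [stss_round()]).
#' @param initial_sig optional significance set used for the first round only
#'   (see [stss_round()]'s `sig_set`; later rounds rebuild significance from
#'   the retrained model).
#' @return An object of class `stss_history`; see [print.stss_history()].
#'   Entry `i` describes the state after round `i - 1` (entry 1 is the base
#'   model).
#' @examples
#' fx <- edge_detection_fixture(scale = 0.0005, seed = 1)
#' cfg <- stss_config(max_iter = 2, mode = "self_label", seed = 1)
#' hist <- run_stss(fx$train, fx$pool, cfg)
#' hist
#' @export
run_stss <- function(train, pool, config, dev = NULL, model = NULL,
                     sig_model = NULL, initial_sig = NULL) {
  with_seed(config$seed, {
    svm1 <- model %||% train_ovr(train, C = config$C1, seed = config$seed,
                                 sv_tolerance = config$sv_tolerance)
    history <- new_history(config)
    history <- record_iteration(history, svm1, train, pool, dev,
                                stats = NULL, iteration = 0L)
    empty_streak <- 0L
    it <- 0L
    while (it < config$max_iter && nrow(pool$features) > 0L) {
      it <- it + 1L
      step <- tryCatch(
        stss_round(train, pool, svm1, config, sig_model = sig_model,
                   sig_set = if (it == 1L) initial_sig),
        stss_degenerate_significance = function(e) {
          stss_log("warn", "stopping: ", conditionMessage(e))
          NULL
        })
      if (is.null(step)) break
      train <- step$train; pool <- step$pool; svm1 <- step$model
      history <- record_iteration(history, svm1, train, pool, dev,
                                  stats = step$stats, iteration = it)
      log_round(it, step$stats)
      if (step$stats$n_selected == 0L) {
        # nothing changed this round: with a deterministic strategy the next
        # round is provably identical, so stop; random draws get a second try
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

# --- history ----------------------------------------------------------------

new_history <- function(config, method = "stss") {
  structure(list(config = config, method = method, iterations = list(),
                 final_train = NULL, final_pool = NULL),
            class = "stss_history")
}

record_iteration <- function(history, model, train, pool, dev, stats, iteration) {
  dev_metrics <- if (!is.null(dev)) {
    pr <- predict_with_confidence(model, dev)
    per_class_prf(dev$labels, pr$labels, classes = dev$label_map)
  }
  history$iterations[[length(history$iterations) + 1L]] <-
    list(iteration = iteration, model = model,
         train_size = nrow(train$features),
         pool_remaining = nrow(pool$features),
         n_significant = stats$n_significant %||% NA_integer_,
         n_queried = stats$n_queried %||% NA_integer_,
         n_selected = stats$n_selected %||% NA_integer_,
         added_per_class = stats$added_per_class %||% integer(0),
         dev_metrics = dev_metrics)
  history
}

log_round <- function(it, stats) {
  stss_log("info", sprintf(
    "iter=%d significant=%d queried=%d selected=%d pool_remaining=%d added=[%s]",
    it, stats$n_significant, stats$n_queried, stats$n_selected,
    stats$pool_remaining,
    paste(sprintf("%s:%d", names(stats$added_per_class), stats$added_per_class),
          collapse = " ")))
}

#' @exportS3Method base::print
print.stss_history <- function(x, ...) {
  cat(sprintf("<stss_history: %s, %d stored models>\n", x$method,
              length(x$iterations)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' History as a per-iteration data frame
#' @param x an `stss_history`.
#' @param ... ignored.
#' @return data.frame with one row per stored iteration: sizes of the
#'   significance set, query, selection, training set and pool, plus dev-set
#'   macro F when a dev set was supplied.
#' @export
as.data.frame.stss_history <- function(x, ...) {
  rows <- lapply(x$iterations, function(rec) {
    data.frame(iteration = rec$iteration,
               train_size = rec$train_size,
               pool_remaining = rec$pool_remaining,
               n_significant = rec$n_significant,
               n_queried = rec$n_queried,
               n_selected = rec$n_selected,
               dev_macro_f = if (!is.null(rec$dev_metrics)) {
                 macro_f(rec$dev_metrics)
               } else NA_real_)
  })
  do.call(rbind, rows)
}

#' @exportS3Method base::summary
summary.stss_history <- function(object, ...) {
  df <- as.data.frame(object)
  per_iter <- Filter(length, lapply(object$iterations, `[[`, "added_per_class"))
  added <- if (length(per_iter)) Reduce(`+`, per_iter)
  structure(list(table = df, total_added = added, method = object$method),
            class = "summary.stss_history")
}

#' @exportS3Method base::print
print.summary.stss_history <- function(x, ...) {
  cat(sprintf("STSS history (%s): %d iterations\n", x$method, nrow(x$table) - 1L))
  print(x$table, row.names = FALSE)
  if (!is.null(x$total_added)) {
    cat("total added per class:\n")
    print(x$total_added)
  }
  invisible(x)
}

#' Plot the learning trajectory
#'
#' Training-set growth and (when a dev set was tracked) dev-set macro F over
#' iterations.
#'
#' @param x an `stss_history`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stss_history <- function(x, ...) {
  df <- as.data.frame(x)
  has_dev <- any(!is.na(df$dev_macro_f))
  if (has_dev) {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  }
  graphics::plot(df$iteration, df$train_size, type = "b", pch = 19,
                 xlab = "iteration", ylab = "training-set size", ...)
  if (has_dev) {
    graphics::plot(df$iteration, df$dev_macro_f, type = "b", pch = 19,
                   xlab = "iteration", ylab = "dev macro F (%)", ...)
  }
  invisible(x)
}

#' Export a history as machine-readable JSON
#'
#' @param history an `stss_history`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history_json <- function(history, path) {
  recs <- lapply(history$iterations, function(r) {
    list(iteration = r$iteration, train_size = r$train_size,
         pool_remaining = r$pool_remaining,
         n_significant = r$n_significant, n_queried = r$n_queried,
         n_selected = r$n_selected,
         added_per_class = as.list(r$added_per_class),
         dev_macro_f = if (!is.null(r$dev_metrics)) macro_f(r$dev_metrics))
  })
  cfg <- history$config
  obj <- list(method = history$method,
              config = list(C1 = cfg$C1, C2 = cfg$C2, mode = cfg$mode,
                            max_iter = cfg$max_iter, seed = cfg$seed,
                            strategy = cfg$strategy[!vapply(cfg$strategy, is.null, TRUE)]),
              iterations = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
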