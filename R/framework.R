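# The STSS-based two-phase learning framework.
#
# Phase I balances the training data: for every positive class, start from
# all its positives plus an equal number of randomly chosen majority-class
# negatives, then let STSS (labeled-pool mode) iteratively pull informative
# negatives out of the remainder of the training data. Phase II takes the
# resulting model and balanced subsets and exploits a genuinely unlabeled
# pool by self-labeling.

#' Phase I: balance the training data by informative-subset selection
#'
#' For each one-vs-rest subproblem (every class against the designated
#' majority class plus the other classes), the initial training set contains
#' all positive examples and the same number of randomly chosen majority-class
#' negatives; the remaining training instances act as a labeled pool from
#' which STSS iteratively adds informative examples under their true labels.
#' The per-class balanced subsets and the task model assembled from the
#' per-class fits are returned.
#'
#' @param D labeled [svm_dataset] containing the majority class named in
#'   `config$majority_class` and at least one other class.
#' @param config an [stss_config()]; its mode is forced to `"labeled_pool"`.
#' @param init_fraction optional fraction in (0, 1]: stratified subsample of
#'   the per-class labeled pool, bounding Phase-I work on very large training
#'   sets. Default uses the whole remainder.
#' @param seed master seed; per-class subproblems run on seeds derived from it.
#' @return An object of class `phase_one_result`: per-class balanced subsets
#'   (`subsets`, each with `data`, a binary-labeled [svm_dataset], and
#'   `provenance`, row indices into `D`), the multiclass union training set
#'   (`train`, original labels), and the assembled task `model` with the
#'   majority class as fallback.
#' @seealso [phase_two()], [two_phase()]
#' @export
phase_one <- function(D, config, init_fraction = NULL, seed = config$seed) {
  if (!is_labeled(D)) stopf("phase_one() needs a labeled dataset")
  maj_code <- D$label_map$code[match(config$majority_class, D$label_map$name)]
  if (is.na(maj_code) || !any(D$labels == maj_code)) {
    stopf("designated majority class '%s' not present", config$majority_class)
  }
  if (!is.null(init_fraction) && (init_fraction <= 0 || init_fraction > 1)) {
    stopf("init_fraction must be in (0, 1]")
  }
  if (is.null(D$instance_ids)) {
    D$instance_ids <- as.character(seq_len(nrow(D$features)))
  }
  pos_codes <- setdiff(sort(unique(D$labels)), maj_code)
  if (!length(pos_codes)) stopf("no positive classes besides the majority class")
  maj_idx <- which(D$labels == maj_code)

  subsets <- vector("list", length(pos_codes))
  components <- vector("list", length(pos_codes))
  names(subsets) <- names(components) <-
    D$label_map$name[match(pos_codes, D$label_map$code)]

  for (k in seq_along(pos_codes)) {
    code <- pos_codes[[k]]
    cls_name <- names(subsets)[[k]]
    sub_seed <- derive_seed(seed, k)
    pos_idx <- which(D$labels == code)
    n_init <- min(length(pos_idx), length(maj_idx))
    neg_init <- with_seed(sub_seed, sort(sample(maj_idx, n_init)))
    init_idx <- c(pos_idx, neg_init)
    pool_idx <- setdiff(seq_len(nrow(D$features)), init_idx)
    if (!is.null(init_fraction) && init_fraction < 1 && length(pool_idx)) {
      pool_idx <- with_seed(derive_seed(sub_seed, 1L), {
        sort(sample(pool_idx, max(1L, round(init_fraction * length(pool_idx)))))
      })
    }
    bin_map <- data.frame(code = c(0L, 1L), name = c("rest", cls_name),
                          stringsAsFactors = FALSE)
    binarize <- function(idx) {
      svm_dataset(D$features[idx, , drop = FALSE],
                  labels = as.integer(D$labels[idx] == code),
                  label_map = bin_map,
                  instance_ids = D$instance_ids[idx])
    }
    cfg <- config
    cfg$mode <- "labeled_pool"
    cfg$seed <- sub_seed
    hist <- run_stss(binarize(init_idx), binarize(pool_idx), cfg)
    ds_k <- hist$final_train
    final_model <- hist$iterations[[length(hist$iterations)]]$model
    comp <- final_model$models[["1"]]       # the class-vs-rest component
    sv_local <- support_indices(comp, ds_k)
    comp$pos_code <- code
    components[[k]] <- comp
    subsets[[k]] <- list(data = ds_k,
                         provenance = as.integer(ds_k$instance_ids),
                         sv_provenance = as.integer(ds_k$instance_ids)[sv_local],
                         history = hist)
    stss_log("info", sprintf(
      "phase I [%s]: %d pos, %d -> %d instances in balanced subset",
      cls_name, length(pos_idx), length(init_idx), nrow(ds_k$features)))
  }

  union_idx <- sort(unique(unlist(lapply(subsets, `[[`, "provenance"))))
  train <- D[union_idx]
  # a union row is significant iff it supports the subproblem that trained on
  # it: the components' margins are meaningless on rows they never saw
  sv_idx <- sort(unique(unlist(lapply(subsets, `[[`, "sv_provenance"))))
  train_significant <- as.integer(union_idx %in% sv_idx)
  model <- assemble_ovr(components, D$label_map,
                        meta = list(seed = as.integer(seed), C = config$C1,
                                    weighting = FALSE, phase = 1L),
                        default_class = maj_code)
  structure(list(subsets = subsets, train = train, train_idx = union_idx,
                 train_significant = train_significant,
                 model = model, majority_class = config$majority_class,
                 config = config),
            class = "phase_one_result")
}

#' @exportS3Method base::print
print.phase_one_result <- function(x, ...) {
  cat(sprintf("<phase_one_result: %d per-class balanced subsets, union train %d instances>\n",
              length(x$subsets), nrow(x$train$features)))
  for (nm in names(x$subsets)) {
    cc <- class_counts(x$subsets[[nm]]$data)
    cat(sprintf("  %-12s pos %6d  neg %8d  (1:%d)\n", nm, cc[[nm]], cc[["rest"]],
                imbalance_ratio(cc[[nm]], cc[["rest"]])))
  }
  invisible(x)
}

#' Per-class imbalance summary of a Phase-I result
#'
#' @param object a [phase_one_result][phase_one].
#' @param D the original training [svm_dataset] (for the original ratios).
#' @param ... ignored.
#' @return data.frame with per-class positive / negative counts and
#'   floor-convention imbalance-ratio denominators, before (whole training
#'   set) and after (balanced subset).
#' @exportS3Method base::summary
summary.phase_one_result <- function(object, D = NULL, ...) {
  rows <- lapply(names(object$subsets), function(nm) {
    cc <- class_counts(object$subsets[[nm]]$data)
    n_pos <- cc[[nm]]
    n_neg <- cc[["rest"]]
    orig_pos <- orig_neg <- NA_integer_
    if (!is.null(D)) {
      code <- D$label_map$code[match(nm, D$label_map$name)]
      orig_pos <- sum(D$labels == code)
      orig_neg <- sum(D$labels != code)
    }
    data.frame(class = nm, n_pos = n_pos, n_neg = n_neg,
               ratio = imbalance_ratio(n_pos, n_neg),
               orig_pos = orig_pos, orig_neg = orig_neg,
               orig_ratio = if (!is.na(orig_pos)) imbalance_ratio(orig_pos, orig_neg) else NA_integer_)
  })
  do.call(rbind, rows)
}

#' Phase II: exploit unlabeled data by self-labeling
#'
#' Runs the STSS loop in self-label mode, seeded with the Phase-I model and
#' balanced training data: each round queries the significant subset of the
#' unlabeled pool, lets the task model label it, keeps the confident subset
#' and retrains. Every iteration's model is stored for later evaluation.
#'
#' @param svm1 the Phase-I task [ovr_model][train_ovr] (or any OvR model).
#' @param D_s the balanced training data: a [phase_one_result][phase_one]
#'   (its union training set is used) or a labeled [svm_dataset].
#' @param pool unlabeled [svm_dataset] of matching width.
#' @param config an [stss_config()]; its mode is forced to `"self_label"`.
#' @param dev optional labeled dev set tracked per iteration.
#' @return An `stss_history` (see [run_stss()]).
#' @export
phase_two <- function(svm1, D_s, pool, config, dev = NULL) {
  initial_sig <- NULL
  if (inherits(D_s, "phase_one_result")) {
    train <- D_s$train
    # significance of the assembled model is defined by provenance: each
    # component's SVs among the rows of its own balanced subset
    initial_sig <- structure(
      list(source = train, significant = D_s$train_significant),
      class = "significance_set")
  } else {
    train <- D_s
  }
  if (!is_labeled(train)) stopf("phase_two() needs labeled balanced data")
  cfg <- config
  cfg$mode <- "self_label"
  run_stss(train, pool, cfg, dev = dev, model = svm1, initial_sig = initial_sig)
}

#' The full two-phase framework
#'
#' [phase_one()] followed by [phase_two()]; one master seed governs all
#' randomness in both phases.
#'
#' @param D labeled training [svm_dataset].
#' @param pool unlabeled [svm_dataset].
#' @param config an [stss_config()].
#' @param init_fraction see [phase_one()].
#' @param seed master seed (default `config$seed`).
#' @param dev optional labeled dev set tracked through Phase II.
#' @return List of class `two_phase_result` with `phase1`
#'   (a [phase_one_result][phase_one]) and `history` (Phase-II
#'   `stss_history`).
#' @export
two_phase <- function(D, pool, config, init_fraction = NULL,
                      seed = config$seed, dev = NULL) {
  p1 <- phase_one(D, config, init_fraction = init_fraction, seed = seed)
  cfg <- config
  cfg$seed <- derive_seed(seed, 104729L)
  hist <- phase_two(p1$model, p1, pool, cfg, dev = dev)
  structure(list(phase1 = p1, history = hist), class = "two_phase_result")
}

#' @exportS3Method base::print
print.two_phase_result <- function(x, ...) {
  print(x$phase1)
  print(x$history)
  invisible(x)
}
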