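# Documented desk-scale benchmark studies on the edge-detection-shaped
# synthetic fixture: Phase-I data-efficiency audit and the STSS vs
# traditional self-training comparison. The vignette records the study
# design; these functions are what the acceptance script and the test suite
# run.

#' Phase-I data-efficiency audit
#'
#' Runs Phase I on an edge-detection-shaped fixture and reports, per positive
#' class, the balanced subset's composition against the original training
#' set, together with a row-level soundness check (every balanced-subset
#' instance must be bit-identical to its provenance row in the original data,
#' with the consistent one-vs-rest label).
#'
#' @param fixture an [edge_detection_fixture()] result (or any list with a
#'   labeled `train`).
#' @param config an [stss_config()]; drives the per-class STSS runs.
#' @param seed master seed for Phase I.
#' @return List: `table` (per-class counts and floor-convention imbalance
#'   ratios, original vs balanced, column `reduced` = ratio strictly
#'   decreased), `sound` (all provenance rows match), `result` (the
#'   [phase_one_result][phase_one]).
#' @export
phase_one_audit <- function(fixture, config, seed = config$seed) {
  D <- fixture$train
  p1 <- phase_one(D, config, seed = seed)
  tab <- summary(p1, D)
  tab$reduced <- tab$ratio < tab$orig_ratio
  sound <- TRUE
  for (nm in names(p1$subsets)) {
    sub <- p1$subsets[[nm]]
    code <- D$label_map$code[match(nm, D$label_map$name)]
    prov <- sub$provenance
    same_feat <- identical(
      as(sub$data$features, "CsparseMatrix"),
      as(D$features[prov, , drop = FALSE], "CsparseMatrix"))
    same_lab <- all(sub$data$labels == as.integer(D$labels[prov] == code))
    sound <- sound && same_feat && same_lab
  }
  list(table = tab, sound = sound, result = p1)
}

#' STSS vs traditional self-training on the synthetic benchmark
#'
#' The controlled comparison isolating the significance-querying step, in the
#' second-phase setting: Phase I first balances the fixture's training data
#' (equal-negative seeding plus one round of informative-negative selection),
#' then both semi-supervised learners start from the identical Phase-I model
#' and balanced training set, share the same unlabeled pool, selection
#' strategy, stopping rules and seeds, and differ only in whether the pool is
#' first filtered through the significance model. Each stored model is
#' evaluated on a noise-free dev set drawn from the same generative process
#' (balanced enough that per-class F is measurable); a method's score for the
#' seed is its best dev macro F across stored models.
#'
#' @param scale fixture scale (default 0.01).
#' @param seeds integer vector of fixture seeds (one run per seed).
#' @param max_iter Phase-II rounds per method (default 1; each round retrains
#'   the full one-vs-rest model, the dominant cost at this scale).
#' @param strategy shared [selection_strategy()]; default is the top-percent
#'   rule with p = 0.10, the flexible-threshold strategy the method favors.
#' @param pool_size unlabeled-pool size drawn from the fixture's generative
#'   process.
#' @param phase1_max_iter,phase1_k Phase-I rounds and per-round cap on added
#'   informative negatives.
#' @param dev_pos,dev_neg dev-set instances per positive class / for the
#'   majority class.
#' @return data.frame with one row per (seed, method): best dev macro F (%),
#'   final training-set size, iterations run.
#' @export
stss_selftrain_benchmark <- function(scale = 0.01, seeds = 1:5, max_iter = 1L,
                                     strategy = selection_strategy("top_pct", p = 0.10),
                                     pool_size = 4000L,
                                     phase1_max_iter = 1L, phase1_k = 100L,
                                     dev_pos = 50L, dev_neg = 500L) {
  rows <- list()
  for (seed in seeds) {
    fx <- edge_detection_fixture(scale, seed = seed, pool_size = pool_size)
    dev <- benchmark_dev_set(fx$spec, dev_pos, dev_neg, seed = derive_seed(seed, 12L))
    p1_cfg <- stss_config(strategy = selection_strategy("top_k", k = phase1_k),
                          max_iter = phase1_max_iter, seed = derive_seed(seed, 11L))
    p1 <- phase_one(fx$train, p1_cfg)
    cfg <- stss_config(strategy = strategy, max_iter = max_iter,
                       mode = "self_label", seed = derive_seed(seed, 13L))
    for (method in c("stss", "self_train")) {
      hist <- if (method == "stss") {
        phase_two(p1$model, p1, fx$pool, cfg, dev = dev)
      } else {
        self_train(p1$train, fx$pool, cfg, dev = dev, model = p1$model)
      }
      fs <- vapply(hist$iterations, function(r) macro_f(r$dev_metrics), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, method = method, macro_f = max(fs),
        final_train_size = nrow(hist$final_train$features),
        iterations = length(hist$iterations) - 1L)
    }
  }
  do.call(rbind, rows)
}

# Dev set drawn from the fixture's generative process, noise-free and with
# per-class counts large enough for stable per-class F; evaluated against
# generative labels.
benchmark_dev_set <- function(spec, dev_pos, dev_neg, seed) {
  counts <- spec$class_counts
  maj <- which(names(counts) == "Negative")
  counts[] <- dev_pos
  counts[maj] <- dev_neg
  dev_spec <- synthetic_spec(counts, n_features = spec$n_features,
                             informative_per_class = spec$informative_per_class,
                             feature_density = spec$feature_density,
                             separation = spec$separation,
                             flip_noise = 0, seed = seed)
  generate_dataset(dev_spec)$dataset
}
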