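toy_setup <- function(seed = 1, flip = 0, n_pool = 150, sep = 0.5) {
  spec <- toy_spec(seed = seed, flip = flip, sep = sep)
  g <- generate_dataset(spec)
  pl <- generate_pool(spec, n_pool)
  list(train = g$dataset, truth = g$truth, pool = pl$pool,
       pool_labels = pl$hidden_labels, spec = spec)
}

test_that("significance relabeling preserves size and counts the SV union", {
  s <- toy_setup(seed = 1)
  m <- train_ovr(s$train)
  S <- build_significance_set(s$train, m)
  expect_length(S$significant, nrow(s$train$features))
  expect_equal(sum(S$significant), length(support_union(m, s$train)))
  expect_identical(S$source$labels, s$train$labels)

  # idempotence: retraining on the same data rebuilds the same set
  S2 <- build_significance_set(s$train, train_ovr(s$train))
  expect_identical(S2$significant, S$significant)

  # single binary component: significance = that component's SV set
  comp <- m$models[[1]]
  Sb <- build_significance_set(s$train, comp)
  expect_equal(which(Sb$significant == 1L), support_indices(comp, s$train))
})

test_that("the significance model separates constructed significance geometry", {
  # significant examples clustered away from non-significant ones
  set.seed(42)
  X <- rbind(matrix(rnorm(40 * 5, mean = 3), 40, 5),
             matrix(rnorm(60 * 5, mean = -3), 60, 5))
  src <- svm_dataset(X, labels = rep(c(1L, 2L), c(40, 60)))
  S <- structure(list(source = src, significant = rep(c(1L, 0L), c(40, 60))),
                 class = "significance_set")
  svm2 <- train_significance_model(S, C2 = 1)
  pred_sig <- as.integer(stss:::binary_decision(svm2, src$features) > 0)
  expect_gte(mean(pred_sig == S$significant), 0.9)
})

test_that("swapping significance labels negates the decision function", {
  set.seed(43)
  X <- matrix(rnorm(30 * 4), 30, 4)
  src <- svm_dataset(X, labels = rep(1:2, 15))
  sig <- as.integer(X[, 1] + 0.3 * rnorm(30) > 0)
  if (sum(sig) %in% c(0L, 30L)) sig[1] <- 1L - sig[1]
  S <- structure(list(source = src, significant = sig), class = "significance_set")
  Sflip <- structure(list(source = src, significant = 1L - sig),
                     class = "significance_set")
  d1 <- stss:::binary_decision(train_significance_model(S), src$features)
  d2 <- stss:::binary_decision(train_significance_model(Sflip), src$features)
  expect_equal(d1, -d2, tolerance = 1e-2)
})

test_that("degenerate significance sets raise the classed error", {
  src <- svm_dataset(matrix(rnorm(20), 10, 2), labels = rep(1:2, 5))
  S_all <- structure(list(source = src, significant = rep(1L, 10)),
                     class = "significance_set")
  err <- tryCatch(train_significance_model(S_all), error = identity)
  expect_s3_class(err, "stss_degenerate_significance")
  expect_match(conditionMessage(err), "10 significant, 0 non-significant")
})

test_that("query_significant partitions the pool and finds planted points", {
  s <- toy_setup(seed = 2)
  m <- train_ovr(s$train)
  S <- build_significance_set(s$train, m)
  svm2 <- train_significance_model(S)

  empty <- svm_dataset(Matrix::Matrix(0, 0, ncol(s$train$features), sparse = TRUE))
  expect_identical(query_significant(svm2, empty), integer(0))

  U <- query_significant(svm2, s$pool)
  expect_true(all(U %in% seq_len(nrow(s$pool$features))))
  d <- stss:::binary_decision(svm2, s$pool$features)
  expect_setequal(U, which(d > 0))

  # a pool instance duplicating a deeply significant training instance
  deep <- which.max(stss:::binary_decision(svm2, s$train$features))
  planted <- svm_dataset(rbind(s$pool$features, s$train$features[deep, , drop = FALSE]))
  expect_true(nrow(planted$features) %in% query_significant(svm2, planted))
})

test_that("confidence filtering matches its worked examples", {
  top2 <- selection_strategy("top_k", k = 2)
  expect_equal(confidence_filter(1:3, c(0.9, 0.8, 0.7), top2), c(1L, 2L))
  half <- selection_strategy("top_pct", p = 0.5)
  expect_length(confidence_filter(1:4, c(0.5, 0.9, 0.2, 0.7), half), 2L)
  thr <- selection_strategy("threshold", tau = 0.85)
  expect_equal(confidence_filter(1:3, c(0.9, 0.8, 0.7), thr), 1L)
  # ties break toward the lower candidate index
  expect_equal(confidence_filter(c(10L, 4L, 7L), c(0.5, 0.5, 0.5), top2),
               c(4L, 7L))
  expect_error(selection_strategy("top_k"), "k >= 1")
  expect_error(selection_strategy("threshold", tau = 2), "tau")
  expect_error(selection_strategy("top_pct", p = 0.5, k = 2), "only p")
  expect_error(confidence_filter(1:3, c(0.5, 0.5), top2), "one confidence")
})

test_that("deterministic strategies match the exhaustive reference", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(1:30, 1)
    cand <- sort(sample.int(500, n))
    conf <- round(runif(n), sample(c(1, 2, 6), 1))   # coarse rounding forces ties
    k <- sample.int(35, 1)
    p <- runif(1, 0.05, 1)
    tau <- runif(1)
    expect_identical(
      confidence_filter(cand, conf, selection_strategy("top_k", k = k)),
      ref_filter("top_k", cand, conf, k = k))
    expect_identical(
      confidence_filter(cand, conf, selection_strategy("top_pct", p = p)),
      ref_filter("top_pct", cand, conf, p = p))
    expect_identical(
      confidence_filter(cand, conf, selection_strategy("threshold", tau = tau)),
      ref_filter("threshold", cand, conf, tau = tau))
  }
})

test_that("random selection draws k distinct candidates uniformly-ish", {
  cand <- c(3L, 8L, 11L, 20L)
  conf <- rep(0.5, 4)
  st <- selection_strategy("random", k = 2)
  set.seed(1)
  picks <- replicate(200, confidence_filter(cand, conf, st), simplify = FALSE)
  expect_true(all(vapply(picks, length, integer(1)) == 2L))
  expect_true(all(unlist(picks) %in% cand))
  expect_setequal(unique(unlist(picks)), cand)   # every candidate shows up
  big <- selection_strategy("random", k = 10)
  set.seed(2)
  expect_setequal(confidence_filter(cand, conf, big), cand)
})

test_that("an STSS round is a no-op on an empty pool", {
  s <- toy_setup(seed = 3)
  m <- train_ovr(s$train)
  empty <- svm_dataset(Matrix::Matrix(0, 0, ncol(s$train$features), sparse = TRUE),
                       label_map = s$train$label_map)
  cfg <- stss_config(mode = "self_label", seed = 1)
  out <- stss_round(s$train, empty, m, cfg)
  expect_identical(out$train$labels, s$train$labels)
  expect_equal(out$stats$n_queried, 0L)
  expect_equal(out$stats$n_selected, 0L)
})

test_that("labeled-pool rounds add instances under their true labels", {
  for (seed in 1:3) {
    s <- toy_setup(seed = seed, flip = 0)
    pool_labeled <- svm_dataset(s$pool$features, labels = s$pool_labels,
                                label_map = s$train$label_map)
    m <- train_ovr(s$train)
    cfg <- stss_config(mode = "labeled_pool", seed = seed,
                       strategy = selection_strategy("top_pct", p = 0.2))
    out <- stss_round(s$train, pool_labeled, m, cfg)
    sel <- out$stats$selected_idx
    expect_true(all(sel %in% out$stats$queried_idx))
    expect_true(all(out$stats$queried_idx %in% seq_len(nrow(pool_labeled$features))))
    if (length(sel)) {
      n0 <- nrow(s$train$features)
      added_labels <- out$train$labels[(n0 + 1):nrow(out$train$features)]
      expect_identical(added_labels, pool_labeled$labels[sel])
      expect_equal(nrow(out$train$features), n0 + length(sel))
      expect_identical(out$train$labels[seq_len(n0)], s$train$labels)
    }
  }
})

test_that("self-label rounds respect the containment chain across seeds", {
  for (seed in 1:8) {
    s <- toy_setup(seed = seed, flip = 0.05, n_pool = 80)
    m <- train_ovr(s$train)
    cfg <- stss_config(mode = "self_label", seed = seed)
    out <- stss_round(s$train, s$pool, m, cfg)
    expect_true(all(out$stats$selected_idx %in% out$stats$queried_idx))
    expect_true(all(out$stats$queried_idx %in% seq_len(nrow(s$pool$features))))
    expect_equal(nrow(out$pool$features),
                 nrow(s$pool$features) - out$stats$n_selected)
  }
})

test_that("run_stss: degenerate loop, monotone pool, stored models", {
  s <- toy_setup(seed = 4)
  cfg0 <- stss_config(max_iter = 0, mode = "self_label", seed = 1)
  h0 <- run_stss(s$train, s$pool, cfg0)
  expect_length(h0$iterations, 1L)
  expect_s3_class(h0$iterations[[1]]$model, "ovr_model")

  cfg <- stss_config(max_iter = 4, mode = "self_label", seed = 2)
  h <- run_stss(s$train, s$pool, cfg)
  df <- as.data.frame(h)
  expect_true(all(diff(df$pool_remaining) <= 0))
  expect_true(all(diff(df$train_size) >= 0))
  expect_equal(df$train_size + df$pool_remaining,
               rep(nrow(s$train$features) + nrow(s$pool$features), nrow(df)))
  expect_lte(nrow(df), cfg$max_iter + 1L)
})

test_that("identical seeds give bit-identical histories", {
  s <- toy_setup(seed = 5, flip = 0.05)
  cfg <- stss_config(max_iter = 3, mode = "self_label", seed = 7,
                     strategy = selection_strategy("random", k = 10))
  h1 <- run_stss(s$train, s$pool, cfg)
  h2 <- run_stss(s$train, s$pool, cfg)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  last1 <- h1$iterations[[length(h1$iterations)]]$model
  last2 <- h2$iterations[[length(h2$iterations)]]$model
  for (k in seq_along(last1$models)) {
    expect_identical(last1$models[[k]]$weights, last2$models[[k]]$weights)
  }
  expect_identical(h1$final_train$labels, h2$final_train$labels)
})

test_that("confident self-labels overwhelmingly match the generative class", {
  agree <- total <- 0
  for (seed in 1:10) {
    s <- toy_setup(seed = 100 + seed, flip = 0, n_pool = 120)
    pool <- s$pool
    pool$instance_ids <- as.character(seq_len(nrow(pool$features)))
    train <- s$train
    train$instance_ids <- sprintf("t%d", seq_len(nrow(train$features)))
    cfg <- stss_config(max_iter = 3, mode = "self_label", seed = seed,
                       strategy = selection_strategy("threshold", tau = 0.95))
    h <- run_stss(train, pool, cfg)
    ft <- h$final_train
    added <- which(!startsWith(ft$instance_ids, "t"))
    if (!length(added)) next
    pool_row <- as.integer(ft$instance_ids[added])
    agree <- agree + sum(ft$labels[added] == s$pool_labels[pool_row])
    total <- total + length(added)
  }
  expect_gt(total, 0)
  expect_gte(agree / total, 0.9)
})

test_that("per-round history exports valid machine-readable JSON", {
  s <- toy_setup(seed = 6)
  cfg <- stss_config(max_iter = 2, mode = "self_label", seed = 3)
  h <- run_stss(s$train, s$pool, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_history_json(h, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$method, "stss")
  expect_equal(nrow(back$iterations), length(h$iterations))
  expect_equal(back$config$max_iter, 2L)
})
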