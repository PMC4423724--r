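# Two well-separated point clouds in 2 dimensions, plus a far interior point
# behind the positive margin.
separable_toy <- function() {
  X <- rbind(c(0, 2), c(0.5, 2.2), c(-0.4, 1.9), c(0, 10),   # class 1
             c(0, -2), c(0.5, -2.2), c(-0.4, -1.9))          # class 2
  svm_dataset(X, labels = c(1L, 1L, 1L, 1L, 2L, 2L, 2L))
}

test_that("one binary component per class; separable toys are fit exactly", {
  spec <- toy_spec(seed = 11)
  g <- generate_dataset(spec)
  m <- train_ovr(g$dataset)
  expect_s3_class(m, "ovr_model")
  expect_length(m$models, 3L)
  expect_equal(m$classes, 1:3)

  toy <- separable_toy()
  mt <- train_ovr(toy)
  expect_equal(predict(mt, toy), toy$labels)

  one_class <- svm_dataset(Matrix::rsparsematrix(5, 3, 0.5), labels = rep(1L, 5))
  expect_error(train_ovr(one_class), "2 classes")
  expect_error(train_ovr(toy, C = -1), "positive")
})

test_that("the two-class model mirrors one binary problem exactly", {
  toy <- separable_toy()
  m <- train_ovr(toy)
  d1 <- predict(m, toy, type = "decision")[, "1"]
  d2 <- predict(m, toy, type = "decision")[, "2"]
  expect_equal(d1, -d2, tolerance = 1e-12)
  expect_setequal(support_indices(m$models[["1"]], toy),
                  support_indices(m$models[["2"]], toy))
  expect_setequal(support_union(m, toy), support_indices(m$models[["1"]], toy))
})

test_that("decision boundaries agree in sign with the primal QP oracle", {
  for (seed in 1:30) {
    prob <- random_binary_problem(seed)
    fit <- package_binary_fit(prob$X, prob$yy)
    o <- qp_primal_svm(prob$X, prob$yy)
    d_pkg <- as.numeric(prob$X %*% fit$w) + fit$b
    d_qp <- as.numeric(prob$X %*% o$w) + o$b
    clear <- abs(d_qp) > 1e-4      # sign is only defined off the boundary
    expect_true(all(sign(d_pkg[clear]) == sign(d_qp[clear])))
  }
})

test_that("margin-criterion SV sets match the brute-force QP solution", {
  compared <- 0L
  for (seed in 1:60) {
    prob <- random_binary_problem(seed)
    fit <- package_binary_fit(prob$X, prob$yy)
    o <- qp_primal_svm(prob$X, prob$yy)
    # both solvers must sit at the same optimum
    expect_equal(primal_objective(fit$w, fit$b, prob$X, prob$yy),
                 primal_objective(o$w, o$b, prob$X, prob$yy),
                 tolerance = 1e-5)
    if (bias_is_ambiguous(o$w, o$b, prob$X, prob$yy)) next
    compared <- compared + 1L
    expect_identical(fit$sv, margin_sv_set(o$w, o$b, prob$X, prob$yy, tol = 1e-4))
  }
  expect_gte(compared, 50L)
})

test_that("minimal and interior-point margin geometry is respected", {
  two <- svm_dataset(rbind(c(0, 1), c(0, -1)), labels = c(1L, 2L))
  m2 <- train_ovr(two)
  expect_setequal(support_indices(m2$models[["1"]], two), 1:2)

  toy <- separable_toy()            # row 4 is far behind the margin
  mt <- train_ovr(toy)
  expect_false(4L %in% support_indices(mt$models[["1"]], toy))
  expect_false(4L %in% support_union(mt, toy))
})

test_that("support_union contains every per-class SV set", {
  spec <- toy_spec(seed = 21, flip = 0.1)
  g <- generate_dataset(spec)
  m <- train_ovr(g$dataset)
  u <- support_union(m, g$dataset)
  for (comp in m$models) {
    expect_true(all(support_indices(comp, g$dataset) %in% u))
  }
  expect_gte(length(u), max(vapply(m$models, function(c)
    length(support_indices(c, g$dataset)), integer(1))))
})

test_that("argmax decoding equals exhaustive per-class comparison", {
  spec <- toy_spec(seed = 31, flip = 0.05)
  g <- generate_dataset(spec)
  m <- train_ovr(g$dataset)
  P <- predict(m, g$dataset, type = "prob")
  pr <- predict_with_confidence(m, g$dataset)
  for (i in seq_len(nrow(P))) {
    best <- m$classes[[1]]
    for (k in seq_along(m$classes)) {
      if (P[i, k] > P[i, match(best, m$classes)]) best <- m$classes[[k]]
    }
    expect_equal(pr$labels[[i]], best)
    expect_equal(pr$confidences[[i]], max(P[i, ]))
  }
  expect_true(all(pr$confidences > 0 & pr$confidences < 1))
})

test_that("exact calibrated-score ties resolve to the smallest class code", {
  lm <- data.frame(code = c(2L, 5L), name = c("two", "five"))
  flat <- lapply(c(2L, 5L), function(code) {
    m <- constant_significance_model(4)
    m$pos_code <- code
    m
  })
  names(flat) <- c("2", "5")
  model <- stss:::assemble_ovr(flat, lm)
  pr <- predict_with_confidence(model, matrix(0, 3, 4))
  expect_equal(pr$labels, rep(2L, 3))
})

test_that("prediction rejects mismatched feature widths", {
  toy <- separable_toy()
  m <- train_ovr(toy)
  expect_error(predict(m, matrix(0, 2, 5)), "width")
  expect_error(support_indices(m$models[["1"]],
                               svm_dataset(matrix(0, 2, 5), labels = c(1L, 1L))),
               "width")
})

test_that("parallel and sequential training give identical models", {
  spec <- toy_spec(seed = 41)
  g <- generate_dataset(spec)
  m1 <- train_ovr(g$dataset, n_workers = 1L)
  m2 <- train_ovr(g$dataset, n_workers = 2L)
  for (k in seq_along(m1$models)) {
    expect_identical(m1$models[[k]]$weights, m2$models[[k]]$weights)
    expect_identical(m1$models[[k]]$bias, m2$models[[k]]$bias)
    expect_identical(m1$models[[k]]$calibration, m2$models[[k]]$calibration)
  }
})

test_that("calibrated scores increase strictly with the decision value", {
  spec <- toy_spec(seed = 51, flip = 0.05)
  g <- generate_dataset(spec)
  m <- train_ovr(g$dataset)
  for (comp in m$models) {
    expect_lt(comp$calibration[["A"]], 0)
    s <- stss:::platt_score(comp$calibration, seq(-3, 3, length.out = 50))
    expect_true(all(diff(s) > 0))
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("raising C on separable data never hurts training accuracy", {
  toy <- separable_toy()
  accs <- vapply(c(0.1, 1, 10), function(C) {
    mean(predict(train_ovr(toy, C = C), toy) == toy$labels)
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[[3]], 1)
})

test_that("every binary component keeps at least one SV per side", {
  spec <- toy_spec(seed = 61, flip = 0.05)
  g <- generate_dataset(spec)
  m <- train_ovr(g$dataset)
  for (comp in m$models) {
    sv <- support_indices(comp, g$dataset)
    y <- g$dataset$labels[sv] == comp$pos_code
    expect_gte(sum(y), 1L)
    expect_gte(sum(!y), 1L)
  }
})

test_that("model serialization round-trips bit-exactly", {
  spec <- toy_spec(seed = 71, flip = 0.05)
  g <- generate_dataset(spec)
  m <- train_ovr(g$dataset, class_weights = inverse_frequency_weights(class_counts(g$dataset)))
  f <- withr::local_tempfile(fileext = ".json")
  write_ovr_model(m, f)
  back <- read_ovr_model(f)
  expect_identical(back$classes, m$classes)
  expect_identical(back$label_map, m$label_map)
  for (k in seq_along(m$models)) {
    expect_identical(back$models[[k]]$weights, m$models[[k]]$weights)
    expect_identical(back$models[[k]]$bias, m$models[[k]]$bias)
    expect_identical(back$models[[k]]$calibration, m$models[[k]]$calibration)
    expect_identical(back$models[[k]]$pos_code, m$models[[k]]$pos_code)
  }
  # reloaded models predict identically
  expect_identical(predict(back, g$dataset), predict(m, g$dataset))
})
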