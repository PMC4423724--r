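# One-vs-rest linear SVM base classifier (the task model of the STSS round).
#
# Each per-class binary problem is solved by libsvm through e1071::svm with a
# linear kernel; the primal weight vector is recovered from the dual
# coefficients, and a Platt sigmoid is fitted on the training decision values
# so every binary component emits a calibrated score in (0, 1).

# --- Platt scaling ----------------------------------------------------------

# Newton fit of P(pos | d) = 1 / (1 + exp(A d + B)) with smoothed targets,
# so perfectly separated training data cannot drive |A| to infinity.
platt_fit <- function(deci, pos, maxiter = 100L, minstep = 1e-10, sigma = 1e-12) {
  prior1 <- sum(pos)
  prior0 <- length(pos) - prior1
  if (prior1 == 0L || prior0 == 0L) {
    stopf("Platt calibration needs both classes present")
  }
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  tt <- ifelse(pos, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  obj <- function(A, B) {
    fApB <- deci * A + B
    sum(ifelse(fApB >= 0,
               tt * fApB + log1p(exp(-fApB)),
               (tt - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- obj(A, B)
  for (it in seq_len(maxiter)) {
    fApB <- deci * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sigma + sum(deci * deci * d2)
    h22 <- sigma + sum(d2)
    h21 <- sum(deci * d2)
    d1 <- tt - p
    g1 <- sum(deci * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    while (stepsize >= minstep) {
      newA <- A + stepsize * dA
      newB <- B + stepsize * dB
      newf <- obj(newA, newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < minstep) break
  }
  c(A = A, B = B)
}

platt_score <- function(calib, d) {
  fApB <- d * calib[["A"]] + calib[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# --- binary linear model ----------------------------------------------------

# Fit one soft-margin linear SVM (pos vs rest) and wrap it as a plain list:
# weights, bias, Platt calibration, and the hyper-parameters needed to
# recompute the margin-criterion SV set.
fit_binary_linear <- function(X, pos, C = 1, weight_pos = NULL, weight_neg = NULL,
                              sv_tolerance = 1e-3, solver_tolerance = 1e-3,
                              pos_code = 1L) {
  if (all(pos) || !any(pos)) stopf("binary training set has a single class")
  y <- factor(ifelse(pos, "pos", "neg"), levels = c("pos", "neg"))
  cw <- if (!is.null(weight_pos) || !is.null(weight_neg)) {
    c(pos = weight_pos %||% 1, neg = weight_neg %||% 1)
  }
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = solver_tolerance, class.weights = cw,
                    cachesize = 200, fitted = FALSE)
  w <- drop(as.matrix(Matrix::crossprod(X[fit$index, , drop = FALSE], fit$coefs)))
  b <- -fit$rho
  # libsvm orders classes by first occurrence in the data, not factor levels:
  # flip so positive decision values mean the positive class.
  if (fit$levels[fit$labels[1]] != "pos") {
    w <- -w
    b <- -b
  }
  d <- as.numeric(X %*% w) + b
  structure(
    list(weights = w, bias = b, calibration = platt_fit(d, pos),
         C = C, class_weight_pos = weight_pos %||% 1,
         class_weight_neg = weight_neg %||% 1,
         sv_tolerance = sv_tolerance, pos_code = as.integer(pos_code),
         n_features = ncol(X)),
    class = "binary_linear_model"
  )
}

# Exact mirror of a binary model: the rest-vs-pos problem has the negated
# unique optimum, so no second solver call is needed; only the Platt sigmoid
# is refitted on the negated decision values.
mirror_binary_linear <- function(model, X, pos_mirror, pos_code) {
  d <- -(as.numeric(X %*% model$weights) + model$bias)
  structure(
    list(weights = -model$weights, bias = -model$bias,
         calibration = platt_fit(d, pos_mirror),
         C = model$C, class_weight_pos = model$class_weight_neg,
         class_weight_neg = model$class_weight_pos,
         sv_tolerance = model$sv_tolerance, pos_code = as.integer(pos_code),
         n_features = model$n_features),
    class = "binary_linear_model"
  )
}

#' @exportS3Method base::print
print.binary_linear_model <- function(x, ...) {
  cat(sprintf("<binary linear SVM: %d features, C = %g, bias = %.4g, Platt A = %.4g>\n",
              x$n_features, x$C, x$bias, x$calibration[["A"]]))
  invisible(x)
}

binary_decision <- function(model, X) {
  if (ncol(X) != model$n_features) {
    stopf("feature width %d does not match model width %d", ncol(X), model$n_features)
  }
  as.numeric(X %*% model$weights) + model$bias
}

# --- one-vs-rest model ------------------------------------------------------

#' Train a one-vs-rest linear SVM
#'
#' Builds one binary linear SVM per class (that class against the rest), each
#' with Platt-calibrated confidence scores. The per-class problems are
#' independent; with `n_workers > 1` they are fitted concurrently with results
#' identical to sequential fitting. For exactly two classes, the second binary
#' problem is the exact negation of the first and is derived rather than
#' refitted.
#'
#' @param ds labeled [svm_dataset] with >= 2 classes present.
#' @param C regularization strength (> 0) shared by all binary problems.
#' @param class_weights optional named numeric vector (names are class names);
#'   class `c`'s binary problem up-weights its positives by `class_weights[c]`
#'   relative to the rest. See [inverse_frequency_weights()].
#' @param seed integer, recorded in the model metadata (training itself is
#'   deterministic).
#' @param n_workers number of parallel workers for per-class fits.
#' @param sv_tolerance slack added to the functional-margin criterion when
#'   identifying support vectors; should dominate the solver tolerance.
#' @param solver_tolerance libsvm termination tolerance.
#' @param default_class optional class code predicted when no per-class
#'   calibrated score reaches 0.5 (used by models assembled from per-class
#'   balanced subsets, where the majority class has no binary model of its own).
#' @return An object of class `ovr_model`: per-class binary models, the label
#'   map, and training metadata.
#' @seealso [predict.ovr_model()], [support_union()], [run_stss()]
#' @examples
#' ds <- generate_dataset(synthetic_spec(class_counts = c(a = 30, b = 30, c = 30),
#'                                       n_features = 50, seed = 1))$dataset
#' m <- train_ovr(ds)
#' table(predict(m, ds))
#' @export
train_ovr <- function(ds, C = 1, class_weights = NULL, seed = 0L, n_workers = 1L,
                      sv_tolerance = 1e-3, solver_tolerance = 1e-3,
                      default_class = NULL) {
  if (!is_labeled(ds)) stopf("train_ovr() needs a labeled dataset")
  if (C <= 0) stopf("C must be positive")
  codes <- sort(unique(ds$labels))
  if (length(codes) < 2) stopf("training needs >= 2 classes, got %d", length(codes))
  X <- ds$features
  wt <- function(code) {
    if (is.null(class_weights)) return(NULL)
    nm <- ds$label_map$name[match(code, ds$label_map$code)]
    if (!nm %in% names(class_weights)) {
      stopf("class_weights has no entry for class '%s'", nm)
    }
    unname(class_weights[[nm]])
  }
  if (length(codes) == 2L) {
    pos <- ds$labels == codes[[1]]
    m1 <- fit_binary_linear(X, pos, C = C, weight_pos = wt(codes[[1]]),
                            weight_neg = wt(codes[[2]]),
                            sv_tolerance = sv_tolerance,
                            solver_tolerance = solver_tolerance,
                            pos_code = codes[[1]])
    m2 <- mirror_binary_linear(m1, X, !pos, codes[[2]])
    models <- list(m1, m2)
  } else {
    fit_one <- function(code) {
      fit_binary_linear(X, ds$labels == code, C = C, weight_pos = wt(code),
                        sv_tolerance = sv_tolerance,
                        solver_tolerance = solver_tolerance, pos_code = code)
    }
    models <- if (n_workers > 1L) {
      parallel::mclapply(codes, fit_one, mc.cores = n_workers)
    } else {
      lapply(codes, fit_one)
    }
  }
  names(models) <- as.character(codes)
  assemble_ovr(models, ds$label_map,
               meta = list(seed = as.integer(seed), C = C,
                           weighting = !is.null(class_weights)),
               default_class = default_class)
}

# Wrap per-class binary models into an ovr_model. Used by train_ovr() and by
# phase_one(), which fits each component on its own balanced subset.
assemble_ovr <- function(models, label_map, meta = list(), default_class = NULL) {
  codes <- unname(vapply(models, function(m) m$pos_code, integer(1)))
  models <- models[order(codes)]
  widths <- vapply(models, function(m) m$n_features, integer(1))
  if (length(unique(widths)) != 1) stopf("component models differ in width")
  structure(
    list(models = models, classes = sort(codes), label_map = label_map,
         n_features = widths[[1]],
         default_class = if (!is.null(default_class)) as.integer(default_class),
         meta = meta),
    class = "ovr_model"
  )
}

#' @exportS3Method base::print
print.ovr_model <- function(x, ...) {
  cat(sprintf("<ovr_model: %d binary linear SVMs over %d features, C = %g>\n",
              length(x$models), x$n_features, x$meta$C %||% NA))
  nm <- x$label_map$name[match(x$classes, x$label_map$code)]
  cat("  classes:", paste(nm, collapse = ", "), "\n")
  if (!is.null(x$default_class)) {
    cat("  fallback class:",
        x$label_map$name[match(x$default_class, x$label_map$code)], "\n")
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.ovr_model <- function(object, ...) {
  comp <- data.frame(
    class = object$label_map$name[match(object$classes, object$label_map$code)],
    code = object$classes,
    bias = vapply(object$models, function(m) m$bias, numeric(1)),
    platt_A = vapply(object$models, function(m) m$calibration[["A"]], numeric(1)),
    platt_B = vapply(object$models, function(m) m$calibration[["B"]], numeric(1)),
    row.names = NULL
  )
  structure(list(components = comp, n_features = object$n_features,
                 meta = object$meta), class = "summary.ovr_model")
}

#' @exportS3Method base::print
print.summary.ovr_model <- function(x, ...) {
  cat(sprintf("One-vs-rest linear SVM (%d features)\n", x$n_features))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ovr_model <- function(object, ...) {
  W <- vapply(object$models, function(m) m$weights, numeric(object$n_features))
  rbind(W, bias = vapply(object$models, function(m) m$bias, numeric(1)))
}

as_feature_matrix <- function(x) {
  if (inherits(x, "svm_dataset")) x$features
  else as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

ovr_scores <- function(model, X, type = c("prob", "decision")) {
  type <- match.arg(type)
  if (ncol(X) != model$n_features) {
    stopf("feature width %d does not match model width %d",
          ncol(X), model$n_features)
  }
  out <- vapply(model$models, function(m) {
    d <- as.numeric(X %*% m$weights) + m$bias
    if (type == "prob") platt_score(m$calibration, d) else d
  }, numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(NULL, as.character(model$classes)))
  out
}

#' Predict classes, probabilities or decision values
#'
#' Decoding is simple voting: the predicted class is the one whose binary
#' component yields the highest calibrated score, ties broken by the smallest
#' class code. If the model carries a fallback (majority) class, it is
#' predicted whenever no per-class score reaches 0.5.
#'
#' @param object an [ovr_model][train_ovr].
#' @param newdata [svm_dataset], pool, or matrix of matching width.
#' @param type `"class"` (integer class codes), `"prob"` (matrix of calibrated
#'   per-class scores), or `"decision"` (raw decision values).
#' @param ... ignored.
#' @return See `type`.
#' @export
predict.ovr_model <- function(object, newdata, type = c("class", "prob", "decision"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (type %in% c("prob", "decision")) {
    return(ovr_scores(object, X, type))
  }
  predict_with_confidence(object, newdata)$labels
}

#' Predict with calibrated confidence scores
#'
#' @param model an [ovr_model][train_ovr].
#' @param newdata dataset, pool, or matrix.
#' @return List with `labels` (integer class codes) and `confidences`
#'   (the winning calibrated score, in (0, 1)). For fallback-class
#'   predictions the confidence is one minus the best positive-class score.
#' @export
predict_with_confidence <- function(model, newdata) {
  X <- as_feature_matrix(newdata)
  P <- ovr_scores(model, X, "prob")
  if (nrow(P) == 0L) {
    return(list(labels = integer(0), confidences = numeric(0)))
  }
  pick <- apply(P, 1L, which.max)        # first max = smallest class code
  labels <- model$classes[pick]
  conf <- P[cbind(seq_len(nrow(P)), pick)]
  if (!is.null(model$default_class)) {
    fallback <- conf < 0.5
    labels[fallback] <- model$default_class
    conf[fallback] <- 1 - conf[fallback]
  }
  list(labels = labels, confidences = conf)
}

# --- support vectors --------------------------------------------------------

#' Support-vector indices of a binary component
#'
#' Identifies support vectors by the functional-margin characterization:
#' instance `i` with one-vs-rest label `y_i` in {+1, -1} is a support vector
#' when `y_i * (w . x_i + b) <= 1 + sv_tolerance`. For the exact solution this
#' margin set coincides with the set of nonzero dual coefficients.
#'
#' @param model a binary component of an [ovr_model][train_ovr] (or the
#'   significance model of [train_significance_model()]).
#' @param ds the labeled [svm_dataset] the model was trained on.
#' @param sv_tolerance margin slack; defaults to the model's own.
#' @return Integer row indices of the support vectors.
#' @export
support_indices <- function(model, ds, sv_tolerance = model$sv_tolerance) {
  if (!is_labeled(ds)) stopf("support_indices() needs the labeled training set")
  d <- binary_decision(model, ds$features)
  y <- ifelse(ds$labels == model$pos_code, 1, -1)
  which(y * d <= 1 + sv_tolerance)
}

#' Union of per-class support-vector sets
#'
#' The ensemble reading of "support vectors of the task model": an instance is
#' significant if it supports any of the one-vs-rest components.
#'
#' @param model an [ovr_model][train_ovr].
#' @param ds the labeled training [svm_dataset].
#' @param sv_tolerance margin slack; defaults to each component's own.
#' @return Sorted integer row indices.
#' @export
support_union <- function(model, ds, sv_tolerance = NULL) {
  sets <- lapply(model$models, function(m) {
    support_indices(m, ds, sv_tolerance %||% m$sv_tolerance)
  })
  sort(unique(unlist(sets, use.names = FALSE)))
}

# --- serialization ----------------------------------------------------------

#' Save / load a one-vs-rest model
#'
#' Models are stored as versioned JSON with doubles serialized as round-trip
#' decimal strings, so a reloaded model is bit-identical to the saved one.
#'
#' @param model an [ovr_model][train_ovr].
#' @param path output / input file.
#' @return `read_ovr_model()` returns the [ovr_model][train_ovr];
#'   `write_ovr_model()` returns `path` invisibly.
#' @export
write_ovr_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  comp <- lapply(model$models, function(m) {
    nz <- which(m$weights != 0)
    list(pos_code = m$pos_code, bias = num(m$bias),
         A = num(m$calibration[["A"]]), B = num(m$calibration[["B"]]),
         C = num(m$C), class_weight_pos = num(m$class_weight_pos),
         class_weight_neg = num(m$class_weight_neg),
         sv_tolerance = num(m$sv_tolerance), n_features = m$n_features,
         w_idx = nz, w_val = num(m$weights[nz]))
  })
  obj <- list(format = "stss_ovr_model", version = 1L,
              n_features = model$n_features, classes = model$classes,
              default_class = model$default_class,
              label_map = model$label_map, meta = model$meta, models = comp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ovr_model
#' @export
read_ovr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "stss_ovr_model")) stopf("not an stss model file: %s", path)
  if (obj$version != 1L) stopf("unsupported model version %s", obj$version)
  comp <- obj$models
  if (is.data.frame(comp)) comp <- split(comp, seq_len(nrow(comp)))
  models <- lapply(comp, function(m) {
    m <- as.list(m)
    w <- numeric(as.integer(m$n_features))
    w[unlist(m$w_idx)] <- as.numeric(unlist(m$w_val))
    structure(
      list(weights = w, bias = as.numeric(m$bias),
           calibration = c(A = as.numeric(m$A), B = as.numeric(m$B)),
           C = as.numeric(m$C),
           class_weight_pos = as.numeric(m$class_weight_pos),
           class_weight_neg = as.numeric(m$class_weight_neg),
           sv_tolerance = as.numeric(m$sv_tolerance),
           pos_code = as.integer(m$pos_code),
           n_features = as.integer(m$n_features)),
      class = "binary_linear_model"
    )
  })
  names(models) <- as.character(vapply(models, `[[`, integer(1), "pos_code"))
  lm <- validate_label_map(as.data.frame(obj$label_map))
  assemble_ovr(models, lm, meta = as.list(obj$meta),
               default_class = obj$default_class)
}
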