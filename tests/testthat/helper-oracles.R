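# Independent oracles and small generators shared across the suite.

options(stss.log_level = "quiet")

# --- primal soft-margin QP oracle (quadprog), independent of libsvm's SMO ---

# min 0.5 ||w||^2 + C sum(xi)  s.t.  y_i (w.x_i + b) >= 1 - xi_i, xi >= 0,
# solved directly in (w, b, xi). The tiny ridge on b and xi keeps the
# quadratic form positive definite without moving the optimum measurably.
qp_primal_svm <- function(X, yy, C = 1, eps = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  D <- diag(c(rep(1, p), eps, rep(eps, n)))
  d <- c(rep(0, p + 1), rep(-C, n))
  A1 <- cbind(yy * X, yy, diag(n))
  A2 <- cbind(matrix(0, n, p + 1), diag(n))
  sol <- quadprog::solve.QP(D, d, t(rbind(A1, A2)), c(rep(1, n), rep(0, n)))
  list(w = sol$solution[1:p], b = sol$solution[p + 1])
}

primal_objective <- function(w, b, X, yy, C = 1) {
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - yy * (as.numeric(as.matrix(X) %*% w) + b)))
}

# The bias of the soft-margin SVM is non-unique when the hinge subgradient
# in b is flat at the optimum (no "free" support vector pins it); on such
# degenerate problems the margin-SV set is ill-defined, so oracle
# comparisons skip them. Detected from the one-sided subgradients.
bias_is_ambiguous <- function(w, b, X, yy, band = 1e-6) {
  m <- yy * (as.numeric(as.matrix(X) %*% w) + b)
  below <- m < 1 - band
  at <- abs(m - 1) <= band
  right <- -sum(yy[below] == 1) + sum(yy[below] == -1) + sum(yy[at] == -1)
  left <- -sum(yy[below] == 1) - sum(yy[at] == 1) + sum(yy[below] == -1)
  right == 0 || left == 0
}

margin_sv_set <- function(w, b, X, yy, tol = 1e-6) {
  which(yy * (as.numeric(as.matrix(X) %*% w) + b) <= 1 + tol)
}

# Random tiny binary problems for SV-oracle comparisons: Gaussian features,
# random labels (guaranteed to include both).
random_binary_problem <- function(seed) {
  set.seed(seed)
  n <- sample(6:20, 1)
  p <- sample(2:5, 1)
  X <- matrix(rnorm(n * p), n, p)
  yy <- sample(c(-1, 1), n, replace = TRUE)
  if (length(unique(yy)) < 2) yy[1] <- -yy[1]
  list(X = X, yy = yy, n = n, p = p)
}

# Fit the package's binary SVM path on a tiny problem at high solver
# precision (so the margin tolerance dominates solver slack) and return the
# margin-criterion SV set plus the primal solution.
package_binary_fit <- function(X, yy, C = 1) {
  ds <- svm_dataset(X, labels = as.integer(yy > 0),
                    label_map = data.frame(code = 0:1, name = c("neg", "pos")))
  m <- stss:::fit_binary_linear(ds$features, yy > 0, C = C,
                                solver_tolerance = 1e-7, sv_tolerance = 1e-4,
                                pos_code = 1L)
  list(model = m, w = m$weights, b = m$bias,
       sv = support_indices(m, ds, sv_tolerance = 1e-4))
}

# --- reference confidence-filter implementations (naive, loop-based) --------

ref_filter <- function(kind, candidates, conf, k = NULL, p = NULL, tau = NULL) {
  n <- length(candidates)
  pick_top <- function(m) {
    m <- min(m, n)
    left <- seq_len(n)
    chosen <- integer(0)
    for (i in seq_len(m)) {
      best <- left[[1]]
      for (j in left) {
        if (conf[j] > conf[best] || (conf[j] == conf[best] && candidates[j] < candidates[best])) {
          best <- j
        }
      }
      chosen <- c(chosen, best)
      left <- setdiff(left, best)
    }
    sort(candidates[chosen])
  }
  switch(kind,
    top_k = pick_top(k),
    top_pct = pick_top(ceiling(p * n)),
    threshold = candidates[conf >= tau],
    random = stop("random handled separately"))
}

# --- misc -------------------------------------------------------------------

# Random sparse labeled dataset for I/O round-trips and count properties.
random_dataset <- function(n = 20, p = 50, n_classes = 3, density = 0.2,
                           seed = 1) {
  set.seed(seed)
  X <- Matrix::rsparsematrix(n, p, density)
  svm_dataset(X, labels = sample.int(n_classes, n, replace = TRUE))
}

# Naive confusion-matrix metrics, independent of per_class_prf().
naive_prf <- function(truth, pred, codes) {
  out <- list()
  for (c in codes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(truth)) {
      if (pred[i] == c && truth[i] == c) tp <- tp + 1
      if (pred[i] == c && truth[i] != c) fp <- fp + 1
      if (pred[i] != c && truth[i] == c) fn <- fn + 1
    }
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out[[as.character(c)]] <- c(p = p, r = r, f = f)
  }
  out
}

# The printed edge-detection class distribution used in worked examples.
edge_counts_printed <- c(
  "AtLoc" = 48L, "Cause" = 1117L, "Cause-Theme" = 6L, "Site" = 425L,
  "Site-Theme" = 3L, "Theme" = 9246L, "ToLoc" = 50L, "Negative" = 3650680L)

# A small well-separated multiclass spec used in several behavioral tests.
toy_spec <- function(seed = 1, flip = 0, sep = 0.5,
                     counts = c(a = 40, b = 40, Negative = 200)) {
  synthetic_spec(counts, n_features = 120, informative_per_class = 15,
                 feature_density = 0.02, separation = sep, flip_noise = flip,
                 seed = seed)
}
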