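# Synthetic sparse, severely imbalanced multi-class data with known ground
# truth, emulating the structure of biomedical event-extraction edge-detection
# feature data: hundreds of thousands of binary indicator features, extreme
# negative-class skew, and a handful of ultra-rare positive classes.

# Edge-detection training-set class distribution (instances per class).
EDGE_CLASS_COUNTS <- c(
  "AtLoc" = 48L, "Cause" = 1117L, "Cause-Theme" = 6L, "Site" = 425L,
  "Site-Theme" = 3L, "Theme" = 9246L, "ToLoc" = 50L, "Negative" = 3650680L
)
EDGE_N_FEATURES <- 412753L

#' Specification for the synthetic generator
#'
#' Instances are sparse binary feature vectors: every feature activates with
#' probability `feature_density` (background), and each class owns a disjoint
#' block of `informative_per_class` features that activate with probability
#' `min(1, feature_density + separation)` for instances of that class.
#' Observed labels are flipped to a uniformly random other class with
#' probability `flip_noise`; the generative assignment is returned separately
#' as ground truth.
#'
#' @param class_counts named integer vector: instances per class (>= 1 each).
#' @param n_features total feature count; must accommodate the informative
#'   blocks (`n_classes * informative_per_class <= n_features`).
#' @param informative_per_class size of each class's informative block.
#' @param feature_density background activation probability.
#' @param separation activation-probability boost of a class's own block;
#'   larger values make classes more linearly separable.
#' @param flip_noise label-flip probability in \[0, 0.5).
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_counts, n_features,
                           informative_per_class = 20L,
                           feature_density = 0.01,
                           separation = 0.3,
                           flip_noise = 0,
                           seed = 0L) {
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts)))) {
    stopf("class_counts must be a named vector")
  }
  if (any(class_counts < 1)) stopf("every class count must be >= 1")
  if (n_features < 1) stopf("n_features must be >= 1")
  if (informative_per_class < 1) stopf("informative_per_class must be >= 1")
  if (length(class_counts) * informative_per_class > n_features) {
    stopf("informative blocks (%d x %d) exceed n_features = %d",
          length(class_counts), informative_per_class, n_features)
  }
  if (feature_density < 0 || feature_density > 1) stopf("feature_density must be in [0, 1]")
  if (separation <= 0) stopf("separation must be positive")
  if (flip_noise < 0 || flip_noise >= 0.5) stopf("flip_noise must be in [0, 0.5)")
  structure(list(class_counts = as.integer(class_counts) |>
                   stats::setNames(names(class_counts)),
                 n_features = as.integer(n_features),
                 informative_per_class = as.integer(informative_per_class),
                 feature_density = feature_density, separation = separation,
                 flip_noise = flip_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @exportS3Method base::print
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec: %d classes, %d instances, %d features, ",
                     "density %g, separation %g, flip noise %g>\n"),
              length(x$class_counts), sum(x$class_counts), x$n_features,
              x$feature_density, x$separation, x$flip_noise))
  invisible(x)
}

# Informative block of class k (1-based): columns [(k-1)*m + 1, k*m].
informative_block <- function(spec, k) {
  m <- spec$informative_per_class
  ((k - 1L) * m + 1L):(k * m)
}

# Draw the sparse feature rows for n instances of generative class k.
draw_rows <- function(spec, k, n) {
  if (n == 0L) return(list(i = integer(0), j = integer(0)))
  m <- spec$informative_per_class
  block <- informative_block(spec, k)
  p_bg <- spec$feature_density
  p_hi <- min(1, spec$feature_density + spec$separation)
  # background activations outside the class's own block
  n_bg_cols <- spec$n_features - m
  bg_counts <- rbinom(n, n_bg_cols, p_bg)
  hi_counts <- rbinom(n, m, p_hi)
  other_cols <- setdiff(seq_len(spec$n_features), block)
  j_bg <- lapply(seq_len(n), function(r) {
    if (bg_counts[r] > 0L) other_cols[sample.int(n_bg_cols, bg_counts[r])] else integer(0)
  })
  j_hi <- lapply(seq_len(n), function(r) {
    if (hi_counts[r] > 0L) block[sample.int(m, hi_counts[r])] else integer(0)
  })
  j <- mapply(c, j_bg, j_hi, SIMPLIFY = FALSE)
  list(i = rep.int(seq_len(n), lengths(j)), j = unlist(j, use.names = FALSE))
}

generate_core <- function(spec, counts) {
  codes <- seq_along(spec$class_counts)
  parts <- lapply(codes, function(k) draw_rows(spec, k, counts[[k]]))
  offs <- cumsum(c(0L, counts[-length(counts)]))
  i <- unlist(mapply(function(p, o) p$i + o, parts, offs, SIMPLIFY = FALSE),
              use.names = FALSE)
  j <- unlist(lapply(parts, `[[`, "j"), use.names = FALSE)
  X <- sparseMatrix(i = i, j = j, x = 1, dims = c(sum(counts), spec$n_features))
  truth <- rep.int(codes, counts)
  observed <- truth
  if (spec$flip_noise > 0) {
    flip <- runif(length(truth)) < spec$flip_noise
    if (any(flip)) {
      K <- length(codes)
      shift <- sample.int(K - 1L, sum(flip), replace = TRUE)
      observed[flip] <- ((truth[flip] - 1L + shift) %% K) + 1L
    }
  }
  list(X = X, truth = truth, observed = observed)
}

spec_label_map <- function(spec) {
  data.frame(code = seq_along(spec$class_counts), name = names(spec$class_counts),
             stringsAsFactors = FALSE)
}

#' Generate a labeled synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (labeled [svm_dataset] carrying the observed,
#'   possibly noise-flipped labels) and `truth` (integer generative labels).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- with_seed(spec$seed, generate_core(spec, spec$class_counts))
  list(dataset = svm_dataset(out$X, labels = out$observed,
                             label_map = spec_label_map(spec)),
       truth = out$truth)
}

#' Generate an unlabeled pool from the same process
#'
#' Class sizes are drawn multinomially with probabilities proportional to the
#' spec's class counts; the generative labels are withheld from the pool
#' object but returned for auditing.
#'
#' @param spec a [synthetic_spec()].
#' @param n pool size (>= 0).
#' @param seed optional seed override (default: `spec$seed + 1`, so a pool
#'   drawn next to its dataset differs from it).
#' @return List with `pool` (unlabeled [svm_dataset]) and `hidden_labels`
#'   (integer generative labels, after flip noise).
#' @export
generate_pool <- function(spec, n, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n < 0) stopf("n must be >= 0")
  if (n == 0L) {
    return(list(pool = svm_dataset(Matrix(0, 0, spec$n_features, sparse = TRUE),
                                   label_map = spec_label_map(spec)),
                hidden_labels = integer(0)))
  }
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1, n, spec$class_counts / sum(spec$class_counts)))
    out <- generate_core(spec, counts)
    ord <- with_seed(derive_seed(seed, 1L), sample.int(nrow(out$X)))
    list(pool = svm_dataset(out$X[ord, , drop = FALSE],
                            label_map = spec_label_map(spec)),
         hidden_labels = out$observed[ord])
  })
}

#' Scaled class counts of the edge-detection training distribution
#'
#' Per-class counts `max(1, round(scale * count))` (round half up), so
#' ultra-rare classes survive scaling.
#'
#' @param scale fraction in (0, 1].
#' @return Named integer vector over the 8 edge-detection classes.
#' @examples
#' edge_detection_counts(1)        # the full distribution
#' edge_detection_counts(0.001)[["Theme"]]  # 9
#' @export
edge_detection_counts <- function(scale = 1) {
  if (scale <= 0 || scale > 1) stopf("scale must be in (0, 1]")
  pmax(1L, as.integer(floor(scale * EDGE_CLASS_COUNTS + 0.5))) |>
    stats::setNames(names(EDGE_CLASS_COUNTS))
}

#' Scaled edge-detection-shaped fixture
#'
#' A labeled training set plus unlabeled pool whose class skew and sparse
#' dimensionality follow the edge-detection training data, scaled down by
#' `scale`: per-class counts from [edge_detection_counts()], feature count
#' `max(100, round(scale * 412753))`, background density 0.01, separation 0.3
#' and 5 percent label-flip noise by default.
#'
#' @param scale fraction in (0, 1].
#' @param seed integer seed.
#' @param pool_size pool size (default: half the training size).
#' @param flip_noise label-flip probability (default 0.05).
#' @param separation informative-block activation boost (default 0.3).
#' @return List with `train` (labeled [svm_dataset]), `truth` (generative
#'   labels of `train`), `pool` (unlabeled [svm_dataset]), `pool_labels`
#'   (hidden generative labels of the pool) and `spec`.
#' @export
edge_detection_fixture <- function(scale, seed = 0L, pool_size = NULL,
                                   flip_noise = 0.05, separation = 0.3) {
  counts <- edge_detection_counts(scale)
  nf <- max(100L, as.integer(floor(scale * EDGE_N_FEATURES + 0.5)))
  spec <- synthetic_spec(counts, n_features = nf, informative_per_class = 20L,
                         feature_density = 0.01, separation = separation,
                         flip_noise = flip_noise, seed = seed)
  gen <- generate_dataset(spec)
  n_pool <- pool_size %||% as.integer(ceiling(sum(counts) / 2))
  pl <- generate_pool(spec, n_pool)
  list(train = gen$dataset, truth = gen$truth, pool = pl$pool,
       pool_labels = pl$hidden_labels, spec = spec)
}

#' Write a fixture to disk (svmlight + label map + ground-truth sidecar)
#'
#' @param fixture an [edge_detection_fixture()] result (or any list with
#'   `train`, `truth`, `pool`, `pool_labels`).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. Files: `train.svmlight`, `labels.tsv`,
#'   `pool.svmlight`, `train_truth.tsv`, `pool_truth.tsv`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_svmlight(fixture$train, file.path(dir, "train.svmlight"),
                 label_map_path = file.path(dir, "labels.tsv"))
  write_svmlight(fixture$pool, file.path(dir, "pool.svmlight"))
  write.table(data.frame(row = seq_along(fixture$truth), code = fixture$truth),
              file.path(dir, "train_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(row = seq_along(fixture$pool_labels),
                         code = fixture$pool_labels),
              file.path(dir, "pool_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
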