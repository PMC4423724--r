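#' Sparse labeled dataset / unlabeled pool container
#'
#' The basic data container of the package: a sparse instance-by-feature
#' matrix, optionally carrying integer class labels plus a label map (a
#' bijection between integer class codes and class names). Passing
#' `labels = NULL` yields an unlabeled pool. Feature indexing is 0-based
#' internally only in the sense that column `j` of the matrix corresponds to
#' external svmlight index `j` (1-based on disk).
#'
#' @param features sparse or dense numeric matrix (instances x features);
#'   coerced to [Matrix::dgCMatrix-class]. All values must be finite.
#' @param labels optional integer vector of class codes, one per instance.
#' @param label_map optional data.frame with columns `code` (integer) and
#'   `name` (character). Defaults to codes found in `labels` with names
#'   `"class<code>"`.
#' @param instance_ids optional character vector of opaque identifiers.
#'
#' @return An object of class `svm_dataset`.
#' @examples
#' X <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 7), x = c(0.5, 1), dims = c(2, 10))
#' ds <- svm_dataset(X, labels = c(1L, 2L))
#' nrow(ds)
#' class_counts(ds)
#' @export
svm_dataset <- function(features, labels = NULL, label_map = NULL, instance_ids = NULL) {
  features <- as(as(as(features, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(!is.finite(features@x))) {
    stopf("feature matrix contains non-finite values")
  }
  n <- nrow(features)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) {
      stopf("row count (%d) != label count (%d)", n, length(labels))
    }
    if (is.null(label_map)) {
      codes <- sort(unique(labels))
      label_map <- data.frame(code = codes, name = sprintf("class%d", codes),
                              stringsAsFactors = FALSE)
    }
    label_map <- validate_label_map(label_map)
    if (!all(labels %in% label_map$code)) {
      stopf("labels contain codes missing from label_map: %s",
            paste(setdiff(unique(labels), label_map$code), collapse = ", "))
    }
  } else if (!is.null(label_map)) {
    label_map <- validate_label_map(label_map)
  }
  if (!is.null(instance_ids) && length(instance_ids) != n) {
    stopf("instance_ids length must equal row count")
  }
  structure(
    list(features = features, labels = labels, label_map = label_map,
         instance_ids = instance_ids),
    class = "svm_dataset"
  )
}

validate_label_map <- function(label_map) {
  if (!is.data.frame(label_map) || !all(c("code", "name") %in% names(label_map))) {
    stopf("label_map must be a data.frame with columns 'code' and 'name'")
  }
  label_map$code <- as.integer(label_map$code)
  label_map$name <- as.character(label_map$name)
  if (anyDuplicated(label_map$code) || anyDuplicated(label_map$name)) {
    stopf("label_map codes and names must be unique")
  }
  label_map[order(label_map$code), c("code", "name"), drop = FALSE]
}

#' @exportS3Method base::print
print.svm_dataset <- function(x, ...) {
  kind <- if (is_labeled(x)) "labeled dataset" else "unlabeled pool"
  cat(sprintf("<svm_dataset: %s, %d instances x %d features, %d nonzeros>\n",
              kind, nrow(x$features), ncol(x$features), length(x$features@x)))
  if (is_labeled(x)) {
    cc <- class_counts(x)
    cat("  classes:", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.svm_dataset <- function(x) dim(x$features)

#' Test whether a dataset carries labels
#' @param ds an [svm_dataset].
#' @return `TRUE` for a labeled dataset, `FALSE` for a pool.
#' @export
is_labeled <- function(ds) !is.null(ds$labels)

#' Row subset of a dataset
#'
#' @param x an [svm_dataset].
#' @param i integer row indices.
#' @param ... ignored.
#' @return The subset as an [svm_dataset], labels and ids carried along.
#' @export
`[.svm_dataset` <- function(x, i, ...) {
  svm_dataset(x$features[i, , drop = FALSE],
              labels = if (is_labeled(x)) x$labels[i],
              label_map = x$label_map,
              instance_ids = if (!is.null(x$instance_ids)) x$instance_ids[i])
}

#' Concatenate two datasets row-wise
#'
#' Both datasets must share the feature-space width; label maps are merged
#' (conflicting code/name pairs are an error).
#'
#' @param a,b [svm_dataset] objects.
#' @return The row-bound [svm_dataset].
#' @export
dataset_bind <- function(a, b) {
  if (ncol(a$features) != ncol(b$features)) {
    stopf("feature widths differ: %d vs %d", ncol(a$features), ncol(b$features))
  }
  if (is_labeled(a) != is_labeled(b)) {
    stopf("cannot bind a labeled dataset with an unlabeled pool")
  }
  lm <- merge_label_maps(a$label_map, b$label_map)
  ids <- if (!is.null(a$instance_ids) && !is.null(b$instance_ids)) {
    c(a$instance_ids, b$instance_ids)
  }
  svm_dataset(rbind(a$features, b$features),
              labels = if (is_labeled(a)) c(a$labels, b$labels),
              label_map = lm, instance_ids = ids)
}

merge_label_maps <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  m <- unique(rbind(a, b))
  if (anyDuplicated(m$code) || anyDuplicated(m$name)) {
    stopf("conflicting label maps")
  }
  m[order(m$code), , drop = FALSE]
}

#' Map class codes to class names
#' @param ds an [svm_dataset] with a label map.
#' @param codes integer class codes (default: the dataset's labels).
#' @return Character vector of class names.
#' @export
class_names <- function(ds, codes = ds$labels) {
  ds$label_map$name[match(codes, ds$label_map$code)]
}

# ---------------------------------------------------------------------------
# svmlight I/O
#
# Dialect: "<label> <idx>:<val> ..." with 1-based strictly ascending indices,
# zeros omitted, values in shortest round-trip decimal form. Unlabeled pools
# use the sentinel label column "0" which is ignored on read when
# unlabeled = TRUE. The sidecar label map is a two-column TSV (code, name).
# ---------------------------------------------------------------------------

#' Read a sparse dataset in svmlight format
#'
#' @param path svmlight file.
#' @param label_map_path optional sidecar TSV (columns: code, name).
#' @param n_features optional width override; defaults to the maximum feature
#'   index seen (0 columns for an empty file).
#' @param unlabeled if `TRUE`, the (sentinel) label column is ignored and an
#'   unlabeled pool is returned.
#' @return An [svm_dataset]; a pool when `unlabeled = TRUE`.
#' @seealso [write_svmlight()]
#' @export
read_svmlight <- function(path, label_map_path = NULL, n_features = NULL,
                          unlabeled = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  labels <- integer(n)
  ii <- jj <- xx <- vector("list", n)
  for (k in seq_len(n)) {
    toks <- strsplit(trimws(lines[[k]]), "[[:space:]]+")[[1]]
    lab <- suppressWarnings(as.integer(toks[[1]]))
    if (is.na(lab)) stopf("line %d: malformed label '%s'", k, toks[[1]])
    labels[[k]] <- lab
    if (length(toks) > 1) {
      pairs <- strsplit(toks[-1], ":", fixed = TRUE)
      bad <- which(lengths(pairs) != 2)
      if (length(bad)) stopf("line %d: malformed pair '%s'", k, toks[-1][bad[1]])
      idx <- suppressWarnings(as.integer(vapply(pairs, `[[`, "", 1L)))
      val <- suppressWarnings(as.numeric(vapply(pairs, `[[`, "", 2L)))
      if (anyNA(idx) || anyNA(val)) stopf("line %d: malformed index:value pair", k)
      if (any(idx < 1L)) stopf("line %d: feature indices must be >= 1", k)
      if (is.unsorted(idx, strictly = TRUE)) {
        stopf("line %d: feature indices not strictly ascending", k)
      }
      keep <- val != 0
      ii[[k]] <- rep.int(k, sum(keep)); jj[[k]] <- idx[keep]; xx[[k]] <- val[keep]
    } else {
      ii[[k]] <- integer(0); jj[[k]] <- integer(0); xx[[k]] <- numeric(0)
    }
  }
  j <- unlist(jj)
  p <- n_features %||% if (length(j)) max(j) else 0L
  if (length(j) && max(j) > p) {
    stss_log("warn", sprintf("truncating %d entries beyond feature width %d",
                             sum(j > p), p))
    keep <- j <= p
    ii <- list(unlist(ii)[keep]); jj <- list(j[keep]); xx <- list(unlist(xx)[keep])
    j <- jj[[1]]
  }
  X <- if (length(j)) {
    sparseMatrix(i = unlist(ii), j = j, x = unlist(xx), dims = c(n, p))
  } else {
    Matrix(0, n, p, sparse = TRUE)
  }
  lm <- if (!is.null(label_map_path)) read_label_map(label_map_path)
  if (unlabeled) {
    svm_dataset(X, label_map = lm)
  } else {
    svm_dataset(X, labels = labels, label_map = lm)
  }
}

#' Write a sparse dataset in svmlight format
#'
#' Emits 1-based ascending indices, omitting zeros; unlabeled pools get the
#' sentinel label `0`. `read_svmlight(write_svmlight(ds))` reproduces values,
#' labels and ordering exactly.
#'
#' @param ds an [svm_dataset].
#' @param path output file.
#' @param label_map_path optional path for the sidecar label-map TSV.
#' @return `path`, invisibly.
#' @export
write_svmlight <- function(ds, path, label_map_path = NULL) {
  X <- ds$features
  n <- nrow(X)
  Xt <- as(Matrix::t(X), "CsparseMatrix")  # column k = instance k
  vals <- format_shortest(Xt@x)
  lines <- character(n)
  labs <- if (is_labeled(ds)) ds$labels else rep.int(0L, n)
  for (k in seq_len(n)) {
    a <- Xt@p[k] + 1L; b <- Xt@p[k + 1L]
    if (b >= a) {
      ord <- a:b
      lines[[k]] <- paste0(labs[[k]], " ",
                           paste0(Xt@i[ord] + 1L, ":", vals[ord], collapse = " "))
    } else {
      lines[[k]] <- as.character(labs[[k]])
    }
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stopf("cannot write '%s': %s", path, conditionMessage(e)))
  if (!is.null(label_map_path) && !is.null(ds$label_map)) {
    write_label_map(ds$label_map, label_map_path)
  }
  invisible(path)
}

#' Read / write a label-map sidecar (two-column TSV: code, name)
#' @param path TSV file.
#' @return `read_label_map()`: data.frame with columns `code`, `name`.
#' @export
read_label_map <- function(path) {
  m <- read.table(path, sep = "\t", header = FALSE, col.names = c("code", "name"),
                  colClasses = c("integer", "character"), quote = "")
  validate_label_map(m)
}

#' @rdname read_label_map
#' @param label_map data.frame with columns `code`, `name`.
#' @export
write_label_map <- function(label_map, path) {
  write.table(validate_label_map(label_map), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Label bookkeeping
# ---------------------------------------------------------------------------

#' Per-class instance counts
#'
#' @param ds a labeled [svm_dataset].
#' @return Named integer vector (names are class names, in label-map order),
#'   one entry per class in the label map including empty classes.
#' @export
class_counts <- function(ds) {
  if (!is_labeled(ds)) stopf("class_counts() needs a labeled dataset")
  tab <- table(factor(ds$labels, levels = ds$label_map$code))
  counts <- as.integer(tab)
  names(counts) <- ds$label_map$name
  counts
}

#' Imbalance-ratio denominator
#'
#' The minority:majority imbalance ratio reported as `1:<value>` with
#' `value = floor(n_neg / n_pos)`.
#'
#' @param n_pos positive (minority) count, must be >= 1.
#' @param n_neg negative (majority) count, >= 0.
#' @return Integer ratio denominator.
#' @examples
#' imbalance_ratio(1117, 27505)  # 24, i.e. "1:24"
#' @export
imbalance_ratio <- function(n_pos, n_neg) {
  if (length(n_pos) != 1 || length(n_neg) != 1 || is.na(n_pos) || is.na(n_neg)) {
    stopf("n_pos and n_neg must be scalar counts")
  }
  if (n_pos < 1) stopf("imbalance ratio undefined for n_pos = 0")
  if (n_neg < 0) stopf("n_neg must be non-negative")
  as.integer(floor(n_neg / n_pos))
}

#' Stratified split into initial set and pool
#'
#' Splits a labeled dataset into an initial training part and a (much larger)
#' remainder, stratified by class: each class contributes
#' `max(1, round(init_fraction * n_class))` instances to the initial part, so
#' every class is represented there. Deterministic for a fixed seed.
#'
#' @param ds labeled [svm_dataset]; every class must have >= 1 instance.
#' @param init_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return List with elements `initial` and `rest`, both [svm_dataset]s, plus
#'   `initial_idx` / `rest_idx` (row indices into `ds`).
#' @export
partition_dataset <- function(ds, init_fraction, seed) {
  if (!is_labeled(ds)) stopf("partition_dataset() needs a labeled dataset")
  if (init_fraction <= 0 || init_fraction >= 1) {
    stopf("init_fraction must lie in (0, 1)")
  }
  idx <- with_seed(seed, {
    picked <- lapply(split(seq_along(ds$labels), ds$labels), function(rows) {
      k <- max(1L, as.integer(round(init_fraction * length(rows))))
      k <- min(k, length(rows))
      if (length(rows) == 1L) rows else sample(rows, k)
    })
    sort(unlist(picked, use.names = FALSE))
  })
  rest <- setdiff(seq_along(ds$labels), idx)
  list(initial = ds[idx], rest = ds[rest], initial_idx = idx, rest_idx = rest)
}

#' Drop classes rarer than a threshold
#'
#' Removes all instances of classes with fewer than `min_class_count`
#' instances; surviving instances are unchanged and keep their original order.
#' The label map is restricted to surviving classes.
#'
#' @param ds labeled [svm_dataset].
#' @param min_class_count minimum per-class count to keep (>= 1).
#' @return The filtered [svm_dataset].
#' @export
remove_rare_classes <- function(ds, min_class_count) {
  if (!is_labeled(ds)) stopf("remove_rare_classes() needs a labeled dataset")
  if (min_class_count < 1) stopf("min_class_count must be >= 1")
  tab <- table(ds$labels)
  keep_codes <- as.integer(names(tab)[tab >= min_class_count])
  if (!length(keep_codes)) stopf("all classes removed by min_class_count = %d",
                                 min_class_count)
  rows <- which(ds$labels %in% keep_codes)
  out <- ds[rows]
  out$label_map <- out$label_map[out$label_map$code %in% keep_codes, , drop = FALSE]
  out
}
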