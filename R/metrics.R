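# Per-class evaluation metrics and comparison tables in the layout used for
# edge-detection results: per-class precision / recall / F-measure in
# percent, plus macro averages.

#' Per-class precision, recall and F-measure
#'
#' One-vs-rest metrics per class, in percent. 0/0 cases (a class with no
#' predictions, no true instances, or no true positives) are defined as 0,
#' and F = 2PR / (P + R) with the same convention. Values are unrounded;
#' the print method displays 2 decimals.
#'
#' @param truth integer vector of true class codes.
#' @param pred integer vector of predicted class codes, same length.
#' @param classes the class universe: a label-map data.frame (`code`,
#'   `name`), a named vector of codes, or a plain code vector. Defaults to
#'   the classes present in `truth` or `pred`.
#' @return An object of class `metrics_table`: data.frame with columns
#'   `class`, `code`, `precision`, `recall`, `f`, `support` and a
#'   `"macro"` attribute holding the macro averages.
#' @examples
#' per_class_prf(c(1, 1, 2, 2), c(1, 2, 2, 2))
#' @export
per_class_prf <- function(truth, pred, classes = NULL) {
  if (length(truth) != length(pred)) {
    stopf("truth and pred lengths differ (%d vs %d)", length(truth), length(pred))
  }
  if (is.null(classes)) {
    codes <- sort(unique(c(truth, pred)))
    nms <- sprintf("class%d", codes)
  } else if (is.data.frame(classes)) {
    lm <- validate_label_map(classes)
    codes <- lm$code
    nms <- lm$name
  } else {
    codes <- as.integer(classes)
    nms <- names(classes) %||% sprintf("class%d", codes)
  }
  bad <- setdiff(unique(c(truth, pred)), codes)
  if (length(bad)) stopf("codes outside the class universe: %s",
                         paste(bad, collapse = ", "))
  rows <- lapply(seq_along(codes), function(k) {
    c <- codes[[k]]
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = nms[[k]], code = c, precision = p, recall = r, f = f,
               support = tp + fn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "macro") <- c(precision = mean(out$precision),
                          recall = mean(out$recall), f = mean(out$f))
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' Macro-averaged F-measure of a metrics table
#' @param mt a [per_class_prf()] result.
#' @param exclude optional class names to leave out of the average (e.g. the
#'   majority class).
#' @return Macro F in percent.
#' @export
macro_f <- function(mt, exclude = NULL) {
  keep <- !(mt$class %in% exclude)
  mean(mt$f[keep])
}

#' @exportS3Method base::print
print.metrics_table <- function(x, digits = 2, ...) {
  df <- data.frame(class = x$class,
                   precision = round(x$precision, digits),
                   recall = round(x$recall, digits),
                   f = round(x$f, digits),
                   support = x$support)
  print(df, row.names = FALSE)
  m <- attr(x, "macro")
  cat(sprintf("macro: P %.2f  R %.2f  F %.2f\n", m[["precision"]],
              m[["recall"]], m[["f"]]))
  invisible(x)
}

#' Side-by-side comparison of metric tables
#'
#' Renders several [per_class_prf()] tables (e.g. different methods on the
#' same test set) side by side, flagging the best F-measure per class.
#'
#' @param tables named list of `metrics_table`s sharing one class set.
#' @param exclude optional class names dropped from the rendering (e.g. the
#'   majority class).
#' @return An object of class `compare_report`: long-format data.frame with
#'   columns `class`, `method`, `precision`, `recall`, `f`, `best` (logical,
#'   max F in its class).
#' @export
compare_report <- function(tables, exclude = NULL) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stopf("tables must be a named list")
  }
  ref <- tables[[1]]$class
  for (t in tables) {
    if (!identical(t$class, ref)) stopf("tables do not share one class set")
  }
  rows <- do.call(rbind, lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    data.frame(class = t$class, method = nm, precision = t$precision,
               recall = t$recall, f = t$f, stringsAsFactors = FALSE)
  }))
  rows <- rows[!(rows$class %in% exclude), , drop = FALSE]
  best <- vapply(seq_len(nrow(rows)), function(i) {
    fs <- rows$f[rows$class == rows$class[[i]]]
    rows$f[[i]] == max(fs)
  }, logical(1))
  rows$best <- best
  class(rows) <- c("compare_report", "data.frame")
  rows
}

#' @exportS3Method base::print
print.compare_report <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$precision <- round(df$precision, digits)
  df$recall <- round(df$recall, digits)
  df$f <- ifelse(df$best, sprintf("*%.*f", digits, df$f),
                 sprintf(" %.*f", digits, df$f))
  df$best <- NULL
  print(df, row.names = FALSE)
  cat("(* best F-measure in class)\n")
  invisible(x)
}

#' Write / read a metrics table as TSV
#'
#' Numbers are serialized in round-trip decimal form, so a re-parse
#' reproduces them exactly.
#'
#' @param mt a [per_class_prf()] result (or `compare_report`).
#' @param path TSV file.
#' @return `read_metrics_tsv()` returns the parsed data.frame.
#' @export
write_metrics_tsv <- function(mt, path) {
  df <- as.data.frame(mt)
  for (col in intersect(c("precision", "recall", "f"), names(df))) {
    df[[col]] <- format_shortest(df[[col]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_tsv
#' @export
read_metrics_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
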