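#' Read a labeled sample-by-feature matrix from delimited text
#'
#' Reads an expression-style matrix from CSV or TSV text: one row per sample,
#' one column per feature, plus a class-label column. This is the
#' high-dimension small-sample layout typical of microarray studies (tens of
#' samples, thousands of genes), so samples-in-rows is the expected
#' orientation. No transformation or scaling is applied at load time;
#' standardization is an explicit option of the downstream selectors.
#'
#' @param path Path to a delimited text file with a mandatory header row.
#' @param label_column Name of the column holding the class labels
#'   (default `"label"`).
#' @param delimiter Field separator. The default `NULL` sniffs the header
#'   line: a tab if present, otherwise a comma.
#' @param id_column Optional name of a column holding sample identifiers. If
#'   `NULL` (default) and the file's first column is non-numeric and is not
#'   the label column, it is taken as the sample identifier column; otherwise
#'   samples are named `S1..Sn` in file order.
#'
#' @return A `labeled_dataset`: a list with components `x` (numeric matrix,
#'   samples x features, with sample and feature names) and `y` (factor of
#'   class labels, one per row of `x`). Sample order is exactly file order
#'   and feature order is exactly column order; nearest-neighbour
#'   tie-breaking downstream depends on this.
#'
#' @details Every non-label cell must parse as a finite number; a cell that
#'   does not is reported with its row number and column name. Missing values
#'   are rejected rather than imputed. The file must contain at least two
#'   distinct classes, each with at least two samples, and feature and sample
#'   identifiers must be unique.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' sim <- simulate_hdlss(n_per_class = c(5, 5), m = 8, q = 2, delta = 3)
#' write_labeled_dataset(sim, tf)
#' ds <- read_labeled_dataset(tf)
#' dim(ds$x)
#' table(ds$y)
#' @seealso [write_labeled_dataset()], [svm_rfe()]
#' @export
read_labeled_dataset <- function(path, label_column = "label",
                                 delimiter = NULL, id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path,
         call. = FALSE)
  }

  first_col_numeric <- !anyNA(suppressWarnings(as.numeric(df[[1L]])))
  if (is.null(id_column) && names(df)[1L] != label_column &&
      !first_col_numeric) {
    id_column <- names(df)[1L]
  }
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop("id column '", id_column, "' not found", call. = FALSE)
    }
    sample_ids <- df[[id_column]]
    df[[id_column]] <- NULL
  } else {
    sample_ids <- paste0("S", seq_len(nrow(df)))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }

  labels <- df[[label_column]]
  df[[label_column]] <- NULL
  feature_ids <- names(df)
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }

  x <- matrix(NA_real_, nrow(df), length(feature_ids),
              dimnames = list(sample_ids, feature_ids))
  for (j in seq_along(feature_ids)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v) | is.na(df[[j]]) | !nzchar(df[[j]]))
    if (length(bad)) {
      stop("non-numeric or missing value at row ", bad[1L], ", column '",
           feature_ids[j], "'", call. = FALSE)
    }
    x[, j] <- v
  }
  new_labeled_dataset(x, labels)
}

#' Construct and validate a labeled dataset
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param y Class labels, one per row of `x` (coerced to factor).
#' @return A validated `labeled_dataset` list with components `x` and `y`.
#' @export
new_labeled_dataset <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(as.character(y))
  if (nrow(x) < 2L) stop("at least 2 samples required", call. = FALSE)
  if (ncol(x) < 1L) stop("at least 1 feature required", call. = FALSE)
  if (length(y) != nrow(x)) {
    stop("labels and rows of x differ in length", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("x contains missing or non-finite values", call. = FALSE)
  }
  if (nlevels(y) < 2L) {
    stop("fewer than 2 classes in the label column", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("every class needs at least 2 samples (smallest has ",
         min(table(y)), ")", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, y = y), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", nrow(x$x), "samples x", ncol(x$x), "features\n")
  print(table(class = x$y))
  invisible(x)
}

#' Write a labeled dataset as delimited text
#'
#' Writes the transpose-free dialect read by [read_labeled_dataset()]: one
#' row per sample with a `sample` id column and a `label` column. For
#' simulated data (see [simulate_hdlss()]) the ground-truth informative
#' feature identifiers can be written to a sidecar file.
#'
#' @param data A `labeled_dataset` (or the list returned by
#'   [simulate_hdlss()]).
#' @param path Output file path.
#' @param delimiter Field separator (default tab).
#' @param truth_path Optional path for a one-column sidecar listing the
#'   informative features, written only when `data` carries ground truth.
#' @return `path`, invisibly.
#' @export
write_labeled_dataset <- function(data, path, delimiter = "\t",
                                  truth_path = NULL) {
  df <- data.frame(sample = rownames(data$x), label = as.character(data$y),
                   data$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth_path) && !is.null(data$informative)) {
    utils::write.table(data.frame(informative = data$informative),
                       truth_path, sep = delimiter, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a selection result with its iteration trace
#'
#' Writes the ranked selected features as a two-column delimited file
#' (`rank`, `feature`) and the full per-iteration audit trail as JSON lines,
#' one record per elimination iteration with the iteration index, active
#' feature count, cross-validated accuracy, average overlap degree, subset
#' score, number of screened samples and whether that iteration holds the
#' returned subset.
#'
#' @param result An object of class `svm_rfe` (see [svm_rfe()]).
#' @param path Output path for the ranked feature list.
#' @param trace_path Output path for the JSON-lines trace; default
#'   `paste0(path, ".trace.jsonl")`. `NULL` suppresses the trace file.
#' @param delimiter Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path,
                            trace_path = paste0(path, ".trace.jsonl"),
                            delimiter = ",") {
  stopifnot(inherits(result, "svm_rfe"))
  if (nrow(result$trace) == 0L) stop("trace must be non-empty", call. = FALSE)
  sel <- data.frame(rank = seq_along(result$selected),
                    feature = result$selected, stringsAsFactors = FALSE)
  utils::write.table(sel, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  if (!is.null(trace_path)) {
    tr <- result$trace
    recs <- vapply(seq_len(nrow(tr)), function(i) {
      jsonlite::toJSON(list(
        iteration = tr$iteration[i],
        n_features = tr$n_features[i],
        t_c_acc = tr$t_c_acc[i],
        t_c_oa = tr$t_c_oa[i],
        score = tr$score[i],
        n_screened = tr$n_screened[i],
        selected = tr$iteration[i] == result$winning_iteration,
        config = result$config
      ), auto_unbox = TRUE, digits = NA, na = "null")
    }, character(1))
    writeLines(recs, trace_path)
  }
  invisible(path)
}

#' Read back a ranked feature list written by [write_selection()]
#'
#' @param path Path to the two-column (`rank`, `feature`) file.
#' @param delimiter Field separator (default comma).
#' @return Character vector of feature identifiers in rank order.
#' @export
read_selection <- function(path, delimiter = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  df$feature[order(as.integer(df$rank))]
}

#' Write an evaluation report
#'
#' Writes one detail row per (repeat, fold) as CSV, preceded by `#`-prefixed
#' header lines carrying the protocol descriptor and the aggregate block
#' (mean and standard deviation per metric, pooled across all repeat-fold
#' cells). A machine-readable JSON summary is written alongside.
#'
#' @param report An object of class `svm_rfe_cv` (see [cross_validate()]).
#' @param path Output CSV path.
#' @param json_path Path for the JSON summary; default
#'   `paste0(path, ".json")`; `NULL` suppresses it.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, json_path = paste0(path, ".json")) {
  stopifnot(inherits(report, "svm_rfe_cv"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  proto <- report$protocol
  writeLines(c(
    paste0("# selector: ", proto$method),
    paste0("# k: ", proto$k, "  t: ", proto$t, "  d: ", proto$d,
           "  cost: ", proto$cost),
    paste0("# outer_folds: ", proto$outer_folds, "  repeats: ",
           proto$repeats, "  seed: ", proto$seed),
    paste0("# standardize: ", proto$standardize,
           "  positive_class: ", proto$positive_class %||% "NA"),
    paste0("# sd convention: pooled across all repeat-fold cells")
  ), con)
  agg <- report$summary
  for (i in seq_len(nrow(agg))) {
    writeLines(sprintf("# aggregate %s: %.6f +/- %.6f", agg$metric[i],
                       agg$mean[i], agg$sd[i]), con)
  }
  utils::write.table(report$detail, con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(protocol = proto,
                              aggregates = agg,
                              detail = report$detail),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept either (x, y) or a labeled_dataset in fitting functions.
as_xy <- function(x, y) {
  if (inherits(x, "labeled_dataset")) {
    list(x = x$x, y = x$y)
  } else {
    ds <- new_labeled_dataset(x, y)
    list(x = ds$x, y = ds$y)
  }
}
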