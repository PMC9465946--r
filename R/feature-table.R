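#' Feature tables
#'
#' A `feature_table` holds an n x d matrix of learned-feature activations
#' (one row per 30-s epoch) together with per-sample metadata: the class
#' label (e.g. one of the five sleep stages), the domain the sample came
#' from (`"source"` or `"target"`), a subject ID, and a within-subject
#' recording ID.  All adaptation algorithms and transferability measures in
#' the package consume this container.
#'
#' @param features numeric n x d matrix; all values must be finite.
#' @param labels length-n vector of class labels (coerced to character).
#' @param domain length-n vector with values `"source"` or `"target"`, or a
#'   single value recycled to length n.
#' @param subject length-n subject identifiers (recycled if length 1).
#' @param recording length-n within-subject recording identifiers (recycled
#'   if length 1).
#' @return an object of class `feature_table`: a list with elements
#'   `features`, `labels`, `domain`, `subject`, `recording`.
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2), labels = rep(c("N2", "REM"), 5),
#'                     domain = "target", subject = "s01", recording = "r1")
#' ft
#' @export
feature_table <- function(features, labels, domain = "source",
                          subject = "s1", recording = "r1") {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features)) {
    stopf("`features` must be a numeric matrix")
  }
  n <- nrow(features)
  d <- ncol(features)
  if (n < 1L || d < 1L) stopf("`features` must have n >= 1 rows and d >= 1 columns")
  if (!all(is.finite(features))) {
    bad <- which(!apply(is.finite(features), 1L, all))[1L]
    stopf("non-finite feature value at row %d", bad)
  }
  recycle <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stopf("`%s` must have length %d (one per sample)", what, n)
    as.character(x)
  }
  labels <- recycle(labels, "labels")
  domain <- recycle(domain, "domain")
  subject <- recycle(subject, "subject")
  recording <- recycle(recording, "recording")
  if (!all(domain %in% c("source", "target"))) {
    stopf("`domain` values must be \"source\" or \"target\"")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("feature_", seq_len(d) - 1L)
  }
  structure(
    list(features = features, labels = labels, domain = domain,
         subject = subject, recording = recording),
    class = "feature_table"
  )
}

#' @rdname feature_table
#' @param x object to test or print.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat("  domains:  ", paste(sprintf("%s (%d)", names(table(x$domain)),
                                    table(x$domain)), collapse = ", "), "\n")
  cat("  classes:  ", paste(sort(unique(x$labels)), collapse = ", "), "\n")
  cat("  subjects: ", length(unique(x$subject)), "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- as.data.frame(x$features)
  df$label <- x$labels
  df$domain <- x$domain
  df$subject <- x$subject
  df$recording <- x$recording
  df
}

#' @export
dim.feature_table <- function(x) dim(x$features)

## row subset preserving metadata
subset_rows <- function(ft, idx) {
  feature_table(ft$features[idx, , drop = FALSE], ft$labels[idx],
                ft$domain[idx], ft$subject[idx], ft$recording[idx])
}

#' Read and write feature tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `feature_0,...,feature_{d-1},label,domain,subject,recording`.  Feature
#' values are written with 17 significant digits so that a write/read round
#' trip reproduces the doubles exactly.  The loader rejects missing columns
#' (naming the column) and non-numeric or non-finite feature cells (naming
#' the row).
#'
#' @param path path to a CSV file.
#' @param dialect optional named list remapping the metadata column names,
#'   e.g. `list(label = "stage")`.
#' @return `load_feature_table()` returns a [feature_table()];
#'   `write_feature_table()` returns `path` invisibly.
#' @export
load_feature_table <- function(path, dialect = list()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  cols <- list(label = "label", domain = "domain",
               subject = "subject", recording = "recording")
  cols[names(dialect)] <- dialect
  df <- read.csv(path, check.names = FALSE, colClasses = NA,
                 stringsAsFactors = FALSE)
  for (nm in unlist(cols)) {
    if (!nm %in% names(df)) stopf("missing required column \"%s\" in %s", nm, path)
  }
  meta <- unlist(cols)
  feat_cols <- setdiff(names(df), meta)
  if (length(feat_cols) == 0L) stopf("no feature columns found in %s", path)
  feats <- df[feat_cols]
  for (nm in feat_cols) {
    v <- feats[[nm]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stopf("non-numeric or non-finite value in feature column \"%s\" at row %d",
            nm, bad[1L])
    }
    feats[[nm]] <- v
  }
  X <- as.matrix(feats)
  colnames(X) <- feat_cols
  feature_table(X, df[[cols$label]], df[[cols$domain]],
                df[[cols$subject]], df[[cols$recording]])
}

#' @rdname load_feature_table
#' @param ft a [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(is_feature_table(ft))
  X <- ft$features
  out <- as.data.frame(lapply(seq_len(ncol(X)), function(j) {
    sprintf("%.17g", X[, j])
  }), col.names = colnames(X), check.names = FALSE, optional = TRUE)
  names(out) <- colnames(X)
  out$label <- ft$labels
  out$domain <- ft$domain
  out$subject <- ft$subject
  out$recording <- ft$recording
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
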