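#' Labelled expression container
#'
#' Bundles a log2 expression matrix (features x samples) with per-sample
#' class labels (`"CAF"` or `"NOF"`) and a feature annotation table mapping
#' probes to gene symbols and biotypes. This is the substrate of every
#' downstream stage.
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimensions must be named. Values are assumed log2-scale; missing values
#'   are rejected.
#' @param sample_labels named character vector (names = sample ids) with
#'   values `"CAF"` or `"NOF"`, covering every column of `values`.
#' @param annotation data frame with columns `feature_id`, `symbol`,
#'   `biotype` (`"lncRNA"` or `"coding"`), covering every row of `values`.
#' @return an object of class `labelled_expression`.
#' @export
labelled_expression <- function(values, sample_labels, annotation) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have row (feature) and column (sample) names")
  }
  if (anyNA(values)) stop("expression matrix contains missing values; impute or filter upstream")
  missing_lab <- setdiff(colnames(values), names(sample_labels))
  if (length(missing_lab)) {
    stop("samples without a label: ", paste(head(missing_lab), collapse = ", "))
  }
  sample_labels <- sample_labels[colnames(values)]
  if (!all(sample_labels %in% c("CAF", "NOF"))) {
    stop("sample labels must be 'CAF' or 'NOF'")
  }
  req <- c("feature_id", "symbol", "biotype")
  if (!all(req %in% names(annotation))) {
    stop("annotation needs columns: ", paste(req, collapse = ", "))
  }
  missing_ann <- setdiff(rownames(values), annotation$feature_id)
  if (length(missing_ann)) {
    stop("features without annotation: ", paste(head(missing_ann), collapse = ", "))
  }
  annotation <- annotation[match(rownames(values), annotation$feature_id), req]
  rownames(annotation) <- NULL
  structure(
    list(values = values, sample_labels = sample_labels, annotation = annotation),
    class = "labelled_expression"
  )
}

#' @export
print.labelled_expression <- function(x, ...) {
  tab <- table(x$sample_labels)
  cat(sprintf(
    "labelled_expression: %d features x %d samples (%s)\n  biotypes: %s\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
    paste(sprintf("%d %s", table(x$annotation$biotype),
                  names(table(x$annotation$biotype))), collapse = ", ")
  ))
  invisible(x)
}

#' Subset a labelled expression object
#'
#' @param x a [labelled_expression()] object.
#' @param features optional character vector of feature ids to keep.
#' @param samples optional character vector of sample ids to keep.
#' @return a `labelled_expression` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "labelled_expression"))
  v <- x$values
  if (!is.null(features)) {
    bad <- setdiff(features, rownames(v))
    if (length(bad)) stop("unknown features: ", paste(head(bad), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    bad <- setdiff(samples, colnames(v))
    if (length(bad)) stop("unknown samples: ", paste(head(bad), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  labelled_expression(v, x$sample_labels[colnames(v)],
                      x$annotation[x$annotation$feature_id %in% rownames(v), ])
}
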