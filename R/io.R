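#' Write a labelled expression object to TSV files
#'
#' Expression is written as a TSV whose first column (`feature_id`) holds
#' probe ids and remaining columns hold samples; labels and annotation go to
#' companion TSVs.
#'
#' @param x a [labelled_expression()] object.
#' @param expr_path,labels_path,annotation_path output file paths.
#' @return invisibly, the three paths.
#' @export
write_expression_tsv <- function(x, expr_path, labels_path, annotation_path) {
  stopifnot(inherits(x, "labelled_expression"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = names(x$sample_labels),
                    label = unname(x$sample_labels))
  write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$annotation, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(expr_path, labels_path, annotation_path))
}

#' Read a labelled expression object from TSV files
#'
#' @param expr_path,labels_path,annotation_path paths written by
#'   [write_expression_tsv()] (or equivalent external files).
#' @return a [labelled_expression()] object.
#' @export
read_expression_tsv <- function(expr_path, labels_path, annotation_path) {
  df <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  lab <- read.delim(labels_path, stringsAsFactors = FALSE)
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  labelled_expression(values, setNames(lab$label, lab$sample_id), ann)
}

#' Read / write TF interaction tables
#'
#' Interaction tables are TSVs with columns `tf_symbol`, `target_symbol`
#' and `rank` (evidence rank, e.g. `"Rank 1"` for experimentally validated
#' interactions), the flat-file layout used by ChIPBase- and ORTI-style
#' exports.
#'
#' @param path file path.
#' @return for the reader, a data frame with the three columns above.
#' @export
read_interactions_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("tf_symbol", "target_symbol", "rank")
  if (!all(req %in% names(df))) {
    stop("interaction table needs columns: ", paste(req, collapse = ", "))
  }
  df[, req]
}

#' @rdname read_interactions_tsv
#' @param x data frame with columns `tf_symbol`, `target_symbol`, `rank`.
#' @export
write_interactions_tsv <- function(x, path) {
  stopifnot(all(c("tf_symbol", "target_symbol", "rank") %in% names(x)))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated set name,
#' description, then member gene symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param pathways named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled; defaults to `"na"`).
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  descriptions <- rep_len(descriptions %||% "na", length(pathways))
  lines <- vapply(seq_along(pathways), function(i) {
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
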