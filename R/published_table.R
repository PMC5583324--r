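#' Published CAF vs NOF differentially expressed lncRNAs
#'
#' Symbol-level moderated-t statistics for the 39 lncRNAs reported as
#' differentially expressed between ovarian cancer-associated fibroblasts
#' and normal ovarian fibroblasts in the microdissected HGSOC microarray
#' cohort (GEO accession GSE40595, Affymetrix U133 Plus 2.0). Positive
#' `logFC` indicates up-regulation in CAFs. The table ships with the
#' package as a worked example of the symbol-collapsing and direction
#' logic; it is not used by any estimation step.
#'
#' @return data frame with columns `symbol`, `logFC`, `p`, `adj_p` and a
#'   `feature_id` column equal to `symbol` (the records are already
#'   symbol-level) so it can flow through [apply_de_filter()] and
#'   [collapse_to_symbols()] directly.
#' @export
published_de_lncrnas <- function() {
  path <- system.file("extdata", "caf_nof_de_lncrnas.tsv",
                      package = "caflncnet", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$feature_id <- df$symbol
  df
}
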