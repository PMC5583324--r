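#' Hypergeometric TF enrichment against a differentially expressed gene list
#'
#' Upper-tail hypergeometric test of the overlap between a TF's target set
#' and the DE gene list, drawn from a background universe: population
#' `N = |background|`, successes `K = |targets in background|`, draws
#' `n = |DE genes|`, observed `k = |targets in DE genes|`;
#' `p = P(X >= k)`.
#'
#' @param tf_targets character vector of the TF's target gene symbols.
#' @param de_genes character vector of DE gene symbols (must be a subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @return upper-tail p-value.
#' @export
tf_enrichment <- function(tf_targets, de_genes, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background universe")
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% background)) {
    stop("de_genes must be a subset of the background universe")
  }
  tf_targets <- intersect(unique(tf_targets), background)
  N <- length(background)
  K <- length(tf_targets)
  n <- length(de_genes)
  k <- length(intersect(tf_targets, de_genes))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build the context-specific TF regulatory network
#'
#' TFs are tested for enrichment of their (rank-filtered, de-duplicated)
#' coding gene targets within the DE gene list by [tf_enrichment()]; TFs
#' with `p < alpha` are "active" in the study context. The network then
#' keeps the bipartite edges from enriched TFs to differentially expressed
#' targets: TF -> lncRNA edges whose target is a DE lncRNA, and
#' TF -> gene edges whose target is a DE gene. Symbols are harmonized by
#' exact uppercase match (apply any alias mapping upstream).
#'
#' @param tf_lncrna interaction table (columns `tf_symbol`,
#'   `target_symbol`, `rank`) of TF -> lncRNA edges.
#' @param tf_tg interaction table of TF -> target-gene edges.
#' @param de_lncrnas,de_genes character vectors of DE lncRNA and DE gene
#'   symbols.
#' @param background gene universe for the enrichment test (typically all
#'   coding symbols measured on the array).
#' @param alpha TF enrichment threshold (default 0.05).
#' @param rank_filter keep only TF -> gene rows with this evidence rank
#'   (default `"Rank 1"`); `NULL` keeps all rows.
#' @param adjust if `TRUE`, threshold BH-adjusted TF enrichment p-values
#'   instead of raw ones (default `FALSE`, matching the uncorrected
#'   `p < 0.05` rule).
#' @return object of class `context_network`: list with `tf_table` (per-TF
#'   `tf`, `n_targets`, `n_de_targets`, `p`, `adj_p`, `enriched`) and
#'   `edges` (`tf`, `target`, `target_kind`, `tf_p`).
#' @export
build_context_network <- function(tf_lncrna, tf_tg, de_lncrnas, de_genes,
                                  background, alpha = 0.05,
                                  rank_filter = "Rank 1", adjust = FALSE) {
  norm <- function(x) toupper(trimws(x))
  de_lncrnas <- unique(norm(de_lncrnas))
  de_genes <- unique(norm(de_genes))
  background <- unique(norm(background))
  de_genes <- intersect(de_genes, background)

  tf_lncrna$tf_symbol <- norm(tf_lncrna$tf_symbol)
  tf_lncrna$target_symbol <- norm(tf_lncrna$target_symbol)
  tf_tg$tf_symbol <- norm(tf_tg$tf_symbol)
  tf_tg$target_symbol <- norm(tf_tg$target_symbol)
  if (!is.null(rank_filter) && "rank" %in% names(tf_tg)) {
    tf_tg <- tf_tg[tf_tg$rank %in% rank_filter, , drop = FALSE]
  }
  tf_lncrna <- tf_lncrna[!duplicated(tf_lncrna[c("tf_symbol", "target_symbol")]), ]
  tf_tg <- tf_tg[!duplicated(tf_tg[c("tf_symbol", "target_symbol")]), ]

  tfs <- sort(unique(c(tf_lncrna$tf_symbol, tf_tg$tf_symbol)))
  tf_table <- do.call(rbind, lapply(tfs, function(tf) {
    targets <- tf_tg$target_symbol[tf_tg$tf_symbol == tf]
    data.frame(tf = tf,
               n_targets = length(intersect(targets, background)),
               n_de_targets = length(intersect(targets, de_genes)),
               p = tf_enrichment(targets, de_genes, background),
               stringsAsFactors = FALSE)
  })) %||% data.frame(tf = character(), n_targets = integer(),
                      n_de_targets = integer(), p = numeric())
  tf_table$adj_p <- p.adjust(tf_table$p, method = "BH")
  tf_table$enriched <- (if (adjust) tf_table$adj_p else tf_table$p) < alpha

  enriched <- tf_table$tf[tf_table$enriched]
  if (!length(enriched)) {
    warning("no TF enriched at alpha = ", alpha, "; network is empty")
  }
  e_lnc <- tf_lncrna[tf_lncrna$tf_symbol %in% enriched &
                       tf_lncrna$target_symbol %in% de_lncrnas, , drop = FALSE]
  e_tg <- tf_tg[tf_tg$tf_symbol %in% enriched &
                  tf_tg$target_symbol %in% de_genes, , drop = FALSE]
  edges <- rbind(
    if (nrow(e_lnc)) data.frame(tf = e_lnc$tf_symbol, target = e_lnc$target_symbol,
                                target_kind = "lncRNA", stringsAsFactors = FALSE),
    if (nrow(e_tg)) data.frame(tf = e_tg$tf_symbol, target = e_tg$target_symbol,
                               target_kind = "gene", stringsAsFactors = FALSE)
  ) %||% data.frame(tf = character(), target = character(),
                    target_kind = character())
  edges$tf_p <- tf_table$p[match(edges$tf, tf_table$tf)]
  rownames(edges) <- NULL
  structure(list(tf_table = tf_table, edges = edges, alpha = alpha),
            class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat(sprintf(
    "context_network: %d enriched TF(s), %d edges (%d TF-lncRNA, %d TF-gene)\n",
    sum(x$tf_table$enriched), nrow(x$edges),
    sum(x$edges$target_kind == "lncRNA"), sum(x$edges$target_kind == "gene")))
  invisible(x)
}

#' Write a context network as a flat TSV edge list
#'
#' @param net a [build_context_network()] result.
#' @param path output TSV path.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "context_network"))
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
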