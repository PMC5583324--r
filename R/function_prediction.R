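#' Right-sided hypergeometric pathway enrichment of a module's genes
#'
#' Right-sided Fisher test of the overlap between a module's coding genes
#' and a pathway gene set over a background universe; the p-value is the
#' upper tail of the hypergeometric distribution on the 2x2 table. lncRNA
#' members must be removed before calling (pathways are coding gene sets).
#'
#' @param module_genes character vector of the module's coding gene symbols
#'   (subset of `background`).
#' @param pathway_genes character vector of pathway member symbols.
#' @param background gene universe.
#' @return upper-tail p-value `P(X >= |overlap|)`.
#' @export
module_pathway_enrichment <- function(module_genes, pathway_genes, background) {
  background <- unique(toupper(background))
  if (!length(background)) stop("empty background universe")
  module_genes <- unique(toupper(module_genes))
  if (!all(module_genes %in% background)) {
    stop("module_genes must be a subset of the background universe")
  }
  pathway_genes <- intersect(unique(toupper(pathway_genes)), background)
  N <- length(background)
  K <- length(pathway_genes)
  n <- length(module_genes)
  k <- length(intersect(module_genes, pathway_genes))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrich every co-regulatory module against a pathway collection
#'
#' Tests each module's coding genes against every pathway with
#' [module_pathway_enrichment()] and applies Benjamini-Hochberg correction.
#' By default the correction family is the set of pathways within one
#' module; `adjust_by = "global"` corrects across all (module, pathway)
#' pairs instead. Modules with no coding gene after removing lncRNAs are
#' skipped with a warning.
#'
#' @param modules a [extract_modules()] result (rows may come from several
#'   TFs concatenated with `rbind`).
#' @param pathways named list of pathway gene sets (see [read_gmt()]).
#' @param background coding gene universe.
#' @param lncrna_symbols symbols to treat as lncRNAs (excluded from the
#'   2x2 table).
#' @param adjust_by `"module"` (default) or `"global"` BH family.
#' @param alpha significance threshold on the adjusted p-value (default
#'   0.1), recorded in the `significant` column.
#' @return data frame: `tf`, `module_id`, `pathway_id`, `overlap`,
#'   `n_module_genes`, `n_pathway`, `p`, `adj_p`, `significant`.
#' @export
enrich_all_modules <- function(modules, pathways, background, lncrna_symbols,
                               adjust_by = c("module", "global"),
                               alpha = 0.1) {
  adjust_by <- match.arg(adjust_by)
  stopifnot(is.list(pathways))
  empty <- data.frame(tf = character(), module_id = character(),
                      pathway_id = character(), overlap = integer(),
                      n_module_genes = integer(), n_pathway = integer(),
                      p = numeric(), adj_p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (nrow(modules) == 0L || length(pathways) == 0L) return(empty)
  background <- unique(toupper(background))
  lncrna_symbols <- unique(toupper(lncrna_symbols))
  rows <- list()
  for (i in seq_len(nrow(modules))) {
    members <- toupper(modules$members[[i]])
    genes <- intersect(setdiff(members, lncrna_symbols), background)
    if (!length(genes)) {
      warning("module ", modules$module_id[i],
              " has no coding genes in the background; skipped")
      next
    }
    for (pw in names(pathways)) {
      pw_genes <- intersect(unique(toupper(pathways[[pw]])), background)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = modules$tf[i], module_id = modules$module_id[i],
        pathway_id = pw, overlap = length(intersect(genes, pw_genes)),
        n_module_genes = length(genes), n_pathway = length(pw_genes),
        p = module_pathway_enrichment(genes, pw_genes, background),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (adjust_by == "module") {
    out$adj_p <- stats::ave(out$p, out$module_id,
                            FUN = function(p) p.adjust(p, method = "BH"))
  } else {
    out$adj_p <- p.adjust(out$p, method = "BH")
  }
  out$significant <- out$adj_p < alpha
  rownames(out) <- NULL
  out
}

#' Transfer enriched pathways to a module's lncRNA members
#'
#' Guilt-by-association: every lncRNA member of a module is predicted to be
#' involved in the pathways significantly enriched (adjusted p below the
#' threshold used in [enrich_all_modules()]) by the module's coding genes.
#' The lncRNA's expression direction in CAFs can be carried along from the
#' differential-expression stage.
#'
#' @param modules a [extract_modules()] result.
#' @param enrichment a [enrich_all_modules()] table.
#' @param lncrna_symbols symbols treated as lncRNAs.
#' @param directions optional named character vector (symbol -> `"up"` /
#'   `"down"` in CAFs).
#' @return data frame: `lncrna`, `direction`, `tf`, `module_id`,
#'   `pathway_id`, `p`, `adj_p`; zero rows if no module contains a lncRNA
#'   or no pathway is significant.
#' @export
assign_lncrna_functions <- function(modules, enrichment, lncrna_symbols,
                                    directions = NULL) {
  lncrna_symbols <- unique(toupper(lncrna_symbols))
  rows <- list()
  for (i in seq_len(nrow(modules))) {
    lncs <- intersect(toupper(modules$members[[i]]), lncrna_symbols)
    if (!length(lncs)) next
    sig <- enrichment[enrichment$module_id == modules$module_id[i] &
                        enrichment$significant, , drop = FALSE]
    if (!nrow(sig)) next
    for (l in lncs) {
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna = l,
        direction = if (!is.null(directions) && l %in% toupper(names(directions)))
          unname(directions[match(l, toupper(names(directions)))])
        else NA_character_,
        tf = modules$tf[i], module_id = modules$module_id[i],
        pathway_id = sig$pathway_id, p = sig$p, adj_p = sig$adj_p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(lncrna = character(), direction = character(),
               tf = character(), module_id = character(),
               pathway_id = character(), p = numeric(), adj_p = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select TFs whose predominant module meets the reporting criteria
#'
#' A TF is reportable when its predominant (largest significant)
#' co-regulatory module enriches more than `min_pathways` pathways,
#' contains at least one lncRNA, and has fewer lncRNA members than coding
#' gene members.
#'
#' @param modules a [extract_modules()] result (all TFs concatenated).
#' @param enrichment a [enrich_all_modules()] table.
#' @param lncrna_symbols symbols treated as lncRNAs.
#' @param min_pathways strict lower bound on the number of enriched
#'   pathways (default 5, i.e. more than 5 are required).
#' @return data frame: `tf`, `module_id`, `n_pathways`, `n_lncrna`,
#'   `n_genes`, `reportable`.
#' @export
select_reportable_tfs <- function(modules, enrichment, lncrna_symbols,
                                  min_pathways = 5) {
  lncrna_symbols <- unique(toupper(lncrna_symbols))
  pred <- modules[modules$predominant, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pred)), function(i) {
    members <- toupper(pred$members[[i]])
    n_lnc <- length(intersect(members, lncrna_symbols))
    n_gene <- length(setdiff(members, lncrna_symbols))
    n_pw <- sum(enrichment$module_id == pred$module_id[i] &
                  enrichment$significant)
    data.frame(tf = pred$tf[i], module_id = pred$module_id[i],
               n_pathways = n_pw, n_lncrna = n_lnc, n_genes = n_gene,
               reportable = n_pw > min_pathways & n_lnc >= 1L & n_lnc < n_gene,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(tf = character(), module_id = character(),
               n_pathways = integer(), n_lncrna = integer(),
               n_genes = integer(), reportable = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
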