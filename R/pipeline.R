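#' Default pipeline parameters
#'
#' Every workflow threshold appears explicitly: the differential-expression
#' filter (|logFC| > 1, p < 0.05, adjusted p < 0.1), SMOTE percentages
#' (50/50, k = 5), 100 evaluation iterations, TF enrichment alpha 0.05,
#' cluster alpha 0.05 on 1 - AU, pathway adjusted-p alpha 0.1, and the
#' more-than-5-pathways reporting rule.
#'
#' @return named list of defaults, overridable through the `params` block
#'   of the pipeline configuration.
#' @export
default_pipeline_params <- function() {
  list(
    logfc_cutoff = 1, p_cutoff = 0.05, adj_p_cutoff = 0.1,
    percent_over = 50, percent_under = 50, smote_k = 5,
    n_iter = 100, models = c("lr", "rf", "svm"),
    rf_trees = 500, svm_cost = 1, fraction = 0.5,
    tf_alpha = 0.05, rank_filter = "Rank 1",
    scales = seq(0.5, 1.4, by = 0.1), n_boot = 1000,
    cluster_alpha = 0.05,
    pathway_alpha = 0.1, adjust_by = "module",
    min_pathways = 5,
    seed = 1
  )
}

.validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  params <- utils::modifyList(default_pipeline_params(), config$params %||% list())
  for (a in c("tf_alpha", "cluster_alpha", "pathway_alpha")) {
    if (params[[a]] <= 0 || params[[a]] >= 1) {
      stop("'", a, "' must lie in (0, 1)")
    }
  }
  if (is.null(config$synthetic)) {
    req <- c("expression", "labels", "annotation", "tf_lncrna", "tf_tg", "pathways")
    paths <- config$inputs %||% list()
    missing <- setdiff(req, names(paths))
    if (length(missing)) {
      stop("configuration must provide either a 'synthetic' block or input ",
           "paths for: ", paste(missing, collapse = ", "))
    }
    absent <- unlist(paths[req])[!file.exists(unlist(paths[req]))]
    if (length(absent)) {
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
    }
  }
  list(params = params, synthetic = config$synthetic, inputs = config$inputs)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the complete workflow
#'
#' Executes, in order: differential expression, class balancing, predictive
#' evaluation, context-network construction, per-TF co-regulatory module
#' extraction with multiscale bootstrap, and pathway-based lncRNA function
#' prediction. Each stage's outputs are written to `outdir` before the next
#' stage begins, so a failure leaves all completed stages on disk; the
#' failing stage is named in the error. A `manifest.json` echoes the
#' parameters, seed and per-stage record counts.
#'
#' @param config either a path to a YAML configuration file or a list, with
#'   entries `synthetic` (arguments to [synthetic_config()]) or `inputs`
#'   (paths: `expression`, `labels`, `annotation`, `tf_lncrna`, `tf_tg`,
#'   `pathways`), and an optional `params` block overriding
#'   [default_pipeline_params()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- .validate_pipeline_config(config)
  p <- cfg$params
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # ---- inputs -------------------------------------------------------------
  inp <- stage("inputs", {
    if (!is.null(cfg$synthetic)) {
      syn_args <- cfg$synthetic
      syn_args$seed <- syn_args$seed %||% p$seed
      sim <- simulate_study(do.call(synthetic_config, syn_args))
      idir <- file.path(outdir, "inputs")
      dir.create(idir, showWarnings = FALSE)
      write_expression_tsv(sim$data, file.path(idir, "expression.tsv"),
                           file.path(idir, "labels.tsv"),
                           file.path(idir, "annotation.tsv"))
      write_interactions_tsv(sim$tf_lncrna, file.path(idir, "tf_lncrna.tsv"))
      write_interactions_tsv(sim$tf_tg, file.path(idir, "tf_tg.tsv"))
      write_gmt(sim$pathways, file.path(idir, "pathways.gmt"))
      sim
    } else {
      list(
        data = read_expression_tsv(cfg$inputs$expression, cfg$inputs$labels,
                                   cfg$inputs$annotation),
        tf_lncrna = read_interactions_tsv(cfg$inputs$tf_lncrna),
        tf_tg = read_interactions_tsv(cfg$inputs$tf_tg),
        pathways = read_gmt(cfg$inputs$pathways),
        truth = NULL
      )
    }
  })
  data <- inp$data
  ann <- data$annotation
  lnc_symbols <- unique(ann$symbol[ann$biotype == "lncRNA"])
  coding_symbols <- unique(ann$symbol[ann$biotype == "coding"])

  # ---- stage 1: differential expression -----------------------------------
  de <- stage("differential_expression", {
    res <- moderated_t(data, logfc_cutoff = p$logfc_cutoff,
                       p_cutoff = p$p_cutoff, adj_p_cutoff = p$adj_p_cutoff)
    lnc <- collapse_to_symbols(res, biotype = "lncRNA")
    gene <- collapse_to_symbols(res, biotype = "coding")
    .write_tsv(as.data.frame(res), file.path(outdir, "de_probes.tsv"))
    .write_tsv(lnc, file.path(outdir, "de_lncrna_symbols.tsv"))
    .write_tsv(gene, file.path(outdir, "de_gene_symbols.tsv"))
    list(result = res, lncrna = lnc, gene = gene)
  })
  counts$de_probes <- sum(de$result$is_de)
  counts$de_lncrna_symbols <- nrow(de$lncrna)
  counts$de_gene_symbols <- nrow(de$gene)
  de_lnc_probes <- de$result$feature_id[de$result$is_de &
                                          de$result$biotype == "lncRNA"]

  # ---- stage 2: class balancing -------------------------------------------
  bal <- stage("class_balance", {
    if (!length(de_lnc_probes)) stop("no DE lncRNA probes to balance on")
    b <- balance(data, feature_space = de_lnc_probes,
                 percent_over = p$percent_over, percent_under = p$percent_under,
                 k = min(p$smote_k, sum(data$sample_labels == "NOF") - 1L),
                 seed = p$seed)
    .write_tsv(b$provenance, file.path(outdir, "balanced_samples.tsv"))
    b
  })
  counts$balanced_minority <- sum(bal$sample_labels == "NOF")
  counts$balanced_majority <- sum(bal$sample_labels == "CAF")

  # ---- stage 3: predictive evaluation -------------------------------------
  ev <- stage("predictive_evaluation", {
    e <- evaluate_models(bal, n_iter = p$n_iter, models = p$models,
                         seed = p$seed, fraction = p$fraction,
                         logfc_cutoff = p$logfc_cutoff, p_cutoff = p$p_cutoff,
                         rf_trees = p$rf_trees, svm_cost = p$svm_cost)
    st <- feature_stability(e)
    .write_tsv(e$summary, file.path(outdir, "model_performance.tsv"))
    .write_tsv(st, file.path(outdir, "feature_stability.tsv"))
    if ("rf" %in% p$models) {
      .write_tsv(rf_importance(e), file.path(outdir, "rf_importance.tsv"))
    }
    if (length(p$models) > 1L) {
      .write_tsv(compare_models(e), file.path(outdir, "model_comparisons.tsv"))
    }
    list(eval = e, stability = st)
  })
  counts$stable_features <- sum(ev$stability$stable)

  # ---- stage 4: context network -------------------------------------------
  de_lnc_syms <- de$lncrna$symbol
  de_gene_syms <- de$gene$symbol
  net <- stage("network_construction", {
    n <- build_context_network(inp$tf_lncrna, inp$tf_tg,
                               de_lncrnas = de_lnc_syms,
                               de_genes = de_gene_syms,
                               background = coding_symbols,
                               alpha = p$tf_alpha, rank_filter = p$rank_filter)
    .write_tsv(n$tf_table, file.path(outdir, "tf_enrichment.tsv"))
    write_network_tsv(n, file.path(outdir, "context_network.tsv"))
    n
  })
  counts$enriched_tfs <- sum(net$tf_table$enriched)
  counts$network_edges <- nrow(net$edges)

  # ---- stage 5: co-regulatory modules -------------------------------------
  mods <- stage("coregulatory_modules", {
    enriched <- unique(net$edges$tf)
    all_mods <- list()
    for (tf in enriched) {
      targets <- unique(net$edges$target[net$edges$tf == tf])
      # representative probe per symbol: smallest DE p-value
      reps <- vapply(targets, function(sym) {
        probes <- de$result[toupper(de$result$symbol) == sym, , drop = FALSE]
        probes$feature_id[which.min(probes$p)]
      }, character(1))
      if (length(targets) < 3L) next
      prof <- data$values[reps, , drop = FALSE]
      rownames(prof) <- targets
      tree <- multiscale_bootstrap(prof, scales = p$scales, n_boot = p$n_boot,
                                   seed = derive_seed(p$seed, 500L + match(tf, enriched)))
      write_annotated_newick(tree, file.path(outdir, sprintf("dendrogram_%s.nwk", tf)))
      all_mods[[tf]] <- extract_modules(tree, tf = tf, alpha = p$cluster_alpha)
    }
    m <- do.call(rbind, all_mods) %||% extract_modules_empty()
    flat <- if (nrow(m)) {
      do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
        data.frame(tf = m$tf[i], module_id = m$module_id[i],
                   member = m$members[[i]],
                   member_kind = ifelse(m$members[[i]] %in% toupper(lnc_symbols),
                                        "lncRNA", "gene"),
                   cluster_p = m$cluster_p[i], predominant = m$predominant[i],
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(tf = character(), module_id = character(), member = character(),
                 member_kind = character(), cluster_p = numeric(),
                 predominant = logical())
    }
    .write_tsv(flat, file.path(outdir, "coreg_modules.tsv"))
    m
  })
  counts$modules <- nrow(mods)

  # ---- stage 6: function prediction ---------------------------------------
  fun <- stage("function_prediction", {
    enr <- enrich_all_modules(mods, inp$pathways,
                              background = coding_symbols,
                              lncrna_symbols = lnc_symbols,
                              adjust_by = p$adjust_by, alpha = p$pathway_alpha)
    dirs <- setNames(de$lncrna$direction, de$lncrna$symbol)
    pred <- assign_lncrna_functions(mods, enr, lncrna_symbols = lnc_symbols,
                                    directions = dirs)
    rep_tfs <- select_reportable_tfs(mods, enr, lncrna_symbols = lnc_symbols,
                                     min_pathways = p$min_pathways)
    .write_tsv(enr, file.path(outdir, "module_pathway_enrichment.tsv"))
    .write_tsv(pred, file.path(outdir, "lncrna_function_predictions.tsv"))
    .write_tsv(rep_tfs, file.path(outdir, "reportable_tfs.tsv"))
    list(enrichment = enr, predictions = pred, reportable = rep_tfs)
  })
  counts$significant_module_pathways <- sum(fun$enrichment$significant)
  counts$lncrna_predictions <- nrow(fun$predictions)
  counts$reportable_tfs <- sum(fun$reportable$reportable)

  manifest <- list(
    package = "caflncnet",
    version = as.character(packageVersion("caflncnet")),
    seed = p$seed,
    params = p[order(names(p))],
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(data = data, truth = inp$truth, de = de, balanced = bal,
                 evaluation = ev, network = net, modules = mods,
                 functions = fun, manifest = manifest))
}

# zero-row module table with the right columns
extract_modules_empty <- function() {
  empty <- data.frame(tf = character(), module_id = character(),
                      node = integer(), size = integer(),
                      cluster_p = numeric(), predominant = logical(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  structure(empty, class = c("coreg_modules", "data.frame"))
}
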