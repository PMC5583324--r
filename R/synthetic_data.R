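#' Configuration for the synthetic study generator
#'
#' The defaults emulate the design of the ovarian fibroblast microarray
#' study the workflow targets: a strongly imbalanced cohort (10 NOF vs 67
#' CAF samples), a few thousand probes of which a block is re-annotated as
#' lncRNA probes with multiple probes per symbol, a planted set of
#' differentially expressed symbols with |log2 fold change| above the
#' workflow's cutoff, per-TF co-regulated target blocks driven by a shared
#' latent factor, and pathway gene sets enriched for those blocks.
#'
#' The latent-factor construction gives module members an expected pairwise
#' Pearson correlation of
#' `module_latent_sd^2 / (module_latent_sd^2 + noise_sd^2)`, so tests can
#' target a correlation level directly (the defaults give 0.9).
#'
#' @param n_minority,n_majority NOF and CAF sample counts.
#' @param n_features total probe count.
#' @param n_lncrna_probes number of probes (the first block) annotated as
#'   lncRNA; the rest are protein coding.
#' @param probes_per_symbol probes mapping to each gene symbol; must divide
#'   `n_de_features`.
#' @param n_de_features number of probes carrying a planted two-group shift.
#' @param de_effect absolute log2 mean shift (CAF minus NOF) of planted
#'   features; the sign per symbol is random, except that all members of
#'   one TF's module share the TF's direction (a TF activates or represses
#'   its targets coherently). `0` gives a global null.
#' @param noise_sd per-probe Gaussian noise standard deviation (log2 units).
#' @param n_tfs number of transcription factors with planted target modules.
#' @param targets_per_tf module size per TF; members are drawn from the
#'   planted DE symbols (roughly one third lncRNA, the rest coding) and are
#'   disjoint across TFs.
#' @param decoys_per_tf random non-module interaction-table edges per TF.
#' @param module_latent_sd standard deviation of each TF's shared latent
#'   factor (controls within-module correlation, see above).
#' @param n_pathways,pathway_size number and size of generated gene sets.
#' @param planted_enrichment_fraction fraction of a TF's coding module
#'   members seeded into each pathway planted for that TF.
#' @param planted_pathway_counts optional integer vector (length `n_tfs`)
#'   giving how many pathways are planted for each TF; the default assigns
#'   pathways to TFs round-robin. Pathways beyond the planted ones are
#'   random background sets.
#' @param seed master integer seed; all sub-generators derive child seeds
#'   from it deterministically.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_minority = 10, n_majority = 67,
                             n_features = 2000, n_lncrna_probes = 240,
                             probes_per_symbol = 2, n_de_features = 60,
                             de_effect = 2, noise_sd = 0.5,
                             n_tfs = 4, targets_per_tf = 6, decoys_per_tf = 10,
                             module_latent_sd = 1.5,
                             n_pathways = 10, pathway_size = 20,
                             planted_enrichment_fraction = 1,
                             planted_pathway_counts = NULL,
                             seed = 1) {
  .assert_count(n_minority, "n_minority")
  .assert_count(n_majority, "n_majority")
  .assert_count(n_features, "n_features")
  .assert_count(n_lncrna_probes, "n_lncrna_probes")
  .assert_count(probes_per_symbol, "probes_per_symbol")
  .assert_count(n_de_features, "n_de_features", min = 0L)
  .assert_count(n_tfs, "n_tfs", min = 0L)
  .assert_count(targets_per_tf, "targets_per_tf", min = 0L)
  .assert_count(decoys_per_tf, "decoys_per_tf", min = 0L)
  .assert_count(n_pathways, "n_pathways", min = 0L)
  .assert_count(pathway_size, "pathway_size")
  .assert_fraction(planted_enrichment_fraction, "planted_enrichment_fraction")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (!is.numeric(de_effect) || de_effect < 0) stop("'de_effect' must be >= 0")
  if (!is.numeric(module_latent_sd) || module_latent_sd < 0) {
    stop("'module_latent_sd' must be >= 0")
  }
  if (n_de_features > n_features) stop("n_de_features exceeds n_features")
  if (n_lncrna_probes > n_features) stop("n_lncrna_probes exceeds n_features")
  if (n_de_features %% probes_per_symbol != 0) {
    stop("n_de_features must be a multiple of probes_per_symbol ",
         "(differential expression is planted at the symbol level)")
  }
  n_de_sym <- n_de_features %/% probes_per_symbol
  if (n_tfs > 0 && n_tfs * targets_per_tf > n_de_sym) {
    stop("not enough planted DE symbols to populate disjoint TF modules: ",
         sprintf("need %d, have %d", n_tfs * targets_per_tf, n_de_sym))
  }
  if (!is.null(planted_pathway_counts)) {
    if (length(planted_pathway_counts) != n_tfs ||
        any(planted_pathway_counts < 0) ||
        sum(planted_pathway_counts) > n_pathways) {
      stop("planted_pathway_counts must have length n_tfs and sum <= n_pathways")
    }
  }
  structure(
    list(n_minority = as.integer(n_minority), n_majority = as.integer(n_majority),
         n_features = as.integer(n_features),
         n_lncrna_probes = as.integer(n_lncrna_probes),
         probes_per_symbol = as.integer(probes_per_symbol),
         n_de_features = as.integer(n_de_features),
         de_effect = de_effect, noise_sd = noise_sd,
         n_tfs = as.integer(n_tfs), targets_per_tf = as.integer(targets_per_tf),
         decoys_per_tf = as.integer(decoys_per_tf),
         module_latent_sd = module_latent_sd,
         n_pathways = as.integer(n_pathways), pathway_size = as.integer(pathway_size),
         planted_enrichment_fraction = planted_enrichment_fraction,
         planted_pathway_counts = planted_pathway_counts,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# lncRNA share of each TF module: about one third, at least one, and at
# least one coding member so modules can carry pathway signal
.lnc_per_tf <- function(targets_per_tf) {
  if (targets_per_tf < 2L) return(0L)
  min(targets_per_tf - 1L, max(1L, as.integer(round(0.3 * targets_per_tf))))
}

#' Generate a synthetic labelled expression matrix with planted truth
#'
#' Draws Gaussian log2 expression for `n_features` probes over
#' `n_minority + n_majority` samples. Probes of one symbol share the
#' symbol's baseline and group means plus independent probe noise, so
#' probe-level differential-expression calls for a symbol usually agree.
#' Planted DE symbols get a CAF-minus-NOF mean shift of `+/- de_effect`;
#' TF-module members additionally load on their TF's shared latent factor,
#' which induces high within-module pairwise correlation.
#'
#' @param cfg a [synthetic_config()].
#' @return a list with elements `data` (a [labelled_expression()]) and
#'   `truth` (class `planted_truth`: planted DE features/symbols and
#'   directions, TF module membership, the planted TF/pathway pairing, and
#'   the symbol universe by biotype).
#' @export
generate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(derive_seed(cfg$seed, 1L))

  n_samp <- cfg$n_minority + cfg$n_majority
  sample_ids <- c(sprintf("NOF_%02d", seq_len(cfg$n_minority)),
                  sprintf("CAF_%02d", seq_len(cfg$n_majority)))
  labels <- setNames(rep(c("NOF", "CAF"), c(cfg$n_minority, cfg$n_majority)),
                     sample_ids)

  pps <- cfg$probes_per_symbol
  n_lnc <- cfg$n_lncrna_probes
  n_cod <- cfg$n_features - n_lnc
  feature_id <- sprintf("P%05d", seq_len(cfg$n_features))
  symbol <- c(sprintf("LNC%04d", ceiling(seq_len(n_lnc) / pps)),
              if (n_cod > 0) sprintf("GENE%04d", ceiling(seq_len(n_cod) / pps)))
  biotype <- rep(c("lncRNA", "coding"), c(n_lnc, n_cod))
  annotation <- data.frame(feature_id = feature_id, symbol = symbol,
                           biotype = biotype, stringsAsFactors = FALSE)

  # symbols carrying the full probe multiplicity (block remainders excluded
  # so planted probe counts come out exact)
  sym_counts <- table(symbol)
  full_syms <- names(sym_counts)[sym_counts == pps]
  lnc_syms_full <- grep("^LNC", full_syms, value = TRUE)
  cod_syms_full <- grep("^GENE", full_syms, value = TRUE)

  n_de_sym <- cfg$n_de_features %/% pps
  lnc_per_tf <- .lnc_per_tf(cfg$targets_per_tf)
  cod_per_tf <- cfg$targets_per_tf - lnc_per_tf
  need_lnc <- cfg$n_tfs * lnc_per_tf
  need_cod <- cfg$n_tfs * cod_per_tf
  if (need_lnc + need_cod > n_de_sym) {
    stop("not enough planted DE symbols to populate disjoint TF modules: ",
         sprintf("need %d, have %d", need_lnc + need_cod, n_de_sym))
  }
  n_de_lnc <- min(max(need_lnc, as.integer(round(n_de_sym / 3))),
                  n_de_sym - need_cod)
  n_de_cod <- n_de_sym - n_de_lnc
  if (n_de_lnc > length(lnc_syms_full) || n_de_cod > length(cod_syms_full)) {
    stop("feature space too small for the requested planted DE symbols")
  }
  de_lnc_syms <- sample(lnc_syms_full, n_de_lnc)
  de_cod_syms <- sample(cod_syms_full, n_de_cod)
  de_syms <- c(de_lnc_syms, de_cod_syms)
  sym_direction <- setNames(sample(c("up", "down"), length(de_syms),
                                   replace = TRUE), de_syms)
  # a TF drives its whole module coherently (activation or repression), so
  # module members share one direction; other DE symbols stay independent
  tf_dir <- sample(c("up", "down"), cfg$n_tfs, replace = TRUE)

  # disjoint TF modules drawn from the planted DE symbols
  tf_names <- if (cfg$n_tfs > 0) sprintf("TF%02d", seq_len(cfg$n_tfs)) else character()
  tf_modules <- list()
  for (i in seq_along(tf_names)) {
    lnc_m <- if (lnc_per_tf > 0) de_lnc_syms[((i - 1) * lnc_per_tf + 1):(i * lnc_per_tf)] else character()
    cod_m <- if (cod_per_tf > 0) de_cod_syms[((i - 1) * cod_per_tf + 1):(i * cod_per_tf)] else character()
    feats <- annotation$feature_id[annotation$symbol %in% c(lnc_m, cod_m)]
    tf_modules[[tf_names[i]]] <- list(symbols = c(lnc_m, cod_m), lncrna = lnc_m,
                                      coding = cod_m, features = feats)
    sym_direction[c(lnc_m, cod_m)] <- tf_dir[i]
  }

  # per-symbol baseline on the log2 scale, typical of RMA summaries
  all_syms <- unique(symbol)
  mu <- setNames(rnorm(length(all_syms), mean = 7, sd = 1), all_syms)
  shift <- setNames(numeric(length(all_syms)), all_syms)
  shift[de_syms] <- ifelse(sym_direction == "up", cfg$de_effect, -cfg$de_effect)

  vals <- matrix(rnorm(cfg$n_features * n_samp, sd = cfg$noise_sd),
                 nrow = cfg$n_features, ncol = n_samp,
                 dimnames = list(feature_id, sample_ids))
  vals <- vals + mu[symbol]
  caf <- labels == "CAF"
  vals[, caf] <- vals[, caf] + shift[symbol]
  if (cfg$module_latent_sd > 0) {
    for (tf in tf_names) {
      f <- rnorm(n_samp, sd = cfg$module_latent_sd)
      rows <- symbol %in% tf_modules[[tf]]$symbols
      vals[rows, ] <- vals[rows, ] + rep(f, each = sum(rows))
    }
  }

  de_features <- annotation$feature_id[annotation$symbol %in% de_syms]
  de_direction <- setNames(
    sym_direction[annotation$symbol[match(de_features, annotation$feature_id)]],
    de_features)

  # planted TF/pathway pairing (consumed by generate_pathways)
  pw_ids <- if (cfg$n_pathways > 0) sprintf("PW%02d", seq_len(cfg$n_pathways)) else character()
  pw_tf <- rep(NA_character_, cfg$n_pathways)
  if (cfg$n_tfs > 0 && cfg$n_pathways > 0) {
    if (is.null(cfg$planted_pathway_counts)) {
      pw_tf <- rep_len(tf_names, cfg$n_pathways)
    } else {
      planted <- rep(tf_names, cfg$planted_pathway_counts)
      pw_tf[seq_along(planted)] <- planted
    }
  }
  pathway_truth <- data.frame(pathway_id = pw_ids, tf = pw_tf,
                              stringsAsFactors = FALSE)

  truth <- structure(
    list(de_features = de_features, de_symbols = de_syms,
         de_direction = de_direction, symbol_direction = sym_direction,
         tf_modules = tf_modules, pathway_truth = pathway_truth,
         symbols_lncrna = unique(symbol[biotype == "lncRNA"]),
         symbols_coding = unique(symbol[biotype == "coding"])),
    class = "planted_truth"
  )
  list(data = labelled_expression(vals, labels, annotation), truth = truth)
}

#' Generate TF interaction tables from planted truth
#'
#' Emulates ChIPBase-style TF -> lncRNA and ORTI-style TF -> target-gene
#' flat files: each TF gets edges to its planted module members (split by
#' biotype into the two tables) plus `decoys_per_tf` edges to non-module
#' symbols — half of them cross-talk edges to DE symbols outside the
#' module, the rest random background symbols. All rows carry evidence
#' rank `"Rank 1"`.
#'
#' @param cfg a [synthetic_config()].
#' @param truth planted truth from [generate_expression()].
#' @return list with data frames `tf_lncrna` and `tf_tg`, each with columns
#'   `tf_symbol`, `target_symbol`, `rank`.
#' @export
generate_interaction_tables <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "planted_truth"))
  set.seed(derive_seed(cfg$seed, 2L))
  empty <- data.frame(tf_symbol = character(), target_symbol = character(),
                      rank = character(), stringsAsFactors = FALSE)
  rows_lnc <- list(empty)
  rows_tg <- list(empty)
  for (tf in names(truth$tf_modules)) {
    m <- truth$tf_modules[[tf]]
    # half the decoys are cross-talk edges to DE symbols outside every
    # module (TFs bind many differentially expressed genes beyond their
    # own module), the rest go to random background symbols
    all_module_syms <- unlist(lapply(truth$tf_modules, `[[`, "symbols"),
                              use.names = FALSE)
    de_pool <- setdiff(truth$de_symbols, all_module_syms)
    bg_pool <- setdiff(c(truth$symbols_lncrna, truth$symbols_coding),
                       c(m$symbols, de_pool))
    decoys <- if (cfg$decoys_per_tf > 0) {
      n_de_dec <- min(ceiling(cfg$decoys_per_tf / 2), length(de_pool))
      c(if (n_de_dec > 0) sample(de_pool, n_de_dec),
        sample(bg_pool, min(cfg$decoys_per_tf - n_de_dec, length(bg_pool))))
    } else character()
    lnc_t <- c(m$lncrna, intersect(decoys, truth$symbols_lncrna))
    cod_t <- c(m$coding, intersect(decoys, truth$symbols_coding))
    if (length(lnc_t)) {
      rows_lnc[[length(rows_lnc) + 1L]] <- data.frame(
        tf_symbol = tf, target_symbol = lnc_t, rank = "Rank 1",
        stringsAsFactors = FALSE)
    }
    if (length(cod_t)) {
      rows_tg[[length(rows_tg) + 1L]] <- data.frame(
        tf_symbol = tf, target_symbol = cod_t, rank = "Rank 1",
        stringsAsFactors = FALSE)
    }
  }
  lnc_tab <- do.call(rbind, rows_lnc)
  tg_tab <- do.call(rbind, rows_tg)
  rownames(lnc_tab) <- rownames(tg_tab) <- NULL
  list(tf_lncrna = lnc_tab, tf_tg = tg_tab)
}

#' Generate metastasis-style pathway gene sets from planted truth
#'
#' For every (TF, pathway) pair flagged in the planted pairing, the pathway
#' receives `ceiling(planted_enrichment_fraction * n)` of that TF's coding
#' module members; remaining slots (and entire unplanted pathways) are
#' filled from the coding background at random.
#'
#' @param cfg a [synthetic_config()].
#' @param truth planted truth from [generate_expression()].
#' @return named list of character vectors of coding gene symbols.
#' @export
generate_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "planted_truth"))
  set.seed(derive_seed(cfg$seed, 3L))
  out <- list()
  for (i in seq_len(nrow(truth$pathway_truth))) {
    pw <- truth$pathway_truth$pathway_id[i]
    tf <- truth$pathway_truth$tf[i]
    planted <- character()
    if (!is.na(tf)) {
      cod_m <- truth$tf_modules[[tf]]$coding
      n_plant <- as.integer(ceiling(cfg$planted_enrichment_fraction * length(cod_m)))
      if (n_plant > cfg$pathway_size) {
        stop("pathway_size too small for the requested planted overlap")
      }
      if (n_plant > 0) planted <- sample(cod_m, n_plant)
    }
    fill_pool <- setdiff(truth$symbols_coding, planted)
    fill <- sample(fill_pool, cfg$pathway_size - length(planted))
    out[[pw]] <- c(planted, fill)
  }
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_expression()],
#' [generate_interaction_tables()] and [generate_pathways()] in one call.
#'
#' @param cfg a [synthetic_config()] (or arguments passed to it via `...`).
#' @param ... arguments forwarded to [synthetic_config()] when `cfg` is
#'   missing.
#' @return list with `data`, `truth`, `tf_lncrna`, `tf_tg`, `pathways`.
#' @export
simulate_study <- function(cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- synthetic_config(...)
  gen <- generate_expression(cfg)
  tabs <- generate_interaction_tables(cfg, gen$truth)
  pws <- generate_pathways(cfg, gen$truth)
  list(config = cfg, data = gen$data, truth = gen$truth,
       tf_lncrna = tabs$tf_lncrna, tf_tg = tabs$tf_tg, pathways = pws)
}
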