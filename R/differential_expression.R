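# Newton solve of trigamma(x) = y, used by the method-of-moments fit of the
# scaled-inverse-chi-square prior on feature variances
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Method-of-moments fit of (d0, s0^2): the sampling distribution of
# log(s_g^2) around log(s0^2) has known digamma/trigamma moments when
# s_g^2 ~ s0^2 * F(d_g, d0); matching mean and variance of
# e_g = log(s_g^2) - digamma(d/2) + log(d/2) yields the prior.
.fit_variance_prior <- function(s2, df, quiet = FALSE) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    if (!quiet) warning("too few positive variances to fit a prior; using full pooling")
    return(list(df_prior = Inf, s2_prior = mean(s2[ok]) %||% NA_real_))
  }
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    if (!quiet) {
      warning("variance prior degrees of freedom not estimable; ",
              "pooling all feature variances (d0 = Inf)")
    }
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

# Core moderated-t computation on a plain matrix + label vector; reused by
# the per-split re-selection inside the predictive evaluation loop.
.moderated_t_core <- function(values, labels, prior_df = NULL,
                              logfc_cutoff = 1, p_cutoff = 0.05,
                              adj_p_cutoff = 0.1, quiet = FALSE) {
  labels <- labels[colnames(values)]
  n1 <- sum(labels == "CAF")
  n2 <- sum(labels == "NOF")
  if (n1 < 2L || n2 < 2L) {
    stop("insufficient replication: each class needs at least 2 samples ",
         sprintf("(CAF = %d, NOF = %d)", n1, n2))
  }
  caf <- values[, labels == "CAF", drop = FALSE]
  nof <- values[, labels == "NOF", drop = FALSE]
  m1 <- rowMeans(caf)
  m2 <- rowMeans(nof)
  logfc <- m1 - m2
  df_resid <- n1 + n2 - 2L
  s2 <- (rowSums((caf - m1)^2) + rowSums((nof - m2)^2)) / df_resid

  if (is.null(prior_df)) {
    prior <- .fit_variance_prior(s2, df_resid, quiet = quiet)
  } else if (identical(prior_df, 0) || identical(prior_df, 0L)) {
    prior <- list(df_prior = 0, s2_prior = NA_real_)
  } else {
    stop("'prior_df' must be NULL (estimate) or 0 (disable shrinkage)")
  }

  if (prior$df_prior == 0) {
    s2_tilde <- s2
  } else if (is.infinite(prior$df_prior)) {
    s2_tilde <- rep(prior$s2_prior, length(s2))
  } else {
    s2_tilde <- (prior$df_prior * prior$s2_prior + df_resid * s2) /
      (prior$df_prior + df_resid)
  }

  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- logfc / se
  df_total <- df_resid + prior$df_prior
  p <- 2 * pt(-abs(t_mod), df = df_total)
  # features whose shrunken variance is still zero carry no information
  p[!is.finite(t_mod) | s2_tilde == 0] <- NA_real_
  t_mod[s2_tilde == 0 & logfc == 0] <- 0

  adj_p <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  adj_p[tested] <- p.adjust(p[tested], method = "BH")

  res <- data.frame(
    feature_id = rownames(values), logFC = logfc, t_mod = t_mod,
    df_total = rep(df_total, length(logfc)), p = p, adj_p = adj_p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$is_de <- !is.na(res$p) &
    abs(res$logFC) > logfc_cutoff & res$p < p_cutoff & res$adj_p < adj_p_cutoff
  attr(res, "prior") <- prior
  attr(res, "n") <- c(CAF = n1, NOF = n2)
  attr(res, "cutoffs") <- c(logfc = logfc_cutoff, p = p_cutoff, adj_p = adj_p_cutoff)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Moderated t-test differential expression (CAF vs NOF)
#'
#' Empirical-Bayes moderated two-sample t-test on log2 expression. For each
#' feature the pooled residual variance `s_g^2` (with `d_g = n - 2` degrees
#' of freedom) is shrunk towards a prior `s_0^2` estimated together with its
#' degrees of freedom `d_0` from the distribution of `log s_g^2` across
#' features by the method of moments:
#' `s_tilde^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)`. The moderated
#' statistic `t = logFC / (s_tilde * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution with `d_0 + d_g` degrees of freedom, and p-values are
#' Benjamini-Hochberg adjusted over all tested features. `logFC` is the CAF
#' mean minus the NOF mean, so positive values indicate up-regulation in
#' CAFs.
#'
#' Features with zero variance in both classes rely entirely on the shrunken
#' denominator; if the prior carries no weight they are reported with
#' `p = NA` and excluded from the BH family.
#'
#' @param data a [labelled_expression()] object with at least 2 samples per
#'   class.
#' @param prior_df `NULL` to estimate the prior degrees of freedom
#'   (default), or `0` to disable shrinkage and recover the ordinary
#'   pooled-variance t-test.
#' @param logfc_cutoff,p_cutoff,adj_p_cutoff thresholds of the significance
#'   filter `|logFC| > logfc_cutoff & p < p_cutoff & adj_p < adj_p_cutoff`
#'   (all strict) recorded in the `is_de` column.
#' @return a `differential_result` data frame with columns `feature_id`,
#'   `logFC`, `t_mod`, `df_total`, `p`, `adj_p`, `is_de`, plus `symbol` and
#'   `biotype` from the annotation. The fitted prior is stored in
#'   `attr(, "prior")`.
#' @export
moderated_t <- function(data, prior_df = NULL, logfc_cutoff = 1,
                        p_cutoff = 0.05, adj_p_cutoff = 0.1) {
  stopifnot(inherits(data, "labelled_expression"))
  res <- .moderated_t_core(data$values, data$sample_labels, prior_df,
                           logfc_cutoff, p_cutoff, adj_p_cutoff)
  idx <- match(res$feature_id, data$annotation$feature_id)
  res$symbol <- data$annotation$symbol[idx]
  res$biotype <- data$annotation$biotype[idx]
  res
}

#' Apply the differential-expression significance filter
#'
#' Returns the features passing all three gates with strict inequalities:
#' `|logFC| > logfc_cutoff`, `p < p_cutoff`, `adj_p < adj_p_cutoff`.
#'
#' @param result a `differential_result` (or any data frame with columns
#'   `feature_id`, `logFC`, `p`, `adj_p`).
#' @param logfc_cutoff,p_cutoff,adj_p_cutoff filter thresholds.
#' @return character vector of passing feature ids.
#' @export
apply_de_filter <- function(result, logfc_cutoff = 1, p_cutoff = 0.05,
                            adj_p_cutoff = 0.1) {
  stopifnot(all(c("feature_id", "logFC", "p", "adj_p") %in% names(result)))
  keep <- !is.na(result$p) & abs(result$logFC) > logfc_cutoff &
    result$p < p_cutoff & result$adj_p < adj_p_cutoff
  result$feature_id[keep]
}

#' Collapse probe-level DE calls to unique gene symbols
#'
#' One record per distinct symbol among the selected features (optionally
#' restricted by biotype). The representative statistics for a symbol come
#' from its probe with the smallest p-value; direction is `"up"` for
#' positive and `"down"` for negative representative logFC. Symbols whose
#' probes disagree in sign are flagged discordant, get `NA` direction and a
#' warning, and are excluded from direction counts.
#'
#' @param result a `differential_result` data frame (must carry `symbol`;
#'   `biotype` is required only when `biotype` filtering is requested).
#' @param features feature ids to collapse; defaults to the DE set
#'   (`is_de`, or [apply_de_filter()] when `is_de` is absent).
#' @param biotype optional biotype filter (`"lncRNA"` or `"coding"`).
#' @return data frame with one row per symbol: `symbol`, `n_probes`,
#'   `feature_id` (representative probe), `logFC`, `p`, `adj_p`,
#'   `direction`, `discordant`.
#' @export
collapse_to_symbols <- function(result, features = NULL, biotype = NULL) {
  stopifnot(all(c("feature_id", "symbol", "logFC", "p", "adj_p") %in% names(result)))
  if (is.null(features)) {
    features <- if ("is_de" %in% names(result)) {
      result$feature_id[result$is_de]
    } else {
      apply_de_filter(result)
    }
  }
  sub <- result[result$feature_id %in% features, , drop = FALSE]
  if (!is.null(biotype)) {
    if (!"biotype" %in% names(sub)) stop("no biotype column to filter on")
    sub <- sub[sub$biotype %in% biotype, , drop = FALSE]
  }
  if (nrow(sub) == 0L) {
    return(data.frame(symbol = character(), n_probes = integer(),
                      feature_id = character(), logFC = numeric(),
                      p = numeric(), adj_p = numeric(),
                      direction = character(), discordant = logical(),
                      stringsAsFactors = FALSE))
  }
  pieces <- lapply(split(sub, sub$symbol), function(g) {
    rep_row <- g[which.min(g$p), , drop = FALSE]
    disc <- length(unique(sign(g$logFC[g$logFC != 0]))) > 1L
    data.frame(symbol = rep_row$symbol, n_probes = nrow(g),
               feature_id = rep_row$feature_id, logFC = rep_row$logFC,
               p = rep_row$p, adj_p = rep_row$adj_p,
               direction = if (disc) NA_character_ else
                 if (rep_row$logFC > 0) "up" else "down",
               discordant = disc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (any(out$discordant)) {
    warning("probes with opposite DE signs for symbol(s): ",
            paste(out$symbol[out$discordant], collapse = ", "),
            "; excluded from direction counts")
  }
  out[order(out$symbol), , drop = FALSE]
}
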