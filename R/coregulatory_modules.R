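#' Correlation distance between expression profiles
#'
#' `d(x, y) = 1 - r(x, y)` with Pearson (default) or Spearman correlation
#' computed across samples, so `d` lies in `[0, 2]`, identical profiles are
#' at distance 0 and perfectly anti-correlated profiles at distance 2.
#'
#' @param profiles numeric matrix, targets x samples (row names required).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L,
            !is.null(rownames(profiles)))
  sds <- apply(profiles, 1L, sd)
  if (any(sds == 0)) {
    stop("zero-variance profile(s): ",
         paste(head(rownames(profiles)[sds == 0]), collapse = ", "))
  }
  d <- 1 - cor(t(profiles), method = method)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' @param d distance matrix or `dist` object.
#' @return an `hclust` tree with non-decreasing merge heights.
#' @export
average_linkage <- function(d) {
  hclust(as.dist(d), method = "average")
}

# sorted member sets of every internal node of an hclust tree, in merge order
.node_members <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- hc$merge[i, ]
    left <- if (m[1] < 0) hc$labels[-m[1]] else sets[[m[1]]]
    right <- if (m[2] < 0) hc$labels[-m[2]] else sets[[m[2]]]
    sets[[i]] <- sort(c(left, right))
  }
  sets
}

.node_keys <- function(sets) {
  vapply(sets, paste, character(1), collapse = "\x1f")
}

# WLS fit of psi(r) = v*sqrt(r) + c/sqrt(r) for one node; returns the
# approximately unbiased p-value au = 1 - Phi(v - c) and the smoothed
# bootstrap probability 1 - Phi(v + c). Scales whose observed proportion is
# exactly 0 or 1 carry no curve information (psi is infinite) and are
# dropped from the regression; when fewer than two informative scales
# remain the node is saturated and au takes the limiting value 1 (node
# recovered in essentially every replicate) or 0 (never recovered), after
# clamping by the resolution 1/(2B) of the bootstrap.
.fit_au <- function(bp, r, n_boot) {
  if (all(bp == 0)) {
    return(list(au = 0, bp_fit = 0, v = NA_real_, c = NA_real_, fit_ok = FALSE))
  }
  eps <- 1 / (2 * n_boot)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  if (length(unique(round(r, 10))) < 2L) {
    # single scale: the model degenerates to the classical bootstrap
    psi1 <- qnorm(1 - bpc[1])
    return(list(au = 1 - pnorm(psi1), bp_fit = bpc[1],
                v = psi1, c = 0, fit_ok = FALSE))
  }
  # proportions within the bootstrap's resolution of 0 or 1 pin psi at
  # +/- infinity and carry no curve information; the fit needs at least
  # three informative scales to separate v from c
  use <- bp > 1 / n_boot & bp < 1 - 1 / n_boot
  if (sum(use) < 3L) {
    sat <- mean(bp) >= 0.5
    return(list(au = if (sat) 1 - eps else eps,
                bp_fit = if (sat) 1 - eps else eps,
                v = NA_real_, c = NA_real_, fit_ok = FALSE))
  }
  psi <- qnorm(1 - bp[use])
  ru <- r[use]
  X <- cbind(sqrt(ru), 1 / sqrt(ru))
  w <- n_boot * dnorm(psi)^2 / (bp[use] * (1 - bp[use]))
  coefs <- tryCatch({
    if (!all(is.finite(w)) || all(w == 0)) stop("degenerate weights")
    lm.wfit(X, psi, w)$coefficients
  }, error = function(e) lm.fit(X, psi)$coefficients)
  if (anyNA(coefs)) {
    return(list(au = 1 - pnorm(qnorm(1 - bpc[which.min(abs(r - 1))])),
                bp_fit = bpc[which.min(abs(r - 1))],
                v = NA_real_, c = NA_real_, fit_ok = FALSE))
  }
  v <- unname(coefs[1L])
  cc <- unname(coefs[2L])
  list(au = 1 - pnorm(v - cc), bp_fit = 1 - pnorm(v + cc),
       v = v, c = cc, fit_ok = TRUE)
}

#' Multiscale bootstrap cluster support (AU/BP p-values)
#'
#' Clusters target expression profiles by average linkage on correlation
#' distance, then assesses every internal node by multiscale bootstrap
#' resampling: for each scale `r` the samples (columns) are resampled with
#' replacement to size `round(r * n)` and re-clustered, and the bootstrap
#' probability `bp_r` of a node is the fraction of replicates whose tree
#' contains exactly the node's member set. The normal-quantile transform
#' `psi(r) = qnorm(1 - bp_r)` is fitted against
#' `psi(r) = v * sqrt(r) + c / sqrt(r)` by weighted least squares (weights
#' from the delta-method variance of `psi`), giving the approximately
#' unbiased p-value `AU = 1 - pnorm(v - c)`. Scales with degenerate
#' proportions (exactly 0 or 1) are excluded from the fit; nodes observed
#' in essentially all (or no) replicates at every scale take the limiting
#' AU of `1 - 1/(2B)` (or `1/(2B)`). The root has `AU = 1` by convention.
#'
#' @param profiles numeric matrix, targets x samples (at least 3 samples).
#' @param scales relative resampling sizes; default `seq(0.5, 1.4, 0.1)`,
#'   spanning scales below and above 1 as the curve fit requires.
#' @param n_boot bootstrap replicates per scale (default 1000).
#' @param seed optional integer seed for the whole bootstrap.
#' @param method correlation method passed to [correlation_distance()].
#' @return object of class `annotated_dendrogram`: list with `hclust` (the
#'   tree on the original data), `members` (per-node member sets),
#'   `nodes` (data frame: `node`, `size`, `au`, `bp_raw` bootstrap
#'   probability at the scale closest to 1, `v`, `c`, `fit_ok`),
#'   `bp` (node x scale matrix of bootstrap probabilities), `scales`
#'   (actual ratios `round(r*n)/n` used), `n_boot`.
#' @export
multiscale_bootstrap <- function(profiles, scales = seq(0.5, 1.4, by = 0.1),
                                 n_boot = 1000, seed = NULL,
                                 method = "pearson") {
  stopifnot(is.matrix(profiles))
  n <- ncol(profiles)
  if (n < 3L) stop("multiscale bootstrap needs at least 3 samples")
  if (!length(scales) || any(scales <= 0)) stop("scales must be positive")
  .assert_count(n_boot, "n_boot")
  hc <- average_linkage(correlation_distance(profiles, method))
  sets <- .node_members(hc)
  keys <- .node_keys(sets)
  sizes <- lengths(sets)

  .maybe_seed(seed)
  m_per_scale <- pmax(3L, as.integer(round(scales * n)))
  r_actual <- m_per_scale / n
  counts <- matrix(0L, nrow = length(sets), ncol = length(scales))
  tp <- t(profiles)
  for (si in seq_along(scales)) {
    m <- m_per_scale[si]
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, m, replace = TRUE)
      cr <- suppressWarnings(cor(tp[idx, , drop = FALSE], method = method))
      cr[!is.finite(cr)] <- 0
      diag(cr) <- 1
      bh <- hclust(as.dist(1 - cr), method = "average")
      bkeys <- .node_keys(.node_members(bh))
      counts[, si] <- counts[, si] + (keys %in% bkeys)
    }
  }
  bp <- counts / n_boot
  dimnames(bp) <- list(NULL, sprintf("r=%.3f", r_actual))

  near1 <- which.min(abs(r_actual - 1))
  fits <- lapply(seq_along(sets), function(i) .fit_au(bp[i, ], r_actual, n_boot))
  nodes <- data.frame(
    node = seq_along(sets), size = sizes,
    au = vapply(fits, `[[`, numeric(1), "au"),
    bp_raw = bp[, near1],
    v = vapply(fits, `[[`, numeric(1), "v"),
    c = vapply(fits, `[[`, numeric(1), "c"),
    fit_ok = vapply(fits, `[[`, logical(1), "fit_ok"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # the root is present in every replicate by construction
  root <- which.max(sizes)
  nodes$au[root] <- 1
  nodes$fit_ok[root] <- TRUE
  nodes$au <- pmin(pmax(nodes$au, 0), 1)
  structure(list(hclust = hc, members = sets, nodes = nodes, bp = bp,
                 scales = r_actual, n_boot = n_boot),
            class = "annotated_dendrogram")
}

#' @export
print.annotated_dendrogram <- function(x, ...) {
  cat(sprintf(
    "annotated_dendrogram: %d leaves, %d internal nodes, %d scales x %d replicates\n",
    length(x$hclust$labels), nrow(x$nodes), length(x$scales), x$n_boot))
  invisible(x)
}

#' Extract significant co-regulatory modules from an annotated dendrogram
#'
#' Internal nodes (excluding the root) with cluster p-value `1 - AU <
#' alpha` are candidate modules; nested significant nodes are resolved by
#' keeping only the maximal (outermost) ones, and the largest retained
#' module of the TF is flagged predominant (ties broken by smaller cluster
#' p-value).
#'
#' @param tree an [multiscale_bootstrap()] result.
#' @param tf TF symbol the tree belongs to (recorded in the output).
#' @param alpha significance threshold on `1 - AU` (default 0.05).
#' @return data frame (class `coreg_modules`) with one row per module:
#'   `tf`, `module_id`, `node`, `size`, `cluster_p`, `predominant`, and a
#'   list column `members` of target symbols. Zero rows when no node is
#'   significant.
#' @export
extract_modules <- function(tree, tf = NA_character_, alpha = 0.05) {
  stopifnot(inherits(tree, "annotated_dendrogram"))
  nd <- tree$nodes
  root <- which.max(nd$size)
  cand <- which(1 - nd$au < alpha & seq_len(nrow(nd)) != root)
  empty <- data.frame(tf = character(), module_id = character(),
                      node = integer(), size = integer(),
                      cluster_p = numeric(), predominant = logical(),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  if (!length(cand)) return(structure(empty, class = c("coreg_modules", "data.frame")))
  # outermost-first: keep a significant node unless nested in a kept one
  cand <- cand[order(-nd$size[cand], 1 - nd$au[cand])]
  kept <- integer()
  for (i in cand) {
    nested <- any(vapply(kept, function(j) {
      all(tree$members[[i]] %in% tree$members[[j]])
    }, logical(1)))
    if (!nested) kept <- c(kept, i)
  }
  out <- data.frame(
    tf = tf, module_id = sprintf("%s_M%02d", tf, seq_along(kept)),
    node = kept, size = nd$size[kept], cluster_p = 1 - nd$au[kept],
    predominant = FALSE, stringsAsFactors = FALSE
  )
  out$members <- tree$members[kept]
  pred <- order(-out$size, out$cluster_p)[1L]
  out$predominant[pred] <- TRUE
  structure(out, class = c("coreg_modules", "data.frame"))
}

#' Write an annotated dendrogram as Newick with AU node labels
#'
#' @param tree an [multiscale_bootstrap()] result.
#' @param path output file.
#' @export
write_annotated_newick <- function(tree, path) {
  stopifnot(inherits(tree, "annotated_dendrogram"))
  phy <- ape::as.phylo(tree$hclust)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  phy_keys <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "\x1f"),
                     character(1))
  au <- tree$nodes$au[match(phy_keys, .node_keys(tree$members))]
  phy$node.label <- sprintf("au=%.4f", au)
  ape::write.tree(phy, file = path)
  invisible(path)
}
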