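#' SMOTE oversampling of the minority class
#'
#' Generates `round(percent_over/100 * n)` synthetic minority samples by
#' linear interpolation: each synthetic sample is
#' `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`, where `x_i` is a
#' minority seed point chosen cyclically and `x_nn` is one of its `k`
#' Euclidean nearest minority neighbours picked at random. No scaling is
#' applied; values are assumed to share a common (log2) scale.
#'
#' @param minority numeric matrix, features x samples (minority class only),
#'   with more than `k` samples.
#' @param percent_over oversampling percentage (50 adds half as many
#'   synthetic samples as there are originals).
#' @param k number of nearest neighbours to interpolate towards.
#' @param seed optional integer seed.
#' @return list with `values` (originals followed by synthetic samples,
#'   named `SYN_01`, ...) and `provenance` (data frame: `sample_id`,
#'   `status`, `parent1`, `parent2`).
#' @export
smote_oversample <- function(minority, percent_over = 100, k = 5, seed = NULL) {
  stopifnot(is.matrix(minority), is.numeric(minority))
  n_min <- ncol(minority)
  if (!is.numeric(percent_over) || percent_over < 0) {
    stop("'percent_over' must be >= 0")
  }
  n_syn <- as.integer(round(percent_over / 100 * n_min))
  prov_orig <- data.frame(sample_id = colnames(minority), status = "original",
                          parent1 = NA_character_, parent2 = NA_character_,
                          stringsAsFactors = FALSE)
  if (n_syn == 0L) {
    return(list(values = minority, provenance = prov_orig))
  }
  if (k >= n_min) {
    stop(sprintf("k = %d nearest neighbours requested but only %d minority samples",
                 k, n_min))
  }
  .maybe_seed(seed)
  dmat <- as.matrix(dist(t(minority)))
  syn <- matrix(NA_real_, nrow = nrow(minority), ncol = n_syn,
                dimnames = list(rownames(minority),
                                sprintf("SYN_%02d", seq_len(n_syn))))
  parents <- matrix(NA_character_, nrow = 2L, ncol = n_syn)
  for (j in seq_len(n_syn)) {
    i <- (j - 1L) %% n_min + 1L
    nn <- order(dmat[i, -i])[seq_len(k)]
    nn_idx <- seq_len(n_min)[-i][nn]
    pick <- nn_idx[sample.int(k, 1L)]
    u <- runif(1)
    syn[, j] <- minority[, i] + u * (minority[, pick] - minority[, i])
    parents[, j] <- colnames(minority)[c(i, pick)]
  }
  prov_syn <- data.frame(sample_id = colnames(syn), status = "synthetic",
                         parent1 = parents[1L, ], parent2 = parents[2L, ],
                         stringsAsFactors = FALSE)
  list(values = cbind(minority, syn), provenance = rbind(prov_orig, prov_syn))
}

#' Random undersampling of the majority class
#'
#' Retains `floor((1 - percent_under/100) * n)` majority samples, drawn
#' uniformly at random without replacement. `percent_under` is the fraction
#' of majority samples removed, so 67 majority samples at
#' `percent_under = 50` leave exactly 33.
#'
#' @param majority numeric matrix, features x samples (majority class only).
#' @param percent_under percentage of majority samples to remove, in
#'   `[0, 100)` effectively (removing all samples is an error).
#' @param seed optional integer seed.
#' @return the retained columns of `majority` (original order preserved).
#' @export
undersample_majority <- function(majority, percent_under = 50, seed = NULL) {
  stopifnot(is.matrix(majority), is.numeric(majority))
  if (!is.numeric(percent_under) || percent_under < 0 || percent_under > 100) {
    stop("'percent_under' must lie in [0, 100]")
  }
  n_maj <- ncol(majority)
  n_keep <- as.integer(floor((1 - percent_under / 100) * n_maj))
  if (n_keep < 1L) stop("undersampling would remove every majority sample")
  .maybe_seed(seed)
  keep <- sort(sample.int(n_maj, n_keep))
  majority[, keep, drop = FALSE]
}

#' Balance a labelled expression dataset (SMOTE + undersampling)
#'
#' Composition of [smote_oversample()] on the minority (NOF) class and
#' [undersample_majority()] on the majority (CAF) class over a chosen
#' feature space, with per-sample provenance. The defaults reproduce the
#' published design: 10 NOF and 67 CAF samples with
#' `percent_over = percent_under = 50` yield 15 NOF and 33 CAF samples.
#'
#' @param data a [labelled_expression()] object with both classes present.
#' @param feature_space feature ids defining the space in which neighbours
#'   are computed (typically the DE lncRNA probes); default all features.
#' @param percent_over,percent_under percentages passed to the component
#'   operations.
#' @param k SMOTE neighbour count.
#' @param seed optional integer seed (drives both components).
#' @return an object of class `balanced_dataset`: list with `values`
#'   (features x samples), `sample_labels`, and `provenance` (data frame
#'   with `sample_id`, `label`, `status` in original/synthetic/retained,
#'   `parent1`, `parent2`).
#' @export
balance <- function(data, feature_space = NULL, percent_over = 50,
                    percent_under = 50, k = 5, seed = NULL) {
  stopifnot(inherits(data, "labelled_expression"))
  lab <- data$sample_labels
  if (!all(c("CAF", "NOF") %in% lab)) stop("both classes must be present")
  v <- data$values
  if (!is.null(feature_space)) {
    bad <- setdiff(feature_space, rownames(v))
    if (length(bad)) stop("feature_space ids absent from data: ",
                          paste(head(bad), collapse = ", "))
    v <- v[feature_space, , drop = FALSE]
  }
  .maybe_seed(if (is.null(seed)) NULL else derive_seed(seed, 11L))
  minority <- v[, names(lab)[lab == "NOF"], drop = FALSE]
  majority <- v[, names(lab)[lab == "CAF"], drop = FALSE]
  sm <- smote_oversample(minority, percent_over = percent_over, k = k)
  kept <- undersample_majority(majority, percent_under = percent_under)
  values <- cbind(sm$values, kept)
  labels <- setNames(rep(c("NOF", "CAF"), c(ncol(sm$values), ncol(kept))),
                     colnames(values))
  prov <- rbind(
    transform(sm$provenance, label = "NOF"),
    data.frame(sample_id = colnames(kept), status = "retained",
               parent1 = NA_character_, parent2 = NA_character_,
               label = "CAF", stringsAsFactors = FALSE)
  )
  prov <- prov[, c("sample_id", "label", "status", "parent1", "parent2")]
  rownames(prov) <- NULL
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids after balancing")
  structure(list(values = values, sample_labels = labels, provenance = prov),
            class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  tab <- table(x$provenance$label, x$provenance$status)
  cat(sprintf("balanced_dataset: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(tab)
  invisible(x)
}
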