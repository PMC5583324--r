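#' Stratified discovery/validation partition
#'
#' Randomly splits samples into two disjoint covering sets, stratified by
#' class so both sets contain both labels. Within each class the discovery
#' set receives `round(fraction * n_class)` samples.
#'
#' @param labels named character vector of sample labels.
#' @param fraction discovery fraction (default 0.5).
#' @param seed optional integer seed.
#' @return list with character vectors `discovery` and `validation`.
#' @export
partition <- function(labels, fraction = 0.5, seed = NULL) {
  stopifnot(!is.null(names(labels)))
  .assert_fraction(fraction, "fraction")
  .maybe_seed(seed)
  disc <- character()
  for (cls in unique(labels)) {
    ids <- names(labels)[labels == cls]
    n_d <- as.integer(round(fraction * length(ids)))
    if (length(ids) < 2L || n_d < 1L || n_d >= length(ids)) {
      stop(sprintf("cannot stratify class '%s' with %d sample(s)",
                   cls, length(ids)))
    }
    disc <- c(disc, sample(ids, n_d))
  }
  list(discovery = disc, validation = setdiff(names(labels), disc))
}

.classification_metrics <- function(truth, predicted) {
  acc <- mean(predicted == truth)
  sens <- if (any(truth == "CAF")) mean(predicted[truth == "CAF"] == "CAF") else NA_real_
  spec <- if (any(truth == "NOF")) mean(predicted[truth == "NOF"] == "NOF") else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

.train_predict <- function(model, x_tr, y_tr, x_val, rf_trees, svm_cost,
                           want_importance = FALSE) {
  y_tr <- factor(y_tr, levels = c("NOF", "CAF"))
  tr <- as.data.frame(x_tr)
  val <- as.data.frame(x_val)
  imp <- NULL
  pred <- switch(
    model,
    lr = {
      dat <- cbind(tr, .y = y_tr)
      fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
      pr <- suppressWarnings(predict(fit, newdata = val, type = "response"))
      ifelse(pr > 0.5, "CAF", "NOF")
    },
    rf = {
      fit <- randomForest::randomForest(x = tr, y = y_tr, ntree = rf_trees,
                                        importance = want_importance)
      if (want_importance) {
        im <- randomForest::importance(fit, type = 1L, scale = FALSE)
        imp <- setNames(im[, 1L], rownames(im))
      }
      as.character(predict(fit, newdata = val))
    },
    svm = {
      fit <- e1071::svm(x = as.matrix(tr), y = y_tr, kernel = "linear",
                        cost = svm_cost)
      as.character(predict(fit, newdata = as.matrix(val)))
    },
    stop("unknown model: ", model)
  )
  list(pred = pred, importance = imp)
}

#' Repeated discovery/validation evaluation of multivariate classifiers
#'
#' For each of `n_iter` iterations: samples are split (stratified) into
#' discovery and validation halves; the differential-expression filter
#' (`|logFC| > logfc_cutoff & p < p_cutoff`, moderated t) is re-run on the
#' discovery samples only and the passing features become the predictors;
#' each model is trained on discovery and evaluated on validation.
#' Accuracy is the proportion of correct predictions, sensitivity the
#' proportion of CAFs correctly identified and specificity the proportion
#' of NOFs correctly identified. Iterations selecting zero features fall
#' back to a majority-class predictor and are flagged degenerate.
#'
#' Validation-set moderated-t statistics (logFC and p for every feature)
#' are recorded per iteration so that [feature_stability()] can report the
#' averaged validation effect sizes.
#'
#' @param balanced a [balance()]d dataset.
#' @param n_iter number of resampling iterations (default 100).
#' @param models subset of `c("lr", "rf", "svm")`.
#' @param seed master seed; each iteration gets an independently derived
#'   seed so it is reproducible in isolation.
#' @param fraction discovery fraction (default 0.5).
#' @param logfc_cutoff,p_cutoff per-split feature-selection thresholds
#'   (the within-iteration filter does not re-apply the FDR gate).
#' @param adj_p_cutoff optional adjusted-p gate for the within-iteration
#'   filter; `NULL` (default) disables it.
#' @param rf_trees random-forest tree count (default 500).
#' @param svm_cost linear-SVM cost parameter (default 1).
#' @return object of class `model_evaluation`: list with `iterations` (one
#'   entry per iteration: `selected`, `degenerate`, `metrics` matrix
#'   (model x metric), `val_logFC`, `val_p`, `rf_importance`), `summary`
#'   (data frame of mean and sd per model and metric), `features`,
#'   `labels`, `models`, `n_iter`.
#' @export
evaluate_models <- function(balanced, n_iter = 100, models = c("lr", "rf", "svm"),
                            seed = 1, fraction = 0.5, logfc_cutoff = 1,
                            p_cutoff = 0.05, adj_p_cutoff = NULL,
                            rf_trees = 500, svm_cost = 1) {
  stopifnot(inherits(balanced, "balanced_dataset"))
  models <- match.arg(models, c("lr", "rf", "svm"), several.ok = TRUE)
  .assert_count(n_iter, "n_iter")
  v <- balanced$values
  lab <- balanced$sample_labels
  set.seed(derive_seed(seed, 400L))
  iter_seeds <- sample.int(2147483646L, n_iter)
  n_degenerate <- 0L

  iterations <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    sp <- partition(lab, fraction = fraction, seed = iter_seeds[it])
    disc_v <- v[, sp$discovery, drop = FALSE]
    val_v <- v[, sp$validation, drop = FALSE]
    # on the small homogeneous-variance lncRNA feature space the prior fit
    # may legitimately fall back to full pooling; keep the loop quiet
    de <- .moderated_t_core(disc_v, lab, quiet = TRUE)
    sel <- de$feature_id[!is.na(de$p) & abs(de$logFC) > logfc_cutoff &
                           de$p < p_cutoff &
                           (if (is.null(adj_p_cutoff)) TRUE else de$adj_p < adj_p_cutoff)]
    val_de <- .moderated_t_core(val_v, lab, quiet = TRUE)
    truth <- lab[sp$validation]
    degenerate <- length(sel) == 0L
    metrics <- matrix(NA_real_, nrow = length(models), ncol = 3L,
                      dimnames = list(models,
                                      c("accuracy", "sensitivity", "specificity")))
    rf_imp <- NULL
    if (degenerate) {
      n_degenerate <- n_degenerate + 1L
      maj <- names(which.max(table(lab[sp$discovery])))
      pred <- rep(maj, length(truth))
      for (m in models) metrics[m, ] <- .classification_metrics(truth, pred)
    } else {
      x_tr <- t(disc_v[sel, , drop = FALSE])
      x_val <- t(val_v[sel, , drop = FALSE])
      for (m in models) {
        out <- .train_predict(m, x_tr, lab[sp$discovery], x_val,
                              rf_trees, svm_cost,
                              want_importance = identical(m, "rf"))
        metrics[m, ] <- .classification_metrics(truth, out$pred)
        if (identical(m, "rf")) rf_imp <- out$importance
      }
    }
    iterations[[it]] <- list(
      iteration = it, selected = sel, degenerate = degenerate,
      metrics = metrics,
      val_logFC = setNames(val_de$logFC, val_de$feature_id),
      val_p = setNames(val_de$p, val_de$feature_id),
      rf_importance = rf_imp
    )
  }
  if (n_degenerate > 0L) {
    warning(sprintf("%d iteration(s) selected zero features; %s",
                    n_degenerate, "majority-class predictor used"))
  }

  summ <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(c("accuracy", "sensitivity", "specificity"), function(me) {
      vals <- vapply(iterations, function(x) x$metrics[m, me], numeric(1))
      data.frame(model = m, metric = me, mean = mean(vals, na.rm = TRUE),
                 sd = sd(vals, na.rm = TRUE), stringsAsFactors = FALSE)
    }))
  }))
  structure(list(iterations = iterations, summary = summ,
                 features = rownames(v), labels = lab, models = models,
                 n_iter = n_iter),
            class = "model_evaluation")
}

#' Per-iteration metric values for one model
#'
#' @param eval a [evaluate_models()] result.
#' @param model model name.
#' @param metric one of `"accuracy"`, `"sensitivity"`, `"specificity"`.
#' @return numeric vector of length `n_iter`.
#' @export
metric_values <- function(eval, model, metric = "accuracy") {
  stopifnot(inherits(eval, "model_evaluation"), model %in% eval$models)
  vapply(eval$iterations, function(x) x$metrics[model, metric], numeric(1))
}

#' Feature stability across resampling iterations
#'
#' Stability of a feature is the fraction of iterations in which it passed
#' the discovery-split differential-expression filter; the stable set uses
#' the strict rule `stability > 0.5`. Validation-split logFC and p-values
#' are averaged across iterations.
#'
#' @param eval a [evaluate_models()] result.
#' @return data frame: `feature_id`, `stability`, `stable`,
#'   `mean_val_logFC`, `mean_val_p`, ordered by decreasing stability.
#' @export
feature_stability <- function(eval) {
  stopifnot(inherits(eval, "model_evaluation"))
  feats <- eval$features
  n_sel <- vapply(feats, function(f) {
    sum(vapply(eval$iterations, function(x) f %in% x$selected, logical(1)))
  }, numeric(1))
  mlfc <- rowMeans(vapply(eval$iterations, function(x) x$val_logFC[feats],
                          numeric(length(feats))))
  mp <- rowMeans(vapply(eval$iterations, function(x) x$val_p[feats],
                        numeric(length(feats))), na.rm = TRUE)
  out <- data.frame(feature_id = feats, stability = n_sel / eval$n_iter,
                    stable = n_sel / eval$n_iter > 0.5,
                    mean_val_logFC = mlfc, mean_val_p = mp,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$stability, out$feature_id), , drop = FALSE]
}

#' Random-forest permutation importance averaged across iterations
#'
#' Mean decrease in accuracy (raw permutation importance on out-of-bag
#' predictions) of each feature, averaged over the iterations in which the
#' feature was selected.
#'
#' @param eval a [evaluate_models()] result that included the `"rf"` model.
#' @param features features to report; default the stable set from
#'   [feature_stability()].
#' @return data frame: `feature_id`, `mean_decrease_accuracy`,
#'   `n_iterations` (iterations contributing).
#' @export
rf_importance <- function(eval, features = NULL) {
  stopifnot(inherits(eval, "model_evaluation"))
  if (!"rf" %in% eval$models) stop("evaluation did not include the rf model")
  if (is.null(features)) {
    st <- feature_stability(eval)
    features <- st$feature_id[st$stable]
  }
  rows <- lapply(features, function(f) {
    vals <- unlist(lapply(eval$iterations, function(x) {
      if (!is.null(x$rf_importance) && f %in% names(x$rf_importance)) {
        x$rf_importance[[f]]
      }
    }))
    data.frame(feature_id = f,
               mean_decrease_accuracy = if (length(vals)) mean(vals) else NA_real_,
               n_iterations = length(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(feature_id = character(), mean_decrease_accuracy = numeric(),
               n_iterations = integer())
  rownames(out) <- NULL
  out
}

#' Univariate logistic-regression assessment of single features
#'
#' Repeats the discovery/validation evaluation with a logistic-regression
#' model whose sole predictor is one feature's expression, for each
#' requested feature, and averages the metrics across iterations.
#'
#' @param balanced a [balance()]d dataset.
#' @param features features to assess; default all features of `balanced`.
#' @param n_iter,seed,fraction as in [evaluate_models()].
#' @return data frame: `feature_id`, `accuracy`, `sensitivity`,
#'   `specificity` (means across iterations).
#' @export
univariate_lr <- function(balanced, features = NULL, n_iter = 100, seed = 1,
                          fraction = 0.5) {
  stopifnot(inherits(balanced, "balanced_dataset"))
  features <- features %||% rownames(balanced$values)
  lab <- balanced$sample_labels
  v <- balanced$values
  set.seed(derive_seed(seed, 400L))
  iter_seeds <- sample.int(2147483646L, n_iter)
  acc <- matrix(NA_real_, nrow = length(features), ncol = 3L,
                dimnames = list(features, c("accuracy", "sensitivity", "specificity")))
  sums <- array(0, dim = c(length(features), 3L))
  for (it in seq_len(n_iter)) {
    sp <- partition(lab, fraction = fraction, seed = iter_seeds[it])
    truth <- lab[sp$validation]
    for (fi in seq_along(features)) {
      f <- features[fi]
      x_tr <- v[f, sp$discovery, drop = FALSE]
      x_val <- v[f, sp$validation, drop = FALSE]
      out <- .train_predict("lr", t(x_tr), lab[sp$discovery], t(x_val),
                            rf_trees = 0, svm_cost = 1)
      sums[fi, ] <- sums[fi, ] + .classification_metrics(truth, out$pred)
    }
  }
  data.frame(feature_id = features,
             accuracy = sums[, 1L] / n_iter,
             sensitivity = sums[, 2L] / n_iter,
             specificity = sums[, 3L] / n_iter,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise paired Wilcoxon comparison of models
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-iteration values
#' of a metric for every pair of evaluated models. If every paired
#' difference is zero the p-value is reported as 1 with a tie warning.
#'
#' @param eval a [evaluate_models()] result.
#' @param metric metric to compare (default `"accuracy"`).
#' @return data frame: `model_a`, `model_b`, `p`, `mean_a`, `mean_b`.
#' @export
compare_models <- function(eval, metric = "accuracy") {
  stopifnot(inherits(eval, "model_evaluation"))
  ms <- eval$models
  rows <- list()
  for (i in seq_along(ms)) {
    for (j in seq_along(ms)) {
      if (i >= j) next
      a <- metric_values(eval, ms[i], metric)
      b <- metric_values(eval, ms[j], metric)
      d <- a - b
      p <- if (all(d == 0, na.rm = TRUE)) {
        warning(sprintf("all paired differences are zero for %s vs %s (tie)",
                        ms[i], ms[j]))
        1
      } else {
        suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model_a = ms[i], model_b = ms[j], p = p,
        mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
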