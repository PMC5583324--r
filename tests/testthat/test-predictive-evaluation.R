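# small, strongly separated balanced dataset shared by several tests
.eval_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 1, n_minority = 10, n_majority = 22,
                              n_features = 300, n_lncrna_probes = 60,
                              probes_per_symbol = 1, n_de_features = 12,
                              de_effect = 3, noise_sd = 0.3, n_tfs = 0)
      sim <- generate_expression(cfg)
      r <- moderated_t(sim$data)
      cache <<- balance(sim$data,
                        feature_space = r$feature_id[r$is_de & r$biotype == "lncRNA"],
                        percent_over = 50, percent_under = 0, seed = 1)
    }
    cache
  }
})

test_that("stratified partitions are disjoint, covering and reproducible", {
  lab <- setNames(rep(c("NOF", "CAF"), c(15, 33)), paste0("S", 1:48))
  sp <- partition(lab, seed = 1)
  expect_length(sp$discovery, 24)
  expect_length(sp$validation, 24)
  for (s in 1:20) {
    sp_i <- partition(lab, seed = s)
    expect_length(intersect(sp_i$discovery, sp_i$validation), 0)
    expect_setequal(c(sp_i$discovery, sp_i$validation), names(lab))
    expect_true(all(c("NOF", "CAF") %in% lab[sp_i$discovery]))
    expect_true(all(c("NOF", "CAF") %in% lab[sp_i$validation]))
  }
  expect_identical(partition(lab, seed = 3), partition(lab, seed = 3))
  lab_bad <- setNames(c("NOF", rep("CAF", 5)), paste0("S", 1:6))
  expect_error(partition(lab_bad), "stratify")
})

test_that("classification metrics follow their definitions and the weighting identity", {
  # confusion: 3 CAFs correct, 1 CAF missed is absent (FN=0), 1 NOF correct,
  # 1 NOF called CAF
  truth <- c("CAF", "CAF", "CAF", "NOF", "NOF")
  pred <- c("CAF", "CAF", "CAF", "NOF", "CAF")
  m <- caflncnet:::.classification_metrics(truth, pred)
  expect_equal(unname(m), c(0.8, 1.0, 0.5))

  # accuracy equals the class-size weighted mean of sensitivity and
  # specificity on every iteration
  ev2 <- evaluate_models(.eval_fixture(), n_iter = 5, models = "lr", seed = 2)
  lab <- .eval_fixture()$sample_labels
  set.seed(derive_seed(2, 400L))
  iter_seeds <- sample.int(2147483646L, 5)
  for (i in seq_len(5)) {
    sp <- partition(lab, seed = iter_seeds[i])
    val_lab <- lab[sp$validation]
    met <- ev2$iterations[[i]]$metrics["lr", ]
    expect_equal(
      unname(met["accuracy"]),
      unname((met["sensitivity"] * sum(val_lab == "CAF") +
                met["specificity"] * sum(val_lab == "NOF")) / length(val_lab)))
  }
})

test_that("strongly separated classes are classified almost perfectly", {
  ev <- evaluate_models(.eval_fixture(), n_iter = 10, seed = 1)
  for (m in c("lr", "rf", "svm")) {
    expect_gte(mean(metric_values(ev, m, "accuracy")), 0.9)
  }
})

test_that("feature selection sees only discovery samples", {
  bal <- .eval_fixture()
  ev_a <- evaluate_models(bal, n_iter = 1, models = "lr", seed = 7)
  # corrupt exactly the validation samples of that iteration
  set.seed(derive_seed(7, 400L))
  it_seed <- sample.int(2147483646L, 1)
  sp <- partition(bal$sample_labels, seed = it_seed)
  bal2 <- bal
  bal2$values[, sp$validation] <- matrix(
    rnorm(length(bal2$values[, sp$validation]), sd = 10),
    nrow = nrow(bal2$values))
  ev_b <- suppressWarnings(evaluate_models(bal2, n_iter = 1, models = "lr", seed = 7))
  expect_identical(ev_a$iterations[[1]]$selected, ev_b$iterations[[1]]$selected)
})

test_that("feature stability applies the strict majority rule", {
  mk_iter <- function(sel) list(selected = sel, metrics = NULL,
                                val_logFC = c(A = 1, B = -1),
                                val_p = c(A = 0.01, B = 0.5),
                                rf_importance = NULL)
  fake <- structure(list(
    iterations = c(replicate(51, mk_iter("A"), simplify = FALSE),
                   replicate(49, mk_iter(character()), simplify = FALSE)),
    features = c("A", "B"), n_iter = 100, models = "lr"),
    class = "model_evaluation")
  st <- feature_stability(fake)
  expect_equal(st$stability[st$feature_id == "A"], 0.51)
  expect_true(st$stable[st$feature_id == "A"])
  expect_equal(st$stability[st$feature_id == "B"], 0)
  expect_false(st$stable[st$feature_id == "B"])

  # exactly half is not stable (strict inequality)
  fake$iterations <- c(replicate(50, mk_iter("A"), simplify = FALSE),
                       replicate(50, mk_iter(character()), simplify = FALSE))
  expect_false(feature_stability(fake)$stable[1])

  # invariant to iteration order
  fake$iterations <- rev(fake$iterations)
  expect_equal(feature_stability(fake)$stability[1], 0.5)
})

test_that("random-forest importance singles out the informative feature", {
  set.seed(3)
  n <- 40
  v <- rbind(SIGNAL = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
             N1 = rnorm(n), N2 = rnorm(n), N3 = rnorm(n), N4 = rnorm(n))
  colnames(v) <- paste0("S", 1:n)
  lab <- setNames(rep(c("CAF", "NOF"), each = n / 2), colnames(v))
  bal <- structure(list(values = v, sample_labels = lab,
                        provenance = data.frame(sample_id = colnames(v),
                                                label = lab,
                                                status = "original")),
                   class = "balanced_dataset")
  ev <- suppressWarnings(
    evaluate_models(bal, n_iter = 5, models = "rf", seed = 1,
                    logfc_cutoff = 0, p_cutoff = 1.1))
  imp <- rf_importance(ev, features = rownames(v))
  expect_identical(imp$feature_id[which.max(imp$mean_decrease_accuracy)],
                   "SIGNAL")
  noise_imp <- imp$mean_decrease_accuracy[imp$feature_id != "SIGNAL"]
  expect_true(all(noise_imp < max(imp$mean_decrease_accuracy) / 2))
})

test_that("univariate logistic regression tracks single-feature signal", {
  bal <- .eval_fixture()
  # the balanced fixture's features carry strong planted signal
  uni <- univariate_lr(bal, features = rownames(bal$values)[1:2],
                       n_iter = 10, seed = 1)
  expect_identical(nrow(uni), 2L)
  expect_true(all(uni$accuracy > 0.85))
  # a pure-noise feature stays near the majority base rate
  bal_noise <- bal
  bal_noise$values <- rbind(bal$values,
                            NOISE = rnorm(ncol(bal$values)))
  uni_n <- univariate_lr(bal_noise, features = "NOISE", n_iter = 20, seed = 1)
  base <- max(table(bal$sample_labels)) / length(bal$sample_labels)
  expect_lt(abs(uni_n$accuracy - base), 0.2)
})

test_that("model comparisons use the paired signed-rank test symmetrically", {
  mk_eval <- function(acc_a, acc_b) {
    its <- lapply(seq_along(acc_a), function(i) {
      list(selected = "A",
           metrics = matrix(c(acc_a[i], NA, NA, acc_b[i], NA, NA),
                            nrow = 2, byrow = TRUE,
                            dimnames = list(c("lr", "svm"),
                                            c("accuracy", "sensitivity",
                                              "specificity"))),
           val_logFC = c(A = 0), val_p = c(A = 1), rf_importance = NULL)
    })
    structure(list(iterations = its, features = "A", n_iter = length(acc_a),
                   models = c("lr", "svm")), class = "model_evaluation")
  }
  set.seed(6)
  base <- runif(100, 0.7, 0.9)
  ev <- mk_eval(base + 0.1, base)
  cmp <- compare_models(ev, "accuracy")
  expect_lt(cmp$p, 0.001)

  # swapping the models leaves the two-sided p unchanged
  ev_sw <- mk_eval(base, base + 0.1)
  expect_equal(compare_models(ev_sw, "accuracy")$p, cmp$p)

  # identical vectors tie out with a warning
  expect_warning(cmp0 <- compare_models(mk_eval(base, base)), "tie")
  expect_equal(cmp0$p, 1)
})

test_that("iterations with empty selection fall back to the majority class", {
  bal <- .eval_fixture()
  expect_warning(
    ev <- evaluate_models(bal, n_iter = 2, models = "lr", seed = 1,
                          logfc_cutoff = 100),
    "zero features")
  expect_true(all(vapply(ev$iterations, `[[`, logical(1), "degenerate")))
  base <- max(table(bal$sample_labels)) / length(bal$sample_labels)
  expect_equal(mean(metric_values(ev, "lr", "accuracy")), base, tolerance = 0.15)
})
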