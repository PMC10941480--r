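test_that("TPM preprocessing filters, collapses and log-transforms", {
  m <- matrix(c(0, 0, 0, 5,    # zero in 75% -> dropped
                1, 1, 1, 1,    # TPM 1 -> log2 2 = 1
                0, 2, 3, 4),   # minority zero survives as 0
              nrow = 3, byrow = TRUE, dimnames = list(NULL, paste0("s", 1:4)))
  x <- expr_matrix(m, c("a", "b", "c"), paste0("s", 1:4), unit = "tpm")
  y <- preprocess_tpm(x)
  expect_setequal(y$gene_ids, c("b", "c"))
  expect_equal(unname(y$values[match("b", y$gene_ids), ]), rep(1, 4))
  expect_equal(unname(y$values[match("c", y$gene_ids), 1]), 0)
  expect_equal(y$unit, "log2tpm")
  expect_error(preprocess_tpm(expr_matrix(m, letters[1:3], paste0("s", 1:4),
                                          unit = "count")), "tpm")
  # duplicate symbols collapse by mean before the log
  m2 <- matrix(c(2, 4, 4, 6), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2")))
  x2 <- expr_matrix(m2, c("G", "G"), c("s1", "s2"), unit = "tpm")
  y2 <- preprocess_tpm(x2)
  expect_equal(unname(y2$values[1, ]), log2(c(3, 5) + 1))
})

test_that("TPM from counts normalizes each sample to one million", {
  x <- expr_matrix(matrix(c(10, 10), 2, 1, dimnames = list(NULL, "s1")),
                   c("a", "b"), "s1", unit = "count")
  tpm <- tpm_from_counts(x, c(a = 1000, b = 2000))
  expect_equal(unname(tpm$values[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  one <- tpm_from_counts(expr_matrix(matrix(7, 1, 1, dimnames = list(NULL, "s1")),
                                     "a", "s1"), c(a = 500))
  expect_equal(unname(one$values[1, 1]), 1e6)
  set.seed(51)
  cx <- expr_matrix(matrix(rpois(50, 20), 10, 5,
                           dimnames = list(NULL, paste0("s", 1:5))),
                    sprintf("g%02d", 1:10), paste0("s", 1:5))
  lens <- setNames(runif(10, 200, 2000), sprintf("g%02d", 1:10))
  t2 <- tpm_from_counts(cx, lens)
  expect_equal(unname(colSums(t2$values)), rep(1e6, 5))
  lens2 <- lens[-1]
  expect_message(t3 <- tpm_from_counts(cx, lens2), "without length")
  expect_equal(length(t3$gene_ids), 9)
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
  same <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(unname(quantile_normalize(same)), unname(same))
  set.seed(52)
  big <- matrix(rnorm(500), 100, 5)
  qb <- quantile_normalize(big)
  sorted <- apply(qb, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_error(quantile_normalize(matrix(1:3, 3, 1)), "2 samples")
})

test_that("test-to-train rescaling is a monotone quantile map", {
  set.seed(53)
  ref <- sort(rnorm(1000))
  test <- matrix(rnorm(200, mean = 3, sd = 2), 100, 2,
                 dimnames = list(NULL, c("t1", "t2")))
  out <- rescale_test_to_train(test, ref)
  # order within each sample preserved
  expect_identical(order(out[, 1]), order(test[, 1]))
  # KS distance to the reference <= 1/n
  ks <- suppressWarnings(stats::ks.test(out[, 1], ref)$statistic)
  expect_lte(unname(ks), 1 / 100 + 1e-9)
  # a sample matching the reference size maps onto it exactly
  refcol <- matrix(sample(ref), ncol = 1, dimnames = list(NULL, "t"))
  mapped <- rescale_test_to_train(refcol, ref)
  expect_equal(sort(mapped[, 1]), ref, tolerance = 1e-9)
  expect_warning(rescale_test_to_train(matrix(5, 10, 1), ref), "constant")
})

test_that("balanced bootstrap keeps all healthy samples per run", {
  labels <- setNames(rep(c("N", "OA"), c(10, 60)), sprintf("s%02d", 1:70))
  runs <- balanced_bootstrap_runs(labels, n_boot = 100, seed = 5)
  expect_length(runs, 100)
  healthy <- names(labels)[labels == "N"]
  for (r in runs[1:5]) {
    expect_length(r, 20)
    expect_true(all(healthy %in% r))
    oa <- setdiff(r, healthy)
    expect_length(unique(oa), 10)   # without replacement
  }
  expect_identical(runs, balanced_bootstrap_runs(labels, n_boot = 100, seed = 5))
  # union of OA draws covers nearly all OA samples
  covered <- unique(unlist(lapply(runs, setdiff, healthy)))
  expect_gte(length(covered), 0.95 * 60)
  bad <- setNames(rep(c("N", "OA"), c(10, 5)), sprintf("s%02d", 1:15))
  expect_error(balanced_bootstrap_runs(bad), "impossible")
})

test_that("elastic net selects planted features and groups duplicates", {
  set.seed(54)
  n <- 60; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  eta <- 3 * X[, 1]
  y <- ifelse(runif(n) < plogis(eta), "OA", "N")
  hits <- replicate(20, {
    idx <- sample(n)
    co <- fit_enet_logistic(X[idx, ], y[idx])
    co["f01"] > 0
  })
  expect_gte(mean(hits), 0.95)
  # grouping effect: duplicated informative columns both enter
  X2 <- cbind(X, f_dup = X[, 1])
  co2 <- fit_enet_logistic(X2, y, alpha_mix = 0.5)
  expect_true(co2["f01"] != 0 && co2["f_dup"] != 0)
  expect_lt(abs(co2["f01"] - co2["f_dup"]), 0.2 * max(abs(co2)))
})

test_that("stability selection applies the inclusive 50% rule", {
  cm <- matrix(0, 100, 3, dimnames = list(NULL, c("in50", "in49", "in80")))
  cm[1:50, "in50"] <- 1
  cm[1:49, "in49"] <- 2
  cm[1:80, "in80"] <- 0.5
  model <- stability_select(cm, 0.5)
  expect_setequal(model$genes, c("in50", "in80"))
  expect_equal(unname(coef(model)["in50"]), 50 * 1 / 100)
  expect_equal(unname(coef(model)["in80"]), 80 * 0.5 / 100)
  m2 <- stability_select(cm, 0.5, average = "nonzero")
  expect_equal(unname(coef(m2)["in50"]), 1)
  expect_error(stability_select(cm, 0.9), "no gene selected")
})

test_that("risk scores are intercept-free linear indices", {
  model <- risk_model("reduced", c(g1 = 1, g2 = -0.5))
  X <- rbind(s1 = c(g1 = 2, g2 = 4), s2 = c(g1 = 0, g2 = 0))
  s <- score_samples(model, X)
  expect_equal(unname(s), c(0, 0))
  X2 <- X; X2[, "g1"] <- X2[, "g1"] + 3    # constant shift in one gene
  expect_equal(unname(score_samples(model, X2) - s), rep(3 * 1, 2))
  zero <- risk_model("reduced", c(g1 = 0, g2 = 0))
  expect_equal(unname(score_samples(zero, X)), c(0, 0))
  expect_error(score_samples(risk_model("reduced", c(zz = 1)), X), "missing")
})

test_that("ridge model keeps every gene with finite coefficients", {
  set.seed(55)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, sprintf("g%d", 1:5)))
  X <- cbind(X, g6 = X[, 1] + rnorm(n, 0, 1e-6))  # near-collinear pair
  y <- ifelse(runif(n) < plogis(2 * X[, 1]), "OA", "N")
  model <- fit_ridge_logistic(X, y)
  expect_length(coef(model), 6)
  expect_true(all(is.finite(coef(model))))
})

test_that("AUC equals the pairwise oracle and reference implementations", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11), rep(c("N", "OA"), c(3, 2)))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$curve$tpr[nrow(perfect$curve)], 1)
  expect_error(roc_auc(1:3, rep("OA", 3)), "both classes")
  set.seed(56)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- sample(round(rnorm(n), 1))  # ties likely
    labels <- sample(rep(c("N", "OA"), length.out = n))
    expect_equal(roc_auc(scores, labels)$auc, bf_auc(scores, labels))
  }
  skip_if_not_installed("pROC")
  scores <- rnorm(50); labels <- sample(rep(c("N", "OA"), 25))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("N", "OA"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("DeLong test matches pROC and handles degenerate input", {
  set.seed(57)
  labels <- rep(c("N", "OA"), c(30, 40))
  signal <- rnorm(70) + 1.2 * (labels == "OA")
  sA <- signal + rnorm(70, 0, 0.5)
  sB <- signal + rnorm(70, 0, 0.5)
  same <- delong_test(sA, sA, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  got <- delong_test(sA, sB, labels)
  skip_if_not_installed("pROC")
  rocA <- pROC::roc(labels, sA, levels = c("N", "OA"), direction = "<", quiet = TRUE)
  rocB <- pROC::roc(labels, sB, levels = c("N", "OA"), direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(rocA, rocB, method = "delong", paired = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(got$z), abs(unname(ref$statistic)), tolerance = 1e-9)
})

test_that("Wilcoxon wrapper is exact for small untied samples", {
  p <- wilcoxon_ranksum(c(1, 2, 3, 11, 12, 13),
                        rep(c("N", "OA"), each = 3))
  expect_equal(p, 0.1)   # 2 of choose(6,3)=20 orderings
  expect_equal(wilcoxon_ranksum(rep(c(1, 2), 4), rep(c("A", "B"), each = 4)), 1)
  set.seed(58)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  ex <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  ap <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(ex - ap), 0.01)
})

test_that("the full risk pipeline is deterministic and recovers planted genes", {
  consensus <- sprintf("CG%02d", 1:20)
  spec <- risk_spec(informative_genes = consensus[1:4], effect = 2,
                    n_train_ctrl = 8, n_train_case = 24,
                    n_test_ctrl = 10, n_test_case = 12, n_null_genes = 80)
  rc <- simulate_risk_cohorts(spec, consensus, seed = 6)
  cfg <- run_config(n_boot = 25, seed = 3)
  res <- risk_pipeline(rc$train, rc$test, rc$train_labels, rc$test_labels,
                       consensus, cfg)
  expect_s3_class(res, "risk_result")
  expect_gte(sum(rc$truth %in% res$reduced$genes), 3)
  expect_gt(res$stats$auc_sR_test, 0.8)
  expect_true(all(abs(res$total$coefficients) > 0))
  res2 <- risk_pipeline(rc$train, rc$test, rc$train_labels, rc$test_labels,
                        consensus, cfg)
  expect_identical(res$reduced$coefficients, res2$reduced$coefficients)
  expect_identical(res$stats, res2$stats)
})
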