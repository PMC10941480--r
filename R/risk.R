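#' Preprocess a TPM matrix for risk scoring
#'
#' Keeps genes with TPM > 0 in at least 50% of samples, collapses duplicate
#' gene symbols by their mean, and transforms to log2(TPM + 1) (the
#' pseudocount keeps surviving minority zeros finite).
#'
#' @param tpm an [expr_matrix()] with unit `"tpm"`.
#' @param min_fraction minimum fraction of samples with TPM > 0.
#' @return an [expr_matrix()] with unit `"log2tpm"`.
#' @export
preprocess_tpm <- function(tpm, min_fraction = 0.5) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$unit != "tpm") stop("expected unit 'tpm', got '", tpm$unit, "'")
  need <- ceiling(min_fraction * length(tpm$sample_ids))
  keep <- rowSums(tpm$values > 0) >= need
  x <- expr_matrix(tpm$values[keep, , drop = FALSE], tpm$gene_ids[keep],
                   tpm$sample_ids, unit = "tpm")
  x <- collapse_isoforms(x)
  expr_matrix(log2(x$values + 1), x$gene_ids, x$sample_ids, unit = "log2tpm")
}

#' TPM from raw counts and gene lengths
#'
#' Per sample: rate = count / length (length in bases); TPM = rate scaled to
#' sum to 1e6. Genes without a length are dropped with a message.
#'
#' @param counts an [expr_matrix()] of raw counts.
#' @param gene_lengths named numeric vector of gene lengths (> 0).
#' @return an [expr_matrix()] with unit `"tpm"`.
#' @export
tpm_from_counts <- function(counts, gene_lengths) {
  stopifnot(inherits(counts, "expr_matrix"))
  len <- gene_lengths[counts$gene_ids]
  miss <- is.na(len)
  if (any(miss)) message("dropping ", sum(miss), " gene(s) without length")
  if (any(len[!miss] <= 0)) stop("gene lengths must be > 0")
  vals <- counts$values[!miss, , drop = FALSE]
  rate <- vals / len[!miss]
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expr_matrix(tpm, counts$gene_ids[!miss], counts$sample_ids, unit = "tpm")
}

#' Quantile normalization
#'
#' Classic rank-based normalization (each column's sorted values replaced by
#' the across-column mean of sorted values; ties get the mean of their tied
#' positions), delegated to [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix or [expr_matrix()] (>= 2 columns).
#' @return same type as the input, normalized.
#' @export
quantile_normalize <- function(x) {
  wrap <- inherits(x, "expr_matrix")
  m <- if (wrap) x$values else x
  if (ncol(m) < 2) stop("need at least 2 samples")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  if (wrap) expr_matrix(qn, x$gene_ids, x$sample_ids, unit = x$unit) else qn
}

#' Rescale test samples onto the training reference distribution
#'
#' Empirical quantile mapping: within each test sample, the value of rank r
#' (mid-ranks on ties) among n values is replaced by the training-reference
#' quantile at fraction (r - 1)/(n - 1), linearly interpolated between the
#' reference order statistics. A constant test sample maps entirely to the
#' reference median (with a warning).
#'
#' @param test numeric matrix or [expr_matrix()] (samples in columns).
#' @param reference numeric vector: the pooled (sorted or unsorted)
#'   quantile-normalized training values.
#' @return rescaled object of the same type.
#' @export
rescale_test_to_train <- function(test, reference) {
  wrap <- inherits(test, "expr_matrix")
  m <- if (wrap) test$values else test
  ref <- sort(reference)
  out <- apply(m, 2, function(col) {
    n <- length(col)
    r <- rank(col, ties.method = "average")
    if (min(col) == max(col)) {
      warning("constant test sample; mapping to the reference median")
      return(rep(stats::median(ref), n))
    }
    probs <- (r - 1) / (n - 1)
    stats::quantile(ref, probs = probs, names = FALSE, type = 7)
  })
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  if (wrap) expr_matrix(out, test$gene_ids, test$sample_ids, unit = test$unit)
  else out
}

#' Balanced bootstrap subsets for class-imbalanced training
#'
#' Each subset contains every minority-class (healthy) sample plus an
#' equal-sized simple random sample, without replacement, of the majority
#' (case) samples; draws are independent across runs.
#'
#' @param labels named character vector of class labels (names = sample ids).
#' @param healthy_level the minority/control label (default `"N"`).
#' @param n_boot number of subsets (default 100).
#' @param seed integer seed.
#' @return list of character vectors of sample ids.
#' @export
balanced_bootstrap_runs <- function(labels, healthy_level = "N",
                                    n_boot = 100, seed = 1) {
  ids_h <- names(labels)[labels == healthy_level]
  ids_c <- names(labels)[labels != healthy_level]
  if (length(ids_c) < length(ids_h))
    stop("case count (", length(ids_c), ") below healthy count (",
         length(ids_h), "): balanced draw impossible")
  set.seed(as.integer(seed))
  lapply(seq_len(n_boot), function(b) c(ids_h, sample(ids_c, length(ids_h))))
}

#' Elastic-net logistic fit with leave-one-out lambda tuning
#'
#' Penalized logistic regression (glmnet): mixing parameter `alpha_mix`
#' between lasso (1) and ridge (0), lambda grid of `n_lambda` points
#' log-spaced from the data-derived maximum down to
#' `lambda_min_ratio` times it, lambda chosen by leave-one-out
#' cross-validation minimizing binomial deviance. Features are standardized
#' internally; coefficients are returned on the original scale with the
#' intercept discarded (the risk scores are intercept-free linear indices).
#'
#' @param X samples x genes numeric matrix.
#' @param y binary labels (factor/character; the second sorted level is the
#'   positive class).
#' @param alpha_mix elastic-net mixing (default 0.5).
#' @param n_lambda,lambda_min_ratio lambda grid shape.
#' @return named numeric coefficient vector (zeros = unselected).
#' @export
fit_enet_logistic <- function(X, y, alpha_mix = 0.5, n_lambda = 50,
                              lambda_min_ratio = 1e-3) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  yb <- as.integer(y) - 1L
  n <- nrow(X)
  # balanced bootstrap subsets are small by design (2 x the healthy count),
  # so glmnet's small-class warning fires on every leave-one-out fold; it is
  # muffled here as it describes the intended design, not a defect
  fit <- suppressWarnings(
    glmnet::glmnet(X, yb, family = "binomial", alpha = alpha_mix,
                   nlambda = n_lambda,
                   lambda.min.ratio = lambda_min_ratio,
                   standardize = TRUE))
  lam <- fit$lambda
  # explicit leave-one-out loop (lean on raw glmnet calls): held-out
  # binomial deviance per lambda, averaged over folds
  dev <- matrix(NA_real_, n, length(lam))
  for (i in seq_len(n)) {
    fi <- tryCatch(
      suppressWarnings(
        glmnet::glmnet(X[-i, , drop = FALSE], yb[-i], family = "binomial",
                       alpha = alpha_mix, lambda = lam, standardize = TRUE)),
      error = function(e) NULL)
    if (is.null(fi)) next  # non-converged fold skipped (logged via NA)
    p <- stats::predict(fi, X[i, , drop = FALSE], type = "response")
    p <- pmin(pmax(as.numeric(p), 1e-10), 1 - 1e-10)
    k <- length(p)
    dev[i, seq_len(k)] <- -2 * (yb[i] * log(p) + (1 - yb[i]) * log(1 - p))
  }
  cvm <- colMeans(dev)
  ok <- which(is.finite(cvm))
  if (!length(ok)) stop("leave-one-out tuning failed at every lambda")
  # first index = largest lambda attaining the minimum (lam is decreasing)
  best <- lam[ok[which.min(cvm[ok])]]
  co <- as.matrix(stats::coef(fit, s = best, exact = FALSE))[, 1]
  co[-1]  # drop intercept
}

#' Risk model container
#'
#' @param kind `"reduced"` (stability-selected, averaged coefficients a_j)
#'   or `"total"` (full-signature ridge coefficients b_j).
#' @param coefficients named numeric vector aligned to `genes`.
#' @param reference sorted pooled quantile-normalized training values, kept
#'   for rescaling future test cohorts.
#' @param selection optional runs x genes 0/1 selection matrix (reduced).
#' @param frequency optional per-gene selection frequencies (reduced).
#' @return object of class `risk_model`.
#' @export
risk_model <- function(kind, coefficients, reference = NULL,
                       selection = NULL, frequency = NULL) {
  stopifnot(kind %in% c("reduced", "total"))
  structure(list(kind = kind, genes = names(coefficients),
                 coefficients = coefficients, reference = reference,
                 selection = selection, frequency = frequency),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model '", x$kind, "'> ", length(x$genes), " gene(s)\n", sep = "")
  print(round(sort(x$coefficients, decreasing = TRUE), 4))
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$coefficients

#' Predict risk scores from a model
#'
#' @param object a [risk_model()].
#' @param newdata samples x genes matrix or genes x samples [expr_matrix()]
#'   of (normalized/rescaled) log2 TPM values.
#' @param ... unused.
#' @return named numeric score vector (one per sample).
#' @export
predict.risk_model <- function(object, newdata, ...) {
  score_samples(object, newdata)
}

#' Stability selection over bootstrap elastic-net runs
#'
#' Genes with a nonzero coefficient in at least
#' `selection_fraction * n_boot` runs (inclusive boundary) form the reduced
#' signature; each retained gene's coefficient a_j is the arithmetic mean of
#' its coefficients across **all** runs (zeros from unselecting runs
#' included; `average = "nonzero"` averages the selecting runs only).
#'
#' @param coef_matrix runs x genes coefficient matrix.
#' @param selection_fraction fraction of runs required (default 0.5).
#' @param average `"all"` (default) or `"nonzero"`.
#' @param reference optional training reference for the resulting model.
#' @return a [risk_model()] of kind `"reduced"`.
#' @export
stability_select <- function(coef_matrix, selection_fraction = 0.5,
                             average = c("all", "nonzero"), reference = NULL) {
  average <- match.arg(average)
  freq <- colMeans(coef_matrix != 0)
  sel <- freq >= selection_fraction
  if (!any(sel)) {
    stop("no gene selected in >= ", selection_fraction * 100,
         "% of runs; top frequencies: ",
         paste(sprintf("%s=%.2f", names(utils::head(sort(freq, decreasing = TRUE), 5)),
                       utils::head(sort(freq, decreasing = TRUE), 5)),
               collapse = ", "))
  }
  a <- if (average == "all") colMeans(coef_matrix[, sel, drop = FALSE])
       else apply(coef_matrix[, sel, drop = FALSE], 2,
                  function(v) mean(v[v != 0]))
  risk_model("reduced", a, reference = reference,
             selection = (coef_matrix != 0) * 1L, frequency = freq)
}

#' Full-signature ridge model
#'
#' Ridge-penalized logistic regression over all consensus genes
#' (`alpha_mix = 0`, so no coefficient is zeroed), lambda by leave-one-out
#' cross-validation as in [fit_enet_logistic()].
#'
#' @param X samples x genes matrix (all consensus genes).
#' @param y binary labels.
#' @param n_lambda,lambda_min_ratio lambda grid shape.
#' @param reference optional training reference.
#' @return a [risk_model()] of kind `"total"`.
#' @export
fit_ridge_logistic <- function(X, y, n_lambda = 50, lambda_min_ratio = 1e-3,
                               reference = NULL) {
  b <- fit_enet_logistic(X, y, alpha_mix = 0, n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio)
  risk_model("total", b, reference = reference)
}

#' Linear risk score of samples
#'
#' s(i) = sum_j coef_j * z_{j,i} over the model genes, with z the matrix
#' values as given (training: quantile-normalized log2 TPM; test: rescaled).
#' No intercept.
#'
#' @param model a [risk_model()].
#' @param data samples x genes matrix, or genes x samples [expr_matrix()].
#' @return named numeric vector of scores.
#' @export
score_samples <- function(model, data) {
  if (inherits(data, "expr_matrix")) {
    m <- t(data$values)
    colnames(m) <- data$gene_ids
  } else m <- data
  miss <- setdiff(model$genes, colnames(m))
  if (length(miss))
    stop("model gene(s) missing from data: ", paste(miss, collapse = ", "))
  drop(m[, model$genes, drop = FALSE] %*% model$coefficients)
}

#' ROC curve and AUC
#'
#' AUC as the Mann-Whitney probability that a random positive outscores a
#' random negative, ties counted 1/2 (computed from rank sums); the curve
#' enumerates (FPR, TPR) at every distinct threshold.
#'
#' @param scores numeric vector.
#' @param labels binary labels; `positive` names the positive class.
#' @param positive positive class label (default `"OA"`).
#' @return list with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels, positive = "OA") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, th),
    fpr = c(0, vapply(th, function(t) sum(scores[!pos] >= t) / n0, 0)),
    tpr = c(0, vapply(th, function(t) sum(scores[pos] >= t) / n1, 0)))
  list(auc = auc, curve = curve)
}

# Per-observation structural components of the AUC (placement values).
delong_components <- function(scores, pos) {
  x <- scores[pos]; y <- scores[!pos]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors computed on the same
#' samples, using the structural-component (placement-value) covariance
#' estimate; two-sided normal p-value. Identical scores (zero variance of
#' the difference) return z = 0, p = 1 with a `degenerate` flag.
#'
#' @param scoresA,scoresB numeric score vectors (same samples).
#' @param labels binary labels; `positive` names the positive class.
#' @param positive positive class label (default `"OA"`).
#' @return list with `aucA`, `aucB`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scoresA, scoresB, labels, positive = "OA") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  a <- delong_components(scoresA, pos)
  b <- delong_components(scoresB, pos)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (v <= .Machine$double.eps)
    return(list(aucA = a$auc, aucB = b$auc, z = 0, p = 1, degenerate = TRUE))
  z <- (a$auc - b$auc) / sqrt(v)
  list(aucA = a$auc, aucB = b$auc, z = z, p = 2 * stats::pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Two-sided Wilcoxon rank-sum p-value between score classes
#'
#' Exact enumeration when both groups have at most 10 untied observations,
#' the tie-corrected normal approximation otherwise
#' (delegates to [stats::wilcox.test()]).
#'
#' @param scores numeric vector.
#' @param labels binary labels.
#' @return p-value.
#' @export
wilcoxon_ranksum <- function(scores, labels) {
  g <- split(scores, labels)
  if (length(g) != 2) stop("need exactly two classes")
  x <- g[[1]]; y <- g[[2]]
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Full patient-centric risk pipeline
#'
#' Preprocesses the train/test TPM cohorts (TPM > 0 majority filter, isoform
#' collapse, log2), restricts to their common genes, quantile-normalizes the
#' training set, rescales each test sample onto the pooled training
#' reference, restricts to the consensus genes present in both cohorts, then
#' fits (a) the reduced model — `n_boot` balanced bootstrap elastic-net runs
#' with leave-one-out lambda tuning, stability selection at
#' `selection_fraction`, coefficients averaged across all runs — and (b) the
#' total ridge model on all available consensus genes. Reports scores, ROC
#' AUCs, class-difference Wilcoxon p-values on train and test, and the
#' DeLong comparison of the two test AUCs.
#'
#' @param train_tpm,test_tpm [expr_matrix()] objects with unit `"tpm"`.
#' @param train_labels,test_labels named label vectors (`"N"`/`"OA"`).
#' @param signature_genes consensus gene list.
#' @param config a [run_config()] (fields `alpha_mix`, `n_boot`,
#'   `selection_fraction`, `n_lambda`, `lambda_min_ratio`, `coef_average`,
#'   `seed`).
#' @return object of class `risk_result`: list with `reduced`, `total`
#'   ([risk_model()]s), `genes_used`, `scores` (long data.frame), `stats`
#'   (AUCs, Wilcoxon and DeLong results).
#' @export
risk_pipeline <- function(train_tpm, test_tpm, train_labels, test_labels,
                          signature_genes, config = run_config()) {
  tr <- preprocess_tpm(train_tpm)
  te <- preprocess_tpm(test_tpm)
  common <- intersect(tr$gene_ids, te$gene_ids)
  tr <- expr_matrix(tr$values[match(common, tr$gene_ids), , drop = FALSE],
                    common, tr$sample_ids, unit = "log2tpm")
  te <- expr_matrix(te$values[match(common, te$gene_ids), , drop = FALSE],
                    common, te$sample_ids, unit = "log2tpm")
  trq <- quantile_normalize(tr)
  reference <- sort(as.vector(trq$values))
  teq <- rescale_test_to_train(te, reference)

  genes <- intersect(signature_genes, common)
  if (length(genes) < 2) stop("fewer than two consensus genes available")
  Xtr <- t(trq$values[match(genes, common), , drop = FALSE]); colnames(Xtr) <- genes
  Xte <- t(teq$values[match(genes, common), , drop = FALSE]); colnames(Xte) <- genes
  ytr <- train_labels[rownames(Xtr)]
  yte <- test_labels[rownames(Xte)]

  runs <- balanced_bootstrap_runs(ytr, healthy_level = "N",
                                  n_boot = config$n_boot, seed = config$seed)
  coefs <- matrix(0, config$n_boot, length(genes),
                  dimnames = list(NULL, genes))
  for (b in seq_along(runs)) {
    ids <- runs[[b]]
    coefs[b, ] <- fit_enet_logistic(Xtr[ids, , drop = FALSE], ytr[ids],
                                    alpha_mix = config$alpha_mix,
                                    n_lambda = config$n_lambda,
                                    lambda_min_ratio = config$lambda_min_ratio)
  }
  reduced <- tryCatch(
    stability_select(coefs, selection_fraction = config$selection_fraction,
                     average = config$coef_average, reference = reference),
    error = function(e) {
      # no stably selected gene (expected when the data carry no signal):
      # fall back to an all-zero reduced model, whose scores are constant
      warning("stability selection found no stable gene; ",
              "reduced score is degenerate (all-zero coefficients)")
      risk_model("reduced", stats::setNames(numeric(length(genes)), genes),
                 reference = reference, selection = (coefs != 0) * 1L,
                 frequency = colMeans(coefs != 0))
    })
  total <- fit_ridge_logistic(Xtr, ytr, n_lambda = config$n_lambda,
                              lambda_min_ratio = config$lambda_min_ratio,
                              reference = reference)

  sc <- list(sR_train = score_samples(reduced, Xtr),
             sR_test = score_samples(reduced, Xte),
             sT_train = score_samples(total, Xtr),
             sT_test = score_samples(total, Xte))
  stats <- list(
    auc_sR_train = roc_auc(sc$sR_train, ytr)$auc,
    auc_sR_test = roc_auc(sc$sR_test, yte)$auc,
    auc_sT_train = roc_auc(sc$sT_train, ytr)$auc,
    auc_sT_test = roc_auc(sc$sT_test, yte)$auc,
    wilcox_sR_train = wilcoxon_ranksum(sc$sR_train, ytr),
    wilcox_sR_test = wilcoxon_ranksum(sc$sR_test, yte),
    delong = delong_test(sc$sR_test, sc$sT_test, yte))
  scores <- rbind(
    data.frame(sample_id = names(sc$sR_train), score = unname(sc$sR_train),
               label = unname(ytr), kind = "s_R", cohort = "train"),
    data.frame(sample_id = names(sc$sR_test), score = unname(sc$sR_test),
               label = unname(yte), kind = "s_R", cohort = "test"),
    data.frame(sample_id = names(sc$sT_train), score = unname(sc$sT_train),
               label = unname(ytr), kind = "s_T", cohort = "train"),
    data.frame(sample_id = names(sc$sT_test), score = unname(sc$sT_test),
               label = unname(yte), kind = "s_T", cohort = "test"))
  structure(list(reduced = reduced, total = total, genes_used = genes,
                 scores = scores, stats = stats, config = config),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  s <- x$stats
  cat("Patient-centric risk scores over ", length(x$genes_used),
      " consensus gene(s)\n", sep = "")
  cat("  reduced signature: ", length(x$reduced$genes), " gene(s) [",
      paste(utils::head(x$reduced$genes, 8), collapse = " "),
      if (length(x$reduced$genes) > 8) " ..." else "", "]\n", sep = "")
  cat(sprintf("  s_R AUC train %.3f / test %.3f; s_T AUC train %.3f / test %.3f\n",
              s$auc_sR_train, s$auc_sR_test, s$auc_sT_train, s$auc_sT_test))
  cat(sprintf("  DeLong s_R vs s_T (test): z = %.3f, p = %.3f\n",
              s$delong$z, s$delong$p))
  invisible(x)
}
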