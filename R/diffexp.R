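#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums raw counts over all cells belonging to each (patient, condition)
#' group, producing one pseudo-bulk column per group named
#' `<patient>_<condition>`. Groups with no cells simply have no column.
#'
#' @param cells an [expr_matrix()] of per-cell counts.
#' @param cell_meta data.frame with columns `sample_id` (cell barcode),
#'   `condition`, `donor` (patient).
#' @return list with `counts` (pseudo-bulk [expr_matrix()]) and `samples`
#'   (pseudo-bulk sample table with `sample_id`, `condition`, `donor`).
#' @export
pseudobulk <- function(cells, cell_meta) {
  stopifnot(inherits(cells, "expr_matrix"))
  idx <- match(cells$sample_ids, cell_meta$sample_id)
  if (anyNA(idx))
    stop("cells without metadata: ",
         paste(utils::head(cells$sample_ids[is.na(idx)], 3), collapse = ", "))
  meta <- cell_meta[idx, , drop = FALSE]
  if (anyNA(meta$condition) || anyNA(meta$donor))
    stop("cell metadata has missing condition/donor")
  grp <- paste(meta$donor, meta$condition, sep = "_")
  glev <- unique(grp)
  agg <- vapply(glev, function(g)
    rowSums(cells$values[, grp == g, drop = FALSE]), numeric(length(cells$gene_ids)))
  agg <- matrix(agg, nrow = length(cells$gene_ids),
                dimnames = list(NULL, glev))
  key <- !duplicated(grp)
  samples <- data.frame(sample_id = glev,
                        condition = meta$condition[key][match(glev, grp[key])],
                        donor = meta$donor[key][match(glev, grp[key])],
                        stringsAsFactors = FALSE)
  list(counts = expr_matrix(agg, cells$gene_ids, glev, unit = "count"),
       samples = samples)
}

#' Filter lowly expressed genes
#'
#' Keeps a gene iff its count is at least `min_count` in at least
#' `ceiling(min_fraction * n_samples)` samples (the "min 15 counts in at
#' least 50% of patients" style rule).
#'
#' @param counts an [expr_matrix()] of raw counts.
#' @param min_count minimum count.
#' @param min_fraction minimum fraction of samples, in (0, 1].
#' @return Filtered [expr_matrix()].
#' @export
filter_low_expressed <- function(counts, min_count, min_fraction) {
  stopifnot(inherits(counts, "expr_matrix"),
            min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * length(counts$sample_ids))
  keep <- rowSums(counts$values >= min_count) >= need
  expr_matrix(counts$values[keep, , drop = FALSE], counts$gene_ids[keep],
              counts$sample_ids, unit = counts$unit)
}

#' Collapse duplicated gene rows (isoforms) by their mean
#'
#' @param x an [expr_matrix()] possibly containing repeated gene ids.
#' @return [expr_matrix()] with one row per gene id (element-wise mean of
#'   duplicates); unique rows are untouched and original first-occurrence
#'   order is preserved.
#' @export
collapse_isoforms <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!anyDuplicated(x$gene_ids)) return(x)
  f <- factor(x$gene_ids, levels = unique(x$gene_ids))
  vals <- apply(x$values, 2, function(col) tapply(col, f, mean))
  vals <- matrix(vals, nrow = nlevels(f), dimnames = list(NULL, x$sample_ids))
  expr_matrix(vals, levels(f), x$sample_ids, unit = x$unit)
}

#' Reference differential-expression test
#'
#' A deliberately simple, tool-agnostic DE stand-in: for each gene, an
#' ordinary least-squares fit of log2(CPM + 1) on condition plus optional
#' covariates (donor, batch). The reported log2 fold change is the condition
#' coefficient, the p-value the two-sided t-test of that coefficient, and
#' `padj` the Benjamini-Hochberg adjustment. The meta-analysis downstream
#' accepts any externally produced DE table with the same columns.
#'
#' @param counts an [expr_matrix()] of raw counts (filtered, collapsed).
#' @param samples sample table matching the columns of `counts`.
#' @param covariates character vector of extra sample-table columns to
#'   adjust for (e.g. `"donor"`, `"batch"`).
#' @param ref_level reference condition level; defaults to `"N"` or `"OLT"`
#'   when present, else the alphabetically first level.
#' @param lfc_cut,fdr_cut thresholds passed to [label_de()].
#' @return A DE data.frame: `gene`, `log2fc`, `pvalue`, `padj`, `status`.
#' @export
reference_de <- function(counts, samples, covariates = character(0),
                         ref_level = NULL, lfc_cut = 1.5, fdr_cut = 0.05) {
  stopifnot(inherits(counts, "expr_matrix"))
  idx <- match(counts$sample_ids, samples$sample_id)
  if (anyNA(idx)) stop("samples missing from sample table")
  samples <- samples[idx, , drop = FALSE]
  cond <- as.character(samples$condition)
  lev <- sort(unique(cond))
  if (length(lev) != 2) stop("condition must have exactly two levels, got: ",
                             paste(lev, collapse = ", "))
  if (is.null(ref_level)) ref_level <- intersect(c("N", "OLT"), lev)[1]
  if (is.na(ref_level) || !length(ref_level)) ref_level <- lev[1]
  cond <- factor(cond, levels = c(ref_level, setdiff(lev, ref_level)))

  dat <- data.frame(condition = cond)
  for (cv in covariates) {
    if (!cv %in% names(samples)) stop("covariate not in sample table: ", cv)
    dat[[cv]] <- factor(samples[[cv]])
  }
  X <- stats::model.matrix(~ ., data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ", paste(dropped, collapse = ", "))
  }

  libsize <- colSums(counts$values)
  if (any(libsize == 0)) stop("sample with zero total counts")
  y <- log2(sweep(counts$values, 2, libsize, "/") * 1e6 + 1)

  beta <- qr.coef(qrX, t(y))                       # p x genes
  fitted <- X %*% beta
  res <- t(y) - fitted
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrX))
  ci <- which(colnames(X) == paste0("condition", levels(cond)[2]))
  se <- sqrt(sigma2 * xtxinv[ci, ci])
  lfc <- beta[ci, ]
  # constant-expression genes: fitted exactly, so effect and evidence are nil
  tiny <- 1e-8 * (1 + colMeans(abs(t(y))))
  se[sigma2 < tiny^2] <- 0
  lfc[se == 0 & abs(lfc) < tiny] <- 0
  tstat <- ifelse(se > 0, lfc / se, ifelse(abs(lfc) > 0, Inf, 0))
  pval <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(gene = counts$gene_ids, log2fc = unname(lfc),
                    pvalue = unname(pval), stringsAsFactors = FALSE)
  out$padj <- benjamini_hochberg(out$pvalue)
  label_de(out, lfc_cut = lfc_cut, fdr_cut = fdr_cut)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]); validates the
#' input range and propagates `NA`s.
#'
#' @param pvalues numeric vector in \[0, 1\], `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Label DE status from thresholds
#'
#' Inclusive boundaries throughout: `up` iff `log2fc >= lfc_cut` and
#' `padj <= fdr_cut`; `down` symmetric; else `ns`. Genes with `NA` p-values
#' are labelled `ns` (and dropped later, before meta-analysis, with a count).
#'
#' @param table DE data.frame with `log2fc` and `padj`.
#' @param lfc_cut positive log2 fold-change threshold.
#' @param fdr_cut FDR threshold.
#' @return the table with a `status` column.
#' @export
label_de <- function(table, lfc_cut, fdr_cut) {
  stopifnot(lfc_cut > 0, fdr_cut > 0, fdr_cut < 1)
  sig <- !is.na(table$padj) & table$padj <= fdr_cut
  status <- rep("ns", nrow(table))
  status[sig & table$log2fc >= lfc_cut] <- "up"
  status[sig & table$log2fc <= -lfc_cut] <- "down"
  table$status <- status
  table
}

#' Drop genes with missing p-values
#'
#' @param table DE data.frame.
#' @return table without `NA`-p genes; the number removed is reported via
#'   `message()` when positive.
#' @export
drop_na_pvalues <- function(table) {
  na <- is.na(table$pvalue)
  if (any(na)) message("dropping ", sum(na), " gene(s) with NA p-value")
  table[!na, , drop = FALSE]
}
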