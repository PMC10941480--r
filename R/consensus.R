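#' Harmonize per-cohort DE tables into one meta-analysis record table
#'
#' Builds the union gene universe over k cohorts. For each gene, the log2
#' fold change vector holds the measured values with `0` imputed where the
#' gene is absent from a cohort; `present` records which entries were
#' measured; p-values stay missing (`NA`) where unmeasured.
#'
#' @param tables list of DE data.frames (columns `gene`, `log2fc`, `pvalue`).
#'   The study design uses exactly three cohorts; any k >= 2 is accepted.
#' @return An object of class `meta_records`: list with `gene` (character),
#'   `lfc`, `present`, `p` (n x k matrices).
#' @export
harmonize <- function(tables) {
  k <- length(tables)
  if (k < 2) stop("need at least two cohorts")
  for (i in seq_len(k)) {
    if (anyDuplicated(tables[[i]]$gene))
      stop("duplicated genes within cohort ", i)
  }
  genes <- unique(unlist(lapply(tables, `[[`, "gene")))
  n <- length(genes)
  lfc <- matrix(0, n, k)
  present <- matrix(FALSE, n, k)
  p <- matrix(NA_real_, n, k)
  for (i in seq_len(k)) {
    idx <- match(tables[[i]]$gene, genes)
    lfc[idx, i] <- tables[[i]]$log2fc
    present[idx, i] <- TRUE
    p[idx, i] <- tables[[i]]$pvalue
  }
  structure(list(gene = genes, lfc = lfc, present = present, p = p),
            class = "meta_records")
}

#' @export
print.meta_records <- function(x, ...) {
  cat("<meta_records> ", length(x$gene), " genes x ", ncol(x$lfc), " cohorts\n",
      sep = "")
  invisible(x)
}

#' Zero out negligible fold changes
#'
#' Log2 fold changes within `[-band, band]` (inclusive) are set to exactly 0
#' before sign comparison and median computation; the measured flag is kept.
#'
#' @param records a `meta_records` object.
#' @param band half-width of the shrink band (default 0.1).
#' @return updated `meta_records`.
#' @export
shrink_small_lfc <- function(records, band = 0.1) {
  stopifnot(inherits(records, "meta_records"), band > 0)
  records$lfc[abs(records$lfc) <= band] <- 0
  records
}

#' Remove genes with no change in any cohort
#'
#' After shrinking and imputation, a gene whose fold-change vector is all
#' zero carries no directional information and is removed.
#'
#' @param records a `meta_records` object.
#' @return updated `meta_records`; removed count reported via `message()`.
#' @export
drop_all_zero <- function(records) {
  stopifnot(inherits(records, "meta_records"))
  keep <- rowSums(records$lfc != 0) > 0
  if (any(!keep)) message("dropping ", sum(!keep), " all-zero gene(s)")
  subset_records(records, keep)
}

subset_records <- function(records, keep) {
  for (nm in names(records)) {
    el <- records[[nm]]
    records[[nm]] <- if (is.matrix(el)) el[keep, , drop = FALSE] else el[keep]
  }
  records
}

#' Flag discordant genes
#'
#' A gene is discordant iff its (shrunk, imputed) fold-change vector contains
#' at least one strictly positive and one strictly negative entry. Zeros
#' (shrunk or imputed) are sign-neutral.
#'
#' @param records a `meta_records` object.
#' @return updated `meta_records` with a logical `discordant` element.
#' @export
flag_discordant <- function(records) {
  stopifnot(inherits(records, "meta_records"))
  records$discordant <- rowSums(records$lfc > 0) > 0 & rowSums(records$lfc < 0) > 0
  records
}

#' Fisher's combined probability test across cohorts
#'
#' Combines the unadjusted per-cohort p-values of every gene measured in at
#' least two cohorts: X = -2 * sum(log p_i) is referred to the upper tail of
#' a chi-square distribution with 2k degrees of freedom (k = number of
#' available p-values). Genes measured in fewer than two cohorts are removed.
#' Discordant genes have their combined p-value forced to 1. Zero p-values
#' are floored at 1e-300 before the log.
#'
#' @param records a `meta_records` object with `discordant` set.
#' @return updated `meta_records` with `k_avail` and `combined_p`.
#' @export
fisher_combine <- function(records) {
  stopifnot(inherits(records, "meta_records"))
  if (is.null(records$discordant)) stop("run flag_discordant() first")
  p <- records$p
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  k_avail <- rowSums(ok)
  keep <- k_avail >= 2
  if (any(!keep)) message("dropping ", sum(!keep),
                          " gene(s) with fewer than two p-values")
  records <- subset_records(records, keep)
  p <- records$p
  nfloor <- sum(p == 0, na.rm = TRUE)
  if (nfloor) message("flooring ", nfloor, " zero p-value(s) at 1e-300")
  p[!is.na(p) & p == 0] <- 1e-300
  X <- -2 * rowSums(log(p), na.rm = TRUE)
  records$k_avail <- rowSums(!is.na(p))
  records$combined_p <- stats::pchisq(X, df = 2 * records$k_avail,
                                      lower.tail = FALSE)
  records$combined_p[records$discordant] <- 1
  records
}

#' Combined median log2 fold change
#'
#' The median of the full fold-change vector including imputed zeros, so a
#' gene measured in only two cohorts is pulled toward zero (smaller in
#' absolute value than the two-value mean).
#'
#' @param records a `meta_records` object.
#' @return updated `meta_records` with `combined_lfc`.
#' @export
combined_median_lfc <- function(records) {
  stopifnot(inherits(records, "meta_records"))
  records$combined_lfc <- apply(records$lfc, 1, stats::median)
  records
}

#' Select the consensus signature
#'
#' Applies BH adjustment to the combined p-values over all retained genes,
#' then selects genes with adjusted combined p <= `fdr_cut` and
#' |combined median log2FC| >= `lfc_cut` (both boundaries inclusive),
#' splitting them into up- and down-regulated lists.
#'
#' @param records a `meta_records` object with `combined_p`, `combined_lfc`.
#' @param fdr_cut adjusted combined p-value threshold (default 0.01).
#' @param lfc_cut combined |log2FC| threshold (default 1.5).
#' @return An object of class `consensus_signature`: list with `up`, `down`
#'   (character vectors) and `records` (data.frame of all per-gene fields).
#' @export
select_consensus <- function(records, fdr_cut = 0.01, lfc_cut = 1.5) {
  stopifnot(inherits(records, "meta_records"))
  if (is.null(records$combined_p) || is.null(records$combined_lfc))
    stop("run fisher_combine() and combined_median_lfc() first")
  records$combined_fdr <- benjamini_hochberg(records$combined_p)
  sel <- records$combined_fdr <= fdr_cut
  up <- records$gene[sel & records$combined_lfc >= lfc_cut]
  down <- records$gene[sel & records$combined_lfc <= -lfc_cut]
  structure(list(up = up, down = down,
                 records = as.data.frame(records),
                 fdr_cut = fdr_cut, lfc_cut = lfc_cut),
            class = "consensus_signature")
}

#' @export
as.data.frame.meta_records <- function(x, ...) {
  k <- ncol(x$lfc)
  df <- data.frame(gene = x$gene, stringsAsFactors = FALSE)
  for (i in seq_len(k)) df[[paste0("lfc", i)]] <- x$lfc[, i]
  for (i in seq_len(k)) df[[paste0("present", i)]] <- x$present[, i]
  for (i in seq_len(k)) df[[paste0("p", i)]] <- x$p[, i]
  for (nm in c("discordant", "k_avail", "combined_p", "combined_lfc", "combined_fdr"))
    if (!is.null(x[[nm]])) df[[nm]] <- x[[nm]]
  df
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat("Consensus signature: ", length(x$up) + length(x$down), " genes (",
      length(x$up), " up, ", length(x$down), " down)\n", sep = "")
  cat("  cuts: combined FDR <= ", x$fdr_cut, ", |combined log2FC| >= ",
      x$lfc_cut, "\n", sep = "")
  invisible(x)
}

#' @export
summary.consensus_signature <- function(object, ...) {
  r <- object$records
  cat("Genes entering selection: ", nrow(r), "\n", sep = "")
  cat("Discordant (combined p forced to 1): ", sum(r$discordant), "\n", sep = "")
  print(object)
  if (length(object$up)) cat("up:   ", paste(utils::head(object$up, 10), collapse = " "),
                             if (length(object$up) > 10) " ..." else "", "\n", sep = "")
  if (length(object$down)) cat("down: ", paste(utils::head(object$down, 10), collapse = " "),
                               if (length(object$down) > 10) " ..." else "", "\n", sep = "")
  invisible(object)
}

#' Full consensus meta-analysis in one call
#'
#' Runs the complete rule chain on a list of per-cohort DE tables:
#' harmonize (union universe, zero imputation) -> shrink negligible fold
#' changes -> drop all-zero genes -> flag discordant genes -> Fisher
#' combination (>= 2 cohorts; discordant p forced to 1) -> combined median
#' log2FC -> BH -> threshold selection.
#'
#' @param tables list of DE data.frames (`gene`, `log2fc`, `pvalue`); genes
#'   with `NA` p-values are dropped per cohort first.
#' @param fdr_cut,lfc_cut selection thresholds (defaults 0.01 and 1.5).
#' @param band shrink band half-width (default 0.1).
#' @return A [`consensus_signature`][select_consensus] object.
#' @export
consensus_signature <- function(tables, fdr_cut = 0.01, lfc_cut = 1.5,
                                band = 0.1) {
  tables <- lapply(tables, drop_na_pvalues)
  rec <- harmonize(tables)
  rec <- shrink_small_lfc(rec, band = band)
  rec <- drop_all_zero(rec)
  rec <- flag_discordant(rec)
  rec <- fisher_combine(rec)
  rec <- combined_median_lfc(rec)
  select_consensus(rec, fdr_cut = fdr_cut, lfc_cut = lfc_cut)
}

#' Write / read a consensus signature gene list
#'
#' TSV with columns `gene`, `direction`.
#' @param sig a `consensus_signature` or a data.frame with `gene`, `direction`.
#' @param path file path.
#' @export
write_signature <- function(sig, path) {
  if (inherits(sig, "consensus_signature"))
    sig <- data.frame(gene = c(sig$up, sig$down),
                      direction = rep(c("up", "down"),
                                      c(length(sig$up), length(sig$down))),
                      stringsAsFactors = FALSE)
  utils::write.table(sig, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "direction") %in% names(df)))
    stop("signature file needs columns gene, direction")
  df
}
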