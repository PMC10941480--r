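#' Expression matrix container
#'
#' Bundles a numeric genes x samples matrix with its identifier lists and a
#' unit label. Duplicate gene ids are allowed on input (isoform rows) and are
#' only removed by [collapse_isoforms()] / [preprocess_tpm()]; duplicate
#' sample ids are never allowed.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector, one per row.
#' @param sample_ids character vector, one per column, unique.
#' @param unit one of `"count"`, `"tpm"`, `"log2tpm"`, `"logcpm"`, `"zscore"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        sample_ids = colnames(values), unit = "count") {
  unit <- match.arg(unit, c("count", "tpm", "log2tpm", "logcpm", "zscore"))
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != nrow(values) (", nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids), ") != ncol(values) (", ncol(values), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  storage.mode(values) <- "double"
  dimnames(values) <- list(NULL, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", length(x$gene_ids), " genes x ", length(x$sample_ids),
      " samples [", x$unit, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

fmt_num <- function(x) {
  # fixed 10-significant-digit formatting so write(read(x)) round-trips
  out <- sprintf("%.10g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read an expression matrix
#'
#' TSV layout: header line `gene<TAB>sample1<TAB>...`, one row per gene.
#' MatrixMarket layout (`format = "mtx"`): a coordinate triplet `.mtx` file
#' plus sidecar id files; by default `<stem>.genes.txt` and
#' `<stem>.samples.txt` next to the matrix (one id per line).
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param unit unit label recorded on the result.
#' @param genes_path,samples_path sidecar id files for `format = "mtx"`.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx"), unit = "count",
                            genes_path = NULL, samples_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) stop("empty expression file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1]]
    if (length(header) < 2) stop("parse error at line 1: need gene column plus >= 1 sample")
    sample_ids <- header[-1]
    if (anyDuplicated(sample_ids))
      stop("duplicated sample column name(s): ",
           paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
    body <- fields[-1]
    bad <- which(lengths(body) != length(header))
    if (length(bad))
      stop("parse error at line ", bad[1] + 1L, ": expected ",
           length(header), " fields, got ", lengths(body)[bad[1]])
    genes <- vapply(body, `[[`, "", 1L)
    vals <- matrix(as.numeric(unlist(lapply(body, `[`, -1L))),
                   nrow = length(body), byrow = TRUE)
    expr_matrix(vals, genes, sample_ids, unit = unit)
  } else {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(genes_path)) genes_path <- paste0(stem, ".genes.txt")
    if (is.null(samples_path)) samples_path <- paste0(stem, ".samples.txt")
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    samples <- readLines(samples_path)
    expr_matrix(m, genes, samples, unit = unit)
  }
}

#' Write an expression matrix as TSV (10 significant digits)
#'
#' @param x an [expr_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  header <- paste(c("gene", x$sample_ids), collapse = "\t")
  rows <- vapply(seq_along(x$gene_ids), function(i) {
    paste(c(x$gene_ids[i], fmt_num(x$values[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `condition` and optionally `donor`, `batch`.
#' @param path file path.
#' @return data.frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in sample table")
  df
}

#' @rdname read_samples
#' @param df sample data.frame.
#' @export
write_samples <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: `set_id<TAB>description<TAB>gene1<TAB>gene2...`, one set per
#' line, at least one member per set.
#'
#' @param path file path.
#' @return A named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT parse error at line ", short[1], ": fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicated set id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  descr <- vapply(fields, `[[`, "", 2L)
  names(descr) <- ids
  attr(sets, "descriptions") <- descr
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional named descriptions (defaults to set ids).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions)) descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-interaction edge list
#'
#' TSV with columns `protein1`, `protein2`, `combined_score` (integer,
#' 0-1000, STRING-style). Self-loops are dropped with a message; out-of-range
#' scores are an error.
#'
#' @param path file path.
#' @return data.frame with columns `a`, `b`, `combined_score`.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) stop("edge file needs 3 columns (protein1, protein2, combined_score)")
  names(df)[1:3] <- c("a", "b", "combined_score")
  validate_edges(df[c("a", "b", "combined_score")])
}

validate_edges <- function(df) {
  sc <- df$combined_score
  if (any(is.na(sc)) || any(sc != round(sc)))
    stop("combined_score must be integer")
  if (any(sc < 0 | sc > 1000))
    stop("combined_score out of range [0, 1000]: ",
         paste(utils::head(sc[sc < 0 | sc > 1000], 3), collapse = ", "))
  loops <- df$a == df$b
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    df <- df[!loops, , drop = FALSE]
  }
  df$combined_score <- as.integer(df$combined_score)
  rownames(df) <- NULL
  df
}

#' @rdname read_edges
#' @param df edge data.frame.
#' @export
write_edges <- function(df, path) {
  out <- df
  names(out)[1:3] <- c("protein1", "protein2", "combined_score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write differential-expression result tables
#'
#' TSV with columns `gene`, `log2fc`, `pvalue`, `padj`, `status`.
#' @param path file path.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_de_table
#' @param df DE data.frame.
#' @export
write_de_table <- function(df, path) {
  out <- df
  for (col in intersect(c("log2fc", "pvalue", "padj"), names(out)))
    out[[col]] <- fmt_num(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration with study defaults
#'
#' Collects every tunable of the downstream stages. Defaults are the study
#' conditions: per-cohort DE thresholds, meta-analysis cuts (FDR 0.01,
#' |log2FC| 1.5, shrink band 0.1), PPI score filter (> 500), top-50 drugs,
#' elastic-net mixing 0.5 with 100 balanced bootstrap runs and 50% stability
#' selection.
#'
#' @param ... overrides of any default field.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # differential expression
    sc_lfc_cut = 1.5, sc_fdr_cut = 0.05,
    paired_lfc_cut = 0.8, paired_fdr_cut = 0.05,
    paired_min_count = 15, paired_min_fraction = 0.5,
    unpaired_lfc_cut = 1.5, unpaired_fdr_cut = 0.05,
    unpaired_min_count = 5, unpaired_min_fraction = 0.5,
    # consensus meta-analysis
    meta_fdr_cut = 0.01, meta_lfc_cut = 1.5, shrink_band = 0.1,
    # enrichment
    gsea_weight = 1, n_perm = 1000, gsea_fdr_cut = 0.15, ora_fdr_cut = 0.05,
    # drug prioritization
    top_drugs = 50, aggregate = "min",
    # network
    ppi_threshold = 500, n_candidates = 10,
    # risk score
    alpha_mix = 0.5, n_boot = 100, selection_fraction = 0.5,
    n_lambda = 50, lambda_min_ratio = 1e-3,
    coef_average = "all",
    seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  class(cfg) <- "run_config"
  cfg
}

# deterministic per-stage seeds derived from the run seed by fixed offsets
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, de = 211L, consensus = 307L, enrich = 401L,
               drugs = 503L, network = 601L, risk = 701L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}
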