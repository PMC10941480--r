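#' Simulate a complete analysis workspace
#'
#' Writes every input the three pipelines consume, with planted ground
#' truth: three cohorts sharing a concordant signature (single-cell paired,
#' bulk paired, bulk unpaired at the study's cohort sizes), a drug
#' compendium with planted signature-reversing and signature-mimicking
#' profiles, a pathway collection covering the planted signature, a PPI
#' graph with planted direct signature-target edges, a drug-target map, and
#' train/test TPM cohorts with planted informative genes. All generators
#' derive their seeds from `seed` by fixed offsets.
#'
#' @param dir output directory (created).
#' @param seed integer run seed.
#' @param n_genes gene universe size (default 2000).
#' @param n_concordant_up,n_concordant_down,n_discordant planted class sizes
#'   (defaults 40/10/20, rest null).
#' @param n_profiles,n_reversers,n_mimics drug compendium shape.
#' @param n_pathways pathway collection size.
#' @param n_edges random PPI edge count.
#' @param n_informative planted risk-informative genes (default 8).
#' @return `dir`, invisibly; writes a `truth/` subdirectory alongside the
#'   inputs.
#' @export
simulate_workspace <- function(dir, seed = 1, n_genes = 2000,
                               n_concordant_up = 40, n_concordant_down = 10,
                               n_discordant = 20, n_profiles = 200,
                               n_reversers = 5, n_mimics = 5,
                               n_pathways = 300, n_edges = 5000,
                               n_informative = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  s <- stage_seed(seed, "simulate")
  n_null <- n_genes - n_concordant_up - n_concordant_down - n_discordant
  truth <- make_truth(n_concordant_up, n_concordant_down, n_discordant,
                      n_null, effect_lfc = 2, seed = s)
  utils::write.table(truth, file.path(dir, "truth", "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  specs <- table1_cohort_specs(n_genes = n_genes)
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    sim <- simulate_cohort(specs[[i]], truth, cohort_index = i, seed = s + i)
    write_expression(sim$counts, file.path(dir, paste0(nm, "_counts.tsv")))
    write_samples(sim$samples, file.path(dir, paste0(nm, "_samples.tsv")))
  }

  up <- truth$gene[truth$class == "concordant_up"]
  down <- truth$gene[truth$class == "concordant_down"]
  disease <- stats::setNames(rowMeans(truth[, grep("^lfc", names(truth))]),
                             truth$gene)
  comp <- simulate_drug_compendium(disease, n_profiles = n_profiles,
                                   n_reversers = n_reversers,
                                   n_mimics = n_mimics, seed = s + 11)
  prof_em <- expr_matrix(t(comp$profiles), colnames(comp$profiles),
                         rownames(comp$profiles), unit = "zscore")
  write_expression(prof_em, file.path(dir, "drug_profiles.tsv"))
  utils::write.table(comp$manifest, file.path(dir, "drug_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sets <- simulate_pathways(truth$gene, up, down, n_sets = n_pathways,
                            seed = s + 12)
  write_gmt(sets, file.path(dir, "pathways.gmt"))

  # drug targets: every drug targets a couple of random genes; planted
  # direct PPI pairs link signature genes to some of those targets
  set.seed(s + 13)
  drugs <- unique(comp$manifest$drug_id)
  targets <- data.frame(
    drug_id = rep(drugs, each = 2),
    target_gene = sample(truth$gene, 2 * length(drugs), replace = TRUE),
    stringsAsFactors = FALSE)
  utils::write.table(targets, file.path(dir, "drug_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  planted <- data.frame(signature = sample(up, 10, replace = FALSE),
                        target = sample(unique(targets$target_gene), 10,
                                        replace = TRUE),
                        stringsAsFactors = FALSE)
  ppi <- simulate_ppi(truth$gene, up, unique(targets$target_gene),
                      n_edges = n_edges, planted_pairs = planted,
                      seed = s + 14)
  write_edges(ppi$edges, file.path(dir, "ppi_edges.tsv"))
  utils::write.table(planted, file.path(dir, "truth", "planted_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  consensus <- c(up, down)
  rs <- risk_spec(informative_genes = up[seq_len(n_informative)],
                  n_null_genes = max(0, n_genes - length(consensus)))
  risk <- simulate_risk_cohorts(rs, consensus, seed = s + 15)
  write_expression(risk$train, file.path(dir, "train_tpm.tsv"))
  write_expression(risk$test, file.path(dir, "test_tpm.tsv"))
  lab <- function(v) data.frame(sample_id = names(v), condition = unname(v),
                                stringsAsFactors = FALSE)
  write_samples(lab(risk$train_labels), file.path(dir, "train_labels.tsv"))
  write_samples(lab(risk$test_labels), file.path(dir, "test_labels.tsv"))
  writeLines(risk$truth, file.path(dir, "truth", "informative_genes.txt"))
  invisible(dir)
}

de_stage <- function(ws, out, config) {
  read_pair <- function(nm) {
    list(counts = read_expression(file.path(ws, paste0(nm, "_counts.tsv"))),
         samples = read_samples(file.path(ws, paste0(nm, "_samples.tsv"))))
  }
  sc <- read_pair("single_cell")
  pb <- pseudobulk(sc$counts, sc$samples)
  de1 <- reference_de(pb$counts, pb$samples, covariates = "donor",
                      lfc_cut = config$sc_lfc_cut, fdr_cut = config$sc_fdr_cut)

  bp <- read_pair("bulk_paired")
  cnt2 <- collapse_isoforms(filter_low_expressed(bp$counts,
                                                 config$paired_min_count,
                                                 config$paired_min_fraction))
  de2 <- reference_de(cnt2, bp$samples, covariates = "donor",
                      lfc_cut = config$paired_lfc_cut,
                      fdr_cut = config$paired_fdr_cut)

  bu <- read_pair("bulk_unpaired")
  cnt3 <- collapse_isoforms(filter_low_expressed(bu$counts,
                                                 config$unpaired_min_count,
                                                 config$unpaired_min_fraction))
  cov3 <- if ("batch" %in% names(bu$samples)) "batch" else character(0)
  de3 <- reference_de(cnt3, bu$samples, covariates = cov3,
                      lfc_cut = config$unpaired_lfc_cut,
                      fdr_cut = config$unpaired_fdr_cut)
  tabs <- list(de1, de2, de3)
  for (i in 1:3)
    write_de_table(tabs[[i]], file.path(out, sprintf("de_cohort%d.tsv", i)))
  tabs
}

#' Run the full pipeline on a simulated or user workspace
#'
#' Reads the workspace inputs, runs per-cohort differential expression, the
#' consensus meta-analysis, signature enrichment, drug prioritization,
#' network proximity and the risk score, writing every stage output under
#' `out`.
#'
#' @param ws workspace directory (see [simulate_workspace()]).
#' @param out output directory (created).
#' @param config a [run_config()].
#' @return list of in-memory stage results, invisibly.
#' @export
run_workspace <- function(ws, out, config = run_config()) {
  for (f in c("single_cell_counts.tsv", "bulk_paired_counts.tsv",
              "bulk_unpaired_counts.tsv"))
    if (!file.exists(file.path(ws, f))) stop("missing workspace input: ", f)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  tabs <- de_stage(ws, out, config)
  sig <- consensus_signature(tabs, fdr_cut = config$meta_fdr_cut,
                             lfc_cut = config$meta_lfc_cut,
                             band = config$shrink_band)
  utils::write.table(sig$records, file.path(out, "consensus_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_signature(sig, file.path(out, "consensus_signature.tsv"))

  sets_gmt <- read_gmt(file.path(ws, "pathways.gmt"))
  rec <- sig$records
  ranked <- rank_genes(stats::setNames(rec$combined_lfc, rec$gene))
  enr <- gsea_preranked(ranked, sets_gmt, n_perm = max(100, config$n_perm),
                        seed = stage_seed(config$seed, "enrich"))
  utils::write.table(enr, file.path(out, "enrichment_gsea.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rpd <- running_plot_data(ranked, c(sig$up, sig$down))
  utils::write.table(rpd, file.path(out, "running_plot.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prof_em <- read_expression(file.path(ws, "drug_profiles.tsv"), unit = "zscore")
  profiles <- t(prof_em$values)
  rownames(profiles) <- prof_em$sample_ids
  colnames(profiles) <- prof_em$gene_ids
  manifest <- utils::read.delim(file.path(ws, "drug_manifest.tsv"),
                                stringsAsFactors = FALSE)
  peps <- build_peps(profiles, sets_gmt, weight_exp = config$gsea_weight)
  sets <- select_signature_pathways(sets_gmt, sig)
  ranking <- rank_drugs(peps, sets, manifest, aggregate = config$aggregate)
  utils::write.table(as.data.frame(ranking), file.path(out, "drug_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  edges <- read_edges(file.path(ws, "ppi_edges.tsv"))
  g <- filter_ppi(ppi_graph(edges), threshold = config$ppi_threshold)
  tmap <- utils::read.delim(file.path(ws, "drug_targets.tsv"),
                            stringsAsFactors = FALSE)
  top <- top_k(ranking, min(config$top_drugs, nrow(ranking)))
  top_targets <- unique(tmap$target_gene[tmap$drug_id %in% top])
  prox <- proximity(g, c(sig$up, sig$down), top_targets)
  utils::write.table(prox, file.path(out, "proximity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sub <- extract_subgraph(g, c(sig$up, sig$down), top_targets)
  sub_edges <- igraph::as_data_frame(sub$graph, what = "edges")
  utils::write.table(sub_edges, file.path(out, "subgraph_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sub$nodes, file.path(out, "subgraph_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- select_validation_candidates(sig$up, prox, k = config$n_candidates)
  writeLines(cand, file.path(out, "validation_candidates.txt"))

  train <- read_expression(file.path(ws, "train_tpm.tsv"), unit = "tpm")
  test <- read_expression(file.path(ws, "test_tpm.tsv"), unit = "tpm")
  trl <- read_samples(file.path(ws, "train_labels.tsv"))
  tel <- read_samples(file.path(ws, "test_labels.tsv"))
  rcfg <- config
  rcfg$seed <- stage_seed(config$seed, "risk")
  risk <- risk_pipeline(train, test,
                        stats::setNames(trl$condition, trl$sample_id),
                        stats::setNames(tel$condition, tel$sample_id),
                        c(sig$up, sig$down), config = rcfg)
  utils::write.table(risk$scores, file.path(out, "risk_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(reduced = list(genes = risk$reduced$genes,
                        coefficients = unname(risk$reduced$coefficients)),
         total = list(genes = risk$total$genes,
                      coefficients = unname(risk$total$coefficients)),
         stats = list(auc_sR_test = risk$stats$auc_sR_test,
                      auc_sT_test = risk$stats$auc_sT_test,
                      delong_z = risk$stats$delong$z,
                      delong_p = risk$stats$delong$p)),
    file.path(out, "risk_model.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(risk$reduced$selection,
                     file.path(out, "risk_selection_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(de = tabs, signature = sig, enrichment = enr,
                 ranking = ranking, proximity = prox, candidates = cand,
                 risk = risk))
}

cli_usage <- function() {
  cat("usage: oasig <subcommand> [flags]\n",
      "subcommands: simulate, run-all, de, consensus, drugs, network, risk\n",
      "flags: --seed INT  --workspace DIR  --out DIR  [--config FILE.yaml]\n",
      sep = "")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(NULL)
    key <- sub("^--", "", a)
    if (i + 1 > length(args)) return(NULL)
    flags[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

#' Command-line entry point
#'
#' Thin dispatcher over [simulate_workspace()] and [run_workspace()]:
#' `simulate --seed S --out DIR` writes a seeded fixture workspace;
#' `run-all --seed S --workspace DIR --out DIR` runs every stage;
#' the per-stage subcommands (`de`, `consensus`, `drugs`, `network`,
#' `risk`) run the same pipeline and are provided for orchestration
#' symmetry. Returns a shell exit code (0 success, 1 missing input,
#' 2 usage error) rather than calling `quit()`, so it is testable
#' in-process; `inst/scripts/oasig` wraps it for the shell.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
oa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(2L)) }
  cmd <- args[1]
  known <- c("simulate", "run-all", "de", "consensus", "enrich", "drugs",
             "network", "risk")
  if (!cmd %in% known) { cli_usage(); return(invisible(2L)) }
  flags <- parse_flags(args[-1])
  if (is.null(flags)) { cli_usage(); return(invisible(2L)) }
  seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else 1L
  cfg_args <- list(seed = seed)
  if (!is.null(flags$config)) {
    if (!file.exists(flags$config)) {
      message("config file not found: ", flags$config); return(invisible(1L))
    }
    y <- parse_simple_yaml(flags$config)
    cfg_args <- utils::modifyList(y, cfg_args["seed"])
  }
  config <- do.call(run_config, cfg_args)
  out <- flags$out
  if (is.null(out)) { message("--out is required"); return(invisible(1L)) }
  if (cmd == "simulate") {
    simulate_workspace(out, seed = seed)
    message("workspace written to ", out)
    return(invisible(0L))
  }
  ws <- flags$workspace
  if (is.null(ws) || !dir.exists(ws)) {
    message("missing or absent --workspace directory")
    return(invisible(1L))
  }
  res <- tryCatch(run_workspace(ws, out, config), error = function(e) {
    message("error: ", conditionMessage(e)); NULL
  })
  invisible(if (is.null(res)) 1L else 0L)
}

# minimal "key: value" YAML subset reader for run_config overrides
parse_simple_yaml <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl(":", lines, fixed = TRUE) & !grepl("^\\s*#", lines)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
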