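#' Planted ground truth for the meta-analysis
#'
#' Assigns each gene a class — concordant up, concordant down, discordant, or
#' null — and draws per-cohort true log2 fold changes. Concordant effects are
#' `sign * effect_lfc * U(0.8, 1.2)` independently per cohort; discordant
#' genes receive strictly opposite signs in two cohorts (the third gets a
#' random sign); null genes are zero everywhere.
#'
#' @param n_concordant_up,n_concordant_down,n_discordant,n_null class sizes.
#' @param effect_lfc base |log2FC| of planted effects (> 0).
#' @param n_cohorts number of cohorts (default 3).
#' @param seed integer seed.
#' @return data.frame with `gene`, `class`, and `lfc1..lfck` columns.
#' @export
make_truth <- function(n_concordant_up, n_concordant_down, n_discordant,
                       n_null, effect_lfc = 2, n_cohorts = 3, seed = 1) {
  stopifnot(n_concordant_up >= 0, n_concordant_down >= 0,
            n_discordant >= 0, n_null >= 0)
  if (effect_lfc <= 0) stop("effect_lfc must be > 0")
  set.seed(as.integer(seed))
  n <- n_concordant_up + n_concordant_down + n_discordant + n_null
  gene <- sprintf("G%05d", seq_len(n))
  cls <- rep(c("concordant_up", "concordant_down", "discordant", "null"),
             c(n_concordant_up, n_concordant_down, n_discordant, n_null))
  lfc <- matrix(0, n, n_cohorts)
  mag <- function(m) effect_lfc * stats::runif(m, 0.8, 1.2)
  for (j in seq_len(n_cohorts)) {
    lfc[cls == "concordant_up", j] <- mag(n_concordant_up)
    lfc[cls == "concordant_down", j] <- -mag(n_concordant_down)
  }
  if (n_discordant > 0) {
    for (i in which(cls == "discordant")) {
      pair <- sample.int(n_cohorts, 2)
      signs <- integer(n_cohorts)
      signs[pair] <- c(1, -1)
      signs[signs == 0] <- sample(c(-1, 1), sum(signs == 0), replace = TRUE)
      lfc[i, ] <- signs * mag(n_cohorts)
    }
  }
  out <- data.frame(gene = gene, class = cls, stringsAsFactors = FALSE)
  for (j in seq_len(n_cohorts)) out[[paste0("lfc", j)]] <- lfc[, j]
  out
}

#' Cohort design specification
#'
#' @param design `"single_cell_paired"`, `"bulk_paired"` or
#'   `"bulk_unpaired"`.
#' @param n_genes gene count.
#' @param n_donors donors for paired designs.
#' @param n_case,n_ctrl per-class sample counts (unpaired design).
#' @param cells_per_group cells per donor x condition (single-cell design).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_range library-size range (uniform draw per column).
#' @param donor_sd,batch_sd log-scale effect standard deviations.
#' @param n_batches number of batch levels (0 = no batch structure).
#' @param conditions condition labels, control first.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(design = c("bulk_unpaired", "bulk_paired", "single_cell_paired"),
                        n_genes = 2000, n_donors = 12, n_case = 60, n_ctrl = 10,
                        cells_per_group = 100, dispersion = 0.1,
                        libsize_range = c(8e5, 1.2e6), donor_sd = 0.1,
                        batch_sd = 0.1, n_batches = 0,
                        conditions = c("N", "OA")) {
  design <- match.arg(design)
  structure(list(design = design, n_genes = n_genes, n_donors = n_donors,
                 n_case = n_case, n_ctrl = n_ctrl,
                 cells_per_group = cells_per_group, dispersion = dispersion,
                 libsize_range = libsize_range, donor_sd = donor_sd,
                 batch_sd = batch_sd, n_batches = n_batches,
                 conditions = conditions),
            class = "cohort_spec")
}

#' The three study-cohort specifications
#'
#' Cohort sizes mirror the study design: a single-cell paired cohort of 3
#' donors (damaged vs minimally damaged tissue, pseudo-bulked downstream), a
#' paired bulk cohort of 12 donors, and an unpaired bulk cohort of 60 cases
#' vs 10 controls with a batch structure.
#'
#' @param n_genes shared gene universe size (default 2000).
#' @return named list of three [cohort_spec()]s.
#' @export
table1_cohort_specs <- function(n_genes = 2000) {
  list(
    single_cell = cohort_spec("single_cell_paired", n_genes = n_genes,
                              n_donors = 3, cells_per_group = 100,
                              dispersion = 0.3, libsize_range = c(2000, 6000),
                              donor_sd = 0.15, conditions = c("OLT", "MT")),
    bulk_paired = cohort_spec("bulk_paired", n_genes = n_genes, n_donors = 12,
                              dispersion = 0.1, donor_sd = 0.2),
    bulk_unpaired = cohort_spec("bulk_unpaired", n_genes = n_genes,
                                n_case = 60, n_ctrl = 10, dispersion = 0.1,
                                n_batches = 2, batch_sd = 0.15))
}

#' Simulate an RNA-seq count cohort
#'
#' Negative-binomial counts with per-column expected values
#' `libsize * softmax(baseline + condition * log2FC * ln 2 + donor + batch)`:
#' gene baselines are log-normal, donor and batch effects are additive
#' Gaussian perturbations on the log scale, and the planted condition effect
#' for each gene comes from the truth table's column for this cohort.
#'
#' @param spec a [cohort_spec()].
#' @param truth data.frame from [make_truth()].
#' @param cohort_index which truth log2FC column applies to this cohort.
#' @param seed integer seed.
#' @return list with `counts` ([expr_matrix()]) and `samples` (data.frame
#'   with `sample_id`, `condition`, and `donor`/`batch` where applicable).
#' @export
simulate_cohort <- function(spec, truth, cohort_index = 1, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_genes <- spec$n_genes
  if (nrow(truth) != n_genes)
    stop("truth covers ", nrow(truth), " genes but spec expects ", n_genes)
  set.seed(as.integer(seed))
  lfc <- truth[[paste0("lfc", cohort_index)]]
  # null genes span the full abundance range (so expression filters have
  # work to do); planted genes are solidly expressed, as DE genes worth
  # planting must clear the count filters to be identifiable at all
  baseline <- stats::rnorm(n_genes, mean = 4, sd = 1.5)  # natural-log scale
  planted <- truth$class != "null"
  baseline[planted] <- stats::rnorm(sum(planted), mean = 6, sd = 0.8)

  cond_ctrl <- spec$conditions[1]
  cond_case <- spec$conditions[2]
  if (spec$design == "bulk_unpaired") {
    n <- spec$n_case + spec$n_ctrl
    condition <- rep(c(cond_case, cond_ctrl), c(spec$n_case, spec$n_ctrl))
    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      condition = condition, stringsAsFactors = FALSE)
    if (spec$n_batches > 0)
      samples$batch <- paste0("B", rep_len(seq_len(spec$n_batches), n))
    donor_of <- NULL
  } else if (spec$design == "bulk_paired") {
    donors <- sprintf("D%02d", seq_len(spec$n_donors))
    samples <- data.frame(
      sample_id = paste0(rep(donors, each = 2), "_", c(cond_ctrl, cond_case)),
      condition = rep(c(cond_ctrl, cond_case), spec$n_donors),
      donor = rep(donors, each = 2), stringsAsFactors = FALSE)
    donor_of <- samples$donor
  } else {
    donors <- sprintf("P%02d", seq_len(spec$n_donors))
    grid <- expand.grid(cell = seq_len(spec$cells_per_group),
                        condition = c(cond_ctrl, cond_case), donor = donors,
                        stringsAsFactors = FALSE)
    samples <- data.frame(
      sample_id = sprintf("%s_%s_c%03d", grid$donor, grid$condition, grid$cell),
      condition = grid$condition, donor = grid$donor, stringsAsFactors = FALSE)
    donor_of <- samples$donor
  }

  n <- nrow(samples)
  logmu <- matrix(baseline, n_genes, n)
  case <- samples$condition == cond_case
  logmu[, case] <- logmu[, case] + lfc * log(2)
  if (!is.null(donor_of)) {
    donors <- unique(donor_of)
    deff <- matrix(stats::rnorm(n_genes * length(donors), 0, spec$donor_sd),
                   n_genes, length(donors))
    logmu <- logmu + deff[, match(donor_of, donors), drop = FALSE]
  }
  if (!is.null(samples$batch)) {
    batches <- unique(samples$batch)
    beff <- matrix(stats::rnorm(n_genes * length(batches), 0, spec$batch_sd),
                   n_genes, length(batches))
    logmu <- logmu + beff[, match(samples$batch, batches), drop = FALSE]
  }
  prob <- exp(sweep(logmu, 2, apply(logmu, 2, max), "-"))
  prob <- sweep(prob, 2, colSums(prob), "/")
  libsize <- stats::runif(n, spec$libsize_range[1], spec$libsize_range[2])
  mu <- sweep(prob, 2, libsize, "*")
  counts <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = 1 / spec$dispersion),
                   n_genes, n)
  list(counts = expr_matrix(counts, truth$gene, samples$sample_id, unit = "count"),
       samples = samples)
}

#' Simulate a drug-induced expression compendium
#'
#' Profiles are differential-expression score vectors over the gene
#' universe. Planted reversers are `-disease_scores + noise`, planted mimics
#' `+disease_scores + noise`, everything else pure noise on the scale of the
#' disease scores. A drug may own several profiles (noisy replicates of its
#' archetype).
#'
#' @param disease_scores named numeric vector over the gene universe.
#' @param n_profiles total profile count.
#' @param n_reversers,n_mimics planted class sizes.
#' @param profiles_per_drug replicates per drug (default 1).
#' @param noise_sd Gaussian noise sd as a multiple of `sd(disease_scores)`.
#' @param seed integer seed.
#' @return list with `profiles` (profiles x genes matrix), `manifest`
#'   (data.frame `profile_id`, `drug_id`, `class`).
#' @export
simulate_drug_compendium <- function(disease_scores, n_profiles = 200,
                                     n_reversers = 5, n_mimics = 5,
                                     profiles_per_drug = 1, noise_sd = 0.5,
                                     seed = 1) {
  if (is.null(names(disease_scores))) stop("disease_scores must be named by gene")
  if (n_reversers + n_mimics > n_profiles / profiles_per_drug)
    stop("more planted drugs than profiles allow")
  set.seed(as.integer(seed))
  n_drugs <- n_profiles %/% profiles_per_drug
  if (n_drugs * profiles_per_drug != n_profiles)
    stop("n_profiles must be a multiple of profiles_per_drug")
  g <- length(disease_scores)
  scale <- stats::sd(disease_scores)
  cls <- rep("null", n_drugs)
  cls[seq_len(n_reversers)] <- "reverser"
  if (n_mimics > 0) cls[n_reversers + seq_len(n_mimics)] <- "mimic"
  cls <- sample(cls)  # shuffle drug order
  drug_id <- sprintf("DRUG%04d", seq_len(n_drugs))
  archetype <- matrix(0, n_drugs, g)
  for (i in which(cls == "reverser")) archetype[i, ] <- -disease_scores
  for (i in which(cls == "mimic")) archetype[i, ] <- disease_scores
  rows <- rep(seq_len(n_drugs), each = profiles_per_drug)
  profiles <- archetype[rows, , drop = FALSE] +
    matrix(stats::rnorm(n_profiles * g, 0, noise_sd * scale), n_profiles, g)
  colnames(profiles) <- names(disease_scores)
  manifest <- data.frame(
    profile_id = sprintf("%s_p%d", drug_id[rows],
                         rep(seq_len(profiles_per_drug), n_drugs)),
    drug_id = drug_id[rows], class = cls[rows], stringsAsFactors = FALSE)
  rownames(profiles) <- manifest$profile_id
  list(profiles = profiles, manifest = manifest)
}

#' Simulate a pathway collection covering a signature
#'
#' Random gene sets of sizes drawn from `size_range`; every signature gene is
#' guaranteed to belong to at least one set (appended to a random set when
#' left uncovered), so the up/down pathway sets downstream are non-empty.
#'
#' @param gene_universe character vector.
#' @param signature_up,signature_down signature gene lists.
#' @param n_sets number of sets (> 0).
#' @param size_range integer range of set sizes.
#' @param seed integer seed.
#' @return named list of gene sets (GMT-compatible).
#' @export
simulate_pathways <- function(gene_universe, signature_up, signature_down,
                              n_sets = 300, size_range = c(10, 50), seed = 1) {
  if (n_sets <= 0) stop("n_sets must be > 0")
  if (max(size_range) > length(gene_universe)) stop("size_range exceeds universe")
  set.seed(as.integer(seed))
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_universe, s))
  names(sets) <- sprintf("PW%04d", seq_len(n_sets))
  sig <- unique(c(signature_up, signature_down))
  covered <- sig %in% unique(unlist(sets))
  for (gene in sig[!covered]) {
    i <- sample.int(n_sets, 1)
    sets[[i]] <- c(sets[[i]], gene)
  }
  attr(sets, "descriptions") <- stats::setNames(
    paste("synthetic pathway", seq_len(n_sets)), names(sets))
  sets
}

#' Simulate a protein-interaction graph with planted signature-target links
#'
#' Random edges with uniform integer scores in 1..1000, plus planted direct
#' edges between chosen (signature gene, drug target) pairs carrying scores
#' in `planted_score_range` (min must exceed 500 so planted pairs survive
#' the confidence filter).
#'
#' @param gene_universe node namespace.
#' @param signature_genes,target_genes node subsets.
#' @param n_edges random edge count.
#' @param planted_pairs data.frame with columns `signature`, `target`.
#' @param planted_score_range integer range for planted edge scores.
#' @param seed integer seed.
#' @return list with `edges` (data.frame `a`, `b`, `combined_score`) and
#'   `planted` (the planted pair table).
#' @export
simulate_ppi <- function(gene_universe, signature_genes, target_genes,
                         n_edges = 5000, planted_pairs = NULL,
                         planted_score_range = c(700, 1000), seed = 1) {
  if (planted_score_range[1] <= 500)
    stop("planted edge scores must exceed 500 to survive the confidence filter")
  if (!is.null(planted_pairs)) {
    if (!all(planted_pairs$signature %in% signature_genes) ||
        !all(planted_pairs$target %in% target_genes))
      stop("planted pairs must link signature genes to target genes")
  }
  set.seed(as.integer(seed))
  a <- sample(gene_universe, n_edges, replace = TRUE)
  b <- sample(gene_universe, n_edges, replace = TRUE)
  keep <- a != b
  edges <- data.frame(a = a[keep], b = b[keep],
                      combined_score = sample.int(1000, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  if (!is.null(planted_pairs) && nrow(planted_pairs)) {
    pl <- data.frame(a = planted_pairs$signature, b = planted_pairs$target,
                     combined_score = sample(planted_score_range[1]:planted_score_range[2],
                                             nrow(planted_pairs), replace = TRUE),
                     stringsAsFactors = FALSE)
    # planted score wins over any random duplicate of the same pair
    key <- function(d) paste(pmin(d$a, d$b), pmax(d$a, d$b))
    edges <- edges[!key(edges) %in% key(pl), , drop = FALSE]
    edges <- rbind(pl, edges)
  }
  rownames(edges) <- NULL
  list(edges = edges, planted = planted_pairs)
}

#' Risk-cohort specification
#'
#' @param informative_genes genes carrying a class effect (subset of the
#'   consensus signature; up-shifted in cases, matching the study's selected
#'   genes all being up-regulated consensus genes).
#' @param effect mean log2(TPM) shift in cases.
#' @param gene_sd within-class sd of log2(TPM).
#' @param n_train_ctrl,n_train_case,n_test_ctrl,n_test_case cohort sizes
#'   (defaults 10/60 train, 18/20 test).
#' @param n_null_genes background genes without class effect.
#' @param test_shift,test_scale mild global location/scale distortion of the
#'   test cohort (exercises test-to-train rescaling).
#' @return list of class `risk_spec`.
#' @export
risk_spec <- function(informative_genes, effect = 2, gene_sd = 1,
                      n_train_ctrl = 10, n_train_case = 60,
                      n_test_ctrl = 18, n_test_case = 20,
                      n_null_genes = 957, test_shift = 0.3, test_scale = 1.1) {
  structure(list(informative_genes = informative_genes, effect = effect,
                 gene_sd = gene_sd, n_train_ctrl = n_train_ctrl,
                 n_train_case = n_train_case, n_test_ctrl = n_test_ctrl,
                 n_test_case = n_test_case, n_null_genes = n_null_genes,
                 test_shift = test_shift, test_scale = test_scale),
            class = "risk_spec")
}

#' Simulate paired train/test TPM cohorts for risk scoring
#'
#' Log-normal TPM values: `log2(TPM)` is Gaussian around a per-gene baseline,
#' with informative genes shifted upward by `effect` in cases. The test
#' cohort receives a mild global location/scale distortion so the
#' quantile-rescaling step has real work to do. A small block of genes is
#' zeroed in most samples to exercise the TPM > 0 filter.
#'
#' @param spec a [risk_spec()].
#' @param consensus_genes full consensus gene list (model universe).
#' @param seed integer seed.
#' @return list with `train`, `test` ([expr_matrix()], unit `tpm`),
#'   `train_labels`, `test_labels` (character vectors, `"N"`/`"OA"`), and
#'   `truth` (the informative gene list).
#' @export
simulate_risk_cohorts <- function(spec, consensus_genes, seed = 1) {
  stopifnot(inherits(spec, "risk_spec"))
  if (!all(spec$informative_genes %in% consensus_genes))
    stop("informative genes must be a subset of the consensus genes")
  set.seed(as.integer(seed))
  null_genes <- if (spec$n_null_genes > 0)
    sprintf("BG%05d", seq_len(spec$n_null_genes)) else character(0)
  genes <- c(consensus_genes, null_genes)
  g <- length(genes)
  baseline <- stats::rnorm(g, mean = 4, sd = 1.5)
  inf <- genes %in% spec$informative_genes
  background <- !(genes %in% consensus_genes)

  gen <- function(n_ctrl, n_case, shift, scale) {
    n <- n_ctrl + n_case
    lab <- rep(c("N", "OA"), c(n_ctrl, n_case))
    l2 <- matrix(stats::rnorm(g * n, baseline, spec$gene_sd), g, n)
    l2[inf, lab == "OA"] <- l2[inf, lab == "OA"] + spec$effect
    l2 <- l2 * scale + shift
    tpm <- pmax(2^l2 - 1, 0)
    # a sparse block of background dropout genes exercises the TPM>0
    # majority filter without touching the consensus model universe
    n_zero <- max(1L, g %/% 50L)
    pool <- if (any(background)) which(background) else which(!inf)
    zi <- pool[seq_len(min(n_zero, length(pool)))]
    for (i in zi) tpm[i, sample.int(n, ceiling(0.6 * n))] <- 0
    list(tpm = tpm, lab = lab)
  }
  tr <- gen(spec$n_train_ctrl, spec$n_train_case, 0, 1)
  te <- gen(spec$n_test_ctrl, spec$n_test_case, spec$test_shift, spec$test_scale)
  ids <- function(prefix, lab) sprintf("%s%03d_%s", prefix, seq_along(lab), lab)
  train_ids <- ids("TR", tr$lab)
  test_ids <- ids("TE", te$lab)
  list(train = expr_matrix(tr$tpm, genes, train_ids, unit = "tpm"),
       test = expr_matrix(te$tpm, genes, test_ids, unit = "tpm"),
       train_labels = stats::setNames(tr$lab, train_ids),
       test_labels = stats::setNames(te$lab, test_ids),
       truth = spec$informative_genes)
}
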