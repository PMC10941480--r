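test_that("planted truth respects class counts, signs and determinism", {
  tr <- make_truth(2, 1, 1, 4, effect_lfc = 2, seed = 1)
  expect_equal(nrow(tr), 8)
  expect_equal(sum(tr$class == "concordant_up"), 2)
  lfc <- as.matrix(tr[grep("^lfc", names(tr))])
  up <- tr$class == "concordant_up"
  expect_true(all(lfc[up, ] > 0))
  expect_true(all(lfc[tr$class == "concordant_down", ] < 0))
  disc <- lfc[tr$class == "discordant", , drop = FALSE]
  expect_true(all(apply(disc, 1, function(v) any(v > 0) && any(v < 0))))
  expect_true(all(lfc[tr$class == "null", ] == 0))
  # magnitudes within the planted band
  expect_true(all(abs(lfc[up, ]) >= 1.6 & abs(lfc[up, ]) <= 2.4))
  expect_identical(tr, make_truth(2, 1, 1, 4, effect_lfc = 2, seed = 1))
  expect_error(make_truth(1, 1, 1, 1, effect_lfc = 0), "effect_lfc")
})

test_that("simulated cohorts have the declared shape and are seeded", {
  tr <- make_truth(5, 5, 0, 190, seed = 2)
  spec <- cohort_spec("bulk_unpaired", n_genes = 200, n_case = 60, n_ctrl = 10)
  sim <- simulate_cohort(spec, tr, cohort_index = 1, seed = 3)
  expect_equal(dim(sim$counts), c(200, 70))
  expect_true(all(sim$counts$values >= 0))
  expect_true(all(sim$counts$values == round(sim$counts$values)))
  expect_equal(sum(sim$samples$condition == "OA"), 60)
  sim2 <- simulate_cohort(spec, tr, cohort_index = 1, seed = 3)
  expect_identical(sim$counts$values, sim2$counts$values)

  spec_p <- cohort_spec("bulk_paired", n_genes = 200, n_donors = 12)
  simp <- simulate_cohort(spec_p, tr, seed = 3)
  expect_equal(dim(simp$counts), c(200, 24))
  expect_true(all(table(simp$samples$donor) == 2))

  spec_sc <- cohort_spec("single_cell_paired", n_genes = 200, n_donors = 3,
                         cells_per_group = 10, libsize_range = c(2000, 6000),
                         conditions = c("OLT", "MT"))
  simc <- simulate_cohort(spec_sc, tr, seed = 3)
  expect_equal(dim(simc$counts), c(200, 60))
})

test_that("empirical fold changes approach planted values as noise vanishes", {
  # planted genes are a negligible library fraction here, so the softmax
  # compositional attenuation is ~0 and the CPM ratio recovers the truth
  tr <- make_truth(3, 0, 0, 1997, effect_lfc = 2, seed = 5)
  spec <- cohort_spec("bulk_unpaired", n_genes = 2000, n_case = 40, n_ctrl = 40,
                      dispersion = 1e-4, libsize_range = c(5e6, 5e6))
  sim <- simulate_cohort(spec, tr, cohort_index = 1, seed = 6)
  oa <- sim$samples$condition == "OA"
  cpm <- sweep(sim$counts$values, 2, colSums(sim$counts$values), "/")
  emp <- log2(rowMeans(cpm[, oa]) / rowMeans(cpm[, !oa]))
  planted <- tr$lfc1[1:3]
  expect_true(all(abs(emp[1:3] - planted) < 0.1))
})

test_that("planted log2FC = 2 genes show a ~4x count ratio at study sizes", {
  # Monte-Carlo check: mean empirical OA/N ratio over seeds within [2.5, 6.5]
  ratios <- sapply(1:10, function(s) {
    tr <- make_truth(5, 0, 0, 495, effect_lfc = 2, seed = s)
    tr$lfc1 <- ifelse(tr$class == "concordant_up", 2, 0)  # exact planted lfc
    spec <- cohort_spec("bulk_unpaired", n_genes = 500, n_case = 60,
                        n_ctrl = 10, dispersion = 0.1)
    sim <- simulate_cohort(spec, tr, cohort_index = 1, seed = s + 100)
    oa <- sim$samples$condition == "OA"
    cpm <- sweep(sim$counts$values, 2, colSums(sim$counts$values), "/") * 1e6
    mean(rowMeans(cpm[1:5, oa]) / rowMeans(cpm[1:5, !oa]))
  })
  expect_gt(mean(ratios), 2.5)
  expect_lt(mean(ratios), 6.5)
})

test_that("drug compendium plants reversers and mimics as labelled", {
  set.seed(9)
  disease <- setNames(rnorm(300), sprintf("G%03d", 1:300))
  comp <- simulate_drug_compendium(disease, n_profiles = 200, n_reversers = 5,
                                   n_mimics = 5, noise_sd = 0.5, seed = 1)
  expect_equal(dim(comp$profiles), c(200, 300))
  rc <- apply(comp$profiles, 1, function(p) cor(p, disease, method = "spearman"))
  rev_ids <- comp$manifest$class == "reverser"
  expect_true(all(rc[rev_ids] < -0.5))
  expect_equal(sum(rc < -0.5), 5)
  expect_true(all(rc[comp$manifest$class == "mimic"] > 0.5))
  # exact reversal at zero noise
  comp0 <- simulate_drug_compendium(disease, n_profiles = 20, n_reversers = 1,
                                    n_mimics = 0, noise_sd = 0, seed = 1)
  r0 <- comp0$profiles[comp0$manifest$class == "reverser", ]
  expect_equal(cor(r0, disease, method = "spearman"), -1)
  comp2 <- simulate_drug_compendium(disease, n_profiles = 200, n_reversers = 5,
                                    n_mimics = 5, noise_sd = 0.5, seed = 1)
  expect_identical(comp$profiles, comp2$profiles)
})

test_that("simulated pathways cover every signature gene", {
  genes <- sprintf("G%04d", 1:500)
  up <- sample(genes, 39)
  down <- setdiff(sample(genes, 50), up)[1:5]
  sets <- simulate_pathways(genes, up, down, n_sets = 300,
                            size_range = c(5, 30), seed = 2)
  expect_length(sets, 300)
  members <- unique(unlist(sets))
  expect_true(all(c(up, down) %in% members))
  expect_error(simulate_pathways(genes, up, down, n_sets = 0), "n_sets")
  expect_identical(sets, simulate_pathways(genes, up, down, n_sets = 300,
                                           size_range = c(5, 30), seed = 2))
})

test_that("simulated PPI plants high-confidence direct pairs only", {
  genes <- sprintf("G%03d", 1:200)
  sig <- genes[1:20]; targ <- genes[101:120]
  pairs <- data.frame(signature = sig[1:5], target = targ[1:5])
  ppi <- simulate_ppi(genes, sig, targ, n_edges = 1000, planted_pairs = pairs,
                      seed = 3)
  g <- filter_ppi(ppi_graph(ppi$edges), 500)
  d <- proximity(g, pairs$signature, pairs$target)
  expect_true(all(d$distance == 1))
  expect_error(
    simulate_ppi(genes, sig, targ, planted_pairs = pairs,
                 planted_score_range = c(400, 600)),
    "exceed 500")
  ppi2 <- simulate_ppi(genes, sig, targ, n_edges = 1000, planted_pairs = pairs,
                       seed = 3)
  expect_identical(ppi$edges, ppi2$edges)
})

test_that("risk cohorts carry planted shifts with the declared shapes", {
  consensus <- sprintf("CG%02d", 1:43)
  spec <- risk_spec(informative_genes = consensus[1:8], effect = 2,
                    n_null_genes = 0)
  rc <- simulate_risk_cohorts(spec, consensus, seed = 4)
  expect_equal(dim(rc$train), c(43, 70))
  expect_equal(dim(rc$test), c(43, 38))
  expect_true(all(rc$train$values >= 0))
  expect_equal(unname(table(rc$train_labels)["N"]), 10)
  l2 <- log2(rc$train$values + 1)
  oa <- rc$train_labels == "OA"
  shift <- rowMeans(l2[, oa]) - rowMeans(l2[, !oa])
  inf <- rc$train$gene_ids %in% rc$truth
  expect_gt(mean(shift[inf]), 1.2)
  expect_lt(mean(abs(shift[!inf])), 0.6)
  rc2 <- simulate_risk_cohorts(spec, consensus, seed = 4)
  expect_identical(rc$train$values, rc2$train$values)
  expect_error(simulate_risk_cohorts(risk_spec("NOTCONSENSUS"), consensus),
               "subset")
})
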