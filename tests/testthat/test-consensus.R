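test_that("harmonization imputes zero fold changes for missing cohorts", {
  t1 <- fake_de(c("A", "B"), c(2.0, 1.0), c(0.01, 0.2))
  t2 <- fake_de(c("A", "C"), c(3.0, -1.0), c(0.02, 0.3))
  t3 <- fake_de("C", 0.5, 0.5)
  rec <- harmonize(list(t1, t2, t3))
  i <- match("A", rec$gene)
  expect_equal(rec$lfc[i, ], c(2, 3, 0))
  expect_equal(rec$present[i, ], c(TRUE, TRUE, FALSE))
  expect_equal(rec$p[i, ], c(0.01, 0.02, NA))
  j <- match("C", rec$gene)
  expect_equal(rec$lfc[j, ], c(0, -1, 0.5))
  expect_error(harmonize(list(fake_de(c("A", "A"), c(1, 1), c(0.1, 0.1)), t2)),
               "duplicated")
})

test_that("shrink band is inclusive and zeros are preserved", {
  rec <- harmonize(list(fake_de("A", 0.1, 0.5), fake_de("A", -0.11, 0.5),
                        fake_de("A", 0, 0.5)))
  rec <- shrink_small_lfc(rec, band = 0.1)
  expect_equal(rec$lfc[1, ], c(0, -0.11, 0))
})

test_that("all-zero genes are dropped before combination", {
  t1 <- fake_de(c("A", "B"), c(0.05, 0.2), c(0.5, 0.5))
  t2 <- fake_de(c("A", "B"), c(-0.02, 0), c(0.5, 0.5))
  t3 <- fake_de(c("A", "B"), c(0, 0), c(0.5, 0.5))
  rec <- shrink_small_lfc(harmonize(list(t1, t2, t3)))
  expect_message(rec <- drop_all_zero(rec), "1 all-zero")
  expect_identical(rec$gene, "B")
})

test_that("discordance needs strictly opposite signs; zeros are neutral", {
  rec <- structure(list(gene = c("a", "b", "c"),
                        lfc = rbind(c(2, -1, 0), c(2, 0, 0), c(1.5, 2, 1.7)),
                        present = matrix(TRUE, 3, 3),
                        p = matrix(0.5, 3, 3)), class = "meta_records")
  rec <- flag_discordant(rec)
  expect_identical(rec$discordant, c(TRUE, FALSE, FALSE))
})

test_that("Fisher combination matches the chi-square closed form", {
  t1 <- fake_de("A", 2, 0.01)
  t2 <- fake_de("A", 2, 0.04)
  rec <- flag_discordant(harmonize(list(t1, t2)))
  rec <- fisher_combine(rec)
  expect_equal(rec$combined_p, bf_fisher(c(0.01, 0.04)), tolerance = 1e-12)
  expect_equal(rec$combined_p, exp(-15.6481 / 2) * (1 + 15.6481 / 2),
               tolerance = 1e-4)

  rec3 <- flag_discordant(harmonize(list(fake_de("A", 1, 0.5),
                                         fake_de("A", 1, 0.5),
                                         fake_de("A", 1, 0.5))))
  rec3 <- fisher_combine(rec3)
  expect_equal(rec3$combined_p, bf_fisher(c(0.5, 0.5, 0.5)), tolerance = 1e-12)
  expect_equal(rec3$combined_p, 0.6552, tolerance = 1e-3)

  # discordant genes are nullified regardless of evidence
  recd <- flag_discordant(harmonize(list(fake_de("A", 2, 1e-10),
                                         fake_de("A", -2, 1e-10))))
  expect_equal(fisher_combine(recd)$combined_p, 1)

  # p = 0 floored, p outside [0,1] rejected
  rec0 <- flag_discordant(harmonize(list(fake_de("A", 1, 0),
                                         fake_de("A", 1, 0.5))))
  expect_message(rec0 <- fisher_combine(rec0), "flooring")
  expect_gt(rec0$combined_p, 0)
  recbad <- flag_discordant(harmonize(list(fake_de("A", 1, 1.5),
                                           fake_de("A", 1, 0.5))))
  expect_error(fisher_combine(recbad), "\\[0, 1\\]")
})

test_that("Fisher combination equals an independent oracle over random inputs", {
  set.seed(21)
  for (k in 2:3) {
    p <- matrix(runif(500 * k), 500, k)
    rec <- structure(list(gene = sprintf("g%03d", 1:500),
                          lfc = matrix(1, 500, 3), present = matrix(TRUE, 500, 3),
                          p = cbind(p, matrix(NA_real_, 500, 3 - k))),
                     class = "meta_records")
    rec <- flag_discordant(rec)
    rec <- fisher_combine(rec)
    oracle <- apply(p, 1, bf_fisher)
    expect_equal(rec$combined_p, oracle, tolerance = 1e-10)
  }
})

test_that("combined p is monotone in each input p-value", {
  set.seed(22)
  for (i in 1:50) {
    p <- runif(3)
    j <- sample(3, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)   # decrease one p-value
    mk <- function(pv) {
      r <- flag_discordant(structure(
        list(gene = "g", lfc = matrix(1, 1, 3), present = matrix(TRUE, 1, 3),
             p = matrix(pv, 1, 3)), class = "meta_records"))
      fisher_combine(r)$combined_p
    }
    expect_lte(mk(p2), mk(p))
  }
})

test_that("genes measured in fewer than two cohorts are removed", {
  t1 <- fake_de(c("A", "B"), c(2, 2), c(0.01, 0.01))
  t2 <- fake_de("A", 2, 0.01)
  t3 <- fake_de("A", 2, 0.01)
  rec <- flag_discordant(shrink_small_lfc(harmonize(list(t1, t2, t3))))
  expect_message(rec <- fisher_combine(rec), "fewer than two")
  expect_identical(rec$gene, "A")
})

test_that("combined median is taken over the zero-imputed vector", {
  rec <- harmonize(list(fake_de(c("A", "B", "C"), c(2, 1.6, -2), c(.1, .1, .1)),
                        fake_de(c("A", "B", "C"), c(3, 1.8, -3), c(.1, .1, .1)),
                        fake_de(c("B", "C"), c(2.0, 0), c(.1, .1))))
  rec <- combined_median_lfc(rec)
  expect_equal(rec$combined_lfc[match("A", rec$gene)], 2)   # median(2,3,0)
  expect_equal(rec$combined_lfc[match("B", rec$gene)], 1.8)
  expect_equal(rec$combined_lfc[match("C", rec$gene)], -2)  # median(-2,-3,0)
})

test_that("selection boundaries are inclusive and discordant genes excluded", {
  tabs <- list(fake_de(c("A", "D"), c(1.5, 2), c(0.001, 1e-8)),
               fake_de(c("A", "D"), c(1.5, -2), c(0.001, 1e-8)),
               fake_de(c("A", "D"), c(1.5, 2), c(0.001, 1e-8)))
  sig <- consensus_signature(tabs, fdr_cut = 0.05, lfc_cut = 1.5)
  expect_true("A" %in% sig$up)
  expect_false("D" %in% c(sig$up, sig$down))
  d <- sig$records[sig$records$gene == "D", ]
  expect_true(d$discordant)
  expect_equal(d$combined_p, 1)
  expect_equal(d$combined_fdr, 1)
})

test_that("the rule chain generalizes beyond three cohorts and is consistent", {
  set.seed(23)
  tabs <- lapply(1:4, function(i)
    fake_de(sprintf("g%02d", 1:30), rnorm(30), runif(30)))
  sig4 <- consensus_signature(tabs, fdr_cut = 0.5, lfc_cut = 0.5)
  expect_equal(ncol(as.matrix(sig4$records[grep("^lfc", names(sig4$records))])), 4)

  # the one-call wrapper equals the explicit step chain on 3 cohorts
  tabs3 <- tabs[1:3]
  rec <- harmonize(lapply(tabs3, drop_na_pvalues))
  rec <- shrink_small_lfc(rec, 0.1)
  rec <- suppressMessages(drop_all_zero(rec))
  rec <- flag_discordant(rec)
  rec <- suppressMessages(fisher_combine(rec))
  rec <- combined_median_lfc(rec)
  manual <- select_consensus(rec, 0.5, 0.5)
  auto <- suppressMessages(consensus_signature(tabs3, 0.5, 0.5))
  expect_identical(auto$up, manual$up)
  expect_identical(auto$records$combined_fdr, manual$records$combined_fdr)
})

test_that("an all-null truth yields an (almost always) empty signature", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    tabs <- lapply(1:3, function(i)
      fake_de(sprintf("g%03d", 1:400), rnorm(400, 0, 0.5), runif(400)))
    sig <- suppressMessages(consensus_signature(tabs))
    length(sig$up) + length(sig$down)
  })
  expect_gte(mean(hits <= 1), 0.95)
})
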