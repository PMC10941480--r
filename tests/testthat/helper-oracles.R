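# Independent brute-force oracles, written against the definitions, not the
# package implementations. Deliberately simple and slow.

# GSEA running sum by explicit walk over the whole ranked list.
bf_gsea_es <- function(ranked, geneset, weight_exp = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% geneset
  w <- abs(ranked$score)^weight_exp
  W <- sum(w[hit])
  if (W <= 0) { w[] <- 1; W <- sum(w[hit]) }
  running <- numeric(N)
  cur <- 0
  miss <- 1 / (N - sum(hit))
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + w[i] / W else cur - miss
    running[i] <- cur
  }
  running[which.max(abs(running))]
}

# Benjamini-Hochberg by the literal step-up definition.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric by explicit enumeration of the pmf.
bf_hyper <- function(overlap, n_set, n_universe, n_hits) {
  js <- overlap:min(n_set, n_hits)
  sum(choose(n_set, js) * choose(n_universe - n_set, n_hits - js)) /
    choose(n_universe, n_hits)
}

# log-gamma hypergeometric tail for big universes
lg_hyper <- function(overlap, n_set, n_universe, n_hits) {
  js <- overlap:min(n_set, n_hits)
  lt <- lchoose(n_set, js) + lchoose(n_universe - n_set, n_hits - js) -
    lchoose(n_universe, n_hits)
  sum(exp(lt))
}

# AUC by O(n^2) pairwise comparison, ties counted 1/2.
bf_auc <- function(scores, labels, positive = "OA") {
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Chi-square survival function for even df via the closed-form series
# exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!   (df = 2k), independent of pchisq.
chisq_surv_even <- function(x, df) {
  k <- df / 2
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Fisher combination through the closed-form series.
bf_fisher <- function(pvec) {
  x <- -2 * sum(log(pvec))
  chisq_surv_even(x, 2 * length(pvec))
}

# All-pairs shortest hop distances by plain BFS on an adjacency list.
bf_bfs_dist <- function(edges_df, from, to) {
  nodes <- unique(c(edges_df$a, edges_df$b, from, to))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_len(nrow(edges_df))) {
    a <- edges_df$a[i]; b <- edges_df$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- matrix(Inf, length(from), length(to), dimnames = list(from, to))
  for (s in from) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    out[s, ] <- dist[to]
  }
  out
}

# small deterministic DE-table builder
fake_de <- function(genes, lfc, p) {
  data.frame(gene = genes, log2fc = lfc, pvalue = p,
             padj = p, status = "ns", stringsAsFactors = FALSE)
}

# simulate the three study cohorts for a truth table and run the reference
# DE stage, mirroring the pipeline defaults
simulate_three_de <- function(truth, seed, n_genes = nrow(truth)) {
  specs <- table1_cohort_specs(n_genes = n_genes)
  sims <- lapply(seq_along(specs), function(i)
    simulate_cohort(specs[[i]], truth, cohort_index = i, seed = seed + i))
  pb <- pseudobulk(sims[[1]]$counts, sims[[1]]$samples)
  de1 <- reference_de(pb$counts, pb$samples, covariates = "donor",
                      lfc_cut = 1.5, fdr_cut = 0.05)
  c2 <- collapse_isoforms(filter_low_expressed(sims[[2]]$counts, 15, 0.5))
  de2 <- reference_de(c2, sims[[2]]$samples, covariates = "donor",
                      lfc_cut = 0.8, fdr_cut = 0.05)
  c3 <- collapse_isoforms(filter_low_expressed(sims[[3]]$counts, 5, 0.5))
  de3 <- reference_de(c3, sims[[3]]$samples, covariates = "batch",
                      lfc_cut = 1.5, fdr_cut = 0.05)
  list(de1, de2, de3)
}
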