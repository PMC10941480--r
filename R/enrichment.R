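#' Build a ranked gene list
#'
#' Orders genes by score, descending, with deterministic tie-breaking
#' (score descending, then gene id ascending).
#'
#' @param scores named numeric vector (names = genes, unique).
#' @return data.frame with columns `gene`, `score`, ordered.
#' @export
rank_genes <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be uniquely named by gene")
  ord <- order(-scores, names(scores), method = "radix")
  data.frame(gene = names(scores)[ord], score = unname(scores)[ord],
             stringsAsFactors = FALSE)
}

# Enrichment score from sorted hit positions. The running sum increments by
# w_i / sum(w) at hit i and decreases by 1/(N - k) per miss; its extrema over
# the whole list occur immediately after a hit or immediately before one, so
# only 2k candidate values need inspecting. Candidates are scanned in list
# order so ties resolve to the earliest position, matching a full scan.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  if (k == 0L) stop("gene set disjoint from the ranked universe")
  if (k >= N) stop("gene set covers the whole universe; no misses to score against")
  W <- sum(w)
  if (W <= 0) { w <- rep(1, k); W <- k }  # all-zero weights: unweighted fallback
  cumw <- cumsum(w) / W
  dec <- 1 / (N - k)
  after <- cumw - (pos - seq_len(k)) * dec
  before <- c(0, cumw[-k]) - (pos - seq_len(k)) * dec
  cand <- numeric(2L * k)
  cand[seq(1L, 2L * k, by = 2L)] <- before
  cand[seq(2L, 2L * k, by = 2L)] <- after
  i <- which.max(abs(cand))
  list(es = cand[i], extremum_hit = (i + 1L) %/% 2L)
}

#' GSEA enrichment score and running sum
#'
#' The weighted Kolmogorov-Smirnov-like running-sum statistic: walking down
#' the ranked list, members of the set add `|score|^weight_exp` (normalized
#' over all members), non-members subtract `1/(N - N_hits)`. The enrichment
#' score (ES) is the running-sum value of maximal absolute deviation from
#' zero; the leading edge contains the members at or before the extremum
#' (at or after it, for negative ES).
#'
#' @param ranked data.frame from [rank_genes()] (or any `gene`, `score`
#'   frame already in ranking order).
#' @param geneset character vector of member genes.
#' @param weight_exp weighting exponent (default 1; 0 = unweighted KS).
#' @return list with `es`, `running_sum` (length-N numeric), `hits`
#'   (positions), `leading_edge` (genes).
#' @export
gsea_es <- function(ranked, geneset, weight_exp = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% geneset
  pos <- which(hit)
  k <- length(pos)
  if (k == 0L) stop("gene set disjoint from the ranked universe")
  if (k >= N) stop("gene set covers the whole universe")
  w <- abs(ranked$score[pos])^weight_exp
  W <- sum(w)
  if (W <= 0) { w <- rep(1, k); W <- k }
  inc <- numeric(N)
  inc[pos] <- w / W
  inc[!hit] <- -1 / (N - k)
  running <- cumsum(inc)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) ranked$gene[pos[pos <= i_ext]]
             else ranked$gene[pos[pos >= i_ext]]
  list(es = es, running_sum = running, hits = pos, leading_edge = leading)
}

#' Pre-ranked GSEA with gene-label permutation
#'
#' For every set in the collection, computes the observed ES, a permutation
#' p-value (random member positions, weights taken from the observed score
#' vector), the normalized enrichment score NES = ES / mean(|same-sign null
#' ES|), and a sign-stratified permutation FDR (ratio of the pooled-null and
#' observed tail fractions at each |NES|, clipped at 1).
#'
#' @param ranked ranked data.frame ([rank_genes()]).
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param weight_exp weighting exponent.
#' @param min_size sets with fewer overlapping genes are skipped.
#' @return data.frame: `set_id`, `size`, `es`, `nes`, `pvalue`, `fdr`,
#'   `leading_edge` (comma-joined).
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, seed = 1,
                           weight_exp = 1, min_size = 1) {
  stopifnot(n_perm >= 100)
  N <- nrow(ranked)
  absw <- abs(ranked$score)^weight_exp
  set.seed(as.integer(seed))
  rows <- lapply(names(collection), function(id) {
    pos <- which(ranked$gene %in% collection[[id]])
    k <- length(pos)
    if (k < min_size || k >= N) return(NULL)
    obs <- gsea_es(ranked, collection[[id]], weight_exp)
    null_es <- vapply(seq_len(n_perm), function(b) {
      rp <- sort.int(sample.int(N, k))
      es_from_positions(rp, absw[rp], N)$es
    }, 0)
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (sum(abs(same) >= abs(obs$es)) + 1) / (length(same) + 1)
    denom <- mean(abs(same))
    nes <- if (length(same) && denom > 0) obs$es / denom else NA_real_
    null_nes <- if (length(same) && denom > 0) null_es / denom else numeric(0)
    data.frame(set_id = id, size = k, es = obs$es, nes = nes, pvalue = p,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE,
               null_nes = I(list(null_nes)))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame())
  pooled <- unlist(res$null_nes)
  res$fdr <- vapply(seq_len(nrow(res)), function(i) {
    nes <- res$nes[i]
    if (is.na(nes)) return(NA_real_)
    same_null <- if (nes >= 0) pooled[pooled >= 0] else pooled[pooled < 0]
    same_obs <- if (nes >= 0) res$nes[!is.na(res$nes) & res$nes >= 0]
                else res$nes[!is.na(res$nes) & res$nes < 0]
    num <- if (length(same_null)) mean(abs(same_null) >= abs(nes)) else 0
    den <- mean(abs(same_obs) >= abs(nes))
    min(1, if (den > 0) num / den else 1)
  }, 0)
  res$null_nes <- NULL
  rownames(res) <- NULL
  res[order(res$pvalue, res$set_id), ]
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' hit list and a gene set drawn from a finite universe:
#' P(X >= overlap) with population `|universe|`, successes `|set|`, draws
#' `|hits|`.
#'
#' @param hits character vector (subset of `universe`).
#' @param set character vector (subset of `universe`).
#' @param universe character vector of all eligible genes.
#' @return list with `overlap` and `p`.
#' @export
ora <- function(hits, set, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  hits <- unique(intersect(hits, universe))
  set <- unique(intersect(set, universe))
  ov <- length(intersect(hits, set))
  p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                     length(hits), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Significance of the overlap between two gene lists
#'
#' Same hypergeometric statistic as [ora()] with `hits = listA`,
#' `set = listB`; symmetric in its two lists.
#'
#' @param listA,listB character vectors (subsets of `universe`).
#' @param universe character vector of eligible genes.
#' @return list with `overlap` and `p`.
#' @export
overlap_test <- function(listA, listB, universe) {
  ora(listA, listB, universe)
}

#' Running-sum series for enrichment plots
#'
#' @param ranked ranked data.frame.
#' @param signature gene set to trace.
#' @param weight_exp weighting exponent.
#' @return data.frame with `position`, `gene`, `hit`, `running_sum`; the ES
#'   is attached as attribute `es`.
#' @export
running_plot_data <- function(ranked, signature, weight_exp = 1) {
  r <- gsea_es(ranked, signature, weight_exp)
  out <- data.frame(position = seq_len(nrow(ranked)), gene = ranked$gene,
                    hit = ranked$gene %in% signature,
                    running_sum = r$running_sum, stringsAsFactors = FALSE)
  attr(out, "es") <- r$es
  out
}
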