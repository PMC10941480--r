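#' Pathway-based expression profile (PEP) of one drug profile
#'
#' Re-expresses a gene-level differential-expression profile as a vector of
#' per-pathway enrichment scores: the profile's genes are ranked by score
#' and each pathway in the collection receives the weighted running-sum ES.
#' Permutation p-values are optional (`n_perm = 0` skips them; drug ranking
#' only consumes the ES).
#'
#' @param profile named numeric vector of per-gene scores.
#' @param collection named list of gene sets.
#' @param weight_exp GSEA weighting exponent.
#' @param n_perm permutations for per-pathway p-values (0 = none).
#' @param seed integer seed (used when `n_perm > 0`).
#' @return data.frame with `pathway`, `es` and (if requested) `pvalue`;
#'   pathways fully outside the profile's gene universe get `NA` ES.
#' @export
build_pep <- function(profile, collection, weight_exp = 1, n_perm = 0,
                      seed = 1) {
  ranked <- rank_genes(profile)
  N <- nrow(ranked)
  absw <- abs(ranked$score)^weight_exp
  if (n_perm > 0) set.seed(as.integer(seed))
  es <- numeric(length(collection))
  pv <- rep(NA_real_, length(collection))
  for (i in seq_along(collection)) {
    pos <- which(ranked$gene %in% collection[[i]])
    if (!length(pos) || length(pos) >= N) {
      es[i] <- NA_real_
      next
    }
    obs <- es_from_positions(pos, absw[pos], N)$es
    es[i] <- obs
    if (n_perm > 0) {
      k <- length(pos)
      null_es <- vapply(seq_len(n_perm), function(b) {
        rp <- sort.int(sample.int(N, k))
        es_from_positions(rp, absw[rp], N)$es
      }, 0)
      same <- if (obs >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      pv[i] <- (sum(abs(same) >= abs(obs)) + 1) / (length(same) + 1)
    }
  }
  if (anyNA(es))
    message(sum(is.na(es)), " pathway(s) outside the profile universe")
  out <- data.frame(pathway = names(collection), es = es,
                    stringsAsFactors = FALSE)
  if (n_perm > 0) out$pvalue <- pv
  out
}

#' PEPs for a whole compendium
#'
#' @param profiles profiles x genes numeric matrix (rownames = profile ids).
#' @param collection named list of gene sets.
#' @param weight_exp GSEA weighting exponent.
#' @return profiles x pathways matrix of enrichment scores.
#' @export
build_peps <- function(profiles, collection, weight_exp = 1) {
  if (is.null(rownames(profiles)) || is.null(colnames(profiles)))
    stop("profiles must have profile ids as rownames and genes as colnames")
  peps <- t(vapply(seq_len(nrow(profiles)), function(i) {
    build_pep(stats::setNames(profiles[i, ], colnames(profiles)),
              collection, weight_exp)$es
  }, numeric(length(collection))))
  dimnames(peps) <- list(rownames(profiles), names(collection))
  peps
}

#' Select the signature's up/down pathway sets
#'
#' The "up set" contains every pathway involving at least one up-regulated
#' signature gene; the "down set" analogously for down-regulated genes. The
#' selections are independent, so a pathway containing both kinds of gene
#' belongs to both sets.
#'
#' @param collection named list of gene sets.
#' @param signature a `consensus_signature` or list with `up`, `down`.
#' @return list with `up_set`, `down_set` (pathway id vectors).
#' @export
select_signature_pathways <- function(collection, signature) {
  has_any <- function(genes) {
    if (!length(genes)) return(character(0))
    names(collection)[vapply(collection, function(s) any(genes %in% s), TRUE)]
  }
  up_set <- has_any(signature$up)
  down_set <- has_any(signature$down)
  if (!length(up_set) && !length(down_set))
    stop("signature not represented in the pathway collection")
  list(up_set = up_set, down_set = down_set)
}

#' Pathway set enrichment analysis (PSEA) of a PEP
#'
#' GSEA applied one level up: pathways are ranked by their PEP enrichment
#' score (descending, ties by id) and the running-sum statistic of a pathway
#' set over that ranking measures whether the set concentrates at the top
#' (ES near +1) or bottom (near -1) of the PEP. p-value by pathway-label
#' permutation.
#'
#' @param pep named numeric vector of pathway ES (one drug profile); `NA`
#'   pathways are excluded.
#' @param pathway_set character vector of pathway ids.
#' @param weight_exp weighting exponent (|ES| weights, default 1).
#' @param n_perm permutations for the p-value (0 = ES only).
#' @param seed integer seed.
#' @return list with `es` and `p` (`NA` when `n_perm = 0`).
#' @export
psea <- function(pep, pathway_set, weight_exp = 1, n_perm = 0, seed = 1) {
  pep <- pep[!is.na(pep)]
  ranked <- rank_genes(pep)
  r <- gsea_es(ranked, pathway_set, weight_exp)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    N <- nrow(ranked)
    absw <- abs(ranked$score)^weight_exp
    k <- length(r$hits)
    null_es <- vapply(seq_len(n_perm), function(b) {
      rp <- sort.int(sample.int(N, k))
      es_from_positions(rp, absw[rp], N)$es
    }, 0)
    same <- if (r$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (sum(abs(same) >= abs(r$es)) + 1) / (length(same) + 1)
  }
  list(es = r$es, p = p)
}

#' Rank drugs by two-set PSEA against the disease signature
#'
#' For each profile, the PSEA enrichment of the down-pathway set (`es_down`)
#' and of the up-pathway set (`es_up`) over its PEP. A signature-reversing
#' profile pushes down-set pathways to the top (positive `es_down`) and
#' up-set pathways to the bottom (negative `es_up`), so profiles are ranked
#' by `es_down` descending and by `es_up` ascending (mid-ranks on ties) and
#' scored by the average of the two ranks. Profiles of the same drug are
#' aggregated to drug level by the best (minimum, default) or mean average
#' rank; the final ordering is ascending with ties broken by drug id.
#'
#' @param peps profiles x pathways ES matrix from [build_peps()].
#' @param sets list with `up_set`, `down_set`.
#' @param manifest data.frame mapping `profile_id` to `drug_id`.
#' @param aggregate `"min"` (best profile) or `"mean"`.
#' @param weight_exp PSEA weighting exponent.
#' @return object of class `drug_ranking`: data.frame with `drug_id`,
#'   `profile_id` (best profile), `es_up`, `es_down`, `rank_up`,
#'   `rank_down`, `avg_rank`, ordered best-first. The per-profile table is
#'   attached as attribute `profiles`.
#' @export
rank_drugs <- function(peps, sets, manifest, aggregate = c("min", "mean"),
                       weight_exp = 1) {
  aggregate <- match.arg(aggregate)
  if (nrow(peps) < 2) stop("need at least two profiles to rank")
  es_up <- numeric(nrow(peps))
  es_down <- numeric(nrow(peps))
  for (i in seq_len(nrow(peps))) {
    pep <- peps[i, ]
    es_up[i] <- psea(pep, sets$up_set, weight_exp)$es
    es_down[i] <- psea(pep, sets$down_set, weight_exp)$es
  }
  prof <- data.frame(profile_id = rownames(peps), es_up = es_up,
                     es_down = es_down, stringsAsFactors = FALSE)
  prof$rank_down <- rank(-prof$es_down, ties.method = "average")
  prof$rank_up <- rank(prof$es_up, ties.method = "average")
  prof$avg_rank <- (prof$rank_up + prof$rank_down) / 2
  prof$drug_id <- manifest$drug_id[match(prof$profile_id, manifest$profile_id)]
  if (anyNA(prof$drug_id)) stop("profile(s) missing from manifest")

  drugs <- do.call(rbind, lapply(split(prof, prof$drug_id), function(d) {
    if (aggregate == "min") {
      best <- d[which.min(d$avg_rank), , drop = FALSE]
      best
    } else {
      best <- d[which.min(d$avg_rank), , drop = FALSE]
      best$avg_rank <- mean(d$avg_rank)
      best
    }
  }))
  drugs <- drugs[order(drugs$avg_rank, drugs$drug_id), ]
  drugs <- drugs[c("drug_id", "profile_id", "es_up", "es_down",
                   "rank_up", "rank_down", "avg_rank")]
  rownames(drugs) <- NULL
  structure(drugs, class = c("drug_ranking", "data.frame"), profiles = prof)
}

#' @export
print.drug_ranking <- function(x, n = 10, ...) {
  cat("<drug_ranking> ", nrow(x), " drugs (ascending avg_rank; top reverse the signature)\n",
      sep = "")
  print.data.frame(utils::head(x, n), digits = 3)
  invisible(x)
}

#' Top-k drugs of a ranking
#'
#' @param ranking a [rank_drugs()] result.
#' @param k how many drugs (default 50).
#' @return character vector of drug ids, best first.
#' @export
top_k <- function(ranking, k = 50) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(ranking)) stop("k exceeds the number of drugs")
  ranking$drug_id[seq_len(k)]
}
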