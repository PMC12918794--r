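#' Rank genes by Spearman correlation with a phenotype
#'
#' Computes, for each row of the matrix, the Spearman correlation (average
#' ranks for ties) with the per-sample phenotype vector, and returns genes in
#' descending correlation order with ties broken by gene name.
#'
#' @param m Genes x samples matrix (expression or dependency).
#' @param phenotype Numeric vector, one value per sample.
#' @return Data frame: gene, score (Spearman rho), ordered descending.
#' @export
rank_by_phenotype <- function(m, phenotype) {
  if (ncol(m) < 3L) stop("need at least 3 samples")
  if (any(!is.finite(phenotype))) stop("non-finite phenotype values")
  if (stats::sd(phenotype) == 0) stop("constant phenotype")
  pr <- rank(phenotype)
  rho <- apply(m, 1L, function(row) {
    if (stats::sd(row) == 0) return(0)
    stats::cor(rank(row), pr)
  })
  ord <- order(-rho, rownames(m))
  data.frame(gene = rownames(m)[ord], score = rho[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Weighted running-sum enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov statistic on a ranked list: walking
#' down the ranking, hits increment the running sum by |score|^w normalized
#' by the total hit weight, misses decrement by 1/(n - m); the ES is the
#' deviation of maximal magnitude. The leading edge is the set members at or
#' before (positive ES) / at or after (negative ES) the extreme position.
#'
#' @param ranked Data frame with columns \code{gene} and \code{score},
#'   descending by score.
#' @param gene_set Character vector of member genes.
#' @param weight_exponent Weight w on |score| (default 1).
#' @return List: \code{es}, \code{running} (length-n running sum),
#'   \code{leading_edge} (character), \code{n_hits}.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  n <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  m <- sum(hit)
  if (m == 0L) stop("no gene-set member present in the ranking")
  w <- abs(ranked$score)^weight_exponent
  wh <- sum(w[hit])
  if (wh == 0) { w[hit] <- 1; wh <- m }  # all-zero hit scores: unweighted
  inc <- numeric(n)
  inc[hit] <- w[hit] / wh
  if (m < n) inc[!hit] <- -1 / (n - m)
  running <- cumsum(inc)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) ranked$gene[seq_len(i_ext)][hit[seq_len(i_ext)]]
  else ranked$gene[i_ext:n][hit[i_ext:n]]
  list(es = es, running = running, leading_edge = leading, n_hits = m)
}

# Fast ES for a set of hit positions (no running vector); exact same extreme
# as enrichment_score. Used for the permutation null.
es_from_positions <- function(w, n, pos) {
  pos <- sort(pos)
  m <- length(pos)
  wh <- sum(w[pos])
  hit_cum <- if (wh == 0) seq_len(m) / m else cumsum(w[pos]) / wh
  miss_step <- if (m < n) 1 / (n - m) else 0
  # running sum at hit k: hit_cum[k] - (pos[k] - k) * miss_step
  at_hit <- hit_cum - (pos - seq_len(m)) * miss_step
  # minimum just before each hit: hit_cum[k-1] - (pos[k] - k) * miss_step
  before_hit <- c(0, hit_cum[-m]) - (pos - seq_len(m)) * miss_step
  hi <- max(at_hit)
  lo <- min(before_hit, if (m < n) -0 else 0)
  # tail after the last hit decreases to 0; min there is approached at n
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Pre-ranked gene-set enrichment with a gene-sampling null
#'
#' Sets are size-filtered on the genes present in the ranking (defaults 15
#' and 500). The null distribution per set size is built by drawing random
#' gene sets of the same size from the ranking; NES = ES divided by the mean
#' |null ES| of matching sign, the nominal p is one-sided within sign, and
#' FDR is Benjamini-Hochberg across tested sets.
#'
#' @param ranked Data frame with \code{gene}, \code{score} (descending).
#' @param collection Named list of gene sets.
#' @param min_size,max_size Size bounds applied to present members.
#' @param n_perm Number of null draws per set (default 1000; a warning is
#'   issued below 100).
#' @param seed Integer seed for the null draws.
#' @param weight_exponent Weight on |score| (default 1).
#' @return Data frame: set, size, es, nes, p, fdr, leading_edge
#'   (semicolon-collapsed).
#' @export
preranked_gsea <- function(ranked, collection, min_size = 15L,
                           max_size = 500L, n_perm = 1000L, seed = 1L,
                           weight_exponent = 1) {
  if (length(collection) == 0L) stop("empty gene-set collection")
  if (n_perm < 100L) warning("n_perm < 100: p-values will be coarse")
  n <- nrow(ranked)
  sizes <- vapply(collection, function(g) sum(ranked$gene %in% g), integer(1L))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    message("no gene set passes the size filter")
    return(data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p = numeric(0), fdr = numeric(0),
                      leading_edge = character(0), stringsAsFactors = FALSE))
  }
  collection <- collection[keep]; sizes <- sizes[keep]
  w <- abs(ranked$score)^weight_exponent
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  res <- vector("list", length(collection))
  null_cache <- list()
  for (si in seq_along(collection)) {
    obs <- enrichment_score(ranked, collection[[si]], weight_exponent)
    sz <- as.character(sizes[si])
    if (is.null(null_cache[[sz]])) {
      set.seed(stage_seed(seed, paste0("gsea_null_", sz)))
      null_cache[[sz]] <- vapply(seq_len(n_perm), function(b)
        es_from_positions(w, n, sample.int(n, sizes[si])), numeric(1L))
    }
    null_es <- null_cache[[sz]]
    same_sign <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    denom <- mean(abs(same_sign))
    nes <- if (length(same_sign) == 0L || denom == 0) NA_real_ else
      obs$es / denom
    p <- if (length(same_sign) == 0L) 1 / (n_perm + 1) else
      (sum(abs(same_sign) >= abs(obs$es)) + 1) / (length(same_sign) + 1)
    res[[si]] <- data.frame(set = names(collection)[si], size = sizes[si],
                            es = obs$es, nes = nes, p = p,
                            leading_edge = paste(obs$leading_edge,
                                                 collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$set), c("set", "size", "es", "nes", "p", "fdr",
                               "leading_edge")]
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test per term: with universe size N,
#' term size K (within the universe), query size n, and overlap k, the
#' p-value is P(X >= k) for X ~ Hypergeometric(N, K, n). BH adjustment is
#' applied across terms.
#'
#' @param query Character vector of genes (members outside the universe are
#'   dropped with a warning).
#' @param collection Named list of gene sets (terms).
#' @param universe Character vector: the gene universe.
#' @return Data frame: term, k (overlap), K (term size), n (query size),
#'   N (universe size), p, fdr, genes (overlap, semicolon-collapsed).
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  query <- unique(query)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    term <- intersect(collection[[nm]], universe)
    K <- length(term)
    ov <- intersect(query, term)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$term), c("term", "k", "K", "n", "N", "p", "fdr",
                                "genes")]
}
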