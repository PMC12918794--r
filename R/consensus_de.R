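#' Sample-level PCA of a z-scored expression matrix
#'
#' Genes are row-wise z-scored (zero-variance genes dropped with a warning),
#' the matrix is transposed to samples x genes, and PCA is computed by SVD
#' with no additional centering or scaling (the z-scoring already centers
#' every gene across samples). Percent variance per component is derived
#' from the singular values and sums to 100 over all components. A
#' deterministic sign convention is applied: within each component the
#' loading of largest magnitude is made positive.
#'
#' @param expr Genes x samples matrix (log2(TPM+1)).
#' @return List: \code{scores} (samples x PCs), \code{percent_var},
#'   \code{cumulative_var}.
#' @export
pca_expression <- function(expr) {
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  z <- suppressWarnings(zscore_rows(expr))
  if (nrow(z) < 2L) stop("fewer than 2 non-degenerate genes")
  x <- t(z)
  sv <- svd(x)
  k <- sum(sv$d > sv$d[1L] * 1e-12)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- sv$d^2
  pv <- 100 * ev / sum(ev)
  rownames(scores) <- colnames(expr)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, percent_var = pv[seq_len(k)],
       cumulative_var = cumsum(pv)[seq_len(k)])
}

#' Flag per-gene differential-expression direction
#'
#' A gene is up if FDR <= \code{fdr} and log2FC > 0, down if FDR <=
#' \code{fdr} and log2FC < 0, and ns otherwise (log2FC exactly 0 is never
#' significant). If the table lacks an \code{fdr} column it is recomputed
#' from \code{p} by Benjamini-Hochberg.
#'
#' @param stats_table Data frame with columns \code{gene}, \code{log2fc},
#'   and \code{fdr} (or \code{p}).
#' @param fdr FDR threshold (default 0.05).
#' @return The table with a \code{direction} column in \{up, down, ns\}.
#' @export
flag_significance <- function(stats_table, fdr = 0.05) {
  if (!all(c("gene", "log2fc") %in% names(stats_table)))
    stop("stats table needs columns gene, log2fc")
  if (!"fdr" %in% names(stats_table)) {
    if (!"p" %in% names(stats_table)) stop("need an fdr or p column")
    stats_table$fdr <- bh_adjust(stats_table$p)
  }
  sig <- stats_table$fdr <= fdr
  stats_table$direction <- ifelse(sig & stats_table$log2fc > 0, "up",
                                  ifelse(sig & stats_table$log2fc < 0,
                                         "down", "ns"))
  stats_table
}

#' Consensus differential-expression sets against an insensitive reference
#'
#' A gene enters the consensus up (down) set iff it is flagged up (down) in
#' every sensitive line and is NOT flagged in the same direction in the
#' reference line; genes non-significant in the reference or changed in the
#' opposite direction are retained. Genes absent from any sensitive table
#' are excluded (intersection rule). The result is order-invariant in the
#' listing of sensitive lines and the up and down sets are disjoint.
#'
#' @param sensitive Named list of flagged tables (from
#'   \code{\link{flag_significance}}), one per sensitive line (>= 2).
#' @param reference Flagged table for the reference line.
#' @return List: \code{up}, \code{down} (character vectors, sorted), and
#'   \code{audit} (per-candidate-gene data frame of directions).
#' @export
consensus_sets <- function(sensitive, reference) {
  if (length(sensitive) < 2L) stop("need at least 2 sensitive lines")
  common <- Reduce(intersect, lapply(sensitive, function(d) d$gene))
  dir_mat <- vapply(sensitive, function(d)
    d$direction[match(common, d$gene)], character(length(common)))
  if (length(common) == 1L) dir_mat <- matrix(dir_mat, nrow = 1L)
  ref_dir <- reference$direction[match(common, reference$gene)]
  ref_dir[is.na(ref_dir)] <- "ns"
  all_up <- rowSums(dir_mat == "up") == ncol(dir_mat)
  all_down <- rowSums(dir_mat == "down") == ncol(dir_mat)
  up <- sort(common[all_up & ref_dir != "up"])
  down <- sort(common[all_down & ref_dir != "down"])
  cand <- all_up | all_down
  audit <- data.frame(gene = common[cand],
                      dir_mat[cand, , drop = FALSE],
                      reference = ref_dir[cand],
                      consensus = ifelse(common[cand] %in% up, "up",
                                         ifelse(common[cand] %in% down,
                                                "down", "excluded")),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(up = up, down = down, audit = audit)
}

#' Merged mean-Wald gene ranking across sensitive lines
#'
#' Restricts to genes present in every table, scores each gene by the
#' unweighted mean of its Wald statistics, and returns a descending ranking
#' with ties broken by gene name. Positive scores indicate consistent
#' upregulation under the perturbation.
#'
#' @param stats_tables List (>= 2) of data frames with columns \code{gene}
#'   and \code{wald}.
#' @return Data frame: gene, score, descending (feeds
#'   \code{\link{preranked_gsea}}).
#' @export
merged_ranking <- function(stats_tables) {
  if (length(stats_tables) < 2L) stop("need at least 2 tables")
  common <- Reduce(intersect, lapply(stats_tables, function(d) d$gene))
  if (length(common) == 0L) stop("empty gene intersection")
  wald <- vapply(stats_tables, function(d) d$wald[match(common, d$gene)],
                 numeric(length(common)))
  if (length(common) == 1L) wald <- matrix(wald, nrow = 1L)
  score <- rowMeans(wald)
  ord <- order(-score, common)
  data.frame(gene = common[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}
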