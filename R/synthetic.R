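#' Synthetic gene-dependency matrix with planted lineage effects
#'
#' Baseline dependency per gene is drawn from a Beta(2, 8) (most genes
#' non-essential, matching the right-skew of the probability-of-dependency
#' scale); planted effects add delta to a gene (or to every member of a
#' planted complex) within the target lineage; independent Gaussian noise is
#' added and values are clipped to \[0, 1\] (clip rate recorded). Effects are
#' specified pre-clip.
#'
#' @param n_lineages Number of lineages.
#' @param lines_per_lineage Cell lines per lineage (scalar or vector).
#' @param n_genes Number of genes.
#' @param catalog Optional named list of complexes over the gene names
#'   (genes are named g0001...; complexes may reference them).
#' @param planted_genes Data frame (gene, lineage, delta) or NULL.
#' @param planted_complexes Data frame (complex, lineage, delta) or NULL
#'   (requires \code{catalog}).
#' @param noise_sd Gaussian noise sd (default 0.1).
#' @param seed Integer seed.
#' @return List: \code{dep} (matrix), \code{annotation} (data frame
#'   cell_line_id, lineage), \code{truth} (list of planted effects, baseline,
#'   clip_rate, seed).
#' @export
gen_dependency_matrix <- function(n_lineages = 5L, lines_per_lineage = 10L,
                                  n_genes = 200L, catalog = NULL,
                                  planted_genes = NULL,
                                  planted_complexes = NULL,
                                  noise_sd = 0.1, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  npl <- rep_len(lines_per_lineage, n_lineages)
  lineages <- paste0("lineage_", sprintf("%02d", seq_len(n_lineages)))
  lin_vec <- rep(lineages, npl)
  n_lines <- sum(npl)
  ids <- paste0("ACH-", sprintf("%06d", seq_len(n_lines)))
  genes <- paste0("g", sprintf("%04d", seq_len(n_genes)))
  baseline <- stats::rbeta(n_genes, 2, 8)
  m <- matrix(rep(baseline, each = n_lines), n_lines, n_genes,
              dimnames = list(ids, genes))
  effect <- matrix(0, n_lines, n_genes, dimnames = dimnames(m))
  if (!is.null(planted_complexes)) {
    if (is.null(catalog)) stop("planted complexes require a catalog")
    for (r in seq_len(nrow(planted_complexes))) {
      members <- intersect(catalog[[planted_complexes$complex[r]]], genes)
      effect[lin_vec == planted_complexes$lineage[r], members] <-
        effect[lin_vec == planted_complexes$lineage[r], members] +
        planted_complexes$delta[r]
    }
  }
  if (!is.null(planted_genes)) {
    for (r in seq_len(nrow(planted_genes))) {
      effect[lin_vec == planted_genes$lineage[r], planted_genes$gene[r]] <-
        effect[lin_vec == planted_genes$lineage[r], planted_genes$gene[r]] +
        planted_genes$delta[r]
    }
  }
  raw <- m + effect + matrix(stats::rnorm(n_lines * n_genes, 0, noise_sd),
                             n_lines, n_genes)
  clipped <- raw < 0 | raw > 1
  dep <- pmin(pmax(raw, 0), 1)
  if (all(clipped)) stop("infeasible parameters: every value clipped")
  ann <- data.frame(cell_line_id = ids, lineage = lin_vec,
                    stringsAsFactors = FALSE)
  list(dep = dep, annotation = ann,
       truth = list(planted_genes = planted_genes,
                    planted_complexes = planted_complexes,
                    baseline = stats::setNames(baseline, genes),
                    clip_rate = mean(clipped), noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic log-expression matrix with two differentiation classes
#'
#' Signature genes of the three melanocytic-side states are shifted up by
#' \code{separation_sd} noise-sd units in melanocytic-class lines and down in
#' undifferentiated-class lines; the three undifferentiated-side states are
#' mirrored; the intermediate state and non-signature genes are pure noise.
#' Values are shifted to be nonnegative like log2(TPM+1) data.
#'
#' @param n_lines Number of cell lines.
#' @param genes_per_state Signature genes per state (default 20).
#' @param n_noise_genes Additional non-signature genes (default 200).
#' @param class_assignment Optional character vector ("melanocytic_like" /
#'   "undifferentiated_ncl"); default: first 60\% melanocytic.
#' @param separation_sd Class separation in noise-sd units (default 3).
#' @param noise_sd Noise sd (default 1).
#' @param seed Integer seed.
#' @return List: \code{expr} (genes x lines), \code{signature} (gene/state
#'   data frame), \code{truth} (class per line, separation, seed).
#' @export
gen_expression_matrix <- function(n_lines = 70L, genes_per_state = 20L,
                                  n_noise_genes = 200L,
                                  class_assignment = NULL,
                                  separation_sd = 3, noise_sd = 1,
                                  seed = 1L) {
  stopifnot(separation_sd >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(class_assignment)) {
    n_mel <- round(0.6 * n_lines)
    class_assignment <- rep(c("melanocytic_like", "undifferentiated_ncl"),
                            c(n_mel, n_lines - n_mel))
  }
  lines <- paste0("line_", sprintf("%03d", seq_len(n_lines)))
  sig <- data.frame(
    gene = paste0("sig", sprintf("%03d", seq_len(7L * genes_per_state))),
    state = rep(MELANOMA_STATES, each = genes_per_state),
    stringsAsFactors = FALSE)
  genes <- c(sig$gene, paste0("noise", sprintf("%04d",
                                               seq_len(n_noise_genes))))
  expr <- matrix(stats::rnorm(length(genes) * n_lines, 0, noise_sd),
                 length(genes), n_lines, dimnames = list(genes, lines))
  is_mel_line <- class_assignment == "melanocytic_like"
  half <- separation_sd * noise_sd / 2
  mel_genes <- sig$gene[sig$state %in% MELANOMA_STATES[1:3]]
  und_genes <- sig$gene[sig$state %in% MELANOMA_STATES[5:7]]
  expr[mel_genes, is_mel_line] <- expr[mel_genes, is_mel_line] + half
  expr[mel_genes, !is_mel_line] <- expr[mel_genes, !is_mel_line] - half
  expr[und_genes, is_mel_line] <- expr[und_genes, is_mel_line] - half
  expr[und_genes, !is_mel_line] <- expr[und_genes, !is_mel_line] + half
  expr <- expr - min(expr)  # nonnegative like log2(TPM+1)
  list(expr = expr, signature = sig,
       truth = list(class = stats::setNames(class_assignment, lines),
                    separation_sd = separation_sd, noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic single-cell intensity tables with latent high/low states
#'
#' Each cell draws a latent high/low state per marker (the first marker from
#' the condition's high fraction; later markers copy the first marker's state
#' with probability \code{coupling} and draw independently otherwise) and
#' emits a lognormal intensity around the state's log-mean. Replicate cell
#' counts are jittered around \code{n_cells}.
#'
#' @param cell_lines Character vector of cell lines.
#' @param markers Character vector of markers.
#' @param conditions Character vector of conditions.
#' @param replicates Number of replicates per condition (default 3).
#' @param high_fraction Named-by-condition numeric: probability a cell is
#'   high (applies to all markers via coupling).
#' @param log_means Length-2 numeric: log10 intensity mean of the low and
#'   high components.
#' @param log_sd Within-component log10 sd (default 0.15).
#' @param coupling Probability a later marker copies the first marker's
#'   latent state (default 1).
#' @param n_cells Cells per replicate before jitter (default 1000).
#' @param seed Integer seed.
#' @return List: \code{table} (cell_id, cell_line, condition, replicate,
#'   marker, intensity), \code{truth}.
#' @export
gen_singlecell_intensities <- function(cell_lines = "MALME3M_syn",
                                       markers = c("CXXC1", "H3K4me3"),
                                       conditions = c("si_NTC", "si_CXXC1"),
                                       replicates = 3L,
                                       high_fraction = c(si_NTC = 0.85,
                                                         si_CXXC1 = 0.25),
                                       log_means = c(1, 2), log_sd = 0.15,
                                       coupling = 1, n_cells = 1000L,
                                       seed = 1L) {
  stopifnot(all(high_fraction >= 0 & high_fraction <= 1),
            coupling >= 0, coupling <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list(); cell_counter <- 0L
  for (cl in cell_lines) for (cond in conditions) for (rep_ in
                                                       seq_len(replicates)) {
    n <- max(50L, round(n_cells * stats::runif(1, 0.9, 1.1)))
    base_state <- stats::rbinom(n, 1L, high_fraction[[cond]])
    ids <- paste0("cell_", cell_counter + seq_len(n))
    cell_counter <- cell_counter + n
    for (mi in seq_along(markers)) {
      state <- if (mi == 1L) base_state else {
        copy <- stats::rbinom(n, 1L, coupling) == 1L
        ifelse(copy, base_state, stats::rbinom(n, 1L, high_fraction[[cond]]))
      }
      lx <- stats::rnorm(n, log_means[state + 1L], log_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = ids, cell_line = cl, condition = cond, replicate = rep_,
        marker = markers[mi], intensity = 10^lx, stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows),
       truth = list(high_fraction = high_fraction, log_means = log_means,
                    log_sd = log_sd, coupling = coupling, seed = seed))
}

#' Synthetic per-line differential-expression statistic tables
#'
#' Null genes draw Wald statistics from the standard normal (uniform p);
#' planted genes get consistent-sign statistics of magnitude \code{effect}
#' (plus unit noise) in every sensitive line and null behavior in the
#' reference. FDR columns are computed by \code{\link{bh_adjust}} per line.
#'
#' @param n_sensitive Number of sensitive lines (default 3).
#' @param n_genes Total genes per table.
#' @param planted_up,planted_down Disjoint character vectors of planted gene
#'   names (subsets of g0001...).
#' @param effect Mean |Wald| of planted genes (default 8).
#' @param seed Integer seed.
#' @return List: \code{sensitive} (named list of tables: gene, log2fc, wald,
#'   p, fdr), \code{reference} (one table), \code{truth}.
#' @export
gen_de_stats_tables <- function(n_sensitive = 3L, n_genes = 1000L,
                                planted_up = paste0("g",
                                                    sprintf("%04d", 1:40)),
                                planted_down = paste0("g",
                                                      sprintf("%04d", 41:80)),
                                effect = 8, seed = 1L) {
  if (length(intersect(planted_up, planted_down)))
    stop("planted up and down sets must be disjoint")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- paste0("g", sprintf("%04d", seq_len(n_genes)))
  stopifnot(all(c(planted_up, planted_down) %in% genes))
  make_table <- function(planted) {
    wald <- stats::rnorm(n_genes)
    if (planted) {
      wald[genes %in% planted_up] <- effect + stats::rnorm(
        sum(genes %in% planted_up))
      wald[genes %in% planted_down] <- -effect + stats::rnorm(
        sum(genes %in% planted_down))
    }
    p <- 2 * stats::pnorm(-abs(wald))
    data.frame(gene = genes, log2fc = wald / 4, wald = wald, p = p,
               fdr = bh_adjust(p), stringsAsFactors = FALSE)
  }
  sens <- lapply(seq_len(n_sensitive), function(i) make_table(TRUE))
  names(sens) <- paste0("sensitive_", seq_len(n_sensitive))
  list(sensitive = sens, reference = make_table(FALSE),
       truth = list(planted_up = planted_up, planted_down = planted_down,
                    effect = effect, seed = seed))
}

#' Synthetic complex catalog
#'
#' Builds a catalog of complexes over a synthetic gene universe with sizes
#' drawn from the curated catalog's 2-19 range.
#'
#' @param n_complexes Number of complexes (default 43, matching the curated
#'   chromatin-complex catalog scale).
#' @param n_genes Gene universe size.
#' @param seed Integer seed.
#' @return Named list of character vectors.
#' @export
gen_complex_catalog <- function(n_complexes = 43L, n_genes = 200L,
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- paste0("g", sprintf("%04d", seq_len(n_genes)))
  sizes <- sample(2:19, n_complexes, replace = TRUE)
  catalog <- lapply(sizes, function(s) sample(genes, s))
  names(catalog) <- paste0("complex_", sprintf("%02d", seq_len(n_complexes)))
  catalog
}
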