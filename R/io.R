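#' Read a gene-dependency matrix from a DepMap-dialect CSV
#'
#' Parses a CSV whose first column holds cell-line identifiers and whose
#' remaining columns hold probability-of-dependency values in \[0, 1\], one
#' column per gene. DepMap-style headers of the form \code{"SYMBOL (ENTREZID)"}
#' are reduced to the bare symbol by splitting on the first \code{" ("};
#' bare-symbol headers pass through unchanged. Genes (columns) containing any
#' missing value are dropped, matching the upstream policy of restricting
#' analysis to genes with no NA across cell lines; rows that are entirely NA
#' are dropped likewise.
#'
#' @param path Path to the CSV file.
#' @param gene_universe Optional character vector; when given, the matrix is
#'   restricted to these genes (after header normalization).
#' @return A numeric matrix, cell lines in rows (rownames = cell-line ids),
#'   genes in columns (colnames = bare symbols), with attribute
#'   \code{"dropped_genes"} recording NA-dropped gene symbols.
#' @export
read_dependency_matrix <- function(path, gene_universe = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("dependency CSV must have a cell-line id column plus gene columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- normalize_gene_symbols(colnames(m))
  if (anyDuplicated(ids)) stop("duplicate cell-line identifiers in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate gene symbols after header normalization in ", path)
  if (!is.null(gene_universe)) {
    m <- m[, colnames(m) %in% gene_universe, drop = FALSE]
  }
  all_na_row <- rowSums(!is.na(m)) == 0L
  if (any(all_na_row)) m <- m[!all_na_row, , drop = FALSE]
  has_na <- colSums(is.na(m)) > 0L
  dropped <- colnames(m)[has_na]
  if (any(has_na)) {
    message(sum(has_na), " gene(s) dropped for missing values")
    m <- m[, !has_na, drop = FALSE]
  }
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("empty dependency matrix after filtering: ", path)
  if (any(m < 0 | m > 1))
    stop("dependency values outside [0, 1] in ", path)
  attr(m, "dropped_genes") <- dropped
  m
}

#' Normalize DepMap gene-column headers to bare symbols
#'
#' @param x Character vector of column headers.
#' @return Bare gene symbols (text before the first \code{" ("}).
#' @export
normalize_gene_symbols <- function(x) {
  sub(" \\(.*$", "", x)
}

#' Filter cell lines to lineages with adequate representation
#'
#' Removes cell lines whose lineage has fewer than \code{min_n} members in the
#' dependency matrix, and cell lines absent from the annotation. The filter is
#' idempotent: applying it twice gives the same result.
#'
#' @param dep Dependency matrix (cell lines x genes) with rownames.
#' @param ann Data frame with columns \code{cell_line_id} and \code{lineage}.
#' @param min_n Minimum number of cell lines per retained lineage (default 5).
#' @param exclude_lineages Optional character vector of lineage labels removed
#'   before the size filter (e.g. non-cancerous lineages).
#' @return List with elements \code{dep} (filtered matrix) and \code{ann}
#'   (filtered annotation, rows aligned to the matrix).
#' @export
filter_lineages <- function(dep, ann, min_n = 5L, exclude_lineages = NULL) {
  stopifnot(min_n >= 1L)
  if (anyDuplicated(ann$cell_line_id)) stop("duplicate cell lines in annotation")
  if (any(!nzchar(ann$lineage))) stop("empty lineage labels in annotation")
  ann <- ann[ann$cell_line_id %in% rownames(dep), , drop = FALSE]
  n_unann <- sum(!rownames(dep) %in% ann$cell_line_id)
  if (n_unann > 0L) message(n_unann, " unannotated cell line(s) dropped")
  if (!is.null(exclude_lineages))
    ann <- ann[!ann$lineage %in% exclude_lineages, , drop = FALSE]
  sizes <- table(ann$lineage)
  keep_lin <- names(sizes)[sizes >= min_n]
  ann <- ann[ann$lineage %in% keep_lin, , drop = FALSE]
  if (nrow(ann) == 0L) stop("no lineage survives the size filter")
  dep <- dep[ann$cell_line_id, , drop = FALSE]
  list(dep = dep, ann = ann)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated \code{name}, description,
#' then member genes. Duplicate members within a line are removed with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed GMT line (fewer than 3 fields): ", substr(ln, 1, 60))
    members <- fields[-c(1L, 2L)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in gene set '", fields[1L], "' deduplicated")
      members <- unique(members)
    }
    sets[[fields[1L]]] <- members
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
}

#' Read a long-format complex catalog CSV
#'
#' Expects columns \code{complex_name} and \code{gene_symbol}. The curated
#' catalog used for chromatin complexes has sizes between 2 and 19 genes;
#' sizes outside that range are reported with a warning, not an error.
#'
#' @param path CSV path.
#' @return Named list of character vectors (complex -> member genes).
#' @export
read_complex_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("complex_name", "gene_symbol") %in% names(df)))
    stop("catalog CSV needs columns complex_name, gene_symbol")
  catalog <- split(df$gene_symbol, df$complex_name)
  catalog <- lapply(catalog, unique)
  sizes <- lengths(catalog)
  if (any(sizes < 2L | sizes > 19L))
    warning(sum(sizes < 2L | sizes > 19L),
            " complex(es) outside the expected 2-19 member range")
  catalog
}

#' Write a numeric matrix to CSV with full precision
#'
#' Values are serialized at 15 significant digits so a write/read round trip
#' reproduces them to within text-float precision.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the first (rowname) column.
#' @export
write_matrix_csv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), signif(m, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a numeric matrix written by \code{write_matrix_csv}
#'
#' @param path CSV path.
#' @return Numeric matrix with rownames from the first column.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Default analysis configuration
#'
#' Central container for the thresholds and tuning constants of the pipeline.
#' Defaults follow the published analysis: gene-level enrichment at
#' FDR <= 0.05 with logFC >= 0.10, complex-level at FDR <= 0.10 with
#' logFC > 0, VIP cutoffs 1.0 (stringent) and 0.6 (permissive), gene-set
#' size bounds 15-500, 100 PLS-DA down-sampling iterations with a 3:1
#' class-ratio cap, and at least five cell lines per retained lineage.
#'
#' @param min_lines_per_lineage Minimum cell lines per lineage.
#' @param gene_fdr,gene_lfc Gene-level enrichment thresholds.
#' @param complex_fdr Complex-level FDR threshold (logFC must be > 0).
#' @param vip_cutoff,vip_cutoff_permissive Signed-VIP magnitude cutoffs.
#' @param gsea_min_size,gsea_max_size Gene-set size bounds.
#' @param n_plsda_iterations Down-sampling iterations for PLS-DA.
#' @param class_ratio_cap Maximum majority:minority class ratio.
#' @param rest_mean How the "rest" group mean is formed in one-vs-rest
#'   contrasts: \code{"of_means"} (unweighted mean of the other lineage
#'   means) or \code{"pooled"} (mean over all other cell lines).
#' @param rng_seed Global seed; stage seeds are derived from it.
#' @return Named list of class \code{chromdep_config}.
#' @export
chromdep_config <- function(min_lines_per_lineage = 5L,
                            gene_fdr = 0.05, gene_lfc = 0.10,
                            complex_fdr = 0.10,
                            vip_cutoff = 1.0, vip_cutoff_permissive = 0.6,
                            gsea_min_size = 15L, gsea_max_size = 500L,
                            n_plsda_iterations = 100L,
                            class_ratio_cap = 3.0,
                            rest_mean = c("of_means", "pooled"),
                            rng_seed = 1L) {
  rest_mean <- match.arg(rest_mean)
  stopifnot(min_lines_per_lineage >= 1, gene_fdr > 0, gene_lfc > 0,
            complex_fdr > 0, vip_cutoff > 0, vip_cutoff_permissive > 0,
            gsea_min_size > 0, gsea_max_size >= gsea_min_size,
            n_plsda_iterations >= 1, class_ratio_cap >= 1)
  structure(list(min_lines_per_lineage = as.integer(min_lines_per_lineage),
                 gene_fdr = gene_fdr, gene_lfc = gene_lfc,
                 complex_fdr = complex_fdr,
                 vip_cutoff = vip_cutoff,
                 vip_cutoff_permissive = vip_cutoff_permissive,
                 gsea_min_size = as.integer(gsea_min_size),
                 gsea_max_size = as.integer(gsea_max_size),
                 n_plsda_iterations = as.integer(n_plsda_iterations),
                 class_ratio_cap = class_ratio_cap,
                 rest_mean = rest_mean,
                 rng_seed = as.integer(rng_seed)),
            class = "chromdep_config")
}

#' Derive a deterministic child seed from a global seed and a stage name
#'
#' Stage seeds are a pure function of (global seed, stage name), so adding or
#' reordering stages never perturbs the random stream of other stages. The
#' result is always in \[1, 2^31 - 2\].
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer(h %% 2147483645L + 1L)
}
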