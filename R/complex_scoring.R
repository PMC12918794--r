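#' Aggregate gene-level dependencies into complex-level scores
#'
#' For each cell line i and complex c the score is the unweighted mean of the
#' probability-of-dependency values of the complex's member genes:
#' S_ic = mean over g in G_c of D_ig. Members absent from the dependency
#' matrix are excluded from the mean (logged once per complex); complexes with
#' no member present are omitted.
#'
#' @param dep Dependency matrix, cell lines x genes, values in \[0, 1\].
#' @param catalog Named list of character vectors (complex -> member genes).
#' @return Matrix cell lines x complexes with attribute
#'   \code{"effective_members"}: the per-complex count of members actually
#'   present in \code{dep}.
#' @export
complex_scores <- function(dep, catalog) {
  if (length(catalog) == 0L) stop("empty complex catalog")
  present <- lapply(catalog, function(g) intersect(g, colnames(dep)))
  n_eff <- lengths(present)
  missing_any <- names(catalog)[lengths(catalog) > n_eff]
  if (length(missing_any))
    message(length(missing_any),
            " complex(es) have members absent from the dependency matrix")
  keep <- n_eff >= 1L
  if (!any(keep)) stop("no catalog gene present in the dependency matrix")
  if (any(!keep))
    message(sum(!keep), " complex(es) omitted (no member present)")
  present <- present[keep]
  scores <- vapply(present, function(g)
    rowMeans(dep[, g, drop = FALSE]), numeric(nrow(dep)))
  if (nrow(dep) == 1L) scores <- matrix(scores, nrow = 1L,
                                        dimnames = list(rownames(dep), names(present)))
  attr(scores, "effective_members") <- lengths(present)
  scores
}

#' Summarize a complex catalog
#'
#' @param catalog Named list of character vectors.
#' @return One-row data frame with the number of complexes, number of unique
#'   genes, and the min/max/median/mean complex size.
#' @export
catalog_summary <- function(catalog) {
  sizes <- lengths(catalog)
  if (length(catalog) == 0L)
    return(data.frame(n_complexes = 0L, n_unique_genes = 0L, size_min = 0L,
                      size_max = 0L, size_median = 0, size_mean = 0))
  data.frame(n_complexes = length(catalog),
             n_unique_genes = length(unique(unlist(catalog, use.names = FALSE))),
             size_min = min(sizes), size_max = max(sizes),
             size_median = stats::median(sizes), size_mean = mean(sizes))
}

#' Core Set1C/COMPASS subunits used for the complex dependency score
#'
#' CXXC1 and SETD1B are complex-specific; ASH2L, DPY30, RBBP5 and WDR5 are
#' shared COMPASS-family core subunits; WDR82 is Set1C-associated. SETD1A is
#' deliberately not included: it is near-uniformly essential and would
#' compress the score's dynamic range.
#' @export
SET1C_SUBUNITS <- c("CXXC1", "SETD1B", "ASH2L", "DPY30", "RBBP5", "WDR5",
                    "WDR82")

#' Per-cell-line Set1C/COMPASS dependency score
#'
#' Unweighted mean dependency over the supplied subunit list; equivalent to
#' \code{complex_scores} with a single-complex catalog.
#'
#' @param dep Dependency matrix, cell lines x genes.
#' @param subunits Character vector of subunit symbols.
#' @return Named numeric vector, one score per cell line.
#' @export
set1c_score <- function(dep, subunits = SET1C_SUBUNITS) {
  present <- intersect(subunits, colnames(dep))
  if (length(present) == 0L) stop("no Set1C subunit present in the matrix")
  if (length(present) < length(subunits))
    message(length(subunits) - length(present), " subunit(s) absent, excluded")
  rowMeans(dep[, present, drop = FALSE])
}
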