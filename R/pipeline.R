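#' Run the full analysis pipeline on a bundle of input files
#'
#' Executes the stages in a fixed order, writing one or more CSV outputs per
#' stage into \code{outdir} plus a run log echoing the configuration and
#' seed. Stages: complex scoring; gene- and complex-level one-vs-rest
#' differential dependency with enrichment calls; Ward clustering of the
#' z-scored logFC matrices; differentiation-state classification; PLS-DA of
#' dependencies vs differentiation class; Spearman-ranked pre-ranked GSEA
#' against the Set1C/COMPASS score; single-cell gating summaries; consensus
#' differential expression. A stage failure aborts with the stage name and
#' cause. Identical inputs, config and seed produce byte-identical outputs.
#'
#' @param config A \code{\link{chromdep_config}}.
#' @param inputs Named list of file paths: \code{dependency},
#'   \code{metadata}, \code{catalog}, \code{expression}, \code{signature},
#'   \code{gmt}, \code{singlecell}, \code{de_stats} (character vector,
#'   sensitive lines then reference last). Optional elements may be NULL;
#'   their stages are skipped with a log entry, except \code{signature},
#'   which is required whenever \code{expression} is given.
#' @param outdir Output directory (created if needed).
#' @param set1c_subunits Subunit list for the complex score (default
#'   \code{SET1C_SUBUNITS}, intersected with available genes).
#' @return Invisibly, a list of the per-stage results.
#' @export
run_pipeline <- function(config, inputs, outdir,
                         set1c_subunits = SET1C_SUBUNITS) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("chromdep pipeline run",
                 paste0("seed: ", config$rng_seed),
                 paste0("config: ", paste(names(unclass(config)),
                                          unlist(config), sep = "=",
                                          collapse = " ")))
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- dependency stages -------------------------------------------------
  if (!is.null(inputs$dependency)) {
    dep <- stage("io", read_dependency_matrix(inputs$dependency))
    ann <- stage("io", utils::read.csv(inputs$metadata,
                                       stringsAsFactors = FALSE))
    flt <- stage("lineage_filter",
                 filter_lineages(dep, ann, config$min_lines_per_lineage))
    dep <- flt$dep; ann <- flt$ann
    log_lines <- c(log_lines, paste0("retained lineages: ",
                                     length(unique(ann$lineage))))
    catalog <- stage("complex_scoring", read_complex_catalog(inputs$catalog))
    cs <- stage("complex_scoring", complex_scores(dep, catalog))
    write_matrix_csv(cs, file.path(outdir, "complex_scores.csv"),
                     id_col = "cell_line")
    utils::write.csv(catalog_summary(catalog),
                     file.path(outdir, "catalog_summary.csv"),
                     row.names = FALSE)
    gene_tab <- stage("diff_dep_gene",
                      call_enriched(differential_dependency(
                        t(dep), ann$lineage, rest_mean = config$rest_mean),
                        "gene", config))
    utils::write.csv(gene_tab, file.path(outdir, "differential_genes.csv"),
                     row.names = FALSE)
    cx_tab <- stage("diff_dep_complex",
                    call_enriched(differential_dependency(
                      t(cs), ann$lineage, rest_mean = config$rest_mean),
                      "complex", config))
    utils::write.csv(cx_tab, file.path(outdir,
                                       "differential_complexes.csv"),
                     row.names = FALSE)
    # lineage x complex logFC matrix, z-scored and clustered
    lfc <- stats::xtabs(logFC ~ lineage + feature, data = cx_tab)
    lfc <- matrix(as.numeric(lfc), nrow(lfc), ncol(lfc),
                  dimnames = dimnames(lfc))
    z <- stage("clustering", suppressWarnings(zscore_rows(lfc)))
    write_matrix_csv(z, file.path(outdir, "zscored_complex_logfc.csv"),
                     id_col = "lineage")
    if (nrow(z) >= 2L) {
      cl <- stage("clustering", ward_cluster(z))
      utils::write.csv(data.frame(left = cl$merge[, 1L],
                                  right = cl$merge[, 2L],
                                  height = signif(cl$height, 15)),
                       file.path(outdir, "lineage_merge_tree.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(order = cl$order,
                                  label = cl$labels[cl$order]),
                       file.path(outdir, "lineage_leaf_order.csv"),
                       row.names = FALSE)
    }
    s1c <- stage("complex_scoring",
                 set1c_score(dep, intersect(set1c_subunits, colnames(dep))))
    utils::write.csv(data.frame(cell_line = names(s1c),
                                set1c_score = signif(s1c, 15)),
                     file.path(outdir, "set1c_scores.csv"),
                     row.names = FALSE)
    results$dep <- dep; results$annotation <- ann
    results$complex_scores <- cs
    results$differential_genes <- gene_tab
    results$differential_complexes <- cx_tab
    results$set1c_score <- s1c
  }

  # --- state classification + PLS-DA ------------------------------------
  if (!is.null(inputs$expression)) {
    if (is.null(inputs$signature) || !file.exists(inputs$signature))
      stop("pipeline stage 'state_classification' failed: ",
           "missing signature file", call. = FALSE)
    expr <- stage("state_classification", read_matrix_csv(inputs$expression))
    sig <- stage("state_classification",
                 utils::read.csv(inputs$signature,
                                 stringsAsFactors = FALSE))
    sc <- stage("state_classification", state_scores(expr, sig))
    prof <- stage("state_classification", diff_axis(sc))
    cls <- stage("state_classification", assign_classes(prof))
    out_prof <- cbind(cls$profile,
                      as.data.frame(signif(sc[cls$profile$cell_line, ,
                                              drop = FALSE], 15)))
    utils::write.csv(out_prof, file.path(outdir, "state_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(parameter = c("pi1", "pi2", "mu1", "mu2",
                                              "sigma1", "sigma2",
                                              "boundary"),
                                value = signif(c(cls$fit$pi, cls$fit$mu,
                                                 cls$fit$sigma,
                                                 cls$boundary), 15)),
                     file.path(outdir, "gmm_fit.csv"), row.names = FALSE)
    results$state <- cls
    if (!is.null(results$dep)) {
      shared <- intersect(rownames(results$dep), cls$profile$cell_line)
      if (length(shared) >= 10L) {
        y <- as.integer(cls$profile$class[match(shared,
                                                cls$profile$cell_line)] ==
                          "melanocytic_like")
        pls_cfg <- config
        pls <- stage("plsda",
                     run_plsda_iterations(results$dep[shared, , drop = FALSE],
                                          y, pls_cfg))
        utils::write.csv(pls$vip_table, file.path(outdir,
                                                  "plsda_signed_vip.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(iteration = seq_along(pls$auc),
                                    chosen_k = pls$chosen_k,
                                    cv_auc = signif(pls$auc, 15)),
                         file.path(outdir, "plsda_cv.csv"),
                         row.names = FALSE)
        results$plsda <- pls
      } else {
        log_lines <- c(log_lines, "plsda skipped: <10 shared cell lines")
      }
    }
  }

  # --- enrichment: Spearman-ranked GSEA vs Set1C score -------------------
  if (!is.null(inputs$gmt) && !is.null(results$set1c_score) &&
      !is.null(inputs$expression)) {
    sets <- stage("gsea", read_gmt(inputs$gmt))
    expr <- read_matrix_csv(inputs$expression)
    shared <- intersect(colnames(expr), names(results$set1c_score))
    if (length(shared) >= 3L) {
      ranked <- stage("gsea",
                      rank_by_phenotype(expr[, shared, drop = FALSE],
                                        results$set1c_score[shared]))
      gs <- stage("gsea",
                  preranked_gsea(ranked, sets,
                                 min_size = config$gsea_min_size,
                                 max_size = config$gsea_max_size,
                                 seed = stage_seed(config$rng_seed, "gsea")))
      utils::write.csv(gs, file.path(outdir, "gsea_set1c.csv"),
                       row.names = FALSE)
      results$gsea <- gs
    }
  }

  # --- single-cell gating ------------------------------------------------
  if (!is.null(inputs$singlecell)) {
    sc_tab <- stage("gating", utils::read.csv(inputs$singlecell,
                                              stringsAsFactors = FALSE))
    gates <- list()
    rows <- list()
    for (cl in unique(sc_tab$cell_line)) for (mk in
                                              unique(sc_tab$marker)) {
      g <- stage("gating", pool_and_gate(sc_tab, mk, cl))
      gates[[paste(cl, mk, sep = "|")]] <- g
      fh <- fraction_high(sc_tab, g, mk, cl)
      fh$by_condition$cell_line <- cl
      fh$by_condition$marker <- mk
      fh$by_condition$threshold <- g$threshold
      rows[[length(rows) + 1L]] <- fh$by_condition
    }
    gate_tab <- do.call(rbind, rows)
    gate_tab$pct_high <- signif(gate_tab$pct_high, 15)
    gate_tab$threshold <- signif(gate_tab$threshold, 15)
    utils::write.csv(gate_tab, file.path(outdir, "fraction_high.csv"),
                     row.names = FALSE)
    results$gates <- gates
  }

  # --- consensus differential expression ---------------------------------
  if (!is.null(inputs$de_stats)) {
    tabs <- stage("consensus_de",
                  lapply(inputs$de_stats, function(p)
                    flag_significance(utils::read.csv(
                      p, stringsAsFactors = FALSE))))
    nref <- length(tabs)
    cons <- stage("consensus_de",
                  consensus_sets(tabs[-nref], tabs[[nref]]))
    writeLines(cons$up, file.path(outdir, "consensus_up.txt"))
    writeLines(cons$down, file.path(outdir, "consensus_down.txt"))
    rk <- stage("consensus_de", merged_ranking(tabs[-nref]))
    rk$score <- signif(rk$score, 15)
    utils::write.csv(rk, file.path(outdir, "merged_ranking.csv"),
                     row.names = FALSE)
    results$consensus <- cons
    results$merged_ranking <- rk
  }

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(results)
}

#' Write a full synthetic input bundle to disk
#'
#' Emits every file type the pipeline consumes, generated with planted
#' ground truth under the given seed, plus the truth tables.
#'
#' @param outdir Directory for the bundle.
#' @param seed Integer seed.
#' @param n_lineages,lines_per_lineage,n_genes Dependency-matrix dimensions.
#' @param planted_complex_delta Effect size of the planted melanoma-like
#'   complex enrichment (default 0.3).
#' @return Invisibly, a named list of the file paths plus the truth objects.
#' @export
write_synthetic_bundle <- function(outdir, seed = 1L, n_lineages = 6L,
                                   lines_per_lineage = 10L, n_genes = 200L,
                                   planted_complex_delta = 0.3) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  catalog <- gen_complex_catalog(n_complexes = 20L, n_genes = n_genes,
                                 seed = stage_seed(seed, "catalog"))
  planted <- data.frame(complex = "complex_01", lineage = "lineage_01",
                        delta = planted_complex_delta,
                        stringsAsFactors = FALSE)
  depgen <- gen_dependency_matrix(n_lineages, lines_per_lineage, n_genes,
                                  catalog = catalog,
                                  planted_complexes = planted,
                                  seed = stage_seed(seed, "dependency"))
  paths <- list(dependency = file.path(outdir, "dependency.csv"),
                metadata = file.path(outdir, "metadata.csv"),
                catalog = file.path(outdir, "catalog.csv"),
                expression = file.path(outdir, "expression.csv"),
                signature = file.path(outdir, "signature.csv"),
                gmt = file.path(outdir, "sets.gmt"),
                singlecell = file.path(outdir, "singlecell.csv"),
                de_stats = file.path(outdir,
                                     paste0("de_stats_",
                                            c("s1", "s2", "s3", "ref"),
                                            ".csv")))
  write_matrix_csv(depgen$dep, paths$dependency, id_col = "cell_line_id")
  utils::write.csv(depgen$annotation, paths$metadata, row.names = FALSE)
  utils::write.csv(data.frame(
    complex_name = rep(names(catalog), lengths(catalog)),
    gene_symbol = unlist(catalog, use.names = FALSE)),
    paths$catalog, row.names = FALSE)
  exprgen <- gen_expression_matrix(n_lines = 70L,
                                   seed = stage_seed(seed, "expression"))
  write_matrix_csv(exprgen$expr, paths$expression, id_col = "gene")
  utils::write.csv(exprgen$signature, paths$signature, row.names = FALSE)
  sets <- list(planted_top = paste0("g", sprintf("%04d", 1:20)),
               null_set = paste0("g", sprintf("%04d", 101:130)))
  write_gmt(sets, paths$gmt)
  scgen <- gen_singlecell_intensities(seed = stage_seed(seed, "singlecell"))
  utils::write.csv(scgen$table, paths$singlecell, row.names = FALSE)
  degen <- gen_de_stats_tables(seed = stage_seed(seed, "de_stats"))
  for (i in 1:3) utils::write.csv(degen$sensitive[[i]],
                                  paths$de_stats[i], row.names = FALSE)
  utils::write.csv(degen$reference, paths$de_stats[4L], row.names = FALSE)
  invisible(c(paths, list(truth = list(dependency = depgen$truth,
                                       expression = exprgen$truth,
                                       singlecell = scgen$truth,
                                       de_stats = degen$truth))))
}
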