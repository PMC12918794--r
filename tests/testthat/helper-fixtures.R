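# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

write_temp_csv <- function(df, name = "fixture.csv") {
  path <- file.path(tempdir(), name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Small DepMap-dialect dependency CSV with configurable NA placement.
make_dep_csv <- function(na_gene = NULL) {
  df <- data.frame(ModelID = c("ACH-1", "ACH-2", "ACH-3"),
                   check.names = FALSE)
  df[["CXXC1 (30827)"]] <- c(0.9, 0.8, 0.7)
  df[["SETD1B (23067)"]] <- c(0.5, 0.4, 0.3)
  df[["PLAIN"]] <- c(0.1, 0.2, 0.3)
  if (!is.null(na_gene)) df[[na_gene]][2L] <- NA
  write_temp_csv(df, "dep_fixture.csv")
}

# Lineage annotation with n lineages of given sizes.
make_annotation <- function(sizes) {
  lineages <- paste0("lin_", seq_along(sizes))
  data.frame(cell_line_id = paste0("ACH-", seq_len(sum(sizes))),
             lineage = rep(lineages, sizes), stringsAsFactors = FALSE)
}

# Dependency matrix matching an annotation (uniform noise, no effects).
make_dep_for_annotation <- function(ann, n_genes = 10L, seed = 1L) {
  set.seed(seed)
  m <- matrix(runif(nrow(ann) * n_genes), nrow(ann), n_genes,
              dimnames = list(ann$cell_line_id,
                              paste0("g", seq_len(n_genes))))
  m
}
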