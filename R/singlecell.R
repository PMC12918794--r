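#' Pool log intensities across conditions and fit a high/low gate
#'
#' Per (cell_line, marker), raw intensities are log-transformed (base 10 by
#' default), pooled across all conditions and replicates of the cell line,
#' and fit with the shared two-component 1-D Gaussian mixture; the gate is
#' the analytic decision boundary between the component means. Cells with
#' nonpositive raw intensity (background-subtraction artifacts) are dropped
#' with a logged count. The same gate applies to every condition of the
#' cell line.
#'
#' @param table Data frame with columns \code{cell_line}, \code{condition},
#'   \code{replicate}, \code{marker}, \code{intensity}.
#' @param marker Marker name to gate.
#' @param cell_line Cell line to gate.
#' @param log_base Log base for the transform (default 10).
#' @return List: \code{threshold} (log units), \code{fit} (\code{gmm1d}),
#'   \code{log_base}, \code{n_cells}, \code{n_dropped_nonpositive}.
#' @export
pool_and_gate <- function(table, marker, cell_line, log_base = 10) {
  sub <- table[table$marker == marker & table$cell_line == cell_line, ,
               drop = FALSE]
  nonpos <- sub$intensity <= 0
  if (any(nonpos)) {
    message(sum(nonpos), " nonpositive intensit(ies) dropped")
    sub <- sub[!nonpos, , drop = FALSE]
  }
  if (nrow(sub) < 50L) stop("fewer than 50 pooled cells for gating")
  lx <- log(sub$intensity, base = log_base)
  fit <- fit_gmm_1d(lx)
  threshold <- gmm_boundary(fit)
  if (threshold <= min(lx) || threshold >= max(lx))
    warning("gate threshold falls outside the data range")
  list(threshold = threshold, fit = fit, log_base = log_base,
       n_cells = nrow(sub), n_dropped_nonpositive = sum(nonpos))
}

#' Fraction of cells in the high state per condition
#'
#' A cell is high iff its log intensity is strictly above the gate threshold
#' (cells exactly at the threshold count as low). Fractions are reported in
#' percent, per replicate and pooled per condition; empty replicates are
#' excluded with a warning.
#'
#' @param table Single-cell data frame (see \code{\link{pool_and_gate}}).
#' @param gate A gate from \code{\link{pool_and_gate}}.
#' @param marker,cell_line Which slice to summarize.
#' @return List with \code{by_replicate} (condition, replicate, n_cells,
#'   pct_high) and \code{by_condition} (condition, n_cells, pct_high pooled).
#' @export
fraction_high <- function(table, gate, marker, cell_line) {
  sub <- table[table$marker == marker & table$cell_line == cell_line &
                 table$intensity > 0, , drop = FALSE]
  lx <- log(sub$intensity, base = gate$log_base)
  high <- lx > gate$threshold
  key <- interaction(sub$condition, sub$replicate, drop = TRUE)
  by_rep <- do.call(rbind, lapply(split(seq_len(nrow(sub)), key), function(i) {
    data.frame(condition = sub$condition[i[1L]],
               replicate = sub$replicate[i[1L]],
               n_cells = length(i),
               pct_high = 100 * mean(high[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(by_rep) <- NULL
  by_cond <- do.call(rbind, lapply(split(seq_len(nrow(sub)), sub$condition),
                                   function(i) {
    data.frame(condition = sub$condition[i[1L]], n_cells = length(i),
               pct_high = 100 * mean(high[i]), stringsAsFactors = FALSE)
  }))
  rownames(by_cond) <- NULL
  list(by_replicate = by_rep, by_condition = by_cond)
}

#' 2x2 quadrant fractions for two gated markers
#'
#' Cells are classified low/high on each marker by its gate (strict > for
#' high) and tabulated into the four quadrants per condition; percentages are
#' computed on all cells of the condition (down-sampling is only ever used
#' for display export, never for the statistics). Per-replicate quadrant
#' percentages and their means are also reported. Quadrant percentages sum
#' to 100 exactly within each condition.
#'
#' @param table Single-cell data frame in wide-by-call form: one row per
#'   (cell, marker); both markers must be measured on the same cells,
#'   identified by a \code{cell_id} column.
#' @param marker_x,marker_y Marker names.
#' @param gate_x,gate_y Gates from \code{\link{pool_and_gate}}.
#' @param cell_line Cell line to analyze.
#' @return Data frame: condition, quadrant (low_low, high_low, low_high,
#'   high_high), pct (pooled), pct_replicate_mean.
#' @export
quadrant_fractions <- function(table, marker_x, marker_y, gate_x, gate_y,
                               cell_line) {
  sx <- table[table$marker == marker_x & table$cell_line == cell_line, ]
  sy <- table[table$marker == marker_y & table$cell_line == cell_line, ]
  m <- merge(sx[, c("cell_id", "condition", "replicate", "intensity")],
             sy[, c("cell_id", "intensity")], by = "cell_id",
             suffixes = c("_x", "_y"))
  m <- m[m$intensity_x > 0 & m$intensity_y > 0, , drop = FALSE]
  hx <- log(m$intensity_x, base = gate_x$log_base) > gate_x$threshold
  hy <- log(m$intensity_y, base = gate_y$log_base) > gate_y$threshold
  quad <- factor(paste(ifelse(hx, "high", "low"), ifelse(hy, "high", "low"),
                       sep = "_"),
                 levels = c("low_low", "high_low", "low_high", "high_high"))
  out <- do.call(rbind, lapply(split(seq_len(nrow(m)), m$condition),
                               function(i) {
    pooled <- 100 * table(quad[i]) / length(i)
    per_rep <- sapply(split(i, m$replicate[i]), function(j)
      100 * table(quad[j]) / length(j))
    data.frame(condition = m$condition[i[1L]],
               quadrant = levels(quad),
               pct = as.numeric(pooled),
               pct_replicate_mean = rowMeans(per_rep),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sided Welch's t-test on replicate-level summaries
#'
#' Welch's unequal-variance t with Welch-Satterthwaite degrees of freedom.
#' When both within-group variances are zero (degenerate replicate values), a
#' tiny epsilon proportional to the squared mean scale is added to the
#' standard error so the statistic exists; the df then defaults to
#' n1 + n2 - 2.
#'
#' @param x,y Replicate-level values (each length >= 2).
#' @return List: \code{t}, \code{df}, \code{p}.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 replicates per group")
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  se2 <- v1 + v2
  if (se2 == 0) {
    eps <- 1e-12 * (abs(mean(x)) + abs(mean(y)) + 1)^2
    se2 <- eps
    df <- length(x) + length(y) - 2
  } else {
    df <- se2^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Normalized cell counts relative to the control condition
#'
#' Each replicate's nuclei count is divided by the mean control-condition
#' count within the same cell line, giving a bulk growth readout in which the
#' control replicates average to 1.
#'
#' @param counts Data frame: cell_line, condition, replicate, n_cells.
#' @param control_condition Name of the control condition.
#' @return Input with a \code{normalized_count} column appended.
#' @export
normalized_cell_count <- function(counts, control_condition) {
  out <- lapply(split(counts, counts$cell_line), function(d) {
    ctrl <- d$n_cells[d$condition == control_condition]
    if (length(ctrl) == 0L || mean(ctrl) == 0)
      stop("missing or zero control counts for cell line ", d$cell_line[1L])
    d$normalized_count <- d$n_cells / mean(ctrl)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit of paired per-line percent changes
#'
#' Regresses delta-percent values of one readout on another across cell
#' lines (e.g. change in fraction of proliferating cells vs change in
#' H3K4me3-high fraction) and reports slope, intercept and R-squared.
#'
#' @param dx,dy Numeric vectors (>= 3 points; \code{dx} must vary).
#' @return List: \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
delta_regression <- function(dx, dy) {
  if (length(dx) < 3L || length(dx) != length(dy))
    stop("need >= 3 paired points")
  if (stats::var(dx) == 0) stop("zero variance in x")
  fit <- stats::lm(dy ~ dx)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dy - mean(dy))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}
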