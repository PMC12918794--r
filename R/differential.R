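#' One-versus-rest group-mean linear fit per feature
#'
#' Fits, for every feature (gene or complex), the ordinary least squares model
#' with one indicator per lineage and no intercept, so the coefficients are
#' the lineage means. For each lineage l the reported effect is
#' logFC = mean(lineage l) - mean(rest), where "rest" is either the
#' unweighted mean of the other lineage means (\code{rest_mean = "of_means"},
#' the contrast implied by a no-intercept group design) or the pooled mean
#' over all other cell lines (\code{"pooled"}). The residual variance is
#' pooled across all groups with n_total - n_lineages degrees of freedom, and
#' the contrast variance multiplier v_l is derived from the contrast weights.
#'
#' @param m Feature x cell-line numeric matrix.
#' @param lineage Character/factor vector of lineage labels, one per column
#'   of \code{m}; every lineage must have at least 2 members and there must
#'   be at least 2 lineages.
#' @param rest_mean \code{"of_means"} or \code{"pooled"}; see Details.
#' @return List with \code{group_means} (feature x lineage), \code{logFC}
#'   (feature x lineage), \code{s2} (pooled residual variance per feature),
#'   \code{df} (residual df, scalar), \code{v} (contrast variance multiplier
#'   per lineage), \code{n} (lineage sizes), \code{rest_mean}.
#' @export
fit_one_vs_rest <- function(m, lineage, rest_mean = c("of_means", "pooled")) {
  rest_mean <- match.arg(rest_mean)
  lineage <- as.character(lineage)
  stopifnot(ncol(m) == length(lineage))
  n_l <- table(lineage)
  if (length(n_l) < 2L) stop("need at least 2 lineages")
  if (any(n_l < 2L)) stop("every lineage needs at least 2 cell lines")
  L <- length(n_l)
  labs <- names(n_l)
  n_tot <- ncol(m)
  grp <- factor(lineage, levels = labs)
  # group means: features x lineages
  gm <- t(rowsum(t(m), grp)) / rep(as.integer(n_l), each = nrow(m))
  colnames(gm) <- labs
  # pooled residual variance around group means
  resid <- m - gm[, as.integer(grp), drop = FALSE]
  df <- n_tot - L
  s2 <- rowSums(resid^2) / df
  nv <- as.numeric(n_l)
  if (rest_mean == "of_means") {
    other_mean <- (rowSums(gm)[row(gm)] - gm) / (L - 1)
    dim(other_mean) <- dim(gm)
    logFC <- gm - other_mean
    v <- 1 / nv + (sum(1 / nv) - 1 / nv) / (L - 1)^2
  } else {
    tot <- gm %*% nv
    pooled_other <- (matrix(tot, nrow(gm), L) - sweep(gm, 2L, nv, "*")) /
      rep(n_tot - nv, each = nrow(gm))
    logFC <- gm - pooled_other
    v <- 1 / nv + 1 / (n_tot - nv)
  }
  dimnames(logFC) <- dimnames(gm)
  names(v) <- labs
  list(group_means = gm, logFC = logFC, s2 = s2, df = df, v = v,
       n = as.integer(n_l), rest_mean = rest_mean)
}

# Inverse of trigamma by Newton iteration (monotone decreasing function).
trigamma_inverse <- function(x) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    if (!is.finite(xi) || xi <= 0) { out[i] <- Inf; next }
    if (xi > 1e7) { out[i] <- 1 / sqrt(xi); next }
    if (xi < 1e-6) { out[i] <- 1 / xi; next }
    y <- 0.5 + 1 / xi
    for (iter in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    out[i] <- y
  }
  out
}

#' Empirical Bayes moderation of residual variances
#'
#' Estimates a scaled inverse-chi-square prior (d0, s0^2) for the per-feature
#' residual variances by matching moments of log(s^2), following the
#' classical log-variance moment estimators: with z = log(s2) and
#' e = z - digamma(df/2) + log(df/2), solve
#' trigamma(d0/2) = var(e) - trigamma(df/2) and recover s0^2 from mean(e).
#' When the observed spread of log-variances is at or below the spread
#' expected from sampling alone, d0 = Inf and the posterior variances all
#' equal s0^2. Posterior variances are
#' s2_tilde = (d0 * s0^2 + df * s2) / (d0 + df).
#'
#' @param s2 Per-feature residual variances (length >= 10 recommended).
#' @param df Residual degrees of freedom (scalar or per-feature vector).
#' @return List with \code{d0}, \code{s0_2}, \code{s2_post} (posterior
#'   variances), and \code{df_total} = df + d0.
#' @export
moderate_variances <- function(s2, df) {
  if (all(s2 == 0)) stop("all residual variances are zero")
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 >= 0
  if (sum(ok) < 2L) stop("need at least 2 usable variances")
  x <- s2[ok]
  x <- pmax(x, 1e-5 * stats::median(x))  # offset exact zeros
  z <- log(x)
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(df[ok] / 2))
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s0_2 <- mean(x)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    d0 <- min(max(d0, 0), 1e6)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + df * s2) / (d0 + df)
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, df_total = df + d0)
}

#' Moderated t-statistics and p-values for one-vs-rest contrasts
#'
#' t = logFC / sqrt(s2_post * v), with two-sided p from the t distribution on
#' df + d0 degrees of freedom (normal when d0 is infinite).
#'
#' @param fit Result of \code{\link{fit_one_vs_rest}}.
#' @param mod Result of \code{\link{moderate_variances}} on \code{fit$s2}
#'   (or NULL to skip moderation, i.e. d0 = 0).
#' @return Long data frame: feature, lineage, logFC, t, p (no FDR yet).
#' @export
moderated_t <- function(fit, mod = NULL) {
  if (is.null(mod)) {
    s2p <- fit$s2
    dft <- rep(fit$df, length(fit$s2))
  } else {
    s2p <- mod$s2_post
    dft <- rep_len(mod$df_total, length(fit$s2))
  }
  feats <- rownames(fit$logFC)
  if (is.null(feats)) feats <- as.character(seq_len(nrow(fit$logFC)))
  labs <- colnames(fit$logFC)
  se <- sqrt(outer(s2p, fit$v))
  tstat <- fit$logFC / se
  tstat[fit$logFC == 0] <- 0  # 0/0 for constant features
  p <- matrix(NA_real_, nrow(tstat), ncol(tstat))
  finite_df <- is.finite(dft)
  for (j in seq_len(ncol(tstat))) {
    p[, j] <- ifelse(finite_df,
                     2 * stats::pt(-abs(tstat[, j]), df = dft),
                     2 * stats::pnorm(-abs(tstat[, j])))
  }
  data.frame(feature = rep(feats, times = length(labs)),
             lineage = rep(labs, each = length(feats)),
             logFC = as.vector(fit$logFC),
             t = as.vector(tstat),
             p = as.vector(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone, tied values share the adjusted value
#'   implied by their largest index).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Run the full one-vs-rest differential pipeline on a feature matrix
#'
#' Fit, moderate, test, and BH-adjust within each lineage contrast.
#'
#' @param m Feature x cell-line matrix.
#' @param lineage Lineage labels per column.
#' @param rest_mean Passed to \code{\link{fit_one_vs_rest}}.
#' @param moderate Apply empirical Bayes moderation (default TRUE).
#' @return Long data frame: feature, lineage, logFC, t, p, fdr.
#' @export
differential_dependency <- function(m, lineage,
                                    rest_mean = c("of_means", "pooled"),
                                    moderate = TRUE) {
  fit <- fit_one_vs_rest(m, lineage, rest_mean = match.arg(rest_mean))
  mod <- if (moderate) moderate_variances(fit$s2, fit$df) else NULL
  tab <- moderated_t(fit, mod)
  # FDR across features, within each lineage contrast
  tab$fdr <- stats::ave(tab$p, tab$lineage, FUN = bh_adjust)
  tab
}

#' Flag lineage-enriched features
#'
#' Gene level: FDR <= 0.05 and logFC >= 0.10. Complex level: FDR <= 0.10 and
#' logFC > 0 (strict). Thresholds come from \code{config}.
#'
#' @param table Data frame with columns \code{logFC} and \code{fdr}.
#' @param level \code{"gene"} or \code{"complex"}.
#' @param config A \code{\link{chromdep_config}}.
#' @return The table with a logical \code{enriched} column appended.
#' @export
call_enriched <- function(table, level = c("gene", "complex"),
                          config = chromdep_config()) {
  level <- match.arg(level)
  table$enriched <- if (level == "gene") {
    table$fdr <= config$gene_fdr & table$logFC >= config$gene_lfc
  } else {
    table$fdr <= config$complex_fdr & table$logFC > 0
  }
  table
}

#' Row-wise z-scoring
#'
#' Centers and scales each row to mean 0 and sample (n-1) standard deviation
#' 1. Rows with zero variance are dropped with a warning.
#'
#' @param m Numeric matrix.
#' @return Z-scored matrix (possibly fewer rows).
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  bad <- sd == 0 | !is.finite(sd)
  if (any(bad)) {
    warning(sum(bad), " constant row(s) dropped before z-scoring")
    m <- m[!bad, , drop = FALSE]; mu <- mu[!bad]; sd <- sd[!bad]
  }
  (m - mu) / sd
}

#' Agglomerative Ward clustering (ward.D2 convention)
#'
#' Lance-Williams recurrence on squared Euclidean distances; merge heights
#' are reported on the distance scale (square root of the squared-distance
#' criterion), matching the ward.D2 convention. Ties are broken by merging
#' the pair with the smallest cluster indices (original leaves first, then
#' merge order).
#'
#' @param m Numeric matrix; rows are the items clustered.
#' @return List with \code{merge} (hclust-style merge matrix), \code{height},
#'   \code{order} (leaf order), \code{labels}.
#' @export
ward_cluster <- function(m) {
  if (!all(is.finite(m))) stop("non-finite values in clustering input")
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 items to cluster")
  d2 <- as.matrix(stats::dist(m))^2
  size <- rep(1L, n)
  id <- -(1:n)                       # hclust convention: negatives = leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(1:n)            # original leaf indices per cluster slot
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (a in seq_along(act)) for (b in seq_len(a - 1L)) {
      i <- act[b]; j <- act[a]
      if (d2[i, j] < bestd - 1e-12) { bestd <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    height[step] <- sqrt(bestd)
    pair <- sort(c(id[i], id[j]))
    # hclust orders: leaves (negative) before merges, by |index|
    merge[step, ] <- if (pair[1L] < 0 && pair[2L] < 0) rev(pair) else pair
    ni <- size[i]; nj <- size[j]
    for (k in act) {
      if (k == i || k == j) next
      nk <- size[k]
      d2new <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                  nk * d2[i, j]) / (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- d2new
    }
    size[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    id[i] <- step
  }
  # leaf order by recursive unfolding of the merge matrix
  unfold <- function(node) {
    if (node < 0) return(-node)
    c(unfold(merge[node, 1L]), unfold(merge[node, 2L]))
  }
  list(merge = merge, height = height,
       order = unfold(n - 1L), labels = rownames(m))
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact p-value (via the null distribution of the Mann-Whitney U statistic)
#' when the combined sample size is at most 30 and there are no ties;
#' otherwise the normal approximation with continuity and tie correction.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return List with \code{W} (U statistic for \code{x}), \code{p}
#'   (two-sided), and \code{method}.
#' @export
rank_sum_compare <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (nx + ny <= 30L && !ties) {
    p <- if (U > nx * ny / 2) {
      stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE) * 2
    } else {
      stats::pwilcox(U, nx, ny) * 2
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    tie_tab <- table(r)
    Nn <- nx + ny
    sigma2 <- nx * ny / 12 * ((Nn + 1) - sum(tie_tab^3 - tie_tab) /
                                (Nn * (Nn - 1)))
    zc <- U - nx * ny / 2
    z <- (zc - sign(zc) * 0.5) / sqrt(sigma2)
    if (sigma2 == 0) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(W = U, p = p, method = method)
}
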