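#' The seven ordered melanoma differentiation states
#' @export
MELANOMA_STATES <- c("melanocytic", "transitory-melanocytic", "transitory",
                     "neural crest-like-transitory", "neural crest-like",
                     "undifferentiated-neural crest-like", "undifferentiated")

#' Per-cell-line differentiation state scores
#'
#' Each signature gene's log2(TPM+1) expression is z-scored across cell lines
#' (sample sd, n-1); each state's score per cell line is the mean z-score
#' over the genes assigned to that state. Signature genes absent from the
#' expression matrix are logged; genes with zero variance are dropped.
#'
#' @param expr Expression matrix, genes x cell lines (log2(TPM+1)).
#' @param signature Data frame with columns \code{gene} and \code{state}
#'   (state labels must be among \code{MELANOMA_STATES}).
#' @return Matrix cell lines x 7 states of state scores.
#' @export
state_scores <- function(expr, signature) {
  bad_state <- setdiff(unique(signature$state), MELANOMA_STATES)
  if (length(bad_state))
    stop("unrecognized state label(s): ", paste(bad_state, collapse = ", "))
  present <- signature$gene %in% rownames(expr)
  if (any(!present))
    message(sum(!present), " signature gene(s) absent from expression matrix")
  signature <- signature[present, , drop = FALSE]
  sub <- expr[signature$gene, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  keep <- sds > 0 & is.finite(sds)
  if (any(!keep)) {
    message(sum(!keep), " zero-variance signature gene(s) dropped")
    sub <- sub[keep, , drop = FALSE]
    signature <- signature[keep, , drop = FALSE]
  }
  z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
  out <- sapply(MELANOMA_STATES, function(st) {
    g <- signature$gene[signature$state == st]
    if (length(g) == 0L) stop("no usable signature gene for state: ", st)
    colMeans(z[g, , drop = FALSE])
  })
  rownames(out) <- colnames(expr)
  out
}

#' Differentiation-axis aggregates
#'
#' Melanocytic aggregate = mean of the melanocytic, transitory-melanocytic,
#' and transitory state scores; undifferentiated aggregate = mean of the
#' neural crest-like, undifferentiated-neural crest-like, and
#' undifferentiated scores. The intermediate neural crest-like-transitory
#' state belongs to neither aggregate. DiffAxis is their difference; higher
#' values mean a more melanocytic-like profile.
#'
#' @param scores Cell line x state matrix from \code{\link{state_scores}}.
#' @return Data frame: cell_line, melanocytic_aggregate,
#'   undifferentiated_aggregate, diff_axis.
#' @export
diff_axis <- function(scores) {
  mel_states <- MELANOMA_STATES[1:3]
  und_states <- MELANOMA_STATES[5:7]
  mel <- rowMeans(scores[, mel_states, drop = FALSE])
  und <- rowMeans(scores[, und_states, drop = FALSE])
  data.frame(cell_line = rownames(scores),
             melanocytic_aggregate = mel,
             undifferentiated_aggregate = und,
             diff_axis = mel - und,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a two-component Gaussian mixture to a 1-D sample by EM
#'
#' Deterministic initialization by median split. Components are ordered so
#' mu1 < mu2. Convergence when the relative log-likelihood change falls
#' below 1e-8 (at most 1000 iterations). Component standard deviations are
#' floored at sqrt(1e-6 * var(x)) to avoid collapse.
#'
#' @param x Numeric vector of at least 4 finite values.
#' @param maxit,tol EM iteration controls.
#' @return List of class \code{gmm1d}: \code{pi}, \code{mu}, \code{sigma}
#'   (each length 2), \code{loglik}, \code{n_iter}, \code{converged}.
#' @export
fit_gmm_1d <- function(x, maxit = 1000L, tol = 1e-8) {
  if (any(!is.finite(x))) stop("non-finite values in input")
  if (length(x) < 4L) stop("need at least 4 values")
  if (stats::var(x) == 0) stop("degenerate input: all values equal")
  floor_sd <- sqrt(1e-6 * stats::var(x))
  med <- stats::median(x)
  lo <- x <= med; hi <- !lo
  if (!any(hi)) { hi <- x >= med; lo <- !hi }  # heavy ties at the median
  pi_ <- c(mean(lo), mean(hi))
  mu <- c(mean(x[lo]), mean(x[hi]))
  sigma <- pmax(c(stats::sd(x[lo]), stats::sd(x[hi])), floor_sd)
  sigma[is.na(sigma)] <- floor_sd
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(maxit)) {
    d1 <- pi_[1L] * stats::dnorm(x, mu[1L], sigma[1L])
    d2 <- pi_[2L] * stats::dnorm(x, mu[2L], sigma[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE; break
    }
    ll_old <- ll
    g1 <- d1 / tot
    n1 <- sum(g1); n2 <- length(x) - n1
    pi_ <- c(n1, n2) / length(x)
    mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
    sigma <- pmax(c(sqrt(sum(g1 * (x - mu[1L])^2) / n1),
                    sqrt(sum((1 - g1) * (x - mu[2L])^2) / n2)), floor_sd)
  }
  if (mu[1L] > mu[2L]) {
    pi_ <- rev(pi_); mu <- rev(mu); sigma <- rev(sigma)
  }
  structure(list(pi = pi_, mu = mu, sigma = sigma, loglik = ll,
                 n_iter = it, converged = converged),
            class = "gmm1d")
}

#' Analytic decision boundary of a two-component 1-D Gaussian mixture
#'
#' Solves pi1 * phi(x; mu1, s1) = pi2 * phi(x; mu2, s2), a quadratic in x,
#' and returns the root between the two component means. If no real root
#' lies between the means (possible with very unequal weights/variances), the
#' posterior-0.5 crossing is located by bisection on (mu1, mu2); if the
#' posterior does not cross 0.5 there either, an error is raised.
#'
#' @param fit A \code{gmm1d} object.
#' @return The boundary x*.
#' @export
gmm_boundary <- function(fit) {
  p <- fit$pi; mu <- fit$mu; s <- fit$sigma
  if (mu[1L] == mu[2L] && s[1L] == s[2L])
    stop("identical components have no decision boundary")
  # log pi1 - log s1 - (x-mu1)^2/(2 s1^2) = log pi2 - log s2 - (x-mu2)^2/(2 s2^2)
  a <- 1 / (2 * s[2L]^2) - 1 / (2 * s[1L]^2)
  b <- mu[1L] / s[1L]^2 - mu[2L] / s[2L]^2
  cc <- mu[2L]^2 / (2 * s[2L]^2) - mu[1L]^2 / (2 * s[1L]^2) +
    log(p[1L] / p[2L]) + log(s[2L] / s[1L])
  roots <- if (abs(a) < 1e-14 * (abs(b) + 1)) {
    if (b == 0) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  tol <- 1e-8 * (abs(mu[2L] - mu[1L]) + s[1L] + s[2L])
  inside <- roots[roots >= min(mu) - tol & roots <= max(mu) + tol]
  if (length(inside) >= 1L) {
    mid <- mean(mu)
    return(inside[which.min(abs(inside - mid))])
  }
  # fallback: posterior-0.5 crossing between the means
  post1 <- function(x) {
    d1 <- p[1L] * stats::dnorm(x, mu[1L], s[1L])
    d2 <- p[2L] * stats::dnorm(x, mu[2L], s[2L])
    d1 / (d1 + d2) - 0.5
  }
  lo <- min(mu); hi <- max(mu)
  if (sign(post1(lo)) == sign(post1(hi)))
    stop("no decision boundary between component means")
  stats::uniroot(post1, c(lo, hi), tol = 1e-12)$root
}

#' Posterior probability of the higher-mean component
#'
#' @param fit A \code{gmm1d} object.
#' @param x Values at which to evaluate.
#' @return Posterior probability of component 2 (the higher mean).
#' @export
gmm_posterior <- function(fit, x) {
  d1 <- fit$pi[1L] * stats::dnorm(x, fit$mu[1L], fit$sigma[1L])
  d2 <- fit$pi[2L] * stats::dnorm(x, fit$mu[2L], fit$sigma[2L])
  d2 / (d1 + d2)
}

#' Classify melanoma cell lines along the differentiation axis
#'
#' Fits the two-component mixture to the DiffAxis values, labels the
#' higher-mean component melanocytic-like, and assigns each line by posterior
#' component membership (ties at posterior 0.5 go to the higher-mean, i.e.
#' melanocytic-like, component). The analytic boundary is recorded as the
#' reporting threshold.
#'
#' @param profile Data frame from \code{\link{diff_axis}}.
#' @return List with \code{profile} (input plus \code{class} and
#'   \code{posterior_melanocytic} columns), \code{fit} (the \code{gmm1d}),
#'   and \code{boundary}.
#' @export
assign_classes <- function(profile) {
  fit <- fit_gmm_1d(profile$diff_axis)
  boundary <- gmm_boundary(fit)
  post <- gmm_posterior(fit, profile$diff_axis)
  profile$posterior_melanocytic <- post
  profile$class <- ifelse(post >= 0.5, "melanocytic_like",
                          "undifferentiated_ncl")
  list(profile = profile, fit = fit, boundary = boundary)
}
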