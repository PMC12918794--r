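#' Conditional down-sampling to cap the class ratio
#'
#' If the majority:minority ratio exceeds \code{ratio_cap}, sample
#' floor(ratio_cap * n_minority) majority members without replacement;
#' otherwise return all indices unchanged.
#'
#' @param labels Two-class vector (any type with exactly 2 levels present).
#' @param ratio_cap Maximum allowed majority/minority ratio (default 3).
#' @param seed Integer seed for the sampling.
#' @return Integer vector of retained indices (sorted).
#' @export
downsample_condition <- function(labels, ratio_cap = 3, seed = 1L) {
  tab <- table(labels)
  if (length(tab) != 2L || any(tab == 0L))
    stop("need exactly two nonempty classes")
  maj <- names(tab)[which.max(tab)]
  mino <- names(tab)[which.min(tab)]
  if (tab[maj] / tab[mino] <= ratio_cap) return(seq_along(labels))
  n_keep <- floor(ratio_cap * tab[[mino]])
  maj_idx <- which(labels == maj)
  old <- .Random.seed_save()
  set.seed(seed)
  keep_maj <- sample(maj_idx, n_keep)
  .Random.seed_restore(old)
  sort(c(which(labels == mino), keep_maj))
}

# Save/restore the RNG state so internal seeding never disturbs user streams.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fit a PLS1 model by NIPALS
#'
#' Univariate-response NIPALS with X and y deflation. Inputs are expected to
#' be preprocessed (features standardized, y centered); the fit itself is
#' deterministic. Weight vectors are unit norm; successive score vectors are
#' orthogonal.
#'
#' @param X n x p matrix (standardized features).
#' @param y Length-n centered numeric response (e.g. centered 0/1 labels).
#' @param k Number of latent variables.
#' @return List of class \code{pls1}: \code{W} (p x k weights), \code{P}
#'   (p x k X-loadings), \code{Q} (length-k y-loadings), \code{Tm} (n x k
#'   scores), \code{ssy} (y-variance explained per LV), \code{B} (length-p
#'   regression coefficient vector), \code{k}.
#' @export
fit_pls <- function(X, y, k) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("zero-variance feature in PLS input; drop upstream")
  k <- min(k, n - 1L, p)
  W <- matrix(0, p, k); P <- matrix(0, p, k); Q <- numeric(k)
  Tm <- matrix(0, n, k); ssy <- numeric(k)
  Xd <- X; yd <- y
  ss_tot <- sum(y^2)
  for (a in seq_len(k)) {
    w <- crossprod(Xd, yd)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { k <- a - 1L; break }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xd, t_)[, 1L] / tt
    q_ <- sum(yd * t_) / tt
    W[, a] <- w; P[, a] <- p_; Q[a] <- q_; Tm[, a] <- t_
    ssy[a] <- q_^2 * tt
    Xd <- Xd - t_ %*% t(p_)
    yd <- yd - t_ * q_
  }
  if (k == 0L) stop("no usable latent variable (X'y is zero)")
  W <- W[, seq_len(k), drop = FALSE]; P <- P[, seq_len(k), drop = FALSE]
  Q <- Q[seq_len(k)]; Tm <- Tm[, seq_len(k), drop = FALSE]
  ssy <- ssy[seq_len(k)]
  B <- W %*% solve(crossprod(P, W), Q)
  structure(list(W = W, P = P, Q = Q, Tm = Tm, ssy = ssy,
                 ssy_frac = ssy / ss_tot, B = as.numeric(B), k = k,
                 features = colnames(X)),
            class = "pls1")
}

#' Continuous PLS decision scores for new data
#'
#' @param model A \code{pls1} fit.
#' @param Xnew Matrix preprocessed identically to the training X.
#' @return Numeric vector of decision scores.
#' @export
predict_pls <- function(model, Xnew) {
  as.numeric(as.matrix(Xnew) %*% model$B)
}

#' Rank-based ROC AUC
#'
#' Probability that a randomly chosen positive scores above a randomly chosen
#' negative (ties count 1/2); invariant to strictly monotone transforms of
#' the scores.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical or 0/1; TRUE/1 = positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin to folds.
stratified_folds <- function(labels, folds, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Select the number of latent variables by stratified cross-validated AUC
#'
#' For each candidate k, fits PLS on the training folds (standardization
#' statistics computed on the training folds only) and scores the held-out
#' fold; the mean AUC over folds is the selection criterion. The smallest k
#' within 1e-12 of the maximum mean AUC is chosen.
#'
#' @param X n x p raw (unstandardized) feature matrix.
#' @param y 0/1 labels.
#' @param k_grid Candidate LV counts.
#' @param folds Number of folds (each class must have >= folds members).
#' @param seed Seed for the fold assignment.
#' @return List with \code{k} (chosen), \code{mean_auc}, \code{sd_auc} (per
#'   candidate), \code{fold_auc} (folds x candidates matrix).
#' @export
cv_select_k <- function(X, y, k_grid = 1:5, folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stop("need exactly two classes")
  if (min(table(y)) < folds) stop("smallest class has fewer members than folds")
  fold_id <- stratified_folds(y, folds, seed)
  k_grid <- k_grid[k_grid <= min(nrow(X) - ceiling(nrow(X) / folds) - 1L,
                                 ncol(X))]
  if (length(k_grid) == 0L) k_grid <- 1L
  fold_auc <- matrix(NA_real_, folds, length(k_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    keep <- sd_ > 0
    Xtr <- scale(X[tr, keep, drop = FALSE], mu[keep], sd_[keep])
    Xte <- scale(X[te, keep, drop = FALSE], mu[keep], sd_[keep])
    ytr <- y[tr] - mean(y[tr])
    for (ki in seq_along(k_grid)) {
      fit <- fit_pls(Xtr, ytr, k_grid[ki])
      fold_auc[f, ki] <- roc_auc(predict_pls(fit, Xte), y[te] == 1L)
    }
  }
  mean_auc <- colMeans(fold_auc)
  best <- which(mean_auc >= max(mean_auc) - 1e-12)[1L]
  list(k = k_grid[best], k_grid = k_grid, mean_auc = mean_auc,
       sd_auc = apply(fold_auc, 2L, stats::sd), fold_auc = fold_auc)
}

#' Variable importance in projection
#'
#' VIP_j = sqrt(p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a) over the
#' first \code{n_lv} latent variables, where SSY_a is the y-variance
#' explained by LV a. The mean of VIP^2 over features equals 1 for any model.
#'
#' @param model A \code{pls1} fit.
#' @param n_lv Number of latent variables used (default 2, capped at the
#'   model's k).
#' @return Numeric vector of VIP scores (one per feature).
#' @export
vip <- function(model, n_lv = 2L) {
  a <- seq_len(min(n_lv, model$k))
  W <- model$W[, a, drop = FALSE]
  ssy <- model$ssy[a]
  Wn2 <- sweep(W^2, 2L, colSums(W^2), "/")
  v <- sqrt(nrow(W) * as.numeric(Wn2 %*% ssy) / sum(ssy))
  names(v) <- model$features
  v
}

# Ridge-penalized logistic regression by Newton-Raphson (small fixed penalty
# so coefficients exist under complete separation). Intercept unpenalized.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 200L, tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wts <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(X1, y - mu) - pen %*% beta
    H <- crossprod(X1 * wts, X1) + pen
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  if (max(abs(step)) >= 1e-4)
    stop("logistic sign fit did not converge")
  beta[-1L]
}

#' Assign directionality to VIP scores
#'
#' The sign of each feature's VIP is the sign of its coefficient in a
#' ridge-penalized logistic regression of the class labels on the same
#' standardized matrix used for the PLS fit (small fixed L2 penalty so the
#' fit exists under complete separation). Positive signed VIP = association
#' with the class coded 1.
#'
#' @param vip_scores Numeric vector from \code{\link{vip}}.
#' @param X Standardized feature matrix (as used in the PLS fit).
#' @param y 0/1 labels.
#' @param lambda Ridge penalty (default 1e-3).
#' @return Numeric vector of signed VIP scores.
#' @export
sign_vip <- function(vip_scores, X, y, lambda = 1e-3) {
  beta <- ridge_logistic(as.matrix(X), as.integer(y), lambda = lambda)
  s <- sign(beta)
  s[s == 0] <- 1
  vip_scores * s
}

#' Full PLS-DA procedure with down-sampling iterations
#'
#' Per iteration (derived seed): conditionally down-sample the majority class
#' to at most a 3:1 ratio; drop zero-variance features and standardize on the
#' retained lines only; select the number of latent variables by 5-fold
#' stratified cross-validated AUC; refit on all retained lines; compute VIP
#' on min(2, chosen k) LVs; sign by ridge logistic regression. Signed VIP is
#' aggregated across iterations by mean (sd and the frequency of passing the
#' stringent cutoff are also reported); features dropped in some iterations
#' contribute only to the iterations where they appear.
#'
#' @param X Cell lines x features dependency matrix (raw).
#' @param y 0/1 class labels (1 = melanocytic-like by convention).
#' @param config A \code{\link{chromdep_config}}.
#' @param k_grid Candidate LV counts for CV selection.
#' @param folds CV folds.
#' @return List with \code{vip_table} (feature, mean_signed_vip, sd_signed_vip,
#'   freq_selected, n_iterations), \code{auc} (per-iteration CV AUC of the
#'   chosen k), \code{mean_auc}, \code{sd_auc}, \code{chosen_k} per iteration.
#' @export
run_plsda_iterations <- function(X, y, config = chromdep_config(),
                                 k_grid = 1:5, folds = 5L) {
  y <- as.integer(y)
  n_iter <- config$n_plsda_iterations
  feats <- colnames(X)
  acc <- matrix(NA_real_, n_iter, ncol(X), dimnames = list(NULL, feats))
  auc_it <- numeric(n_iter); k_it <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    s <- stage_seed(config$rng_seed, paste0("plsda_iter_", i))
    idx <- downsample_condition(y, config$class_ratio_cap, seed = s)
    Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
    sd_ <- apply(Xi, 2L, stats::sd)
    keep <- sd_ > 0
    Xs <- scale(Xi[, keep, drop = FALSE])
    cv <- cv_select_k(Xi[, keep, drop = FALSE], yi, k_grid = k_grid,
                      folds = folds, seed = s)
    k_it[i] <- cv$k
    auc_it[i] <- cv$mean_auc[match(cv$k, cv$k_grid)]
    fit <- fit_pls(Xs, yi - mean(yi), cv$k)
    v <- vip(fit, n_lv = 2L)
    sv <- sign_vip(v, Xs, yi)
    acc[i, names(sv)] <- sv
  }
  n_obs <- colSums(!is.na(acc))
  mean_sv <- colMeans(acc, na.rm = TRUE)
  sd_sv <- apply(acc, 2L, stats::sd, na.rm = TRUE)
  freq <- colMeans(abs(acc) >= config$vip_cutoff, na.rm = TRUE)
  vip_table <- data.frame(feature = feats,
                          mean_signed_vip = mean_sv,
                          sd_signed_vip = sd_sv,
                          freq_selected = freq,
                          n_iterations = n_obs,
                          stringsAsFactors = FALSE, row.names = NULL)
  vip_table$state_associated <- abs(vip_table$mean_signed_vip) >=
    config$vip_cutoff
  vip_table$state_associated_permissive <- abs(vip_table$mean_signed_vip) >=
    config$vip_cutoff_permissive
  list(vip_table = vip_table, auc = auc_it, mean_auc = mean(auc_it),
       sd_auc = stats::sd(auc_it), chosen_k = k_it)
}
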