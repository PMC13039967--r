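#' Per-feature one-way ANOVA across metabotypes
#'
#' Classical one-way fixed-effects ANOVA for every feature (column):
#' `F = MSB / MSW` with p from the F distribution on (g - 1, n - g)
#' degrees of freedom. Features with zero between- and within-group
#' variance get F = 0, p = 1; zero within-group variance with real group
#' differences gives p = 0.
#'
#' @param x Numeric matrix, samples x features (log scale).
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @return Data frame: `feature_id`, per-group means, `F`, `p`.
#' @export
anova_per_feature <- function(x, groups) {
  x <- as.matrix(x)
  g <- factor(groups)
  stopifnot(nrow(x) == length(g))
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  ng <- table(g)
  if (any(ng < 2)) stop("every group needs >= 2 samples")
  n <- nrow(x)
  k <- nlevels(g)
  grand <- colMeans(x)
  means <- rowsum(x, g) / as.vector(ng)
  ssb <- colSums(means^2 * as.vector(ng)) - n * grand^2
  sst <- colSums(x^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  null_feat <- ssw < 1e-12 & ssb < 1e-12
  f[null_feat] <- 0
  p[null_feat] <- 1
  degenerate <- ssw < 1e-12 & ssb >= 1e-12
  f[degenerate] <- Inf
  p[degenerate] <- 0
  out <- data.frame(feature_id = colnames(x) %||%
                      as.character(seq_len(ncol(x))),
                    F = f, p = p, row.names = NULL)
  for (lev in levels(g)) out[[paste0("mean_", lev)]] <- means[lev, ]
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) m p_(j) / j`, mapped back
#' to input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) stop("empty input")
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Tukey-Kramer honest significant difference post-hoc test
#'
#' For every group pair, the studentized-range statistic
#' `q = |m_i - m_j| / sqrt(MSW / 2 * (1/n_i + 1/n_j))` with adjusted p
#' from the studentized-range distribution with k groups and n - g
#' degrees of freedom.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return Data frame: `group_a`, `group_b`, `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  g <- factor(groups)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  ng <- table(g)
  if (any(ng < 2)) stop("every group needs >= 2 samples")
  n <- length(values)
  k <- nlevels(g)
  means <- tapply(values, g, mean)
  msw <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / (n - k)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    d <- means[pr[2]] - means[pr[1]]
    if (msw == 0) stop("zero within-group variance")
    se <- sqrt(msw / 2 * (1 / ng[pr[1]] + 1 / ng[pr[2]]))
    q <- abs(d) / se
    data.frame(group_a = pr[1], group_b = pr[2], diff = unname(d),
               q = unname(q),
               p_adj = stats::ptukey(unname(q), k, n - k,
                                     lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Full differential pipeline for one feature matrix
#'
#' ANOVA per feature, BH adjustment, and Tukey post-hoc tests restricted
#' to features significant at `fdr`.
#'
#' @param x Numeric matrix, samples x features (log scale).
#' @param groups Group labels per sample.
#' @param fdr FDR threshold gating the post-hoc stage (default 0.05).
#' @return List with `result` (ANOVA table + `q`) and `tukey` (long data
#'   frame over significant features).
#' @export
differential_analysis <- function(x, groups, fdr = 0.05) {
  res <- anova_per_feature(x, groups)
  res$q <- bh_fdr(res$p)
  sig <- res$feature_id[res$q < fdr]
  tk <- lapply(sig, function(f) {
    cbind(feature_id = f, tukey_hsd(x[, f], groups))
  })
  list(result = res,
       tukey = if (length(tk)) do.call(rbind, tk) else NULL)
}

#' PLS-DA scores
#'
#' Partial least squares discriminant analysis: PLS regression of the
#' feature matrix on the one-hot class matrix with iterative
#' latent-variable extraction and deflation; successive X-scores are
#' mutually orthogonal. Constant columns are dropped with a warning.
#'
#' @param x Numeric matrix, samples x features.
#' @param labels Class labels (>= 2 classes).
#' @param n_comp Number of components (default 2).
#' @return List with `scores` (samples x n_comp), `loadings`,
#'   `explained_variance` (fraction of X variance per component).
#' @export
plsda_scores <- function(x, labels, n_comp = 2) {
  x <- as.matrix(x)
  g <- factor(labels)
  if (nlevels(g) < 2) stop("at least 2 classes are required")
  sds <- col_sds(x)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant column(s) dropped")
    x <- x[, sds > 0, drop = FALSE]
  }
  fit <- mixOmics::plsda(x, g, ncomp = n_comp, scale = TRUE)
  list(scores = fit$variates$X,
       loadings = fit$loadings$X,
       explained_variance = fit$prop_expl_var$X)
}

#' Spearman screening of features against fibrosis stage
#'
#' The histologic fibrosis stage (0-4) is square-root transformed (the
#' transform addresses zeros and skew; Spearman's rho itself is invariant
#' to it), then each feature's Spearman rank correlation with the
#' transformed stage is computed with average ranks for ties and a
#' two-sided p from the t approximation with n - 2 degrees of freedom.
#'
#' @param x Numeric matrix, samples x features.
#' @param fibrosis_stage Integer vector in 0..4 (not all equal).
#' @param top Number of top features to mark in `rank` (default 20).
#' @return Data frame sorted by p: `feature_id`, `rho`, `p`, `rank`.
#' @export
spearman_fibrosis <- function(x, fibrosis_stage, top = 20) {
  x <- as.matrix(x)
  stopifnot(all(fibrosis_stage %in% 0:4))
  if (length(unique(fibrosis_stage)) < 2) {
    stop("fibrosis stage is constant")
  }
  y <- sqrt(fibrosis_stage)
  n <- nrow(x)
  ry <- rank(y)
  rx <- apply(x, 2, rank)
  rho <- suppressWarnings(as.vector(stats::cor(rx, ry)))
  rho[is.na(rho)] <- 0
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(rho) >= 1] <- 0
  out <- data.frame(feature_id = colnames(x) %||%
                      as.character(seq_len(ncol(x))),
                    rho = rho, p = p, row.names = NULL)
  out <- out[order(out$p, -abs(out$rho)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top
  rownames(out) <- NULL
  out
}
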