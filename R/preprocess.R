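#' Summarize technical replicates and check replicability
#'
#' Computes all pairwise Pearson correlations between the replicate
#' intensity vectors of each sample; samples whose median pairwise r is at
#' or below `min_r` (or undefined because a replicate has zero variance)
#' are flagged. Each sample's intensities are then collapsed to the
#' per-feature median across replicates.
#'
#' @param table A `feature_table` with replicate structure.
#' @param min_r Replicability threshold (samples kept need median r >
#'   `min_r`; default 0.7).
#' @return List with `table` (one row per sample) and `qc` (data frame:
#'   `sample`, `median_r`, `flagged`).
#' @export
summarize_triplicates <- function(table, min_r = 0.7) {
  stopifnot(inherits(table, "feature_table"))
  samples <- unique(table$injection_map$sample)
  med_r <- rep(NA_real_, length(samples))
  names(med_r) <- samples
  summarized <- matrix(0, length(samples), ncol(table$intensities),
                       dimnames = list(samples,
                                       colnames(table$intensities)))
  for (i in seq_along(samples)) {
    rows <- table$injection_map$sample == samples[i]
    m <- table$intensities[rows, , drop = FALSE]
    if (nrow(m) == 1) {
      med_r[i] <- 1
      summarized[i, ] <- m[1, ]
      next
    }
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      # identical replicates correlate perfectly; a flat-lined replicate is
      # undefined and flags the sample
      med_r[i] <- if (all(sds == 0) &&
                        all(apply(m, 2, function(z) length(unique(z)) == 1)))
        1 else NA_real_
    } else {
      cc <- stats::cor(t(m))
      med_r[i] <- stats::median(cc[lower.tri(cc)])
    }
    summarized[i, ] <- apply(m, 2, stats::median)
  }
  flagged <- is.na(med_r) | med_r <= min_r
  out <- feature_table(
    mode = table$mode, features = table$features,
    intensities = summarized,
    injection_map = data.frame(injection = samples, sample = samples,
                               replicate = 1L, stringsAsFactors = FALSE),
    batch_map = table$batch_map)
  list(table = out,
       qc = data.frame(sample = samples, median_r = unname(med_r),
                       flagged = unname(flagged)))
}

#' Filter features by technical coefficient of variation
#'
#' Per feature, the CV (SD / mean) of raw intensities across technical
#' replicates is computed within each sample and median-aggregated across
#' samples; features are kept iff the median CV is strictly below
#' `max_cv`. Features with an undefined CV (zero mean) are dropped and
#' recorded.
#'
#' @param table A `feature_table` with replicate structure.
#' @param max_cv CV cutoff (default 0.75; strict `<`).
#' @return List with `table` (surviving features) and `qc` (data frame:
#'   `feature_id`, `median_cv`, `dropped`, `reason`).
#' @export
filter_by_cv <- function(table, max_cv = 0.75) {
  stopifnot(inherits(table, "feature_table"))
  samples <- unique(table$injection_map$sample)
  cvs <- matrix(NA_real_, length(samples), ncol(table$intensities))
  for (i in seq_along(samples)) {
    rows <- table$injection_map$sample == samples[i]
    m <- table$intensities[rows, , drop = FALSE]
    mu <- colMeans(m)
    s <- apply(m, 2, stats::sd)
    cvs[i, ] <- ifelse(mu == 0, NA_real_, s / mu)
  }
  med_cv <- apply(cvs, 2, function(z) {
    if (all(is.na(z))) NA_real_ else stats::median(z, na.rm = TRUE)
  })
  undefined <- is.na(med_cv)
  keep <- !undefined & med_cv < max_cv
  qc <- data.frame(feature_id = table$features$feature_id,
                   median_cv = med_cv, dropped = !keep,
                   reason = ifelse(undefined, "undefined_cv",
                                   ifelse(keep, "", "cv_above_threshold")))
  out <- feature_table(
    mode = table$mode,
    features = table$features[keep, , drop = FALSE],
    intensities = table$intensities[, keep, drop = FALSE],
    injection_map = table$injection_map, batch_map = table$batch_map)
  list(table = out, qc = qc)
}

#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric empirical-Bayes batch correction of a log-scale matrix: each
#' feature is standardized by its grand mean and pooled SD; per-batch
#' location (gamma) and scale (delta^2) parameters are estimated and shrunk
#' toward their across-feature moments (normal prior on gamma,
#' inverse-gamma on delta^2, method-of-moments hyperparameters); values are
#' adjusted to remove batch location and scale and back-transformed. Each
#' feature's grand mean is preserved exactly.
#'
#' @param x Numeric matrix, samples x features, log scale.
#' @param batches Batch label per sample (>= 2 batches, each >= 2 samples).
#' @param shrink Apply empirical-Bayes shrinkage (default `TRUE`). With
#'   `FALSE` the raw per-batch estimates are removed exactly (the
#'   no-shrinkage limit): per-feature per-batch means then agree to
#'   numerical precision, whereas shrinkage leaves residuals of the order
#'   of the prior pull.
#' @return Adjusted matrix of the same shape.
#' @export
adjust_batch_effects <- function(x, batches, shrink = TRUE) {
  x <- as.matrix(x)
  batches <- as.character(batches)
  stopifnot(nrow(x) == length(batches))
  tab <- table(batches)
  if (length(tab) < 2) stop("at least 2 batches are required")
  if (any(tab < 2)) {
    stop("batch with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  n <- nrow(x)
  p <- ncol(x)
  grand <- colMeans(x)
  # pooled within-batch SD per feature
  lv <- unique(batches)
  within_ss <- matrix(0, length(lv), p)
  bmeans <- matrix(0, length(lv), p)
  for (i in seq_along(lv)) {
    xi <- x[batches == lv[i], , drop = FALSE]
    bmeans[i, ] <- colMeans(xi)
    within_ss[i, ] <- colSums(sweep(xi, 2, bmeans[i, ])^2)
  }
  pooled_sd <- sqrt(colSums(within_ss) / (n - length(lv)))
  pooled_sd[pooled_sd == 0] <- 1
  z <- sweep(sweep(x, 2, grand), 2, pooled_sd, "/")

  z_adj <- z
  for (i in seq_along(lv)) {
    idx <- batches == lv[i]
    ni <- sum(idx)
    zi <- z[idx, , drop = FALSE]
    gamma_hat <- colMeans(zi)
    delta2_hat <- apply(zi, 2, stats::var)
    if (!shrink) {
      delta2_hat[delta2_hat == 0] <- 1
      z_adj[idx, ] <- sweep(sweep(zi, 2, gamma_hat), 2,
                            sqrt(delta2_hat), "/")
      next
    }
    # EB moments across features
    g_bar <- mean(gamma_hat)
    t2 <- stats::var(gamma_hat)
    d_bar <- mean(delta2_hat)
    s2 <- stats::var(delta2_hat)
    # inverse-gamma moment estimates
    lambda <- if (s2 > 0) (2 * s2 + d_bar^2) / s2 else Inf
    theta <- if (is.finite(lambda)) d_bar * (lambda - 1) else d_bar
    gamma_star <- if (t2 > 0) {
      (ni * t2 * gamma_hat + delta2_hat * g_bar) / (ni * t2 + delta2_hat)
    } else {
      rep(g_bar, p)
    }
    delta2_star <- if (is.finite(lambda)) {
      (theta + 0.5 * (ni - 1) * delta2_hat) / (lambda + (ni - 1) / 2 - 1)
    } else {
      rep(d_bar, p)
    }
    delta2_star[delta2_star <= 0] <- d_bar
    z_adj[idx, ] <- sweep(sweep(zi, 2, gamma_star), 2,
                          sqrt(delta2_star), "/")
  }
  out <- sweep(sweep(z_adj, 2, pooled_sd, "*"), 2, grand, "+")
  # pin each feature's grand mean exactly (shrinkage leaves a tiny drift)
  sweep(out, 2, colMeans(out) - grand)
}

#' Match features between two tables by mass and retention time
#'
#' Candidate pairs must satisfy both an inclusive ppm tolerance (computed
#' against the mean of the two masses) and an inclusive RT tolerance.
#' Pairs are accepted greedily by ascending ppm difference (RT difference
#' breaks ties), each source feature participating in at most one match.
#' Unmatched features are excluded from the merged table.
#'
#' @param a,b `feature_table` objects of the same mode.
#' @param ppm_tol Mass tolerance in ppm (default 5, inclusive).
#' @param rt_tol Retention-time tolerance in seconds (default 30,
#'   inclusive).
#' @return An object of class `merged_feature_table`: list with `mode`,
#'   `features` (merged_id, consensus mz = mean of sources, consensus rt,
#'   per-source mz/rt), `intensities` (samples of both sources x matched
#'   features), `batch_map`, `provenance` (merged_id -> source ids).
#' @export
match_features <- function(a, b, ppm_tol = 5, rt_tol = 30) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  if (!identical(a$mode, b$mode)) stop("mode mismatch")
  fa <- a$features
  fb <- b$features
  # candidate pairs within both tolerances
  cand <- NULL
  ord_b <- order(fb$mz)
  mzb <- fb$mz[ord_b]
  for (i in seq_len(nrow(fa))) {
    wdw <- fa$mz[i] * ppm_tol * 1e-6 / (1 - ppm_tol * 5e-7)
    lo <- findInterval(fa$mz[i] - wdw - 1e-9, mzb) + 1
    hi <- findInterval(fa$mz[i] + wdw + 1e-9, mzb)
    if (hi < lo) next
    j <- ord_b[lo:hi]
    ppm <- abs(fa$mz[i] - fb$mz[j]) / ((fa$mz[i] + fb$mz[j]) / 2) * 1e6
    drt <- abs(fa$rt[i] - fb$rt[j])
    ok <- ppm <= ppm_tol & drt <= rt_tol
    if (any(ok)) {
      cand <- rbind(cand, data.frame(i = i, j = j[ok], ppm = ppm[ok],
                                     drt = drt[ok]))
    }
  }
  pairs <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$ppm, cand$drt), , drop = FALSE]
    used_i <- logical(nrow(fa))
    used_j <- logical(nrow(fb))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!used_i[cand$i[r]] && !used_j[cand$j[r]]) {
        keep[r] <- TRUE
        used_i[cand$i[r]] <- TRUE
        used_j[cand$j[r]] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
    pairs <- pairs[order(pairs$i), , drop = FALSE]
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    feats <- data.frame(merged_id = character(0), mz = numeric(0),
                        rt = numeric(0))
    ints <- matrix(0, 0, 0)
    prov <- list()
  } else {
    ids_a <- fa$feature_id[pairs$i]
    ids_b <- fb$feature_id[pairs$j]
    feats <- data.frame(
      merged_id = ids_a,
      mz = (fa$mz[pairs$i] + fb$mz[pairs$j]) / 2,
      rt = (fa$rt[pairs$i] + fb$rt[pairs$j]) / 2,
      mz_a = fa$mz[pairs$i], mz_b = fb$mz[pairs$j],
      rt_a = fa$rt[pairs$i], rt_b = fb$rt[pairs$j],
      ppm = pairs$ppm, stringsAsFactors = FALSE)
    ints <- rbind(a$intensities[, ids_a, drop = FALSE],
                  b$intensities[, ids_b, drop = FALSE])
    colnames(ints) <- ids_a
    prov <- stats::setNames(mapply(c, ids_a, ids_b, SIMPLIFY = FALSE),
                            ids_a)
  }
  structure(list(mode = a$mode, features = feats, intensities = ints,
                 batch_map = rbind(a$batch_map, b$batch_map),
                 provenance = prov),
            class = "merged_feature_table")
}

#' @export
print.merged_feature_table <- function(x, ...) {
  cat("<merged_feature_table> mode:", x$mode, "|", nrow(x$features),
      "matched features x", nrow(x$intensities), "samples\n")
  invisible(x)
}

# sequentially match/merge a list of same-mode feature tables
merge_feature_tables <- function(tables, ppm_tol = 5, rt_tol = 30) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1) {
    t1 <- tables[[1]]
    return(structure(list(
      mode = t1$mode,
      features = data.frame(merged_id = t1$features$feature_id,
                            mz = t1$features$mz, rt = t1$features$rt,
                            stringsAsFactors = FALSE),
      intensities = t1$intensities,
      batch_map = t1$batch_map,
      provenance = stats::setNames(as.list(t1$features$feature_id),
                                   t1$features$feature_id)),
      class = "merged_feature_table"))
  }
  acc <- tables[[1]]
  prov_acc <- NULL
  for (i in 2:length(tables)) {
    merged <- match_features(acc, tables[[i]], ppm_tol, rt_tol)
    prov_acc <- if (is.null(prov_acc)) {
      merged$provenance
    } else {
      lapply(merged$provenance, function(ids) {
        unique(c(unlist(prov_acc[ids[1]]), ids[2]))
      })
    }
    acc <- feature_table(
      mode = merged$mode,
      features = data.frame(feature_id = merged$features$merged_id,
                            mz = merged$features$mz,
                            rt = merged$features$rt,
                            stringsAsFactors = FALSE),
      intensities = merged$intensities,
      injection_map = data.frame(
        injection = rownames(merged$intensities),
        sample = rownames(merged$intensities), replicate = 1L,
        stringsAsFactors = FALSE),
      batch_map = merged$batch_map)
  }
  structure(list(mode = acc$mode,
                 features = data.frame(merged_id = acc$features$feature_id,
                                       mz = acc$features$mz,
                                       rt = acc$features$rt,
                                       stringsAsFactors = FALSE),
                 intensities = acc$intensities,
                 batch_map = acc$batch_map,
                 provenance = prov_acc),
            class = "merged_feature_table")
}

#' Quantile normalization
#'
#' Classical quantile normalization across samples: within each sample,
#' values are replaced by the across-sample mean of the values at the same
#' rank; ties receive the mean of their rank-range targets. Afterwards all
#' samples share an identical sorted vector.
#'
#' @param x Numeric matrix, samples x features (no missing values).
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0) stop("empty matrix")
  if (anyNA(x)) stop("missing values are not allowed")
  # limma normalizes columns; our samples are rows
  t(limma::normalizeQuantiles(t(x), ties = TRUE))
}

#' Log2 transform with half-minimum zero replacement
#'
#' Zeros are replaced per feature by half the smallest positive value of
#' that feature, then log2 is applied. Features that are entirely zero are
#' dropped with a warning.
#'
#' @param x Numeric matrix, samples x features, non-negative.
#' @return Log2 matrix (possibly fewer columns).
#' @export
log2_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative intensities")
  all_zero <- apply(x, 2, function(z) all(z == 0))
  if (any(all_zero)) {
    warning(sum(all_zero), " feature(s) entirely zero; dropped")
    x <- x[, !all_zero, drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    z <- x[, j]
    if (any(z == 0)) {
      x[z == 0, j] <- min(z[z > 0]) / 2
    }
  }
  log2(x)
}

#' Hotelling T-squared multivariate outlier screen
#'
#' PCA (SVD of the column-centered matrix) followed by the per-sample
#' Hotelling statistic over the first `n_pcs` components,
#' `T2 = sum_h t_h^2 / lambda_h`, against the F-based control limit
#' `n_pcs (n - 1) / (n - n_pcs) * F_conf(n_pcs, n - n_pcs)`. Samples above
#' the limit are flagged.
#'
#' @param x Numeric matrix, samples x features.
#' @param n_pcs Number of principal components (default 5).
#' @param conf Confidence level for the control limit (default 0.99).
#' @return List with `t2` (per sample), `limit`, `flagged` (sample names
#'   or indices), `scores`, `explained_variance`.
#' @export
hotelling_outliers <- function(x, n_pcs = 5, conf = 0.99) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= n_pcs + 1) stop("need more samples than n_pcs + 1")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = n_pcs, nv = 0)
  if (sum(sv$d > 1e-10) < n_pcs) stop("matrix rank below n_pcs")
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  # fix component signs: largest-magnitude score positive
  for (h in seq_len(n_pcs)) {
    if (scores[which.max(abs(scores[, h])), h] < 0) {
      scores[, h] <- -scores[, h]
    }
  }
  lambda <- sv$d[seq_len(n_pcs)]^2 / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  limit <- n_pcs * (n - 1) / (n - n_pcs) *
    stats::qf(conf, n_pcs, n - n_pcs)
  flagged <- if (!is.null(rownames(x))) rownames(x)[t2 > limit] else
    which(t2 > limit)
  list(t2 = stats::setNames(t2, rownames(x)), limit = limit,
       flagged = flagged, scores = scores,
       explained_variance = sv$d^2 / sum(sv$d^2))
}
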