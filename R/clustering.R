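#' Derive VLDL cholesterol from triglycerides
#'
#' VLDL cholesterol is estimated as triglycerides divided by five
#' (both in mg/dL).
#'
#' @param tg Triglycerides, mg/dL (non-negative).
#' @return VLDL, mg/dL.
#' @export
#' @examples
#' derive_vldl(110)  # 22
derive_vldl <- function(tg) {
  if (any(tg < 0, na.rm = TRUE)) stop("triglycerides must be non-negative")
  tg / 5
}

#' Median-impute missing clustering variables
#'
#' Replaces every missing cell of the ten clustering variables with that
#' variable's cohort median computed over observed values only. Categorical
#' and profiling variables are untouched.
#'
#' @param table Clinical data frame.
#' @param variables Columns to impute (default [clustering_variables()]).
#' @return The table with missing clustering cells imputed.
#' @export
impute_median <- function(table, variables = clustering_variables()) {
  variables <- intersect(variables, names(table))
  for (v in variables) {
    x <- table[[v]]
    if (all(is.na(x))) stop("column ", v, " is fully missing")
    x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    table[[v]] <- x
  }
  table
}

#' Exclude subjects with extreme clinical values
#'
#' A subject is excluded iff any clustering variable lies strictly more
#' than `threshold_sd` standard deviations from that variable's mean, both
#' computed once on the post-imputation table (single pass, not iterated).
#' Zero-variance variables are flagged and skipped.
#'
#' @param table Clinical data frame (imputed).
#' @param threshold_sd SD multiple defining "extreme" (default 5).
#' @param variables Columns screened (default [clustering_variables()]).
#' @return List with `table` (survivors, unchanged rows), `excluded`
#'   (subject ids) and `skipped_variables` (zero variance).
#' @export
exclude_extreme <- function(table, threshold_sd = 5,
                            variables = clustering_variables()) {
  if (nrow(table) < 3) stop("at least 3 subjects are required")
  variables <- intersect(variables, names(table))
  bad <- rep(FALSE, nrow(table))
  skipped <- character(0)
  for (v in variables) {
    x <- table[[v]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      skipped <- c(skipped, v)
      next
    }
    m <- mean(x, na.rm = TRUE)
    bad <- bad | (!is.na(x) & abs(x - m) > threshold_sd * s)
  }
  list(table = table[!bad, , drop = FALSE],
       excluded = table$subject_id[bad],
       skipped_variables = skipped)
}

#' Z-score scale a numeric matrix
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (denominator n - 1).
#'
#' @param x Numeric matrix or data frame of numeric columns.
#' @return List with `matrix` (scaled) and `scaling_params` (data frame of
#'   per-column `mean` and `sd`).
#' @export
zscore_scale <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  mu <- colMeans(x)
  sds <- col_sds(x)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  list(matrix = scale(x, center = mu, scale = sds)[, , drop = FALSE],
       scaling_params = data.frame(variable = colnames(x), mean = mu,
                                   sd = sds, row.names = NULL))
}

# squared Euclidean distances between rows of x and rows of centers
dist_to_centers <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * x %*% t(centers)
  pmax(d2, 0)
}

# k-means++ initial centers (deterministic given the RNG state)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- dist_to_centers(x, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx <- sample.int(n, 1)
      } else {
        idx <- sample.int(n, 1, prob = d2 / sum(d2))
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, dist_to_centers(x, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

lloyd <- function(x, centers, max_iter) {
  k <- nrow(centers)
  assign_old <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- dist_to_centers(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed from the point farthest from its center
    for (j in which(tabulate(assign_new, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign_new)])
      assign_new[far] <- j
      d2[far, ] <- Inf
    }
    if (identical(assign_new, assign_old)) break
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
    }
    assign_old <- assign_new
  }
  d2 <- dist_to_centers(x, centers)
  assignments <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_along(assignments), assignments)])
  list(centers = centers, assignments = assignments, wss = wss)
}

#' K-means clustering with k-means++ restarts
#'
#' Lloyd iterations from `n_start` k-means++ initializations; the restart
#' with the lowest within-cluster sum of squares is kept. Nearest-centroid
#' ties break toward the lowest cluster index; empty clusters are repaired
#' by reseeding from the farthest point. Deterministic given `seed`.
#'
#' @param x Numeric matrix (rows = observations, typically z-scaled).
#' @param k Number of clusters.
#' @param n_start Number of restarts (default 25).
#' @param max_iter Maximum Lloyd iterations per restart (default 1000).
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @return An object of class `cluster_model`: list with `k`, `centroids`,
#'   `assignments`, `wss`, `mean_silhouette` (`NA` for k = 1),
#'   `restart_wss`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 5), 20))
#' fit_kmeans(x, k = 2, seed = 1)$k
fit_kmeans <- function(x, k, n_start = 25, max_iter = 1000, seed = NULL) {
  x <- as.matrix(x)
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(x)) stop("k cannot exceed the number of rows")
  if (nrow(x) == 0) stop("empty input")
  with_seed(seed, {
    best <- NULL
    restart_wss <- numeric(n_start)
    for (s in seq_len(n_start)) {
      fit <- lloyd(x, kmeanspp_init(x, k), max_iter)
      restart_wss[s] <- fit$wss
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
    ms <- if (k >= 2 && length(unique(best$assignments)) >= 2) {
      silhouette_widths(x, best$assignments)$mean
    } else {
      NA_real_
    }
    structure(list(k = k, centroids = best$centers,
                   assignments = best$assignments, wss = best$wss,
                   mean_silhouette = ms, restart_wss = restart_wss),
              class = "cluster_model")
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k =", x$k, "| WSS =", signif(x$wss, 6),
      "| mean silhouette =", signif(x$mean_silhouette, 4), "\n")
  cat("sizes:", tabulate(x$assignments, x$k), "\n")
  invisible(x)
}

#' Silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean Euclidean
#' distance to the point's own cluster (excluding itself) and `b` the
#' smallest mean distance to any other cluster. Points in singleton
#' clusters get `s = 0`.
#'
#' @param x Numeric matrix.
#' @param assignments Integer cluster labels (>= 2 non-empty clusters).
#' @return List with `widths` (per point) and `mean`.
#' @export
silhouette_widths <- function(x, assignments) {
  x <- as.matrix(x)
  cl <- unique(assignments)
  if (length(cl) < 2) stop("silhouette requires at least 2 clusters")
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  sizes <- table(factor(assignments, levels = sort(cl)))
  # mean distance from each point to each cluster
  md <- vapply(sort(cl), function(j) {
    rowSums(d[, assignments == j, drop = FALSE]) / sum(assignments == j)
  }, numeric(n))
  colnames(md) <- sort(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- as.character(assignments[i])
    ni <- sizes[[own]]
    if (ni == 1) {
      s[i] <- 0
      next
    }
    a <- md[i, own] * ni / (ni - 1)  # exclude self
    b <- min(md[i, setdiff(colnames(md), own)])
    s[i] <- (b - a) / max(a, b)
  }
  list(widths = s, mean = mean(s))
}

# ---- internal validity indices -------------------------------------------

calinski_harabasz <- function(x, fit) {
  n <- nrow(x)
  k <- fit$k
  grand <- colMeans(x)
  ssb <- sum(vapply(seq_len(k), function(j) {
    nj <- sum(fit$assignments == j)
    nj * sum((fit$centroids[j, ] - grand)^2)
  }, numeric(1)))
  (ssb / (k - 1)) / (fit$wss / (n - k))
}

davies_bouldin <- function(x, fit) {
  k <- fit$k
  s <- vapply(seq_len(k), function(j) {
    pts <- x[fit$assignments == j, , drop = FALSE]
    sqrt(mean(rowSums((pts - matrix(fit$centroids[j, ], nrow(pts),
                                    ncol(x), byrow = TRUE))^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(fit$centroids))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / dc[i, j], numeric(1)))
  }, numeric(1)))
}

gap_statistic <- function(x, k_grid, n_ref = 50, n_start = 5,
                          max_iter = 100) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  log_w_ref <- matrix(0, n_ref, length(k_grid))
  for (b in seq_len(n_ref)) {
    ref <- sapply(seq_len(ncol(x)),
                  function(j) stats::runif(nrow(x), lo[j], hi[j]))
    for (ki in seq_along(k_grid)) {
      log_w_ref[b, ki] <- log(fit_kmeans(ref, k_grid[ki],
                                         n_start = n_start,
                                         max_iter = max_iter)$wss)
    }
  }
  log_w_ref
}

#' Select the number of clusters from a panel of validity indices
#'
#' Fits k-means over `k_grid` and scores each k with mean silhouette
#' (maximize), Calinski-Harabasz (maximize), Davies-Bouldin (minimize),
#' the gap statistic with uniform reference sets (first k whose gap beats
#' the next gap minus its simulation error, falling back to the maximum
#' gap), and the WSS elbow (maximum second difference). The recommendation
#' is the majority vote of per-index optima; ties go to the smallest tied
#' k and are flagged.
#'
#' @param x Numeric matrix (scaled).
#' @param k_grid Candidate k values (default 2:10).
#' @param n_start,max_iter Passed to [fit_kmeans()].
#' @param n_ref Uniform reference sets for the gap statistic (default 50).
#' @param seed Integer seed.
#' @return An object of class `k_selection`: list with `recommended_k`,
#'   `tie`, `votes`, and a per-k `table` of all indices.
#' @export
select_k <- function(x, k_grid = 2:10, n_start = 25, max_iter = 1000,
                     n_ref = 50, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) <= max(k_grid)) stop("need more rows than max(k_grid)")
  if (all(col_sds(x) == 0)) stop("degenerate input: all rows identical")
  with_seed(seed, {
    fits <- lapply(k_grid, function(k) {
      fit_kmeans(x, k, n_start = n_start, max_iter = max_iter)
    })
    sil <- vapply(fits, function(f) f$mean_silhouette, numeric(1))
    ch <- vapply(fits, function(f) calinski_harabasz(x, f), numeric(1))
    db <- vapply(fits, function(f) davies_bouldin(x, f), numeric(1))
    wss <- vapply(fits, function(f) f$wss, numeric(1))
    log_w_ref <- gap_statistic(x, k_grid, n_ref = n_ref)
    gap <- colMeans(log_w_ref) - log(wss)
    se_gap <- apply(log_w_ref, 2, stats::sd) * sqrt(1 + 1 / nrow(log_w_ref))

    opt_sil <- k_grid[which.max(sil)]
    opt_ch <- k_grid[which.max(ch)]
    opt_db <- k_grid[which.min(db)]
    gap_ok <- which(gap[-length(gap)] >=
                      gap[-1][seq_len(length(gap) - 1)] -
                      se_gap[-1][seq_len(length(gap) - 1)])
    opt_gap <- if (length(gap_ok)) k_grid[min(gap_ok)] else
      k_grid[which.max(gap)]
    opt_elbow <- if (length(wss) >= 3) {
      d2 <- diff(diff(wss))  # second difference; elbow = max curvature
      k_grid[which.max(d2) + 1]
    } else {
      k_grid[which.min(wss)]
    }
    votes <- c(silhouette = opt_sil, calinski_harabasz = opt_ch,
               davies_bouldin = opt_db, gap = opt_gap, elbow = opt_elbow)
    tab <- table(votes)
    winners <- as.integer(names(tab)[tab == max(tab)])
    structure(list(recommended_k = min(winners),
                   tie = length(winners) > 1,
                   votes = votes,
                   table = data.frame(k = k_grid, silhouette = sil, ch = ch,
                                      db = db, wss = wss, gap = gap,
                                      gap_se = se_gap)),
              class = "k_selection")
  })
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> recommended k =", x$recommended_k,
      if (x$tie) "(tie, smallest reported)" else "", "\n")
  cat("votes:", paste(names(x$votes), x$votes, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

# independently permute the values within each column, preserving every
# column's multiset of values while destroying row structure
permute_columns <- function(x) {
  apply(x, 2, sample)
}

#' Permutation stability test for k-means clustering
#'
#' For each of `B` replicates, every column's values are independently
#' permuted (destroying row structure while preserving marginals), k-means
#' is refit at every k in `k_grid`, and the mean silhouette width is
#' recorded. The add-one-smoothed empirical p per k is
#' `(1 + #\{permuted >= observed\}) / (B + 1)`.
#'
#' @param x Numeric matrix (scaled).
#' @param B Number of permutations (default 100).
#' @param k_grid Candidate k values (default 2:10).
#' @param n_start,max_iter Passed to [fit_kmeans()].
#' @param seed Integer seed.
#' @return An object of class `stability_report`: list with `k_grid`,
#'   `observed_silhouette`, `permuted_silhouettes` (B x |k_grid|),
#'   `empirical_p`, `B`.
#' @export
permutation_stability <- function(x, B = 100, k_grid = 2:10, n_start = 25,
                                  max_iter = 1000, seed = NULL) {
  x <- as.matrix(x)
  if (B < 1) stop("B must be at least 1")
  with_seed(seed, {
    observed <- vapply(k_grid, function(k) {
      fit_kmeans(x, k, n_start = n_start,
                 max_iter = max_iter)$mean_silhouette
    }, numeric(1))
    perm <- matrix(0, B, length(k_grid))
    for (b in seq_len(B)) {
      xp <- permute_columns(x)
      perm[b, ] <- vapply(k_grid, function(k) {
        fit_kmeans(xp, k, n_start = n_start,
                   max_iter = max_iter)$mean_silhouette
      }, numeric(1))
    }
    p <- (1 + colSums(perm >= matrix(observed, B, length(k_grid),
                                     byrow = TRUE))) / (B + 1)
    structure(list(k_grid = k_grid, observed_silhouette = observed,
                   permuted_silhouettes = perm,
                   empirical_p = stats::setNames(p, k_grid), B = B),
              class = "stability_report")
  })
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> B =", x$B, "\n")
  print(data.frame(k = x$k_grid, observed = round(x$observed_silhouette, 4),
                   p = round(x$empirical_p, 4)), row.names = FALSE)
  invisible(x)
}
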