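test_that("median imputation fills only the missing cells", {
  tab <- data.frame(subject_id = c("a", "b", "c", "d"),
                    alt = c(1, 2, NA, 4),
                    ast = c(1, NA, 3, 4),
                    tg = c(5, 6, 7, 8))
  out <- impute_median(tab, variables = c("alt", "ast", "tg"))
  expect_equal(out$alt, c(1, 2, 2, 4))   # median of {1,2,4}
  expect_equal(out$ast, c(1, 3, 3, 4))   # median of {1,3,4}
  expect_equal(out$tg, tab$tg)           # untouched
  expect_identical(impute_median(out, c("alt", "ast", "tg")), out)
  tab$alt <- NA_real_
  expect_error(impute_median(tab, "alt"), "fully missing")
})

test_that("extreme-value screen uses a strict single-pass 5-SD rule", {
  with_seed(1, {
    n <- 60
    tab <- data.frame(subject_id = sprintf("s%02d", 1:n),
                      alt = rnorm(n), ast = rnorm(n))
  })
  m <- mean(tab$alt)
  s <- sd(tab$alt)
  none <- exclude_extreme(tab, variables = c("alt", "ast"))
  expect_length(none$excluded, 0)

  tab2 <- tab
  # far enough that it remains > 5 SD of the contaminated column
  tab2$alt[1] <- m + 20 * s
  out <- exclude_extreme(tab2, variables = c("alt", "ast"))
  expect_identical(out$excluded, "s01")
  expect_equal(nrow(out$table), n - 1)

  # exactly at the threshold (computed on the contaminated table) stays in
  tab3 <- tab
  m3 <- mean(tab3$alt)
  s3 <- sd(tab3$alt)
  # solve x so that |x - mean'| = 5 sd' on the updated column
  f <- function(x) {
    v <- tab$alt; v[1] <- x
    abs(x - mean(v)) - 5 * sd(v)
  }
  x5 <- uniroot(f, c(m3 + 2 * s3, m3 + 40 * s3), tol = 1e-12)$root
  tab3$alt[1] <- x5 - 1e-9
  expect_length(exclude_extreme(tab3, variables = c("alt", "ast"))$excluded,
                0)
  # constant column is flagged and skipped
  tab$ast <- 1
  out2 <- exclude_extreme(tab, variables = c("alt", "ast"))
  expect_identical(out2$skipped_variables, "ast")
})

test_that("z-scoring yields exact zero means and unit sample SDs", {
  expect_equal(zscore_scale(cbind(x = c(1, 2, 3)))$matrix[, 1],
               c(-1, 0, 1), ignore_attr = TRUE)
  with_seed(2, x <- matrix(rnorm(100, 5, 3), 20, 5,
                           dimnames = list(NULL, paste0("v", 1:5))))
  sc <- zscore_scale(x)
  expect_true(all(abs(colMeans(sc$matrix)) < 1e-10))
  expect_equal(unname(apply(sc$matrix, 2, sd)), rep(1, 5))
  # idempotent on standardized input
  expect_equal(zscore_scale(sc$matrix)$matrix, sc$matrix,
               tolerance = 1e-12)
  expect_error(zscore_scale(cbind(a = c(1, 1, 1))), "constant")
})

test_that("k-means solves separable and degenerate cases exactly", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
  fit <- fit_kmeans(x, 2, seed = 1)
  expect_equal(fit$wss, 1.0)
  expect_equal(fit$assignments[1], fit$assignments[2])
  expect_equal(fit$assignments[3], fit$assignments[4])
  cen <- fit$centroids[order(fit$centroids[, 1]), ]
  expect_equal(cen, rbind(c(0, 0.5), c(10, 10.5)), ignore_attr = TRUE)

  fit1 <- fit_kmeans(x, 1, seed = 1)
  expect_equal(fit1$centroids[1, ], colMeans(x))
  expect_equal(fit1$wss, sum(scale(x, scale = FALSE)^2))
  expect_error(fit_kmeans(x, 5, seed = 1), "exceed")
})

test_that("k-means attains the brute-force minimum-WSS bipartition", {
  wss_of <- function(x, a) {
    sum(vapply(unique(a), function(j) {
      xi <- x[a == j, , drop = FALSE]
      sum(scale(xi, scale = FALSE)^2)
    }, numeric(1)))
  }
  for (s in 1:5) {
    with_seed(s, x <- matrix(rnorm(16), 8, 2))
    best <- Inf
    for (code in 1:(2^7 - 1)) {  # fix point 1 in cluster 1; no empties
      a <- c(1L, as.integer(intToBits(code)[1:7]) + 1L)
      if (length(unique(a)) == 2) best <- min(best, wss_of(x, a))
    }
    fit <- fit_kmeans(x, 2, n_start = 50, seed = s)
    expect_equal(fit$wss, best, tolerance = 1e-9)
    # the kept restart is the best of all restarts
    expect_equal(fit$wss, min(fit$restart_wss))
  }
})

test_that("silhouette matches the hand-computed and brute-force values", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  s <- silhouette_widths(x, c(1, 1, 2))
  expect_equal(s$widths, c(0.9, 8 / 9, 0))
  expect_equal(s$mean, mean(c(0.9, 8 / 9, 0)))

  # coincident duplicated clusters: a = 0 so s = 1
  x2 <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(silhouette_widths(x2, c(1, 1, 2, 2))$widths, rep(1, 4))

  brute <- function(x, a) {
    n <- nrow(x)
    d <- as.matrix(dist(x))
    vapply(seq_len(n), function(i) {
      own <- a == a[i]
      if (sum(own) == 1) return(0)
      ai <- mean(d[i, own & seq_len(n) != i])
      bi <- min(vapply(setdiff(unique(a), a[i]),
                       function(j) mean(d[i, a == j]), numeric(1)))
      (bi - ai) / max(ai, bi)
    }, numeric(1))
  }
  for (s in 1:4) {
    with_seed(s, {
      x <- matrix(rnorm(60), 30, 2)
      a <- sample(1:3, 30, replace = TRUE)
    })
    if (length(unique(a)) < 2) next
    got <- silhouette_widths(x, a)
    expect_equal(got$widths, brute(x, a), tolerance = 1e-12)
    expect_true(all(got$widths >= -1 & got$widths <= 1))
  }
  expect_error(silhouette_widths(x, rep(1, 30)), "at least 2")
})

test_that("the validity-index panel recovers planted blob counts", {
  x3 <- make_blobs(100, rbind(c(0, 0), c(12, 0), c(0, 12)), seed = 5)
  sel3 <- select_k(zscore_scale(x3)$matrix, k_grid = 2:6, n_ref = 20,
                   seed = 5)
  expect_equal(sel3$recommended_k, 3)
  expect_false(sel3$tie)

  x2 <- make_blobs(100, rbind(c(0, 0), c(12, 12)), seed = 6)
  sel2 <- select_k(zscore_scale(x2)$matrix, k_grid = 2:6, n_ref = 20,
                   seed = 6)
  expect_equal(sel2$recommended_k, 2)
})

test_that("column permutation preserves each column's multiset", {
  with_seed(3, x <- matrix(rnorm(200), 40, 5))
  xp <- with_seed(4, metabotyper:::permute_columns(x))
  for (j in 1:5) expect_equal(sort(xp[, j]), sort(x[, j]))
  # a single column is left with the same sorted values
  x1 <- matrix(rnorm(20), ncol = 1)
  expect_equal(sort(with_seed(5, metabotyper:::permute_columns(x1))[, 1]),
               sort(x1[, 1]))
})

test_that("permutation stability separates planted structure from noise", {
  x <- make_blobs(40, rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)), seed = 7)
  st <- permutation_stability(zscore_scale(x)$matrix, B = 20,
                              k_grid = 2:4, n_start = 10, seed = 7)
  expect_equal(unname(st$empirical_p["3"]), 1 / 21)
  expect_equal(nrow(st$permuted_silhouettes), 20)
  expect_true(all(st$empirical_p > 0 & st$empirical_p <= 1))

  with_seed(8, noise <- matrix(rnorm(400), 100, 4))
  stn <- permutation_stability(scale(noise), B = 20, k_grid = 3,
                               n_start = 10, seed = 8)
  expect_gt(unname(stn$empirical_p["3"]), 0.05)
})

test_that("scaling then clustering is invariant to affine rescaling", {
  with_seed(9, x <- make_blobs(50, rbind(c(0, 0), c(6, 6)), seed = 9))
  colnames(x) <- c("a", "b")
  y <- x
  y[, 1] <- 100 * y[, 1] - 7
  y[, 2] <- -3 * y[, 2] + 42
  fx <- fit_kmeans(zscore_scale(x)$matrix, 2, seed = 10)
  fy <- fit_kmeans(zscore_scale(y)$matrix, 2, seed = 10)
  # same partition up to label swap
  agree <- mean(fx$assignments == fy$assignments)
  expect_true(agree == 1 || agree == 0)
})

test_that("cluster profiling reproduces small-sample exact statistics", {
  tab <- data.frame(subject_id = sprintf("s%d", 1:6),
                    alt = c(1, 2, 3, 4, 5, 6),
                    sex = c("m", "m", "f", "m", "f", "f"))
  pr <- profile_clusters(tab, c(1, 1, 1, 2, 2, 2), continuous = "alt",
                         categorical = "sex")
  # Mann-Whitney U = 0 on fully separated groups: exact two-sided 2/20
  pw <- pr$pairwise[pr$pairwise$variable == "alt", ]
  expect_equal(pw$p, 0.1)
  expect_equal(pr$continuous$median_1, 2)
  expect_equal(pr$continuous$q25_2, 4.5)
  # percentages sum to 100 within each cluster
  for (cl in 1:2) {
    expect_equal(sum(pr$categorical$percent[pr$categorical$cluster == cl]),
                 100)
  }
  expect_identical(pr$meta$pairwise_adjustment, "none")
})

test_that("profiling omnibus test holds its type-I error under the null", {
  B <- 400
  hits <- 0
  with_seed(12, {
    for (b in seq_len(B)) {
      tab <- data.frame(subject_id = sprintf("s%02d", 1:30),
                        alt = rnorm(30))
      pr <- profile_clusters(tab, rep(1:3, each = 10),
                             continuous = "alt",
                             categorical = character(0))
      hits <- hits + (pr$continuous$p < 0.05)
    }
  })
  # binomial 99.9% envelope around 0.05 at B = 400
  lo <- qbinom(5e-4, B, 0.05)
  hi <- qbinom(1 - 5e-4, B, 0.05)
  expect_gte(hits, lo)
  expect_lte(hits, hi)
})
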