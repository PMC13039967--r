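test_that("triplicate summarization takes medians and checks replicability", {
  # one feature with replicate values (1, 2, 3) summarizes to 2
  set.seed(NULL)
  base <- matrix(c(1, 2, 3,
                   10, 10, 10), 3, 2)
  with_seed(1, noise <- matrix(rnorm(3 * 20), 3, 20))
  tab <- toy_feature_table(cbind(base, 100 + noise +
                                   matrix(seq(1, 20, 1), 3, 20,
                                          byrow = TRUE) * 5),
                           replicates = 3)
  out <- summarize_triplicates(tab)
  expect_equal(unname(out$table$intensities[1, 1:2]), c(2, 10))
  expect_false(out$qc$flagged[1])

  # three identical replicate vectors correlate perfectly
  v <- c(5, 9, 1, 7, 3)
  tab2 <- toy_feature_table(rbind(v, v, v), replicates = 3)
  out2 <- summarize_triplicates(tab2)
  expect_equal(out2$qc$median_r, 1)
  expect_false(out2$qc$flagged)

  # replicates that are independent noise get flagged
  with_seed(2, bad <- matrix(rnorm(3 * 200), 3, 200))
  out3 <- summarize_triplicates(toy_feature_table(bad, replicates = 3))
  expect_lt(abs(out3$qc$median_r), 0.3)
  expect_true(out3$qc$flagged)
})

test_that("CV filter is strict at the threshold and drops undefined CVs", {
  # build 3 samples x 3 replicates with controlled within-sample CV
  make_col <- function(cv) {
    m <- 100
    d <- cv * m  # sd of (m-d, m, m+d) is d, so CV is exactly cv
    rep(c(m - d, m, m + d), 3)
  }
  ints <- cbind(constant = rep(10, 9),
                cv50 = make_col(0.50),
                cv75 = make_col(0.75),
                cv80 = make_col(0.80),
                zero = rep(0, 9))
  tab <- toy_feature_table(ints, replicates = 3)
  out <- filter_by_cv(tab, max_cv = 0.75)
  qc <- out$qc
  expect_equal(qc$median_cv[1], 0)
  expect_false(qc$dropped[qc$feature_id == "f001"])  # CV 0 kept
  expect_false(qc$dropped[qc$feature_id == "f002"])  # 0.50 kept
  expect_true(qc$dropped[qc$feature_id == "f003"])   # exactly 0.75 dropped
  expect_true(qc$dropped[qc$feature_id == "f004"])   # 0.80 dropped
  expect_identical(qc$reason[qc$feature_id == "f005"], "undefined_cv")
  expect_equal(ncol(out$table$intensities), 2)
})

test_that("batch adjustment removes a constructed location shift", {
  with_seed(3, {
    base <- matrix(rnorm(40 * 200, mean = 20), 40, 200)
  })
  x <- base
  x[21:40, ] <- x[21:40, ] + 2  # constant offset on batch 2
  batches <- rep(c("b1", "b2"), each = 20)
  # in the no-shrinkage limit the estimated location is removed exactly
  adj <- adjust_batch_effects(x, batches, shrink = FALSE)
  bm1 <- colMeans(adj[1:20, ])
  bm2 <- colMeans(adj[21:40, ])
  expect_lt(max(abs(bm1 - bm2)), 1e-6)
  # grand mean of every feature preserved
  expect_lt(max(abs(colMeans(adj) - colMeans(x))), 1e-9)
  # EB shrinkage equalizes batch means up to the prior pull
  adj_eb <- adjust_batch_effects(x, batches)
  expect_lt(max(abs(colMeans(adj_eb[1:20, ]) -
                      colMeans(adj_eb[21:40, ]))), 1)
  expect_lt(max(abs(colMeans(adj_eb) - colMeans(x))), 1e-9)
})

test_that("batch adjustment matches a direct standardization oracle and
           shrinks toward it", {
  with_seed(4, {
    x <- matrix(rnorm(30 * 300, 10), 30, 300)
    x[16:30, ] <- x[16:30, ] * 1.4 + 1.5
  })
  batches <- rep(c("b1", "b2"), each = 15)
  adj <- adjust_batch_effects(x, batches)
  # oracle: per feature, full (unshrunk) location/scale removal
  oracle <- x
  for (j in seq_len(ncol(x))) {
    grand <- mean(x[, j])
    pooled <- sqrt(sum(tapply(x[, j], batches,
                              function(v) sum((v - mean(v))^2))) / (30 - 2))
    z <- (x[, j] - grand) / pooled
    for (b in unique(batches)) {
      idx <- batches == b
      z[idx] <- (z[idx] - mean(z[idx])) / sd(z[idx])
    }
    oracle[, j] <- z * pooled + grand
    oracle[, j] <- oracle[, j] - mean(oracle[, j]) + grand
  }
  # no-shrinkage mode reproduces the oracle to numerical precision
  adj0 <- adjust_batch_effects(x, batches, shrink = FALSE)
  expect_equal(adj0, oracle, tolerance = 1e-9)
  # EB estimate equals the no-shrinkage estimate plus a bounded prior pull
  expect_lt(mean(abs(adj - oracle)), 0.15)
  expect_gt(mean(abs(adj - oracle)), 0)
})

test_that("identical batches pass through unchanged", {
  with_seed(5, half <- matrix(rnorm(10 * 50, 15), 10, 50))
  x <- rbind(half, half)
  adj <- adjust_batch_effects(x, rep(c("a", "b"), each = 10))
  expect_equal(adj, x, tolerance = 1e-9)
  expect_error(adjust_batch_effects(x, rep("a", 20)), "2 batches")
  expect_error(adjust_batch_effects(x, c(rep("a", 19), "b")),
               "single sample")
})

test_that("feature matching applies exact ppm/RT rules and greedy pairing", {
  mk <- function(mz, rt, prefix) {
    toy_feature_table(matrix(1, 1, length(mz),
                             dimnames = list(NULL, NULL)),
                      mz = mz, rt = rt) -> t
    t$features$feature_id <- paste0(prefix, seq_along(mz))
    colnames(t$intensities) <- t$features$feature_id
    t
  }
  a <- mk(c(100.0000, 200.0000), c(60, 100), "a")
  b <- mk(c(100.0004, 200.0012), c(80, 100), "b")
  m <- match_features(a, b)
  # 4.0 ppm / 20 s -> matched; 6.0 ppm -> not
  expect_equal(m$features$merged_id, "a1")
  expect_equal(m$features$ppm,
               (100.0004 - 100) / ((100.0004 + 100) / 2) * 1e6)

  # RT boundary is inclusive at exactly 30 s
  b2 <- mk(100.0004, 90, "b")
  a2 <- mk(100.0000, 60, "a")
  expect_equal(nrow(match_features(a2, b2)$features), 1)
  b3 <- mk(100.0004, 90.5, "b")
  expect_equal(nrow(match_features(a2, b3)$features), 0)

  # greedy rule prefers the 1-ppm candidate over the 3-ppm candidate
  a3 <- mk(300.0000, 60, "a")
  b4 <- mk(c(300.0003, 300.0009), c(60, 60), "b")
  m3 <- match_features(a3, b4)
  expect_equal(m3$provenance[["a1"]], c("a1", "b1"), ignore_attr = TRUE)

  expect_error(match_features(a, mk(100, 60, "c") |>
                                (\(t) { t$mode <- "c18_neg"; t })()),
               "mode mismatch")
})

test_that("feature matching is symmetric", {
  with_seed(6, {
    mza <- sort(runif(40, 100, 500))
    mzb <- mza * (1 + rnorm(40, 0, 2e-6))
    rta <- runif(40, 50, 500)
    rtb <- rta + rnorm(40, 0, 10)
  })
  a <- toy_feature_table(matrix(1, 2, 40), mz = mza, rt = rta,
                         replicates = 1)
  b <- toy_feature_table(matrix(1, 2, 40), mz = mzb, rt = rtb,
                         replicates = 1)
  b$features$feature_id <- sprintf("g%03d", 1:40)
  colnames(b$intensities) <- b$features$feature_id
  ab <- match_features(a, b)
  ba <- match_features(b, a)
  pairs_ab <- sort(vapply(ab$provenance, paste, collapse = "|", ""))
  pairs_ba <- sort(vapply(ba$provenance,
                          function(x) paste(rev(x), collapse = "|"), ""))
  expect_equal(unname(pairs_ab), unname(pairs_ba))
})

test_that("quantile normalization matches rank means and is idempotent", {
  x <- rbind(s1 = c(1, 3), s2 = c(2, 4))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn), rbind(c(1.5, 3.5), c(1.5, 3.5)))
  # identical samples are a fixed point
  y <- rbind(a = c(5, 1, 7), b = c(5, 1, 7))
  expect_equal(quantile_normalize(y), y)
  with_seed(7, z <- matrix(rexp(20 * 50), 20, 50))
  q1 <- quantile_normalize(z)
  q2 <- quantile_normalize(q1)
  expect_equal(q2, q1, tolerance = 1e-12)
  # all samples share an identical sorted vector
  sorted <- apply(q1, 1, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_error(quantile_normalize(matrix(numeric(0), 0, 0)), "empty")
})

test_that("log2 transform applies the half-minimum rule and keeps order", {
  expect_equal(log2_transform(matrix(8))[1, 1], 3)
  x <- matrix(c(0, 4), 2, 1)
  expect_equal(log2_transform(x)[, 1], c(1, 2))
  with_seed(8, m <- matrix(rexp(30), 10, 3))
  lt <- log2_transform(m)
  for (j in 1:3) expect_equal(order(lt[, j]), order(m[, j]))
  expect_warning(out <- log2_transform(cbind(c(0, 0), c(1, 2))),
                 "entirely zero")
  expect_equal(ncol(out), 1)
  expect_error(log2_transform(matrix(-1)), "negative")
})

test_that("Hotelling screen uses the F-based limit and flags gross outliers", {
  with_seed(9, x <- matrix(rnorm(100 * 60), 100, 60))
  ho <- hotelling_outliers(x, n_pcs = 5, conf = 0.99)
  expect_equal(ho$limit, 5 * 99 / 95 * qf(0.99, 5, 95))
  # Monte-Carlo oracle for the F quantile itself
  with_seed(10, fdraws <- rf(2e5, 5, 95))
  expect_equal(quantile(fdraws, 0.99, names = FALSE), qf(0.99, 5, 95),
               tolerance = 0.02)
  # null flag rate stays near the nominal 1%
  expect_lte(length(ho$flagged), 4)

  xs <- x
  xs[1, ] <- xs[1, ] + 20  # gross shift on every feature
  rownames(xs) <- sprintf("s%03d", 1:100)
  ho2 <- hotelling_outliers(xs, 5, 0.99)
  expect_true("s001" %in% ho2$flagged)
  expect_error(hotelling_outliers(x[1:5, ], 5), "more samples")
})

test_that("feature table CSV IO round-trips", {
  with_seed(11, ints <- matrix(rexp(6 * 4, 1 / 100), 6, 4))
  tab <- toy_feature_table(ints, replicates = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, f)
  back <- read_feature_csv(f, mode = "hilic_pos")
  expect_equal(back$features$mz, tab$features$mz)
  expect_equal(unname(back$intensities), unname(tab$intensities))
  expect_equal(back$injection_map$sample, tab$injection_map$sample)
  expect_equal(back$batch_map$batch, tab$batch_map$batch)
})

test_that("EB adjustment agrees with the reference ComBat implementation", {
  with_seed(12, {
    x <- matrix(rnorm(30 * 300, 10), 30, 300)
    x[16:30, ] <- x[16:30, ] * 1.2 + 1.5
  })
  batches <- rep(c("b1", "b2"), each = 15)
  adj <- adjust_batch_effects(x, batches)
  cb <- t(sva::ComBat(t(x), batch = batches))
  expect_gt(cor(as.vector(adj), as.vector(cb)), 0.999)
  expect_lt(mean(abs(adj - cb)), 0.1)
})
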