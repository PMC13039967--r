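#' Profile metabotype clusters
#'
#' Summarizes every requested variable by cluster — median and IQR for
#' continuous variables, counts and percentages for categorical ones — with
#' an omnibus test across clusters (tie-corrected Kruskal-Wallis for
#' continuous; chi-squared for categorical, falling back to Fisher's exact
#' test — Monte-Carlo for tables larger than 2x2 — when any expected count
#' is below 5) and unadjusted pairwise tests (two-sided Mann-Whitney U,
#' exact for small tie-free groups, normal approximation with continuity
#' correction otherwise; chi-squared/Fisher for categoricals).
#'
#' @param table Clinical data frame.
#' @param assignments Integer cluster labels, one per row.
#' @param continuous,categorical Variable names to profile; defaults cover
#'   the clustering panel plus common profiling variables present in the
#'   table.
#' @param fisher_B Monte-Carlo tableau count for r x c exact tests.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return An object of class `profile_report`: list with `continuous`
#'   (per variable x cluster medians/IQRs + omnibus p), `categorical`
#'   (counts/percents + omnibus p), `pairwise` (long data frame of
#'   unadjusted pairwise p-values) and `meta` (notes that pairwise p-values
#'   are unadjusted).
#' @export
profile_clusters <- function(table, assignments,
                             continuous = NULL, categorical = NULL,
                             fisher_B = 10000, seed = 1) {
  stopifnot(nrow(table) == length(assignments))
  if (min(table(assignments)) < 2) stop("each cluster needs >= 2 members")
  cl <- sort(unique(assignments))
  if (is.null(continuous)) {
    continuous <- intersect(c(clustering_variables(), "bmi_z", "hdl", "tc"),
                            names(table))
  }
  if (is.null(categorical)) {
    categorical <- intersect(c("sex", "ethnicity", "study", "steatosis",
                               "lobular_inflammation", "ballooning",
                               "fibrosis_stage", "mash_category"),
                             names(table))
  }
  pairs <- utils::combn(cl, 2, simplify = FALSE)

  cont_rows <- list()
  pw_rows <- list()
  for (v in continuous) {
    x <- table[[v]]
    row <- list(variable = v)
    for (j in cl) {
      xi <- x[assignments == j]
      q <- stats::quantile(xi, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      row[[paste0("median_", j)]] <- q[2]
      row[[paste0("q25_", j)]] <- q[1]
      row[[paste0("q75_", j)]] <- q[3]
    }
    row$p <- stats::kruskal.test(x, factor(assignments))$p.value
    cont_rows[[v]] <- as.data.frame(row)
    for (pr in pairs) {
      a <- x[assignments == pr[1]]
      b <- x[assignments == pr[2]]
      exact <- length(a) <= 8 && length(b) <= 8 &&
        !anyDuplicated(c(a, b))
      p <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                               correct = TRUE)$p.value)
      pw_rows[[length(pw_rows) + 1]] <- data.frame(
        variable = v, type = "continuous",
        cluster_a = pr[1], cluster_b = pr[2], p = p)
    }
  }

  cat_rows <- list()
  for (v in categorical) {
    x <- factor(table[[v]])
    tab <- table(x, factor(assignments, levels = cl))
    pct <- sweep(tab, 2, colSums(tab), "/") * 100
    p <- categorical_test_p(tab, fisher_B, seed)
    cat_rows[[v]] <- data.frame(
      variable = v, level = rep(rownames(tab), length(cl)),
      cluster = rep(cl, each = nrow(tab)),
      count = as.vector(tab), percent = as.vector(pct),
      p = p)
    for (pr in pairs) {
      sub <- tab[, as.character(pr), drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      pp <- if (nrow(sub) < 2) NA_real_ else
        categorical_test_p(sub, fisher_B, seed)
      pw_rows[[length(pw_rows) + 1]] <- data.frame(
        variable = v, type = "categorical",
        cluster_a = pr[1], cluster_b = pr[2], p = pp)
    }
  }

  structure(list(continuous = do.call(rbind, cont_rows),
                 categorical = do.call(rbind, cat_rows),
                 pairwise = do.call(rbind, pw_rows),
                 meta = list(pairwise_adjustment = "none")),
            class = "profile_report")
}

# omnibus p for a contingency table: chi-squared, Fisher fallback when any
# expected count < 5 (exact 2x2, Monte-Carlo otherwise)
categorical_test_p <- function(tab, fisher_B = 10000, seed = 1) {
  tab <- as.matrix(tab)
  suppressWarnings({
    cs <- stats::chisq.test(tab, correct = FALSE)
    if (all(cs$expected >= 5)) return(cs$p.value)
    if (all(dim(tab) == c(2, 2))) return(stats::fisher.test(tab)$p.value)
    with_seed(seed,
              stats::fisher.test(tab, simulate.p.value = TRUE,
                                 B = fisher_B)$p.value)
  })
}

#' @export
print.profile_report <- function(x, ...) {
  cat("<profile_report>", nrow(x$continuous), "continuous and",
      length(unique(x$categorical$variable)), "categorical variables\n")
  invisible(x)
}
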