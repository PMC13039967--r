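# Default per-cluster clinical distributions. Locations and spreads are set
# from published cohort summaries of pediatric MASLD metabotypes: cluster 1
# "early-mild", cluster 2 "cardiometabolic", cluster 3
# "inflammatory-fibrotic". Positive right-skewed variables are log-normal
# with the configured value as exact median; age and blood pressures are
# normal. Spread is recovered from the interquartile range
# (sigma = IQR / (2 * qnorm(0.75)) on the relevant scale).
default_clinical_params <- function() {
  p <- list(
    age      = list(dist = "normal",
                    median = c(11, 15, 12),
                    q25 = c(9, 13, 11),   q75 = c(12, 16, 13)),
    alt      = list(dist = "lognormal",
                    median = c(77, 79, 256),
                    q25 = c(54, 56, 219), q75 = c(111, 105, 300)),
    ast      = list(dist = "lognormal",
                    median = c(48, 45, 136),
                    q25 = c(35, 35, 117), q75 = c(62, 60, 164)),
    wc       = list(dist = "lognormal",
                    median = c(96, 114, 106),
                    q25 = c(87, 104, 97), q75 = c(104, 123, 113)),
    ldl      = list(dist = "lognormal",
                    median = c(87, 105, 105),
                    q25 = c(69, 91, 80),  q75 = c(107, 127, 130)),
    tg       = list(dist = "lognormal",
                    median = c(110, 170, 143),
                    q25 = c(77, 129, 111), q75 = c(143, 228, 215)),
    homa2ir  = list(dist = "lognormal",
                    median = c(2.6, 4.4, 4.8),
                    q25 = c(1.8, 2.9, 2.8), q75 = c(3.7, 6.3, 7.0)),
    uric_acid = list(dist = "lognormal",
                    median = c(5.2, 6.8, 5.8),
                    q25 = c(4.5, 5.9, 4.9), q75 = c(6.0, 7.7, 6.6)),
    sbp      = list(dist = "normal",
                    median = c(114, 127, 122),
                    q25 = c(107, 118, 112), q75 = c(123, 135, 129)),
    bmi_z    = list(dist = "normal",
                    median = c(2.2, 2.4, 2.3),
                    q25 = c(1.9, 2.1, 2.0), q75 = c(2.6, 2.7, 2.8)),
    hdl      = list(dist = "lognormal",
                    median = c(40, 36, 40),
                    q25 = c(34, 32, 33),  q75 = c(45, 42, 45)),
    tc       = list(dist = "lognormal",
                    median = c(149, 179, 182),
                    q25 = c(129, 159, 151), q75 = c(173, 206, 210))
  )
  p
}

# Cluster-conditional categorical distributions (columns: cluster 1..3),
# read off published per-metabotype frequencies and renormalized.
default_categorical_params <- function() {
  norm <- function(m) sweep(m, 2, colSums(m), "/")
  list(
    male_prob = c(0.69, 0.78, 0.79),
    hispanic_prob = c(0.81, 0.61, 0.82),
    study = norm(matrix(c(0.043, 0.063, 0.001,
                          0.840, 0.690, 0.770,
                          0.120, 0.250, 0.230), 3, 3, byrow = TRUE,
                        dimnames = list(c("DB1", "DB2", "TONIC"), NULL))),
    steatosis = norm(matrix(c(0.008, 0.011, 0.014,
                              0.270, 0.300, 0.340,
                              0.320, 0.370, 0.280,
                              0.400, 0.320, 0.370), 4, 3, byrow = TRUE,
                            dimnames = list(0:3, NULL))),
    lobular_inflammation = norm(matrix(c(0.008, 0.000, 0.000,
                                         0.670, 0.660, 0.350,
                                         0.300, 0.310, 0.510,
                                         0.024, 0.037, 0.140), 4, 3,
                                       byrow = TRUE,
                                       dimnames = list(0:3, NULL))),
    ballooning = norm(matrix(c(0.730, 0.610, 0.250,
                               0.220, 0.280, 0.370,
                               0.055, 0.110, 0.380), 3, 3, byrow = TRUE,
                             dimnames = list(0:2, NULL))),
    fibrosis_stage = norm(matrix(c(0.330, 0.410, 0.130,
                                   0.390, 0.350, 0.170,
                                   0.110, 0.160, 0.350,
                                   0.150, 0.069, 0.320,
                                   0.012, 0.011, 0.028), 5, 3, byrow = TRUE,
                                 dimnames = list(0:4, NULL))),
    mash_category = norm(matrix(c(0.330, 0.380, 0.040,
                                  0.440, 0.160, 0.130,
                                  0.090, 0.210, 0.210,
                                  0.130, 0.250, 0.620), 4, 3, byrow = TRUE,
                                dimnames = list(c("no", "borderline z1",
                                                  "borderline z3",
                                                  "definite"), NULL)))
  )
}

#' Simulation configuration for a synthetic metabotype cohort
#'
#' Bundles every knob of the synthetic cohort and feature-table generator.
#' Defaults encode the study conditions the package is tested under: a
#' three-metabotype cohort with published per-cluster clinical locations,
#' 0.34\% clinical missingness, two ionization modes acquired in triplicate
#' across three study batches, and pathway-structured intensity effects.
#'
#' @param n_subjects Number of subjects.
#' @param cluster_proportions Mixing fractions per latent cluster (sum 1).
#' @param clinical_params Per-cluster location/scale for each continuous
#'   clinical variable; see `default_clinical_params()` source for layout.
#' @param categorical_params Cluster-conditional categorical distributions.
#' @param missing_rate Fraction of clustering-variable cells set missing.
#' @param n_extreme_subjects Number of injected >5-SD clinical outliers.
#' @param fixed_counts If `TRUE`, cluster sizes are exact
#'   (`round(n * proportions)`); default draws labels i.i.d. categorical.
#' @param studies Named list of study batches, each with `log2_shift`
#'   (additive intensity shift, log2 scale) and `scale` (noise-SD
#'   multiplier).
#' @param modes Named list per ionization mode with `n_background`
#'   (unassigned background features).
#' @param replicates Technical injections per sample (default 3).
#' @param replicate_cv Coefficient of variation across technical replicates.
#' @param ppm_noise_sd Mass-accuracy noise in ppm.
#' @param rt_jitter_sd Between-study retention-time jitter SD, seconds.
#' @param planted_pathways Named list: pathway -> `list(cluster, log2fc)`;
#'   all features of the pathway's compounds are shifted by `log2fc` in the
#'   affected cluster.
#' @param planted_associations List of `list(pathway, cluster, variable, r)`
#'   entries planting a within-cluster correlation between a clinical
#'   variable and the pathway's features.
#' @param outlier_sample_rate Fraction of subjects whose metabolomics noise
#'   covariance is inflated (multivariate outliers).
#' @param outlier_inflation Noise-SD multiplier for outlier samples.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return An object of class `sim_config` (validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 120, seed = 7)
#' cfg$cluster_proportions
sim_config <- function(n_subjects = 514,
                       cluster_proportions = c(254, 189, 71) / 514,
                       clinical_params = default_clinical_params(),
                       categorical_params = default_categorical_params(),
                       missing_rate = 0.0034,
                       n_extreme_subjects = 0,
                       fixed_counts = FALSE,
                       studies = list(
                         DB1 = list(log2_shift = 0,    scale = 1),
                         DB2 = list(log2_shift = 0.4,  scale = 1.1),
                         TONIC = list(log2_shift = -0.3, scale = 0.9)),
                       modes = list(hilic_pos = list(n_background = 150),
                                    c18_neg = list(n_background = 150)),
                       replicates = 3,
                       replicate_cv = 0.15,
                       ppm_noise_sd = 2,
                       rt_jitter_sd = 3,
                       planted_pathways = list(
                         "tryptophan metabolism" =
                           list(cluster = 3, log2fc = 1),
                         "pantothenate and CoA biosynthesis" =
                           list(cluster = 3, log2fc = 0.8),
                         "branched-chain amino acid degradation" =
                           list(cluster = 2, log2fc = 1),
                         "butanoate metabolism" =
                           list(cluster = 2, log2fc = 0.8),
                         "purine metabolism" =
                           list(cluster = 2, log2fc = 0.8),
                         "propanoate metabolism" =
                           list(cluster = 1, log2fc = 0.6)),
                       planted_associations = list(
                         list(pathway = "tryptophan metabolism", cluster = 3,
                              variable = "alt", r = 0.5)),
                       outlier_sample_rate = 24 / 514,
                       outlier_inflation = 4,
                       seed = 1) {
  cfg <- list(n_subjects = n_subjects,
              cluster_proportions = cluster_proportions,
              clinical_params = clinical_params,
              categorical_params = categorical_params,
              missing_rate = missing_rate,
              n_extreme_subjects = n_extreme_subjects,
              fixed_counts = fixed_counts,
              studies = studies, modes = modes,
              replicates = replicates, replicate_cv = replicate_cv,
              ppm_noise_sd = ppm_noise_sd, rt_jitter_sd = rt_jitter_sd,
              planted_pathways = planted_pathways,
              planted_associations = planted_associations,
              outlier_sample_rate = outlier_sample_rate,
              outlier_inflation = outlier_inflation,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  k <- length(cfg$cluster_proportions)
  if (k < 2) stop("at least 2 clusters are required")
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-9) {
    stop("cluster_proportions must sum to 1")
  }
  if (any(cfg$cluster_proportions <= 0)) {
    stop("cluster_proportions must all be > 0")
  }
  if (cfg$n_subjects < 10 * k) {
    stop("n_subjects must be at least 10 per cluster (10 * K)")
  }
  stopifnot(cfg$replicates >= 1, cfg$ppm_noise_sd >= 0,
            cfg$replicate_cv >= 0, cfg$missing_rate >= 0,
            cfg$missing_rate <= 1, cfg$outlier_sample_rate >= 0,
            cfg$outlier_sample_rate <= 1)
  for (v in names(cfg$clinical_params)) {
    pr <- cfg$clinical_params[[v]]
    if (any(pr$q75 <= pr$q25)) stop("non-positive IQR for ", v)
    if (pr$dist == "lognormal" && any(pr$median <= 0)) {
      stop("log-normal variable ", v, " needs positive medians")
    }
  }
  invisible(cfg)
}

# draw one continuous variable for all subjects given cluster labels
draw_clinical_var <- function(pr, labels) {
  n <- length(labels)
  out <- numeric(n)
  z <- 2 * stats::qnorm(0.75)
  for (cl in unique(labels)) {
    idx <- labels == cl
    if (pr$dist == "lognormal") {
      mu <- log(pr$median[cl])
      sigma <- (log(pr$q75[cl]) - log(pr$q25[cl])) / z
      out[idx] <- stats::rlnorm(sum(idx), mu, sigma)
    } else {
      sigma <- (pr$q75[cl] - pr$q25[cl]) / z
      out[idx] <- stats::rnorm(sum(idx), pr$median[cl], sigma)
    }
  }
  out
}

draw_categorical <- function(probs, labels) {
  lev <- rownames(probs)
  vapply(labels, function(cl) sample(lev, 1, prob = probs[, cl]), character(1))
}

#' Generate a synthetic clinical cohort with known metabotype structure
#'
#' Draws cluster labels, per-cluster clinical variables (log-normal for
#' positive skewed labs, normal for age, blood pressure and BMI z-score),
#' VLDL as TG/5, cluster-conditional histology scores and MASH category,
#' study membership, then injects the configured missingness and extreme
#' (>5 SD) subjects. Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `clinical` (data frame, one row per
#'   subject) and `truth` (ground-truth list: `subject_cluster`,
#'   `extreme_subjects`, `outlier_subjects`; feature-level slots are filled
#'   by [generate_feature_tables()]).
#' @export
#' @examples
#' coh <- generate_cohort(sim_config(n_subjects = 60, seed = 1))
#' table(coh$truth$subject_cluster)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  k <- length(config$cluster_proportions)
  n <- config$n_subjects
  with_seed(derive_seed(config$seed, "cohort"), {
    if (config$fixed_counts) {
      counts <- round(n * config$cluster_proportions)
      counts[1] <- n - sum(counts[-1])
      labels <- sample(rep(seq_len(k), counts))
    } else {
      labels <- sample(seq_len(k), n, replace = TRUE,
                       prob = config$cluster_proportions)
    }
    subject_id <- sprintf("S%04d", seq_len(n))
    cat_p <- config$categorical_params
    study_lab <- if (all(rownames(cat_p$study) %in% names(config$studies))) {
      draw_categorical(cat_p$study, labels)
    } else {
      # custom batch layout: uniform study assignment
      sample(names(config$studies), n, replace = TRUE)
    }
    clin <- data.frame(subject_id = subject_id,
                       study = study_lab,
                       sex = ifelse(stats::runif(n) < cat_p$male_prob[labels],
                                    "male", "female"),
                       ethnicity = ifelse(
                         stats::runif(n) < cat_p$hispanic_prob[labels],
                         "hispanic", "not hispanic"),
                       stringsAsFactors = FALSE)
    for (v in names(config$clinical_params)) {
      clin[[v]] <- draw_clinical_var(config$clinical_params[[v]], labels)
    }
    # VLDL is triglycerides / 5 before any rounding
    clin$vldl <- derive_vldl(clin$tg)
    lab_vars <- setdiff(names(config$clinical_params), c("age", "homa2ir"))
    clin[lab_vars] <- lapply(clin[lab_vars], round, digits = 1)
    clin$vldl <- round(clin$vldl, 1)
    clin$age <- round(clin$age, 1)
    clin$homa2ir <- round(clin$homa2ir, 2)
    for (v in c("steatosis", "lobular_inflammation", "ballooning",
                "fibrosis_stage")) {
      clin[[v]] <- as.integer(draw_categorical(cat_p[[v]], labels))
    }
    clin$mash_category <- draw_categorical(cat_p$mash_category, labels)

    extreme <- character(0)
    if (config$n_extreme_subjects > 0) {
      extreme <- sample(subject_id, config$n_extreme_subjects)
      vars <- clustering_variables()
      for (s in extreme) {
        v <- sample(vars, 1)
        clin[[v]][clin$subject_id == s] <-
          mean(clin[[v]], na.rm = TRUE) + 8 * stats::sd(clin[[v]], na.rm = TRUE)
      }
    }
    if (config$missing_rate > 0) {
      vars <- clustering_variables()
      keep <- !(clin$subject_id %in% extreme)
      for (v in vars) {
        miss <- stats::runif(n) < config$missing_rate & keep
        clin[[v]][miss] <- NA_real_
      }
    }
    n_out <- round(config$outlier_sample_rate * n)
    outliers <- if (n_out > 0) sample(subject_id, n_out) else character(0)

    truth <- list(subject_cluster = stats::setNames(labels, subject_id),
                  feature_compound = NULL,
                  differential_features = character(0),
                  outlier_subjects = outliers,
                  extreme_subjects = extreme)
    list(clinical = clin, truth = truth)
  })
}

#' Clinical variables used for clustering
#'
#' The ten routine variables that define the metabotype space: age, ALT,
#' AST, waist circumference, VLDL, LDL, triglycerides, HOMA2-IR, uric acid
#' and systolic blood pressure.
#'
#' @return Character vector of column names.
#' @export
clustering_variables <- function() {
  c("age", "alt", "ast", "wc", "vldl", "ldl", "tg", "homa2ir",
    "uric_acid", "sbp")
}
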