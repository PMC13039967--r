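#' Construct an LC-MS feature table
#'
#' @param mode Ionization mode label (e.g. `"hilic_pos"`, `"c18_neg"`).
#' @param features Data frame with columns `feature_id`, `mz`, `rt`.
#' @param intensities Numeric matrix, injections x features; column names
#'   must equal `features$feature_id`.
#' @param injection_map Data frame `injection`, `sample`, `replicate`.
#' @param batch_map Data frame `sample`, `batch`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(mode, features, intensities, injection_map,
                          batch_map) {
  stopifnot(all(c("feature_id", "mz", "rt") %in% names(features)),
            is.matrix(intensities),
            ncol(intensities) == nrow(features),
            nrow(intensities) == nrow(injection_map))
  if (anyDuplicated(features$feature_id)) {
    stop("feature_id must be unique within a table")
  }
  if (any(features$mz <= 0) || any(features$rt < 0)) {
    stop("mz must be positive and rt non-negative")
  }
  if (!all(injection_map$sample %in% batch_map$sample)) {
    stop("every injection must map to a known sample")
  }
  colnames(intensities) <- features$feature_id
  rownames(intensities) <- injection_map$injection
  structure(list(mode = mode, features = features,
                 intensities = intensities,
                 injection_map = injection_map, batch_map = batch_map),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> mode:", x$mode, "|", nrow(x$features), "features x",
      nrow(x$injection_map), "injections (",
      length(unique(x$injection_map$sample)), "samples,",
      length(unique(x$batch_map$batch)), "batch(es))\n")
  invisible(x)
}

# predicted m/z of a neutral mass under one adduct row
adduct_mz <- function(mass, shift) mass + shift

#' Generate per-study, per-mode synthetic LC-MS feature tables
#'
#' Renders every reference compound as its primary adduct (plus occasional
#' secondary adducts) with ppm-scale mass noise, adds unassigned background
#' features, and draws raw-scale log-normal intensities with: planted
#' per-cluster log2 effects for compounds of the configured pathways,
#' planted within-cluster clinical-metabolite correlations, per-study
#' location/scale batch shifts, inflated-noise multivariate-outlier
#' samples, and technical triplicates sharing a sample mean at the
#' configured replicate CV. One table is produced per (mode, study); the
#' same underlying feature appears in each study's table with study-specific
#' mass/RT jitter, so cross-study matching is non-trivial.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_cohort()] (consistent subjects).
#' @param reference A `pathway_reference`.
#' @param clinical The clinical table from the same cohort; required when
#'   `config$planted_associations` is non-empty.
#' @return A list with `tables` (list of `feature_table`, named
#'   `<mode>.<study>`) and `truth` (input truth enriched with
#'   `feature_compound` and `differential_features`, keyed by base feature
#'   id, i.e. the id before the `@study` suffix).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 60, seed = 2,
#'                   modes = list(hilic_pos = list(n_background = 20)))
#' coh <- generate_cohort(cfg)
#' ft <- generate_feature_tables(cfg, coh$truth, make_toy_pathway_reference(),
#'                               coh$clinical)
#' names(ft$tables)
generate_feature_tables <- function(config, truth, reference,
                                    clinical = NULL) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference, "pathway_reference"))
  if (nrow(reference$compounds) == 0) stop("reference must be non-empty")
  subjects <- names(truth$subject_cluster)
  if (length(subjects) != config$n_subjects) {
    stop("truth is not consistent with config (subject count mismatch)")
  }
  for (pw in names(config$planted_pathways)) {
    if (!pw %in% names(reference$pathways)) {
      stop("planted effect assigned to unknown pathway: ", pw)
    }
  }
  for (m in names(config$modes)) {
    if (!m %in% reference$adducts$mode) {
      stop("mode absent from adduct registry: ", m)
    }
  }
  if (length(config$planted_associations) > 0 && is.null(clinical)) {
    stop("clinical table required to plant clinical-metabolite associations")
  }

  labels <- truth$subject_cluster
  # study assignment comes from the clinical table when available
  study_of <- if (!is.null(clinical)) {
    stats::setNames(clinical$study, clinical$subject_id)[subjects]
  } else {
    stats::setNames(sample(names(config$studies), length(subjects),
                           replace = TRUE), subjects)
  }
  # compound -> first containing pathway (annotation truth)
  pw_of <- rep(NA_character_, nrow(reference$compounds))
  names(pw_of) <- reference$compounds$compound_id
  for (pw in rev(names(reference$pathways))) {
    pw_of[reference$pathways[[pw]]] <- pw
  }

  cv <- config$replicate_cv
  sdlog_rep <- sqrt(log(1 + cv^2))  # log-normal sigma giving CV = cv
  tables <- list()
  feat_truth <- list()
  diff_feats <- character(0)

  with_seed(derive_seed(config$seed, "features"), {
    # per-cluster z-scores of association variables
    assoc_z <- list()
    for (a in config$planted_associations) {
      key <- paste(a$variable, a$cluster, sep = "|")
      x <- stats::setNames(clinical[[a$variable]],
                           clinical$subject_id)[subjects]
      idx <- labels == a$cluster
      z <- rep(0, length(subjects))
      z[idx] <- as.numeric(scale(x[idx]))
      z[is.na(z)] <- 0
      assoc_z[[key]] <- z
    }

    for (mode in names(config$modes)) {
      adducts <- reference$adducts[reference$adducts$mode == mode, ]
      prim <- adducts[adducts$primary, , drop = FALSE][1, ]
      comp <- reference$compounds
      # primary adduct for every compound + a secondary for ~30% of them
      extra <- which(stats::runif(nrow(comp)) < 0.3 & nrow(adducts) > 1)
      sec <- adducts[!adducts$primary, , drop = FALSE]
      rows <- data.frame(
        compound = c(comp$compound_id, comp$compound_id[extra]),
        adduct = c(rep(prim$adduct, nrow(comp)),
                   sec$adduct[1 + (seq_along(extra) %% max(1, nrow(sec)))]),
        stringsAsFactors = FALSE)
      shift <- stats::setNames(adducts$shift, adducts$adduct)
      mass <- stats::setNames(comp$mass, comp$compound_id)
      rows$theo_mz <- adduct_mz(mass[rows$compound], shift[rows$adduct])

      n_bg <- config$modes[[mode]]$n_background %||% 150
      n_feat <- nrow(rows) + n_bg
      base_id <- sprintf("%s_F%04d", mode, seq_len(n_feat))
      theo_mz <- c(rows$theo_mz, stats::runif(n_bg, 85, 850))
      rt_true <- stats::runif(n_feat, 30, 600)
      compound <- c(rows$compound, rep(NA_character_, n_bg))
      adduct <- c(rows$adduct, rep(NA_character_, n_bg))
      pathway <- ifelse(is.na(compound), NA_character_, pw_of[compound])

      feat_truth[[mode]] <- data.frame(
        feature_id = base_id, compound = compound, adduct = adduct,
        pathway = unname(pathway), stringsAsFactors = FALSE)

      # planted per-cluster log2 effects
      effect <- matrix(0, n_feat, length(config$cluster_proportions))
      for (pw in names(config$planted_pathways)) {
        pl <- config$planted_pathways[[pw]]
        hit <- !is.na(compound) &
          compound %in% reference$pathways[[pw]]
        effect[hit, pl$cluster] <- effect[hit, pl$cluster] + pl$log2fc
        diff_feats <- union(diff_feats, base_id[hit])
      }

      base_log2 <- stats::runif(n_feat, 14, 22)
      bio_sd <- stats::runif(n_feat, 0.5, 1.0)

      # sample-level log2 abundance, subjects x features
      ns <- length(subjects)
      mu <- matrix(base_log2, ns, n_feat, byrow = TRUE) +
        t(effect)[labels, , drop = FALSE]
      for (a in config$planted_associations) {
        hit <- !is.na(compound) &
          compound %in% reference$pathways[[a$pathway]]
        key <- paste(a$variable, a$cluster, sep = "|")
        z <- assoc_z[[key]]
        in_cl <- labels == a$cluster
        mu[in_cl, hit] <- mu[in_cl, hit] +
          outer(z[in_cl], a$r * bio_sd[hit])
      }
      noise_sd_subj <- ifelse(subjects %in% truth$outlier_subjects,
                              config$outlier_inflation, 1)
      batch_scale <- vapply(config$studies, function(s) s$scale, numeric(1))
      batch_shift <- vapply(config$studies, function(s) s$log2_shift,
                            numeric(1))
      sc <- batch_scale[study_of] * noise_sd_subj
      log2_sample <- mu + batch_shift[study_of] +
        matrix(stats::rnorm(ns * n_feat), ns, n_feat) *
          outer(sc, rep(1, n_feat)) *
          matrix(bio_sd, ns, n_feat, byrow = TRUE)
      # note: association noise fraction applies within the affected cluster
      for (a in config$planted_associations) {
        hit <- which(!is.na(compound) &
                       compound %in% reference$pathways[[a$pathway]])
        in_cl <- which(labels == a$cluster)
        if (length(hit) && length(in_cl)) {
          adj <- sqrt(1 - a$r^2)
          log2_sample[in_cl, hit] <- mu[in_cl, hit] +
            (log2_sample[in_cl, hit] - mu[in_cl, hit] -
               matrix(batch_shift[study_of[in_cl]], length(in_cl),
                      length(hit))) * adj +
            matrix(batch_shift[study_of[in_cl]], length(in_cl), length(hit))
        }
      }

      for (st in names(config$studies)) {
        s_sub <- subjects[study_of == st]
        if (length(s_sub) == 0) next
        obs_mz <- theo_mz *
          (1 + stats::rnorm(n_feat, 0, config$ppm_noise_sd) * 1e-6)
        obs_rt <- pmax(0, rt_true + stats::rnorm(n_feat, 0,
                                                 config$rt_jitter_sd))
        feats <- data.frame(feature_id = paste0(base_id, "@", st),
                            mz = obs_mz, rt = obs_rt,
                            stringsAsFactors = FALSE)
        idx <- match(s_sub, subjects)
        nrep <- config$replicates
        inj <- data.frame(
          injection = paste0(rep(s_sub, each = nrep), "_",
                             rep(seq_len(nrep), length(s_sub))),
          sample = rep(s_sub, each = nrep),
          replicate = rep(seq_len(nrep), length(s_sub)),
          stringsAsFactors = FALSE)
        m_sample <- 2^log2_sample[idx, , drop = FALSE]
        reps <- m_sample[rep(seq_along(s_sub), each = nrep), ,
                         drop = FALSE]
        if (cv > 0) {
          reps <- reps * exp(matrix(
            stats::rnorm(nrow(reps) * n_feat, 0, sdlog_rep),
            nrow(reps), n_feat))
        }
        tables[[paste(mode, st, sep = ".")]] <- feature_table(
          mode = mode, features = feats, intensities = reps,
          injection_map = inj,
          batch_map = data.frame(sample = s_sub, batch = st,
                                 stringsAsFactors = FALSE))
      }
    }
  })
  truth$feature_compound <- do.call(rbind, unname(feat_truth))
  truth$differential_features <- diff_feats
  list(tables = tables, truth = truth)
}

#' Strip the study suffix from synthetic feature ids
#'
#' Synthetic per-study feature ids are `<base>@<study>`; ground truth is
#' keyed by `<base>`.
#'
#' @param ids Character feature ids.
#' @return Base ids.
#' @export
base_feature_id <- function(ids) sub("@.*$", "", ids)
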