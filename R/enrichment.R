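#' Annotate m/z features by adduct mass matching
#'
#' For every feature and every adduct of the ionization mode, the
#' predicted m/z is the compound's monoisotopic mass plus the adduct
#' shift; a hit is recorded when
#' `|observed - predicted| / predicted * 1e6 <= ppm_tol`. Features on a
#' supplied library-confirmed list are reported at confidence level 1
#' (confirmed structure); mass-match-only hits at level 5 (exact mass
#' only).
#'
#' @param features Data frame with `feature_id` and `mz` columns.
#' @param reference A `pathway_reference`.
#' @param mode Ionization mode present in the reference's adduct registry.
#' @param ppm_tol Mass tolerance in ppm (default 5, inclusive).
#' @param confirmed Optional character vector of feature ids with
#'   library-confirmed identities.
#' @return Data frame of annotation records: `feature_id`, `compound`,
#'   `compound_name`, `adduct`, `primary`, `predicted_mz`, `ppm_error`,
#'   `confidence_level`. Zero rows when nothing matches.
#' @export
#' @examples
#' ref <- make_toy_pathway_reference()
#' feats <- data.frame(feature_id = "f1", mz = 205.0970)
#' annotate_features(feats, ref, "hilic_pos")
annotate_features <- function(features, reference, mode, ppm_tol = 5,
                              confirmed = NULL) {
  stopifnot(inherits(reference, "pathway_reference"),
            all(c("feature_id", "mz") %in% names(features)))
  adducts <- reference$adducts[reference$adducts$mode == mode, ,
                               drop = FALSE]
  if (nrow(adducts) == 0) stop("mode absent from adduct registry: ", mode)
  comp <- reference$compounds
  grid <- merge(comp, adducts)
  grid$predicted_mz <- grid$mass + grid$shift
  grid <- grid[grid$predicted_mz > 0, , drop = FALSE]
  ord <- order(grid$predicted_mz)
  pred <- grid$predicted_mz[ord]
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    mz <- features$mz[i]
    wdw <- mz * ppm_tol * 1e-6 * 1.01
    lo <- findInterval(mz - wdw, pred) + 1
    hi <- findInterval(mz + wdw, pred)
    if (hi < lo) next
    j <- ord[lo:hi]
    ppm_err <- (mz - grid$predicted_mz[j]) / grid$predicted_mz[j] * 1e6
    ok <- abs(ppm_err) <= ppm_tol
    if (!any(ok)) next
    j <- j[ok]
    out[[i]] <- data.frame(
      feature_id = features$feature_id[i],
      compound = grid$compound_id[j],
      compound_name = grid$name[j],
      adduct = grid$adduct[j],
      primary = grid$primary[j],
      predicted_mz = grid$predicted_mz[j],
      ppm_error = ppm_err[ok],
      confidence_level = if (features$feature_id[i] %in% confirmed) 1L
        else 5L,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(feature_id = character(0), compound = character(0),
                      compound_name = character(0), adduct = character(0),
                      primary = logical(0), predicted_mz = numeric(0),
                      ppm_error = numeric(0), confidence_level = integer(0))
  }
  res
}

#' Permutation-based m/z pathway enrichment
#'
#' Mummichog-style enrichment: both the significant set and the full
#' quality-filtered background are annotated by adduct mass matching; a
#' compound counts as hit only through a primary-adduct match (primary
#' ions enforced). Per pathway, the observed overlap is the number of
#' distinct significant compounds; the null redraws `|significant|`
#' features uniformly without replacement from the background `B` times
#' and recomputes the overlap. The add-one-smoothed empirical p is
#' `(1 + #\{null >= observed\}) / (B + 1)`. Pathways are reported only
#' when the observed overlap reaches `min_overlap`; the
#' significant/detected ratio is reported per pathway.
#'
#' @param significant_ids Feature ids of the significant set (subset of
#'   the background).
#' @param background Data frame of all quality-filtered features
#'   (`feature_id`, `mz`).
#' @param reference A `pathway_reference`.
#' @param mode Ionization mode.
#' @param B Number of permutations (default 1000).
#' @param min_overlap Minimum significant-compound overlap to report
#'   (default 3).
#' @param ppm_tol Mass tolerance in ppm.
#' @param seed Integer seed for the permutation draws.
#' @return Data frame (class `enrichment_result`): `pathway`,
#'   `n_significant_hits`, `n_detected_in_pathway`, `ratio`,
#'   `empirical_p`, `B`; attribute `all_pathways` carries the unfiltered
#'   table.
#' @export
enrich_pathways <- function(significant_ids, background, reference, mode,
                            B = 1000, min_overlap = 3, ppm_tol = 5,
                            seed = NULL) {
  stopifnot(B >= 1)
  if (!all(significant_ids %in% background$feature_id)) {
    stop("significant_ids must be a subset of the background features")
  }
  if (length(significant_ids) > nrow(background)) {
    stop("background smaller than significant set")
  }
  ann <- annotate_features(background, reference, mode, ppm_tol = ppm_tol)
  ann <- ann[ann$primary, , drop = FALSE]  # primary ions enforced
  feat_idx <- match(ann$feature_id, background$feature_id)

  # pathway -> compound -> background feature indices
  pw_maps <- lapply(reference$pathways, function(cset) {
    hits <- ann$compound %in% cset
    if (!any(hits)) return(NULL)
    split(feat_idx[hits], ann$compound[hits])
  })

  sig_idx <- match(significant_ids, background$feature_id)
  n_bg <- nrow(background)
  n_sig <- length(sig_idx)

  overlap_count <- function(maps, sel) {
    vapply(maps, function(cmap) {
      if (is.null(cmap)) return(0L)
      sum(vapply(cmap, function(fi) any(sel[fi]), logical(1)))
    }, integer(1))
  }
  sel <- logical(n_bg)
  sel[sig_idx] <- TRUE
  observed <- overlap_count(pw_maps, sel)
  detected <- vapply(pw_maps, function(cmap) length(cmap %||% list()),
                     integer(1))

  null_ge <- integer(length(pw_maps))
  with_seed(seed, {
    for (b in seq_len(B)) {
      sel_b <- logical(n_bg)
      sel_b[sample.int(n_bg, n_sig)] <- TRUE
      null_ge <- null_ge + (overlap_count(pw_maps, sel_b) >= observed)
    }
  })
  p <- (1 + null_ge) / (B + 1)
  full <- data.frame(pathway = names(reference$pathways),
                     n_significant_hits = unname(observed),
                     n_detected_in_pathway = unname(detected),
                     ratio = paste0(observed, "/", detected),
                     empirical_p = unname(p), B = B,
                     stringsAsFactors = FALSE)
  res <- full[full$n_significant_hits >= min_overlap, , drop = FALSE]
  res <- res[order(res$empirical_p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "all_pathways") <- full
  class(res) <- c("enrichment_result", "data.frame")
  res
}
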