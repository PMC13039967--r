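# shared fixtures, built in code

# small single-study config with one planted pathway and one planted
# clinical-metabolite association; used by recovery tests
small_planted_config <- function(seed, n = 150, log2fc = 1,
                                 n_background = 150) {
  sim_config(
    n_subjects = n, cluster_proportions = rep(1 / 3, 3),
    fixed_counts = TRUE, seed = seed,
    studies = list(ST = list(log2_shift = 0, scale = 1)),
    modes = list(hilic_pos = list(n_background = n_background)),
    planted_pathways = list("tryptophan metabolism" =
                              list(cluster = 3, log2fc = log2fc)),
    planted_associations = list(
      list(pathway = "tryptophan metabolism", cluster = 3,
           variable = "alt", r = 0.5)),
    outlier_sample_rate = 0)
}

# well-separated spherical gaussian blobs
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
  })
}

# tiny feature table built by hand
toy_feature_table <- function(intensities, mz = NULL, rt = NULL,
                              replicates = 1, batch = "B1",
                              mode = "hilic_pos") {
  n_feat <- ncol(intensities)
  n_inj <- nrow(intensities)
  n_samp <- n_inj / replicates
  stopifnot(n_samp == round(n_samp))
  samples <- sprintf("S%02d", seq_len(n_samp))
  inj <- data.frame(
    injection = paste0(rep(samples, each = replicates), "_",
                       rep(seq_len(replicates), n_samp)),
    sample = rep(samples, each = replicates),
    replicate = rep(seq_len(replicates), n_samp))
  if (length(batch) == 1) batch <- rep(batch, n_samp)
  feature_table(
    mode = mode,
    features = data.frame(
      feature_id = sprintf("f%03d", seq_len(n_feat)),
      mz = mz %||% (100 + seq_len(n_feat)),
      rt = rt %||% rep(60, n_feat)),
    intensities = as.matrix(intensities),
    injection_map = inj,
    batch_map = data.frame(sample = samples, batch = batch))
}

# hand-made association network over an arbitrary igraph
as_network <- function(g, label = "net") {
  if (is.null(igraph::V(g)$kind)) igraph::V(g)$kind <- "metabolite"
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
  structure(list(label = label, graph = g, n_samples = NA_integer_,
                 communities = NULL, modularity = NA_real_,
                 centrality = NULL),
            class = "association_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
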