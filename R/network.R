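#' Prepare the clinical block for one metabotype
#'
#' Natural-log transforms the skewed variables (ALT, AST, TG, VLDL, LDL,
#' HOMA2-IR), square-root transforms fibrosis stage (handles zeros), leaves
#' the remaining variables untransformed, and z-scales every column.
#'
#' @param table Clinical data frame.
#' @param members Subject ids of the metabotype (non-empty).
#' @param variables Clinical variables to include (default: the ten
#'   clustering variables plus `fibrosis_stage`).
#' @param log_vars Variables natural-log transformed.
#' @return Numeric matrix, members x variables, z-scaled.
#' @export
prepare_clinical_block <- function(table, members,
                                   variables = c(clustering_variables(),
                                                 "fibrosis_stage"),
                                   log_vars = c("alt", "ast", "tg", "vldl",
                                                "ldl", "homa2ir")) {
  if (length(members) == 0) stop("members must be non-empty")
  sub <- table[match(members, table$subject_id), variables, drop = FALSE]
  for (v in intersect(log_vars, variables)) {
    if (any(sub[[v]] <= 0, na.rm = TRUE)) {
      stop("non-positive value in log-transformed column ", v)
    }
    sub[[v]] <- log(sub[[v]])
  }
  if ("fibrosis_stage" %in% variables) {
    sub$fibrosis_stage <- sqrt(sub$fibrosis_stage)
  }
  zscore_scale(as.matrix(sub))$matrix
}

#' Two-block PLS in canonical mode
#'
#' Symmetric two-block partial least squares: latent variables are
#' extracted iteratively to maximize covariance between block variates,
#' with canonical-mode deflation (each block deflated on its own
#' variates and loadings), so neither block is treated as the response.
#' Constant columns are dropped with a warning.
#'
#' @param x,y Numeric matrices with the same rows (x is the reference
#'   block).
#' @param n_comp Number of components (default 3).
#' @return List with `x_variates`, `y_variates`, `x_loadings`,
#'   `y_loadings`, `x_names`, `y_names`, `n`.
#' @export
pls_canonical <- function(x, y, n_comp = 3) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  for (nm in c("x", "y")) {
    m <- get(nm)
    sds <- col_sds(m)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " constant column(s) dropped from ", nm)
      assign(nm, m[, sds > 0, drop = FALSE])
    }
  }
  max_comp <- min(nrow(x) - 1, ncol(x), ncol(y))
  if (n_comp > max_comp) {
    stop("n_comp exceeds the usable rank (max ", max_comp, ")")
  }
  fit <- mixOmics::pls(x, y, ncomp = n_comp, mode = "canonical",
                       scale = TRUE)
  list(x_variates = fit$variates$X, y_variates = fit$variates$Y,
       x_loadings = fit$loadings$X, y_loadings = fit$loadings$Y,
       x_names = colnames(x), y_names = colnames(y), n = nrow(x))
}

#' Association-score matrix from a two-block PLS fit
#'
#' With the shared latent variable `z_h = (t_h + u_h) / 2` (average of the
#' two block variates of component h), the association score between
#' clinical variable i and metabolite j is
#' `r_ij = sum_h cor(X_i, z_h) cor(Y_j, z_h)`, clipped to \[-1, 1\], with
#' a two-sided p from the t distribution on n - 2 degrees of freedom.
#'
#' @param fit A [pls_canonical()] fit.
#' @param x,y The blocks the fit was computed on.
#' @return List with `r` (|x-vars| x |y-vars|) and `p` (same shape).
#' @export
association_matrix <- function(fit, x, y) {
  x <- as.matrix(x)[, fit$x_names, drop = FALSE]
  y <- as.matrix(y)[, fit$y_names, drop = FALSE]
  n <- nrow(x)
  if (n < 4) stop("need at least 4 samples")
  if (any(col_sds(x) == 0) || any(col_sds(y) == 0)) {
    stop("zero-variance column")
  }
  z <- (fit$x_variates + fit$y_variates) / 2
  r <- stats::cor(x, z) %*% t(stats::cor(y, z))
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-tt, n - 2)
  p[abs(r) >= 1] <- 0
  dimnames(r) <- list(fit$x_names, fit$y_names)
  dimnames(p) <- dimnames(r)
  list(r = r, p = p)
}

#' Build a clinical-metabolite association network
#'
#' Keeps an edge between clinical variable i and metabolite j iff
#' `|r_ij| > r_min` (strict) and `p_ij < alpha` (strict); isolated nodes
#' are dropped. The signed score is kept as edge attribute `r`; edge
#' weight is `|r|`.
#'
#' @param r,p Matrices from [association_matrix()] (clinical rows,
#'   metabolite columns).
#' @param r_min Association-score threshold (default 0.3).
#' @param alpha Significance threshold (default 0.05).
#' @param label Network label (e.g. the metabotype name).
#' @param n_samples Number of samples behind the scores.
#' @param metabolite_modes Optional named vector mapping metabolite node
#'   ids to ionization modes.
#' @return An object of class `association_network`: list with `label`,
#'   `graph` (igraph, node attribute `kind` in \{clinical, metabolite\}),
#'   `n_samples`, plus `communities`, `modularity`, `centrality` slots
#'   filled by [detect_communities()] / [network_centrality()].
#' @export
build_network <- function(r, p, r_min = 0.3, alpha = 0.05,
                          label = "network", n_samples = NA_integer_,
                          metabolite_modes = NULL) {
  stopifnot(identical(dim(r), dim(p)))
  keep <- which(abs(r) > r_min & p < alpha, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(r)[keep[, 1]],
    to = colnames(r)[keep[, 2]],
    r = r[keep], p = p[keep],
    weight = abs(r[keep]),
    stringsAsFactors = FALSE)
  nodes <- data.frame(name = unique(c(edges$from, edges$to)),
                      stringsAsFactors = FALSE)
  nodes$kind <- ifelse(nodes$name %in% rownames(r), "clinical",
                       "metabolite")
  nodes$mode <- ifelse(nodes$kind == "metabolite" &
                         !is.null(metabolite_modes),
                       unname(metabolite_modes[nodes$name]), NA_character_)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(label = label, graph = g, n_samples = n_samples,
                 communities = NULL, modularity = NA_real_,
                 centrality = NULL),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat("<association_network>", x$label, "|",
      igraph::vcount(x$graph), "nodes,", igraph::ecount(x$graph),
      "edges\n")
  invisible(x)
}

#' Multilevel (Louvain) community detection
#'
#' Louvain modularity maximization on |r|-weighted edges at resolution 1;
#' the best of `restarts` seeded runs by modularity is kept.
#'
#' @param network An `association_network` with at least one edge.
#' @param seed Integer seed.
#' @param restarts Number of seeded runs (default 10).
#' @return The network with `communities` (named membership vector) and
#'   `modularity` filled in.
#' @export
detect_communities <- function(network, seed = 1, restarts = 10) {
  g <- network$graph
  if (igraph::ecount(g) == 0) stop("empty network")
  best <- NULL
  best_q <- -Inf
  for (s in seq_len(restarts)) {
    memb <- with_seed(derive_seed(seed, paste0("louvain", s)), {
      igraph::membership(igraph::cluster_louvain(
        g, weights = igraph::E(g)$weight, resolution = 1))
    })
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  network$communities <- best
  network$modularity <- best_q
  network
}

#' Eigenvector centrality of an association network
#'
#' Centrality from the dominant eigenvector of the |r|-weighted adjacency
#' matrix of the full (possibly disconnected) graph, scaled so the maximum
#' is 1. On disconnected graphs the mass concentrates on the dominant
#' component; this is flagged in the result.
#'
#' @param network An `association_network` with at least one edge.
#' @return The network with `centrality` (named vector, max 1) filled in
#'   and a `disconnected` flag.
#' @export
network_centrality <- function(network) {
  g <- network$graph
  if (igraph::ecount(g) == 0) stop("empty network")
  ec <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)
  v <- ec$vector
  if (max(v) > 0) v <- v / max(v)
  network$centrality <- v
  network$disconnected <- !igraph::is_connected(g)
  network
}

#' Differential eigenvector centrality between two networks
#'
#' Nodes absent from a network get centrality 0; the comparison is the
#' absolute centrality difference per node, and metabolite nodes with
#' `delta >= threshold` (inclusive) are selected for pairwise pathway
#' enrichment.
#'
#' @param a,b `association_network` objects with centrality computed.
#' @param threshold Selection threshold on |delta| (default 0.025,
#'   inclusive).
#' @return An object of class `centrality_comparison`: list with `pair`
#'   (label), `table` (node, kind, centrality_a, centrality_b, delta,
#'   selected) and `selected` (metabolite node ids).
#' @export
compare_centrality <- function(a, b, threshold = 0.025) {
  ca <- a$centrality %||% stats::setNames(numeric(0), character(0))
  cb <- b$centrality %||% stats::setNames(numeric(0), character(0))
  nodes <- union(names(ca), names(cb))
  va <- ifelse(nodes %in% names(ca), ca[nodes], 0)
  vb <- ifelse(nodes %in% names(cb), cb[nodes], 0)
  kind <- rep("metabolite", length(nodes))
  for (net in list(a, b)) {
    kk <- igraph::V(net$graph)$kind
    names(kk) <- igraph::V(net$graph)$name
    hit <- nodes %in% names(kk)
    kind[hit] <- kk[nodes[hit]]
  }
  delta <- abs(va - vb)
  tab <- data.frame(node = nodes, kind = kind, centrality_a = unname(va),
                    centrality_b = unname(vb), delta = unname(delta),
                    stringsAsFactors = FALSE)
  tab$selected <- tab$kind == "metabolite" & tab$delta >= threshold
  structure(list(pair = paste(a$label, "vs", b$label),
                 table = tab[order(-tab$delta), , drop = FALSE],
                 selected = tab$node[tab$selected],
                 threshold = threshold),
            class = "centrality_comparison")
}

#' Export an association network as GraphML
#'
#' Writes a standards-conformant GraphML file with node attributes
#' (`kind`, `community`, `centrality`) and edge attributes (`r`, `p`),
#' re-importable by generic graph tools.
#'
#' @param network An `association_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  g <- network$graph
  if (!is.null(network$communities)) {
    igraph::V(g)$community <- as.integer(
      network$communities[igraph::V(g)$name])
  }
  if (!is.null(network$centrality)) {
    igraph::V(g)$centrality <- unname(
      network$centrality[igraph::V(g)$name])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
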