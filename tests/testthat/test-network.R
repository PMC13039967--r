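test_that("clinical block applies the declared transforms then z-scales", {
  tab <- data.frame(subject_id = c("a", "b", "c", "d"),
                    alt = c(100, 50, 80, 120),
                    fibrosis_stage = c(0, 1, 4, 2),
                    age = c(10, 12, 14, 16))
  blk <- prepare_clinical_block(tab, c("a", "b", "c", "d"),
                                variables = c("alt", "age",
                                              "fibrosis_stage"),
                                log_vars = "alt")
  # reconstruct the pre-scaling values from the scaled column
  raw_alt <- log(tab$alt)
  expect_equal(blk[, "alt"],
               (raw_alt - mean(raw_alt)) / sd(raw_alt),
               ignore_attr = TRUE)
  raw_fib <- sqrt(c(0, 1, 4, 2))
  expect_equal(blk[, "fibrosis_stage"],
               (raw_fib - mean(raw_fib)) / sd(raw_fib),
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(blk)) < 1e-10))
  tab$alt[1] <- 0
  expect_error(prepare_clinical_block(tab, tab$subject_id,
                                      variables = c("alt", "age"),
                                      log_vars = "alt"),
               "non-positive")
  expect_error(prepare_clinical_block(tab, character(0)), "non-empty")
})

test_that("two-block PLS extracts shared structure with orthogonal variates", {
  with_seed(1, x <- matrix(rnorm(50 * 8), 50, 8))
  colnames(x) <- paste0("v", 1:8)
  fit <- pls_canonical(x, x, n_comp = 3)
  expect_gt(abs(cor(fit$x_variates[, 1], fit$y_variates[, 1])), 1 - 1e-8)
  cross <- crossprod(fit$x_variates)
  expect_lt(max(abs(cross[upper.tri(cross)])), 1e-8)

  # rank-1 planted latent factor is recovered by component 1
  with_seed(2, {
    t_lat <- rnorm(80)
    px <- runif(6)
    qy <- runif(5)
    xx <- outer(t_lat, px) + matrix(rnorm(80 * 6, 0, 0.05), 80)
    yy <- outer(t_lat, qy) + matrix(rnorm(80 * 5, 0, 0.05), 80)
  })
  colnames(xx) <- paste0("x", 1:6)
  colnames(yy) <- paste0("y", 1:5)
  fit2 <- pls_canonical(xx, yy, n_comp = 2)
  expect_gt(abs(cor(fit2$x_variates[, 1], t_lat)), 0.99)
  expect_error(pls_canonical(xx, yy, n_comp = 7), "rank")
})

test_that("association scores find a planted clinical-metabolite pair", {
  with_seed(3, {
    n <- 200
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("clin", 1:5)))
    y <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(NULL, paste0("met", 1:30)))
    y[, 1] <- 0.8 * x[, 1] + sqrt(1 - 0.64) * rnorm(n)
  })
  fit <- pls_canonical(x, y, n_comp = 3)
  am <- association_matrix(fit, x, y)
  expect_true(all(am$r >= -1 & am$r <= 1))
  idx <- which(am$r == max(am$r), arr.ind = TRUE)
  expect_equal(rownames(am$r)[idx[1]], "clin1")
  expect_equal(colnames(am$r)[idx[2]], "met1")
  expect_gt(am$r["clin1", "met1"], 0.3)
  expect_lt(am$p["clin1", "met1"], 0.05)
})

test_that("network construction applies strict |r| and p thresholds", {
  r <- matrix(c(0.31, -0.5, 0.29, 0.1), 2, 2,
              dimnames = list(c("clinA", "clinB"), c("m1", "m2")))
  p <- matrix(c(0.01, 0.01, 0.001, 0.9), 2, 2, dimnames = dimnames(r))
  net <- build_network(r, p, r_min = 0.3, alpha = 0.05)
  g <- net$graph
  ends <- igraph::as_data_frame(g, "edges")
  expect_equal(nrow(ends), 2)
  expect_true(all(sort(ends$r) == c(-0.5, 0.31)))
  # r = 0.29 with tiny p is still excluded; isolated m2 dropped
  expect_false("m2" %in% igraph::V(g)$name)
  expect_setequal(igraph::V(g)$kind[igraph::V(g)$name %in%
                                      c("clinA", "clinB")], "clinical")
})

test_that("Louvain communities reproduce exact modularity cases", {
  # two disconnected triangles: Q = 2 (3/6 - (6/12)^2) = 0.5
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                          directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:6)
  net <- detect_communities(as_network(g), seed = 1)
  expect_equal(net$modularity, 0.5)
  expect_equal(length(unique(net$communities)), 2)
  expect_equal(length(unique(net$communities[c("n1", "n2", "n3")])), 1)

  # complete graph: a single community with modularity ~ 0
  kg <- igraph::make_full_graph(6)
  igraph::V(kg)$name <- paste0("k", 1:6)
  netk <- detect_communities(as_network(kg), seed = 2)
  expect_equal(length(unique(netk$communities)), 1)
  expect_equal(netk$modularity, 0, tolerance = 1e-12)

  # the selected partition beats random partitions of the same graph
  with_seed(3, {
    gr <- igraph::sample_gnp(20, 0.2)
    igraph::V(gr)$name <- paste0("v", 1:20)
  })
  netr <- detect_communities(as_network(gr), seed = 3)
  rand_q <- with_seed(4, {
    replicate(100, igraph::modularity(gr, sample(1:3, 20, replace = TRUE)))
  })
  expect_gte(netr$modularity, max(rand_q))
  expect_error(detect_communities(as_network(igraph::make_empty_graph(
    3, directed = FALSE))), "empty")
})

test_that("eigenvector centrality matches closed forms and a dense oracle", {
  star <- igraph::make_star(5, mode = "undirected")  # center + 4 leaves
  igraph::V(star)$name <- c("c", paste0("l", 1:4))
  net <- network_centrality(as_network(star))
  expect_equal(unname(net$centrality["c"]), 1)
  expect_equal(unname(net$centrality[paste0("l", 1:4)]), rep(0.5, 4),
               tolerance = 1e-10)

  ring <- igraph::make_ring(7)
  igraph::V(ring)$name <- paste0("r", 1:7)
  netr <- network_centrality(as_network(ring))
  expect_equal(unname(netr$centrality), rep(1, 7), tolerance = 1e-10)

  # weighted random graphs against a dense eigendecomposition
  for (s in 1:3) {
    with_seed(s, {
      g <- igraph::sample_gnp(20, 0.25)
      while (igraph::ecount(g) == 0) g <- igraph::sample_gnp(20, 0.25)
      igraph::E(g)$weight <- runif(igraph::ecount(g), 0.3, 1)
      igraph::V(g)$name <- paste0("v", 1:20)
    })
    net <- network_centrality(as_network(g))
    adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                                 sparse = FALSE))
    ev <- eigen(adj, symmetric = TRUE)
    v <- abs(ev$vectors[, which.max(ev$values)])
    v <- v / max(v)
    expect_equal(unname(net$centrality), v, tolerance = 1e-8)
  }
})

test_that("centrality comparison applies the inclusive 0.025 rule", {
  g1 <- igraph::make_graph(c("clin", "m1", "clin", "m2", "clin", "m3"),
                           directed = FALSE)
  igraph::V(g1)$kind <- c("clinical", rep("metabolite", 3))
  a <- as_network(g1, "A")
  a$centrality <- c(clin = 1, m1 = 0.10, m2 = 0.07, m3 = 0.02)
  b <- as_network(g1, "B")
  b$centrality <- c(clin = 1, m1 = 0.07, m2 = 0.045)
  cmp <- compare_centrality(a, b, threshold = 0.025)
  tab <- cmp$table
  expect_equal(tab$delta[tab$node == "m1"], 0.03)
  expect_true("m1" %in% cmp$selected)        # 0.03 >= 0.025
  expect_equal(tab$delta[tab$node == "m2"], 0.025)
  expect_true("m2" %in% cmp$selected)        # inclusive threshold
  expect_false("m3" %in% cmp$selected)       # absent from B: delta 0.02
  expect_false("clin" %in% cmp$selected)     # clinical nodes never selected
  # symmetry of the comparison
  cmp_ba <- compare_centrality(b, a, threshold = 0.025)
  m <- match(cmp$table$node, cmp_ba$table$node)
  expect_equal(cmp$table$delta, cmp_ba$table$delta[m])
  expect_setequal(cmp$selected, cmp_ba$selected)
})

test_that("centrality is invariant to node relabeling", {
  with_seed(5, {
    g <- igraph::sample_gnp(15, 0.3)
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.3, 1)
    igraph::V(g)$name <- paste0("v", 1:15)
  })
  net1 <- network_centrality(as_network(g))
  perm <- sample(15)
  g2 <- igraph::permute(g, perm)
  net2 <- network_centrality(as_network(g2))
  expect_equal(net1$centrality[igraph::V(g)$name],
               net2$centrality[igraph::V(g)$name], tolerance = 1e-8)
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  r <- matrix(c(0.6, -0.45, 0.05, 0.8), 2, 2,
              dimnames = list(c("alt", "ast"), c("m1", "m2")))
  p <- matrix(c(0.001, 0.01, 0.5, 0.001), 2, 2, dimnames = dimnames(r))
  net <- build_network(r, p, label = "t", n_samples = 10)
  net <- detect_communities(net, seed = 1)
  net <- network_centrality(net)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, f)
  back <- igraph::read_graph(f, format = "graphml")
  eb <- igraph::as_data_frame(back, "edges")
  eo <- igraph::as_data_frame(net$graph, "edges")
  m <- match(paste(eo$from, eo$to), paste(eb$from, eb$to))
  expect_false(anyNA(m))
  expect_equal(eb$r[m], eo$r, tolerance = 1e-9)
  expect_equal(eb$p[m], eo$p, tolerance = 1e-9)
  vb <- igraph::as_data_frame(back, "vertices")
  expect_setequal(vb$name, igraph::V(net$graph)$name)
  expect_true(all(c("kind", "community", "centrality") %in% names(vb)))

  # empty network still yields a valid, re-importable file
  empty <- build_network(matrix(0, 1, 1,
                                dimnames = list("a", "b")),
                         matrix(1, 1, 1,
                                dimnames = list("a", "b")))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(empty, f2)
  back2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::ecount(back2), 0)
})
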