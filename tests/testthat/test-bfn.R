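# Band envelopes, correlation matrices, network construction, metrics.

test_that("band envelopes localize frequency content", {
  rate <- 1000
  t <- seq(0, 2, by = 1 / rate)[-1]
  x <- matrix(sin(2 * pi * 10 * t), 1)
  means <- vapply(band_names(), function(b)
    mean(band_envelope(x, rate, b)), numeric(1))
  expect_equal(names(which.max(means)), "alpha2")
  expect_true(all(means[names(means) != "alpha2"] < means["alpha2"]))
  # zero in -> zero out
  z <- band_envelopes(matrix(0, 2, 500), rate, c("delta", "gamma2"))
  expect_true(all(vapply(z, function(e) all(e == 0), logical(1))))
  # band above Nyquist
  expect_error(band_envelope(x, 80, "gamma2"), "Nyquist")
})

test_that("two-tone envelopes agree with a band-pass + Hilbert oracle", {
  rate <- 1000
  t <- seq(0, 2, by = 1 / rate)[-1]
  x <- sin(2 * pi * 5 * t) + 0.8 * sin(2 * pi * 35 * t)
  core <- 300:1700
  for (b in c("theta", "gamma1")) {
    rng <- bfndecode:::band_range(b)
    got <- band_envelope(matrix(x, 1), rate, b)[1, core]
    want <- oracle_band_envelope(x, rate, rng["lo"], rng["hi"])[core]
    expect_lt(abs(mean(got) - mean(want)) / mean(want), 0.10)
  }
})

test_that("correlation matrix is Spearman with forced zero diagonal", {
  set.seed(4)
  env <- matrix(abs(rnorm(3 * 6)), 3)
  p <- correlation_matrix(env)
  expect_equal(diag(unclass(p)), rep(0, 3), ignore_attr = TRUE)
  expect_equal(p[1, 2], p[2, 1])
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(p[i, j], oracle_spearman(env[i, ], env[j, ]),
                 tolerance = 1e-12)
  # monotone copies and reversals
  env2 <- rbind(a = env[1, ], b = env[1, ]^3, c = -env[1, ])
  p2 <- correlation_matrix(env2)
  expect_equal(p2["a", "b"], 1)
  expect_equal(p2["a", "c"], -1)
  # constant row handling
  expect_warning(p3 <- correlation_matrix(rbind(env, 0 * env[1, ])),
                 "constant")
  expect_equal(unname(p3[4, 1:3]), rep(0, 3))
})

test_that("Spearman is invariant to positive per-channel rescaling", {
  set.seed(5)
  env <- matrix(abs(rnorm(4 * 50)), 4)
  p1 <- correlation_matrix(env)
  p2 <- correlation_matrix(env * c(0.1, 3, 7, 100))
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("build_bfn thresholds by cost as specified", {
  # hand-enumerated 4-node example
  p <- matrix(0, 4, 4)
  p[upper.tri(p)] <- c(0.9, 0.7, 0.4, 0.3, 0.2, 0.1)
  p <- p + t(p)
  net <- build_bfn(p, 0.5)
  expect_equal(net$K, 2)
  expect_equal(sort(net$a[upper.tri(net$a)][net$a[upper.tri(net$a)] > 0]),
               c(0.2, 0.4), tolerance = 1e-12)
  # target 0: all positive correlations survive unshifted
  pos <- abs(p)
  net0 <- build_bfn(pos, 0)
  expect_equal(net0$a, pos, ignore_attr = TRUE)
  expect_equal(net0$K, 6)
  # boundary: p == cost everywhere -> empty
  pb <- matrix(0.5, 3, 3); diag(pb) <- 0
  expect_warning(netb <- build_bfn(pb, 0.5), "empty")
  expect_equal(netb$K, 0)
})

test_that("thresholding is monotone in target cost", {
  set.seed(6)
  for (rep in 1:10) {
    p <- matrix(0, 6, 6)
    p[upper.tri(p)] <- runif(15, -1, 1)
    p <- p + t(p)
    ks <- vapply(c(0.05, 0.2, 0.4, 0.6),
                 function(cc) suppressWarnings(build_bfn(p, cc)$K),
                 numeric(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("network metrics match hand-computed archetypes", {
  # complete graph on 5 nodes, weights 0.5
  a <- matrix(0.5, 5, 5); diag(a) <- 0
  nf <- network_features(build_bfn(a + 0.0, 0))
  expect_equal(unname(nf$DVector), rep(4, 5))
  expect_equal(nf$VDegree, 4)
  expect_equal(nf$VPLength, 1)
  expect_equal(nf$Cluster, 1)
  expect_equal(nf$Pbar, 0.5)
  # 5-node path graph: mean pairwise distance 2
  path <- matrix(0, 5, 5)
  for (i in 1:4) path[i, i + 1] <- path[i + 1, i] <- 1
  nfp <- network_features(build_bfn(path, 0))
  expect_equal(nfp$VPLength, 2.0)
  expect_equal(nfp$Cluster, 0)
  # star on 4 nodes: no triangles
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(network_features(build_bfn(star, 0))$Cluster, 0)
})

test_that("disconnected pairs are excluded from the path average", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1                 # one component of 2 + 2 isolated
  nf <- network_features(build_bfn(a, 0))
  expect_equal(nf$VPLength, 1)
  expect_equal(nf$unreachable_pairs, 5)
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:10, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.7))
    net <- suppressWarnings(build_bfn(adj, 0))
    nf <- suppressWarnings(network_features(net))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(nf$DVector), as.numeric(igraph::degree(g)))
    d <- igraph::distances(g)
    ut <- d[upper.tri(d)]
    expect_equal(nf$VPLength,
                 if (any(is.finite(ut))) mean(ut[is.finite(ut)])
                 else NA_real_)
    tr <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    # igraph returns NaN for degree-1 nodes in some versions; treat as 0
    tr[is.nan(tr)] <- 0
    expect_equal(nf$Cluster, mean(tr), tolerance = 1e-12)
  }
})

test_that("analytic small-world clustering reference is exact", {
  expect_equal(ws_clustering_analytic(2, 0.3), 0)
  expect_equal(ws_clustering_analytic(4, 0), 0.5)
  expect_equal(ws_clustering_analytic(6, 0.1), 0.4374)
  expect_error(ws_clustering_analytic(1, 0), ">= 2")
})

test_that("Pbar is bounded by the shifted maximum correlation", {
  set.seed(8)
  for (rep in 1:20) {
    p <- matrix(0, 8, 8)
    p[upper.tri(p)] <- runif(28, -0.5, 1)
    p <- p + t(p)
    net <- suppressWarnings(build_bfn(p, 0.18))
    nf <- suppressWarnings(network_features(net))
    expect_gte(nf$Pbar, 0)
    expect_lte(nf$Pbar, max(max(p) - 0.18, 0) + 1e-12)
  }
})
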