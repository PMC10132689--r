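test_that("strengths follow their definitions and are conserved", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 0.1; W["a", "c"] <- 0.2
  s <- strengths(grooming_network("g", W))
  expect_equal(unname(s$out["a"]), 0.3)
  expect_equal(unname(s$in_["b"]), 0.1)
  for (seed in 1:10) {
    net <- rand_network(sample(3:12, 1), seed = seed)
    s <- strengths(net)
    expect_equal(sum(s$out), sum(s$in_))
    expect_equal(sum(s$out), sum(net$weights))
  }
})

test_that("disparity matches hand values and zero-givers are missing", {
  W <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  W["a", c("b", "c", "d", "e")] <- 0.2        # even split over 4 partners
  W["b", "a"] <- 0.7                          # single partner
  W["c", c("a", "b")] <- c(0.1, 0.3)          # hand value (0.25^2 + 0.75^2)
  Y <- disparity(grooming_network("g", W))
  expect_equal(unname(Y["a"]), 0.25)
  expect_equal(unname(Y["b"]), 1)
  expect_equal(unname(Y["c"]), 0.625)
  expect_true(is.na(Y["d"]))                  # no grooming given -> missing
})

test_that("disparity is bounded by 1/k and 1, and its deviation is non-negative", {
  for (seed in 1:200) {
    net <- rand_network(sample(3:15, 1), seed = seed, density = 0.6)
    Y <- disparity(net)
    k <- out_degree(net)
    ok <- !is.na(Y)
    expect_true(all(Y[ok] <= 1 + 1e-12))
    expect_true(all(Y[ok] >= 1 / k[ok] - 1e-12))
    expect_true(all(Y[ok] - 1 / k[ok] >= -1e-12)) # deviation from disparity
  }
})

test_that("affinity is the weighted mean strength of partners", {
  # two-node network: each node's affinity equals the other's strength
  W <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  W["a", "b"] <- 0.1; W["b", "a"] <- 0.4
  a <- affinity(grooming_network("g", W))
  M <- symmetrize(W); s <- rowSums(M)
  expect_equal(unname(a["a"]), unname(s["b"]))
  expect_equal(unname(a["b"]), unname(s["a"]))

  # 3-node line, hand evaluation from the definition
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 0.1; W["b", "c"] <- 0.2
  a <- affinity(grooming_network("g", W))
  # M: m_ab = 0.1, m_bc = 0.2; s = (0.1, 0.3, 0.2)
  expect_equal(unname(a["b"]), (0.1 * 0.1 + 0.2 * 0.2) / 0.3)

  # regular network: everyone's partners have the same strength s
  W <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(W) <- 0
  a <- affinity(grooming_network("g", W))
  expect_equal(unname(a), rep(1.2, 4)) # s = 3 * 0.4

  # independent brute-force oracle on random networks
  for (seed in 1:25) {
    net <- rand_network(sample(3:10, 1), seed = seed)
    M <- symmetrize(net)
    s <- rowSums(M)
    oracle <- vapply(seq_along(s), function(i) {
      if (s[i] == 0) return(NA_real_)
      sum(vapply(seq_along(s), function(j) M[i, j] * s[j], numeric(1))) / s[i]
    }, numeric(1))
    expect_equal(unname(affinity(net)), oracle)
  }
})

test_that("eigenvector centrality agrees with dense eigendecomposition", {
  # 3-node path: e proportional to (1, sqrt(2), 1)
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- 0.1; W["b", "c"] <- 0.1
  e <- eigenvector_centrality(grooming_network("g", W))
  expect_equal(unname(e), c(1 / sqrt(2), 1, 1 / sqrt(2)), tolerance = 1e-8)

  # complete equal-weight network: all ones; scale invariance
  W <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(W) <- 0
  expect_equal(unname(eigenvector_centrality(grooming_network("g", W))),
               rep(1, 4), tolerance = 1e-9)
  expect_equal(eigenvector_centrality(grooming_network("g", W)),
               eigenvector_centrality(grooming_network("g", 2 * W / 2)))

  # oracle equivalence on 200 random weighted networks
  worst <- 0
  for (seed in 1:200) {
    net <- rand_network(sample(3:15, 1), seed = seed)
    M <- symmetrize(net)
    if (all(M == 0)) next
    e <- suppressWarnings(eigenvector_centrality(net))
    if (isTRUE(attr(e, "disconnected"))) next # oracle below assumes connected
    dense <- eigen(M, symmetric = TRUE)
    v <- abs(dense$vectors[, which.max(dense$values)])
    v <- v / max(v)
    worst <- max(worst, max(abs(unname(e) - v)))
  }
  expect_lt(worst, 1e-8)

  expect_error(eigenvector_centrality(grooming_network("g", W * 0)), "no edges")
})

test_that("disconnected networks are flagged and isolates are missing", {
  W <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  W["a", "b"] <- 0.3; W["c", "d"] <- 0.2 # e isolated
  e <- eigenvector_centrality(grooming_network("g", W))
  expect_true(isTRUE(attr(e, "disconnected")))
  expect_true(is.na(e["e"]))
  expect_equal(max(e, na.rm = TRUE), 1)
})

test_that("group-size standardizations follow their definitions", {
  obs <- toy_obs()
  m <- node_metrics(build_networks(obs), obs$individuals,
                    indirect_min_size = 2L)
  std <- standardize_metrics(m)
  expect_equal(std$out_strength_std, std$out_strength / (std$group_size - 1))
  i <- which(!is.na(std$disparity_dev))
  expect_true(all(std$disparity_dev[i] >= -1e-12))
  # a 0.30 out-strength in a group of 6 standardizes to 0.06
  expect_equal(0.30 / (6 - 1), 0.06)
  for (g in unique(std$group)) {
    a <- std$affinity_scaled[std$group == g]
    if (any(!is.na(a))) expect_equal(max(a, na.rm = TRUE), 1)
  }
})

test_that("indirect measures are withheld from groups below the size minimum", {
  obs <- toy_obs()
  m <- node_metrics(build_networks(obs), obs$individuals, indirect_min_size = 4L)
  expect_true(all(is.na(m$affinity[m$group_size < 4])))
  expect_true(all(is.na(m$eigenvector[m$group_size < 4])))
  expect_false(all(is.na(m$affinity[m$group_size >= 4])))
})

test_that("the correlation screen computes Pearson r and flags |r| > 0.70", {
  m <- data.frame(out_strength = c(1, 2, 3, 4, 5), in_strength = c(5, 4, 3, 2, 1),
                  disparity = c(2, 4, 1, 3, 5), affinity = c(1, 3, 2, 5, 4),
                  eigenvector = c(0.2, 0.4, 0.1, 0.9, 0.5))
  sc <- suppressWarnings(metric_correlation_screen(m))
  expect_equal(diag(sc$r), rep(1, 5), ignore_attr = TRUE)
  expect_equal(sc$r["out_strength", "in_strength"], -1)
  expect_true(sc$pairs$flagged[sc$pairs$measure_1 == "out_strength" &
                                 sc$pairs$measure_2 == "in_strength"])
  expect_equal(sc$r["out_strength", "disparity"],
               stats::cor(m$out_strength, m$disparity))
  # constant column: undefined, reported missing
  m$disparity <- 1
  sc2 <- suppressWarnings(metric_correlation_screen(m))
  expect_true(is.na(sc2$r["out_strength", "disparity"]))
})
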