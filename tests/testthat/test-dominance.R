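test_that("win matrices tally flee-upon-aggression events", {
  obs <- toy_obs()
  win <- build_win_matrix(obs, "A")
  expect_identical(win$wins["a1", "a2"], 2L)
  expect_identical(win$wins["a2", "a1"], 0L)
  expect_true(isSymmetric(win$n))
  expect_warning(build_win_matrix(obs, "C"), "no agonistic events")
  bad <- obs
  bad$agonistic <- data.frame(group = "A", winner = "a1", loser = "b1")
  expect_error(observation_set(obs$individuals, obs$scans, bad$agonistic),
               "outside their group")
})

test_that("dyadic indices apply the chance correction", {
  X <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  X["a", "b"] <- 1L
  idx <- dyadic_indices(win_matrix("g", X))
  expect_equal(idx$P["a", "b"], 1)
  expect_equal(idx$D["a", "b"], 0.75) # 1 - 0.5/2
  X["a", "b"] <- X["b", "a"] <- 3L    # symmetric tie is invariant
  idx <- dyadic_indices(win_matrix("g", X))
  expect_equal(idx$P["a", "b"], 0.5)
  expect_equal(idx$D["a", "b"], 0.5)
  X0 <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  idx <- dyadic_indices(win_matrix("g", X0))
  expect_true(is.na(idx$P["a", "b"]) && is.na(idx$D["a", "b"]))
})

test_that("normalized David's scores match hand values and are conserved", {
  X <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  X["a", "b"] <- 1L
  w <- win_matrix("g", X)
  expect_equal(unname(normalized_davids_scores(w, "Pij")), c(1, 0))
  expect_equal(unname(normalized_davids_scores(w, "Dij")), c(0.75, 0.25))

  for (seed in 1:200) {
    win <- rand_win(sample(3:12, 1), seed = seed)
    N <- length(win$nodes)
    for (method in c("Dij", "Pij")) {
      nds <- normalized_davids_scores(win, method)
      expect_equal(sum(nds), N * (N - 1) / 2)
      expect_equal(sum(center_scores(nds)), 0)
    }
  }
})

test_that("centered scores follow the mean-centering definition", {
  expect_equal(center_scores(c(1, 0)), c(0.5, -0.5))
  X <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  X[upper.tri(X)] <- 1L # perfect linear order a > b > c
  nds <- normalized_davids_scores(win_matrix("g", X), "Pij")
  expect_equal(unname(nds), c(2, 1, 0))
  expect_equal(unname(center_scores(nds)), c(1, 0, -1))
})

test_that("steepness is 1 for a despotic hierarchy and matches hand slopes", {
  X <- matrix(0L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  X[upper.tri(X)] <- 2L
  st <- hierarchy_steepness(win_matrix("g", X), "Pij", n_rand = 200, seed = 7)
  expect_equal(st$steepness, 1)
  expect_lte(st$p, 0.10)

  X2 <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  X2["a", "b"] <- 1L
  st2 <- hierarchy_steepness(win_matrix("g", X2), "Dij", n_rand = 50, seed = 1)
  expect_equal(st2$steepness, 0.5) # slope of (0.75, 0.25) on ranks (1, 2)
})

test_that("steepness p-values are reproducible, bounded and monotone in despotism", {
  win <- rand_win(6, seed = 42, p_unknown = 0)
  a <- hierarchy_steepness(win, n_rand = 300, seed = 9)
  b <- hierarchy_steepness(win, n_rand = 300, seed = 9)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 301)
  expect_lte(a$p, 1)

  # pushing every dyad toward determinism never lowers Pij steepness
  N <- 5
  steep <- vapply(c(0.6, 0.8, 1.0), function(pwin) {
    up_wins <- as.integer(round(10 * pwin))
    U <- matrix(0L, N, N, dimnames = list(paste0("n", 1:N), paste0("n", 1:N)))
    L <- U
    U[upper.tri(U)] <- up_wins
    L[upper.tri(L)] <- 10L - up_wins
    hierarchy_steepness(win_matrix("g", U + t(L)), "Pij", n_rand = 1,
                        seed = 1)$steepness
  }, numeric(1))
  expect_true(all(diff(steep) >= -1e-12))
})

test_that("Landau linearity matches hand values and the brute-force V oracle", {
  X <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  X[upper.tri(X)] <- 1L
  li <- landau_linearity(win_matrix("g", X), n_rand = 100, seed = 5)
  expect_equal(li$h, 1)
  expect_equal(li$h_prime, 1)
  expect_identical(li$u, 0L)

  li0 <- landau_linearity(win_matrix("g", X * 0L), n_rand = 100, seed = 5)
  expect_equal(li0$h, 0)
  expect_equal(li0$h_prime, 0.75) # 6*3 / (27 - 3)
  expect_identical(li0$u, 3L)

  tied <- matrix(1L, 3, 3); diag(tied) <- 0L
  dimnames(tied) <- list(letters[1:3], letters[1:3])
  li_t <- landau_linearity(win_matrix("g", tied), n_rand = 100, seed = 5)
  expect_equal(li_t$h, 0)
  expect_equal(li_t$h_prime, 0)

  expect_error(landau_linearity(win_matrix("g", matrix(0L, 2, 2)), 10), "fewer than 3")

  # independent V-count oracle on random tournaments of size <= 5
  for (seed in 1:50) {
    win <- rand_win(sample(3:5, 1), seed = seed)
    N <- length(win$nodes)
    V <- numeric(N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      if (i == j) next
      if (win$wins[i, j] > win$wins[j, i]) V[i] <- V[i] + 1
      else if (win$wins[i, j] == win$wins[j, i]) V[i] <- V[i] + 0.5
    }
    h_oracle <- 12 / (N^3 - N) * sum((V - (N - 1) / 2)^2)
    li <- landau_linearity(win, n_rand = 1, seed = 1)
    expect_equal(li$h, h_oracle)
  }
})

test_that("group-level dominance analysis is seeded and applies the alpha rule", {
  cfg <- simulation_config(n_groups = 4L, size_range = c(4L, 7L),
                           agonistic_rate = 4, seed = 77L)
  sim <- simulate_study(cfg)
  a <- dominance_analysis(sim$obs, n_rand = 200, seed = 5, alpha = 0.10)
  b <- dominance_analysis(sim$obs, n_rand = 200, seed = 5, alpha = 0.10)
  expect_identical(a$summary, b$summary)
  expect_true(all(a$summary$passes ==
                    (a$summary$p_steepness <= 0.1 & a$summary$p_linearity <= 0.1)))
  if (!is.null(a$scores))
    expect_true(all(abs(tapply(a$scores$centeredDS, a$scores$group, sum)) < 1e-10))
})
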