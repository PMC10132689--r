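# Shared fixtures, all built in code.

# Tiny deterministic 3-group observation set with known grooming structure.
toy_individuals <- function() {
  data.frame(
    group = rep(c("A", "B", "C"), c(3, 4, 3)),
    individual = c("a1", "a2", "a3", "b1", "b2", "b3", "b4", "c1", "c2", "c3"),
    sex = c("male", "female", "female", "male", "male", "female", "female",
            "female", "female", "male"),
    age = c(12, 20, 35, 9, 15, 22, 40, 18, 25, 30),
    rearing = c("mother_reared", "mother_reared", "atypically_reared",
                "mother_reared", "atypically_reared", "mother_reared",
                "mother_reared", "mother_reared", "mother_reared",
                "atypically_reared"),
    stringsAsFactors = FALSE)
}

# one row per (group, scan, individual)
scan_rows <- function(group, scan, inds, groomer = NULL, receiver = NULL,
                      oos = character(0)) {
  data.frame(group = group, scan = scan, individual = inds,
             behavior = ifelse(inds %in% groomer, "groom", "other"),
             partner = ifelse(inds %in% groomer,
                              receiver[match(inds, groomer)], NA_character_),
             visible = !inds %in% oos, stringsAsFactors = FALSE)
}

toy_obs <- function() {
  ind <- toy_individuals()
  scans <- rbind(
    scan_rows("A", 1L, c("a1", "a2", "a3"), groomer = c("a1", "a2"),
              receiver = c("a2", "a1")),                       # mutual bout
    scan_rows("A", 2L, c("a1", "a2", "a3"), groomer = "a3", receiver = "a1"),
    scan_rows("A", 3L, c("a1", "a2", "a3"), oos = "a3"),
    scan_rows("B", 1L, c("b1", "b2", "b3", "b4"), groomer = "b1",
              receiver = "b3"),
    scan_rows("B", 2L, c("b1", "b2", "b3", "b4"), oos = c("b1", "b2")),
    scan_rows("C", 1L, c("c1", "c2", "c3"), groomer = "c2", receiver = "c3"),
    scan_rows("C", 2L, c("c1", "c2", "c3")))
  ag <- data.frame(group = c("A", "A", "B"), winner = c("a1", "a1", "b2"),
                   loser = c("a2", "a2", "b4"), stringsAsFactors = FALSE)
  observation_set(ind, scans, ag)
}

# random weighted directed network on N nodes
rand_network <- function(N, seed, density = 0.7) {
  set.seed(seed)
  W <- matrix(stats::runif(N * N) * (stats::runif(N * N) < density), N, N)
  diag(W) <- 0
  dimnames(W) <- list(paste0("n", seq_len(N)), paste0("n", seq_len(N)))
  grooming_network(paste0("g", seed), W)
}

# random win matrix with dyadic interaction counts up to max_n (some unknown)
rand_win <- function(N, seed, max_n = 4L, p_unknown = 0.2) {
  set.seed(seed)
  X <- matrix(0L, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    if (stats::runif(1) < p_unknown) next
    n <- sample.int(max_n, 1L)
    w <- stats::rbinom(1L, n, 0.5)
    X[i, j] <- w
    X[j, i] <- n - w
  }
  dimnames(X) <- list(paste0("n", seq_len(N)), paste0("n", seq_len(N)))
  win_matrix(paste0("g", seed), X)
}

# 100-scan single-group set: i grooms j in scans 1-10, i and j jointly out of
# sight in scans 81-100 (hand-count oracle: C[i,j] = 10, D[i,j] = 80)
bench_obs <- function() {
  ind <- data.frame(group = "G", individual = c("i", "j", "k"),
                    sex = c("male", "female", "female"), age = c(10, 20, 30),
                    rearing = "mother_reared", stringsAsFactors = FALSE)
  scans <- do.call(rbind, lapply(1:100, function(s) {
    if (s <= 10) scan_rows("G", s, c("i", "j", "k"), groomer = "i",
                           receiver = "j")
    else if (s > 80) scan_rows("G", s, c("i", "j", "k"), oos = c("i", "j"))
    else scan_rows("G", s, c("i", "j", "k"))
  }))
  observation_set(ind, scans)
}
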