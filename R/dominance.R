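# Dominance analytics: flee-upon-aggression win matrices, normalized David's
# scores, hierarchy steepness with a binomial randomization null, and Landau's
# linearity index with the correction for unknown and tied relationships.

#' Flee-upon-aggression win matrix for one group
#'
#' `wins[i, j]` counts the agonistic interactions i won against j (j fled from
#' i). `n = wins + t(wins)` is the per-dyad interaction count.
#'
#' @param obs an `observation_set`.
#' @param group group id.
#' @return a `win_matrix`: list with `group`, `nodes`, `wins`, `n`.
#' @export
build_win_matrix <- function(obs, group) {
  stopifnot(inherits(obs, "observation_set"))
  nodes <- group_members(obs, group)
  ev <- obs$agonistic[obs$agonistic$group == group, , drop = FALSE]
  if (!nrow(ev)) warning("group ", group, " has no agonistic events")
  X <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(ev)) {
    tab <- table(factor(ev$winner, levels = nodes),
                 factor(ev$loser, levels = nodes))
    X <- matrix(as.integer(tab), length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  }
  win_matrix(group, X)
}

#' Construct a validated win matrix
#' @param group group id.
#' @param wins square labeled non-negative integer matrix with zero diagonal.
#' @return a `win_matrix`.
#' @export
win_matrix <- function(group, wins) {
  X <- as.matrix(wins)
  if (nrow(X) != ncol(X)) stop("win matrix must be square")
  if (is.null(rownames(X))) {
    rownames(X) <- colnames(X) <- paste0("id", seq_len(nrow(X)))
  }
  if (!identical(rownames(X), colnames(X)))
    stop("win matrix must have identical row and column labels")
  if (any(X < 0) || any(X != round(X))) stop("win counts must be non-negative integers")
  if (any(diag(X) != 0)) stop("win matrix diagonal must be zero")
  storage.mode(X) <- "integer"
  structure(list(group = as.character(group), nodes = rownames(X), wins = X,
                 n = X + t(X)),
            class = "win_matrix")
}

#' @export
print.win_matrix <- function(x, ...) {
  cat("win_matrix: group", x$group, "-", length(x$nodes), "nodes,",
      sum(x$wins), "decided interactions\n")
  invisible(x)
}

#' Dyadic dominance indices
#'
#' `P[i, j] = wins[i, j] / n[i, j]` is the raw win proportion (NA for unknown
#' dyads). `D[i, j] = P[i, j] - (P[i, j] - 0.5) / (n[i, j] + 1)` is the
#' chance-corrected index, which pulls proportions based on few interactions
#' toward 0.5.
#'
#' @param win a `win_matrix`.
#' @return list with matrices `P` and `D` (NA where `n == 0`).
#' @export
dyadic_indices <- function(win) {
  stopifnot(inherits(win, "win_matrix"))
  n <- win$n
  P <- ifelse(n > 0, win$wins / n, NA_real_)
  D <- P - (P - 0.5) / (n + 1)
  diag(P) <- diag(D) <- NA_real_
  dimnames(P) <- dimnames(D) <- dimnames(win$wins)
  list(P = P, D = D)
}

#' Normalized David's scores
#'
#' With d the chosen dyadic index matrix (unknown dyads contribute 0):
#' `w = rowSums(d)`, `w2 = d %*% w`, `l = colSums(d)`, `l2 = t(d) %*% l`,
#' `DS = w + w2 - l - l2`, and `normDS = (DS + N(N-1)/2) / N`. The normalized
#' scores always sum to `N(N-1)/2`.
#'
#' @param win a `win_matrix`.
#' @param method `"Dij"` (chance-corrected, default) or `"Pij"` (raw win
#'   proportions).
#' @return named numeric vector of normalized David's scores.
#' @export
normalized_davids_scores <- function(win, method = c("Dij", "Pij")) {
  method <- match.arg(method)
  if (length(win$nodes) < 2) stop("David's scores need at least 2 individuals")
  idx <- dyadic_indices(win)
  d <- if (method == "Dij") idx$D else idx$P
  d[is.na(d)] <- 0
  N <- nrow(d)
  w <- rowSums(d)
  w2 <- as.numeric(d %*% w)
  l <- colSums(d)
  l2 <- as.numeric(t(d) %*% l)
  DS <- w + w2 - l - l2
  nds <- (DS + N * (N - 1) / 2) / N
  names(nds) <- win$nodes
  nds
}

#' Mean-center dominance scores within a group
#'
#' Subtracting the group mean (which equals `(N-1)/2` for normalized David's
#' scores) makes scores comparable across groups of different sizes.
#'
#' @param nds normalized David's scores of one group.
#' @return centered scores (sum exactly 0).
#' @export
center_scores <- function(nds) nds - mean(nds)

steepness_of <- function(nds) {
  N <- length(nds)
  ranks <- seq_len(N)
  sorted <- sort(nds, decreasing = TRUE)
  abs(stats::cov(ranks, sorted) / stats::var(ranks))
}

#' Hierarchy steepness with randomization test
#'
#' Steepness is the absolute slope of the normalized David's scores regressed
#' on descending rank (1 = maximally despotic, 0 = egalitarian). The null
#' distribution keeps each dyad's interaction count and redraws wins as
#' Binomial(n, 0.5); the p-value uses the +1 small-sample correction,
#' `p = (#\{null >= observed\} + 1) / (n_rand + 1)`.
#'
#' @param win a `win_matrix`.
#' @param method David's score method, see [normalized_davids_scores()].
#' @param n_rand number of randomizations.
#' @param seed optional integer seed for reproducibility.
#' @return list with `steepness`, `p`, `normDS`, `n_rand`, `method`.
#' @export
hierarchy_steepness <- function(win, method = c("Dij", "Pij"), n_rand = 10000L,
                                seed = NULL) {
  method <- match.arg(method)
  stopifnot(n_rand >= 1)
  nds <- normalized_davids_scores(win, method)
  observed <- steepness_of(nds)
  n <- win$n
  up <- which(upper.tri(n))
  n_up <- n[up]
  nodes <- win$nodes
  null <- with_seed(seed, vapply(seq_len(n_rand), function(r) {
    wins_up <- stats::rbinom(length(n_up), n_up, 0.5)
    U <- matrix(0L, nrow(n), ncol(n), dimnames = list(nodes, nodes))
    L <- U
    U[up] <- as.integer(wins_up)
    L[up] <- as.integer(n_up - wins_up)
    steepness_of(normalized_davids_scores(win_matrix(win$group, U + t(L)),
                                          method))
  }, numeric(1)))
  p <- (sum(null >= observed) + 1) / (n_rand + 1)
  if (sum(win$wins) == 0) { observed <- 0; p <- 1 }
  list(steepness = observed, p = p, normDS = nds, n_rand = n_rand,
       method = method)
}

landau_h_of <- function(V, N) {
  12 / (N^3 - N) * sum((V - (N - 1) / 2)^2)
}

v_counts <- function(wins) {
  X <- wins
  tX <- t(X)
  dominated <- X > tX           # i -> j
  tied_or_unknown <- X == tX    # includes n == 0
  rowSums(dominated) + 0.5 * rowSums(tied_or_unknown) - 0.5 # exclude diagonal
}

#' Landau's linearity index with correction for unknown and tied dyads
#'
#' Each dyad contributes 1 to the winner's V count, or 0.5 to both individuals
#' when tied or unknown. `h = 12/(N^3 - N) * sum((V - (N-1)/2)^2)`;
#' `h' = h + 6u/(N^3 - N)` corrects for the `u` unknown dyads. Significance is
#' assessed against `n_rand` random complete dominance matrices (each dyad's
#' direction a fair coin), with the +1 small-sample correction.
#'
#' @param win a `win_matrix` with at least 3 individuals.
#' @param n_rand number of randomizations.
#' @param seed optional integer seed.
#' @param fill_unknowns if `TRUE`, the observed statistic is the mean `h` over
#'   random completions of the unknown/tied dyads (two-step variant) rather
#'   than the analytically corrected `h'`.
#' @return list with `h`, `h_prime`, `u` (unknown dyads), `p`, `n_rand`.
#' @export
landau_linearity <- function(win, n_rand = 10000L, seed = NULL,
                             fill_unknowns = FALSE) {
  N <- length(win$nodes)
  if (N < 3) stop("Landau's h is undefined for fewer than 3 individuals")
  stopifnot(n_rand >= 1)
  V <- v_counts(win$wins)
  h <- landau_h_of(V, N)
  up <- which(upper.tri(win$n))
  u <- sum(win$n[up] == 0)
  h_prime <- h + 6 * u / (N^3 - N)

  n_dyads <- length(up)
  decided <- win$wins[up] != t(win$wins)[up]
  i_beats_j <- win$wins[up] > t(win$wins)[up]
  rand <- with_seed(seed, {
    filled <- if (fill_unknowns) {
      vapply(seq_len(n_rand), function(r) {
        dir_up <- ifelse(decided, i_beats_j, stats::runif(n_dyads) < 0.5)
        landau_h_of(v_from_directions(dir_up, N), N)
      }, numeric(1))
    }
    null <- vapply(seq_len(n_rand), function(r) {
      landau_h_of(v_from_directions(stats::runif(n_dyads) < 0.5, N), N)
    }, numeric(1))
    list(null = null, filled = filled)
  })
  stat_observed <- if (fill_unknowns) mean(rand$filled) else h_prime
  p <- (sum(rand$null >= stat_observed) + 1) / (n_rand + 1)
  list(h = h, h_prime = h_prime, u = u, p = p, n_rand = n_rand,
       statistic = stat_observed, fill_unknowns = fill_unknowns)
}

# V counts of a complete tournament given upper-triangle directions
# (dir_up[k] TRUE means the lower-index member of dyad k dominates)
v_from_directions <- function(dir_up, N) {
  M <- matrix(FALSE, N, N)
  M[upper.tri(M)] <- dir_up
  Lo <- matrix(FALSE, N, N)
  Lo[upper.tri(Lo)] <- !dir_up
  rowSums(M | t(Lo))
}

#' Group-level dominance analysis
#'
#' Runs the full dominance battery for every group with agonistic data:
#' win matrix, normalized and mean-centered David's scores, steepness and
#' Landau linearity with randomization tests, and the group-inclusion decision
#' (both p-values at or below `alpha`).
#'
#' @param obs an `observation_set`.
#' @param n_rand randomizations per test.
#' @param seed integer seed.
#' @param alpha group-inclusion level (0.10 by convention here: the relaxed
#'   level retains enough groups for rank-age description).
#' @param method David's score method.
#' @return list with `groups` (per-group result lists), `summary` (data.frame:
#'   group, n, steepness, p_steepness, h, h_prime, u, p_linearity, passes) and
#'   `scores` (per-individual centered David's scores of passing groups).
#' @export
dominance_analysis <- function(obs, n_rand = 10000L, seed = NULL, alpha = 0.10,
                               method = c("Dij", "Pij")) {
  method <- match.arg(method)
  grp <- group_summary(obs)
  with_groups <- intersect(grp$group, unique(obs$agonistic$group))
  results <- list()
  summary_rows <- NULL
  scores <- NULL
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             2L * length(with_groups)),
                                  ncol = 2L))
  for (k in seq_along(with_groups)) {
    g <- with_groups[k]
    win <- build_win_matrix(obs, g)
    if (length(win$nodes) < 3) next
    st <- hierarchy_steepness(win, method, n_rand = n_rand, seed = seeds[k, 1L])
    li <- landau_linearity(win, n_rand = n_rand, seed = seeds[k, 2L])
    passes <- st$p <= alpha && li$p <= alpha
    centered <- center_scores(st$normDS)
    results[[g]] <- list(win = win, steepness = st, linearity = li,
                         centered = centered, passes = passes)
    summary_rows <- rbind(summary_rows, data.frame(
      group = g, n = length(win$nodes), n_events = sum(win$wins),
      steepness = st$steepness, p_steepness = st$p, h = li$h,
      h_prime = li$h_prime, u = li$u, p_linearity = li$p, passes = passes,
      stringsAsFactors = FALSE))
    if (passes)
      scores <- rbind(scores, data.frame(group = g, individual = win$nodes,
                                         normDS = unname(st$normDS),
                                         centeredDS = unname(centered),
                                         stringsAsFactors = FALSE))
  }
  list(groups = results, summary = summary_rows, scores = scores,
       alpha = alpha, n_rand = n_rand, seed = seed, method = method)
}
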