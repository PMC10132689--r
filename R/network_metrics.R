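# Node-level grooming network measures and their group-size standardizations.

#' Out- and in-strength
#'
#' Out-strength is the total standardized frequency of grooming given
#' (`sum_j w[i, j]`); in-strength the total received (`sum_j w[j, i]`).
#'
#' @param net a `grooming_network`.
#' @return list with named numeric vectors `out` and `in_`.
#' @export
strengths <- function(net) {
  stopifnot(inherits(net, "grooming_network"))
  list(out = rowSums(net$weights), in_ = colSums(net$weights))
}

#' Disparity of grooming relationships
#'
#' `Y(i) = sum_j (w[i, j] / s_out(i))^2` over i's out-going edges: 1/k when
#' grooming is divided evenly over k partners, 1 when a single partner receives
#' everything. Undefined (NA) for individuals that gave no grooming.
#'
#' @param net a `grooming_network`.
#' @param edges `"out"` (grooming given, default) or `"total"` (symmetrized
#'   edges).
#' @return named numeric vector, NA for nodes with zero strength on the chosen
#'   edge set.
#' @export
disparity <- function(net, edges = c("out", "total")) {
  edges <- match.arg(edges)
  W <- if (edges == "out") net$weights else symmetrize(net)
  s <- rowSums(W)
  Y <- rep(NA_real_, length(s))
  names(Y) <- net$nodes
  pos <- s > 0
  if (any(pos))
    Y[pos] <- rowSums((W[pos, , drop = FALSE] / s[pos])^2)
  Y
}

#' Number of distinct grooming partners (out-degree)
#'
#' Counts partners receiving a strictly positive weight from the node.
#'
#' @param net a `grooming_network`.
#' @return named integer vector.
#' @export
out_degree <- function(net) {
  k <- rowSums(net$weights > 0)
  storage.mode(k) <- "integer"
  k
}

#' Affinity: weighted mean strength of a node's partners
#'
#' Computed on the symmetrized matrix `M = W + t(W)` with node strengths
#' `s(i) = sum_j m[i, j]`: `a(i) = sum_j m[i, j] * s(j) / s(i)`. High affinity
#' means a preference for grooming with high-strength ("popular") individuals.
#' NA for isolated nodes.
#'
#' @param net a `grooming_network`.
#' @param weighted if `FALSE`, use the unweighted mean strength over partners
#'   instead of the edge-weighted mean.
#' @return named numeric vector.
#' @export
affinity <- function(net, weighted = TRUE) {
  M <- symmetrize(net)
  s <- rowSums(M)
  a <- rep(NA_real_, length(s))
  names(a) <- net$nodes
  pos <- s > 0
  if (weighted) {
    a[pos] <- (M %*% s)[pos] / s[pos]
  } else {
    for (i in which(pos)) a[i] <- mean(s[M[i, ] > 0])
  }
  a
}

#' Eigenvector centrality by power iteration
#'
#' Leading eigenvector of the symmetrized weight matrix, non-negative and
#' scaled so the group maximum is 1. Computed by shifted power iteration
#' (`M + cI` with `c` = the largest row sum, which makes the dominant
#' eigenvalue strictly largest in magnitude so the iteration converges even on
#' bipartite-like structures). If the network is disconnected the vector is
#' computed per connected component (each component max-scaled to 1) and the
#' result carries `attr(, "disconnected") = TRUE`; isolated nodes get NA.
#'
#' @param net a `grooming_network` or symmetric matrix.
#' @param tol convergence tolerance on the max absolute change per iteration.
#' @param max_iter iteration cap.
#' @return named numeric vector in `[0, 1]` (NA for isolates).
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 100000L) {
  # symmetrize() doubles an already-symmetric input; eigenvectors are
  # invariant under that scaling, so both network and matrix inputs are fine
  M <- symmetrize(if (inherits(net, "grooming_network")) net$weights else net)
  if (all(M == 0)) stop("no edges: eigenvector centrality is undefined")
  nodes <- rownames(M)
  N <- nrow(M)

  comp <- integer(N)
  cur <- 0L
  for (i in seq_len(N)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      frontier <- i
      comp[i] <- cur
      while (length(frontier)) {
        nb <- which(colSums(M[frontier, , drop = FALSE] > 0) > 0)
        nb <- nb[comp[nb] == 0L]
        comp[nb] <- cur
        frontier <- nb
      }
    }
  }

  e <- rep(NA_real_, N)
  names(e) <- nodes
  nontrivial <- 0L
  for (cc in seq_len(cur)) {
    idx <- which(comp == cc)
    if (length(idx) < 2L || all(M[idx, idx] == 0)) next # isolate
    nontrivial <- nontrivial + 1L
    A <- M[idx, idx, drop = FALSE]
    shift <- max(rowSums(A))
    v <- rep(1 / sqrt(length(idx)), length(idx))
    for (it in seq_len(max_iter)) {
      v_new <- A %*% v + shift * v
      v_new <- v_new / sqrt(sum(v_new^2))
      if (max(abs(v_new - v)) < tol) { v <- v_new; break }
      v <- v_new
    }
    v <- abs(as.numeric(v))
    e[idx] <- v / max(v)
  }
  if (all(is.na(e))) stop("no edges: eigenvector centrality is undefined")
  if (cur > 1L) attr(e, "disconnected") <- TRUE
  e
}

#' Per-individual network measures for a whole study
#'
#' Computes the five node measures for every individual in every group and
#' joins individual traits and group covariates. Indirect measures (affinity,
#' eigenvector centrality) are reported only for groups with at least
#' `indirect_min_size` members, since they are not biologically meaningful in
#' very small networks. Nodes with zero grooming activity get NA (never a
#' silent zero) for disparity, affinity and eigenvector centrality.
#'
#' @param networks named list of `grooming_network` (see [build_networks()]).
#' @param individuals individual metadata data.frame (`group`, `individual`,
#'   `sex`, `age`, `rearing`).
#' @param indirect_min_size minimum group size for indirect measures.
#' @return data.frame, one row per individual-in-group, with columns
#'   `group`, `individual`, `sex`, `age`, `rearing`, `group_size`, `sex_ratio`,
#'   `out_strength`, `in_strength`, `degree`, `disparity`, `affinity`,
#'   `eigenvector`.
#' @export
node_metrics <- function(networks, individuals, indirect_min_size = 5L) {
  obs <- observation_set(individuals)
  grp <- group_summary(obs)
  rows <- lapply(names(networks), function(g) {
    net <- networks[[g]]
    s <- strengths(net)
    N <- length(net$nodes)
    indirect_ok <- N >= indirect_min_size
    a <- if (indirect_ok) affinity(net) else rep(NA_real_, N)
    ev <- if (indirect_ok && any(net$weights > 0)) {
      suppressWarnings(eigenvector_centrality(net))
    } else rep(NA_real_, N)
    data.frame(group = g, individual = net$nodes,
               out_strength = as.numeric(s$out), in_strength = as.numeric(s$in_),
               degree = out_degree(net), disparity = as.numeric(disparity(net)),
               affinity = as.numeric(a), eigenvector = as.numeric(ev),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- merge(obs$individuals, tab, by = c("group", "individual"), all.y = TRUE)
  tab <- merge(tab, grp[, c("group", "group_size", "sex_ratio")], by = "group")
  ord <- order(tab$group, tab$individual)
  tab <- tab[ord, c("group", "individual", "sex", "age", "rearing",
                    "group_size", "sex_ratio", "out_strength", "in_strength",
                    "degree", "disparity", "affinity", "eigenvector")]
  rownames(tab) <- NULL
  tab
}

#' Group-size standardizations of the node measures
#'
#' Adds: `out_strength_std` and `in_strength_std` (strength divided by the
#' number of available grooming partners, N - 1); `disparity_dev`, the
#' deviation from edge-weight disparity (observed Y minus 1/k, the value
#' expected when grooming is divided evenly over the node's k partners; always
#' >= 0); `affinity_scaled` and `eigenvector_scaled` (each individual scaled to
#' the maximum value within their own network, so every group maximum is 1).
#'
#' @param metrics output of [node_metrics()].
#' @return the input data.frame with the five standardized columns appended.
#' @export
standardize_metrics <- function(metrics) {
  if (any(metrics$group_size < 2)) stop("groups of size 1 cannot be standardized")
  out <- metrics
  out$out_strength_std <- out$out_strength / (out$group_size - 1)
  out$in_strength_std <- out$in_strength / (out$group_size - 1)
  out$disparity_dev <- ifelse(out$degree >= 1,
                              out$disparity - 1 / out$degree, NA_real_)
  scale_max <- function(x) {
    m <- suppressWarnings(max(x, na.rm = TRUE))
    if (!is.finite(m) || m == 0) return(rep(NA_real_, length(x)))
    x / m
  }
  out$affinity_scaled <- stats::ave(out$affinity, out$group, FUN = scale_max)
  out$eigenvector_scaled <- stats::ave(out$eigenvector, out$group, FUN = scale_max)
  out
}

#' Inter-measure correlation screen
#'
#' Pearson correlations among the five node measures over all individual-in-
#' group records. Measures are meant to enter separate models; any pair with
#' `|r|` above the threshold is flagged for exclusion.
#'
#' @param metrics output of [node_metrics()].
#' @param threshold absolute correlation above which a pair is flagged.
#' @return list with `r` and `p` (5 x 5 matrices), `pairs` (data.frame of the
#'   10 pairs with r, p and `flagged`), and `flagged` (subset with `|r|` >
#'   threshold).
#' @export
metric_correlation_screen <- function(metrics, threshold = 0.70) {
  vars <- c("out_strength", "in_strength", "disparity", "affinity", "eigenvector")
  X <- metrics[, vars]
  if (sum(stats::complete.cases(X)) < 3)
    stop("need at least 3 complete records for the correlation screen")
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  pairs <- NULL
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    ok <- stats::complete.cases(X[, c(i, j)])
    xi <- X[ok, i]; xj <- X[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      rij <- NA_real_; pij <- NA_real_
    } else {
      ct <- stats::cor.test(xi, xj, method = "pearson")
      rij <- unname(ct$estimate); pij <- ct$p.value
    }
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- pij
    pairs <- rbind(pairs, data.frame(measure_1 = vars[i], measure_2 = vars[j],
                                     r = rij, p = pij, n = sum(ok),
                                     flagged = isTRUE(abs(rij) > threshold),
                                     stringsAsFactors = FALSE))
  }
  if (any(pairs$flagged))
    warning("measure pair(s) exceed |r| > ", threshold, ": ",
            paste(paste(pairs$measure_1[pairs$flagged],
                        pairs$measure_2[pairs$flagged], sep = "-"),
                  collapse = ", "))
  list(r = r, p = p, pairs = pairs, flagged = pairs[pairs$flagged, , drop = FALSE])
}
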