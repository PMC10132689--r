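# From scan records to directed, weighted, observation-effort-standardized
# grooming networks.

#' Tally grooming counts and dyadic denominators for one group
#'
#' For each ordered dyad (i, j), `counts[i, j]` is the number of scans in which
#' i groomed j. The dyadic denominator `denom[i, j]` is the total number of
#' scans minus the number of scans in which i and j were *simultaneously* out
#' of sight: when both are invisible it is unknown whether they groomed, so
#' those scans carry no information about the dyad. A scan where only one of
#' the two is invisible still counts in the denominator.
#'
#' @param obs an `observation_set`.
#' @param group group id.
#' @return a `grooming_counts` object: list with `group`, `nodes` (sorted id
#'   vector), `counts` (N x N integer), `denom` (N x N integer, symmetric),
#'   `n_scans` (total scans for the group).
#' @export
tally_grooming <- function(obs, group) {
  stopifnot(inherits(obs, "observation_set"))
  nodes <- group_members(obs, group)
  sc <- obs$scans[obs$scans$group == group, , drop = FALSE]
  if (!nrow(sc)) stop("group ", group, " has no scans")
  scan_ids <- sort(unique(sc$scan))
  S <- length(scan_ids)
  N <- length(nodes)

  C <- matrix(0L, N, N, dimnames = list(nodes, nodes))
  gr <- sc[!is.na(sc$partner) & sc$behavior == "groom", , drop = FALSE]
  if (nrow(gr)) {
    multi <- duplicated(paste(gr$scan, gr$individual, sep = "\r"))
    if (any(multi))
      warning("actor grooming more than one receiver within a single scan in group ",
              group, "; all pairs counted")
    tab <- table(factor(gr$individual, levels = nodes),
                 factor(gr$partner, levels = nodes))
    C <- C + matrix(as.integer(tab), N, N, dimnames = list(nodes, nodes))
  }

  # out-of-sight indicator per (scan, individual); missing rows treated as visible
  V <- matrix(FALSE, S, N, dimnames = list(scan_ids, nodes))
  oos <- sc[!sc$visible, , drop = FALSE]
  if (nrow(oos))
    V[cbind(match(oos$scan, scan_ids), match(oos$individual, nodes))] <- TRUE
  joint <- crossprod(V) # scans with both i and j out of sight
  D <- matrix(S, N, N, dimnames = list(nodes, nodes)) - joint
  storage.mode(D) <- "integer"

  if (any(C > D))
    stop("inconsistent records in group ", group,
         ": more grooming scans than jointly observable scans for some dyad")
  structure(list(group = group, nodes = nodes, counts = C, denom = D,
                 n_scans = S),
            class = "grooming_counts")
}

#' @export
print.grooming_counts <- function(x, ...) {
  cat("grooming_counts: group", x$group, "-", length(x$nodes), "nodes,",
      x$n_scans, "scans,", sum(x$counts), "grooming records\n")
  invisible(x)
}

#' Construct a grooming network (validated container)
#'
#' @param group group id.
#' @param weights square labeled numeric matrix with zero diagonal and finite
#'   weights in `[0, 1]`.
#' @param counts optional `grooming_counts` provenance.
#' @return a `grooming_network`.
#' @export
grooming_network <- function(group, weights, counts = NULL) {
  W <- as.matrix(weights)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (is.null(rownames(W)) || !identical(rownames(W), colnames(W)))
    stop("weight matrix must have identical row and column labels")
  if (any(!is.finite(W))) stop("weights must be finite")
  if (any(W < 0 | W > 1)) stop("weights must lie in [0, 1]")
  if (any(diag(W) != 0)) stop("weight matrix diagonal must be zero")
  structure(list(group = as.character(group), nodes = rownames(W),
                 weights = W, counts = counts),
            class = "grooming_network")
}

#' @export
print.grooming_network <- function(x, ...) {
  cat("grooming_network: group", x$group, "-", length(x$nodes), "nodes,",
      sum(x$weights > 0), "directed edges, total weight",
      format(sum(x$weights), digits = 4), "\n")
  invisible(x)
}

#' Index-of-interactions edge weights
#'
#' Standardizes raw grooming counts for observation effort:
#' `w[i, j] = counts[i, j] / denom[i, j]`, the proportion of jointly
#' observable scans in which i groomed j. With no out-of-sight scans the
#' denominator reduces to the total number of scans.
#'
#' @param counts a `grooming_counts` object.
#' @param shared_denominator if `TRUE`, divide every count by the group's total
#'   number of scans instead of the per-dyad denominator.
#' @return a `grooming_network`.
#' @export
index_of_interactions <- function(counts, shared_denominator = FALSE) {
  stopifnot(inherits(counts, "grooming_counts"))
  C <- counts$counts
  D <- if (shared_denominator) {
    matrix(counts$n_scans, nrow(C), ncol(C), dimnames = dimnames(C))
  } else counts$denom
  if (any(D == 0 & C > 0))
    stop("dyad with grooming but zero jointly observable scans in group ",
         counts$group)
  if (any(D == 0 & C == 0)) {
    warning("dyad(s) never jointly observable in group ", counts$group,
            "; their weight is set to 0")
  }
  W <- ifelse(D > 0, C / D, 0)
  diag(W) <- 0
  dimnames(W) <- dimnames(C)
  grooming_network(counts$group, W, counts = counts)
}

#' Symmetrized edge weights
#'
#' Total dyadic grooming rate `M = W + t(W)`, used for affinity and
#' eigenvector centrality.
#'
#' @param net a `grooming_network` or a square numeric matrix.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
symmetrize <- function(net) {
  W <- if (inherits(net, "grooming_network")) net$weights else as.matrix(net)
  W + t(W)
}

#' Build all grooming networks of a study
#'
#' @param obs an `observation_set`.
#' @param shared_denominator see [index_of_interactions()].
#' @return named list of `grooming_network`, one per group.
#' @export
build_networks <- function(obs, shared_denominator = FALSE) {
  groups <- group_summary(obs)$group
  nets <- lapply(groups, function(g)
    index_of_interactions(tally_grooming(obs, g),
                          shared_denominator = shared_denominator))
  names(nets) <- groups
  nets
}
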