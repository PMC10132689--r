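# Adjacency matrices and the study archive (plain-text analogue of a
# supplementary workbook: metadata sheet + one adjacency sheet per group +
# published per-individual metric values).

#' Write a labeled adjacency matrix to CSV
#'
#' Weights are serialized with 17 significant digits so that
#' `read_adjacency(write_adjacency(x))` reproduces them bit-exactly.
#'
#' @param net a `grooming_network` (see [index_of_interactions()]) or a square
#'   labeled numeric matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_adjacency <- function(net, path) {
  W <- if (inherits(net, "grooming_network")) net$weights else as.matrix(net)
  if (nrow(W) != ncol(W)) stop("adjacency matrix must be square")
  if (is.null(rownames(W)) || is.null(colnames(W)))
    stop("adjacency matrix must carry row and column labels")
  lines <- c(paste(c("", colnames(W)), collapse = ","),
             vapply(seq_len(nrow(W)), function(i) {
               paste(c(rownames(W)[i], sprintf("%.17g", W[i, ])), collapse = ",")
             }, character(1)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a labeled adjacency matrix from CSV
#'
#' Accepts both point and comma decimal separators in the weight cells (comma
#' decimals are common in European exports).
#'
#' @param path path to a labeled square CSV as written by [write_adjacency()].
#' @param group optional group id to attach; defaults to the file name.
#' @return a `grooming_network`.
#' @export
read_adjacency <- function(path, group = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, header = TRUE, row.names = 1, check.names = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  M <- as.matrix(raw)
  num <- suppressWarnings(matrix(as.numeric(M), nrow(M), ncol(M)))
  if (anyNA(num)) { # retry with decimal commas
    num <- suppressWarnings(matrix(as.numeric(gsub(",", ".", M, fixed = TRUE)),
                                   nrow(M), ncol(M)))
  }
  if (anyNA(num)) stop("non-numeric cells in adjacency file: ", path)
  dimnames(num) <- dimnames(raw)
  if (nrow(num) != ncol(num)) stop("adjacency matrix is not square: ", path)
  if (!identical(rownames(num), colnames(num)))
    stop("row and column labels differ in adjacency file: ", path)
  if (is.null(group))
    group <- sub("\\.[^.]*$", "", basename(path))
  grooming_network(group, num)
}

#' Write a study archive
#'
#' The study archive is the package's plain-text exchange format for a whole
#' multi-group study: `individuals.csv` (metadata), `groups.csv` (composition
#' summary), `metrics.csv` (per individual-in-group network-measure values),
#' `agonistic.csv` (optional) and `matrices/<group>.csv` (one labeled
#' adjacency matrix per group). It mirrors the layout of a supplementary
#' workbook with one metadata sheet plus per-group matrix sheets.
#'
#' @param archive a list with elements `individuals`, `networks` (named list of
#'   `grooming_network`), and optionally `metrics` and `agonistic`, e.g. as
#'   returned by [synthetic_bonobo_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_study_archive <- function(archive, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(archive$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  grp <- group_summary(observation_set(archive$individuals))
  utils::write.csv(grp, file.path(dir, "groups.csv"), row.names = FALSE)
  if (!is.null(archive$metrics))
    utils::write.csv(archive$metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
  if (!is.null(archive$agonistic) && nrow(archive$agonistic))
    utils::write.csv(archive$agonistic, file.path(dir, "agonistic.csv"),
                     row.names = FALSE)
  for (nm in names(archive$networks))
    write_adjacency(archive$networks[[nm]], file.path(dir, "matrices",
                                                      paste0(nm, ".csv")))
  invisible(dir)
}

#' Read a study archive
#'
#' Validates referential integrity: every adjacency matrix must be square with
#' identical, consistently ordered row/column labels matching the group's
#' metadata members.
#'
#' @param dir archive directory (see [write_study_archive()]).
#' @return a list of class `study_archive` with `individuals`, `groups`,
#'   `metrics` (or `NULL`), `agonistic` (or `NULL`) and `networks`.
#' @export
read_study_archive <- function(dir) {
  if (!dir.exists(dir)) stop("archive directory not found: ", dir)
  ind <- utils::read.csv(file.path(dir, "individuals.csv"),
                         stringsAsFactors = FALSE)
  obs <- observation_set(ind) # validates metadata
  grp <- group_summary(obs)
  mfiles <- list.files(file.path(dir, "matrices"), pattern = "\\.csv$",
                       full.names = TRUE)
  networks <- lapply(mfiles, read_adjacency)
  names(networks) <- vapply(networks, function(n) n$group, character(1))
  for (nm in names(networks)) {
    members <- group_members(obs, nm)
    if (!identical(sort(networks[[nm]]$nodes), members))
      stop("adjacency labels for group ", nm,
           " do not match the metadata member list")
  }
  missing <- setdiff(grp$group, names(networks))
  if (length(missing))
    stop("no adjacency matrix for group(s): ", paste(missing, collapse = ", "))
  metrics <- NULL
  if (file.exists(file.path(dir, "metrics.csv")))
    metrics <- utils::read.csv(file.path(dir, "metrics.csv"),
                               stringsAsFactors = FALSE)
  agonistic <- NULL
  if (file.exists(file.path(dir, "agonistic.csv")))
    agonistic <- utils::read.csv(file.path(dir, "agonistic.csv"),
                                 stringsAsFactors = FALSE)
  structure(list(individuals = ind, groups = grp, metrics = metrics,
                 agonistic = agonistic, networks = networks),
            class = "study_archive")
}

#' @export
print.study_archive <- function(x, ...) {
  cat("study_archive:", nrow(x$groups), "group(s),", nrow(x$individuals),
      "individual-in-group record(s)\n")
  invisible(x)
}
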