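#' @keywords internal
"_PACKAGE"

SEX_LEVELS <- c("female", "male")
REARING_LEVELS <- c("mother_reared", "atypically_reared")

#' Assemble a validated observation set
#'
#' An observation set bundles everything recorded for one multi-group
#' scan-sampling study: per-individual metadata (one row per individual *in a
#' group*, since the same animal may be observed in several group
#' compositions), the long-format scan records, and ad libitum agonistic
#' events. All downstream stages (network construction, node metrics,
#' dominance, mixed models) consume this object.
#'
#' @param individuals data.frame with columns `group`, `individual`, `sex`
#'   (`"female"`/`"male"`), `age` (years, numeric), `rearing`
#'   (`"mother_reared"`/`"atypically_reared"`).
#' @param scans data.frame with columns `group`, `scan` (integer ordinal
#'   within group), `individual`, `behavior` (`"groom"` or anything else),
#'   `partner` (receiver id when `behavior == "groom"`, otherwise `NA`),
#'   `visible` (logical; `FALSE` = out of sight during that scan). A mutual
#'   grooming bout appears as two rows (A grooms B and B grooms A).
#' @param agonistic optional data.frame with columns `group`, `winner`,
#'   `loser` (the loser fled from the winner).
#'
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(individuals, scans = NULL, agonistic = NULL) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  need <- c("group", "individual", "sex", "age", "rearing")
  miss <- setdiff(need, names(individuals))
  if (length(miss))
    stop("individuals table is missing column(s): ", paste(miss, collapse = ", "))
  individuals$group <- as.character(individuals$group)
  individuals$individual <- as.character(individuals$individual)
  individuals$age <- as.numeric(individuals$age)

  if (anyNA(individuals$age) || any(individuals$age < 0))
    stop("ages must be non-negative numbers")
  bad_sex <- !individuals$sex %in% SEX_LEVELS
  if (any(bad_sex))
    stop("unknown sex value(s): ", paste(unique(individuals$sex[bad_sex]), collapse = ", "))
  bad_rear <- !individuals$rearing %in% REARING_LEVELS
  if (any(bad_rear))
    stop("unknown rearing value(s): ", paste(unique(individuals$rearing[bad_rear]), collapse = ", "))
  if (anyDuplicated(individuals[, c("group", "individual")]))
    stop("duplicated (group, individual) rows in the metadata table")
  if (any(individuals$age < 7))
    warning("individuals younger than 7 years present; the analysis conventions assume adults only")

  if (!is.null(scans)) {
    scans <- as.data.frame(scans, stringsAsFactors = FALSE)
    need <- c("group", "scan", "individual", "behavior", "partner", "visible")
    miss <- setdiff(need, names(scans))
    if (length(miss))
      stop("scan table is missing column(s): ", paste(miss, collapse = ", "))
    scans$group <- as.character(scans$group)
    scans$individual <- as.character(scans$individual)
    scans$partner <- as.character(scans$partner)
    scans$scan <- as.integer(scans$scan)
    scans$visible <- as.logical(scans$visible)
    if (anyNA(scans$scan))
      stop("malformed scan table: non-integer scan index at row(s) ",
           paste(utils::head(which(is.na(scans$scan)), 5L), collapse = ", "))
    key <- paste(scans$group, scans$individual, sep = "\r")
    known <- paste(individuals$group, individuals$individual, sep = "\r")
    unknown <- !key %in% known
    if (any(unknown))
      stop("scan table references unknown (group, individual) at row(s): ",
           paste(utils::head(which(unknown), 10L), collapse = ", "))
    dup <- duplicated(paste(scans$group, scans$scan, scans$individual, sep = "\r"))
    if (any(dup))
      stop("duplicate (group, scan, individual) records at row(s): ",
           paste(utils::head(which(dup), 10L), collapse = ", "))
    grooming <- !is.na(scans$partner) & scans$behavior == "groom"
    if (any(grooming & scans$individual == scans$partner))
      stop("self-grooming records (actor == receiver) at row(s): ",
           paste(utils::head(which(grooming & scans$individual == scans$partner), 10L),
                 collapse = ", "))
    pk <- paste(scans$group[grooming], scans$partner[grooming], sep = "\r")
    if (any(!pk %in% known))
      stop("grooming partner outside the group at row(s): ",
           paste(utils::head(which(grooming)[!pk %in% known], 10L), collapse = ", "))
    if (any(grooming & !scans$visible))
      stop("grooming recorded for an out-of-sight individual at row(s): ",
           paste(utils::head(which(grooming & !scans$visible), 10L), collapse = ", "))
  } else {
    scans <- data.frame(group = character(), scan = integer(),
                        individual = character(), behavior = character(),
                        partner = character(), visible = logical(),
                        stringsAsFactors = FALSE)
  }

  if (!is.null(agonistic)) {
    agonistic <- as.data.frame(agonistic, stringsAsFactors = FALSE)
    need <- c("group", "winner", "loser")
    miss <- setdiff(need, names(agonistic))
    if (length(miss))
      stop("agonistic table is missing column(s): ", paste(miss, collapse = ", "))
    agonistic$group <- as.character(agonistic$group)
    agonistic$winner <- as.character(agonistic$winner)
    agonistic$loser <- as.character(agonistic$loser)
    known <- paste(individuals$group, individuals$individual, sep = "\r")
    bad <- !(paste(agonistic$group, agonistic$winner, sep = "\r") %in% known) |
           !(paste(agonistic$group, agonistic$loser, sep = "\r") %in% known)
    if (any(bad))
      stop("agonistic events reference ids outside their group at row(s): ",
           paste(utils::head(which(bad), 10L), collapse = ", "))
    if (any(agonistic$winner == agonistic$loser))
      stop("agonistic events with winner == loser")
  } else {
    agonistic <- data.frame(group = character(), winner = character(),
                            loser = character(), stringsAsFactors = FALSE)
  }

  structure(list(individuals = individuals, scans = scans, agonistic = agonistic),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  g <- group_summary(x)
  cat("observation_set:", nrow(g), "group(s),", nrow(x$individuals),
      "individual-in-group record(s),", length(unique(x$individuals$individual)),
      "unique individual(s)\n")
  cat("  scans:", nrow(x$scans), "row(s);  agonistic events:", nrow(x$agonistic), "\n")
  invisible(x)
}

#' Per-group composition summary
#'
#' Group size is the number of adults with metadata rows; the sex ratio is the
#' number of adult males divided by the number of adult females.
#'
#' @param obs an `observation_set`.
#' @return data.frame with `group`, `group_size`, `n_males`, `n_females`,
#'   `sex_ratio`.
#' @export
group_summary <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  ind <- obs$individuals
  sp <- split(ind, ind$group)
  out <- do.call(rbind, lapply(sp, function(d) {
    nm <- sum(d$sex == "male"); nf <- sum(d$sex == "female")
    data.frame(group = d$group[1L], group_size = nrow(d), n_males = nm,
               n_females = nf, sex_ratio = if (nf > 0) nm / nf else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Members of one group
#' @param obs an `observation_set`.
#' @param group group id.
#' @return character vector of individual ids, sorted.
#' @export
group_members <- function(obs, group) {
  m <- obs$individuals$individual[obs$individuals$group == group]
  if (!length(m)) stop("unknown group: ", group)
  sort(m)
}

#' Read scan-sampling tables from delimited text
#'
#' The on-disk schema is long format: one row per individual per scan. See
#' [observation_set()] for the column definitions. Metadata and (optionally)
#' agonistic events live in companion files with the documented headers.
#'
#' @param scans_path path to the scan table CSV.
#' @param individuals_path path to the individual metadata CSV.
#' @param agonistic_path optional path to the agonistic-event CSV
#'   (`group,winner,loser`).
#' @param sep field separator, comma by default.
#' @return an `observation_set`.
#' @export
read_scan_table <- function(scans_path, individuals_path, agonistic_path = NULL,
                            sep = ",") {
  for (p in c(scans_path, individuals_path, agonistic_path))
    if (!file.exists(p)) stop("file not found: ", p)
  ind <- utils::read.table(individuals_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  sc <- utils::read.table(scans_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  ag <- if (!is.null(agonistic_path))
    utils::read.table(agonistic_path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  observation_set(ind, sc, ag)
}

#' Write scan-sampling tables as delimited text
#'
#' Inverse of [read_scan_table()]; `read_scan_table(write_scan_table(x))`
#' round-trips all fields.
#'
#' @param obs an `observation_set`.
#' @param scans_path,individuals_path,agonistic_path output paths; the
#'   agonistic file is written only when a path is given.
#' @return invisibly, the paths written.
#' @export
write_scan_table <- function(obs, scans_path, individuals_path,
                             agonistic_path = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  utils::write.csv(obs$individuals, individuals_path, row.names = FALSE)
  utils::write.csv(obs$scans, scans_path, row.names = FALSE)
  if (!is.null(agonistic_path))
    utils::write.csv(obs$agonistic, agonistic_path, row.names = FALSE)
  invisible(c(scans_path, individuals_path, agonistic_path))
}
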