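# A deterministic synthetic multi-group bonobo study that reproduces the
# published composition structure of the zoo study this pipeline targets:
# 22 compositionally different groups (sizes 3-15, median 6; male/female sex
# ratios 0.20-2.00 with 14 female-biased groups), 84 unique adults observed
# 1-4 times each for 136 individual-in-group records, with the published
# sex-by-rearing sample sizes. Grooming scans and agonistic events are drawn
# from the synthetic generator, so all network and model *values* are
# synthetic; only the composition structure mirrors the real study.

#' Group composition table of the synthetic bonobo study
#'
#' 22 groups whose sizes (3-15, median 6, two groups below the indirect-measure
#' minimum of 5), adult male/female splits (51 male and 85 female records) and
#' sex-ratio distribution (0.20-2.00; 14 female-biased, 3 male-biased, 5 even)
#' match the published multi-group composition.
#'
#' @return data.frame with `group`, `n_males`, `n_females`.
#' @export
bonobo_group_table <- function() {
  data.frame(
    group = sprintf("G%02d", 1:22),
    n_males   = c(2, 2, 2, 2, 1, 3, 2, 1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 2, 2, 3, 4, 4),
    n_females = c(1, 2, 3, 3, 4, 2, 3, 5, 5, 5, 4, 4, 4, 3, 3, 3, 2, 5, 5, 4, 4, 11),
    stringsAsFactors = FALSE)
}

# unique-individual pool: sex, rearing, number of group compositions observed
# in (84 uniques -> 136 records; 48 observed once, 25 twice, 6 thrice,
# 5 four times; datapoint counts 39/12/62/23 for MM/MA/FM/FA)
bonobo_individual_pool <- function() {
  pool <- rbind(
    data.frame(sex = "male", rearing = "mother_reared",
               n_obs = rep(c(4L, 3L, 2L, 1L), c(2, 1, 7, 14))),
    data.frame(sex = "male", rearing = "atypically_reared",
               n_obs = rep(c(2L, 1L), c(3, 6))),
    data.frame(sex = "female", rearing = "mother_reared",
               n_obs = rep(c(4L, 3L, 2L, 1L), c(3, 4, 6, 26))),
    data.frame(sex = "female", rearing = "atypically_reared",
               n_obs = rep(c(3L, 2L, 1L), c(1, 9, 2))))
  pool$individual <- sprintf("%s%02d", ifelse(pool$sex == "male", "M", "F"),
                             stats::ave(seq_len(nrow(pool)), pool$sex,
                                        FUN = seq_along))
  pool
}

# Schedule individuals of one sex into group slots: each individual appears in
# as many *different* groups as its multiplicity. Greedy largest-remaining-
# multiplicity-first, processing groups by descending slot count; determinist.
schedule_members <- function(pool, slots) {
  remaining <- stats::setNames(pool$n_obs, pool$individual)
  assign <- vector("list", length(slots))
  names(assign) <- names(slots)
  for (g in names(sort(slots, decreasing = TRUE))) {
    ord <- order(-remaining, names(remaining))
    take <- names(remaining)[ord][remaining[ord] > 0][seq_len(slots[[g]])]
    if (anyNA(take)) stop("infeasible membership schedule")
    assign[[g]] <- sort(take)
    remaining[take] <- remaining[take] - 1L
  }
  if (any(remaining != 0)) stop("unused observations in membership schedule")
  assign[names(slots)]
}

#' Synthetic multi-group bonobo study (stand-in for the real study data)
#'
#' Deterministically constructs the composition described in
#' [bonobo_group_table()] and [bonobo_individual_pool()], then simulates scan
#' records and agonistic events with the default generator settings. Three
#' individuals in large groups are made fully peripheral (they never groom and
#' are never groomed), so the indirect-measure analysis set comprises 126
#' records from the 20 groups with at least 5 members, matching the published
#' analysis sample. Ages are fixed per individual, span 7-45 years
#' (males) and 7-71 years (females).
#'
#' All grooming and agonistic *values* are synthetic; do not read network or
#' model estimates from this object as empirical results.
#'
#' @param seed integer master seed.
#' @param config optional [simulation_config()] overriding the generator
#'   defaults (its `n_groups`/`size_range` are ignored; the fixed composition
#'   is used).
#' @return list of class `study_archive` with `individuals`, `groups`,
#'   `metrics` (computed five measures per record), `agonistic`, `networks`,
#'   plus `obs` (the full `observation_set`), `truth` and `isolates`.
#' @export
synthetic_bonobo_study <- function(seed = 20230426L, config = NULL) {
  grp <- bonobo_group_table()
  pool <- bonobo_individual_pool()

  males <- schedule_members(pool[pool$sex == "male", ],
                            stats::setNames(grp$n_males, grp$group))
  females <- schedule_members(pool[pool$sex == "female", ],
                              stats::setNames(grp$n_females, grp$group))
  ind <- do.call(rbind, lapply(grp$group, function(g)
    data.frame(group = g, individual = c(males[[g]], females[[g]]),
               stringsAsFactors = FALSE)))
  ind <- merge(ind, pool[, c("individual", "sex", "rearing")],
               by = "individual", sort = FALSE)

  seeds <- child_seeds(seed, 4L)
  ages <- with_seed(seeds[1L], {
    a <- ifelse(pool$sex == "male",
                7 + 38 * stats::rbeta(nrow(pool), 1.1, 3),
                7 + 64 * stats::rbeta(nrow(pool), 1.1, 3))
    a <- round(a, 1)
    # pin the published age-range endpoints on once-observed individuals
    a[match(c("M22", "M23", "F50", "F51"), pool$individual)] <- c(7, 45, 7, 71)
    stats::setNames(a, pool$individual)
  })
  ind$age <- unname(ages[ind$individual])
  ind <- ind[order(ind$group, ind$individual),
             c("group", "individual", "sex", "age", "rearing")]
  rownames(ind) <- NULL

  if (is.null(config)) config <- simulation_config(seed = seed)
  truth <- with_seed(seeds[2L], make_truth(ind, config))

  # fully peripheral animals in three of the largest groups: never groom,
  # never groomed (their indirect measures are undefined, as in the real
  # analysis set of 126 records from 20 groups)
  isolates <- data.frame(group = c("G20", "G21", "G22"), stringsAsFactors = FALSE)
  isolates$individual <- vapply(isolates$group, function(g) {
    cand <- ind[ind$group == g & ind$sex == "female" &
                  ind$rearing == "mother_reared", "individual"]
    sort(cand)[1L]
  }, character(1))
  for (k in seq_len(nrow(isolates))) {
    P <- truth$p_groom[[isolates$group[k]]]
    P[isolates$individual[k], ] <- 0
    P[, isolates$individual[k]] <- 0
    truth$p_groom[[isolates$group[k]]] <- P
  }

  pop <- list(individuals = ind, truth = truth)
  obs <- simulate_scans(pop, config, seed = seeds[3L])
  ag <- simulate_agonistic(pop, config, seed = seeds[4L])
  obs <- observation_set(ind, obs$scans, ag)

  networks <- build_networks(obs)
  metrics <- node_metrics(networks, ind)

  structure(list(individuals = ind,
                 groups = group_summary(obs),
                 metrics = metrics,
                 agonistic = obs$agonistic,
                 networks = networks,
                 obs = obs, truth = truth, isolates = isolates,
                 seed = seed),
            class = c("synthetic_bonobo_study", "study_archive"))
}
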