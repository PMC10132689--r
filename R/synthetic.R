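# Seeded synthetic scan-sampling data with known ground truth, so every
# pipeline stage is testable end to end: multi-group populations with
# realistic compositions, per-scan dyadic grooming driven by planted
# individual effects on the logistic scale, visibility missingness, and
# dyadic agonistic events driven by latent dominance values.

#' Simulation configuration
#'
#' Defaults emulate a multi-group zoo study: 22 groups of 3-15 adults,
#' male-to-female sex ratios within 0.20-2.00, ages 7-71 years, 274-1103 scans
#' per group, and low visibility missingness (zoo animals are easy to see).
#' The grooming model puts a giver propensity on the logistic scale,
#' `g_i = b0 + b_sex_male*male + b_rearing*atypical + b_age*age_p +
#' b_age2*age_p^2 + e_i` with `age_p = age - age_peak`, plus a receiver effect
#' (females receive more), a female-female assortment bonus and dyadic noise;
#' the per-scan, per-ordered-dyad grooming probability is
#' `plogis(g_i + r_j + d_ij)`. The intercept is calibrated so the
#' population-average out-strength is about 0.08, the scale of observed male
#' grooming effort. Latent dominance follows a quadratic age trend per sex
#' (female peak near 35 years, male minimum near 25, females above males on
#' average).
#'
#' @param n_groups number of groups.
#' @param size_range inclusive group-size range (adults).
#' @param sex_ratio_range admissible male/female ratio range.
#' @param age_range age range in years.
#' @param p_atypical probability of an atypical rearing history.
#' @param p_reobserve probability that a group slot is filled by re-observing
#'   an already-created animal of the right sex (animals transfer between
#'   groups or are observed in several compositions, giving the repeated
#'   measurements the individual random intercept controls for).
#' @param n_scans_range per-group scan count range.
#' @param p_out_of_sight per-individual, per-scan probability of being out of
#'   sight.
#' @param b0 giver intercept (logit scale).
#' @param b_sex_male,b_rearing,b_age,b_age2 planted fixed effects on the giver
#'   propensity (logit scale); `b_rearing` applies to atypically reared
#'   animals, `b_age2` to squared age centered at `age_peak`.
#' @param age_peak age (years) at which the quadratic age effect peaks.
#' @param giver_sd,receiver_sd,dyad_sd standard deviations of the individual
#'   giver, individual receiver and dyadic noise terms (logit scale).
#' @param r_female receiver bonus for female receivers (logit scale).
#' @param sex_assort extra logit for female-female dyads.
#' @param agonistic_rate expected agonistic events per unordered dyad.
#' @param dom_age2 curvature of the latent dominance age trends.
#' @param seed integer seed (mandatory; generators are pure functions of the
#'   configuration).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_groups = 22L,
                              size_range = c(3L, 15L),
                              sex_ratio_range = c(0.20, 2.00),
                              age_range = c(7, 71),
                              p_atypical = 0.26,
                              p_reobserve = 0.35,
                              n_scans_range = c(274L, 1103L),
                              p_out_of_sight = 0.05,
                              b0 = -4.0,
                              b_sex_male = -0.05,
                              b_rearing = -0.45,
                              b_age = 0,
                              b_age2 = -0.0025,
                              age_peak = 25,
                              giver_sd = 0.35,
                              receiver_sd = 0.30,
                              dyad_sd = 0.30,
                              r_female = 0.25,
                              sex_assort = 0.30,
                              agonistic_rate = 1.5,
                              dom_age2 = 0.003,
                              seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(size_range[1] >= 3, p_atypical >= 0, p_atypical <= 1,
            p_out_of_sight >= 0, p_out_of_sight <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a multi-group population with ground truth
#'
#' Draws group compositions (size and sex split honouring the admissible
#' sex-ratio range), individual traits (sex, age, rearing) and the latent
#' grooming and dominance values of the generative model.
#'
#' @param config a [simulation_config()].
#' @return list with `individuals` (metadata data.frame) and `truth` (list:
#'   planted coefficients, per-individual giver/receiver/dominance values,
#'   per-group grooming probability matrices).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    groups <- lapply(seq_len(config$n_groups), function(k) {
      for (attempt in 1:100) {
        N <- sample_range(config$size_range[1], config$size_range[2])
        m <- sample_range(1L, N - 1L)
        f <- N - m
        ratio <- m / f
        if (ratio >= config$sex_ratio_range[1] &&
            ratio <= config$sex_ratio_range[2])
          return(list(id = sprintf("G%02d", k), n_males = m, n_females = f))
      }
      stop("could not draw an admissible group composition")
    })
    # fill group slots, re-observing existing animals of the right sex with
    # probability p_reobserve (never twice in the same group)
    animals <- data.frame(individual = character(), sex = character(),
                          stringsAsFactors = FALSE)
    rows <- list()
    for (g in groups) {
      members <- character(0)
      for (sx in c(rep("male", g$n_males), rep("female", g$n_females))) {
        pool <- setdiff(animals$individual[animals$sex == sx], members)
        if (length(pool) && stats::runif(1) < config$p_reobserve) {
          id <- sample(pool, 1L)
        } else {
          id <- sprintf("%s%03d", toupper(substr(sx, 1, 1)),
                        sum(animals$sex == sx) + 1L)
          animals <- rbind(animals, data.frame(individual = id, sex = sx,
                                               stringsAsFactors = FALSE))
        }
        members <- c(members, id)
      }
      rows[[g$id]] <- data.frame(group = g$id, individual = members,
                                 stringsAsFactors = FALSE)
    }
    ind <- do.call(rbind, rows)
    span <- diff(config$age_range)
    animals$age <- round(config$age_range[1] +
                           span * stats::rbeta(nrow(animals), 1.1, 3), 1)
    animals$rearing <- ifelse(stats::runif(nrow(animals)) < config$p_atypical,
                              "atypically_reared", "mother_reared")
    ind <- merge(ind, animals, by = "individual", sort = FALSE)
    ind <- ind[order(ind$group, ind$individual),
               c("group", "individual", "sex", "age", "rearing")]
    rownames(ind) <- NULL
    truth <- make_truth(ind, config)
    list(individuals = ind, truth = truth)
  })
}

# Latent values and per-group grooming probability matrices. Consumes RNG.
# Giver, receiver and dominance noise are animal-level (shared across the
# records of a re-observed animal), which is what the individual random
# intercept of the model stage estimates.
make_truth <- function(ind, config) {
  uniq <- unique(ind$individual)
  at <- match(ind$individual, uniq)
  g_noise <- stats::rnorm(length(uniq), 0, config$giver_sd)
  r_noise <- stats::rnorm(length(uniq), 0, config$receiver_sd)
  dom_noise <- stats::rnorm(length(uniq), 0, 0.5)
  age_p <- ind$age - config$age_peak
  g <- config$b0 +
    config$b_sex_male * (ind$sex == "male") +
    config$b_rearing * (ind$rearing == "atypically_reared") +
    config$b_age * age_p + config$b_age2 * age_p^2 +
    g_noise[at]
  r <- config$r_female * (ind$sex == "female") + r_noise[at]
  dom <- ifelse(ind$sex == "female",
                1 - config$dom_age2 * (ind$age - 35)^2,
                -1 + config$dom_age2 * (ind$age - 25)^2) +
    dom_noise[at]
  key <- paste(ind$group, ind$individual)
  p_groom <- lapply(split(seq_len(nrow(ind)), ind$group), function(rows) {
    ids <- ind$individual[rows]
    N <- length(ids)
    P <- matrix(0, N, N, dimnames = list(ids, ids))
    for (a in seq_len(N)) for (b in seq_len(N)) {
      if (a == b) next
      eta <- g[rows[a]] + r[rows[b]] +
        config$sex_assort * (ind$sex[rows[a]] == "female" &&
                             ind$sex[rows[b]] == "female") +
        stats::rnorm(1, 0, config$dyad_sd)
      P[a, b] <- stats::plogis(eta)
    }
    P
  })
  list(coefficients = config[c("b0", "b_sex_male", "b_rearing", "b_age",
                               "b_age2", "age_peak")],
       giver = stats::setNames(g, key), receiver = stats::setNames(r, key),
       dominance = stats::setNames(dom, key), p_groom = p_groom)
}

#' Simulate scan-sampling records
#'
#' For every scan each individual is independently out of sight with the
#' configured probability; every ordered dyad with both members visible grooms
#' with its ground-truth probability, and when an actor draws several
#' receivers in one scan only the strongest draw is kept (instantaneous scan
#' sampling records one activity per individual).
#'
#' @param population output of [simulate_population()].
#' @param config the same [simulation_config()].
#' @param seed optional seed for the scan stage (defaults to a child of
#'   `config$seed`).
#' @return an `observation_set` (without agonistic events).
#' @export
simulate_scans <- function(population, config, seed = NULL) {
  ind <- population$individuals
  truth <- population$truth
  if (is.null(seed)) seed <- child_seeds(config$seed, 2L)[1L]
  scans <- with_seed(seed, {
    res <- lapply(sort(unique(ind$group)), function(gid) {
      ids <- ind$individual[ind$group == gid]
      N <- length(ids)
      S <- sample_range(config$n_scans_range[1], config$n_scans_range[2])
      P <- truth$p_groom[[gid]][ids, ids]
      visible <- matrix(stats::runif(S * N) >= config$p_out_of_sight, S, N)
      # draws for every (scan, actor, receiver); actor keeps the max draw
      U <- array(stats::runif(S * N * N), dim = c(S, N, N))
      groom_to <- matrix(NA_integer_, S, N)
      for (a in seq_len(N)) {
        Ua <- U[, a, ] # S x N receivers
        succ <- sweep(Ua, 2, 1 - P[a, ], ">") & visible &
          visible[, a] & col(Ua) != a
        Ua[!succ] <- -1
        hit <- rowSums(succ) > 0
        groom_to[hit, a] <- max.col(Ua, ties.method = "first")[hit]
      }
      data.frame(group = gid,
                 scan = rep(seq_len(S), N),
                 individual = rep(ids, each = S),
                 behavior = ifelse(is.na(as.vector(groom_to)), "other", "groom"),
                 partner = ids[as.vector(groom_to)],
                 visible = as.vector(visible),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  scans$behavior[!scans$visible] <- NA
  observation_set(ind, scans)
}

#' Simulate ad libitum agonistic events
#'
#' Per unordered dyad the event count is Poisson with the configured rate; each
#' event is won by i with probability `plogis(dom_i - dom_j)`.
#'
#' @param population output of [simulate_population()].
#' @param config the same [simulation_config()].
#' @param seed optional seed (defaults to a child of `config$seed`).
#' @return data.frame with `group`, `winner`, `loser`.
#' @export
simulate_agonistic <- function(population, config, seed = NULL) {
  ind <- population$individuals
  dom <- population$truth$dominance
  if (is.null(seed)) seed <- child_seeds(config$seed, 2L)[2L]
  with_seed(seed, {
    rows <- lapply(sort(unique(ind$group)), function(gid) {
      ids <- ind$individual[ind$group == gid]
      di <- dom[paste(gid, ids)]
      out <- NULL
      for (a in seq_along(ids)) for (b in seq_along(ids)) {
        if (a >= b) next
        k <- stats::rpois(1, config$agonistic_rate)
        if (!k) next
        a_wins <- stats::rbinom(1, k, stats::plogis(di[a] - di[b]))
        if (a_wins)
          out <- rbind(out, data.frame(group = gid, winner = ids[a],
                                       loser = ids[b],
                                       stringsAsFactors = FALSE)[rep(1, a_wins), ])
        if (k - a_wins)
          out <- rbind(out, data.frame(group = gid, winner = ids[b],
                                       loser = ids[a],
                                       stringsAsFactors = FALSE)[rep(1, k - a_wins), ])
      }
      out
    })
    do.call(rbind, rows)
  })
}

#' Simulate a response directly from the linear mixed model
#'
#' Generates `X beta + u_individual + u_group + e` on a prepared design table,
#' for calibration and parameter-recovery checks of the model stage in
#' isolation from the scan-sampling machinery.
#'
#' @param design a table with `individual`, `group` and the predictor columns
#'   (e.g. from [prepare_design()] or [simulate_population()] +
#'   [node_metrics()]).
#' @param beta named numeric vector of true coefficients; names must match
#'   `model.matrix` column names for `terms` (e.g. `"(Intercept)"`,
#'   `"sexmale"`, `"age_sq"`, `"sexmale:age_c"`); unnamed terms are 0.
#' @param terms fixed-effect term labels used to build the design matrix.
#' @param sd_individual,sd_group,sd_resid standard deviations of the random
#'   intercepts and residual.
#' @param seed optional integer seed.
#' @return numeric response vector aligned with `design` rows.
#' @export
simulate_lmm_response <- function(design, beta, terms = full_fixed_terms(),
                                  sd_individual = 0.01, sd_group = 0.01,
                                  sd_resid = 0.03, seed = NULL) {
  X <- stats::model.matrix(stats::reformulate(terms), data = design)
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  bad <- setdiff(names(beta), names(b))
  if (length(bad)) stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
  b[names(beta)] <- beta
  with_seed(seed, {
    u_i <- stats::rnorm(length(unique(design$individual)), 0, sd_individual)
    u_g <- stats::rnorm(length(unique(design$group)), 0, sd_group)
    as.numeric(X %*% b) +
      u_i[match(design$individual, unique(design$individual))] +
      u_g[match(design$group, unique(design$group))] +
      stats::rnorm(nrow(design), 0, sd_resid)
  })
}

#' Simulate a complete study
#'
#' Population, scan records and agonistic events in one call.
#'
#' @param config a [simulation_config()].
#' @return list with `obs` (an `observation_set` including agonistic events)
#'   and `truth`.
#' @export
simulate_study <- function(config) {
  pop <- simulate_population(config)
  obs <- simulate_scans(pop, config)
  ag <- simulate_agonistic(pop, config)
  obs <- observation_set(pop$individuals, obs$scans, ag)
  list(obs = obs, truth = pop$truth)
}
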