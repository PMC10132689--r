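test_that("design preparation centers age and filters indirect responses", {
  st <- synthetic_bonobo_study(seed = 101L)
  m <- st$metrics
  d <- suppressMessages(prepare_design(m, "out_strength", screen_outliers = FALSE))
  expect_equal(mean(d$age_c), 0)
  expect_equal(d$age_sq, d$age_c^2)
  expect_identical(levels(d$sex), c("female", "male"))
  expect_identical(levels(d$rearing), c("mother_reared", "atypically_reared"))

  d_ind <- suppressMessages(prepare_design(m, "affinity", screen_outliers = FALSE))
  expect_true(all(d_ind$group_size >= 5))
  expect_true(all(!is.na(d_ind$affinity)))
  expect_lt(nrow(d_ind), nrow(d))

  m$eigenvector <- NA_real_
  expect_error(prepare_design(m, "eigenvector"), "missing for every row")
})

test_that("ages centered at the mean are arithmetic: (10,20,30) -> (-10,0,10)", {
  m <- data.frame(group = "G", individual = c("a", "b", "c"),
                  sex = "female", age = c(10, 20, 30), rearing = "mother_reared",
                  group_size = 3, sex_ratio = 0.5, out_strength = c(1, 2, 3))
  d <- prepare_design(m, "out_strength", screen_outliers = FALSE)
  expect_equal(d$age_c, c(-10, 0, 10))
  expect_equal(d$age_sq, c(100, 0, 100))
})

test_that("Rosner's test flags the planted outlier and only it", {
  x <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 100)
  expect_identical(rosner_outliers(x, max_k = 3, alpha = 0.05), 10L)
  expect_length(rosner_outliers(rep(5, 12), max_k = 3), 0)

  # independent reimplementation of the generalized ESD procedure
  gesd_oracle <- function(x, k, alpha) {
    y <- x; removed <- integer(0); R <- lam <- numeric(k)
    for (i in 1:k) {
      z <- abs(y - mean(y)) / stats::sd(y)
      star <- which.max(z)
      R[i] <- z[star]
      removed <- c(removed, which(x == y[star] & !(seq_along(x) %in% removed))[1])
      y <- y[-star]
      n <- length(x) - i + 1
      p <- 1 - alpha / (2 * n)
      t <- stats::qt(p, n - 2)
      lam[i] <- (n - 1) * t / sqrt((n - 2 + t^2) * n)
    }
    n_out <- if (any(R > lam)) max(which(R > lam)) else 0
    sort(removed[seq_len(n_out)])
  }
  for (seed in 1:30) {
    set.seed(seed)
    x <- stats::rnorm(25)
    if (seed %% 3 == 0) x[1:2] <- x[1:2] + 8 # plant outliers sometimes
    expect_identical(sort(rosner_outliers(x, max_k = 4, alpha = 0.05)),
                     as.integer(gesd_oracle(x, 4, 0.05)))
  }
})

test_that("Rosner false-positive rate on clean data stays near alpha", {
  set.seed(404)
  hits <- vapply(1:500, function(i)
    length(rosner_outliers(stats::rnorm(30), max_k = 3, alpha = 0.05)) > 0,
    logical(1))
  expect_lt(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("VIF matches its definition and catches the uncentered-age trap", {
  set.seed(1)
  d <- data.frame(a = stats::rnorm(50), b = stats::rnorm(50), c = stats::rnorm(50))
  v <- vif_check(d, c("a", "b", "c"))
  expect_true(all(abs(v$vif - 1) < 0.5)) # near-orthogonal draws
  d$dup <- d$a
  expect_true(is.infinite(vif_check(d, c("a", "b", "dup"))$vif[
    vif_check(d, c("a", "b", "dup"))$term == "dup"]))

  ages <- seq(7, 45, length.out = 40)
  raw <- data.frame(age = ages, age2 = ages^2, z = stats::rnorm(40))
  cen <- data.frame(age = ages - mean(ages), z = raw$z)
  cen$age2 <- cen$age^2
  expect_true(all(vif_check(raw, c("age", "age2"))$vif > 5))
  expect_true(all(vif_check(cen, c("age", "age2"))$vif < 5))

  # cross-check against the standard car implementation
  skip_if_not_installed("car")
  set.seed(2)
  d2 <- data.frame(x1 = stats::rnorm(60), x2 = stats::rnorm(60))
  d2$x3 <- d2$x1 * 0.8 + stats::rnorm(60, 0, 0.5)
  d2$y <- stats::rnorm(60)
  ours <- vif_check(d2, c("x1", "x2", "x3"))
  theirs <- car::vif(stats::lm(y ~ x1 + x2 + x3, data = d2))
  expect_equal(ours$vif, unname(theirs[ours$term]), tolerance = 1e-10)
})

test_that("the mixed model recovers a planted quadratic age effect within 2 SE", {
  cfg <- simulation_config(n_groups = 33L, seed = 31L)
  pop <- simulate_population(cfg)
  m <- pop$individuals
  m$group_size <- stats::ave(m$age, m$group, FUN = length)
  m$sex_ratio <- stats::ave(m$sex == "male", m$group,
                            FUN = function(s) sum(s) / sum(!s))
  d <- prepare_design(cbind(m, out_strength = 0), "out_strength",
                      screen_outliers = FALSE)
  beta2 <- -5e-5
  d$out_strength <- simulate_lmm_response(
    d, c("(Intercept)" = 0.08, "age_sq" = beta2,
         "rearingatypically_reared" = -0.03),
    sd_individual = 0.01, sd_group = 0.01, sd_resid = 0.03, seed = 99L)
  d$response <- d$out_strength
  fit <- suppressMessages(fit_lmm(d, full_fixed_terms()))
  est <- fit$coefficients[fit$coefficients$term == "age_sq", ]
  expect_lt(abs(est$estimate - beta2), 2 * est$se)
  expect_lt(est$estimate, 0)
})

test_that("type-I error of the model stage is calibrated at the 5% level", {
  cfg <- simulation_config(n_groups = 25L, seed = 13L)
  pop <- simulate_population(cfg)
  m <- pop$individuals
  m$group_size <- stats::ave(m$age, m$group, FUN = length)
  m$sex_ratio <- stats::ave(m$sex == "male", m$group,
                            FUN = function(s) sum(s) / sum(!s))
  d <- prepare_design(cbind(m, y = 0), "y", screen_outliers = FALSE)
  n_sim <- 200
  seeds <- 1000 + seq_len(n_sim)
  rej <- vapply(seeds, function(s) {
    d$y <- simulate_lmm_response(d, c("(Intercept)" = 0.1),
                                 terms = c("sex", "age_c", "age_sq", "rearing"),
                                 sd_individual = 0.005, sd_group = 0.005,
                                 sd_resid = 0.03, seed = s)
    d$response <- d$y
    fit <- suppressMessages(fit_lmm(d, c("sex", "age_c", "age_sq", "rearing")))
    fit$coefficients$p[fit$coefficients$term == "sexmale"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("AIC backward reduction respects marginality and never raises the AIC", {
  st <- synthetic_bonobo_study(seed = 55L)
  m <- standardize_metrics(st$metrics)
  d <- suppressMessages(prepare_design(m, "out_strength"))
  red <- suppressMessages(aic_backward_reduction(d))
  expect_lte(red$final_aic, red$full_aic)
  # replaying the path: every intermediate set must satisfy marginality
  terms <- full_fixed_terms()
  for (dropped in red$path$dropped[-1]) {
    ok_deps <- function(tt) {
      for (t in tt) {
        parts <- if (grepl(":", t)) strsplit(t, ":")[[1]] else
          if (t == "age_sq") "age_c" else character(0)
        if (!all(parts %in% tt)) return(FALSE)
      }
      TRUE
    }
    terms <- setdiff(terms, dropped)
    expect_true(ok_deps(terms))
  }
  if ("age_sq" %in% red$retained) expect_true("age_c" %in% red$retained)
})

test_that("strong planted terms are retained while a null term is dropped", {
  st <- synthetic_bonobo_study(seed = 3L)
  m <- st$metrics
  d <- suppressMessages(prepare_design(m, "out_strength", screen_outliers = FALSE))
  d$y <- simulate_lmm_response(
    d, c("(Intercept)" = 0.1, "sexmale" = 0.08, "age_sq" = -2e-4,
         "rearingatypically_reared" = -0.08),
    sd_individual = 0.005, sd_group = 0.005, sd_resid = 0.02, seed = 8L)
  d$response <- d$y
  attr(d, "response") <- "y"
  red <- suppressMessages(aic_backward_reduction(d))
  expect_true(all(c("sex", "age_sq", "rearing") %in% red$retained))
  expect_false("sex_ratio" %in% red$retained)
})

test_that("Tukey contrasts enumerate 2x2 cells and stay flat under the null", {
  st <- synthetic_bonobo_study(seed = 21L)
  d <- suppressMessages(prepare_design(st$metrics, "out_strength",
                                       screen_outliers = FALSE))
  d$y <- simulate_lmm_response(d, c("(Intercept)" = 0.1),
                               sd_individual = 0.002, sd_group = 0.002,
                               sd_resid = 0.02, seed = 4L)
  d$response <- d$y
  attr(d, "response") <- "y"
  fit <- suppressMessages(fit_lmm(d, c("sex", "rearing", "sex:rearing")))
  ph <- tukey_contrasts(fit, c("sex", "rearing"))
  expect_identical(nrow(ph$emmeans), 4L)
  expect_identical(nrow(ph$contrasts), 6L)
  expect_true(all(ph$contrasts$p.value > 0.2)) # no planted differences
})

test_that("residual diagnostics report Shapiro-Wilk and write plot files", {
  st <- synthetic_bonobo_study(seed = 12L)
  d <- suppressMessages(prepare_design(st$metrics, "out_strength"))
  fit <- suppressMessages(fit_lmm(d, c("sex", "age_c", "age_sq")))
  dir <- withr::local_tempdir()
  rep <- residual_diagnostics(fit, dir = dir)
  expect_true(is.finite(rep$shapiro_p))
  expect_length(rep$files, 2L)
  expect_true(all(file.exists(rep$files)))
  expect_true(all(file.size(rep$files) > 0))
})
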