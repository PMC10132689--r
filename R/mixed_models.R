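# Inferential battery: design preparation, Rosner outlier screening, linear
# mixed models with two random intercepts, AIC backward reduction, VIF and
# residual diagnostics, Tukey post-hoc contrasts.

#' Fixed-effect terms of the full model
#'
#' Sex, mean-centered age and its square, rearing history, group size and sex
#' ratio, plus the two-way interactions of sex with each other predictor.
#'
#' @param include_group_size drop `group_size` (and its sex interaction) when
#'   modelling group-size-standardized responses.
#' @return character vector of term labels.
#' @export
full_fixed_terms <- function(include_group_size = TRUE) {
  mains <- c("sex", "age_c", "age_sq", "rearing", "sex_ratio")
  if (include_group_size) mains <- append(mains, "group_size", after = 4L)
  c(mains, paste0("sex:", setdiff(mains, "sex")))
}

#' Prepare a model table for one response
#'
#' Centers age around the mean of the analysis rows and squares it (avoiding
#' the collinearity of raw age with its square), codes sex and rearing as
#' factors with reference levels female and mother-reared, drops rows with a
#' missing response, restricts indirect responses (affinity, eigenvector
#' centrality and their scaled variants) to groups with at least
#' `indirect_min_size` members, and optionally removes Rosner outliers on the
#' response.
#'
#' @param metrics output of [node_metrics()] (optionally after
#'   [standardize_metrics()]).
#' @param response name of the response column.
#' @param indirect_min_size minimum group size for indirect responses.
#' @param screen_outliers apply [rosner_outliers()] to the response.
#' @param rosner_k,rosner_alpha Rosner test parameters.
#' @return data.frame ready for [fit_lmm()], with attributes `response`,
#'   `removed_outliers` (data.frame of removed rows) and `dropped_missing`
#'   (count).
#' @export
prepare_design <- function(metrics, response, indirect_min_size = 5L,
                           screen_outliers = TRUE, rosner_k = 3L,
                           rosner_alpha = 0.05) {
  if (!response %in% names(metrics)) stop("no column named ", response)
  d <- metrics
  indirect <- response %in% c("affinity", "eigenvector", "affinity_scaled",
                              "eigenvector_scaled")
  if (indirect) d <- d[d$group_size >= indirect_min_size, , drop = FALSE]
  missing <- is.na(d[[response]])
  if (all(missing)) stop("response ", response, " is missing for every row")
  if (any(missing))
    message(sum(missing), " row(s) with missing ", response, " dropped")
  d <- d[!missing, , drop = FALSE]

  removed <- d[0, c("group", "individual")]
  if (screen_outliers && nrow(d) >= 10) {
    out_idx <- rosner_outliers(d[[response]], max_k = rosner_k,
                               alpha = rosner_alpha)
    if (length(out_idx)) {
      removed <- d[out_idx, c("group", "individual")]
      message(length(out_idx), " Rosner outlier(s) removed from the ",
              response, " dataset")
      d <- d[-out_idx, , drop = FALSE]
    }
  }

  d$sex <- factor(d$sex, levels = SEX_LEVELS)
  d$rearing <- factor(d$rearing, levels = REARING_LEVELS)
  d$age_c <- d$age - mean(d$age)
  d$age_sq <- d$age_c^2
  d$response <- d[[response]]
  rownames(d) <- NULL
  attr(d, "response") <- response
  attr(d, "removed_outliers") <- removed
  attr(d, "dropped_missing") <- sum(missing)
  d
}

#' Rosner's generalized extreme studentized deviate test
#'
#' Iteratively removes the most extreme value (largest `|x - mean| / sd`) up to
#' `max_k` times; each statistic `R_i` is compared with its critical value
#' `lambda_i` from the t distribution. The outliers are the first `i` removed
#' values for the *largest* `i` with `R_i > lambda_i`.
#'
#' @param x numeric vector (NAs ignored).
#' @param max_k maximum number of outliers to test for.
#' @param alpha significance level.
#' @return integer indices into `x` of the detected outliers (possibly empty).
#' @export
rosner_outliers <- function(x, max_k = 3L, alpha = 0.05) {
  stopifnot(max_k >= 1)
  idx_all <- which(!is.na(x))
  vals <- x[idx_all]
  n <- length(vals)
  if (n < 3 || max_k >= n - 1) stop("too few observations for Rosner's test")
  keep <- rep(TRUE, n)
  R <- lambda <- numeric(max_k)
  candidates <- integer(max_k)
  for (i in seq_len(max_k)) {
    cur <- vals[keep]
    s <- stats::sd(cur)
    if (s == 0) { R[i] <- 0 } else {
      dev <- abs(cur - mean(cur))
      j <- which(keep)[which.max(dev)]
      R[i] <- max(dev) / s
      candidates[i] <- j
      keep[j] <- FALSE
    }
    ni <- n - i + 1 # sample size the i-th statistic was computed on
    pp <- 1 - alpha / (2 * ni)
    tq <- stats::qt(pp, ni - 2)
    lambda[i] <- (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni)
  }
  n_out <- if (any(R > lambda)) max(which(R > lambda)) else 0L
  if (n_out == 0L) return(integer(0))
  idx_all[candidates[seq_len(n_out)]]
}

#' Fit one linear mixed model
#'
#' Random intercepts for individual identity (repeated observations of the
#' same animal in different group compositions) and group identity
#' (non-independence within groups). Estimation delegates to
#' \pkg{lmerTest}/\pkg{lme4}; coefficient tables use Satterthwaite
#' denominator degrees of freedom.
#'
#' @param data prepared table (see [prepare_design()]); must contain
#'   `individual` and `group` columns.
#' @param fixed_terms character vector of fixed-effect term labels.
#' @param response response column name (defaults to the `response` attribute).
#' @param reml fit by REML (`TRUE`, for final inference) or ML (`FALSE`, for
#'   AIC comparison).
#' @return a `groom_fit`: list with the lmer `fit`, `coefficients` table
#'   (estimate, se, df, t, p), `aic`, `loglik`, `n_obs`, `singular`, `reml`,
#'   `fixed_terms`, `response`.
#' @export
fit_lmm <- function(data, fixed_terms, response = attr(data, "response"),
                    reml = TRUE) {
  if (length(unique(data$group)) < 2 || length(unique(data$individual)) < 2)
    stop("random intercepts require at least 2 groups and 2 individuals")
  rhs <- paste(c(if (length(fixed_terms)) fixed_terms else "1",
                 "(1 | individual)", "(1 | group)"), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- lmerTest::lmer(fml, data = data, REML = reml,
                        control = lme4::lmerControl(check.conv.singular =
                          lme4::.makeCC(action = "message", tol = 1e-4)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  cf <- as.data.frame(summary(fit)$coefficients)
  names(cf) <- c("estimate", "se", "df", "t", "p")
  cf$term <- rownames(cf)
  rownames(cf) <- NULL
  structure(list(fit = fit, coefficients = cf[, c("term", "estimate", "se",
                                                  "df", "t", "p")],
                 aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
                 n_obs = stats::nobs(fit), singular = singular, reml = reml,
                 fixed_terms = fixed_terms, response = response,
                 formula = fml),
            class = "groom_fit")
}

#' @export
print.groom_fit <- function(x, ...) {
  cat("groom_fit:", x$response, "~", paste(x$fixed_terms, collapse = " + "),
      "\n  n =", x$n_obs, " AIC =", format(x$aic, digits = 6),
      if (x$reml) "(REML)" else "(ML)",
      if (x$singular) " [singular fit: a variance component is 0]" else "", "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

# terms whose removal would violate marginality given the present term set
removable_terms <- function(terms) {
  depends_on <- function(t) {
    if (grepl(":", t, fixed = TRUE)) return(strsplit(t, ":", fixed = TRUE)[[1]])
    if (t == "age_sq") return("age_c")
    character(0)
  }
  required <- unique(unlist(lapply(terms, depends_on)))
  setdiff(terms, required)
}

#' Backward model reduction by AIC
#'
#' Single-term backward elimination under ML estimation: at each step the
#' removable fixed term (respecting marginality - interactions before their
#' main effects, the quadratic age term before the linear one) whose removal
#' most lowers the AIC is dropped; the search stops when no removal lowers the
#' AIC. The final model is refit with REML for inference. Ties are broken by
#' the larger AIC drop, then alphabetically.
#'
#' @param data prepared table (see [prepare_design()]).
#' @param fixed_terms starting fixed-effect terms (default [full_fixed_terms()],
#'   without group size if the response is a group-size-standardized variant).
#' @param response response column name.
#' @return list with `final` (REML `groom_fit`), `path` (data.frame: step,
#'   dropped term, AIC after the drop), `full_aic` and `final_aic` (both ML).
#' @export
aic_backward_reduction <- function(data, fixed_terms = NULL,
                                   response = attr(data, "response")) {
  if (is.null(fixed_terms)) {
    std <- grepl("_std$|_scaled$|_dev$", response)
    fixed_terms <- full_fixed_terms(include_group_size = !std)
  }
  current <- fixed_terms
  fit <- fit_lmm(data, current, response, reml = FALSE)
  full_aic <- fit$aic
  path <- data.frame(step = 0L, dropped = NA_character_, aic = fit$aic,
                     stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cands <- sort(removable_terms(current))
    if (!length(cands)) break
    aics <- vapply(cands, function(tm) {
      fit_lmm(data, setdiff(current, tm), response, reml = FALSE)$aic
    }, numeric(1))
    best <- which.min(aics) # ties: smallest AIC, then alphabetical (sorted)
    if (aics[best] >= fit$aic - 1e-9) break
    step <- step + 1L
    current <- setdiff(current, cands[best])
    fit <- fit_lmm(data, current, response, reml = FALSE)
    path <- rbind(path, data.frame(step = step, dropped = cands[best],
                                   aic = fit$aic, stringsAsFactors = FALSE))
  }
  final <- fit_lmm(data, current, response, reml = TRUE)
  list(final = final, path = path, full_aic = full_aic, final_aic = fit$aic,
       retained = current)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each numeric-encoded predictor
#' column on all the others. Values above the threshold flag collinearity;
#' perfectly collinear columns report `Inf`.
#'
#' @param data model table.
#' @param terms main-effect term names (factors are dummy-encoded).
#' @param threshold flag level.
#' @return data.frame with `term`, `vif`, `flagged`.
#' @export
vif_check <- function(data, terms, threshold = 5) {
  X <- stats::model.matrix(stats::reformulate(terms), data = data)[, -1, drop = FALSE]
  if (ncol(X) < 2) stop("VIF needs at least 2 predictors")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = colnames(X), vif = vif, flagged = vif > threshold,
             stringsAsFactors = FALSE)
}

#' Tukey-adjusted post-hoc contrasts
#'
#' Estimated marginal means for the cells of a factor (or factor interaction)
#' at mean covariate values, with all pairwise differences adjusted by the
#' studentized-range (Tukey) method. Used e.g. to unpack a significant
#' sex-by-rearing interaction.
#'
#' @param fit a `groom_fit`.
#' @param factors character vector of factor names, e.g. `c("sex", "rearing")`.
#' @return list with `emmeans` and `contrasts` data.frames.
#' @export
tukey_contrasts <- function(fit, factors = c("sex", "rearing")) {
  spec <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  emm <- emmeans::emmeans(fit$fit, spec, lmer.df = "satterthwaite")
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  list(emmeans = as.data.frame(emm), contrasts = as.data.frame(ctr))
}

#' Residual diagnostics
#'
#' Shapiro-Wilk test of the residuals plus (optionally) residual-vs-fitted and
#' normal QQ plot files. Report only; nothing is acted on automatically.
#'
#' @param fit a `groom_fit`.
#' @param dir optional directory for the plot files.
#' @return list with `shapiro_p` and `files` (character vector, possibly
#'   empty).
#' @export
residual_diagnostics <- function(fit, dir = NULL) {
  res <- stats::residuals(fit$fit)
  shap <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(dir, paste0(fit$response, "_resid_vs_fitted.png"))
    grDevices::png(f1, width = 600, height = 480)
    plot(stats::fitted(fit$fit), res, xlab = "fitted", ylab = "residual",
         main = paste("Residuals vs fitted:", fit$response))
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
    f2 <- file.path(dir, paste0(fit$response, "_qq.png"))
    grDevices::png(f2, width = 600, height = 480)
    stats::qqnorm(res, main = paste("QQ plot:", fit$response))
    stats::qqline(res)
    grDevices::dev.off()
    files <- c(f1, f2)
  }
  list(shapiro_p = shap, files = files)
}
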