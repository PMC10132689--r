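# Descriptive plotting utilities (visual aids only; no inferential claims).

#' Rank-age trend plot
#'
#' Scatter of mean-centered normalized David's scores against age with a
#' quadratic least-squares trend per sex, the conventional visual aid for
#' judging how agonistic rank moves with age in each sex.
#'
#' @param scores per-individual score table (`group`, `individual`,
#'   `centeredDS`), e.g. `dominance_analysis(...)$scores`.
#' @param individuals metadata data.frame with `group`, `individual`, `sex`,
#'   `age`.
#' @param file optional png path; when `NULL` the current device is used.
#' @return invisibly, the merged plotting table.
#' @export
plot_rank_age <- function(scores, individuals, file = NULL) {
  d <- merge(scores, individuals[, c("group", "individual", "sex", "age")],
             by = c("group", "individual"))
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  cols <- c(female = "#c0392b", male = "#2e6da4")
  plot(d$age, d$centeredDS, pch = 19, col = cols[d$sex],
       xlab = "age (years)", ylab = "centered normalized David's score",
       main = "Dominance rank vs age")
  for (s in names(cols)) {
    ds <- d[d$sex == s, ]
    if (nrow(ds) >= 3 && length(unique(ds$age)) >= 3) {
      fit <- stats::lm(centeredDS ~ stats::poly(age, 2), data = ds)
      ax <- seq(min(ds$age), max(ds$age), length.out = 80)
      graphics::lines(ax, stats::predict(fit, data.frame(age = ax)),
                      col = cols[s], lwd = 2)
    }
  }
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(d)
}

#' Metric-vs-age panel
#'
#' Scatter of one network measure against age, optionally per sex with
#' quadratic trends; a descriptive companion to the model battery.
#'
#' @param metrics output of [node_metrics()].
#' @param measure column to plot.
#' @param file optional png path.
#' @return invisibly, the plotted subset.
#' @export
plot_metric_age <- function(metrics, measure = "out_strength", file = NULL) {
  d <- metrics[!is.na(metrics[[measure]]), ]
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  cols <- c(female = "#c0392b", male = "#2e6da4")
  plot(d$age, d[[measure]], pch = 19, col = cols[d$sex],
       xlab = "age (years)", ylab = measure)
  for (s in names(cols)) {
    ds <- d[d$sex == s, ]
    if (nrow(ds) >= 3 && length(unique(ds$age)) >= 3) {
      fit <- stats::lm(ds[[measure]] ~ stats::poly(ds$age, 2))
      ax_ord <- order(ds$age)
      graphics::lines(ds$age[ax_ord], stats::fitted(fit)[ax_ord],
                      col = cols[s], lwd = 2)
    }
  }
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(d)
}
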