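# One reproducible run: networks -> metrics -> correlation screen ->
# dominance -> mixed models, with all tabular artifacts on disk and a manifest
# that suffices to replay the run.

#' Run the full multi-group grooming analysis
#'
#' Stages communicate via on-disk CSV/JSON artifacts so each is independently
#' inspectable. Any stage error halts the run with a stage-labelled message;
#' artifacts written before the failure are preserved.
#'
#' @param input one of: an `observation_set`, a `study_archive` (or the path of
#'   an archive directory), or a list with `scans`, `individuals`, `agonistic`
#'   file paths.
#' @param out_dir output directory.
#' @param seed integer seed for the randomization tests.
#' @param responses response measures to model.
#' @param n_rand randomizations per dominance test.
#' @param alpha group-inclusion level for the dominance hierarchy tests.
#' @param shared_denominator see [index_of_interactions()].
#' @param indirect_min_size minimum group size for indirect measures.
#' @param standardized also run the group-size-standardized battery (strength
#'   over N-1, disparity deviation, within-group max-scaling; group size
#'   dropped as predictor).
#' @return invisibly, a list with `networks`, `metrics`, `screen`, `dominance`,
#'   `models`, `manifest`.
#' @export
run_full_analysis <- function(input, out_dir, seed = 1L,
                              responses = c("out_strength", "in_strength",
                                            "disparity", "affinity",
                                            "eigenvector"),
                              n_rand = 1000L, alpha = 0.10,
                              shared_denominator = FALSE,
                              indirect_min_size = 5L,
                              standardized = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }

  networks_given <- NULL
  obs <- stage("input", {
    if (is.character(input) && length(input) == 1L) input <- read_study_archive(input)
    if (inherits(input, "study_archive")) {
      networks_given <- input$networks
      if (!is.null(input$obs)) input$obs else
        observation_set(input$individuals, agonistic = input$agonistic)
    } else if (inherits(input, "observation_set")) {
      input
    } else if (is.list(input) && !is.null(input$scans)) {
      read_scan_table(input$scans, input$individuals, input$agonistic)
    } else stop("unrecognized input")
  })

  networks <- stage("build-networks", {
    nets <- if (!is.null(networks_given)) networks_given else
      build_networks(obs, shared_denominator = shared_denominator)
    dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
    for (nm in names(nets))
      write_adjacency(nets[[nm]], file.path(out_dir, "networks",
                                            paste0(nm, ".csv")))
    nets
  })

  metrics <- stage("metrics", {
    m <- standardize_metrics(node_metrics(networks, obs$individuals,
                                          indirect_min_size = indirect_min_size))
    utils::write.csv(m, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    m
  })

  screen <- stage("correlation-screen", {
    sc <- metric_correlation_screen(metrics)
    utils::write.csv(sc$pairs, file.path(out_dir, "correlation_screen.csv"),
                     row.names = FALSE)
    sc
  })

  dominance <- if (nrow(obs$agonistic)) stage("dominance", {
    dm <- dominance_analysis(obs, n_rand = n_rand, seed = seed, alpha = alpha)
    utils::write.csv(dm$summary, file.path(out_dir, "dominance_summary.csv"),
                     row.names = FALSE)
    if (!is.null(dm$scores))
      utils::write.csv(dm$scores, file.path(out_dir, "dominance_scores.csv"),
                       row.names = FALSE)
    jsonlite::write_json(dm$summary, file.path(out_dir, "dominance.json"),
                         auto_unbox = TRUE, digits = NA)
    dm
  })

  model_responses <- responses
  if (standardized) {
    std_map <- c(out_strength = "out_strength_std", in_strength = "in_strength_std",
                 disparity = "disparity_dev", affinity = "affinity_scaled",
                 eigenvector = "eigenvector_scaled")
    model_responses <- unname(std_map[responses])
  }
  models <- stage("models", {
    res <- lapply(model_responses, function(resp) {
      d <- prepare_design(metrics, resp, indirect_min_size = indirect_min_size)
      red <- aic_backward_reduction(d)
      diag <- residual_diagnostics(red$final, dir = file.path(out_dir, "diagnostics"))
      posthoc <- if ("sex:rearing" %in% red$retained)
        tukey_contrasts(red$final, c("sex", "rearing"))
      mains <- c("sex", "age_c", "age_sq", "rearing", "sex_ratio",
                 if (!standardized) "group_size")
      list(response = resp, design_n = nrow(d),
           removed_outliers = attr(d, "removed_outliers"),
           vif = vif_check(d, mains),
           reduction = red, diagnostics = diag, posthoc = posthoc)
    })
    names(res) <- model_responses
    coef_tab <- do.call(rbind, lapply(res, function(r)
      cbind(response = r$response, r$reduction$final$coefficients)))
    utils::write.csv(coef_tab, file.path(out_dir, "model_coefficients.csv"),
                     row.names = FALSE)
    path_tab <- do.call(rbind, lapply(res, function(r)
      cbind(response = r$response, r$reduction$path)))
    utils::write.csv(path_tab, file.path(out_dir, "model_reduction_path.csv"),
                     row.names = FALSE)
    res
  })

  manifest <- list(package_version = as.character(utils::packageVersion("groomnet")),
                   seed = seed, n_rand = n_rand, alpha = alpha,
                   responses = model_responses,
                   shared_denominator = shared_denominator,
                   indirect_min_size = indirect_min_size,
                   standardized = standardized)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(networks = networks, metrics = metrics, screen = screen,
                 dominance = dominance, models = models, manifest = manifest))
}
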