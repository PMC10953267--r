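# End-to-end orchestration: panel ingestion/simulation -> scoring ->
# reliability screen -> residualization -> contemporaneous networks (T1, T2)
# -> temporal network -> centralities -> bootstrap stability -> exports,
# with a machine-readable manifest so any run can be replayed and diffed.

#' Assemble and validate a pipeline configuration
#'
#' Every tuning default is explicit here so the manifest's config echo fully
#' describes a run: EBIC gamma 0.5, 100 log-spaced penalties with floor
#' ratio 0.01 (contemporaneous) and 1e-3 (temporal CV), 10 CV folds,
#' 1000 bootstrap replicates for edge CIs and 250 for case-drop stability,
#' reliability threshold 0.60, scoring rule >= 75% items answered. A master
#' seed is mandatory whenever any stochastic stage (simulation,
#' cross-validation, bootstrap) will run.
#'
#' @param input path to a panel CSV, or a `simulation_spec`.
#' @param output_dir run directory (created if needed).
#' @param seed master seed (integer).
#' @param scale_defs scale definitions (default [study_scales()]).
#' @param covariates covariate column names.
#' @param ebic_gamma,nlambda,lambda_min_ratio contemporaneous-network tuning.
#' @param cv_folds,cv_lambda_min_ratio temporal-network tuning.
#' @param n_boot_edges,n_boot_casedrop bootstrap sizes.
#' @param bootstrap run the bootstrap stability stage (default TRUE).
#' @param alpha_threshold reliability screen threshold.
#' @param score_min_prop minimum proportion of answered items per score.
#' @return a `run_config`.
#' @export
run_config <- function(input, output_dir, seed = NULL,
                       scale_defs = study_scales(),
                       covariates = c("gender", "age", "education", "income"),
                       ebic_gamma = 0.5, nlambda = 100L,
                       lambda_min_ratio = 0.01, cv_folds = 10L,
                       cv_lambda_min_ratio = 1e-3,
                       n_boot_edges = 1000L, n_boot_casedrop = 250L,
                       bootstrap = TRUE, alpha_threshold = 0.60,
                       score_min_prop = 0.75) {
  stochastic <- bootstrap || inherits(input, "simulation_spec")
  if (stochastic && is.null(seed))
    pn_config_error("a master seed is required for stochastic stages")
  if (!inherits(input, "simulation_spec") && !is.character(input))
    pn_config_error("input must be a file path or a simulation_spec")
  structure(
    list(input = input, output_dir = output_dir,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         scale_defs = scale_defs, covariates = covariates,
         ebic_gamma = ebic_gamma, nlambda = as.integer(nlambda),
         lambda_min_ratio = lambda_min_ratio,
         cv_folds = as.integer(cv_folds),
         cv_lambda_min_ratio = cv_lambda_min_ratio,
         n_boot_edges = as.integer(n_boot_edges),
         n_boot_casedrop = as.integer(n_boot_casedrop),
         bootstrap = bootstrap, alpha_threshold = alpha_threshold,
         score_min_prop = score_min_prop),
    class = "run_config"
  )
}

edge_names <- function(W, sep = "--") {
  l <- rownames(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  paste0(l[ut[, 1]], sep, l[ut[, 2]])
}

# estimator closures used by the bootstrap stage; exported so users can
# bootstrap the same estimators the pipeline uses

#' Estimator closure: contemporaneous network edge weights
#'
#' Returns a `function(data, seed)` fitting [select_network()] to the rows
#' it is given and returning the upper-triangle partial correlations as a
#' named vector (`a--b`), for use with [bootstrap_edges()] and
#' [case_drop_cs()].
#'
#' @param config a `run_config` (tuning parameters are read from it).
#' @return an estimator function.
#' @export
ggm_estimator <- function(config) {
  function(data, seed) {
    S <- sample_correlation(data)
    net <- select_network(S, n = nrow(data), gamma = config$ebic_gamma,
                          nlambda = config$nlambda,
                          lambda_min_ratio = config$lambda_min_ratio)
    w <- net$weights[upper.tri(net$weights)]
    names(w) <- edge_names(net$weights)
    w
  }
}

#' Estimator closure: temporal network edge weights
#'
#' Returns a `function(data, seed)` expecting the column-bound
#' `[residuals_t1 | residuals_t2]` matrix (wave-suffixed column names) and
#' returning all directed coefficients as a named vector (`a->b`).
#'
#' @param config a `run_config`.
#' @return an estimator function.
#' @export
clpn_estimator <- function(config) {
  function(data, seed) {
    waves <- split_waves(data)
    net <- fit_clpn(waves$t1, waves$t2, seed = seed, folds = config$cv_folds,
                    lambda = NULL)
    d <- as.vector(net$d)
    names(d) <- paste0(rep(net$node_labels, times = length(net$node_labels)),
                       "->", rep(net$node_labels, each = length(net$node_labels)))
    d
  }
}

write_run_csv <- function(x, dir, name) {
  utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  name
}

#' Run the full two-wave network pipeline
#'
#' Executes every stage on the configured input, writes all tabular outputs
#' as CSV (plus GraphML/JSON network exports), a human-readable `log.txt`,
#' and a `manifest.json` from which [replay_run()] can reproduce the run
#' byte for byte.
#'
#' @param config a `run_config`.
#' @return (invisibly) a list with the fitted objects and the run directory.
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$output_dir
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  files <- character()

  # -- stage: data ---------------------------------------------------------
  if (inherits(config$input, "simulation_spec")) {
    spec <- config$input
    write_spec(spec, file.path(out, "sim_spec.yaml"))
    files <- c(files, "sim_spec.yaml")
    pd <- simulate_panel(spec)
    say("data: simulated %d participants (seed %d)", spec$n, spec$seed)
  } else {
    pd <- read_panel(config$input, scale_defs = config$scale_defs)
    say("data: read %d participants from %s (%d parse warnings)",
        nrow(pd$data), config$input, pd$n_warnings)
  }

  # -- stage: scoring and descriptives ------------------------------------
  pd <- score_scales(pd, min_prop = config$score_min_prop)
  descr <- descriptives(pd)
  files <- c(files, write_run_csv(descr, out, "descriptives.csv"))
  retained <- drop_unreliable(descr, config$alpha_threshold)
  dropped <- attr(retained, "dropped")
  say("reliability screen: retained %d scale(s)%s", length(retained),
      if (length(dropped)) paste0("; dropped: ", paste(dropped, collapse = ", "))
      else "")
  files <- c(files, write_run_csv(
    data.frame(scale = c(retained, dropped),
               retained = c(rep(TRUE, length(retained)),
                            rep(FALSE, length(dropped)))),
    out, "reliability_screen.csv"))

  # -- stage: residualization ---------------------------------------------
  score_cols <- as.vector(outer(retained, pd$wave_suffix, paste0))
  covs <- pd$data[intersect(config$covariates, names(pd$data))]
  res <- residualize(pd$data[score_cols], covs)
  say("residualization: %d complete rows retained of %d; covariates: %s",
      nrow(res), nrow(pd$data),
      paste(colnames(attr(res, "covariates")), collapse = ", "))

  # -- stage: contemporaneous networks ------------------------------------
  nets <- lapply(c("t1", "t2"), function(w) {
    S <- sample_correlation(res, w)
    select_network(S, n = attr(S, "n"), gamma = config$ebic_gamma,
                   nlambda = config$nlambda,
                   lambda_min_ratio = config$lambda_min_ratio)
  })
  names(nets) <- c("t1", "t2")
  for (w in c("t1", "t2")) {
    say("ggm %s: lambda = %.4g, %d edge(s)", w, nets[[w]]$lambda_selected,
        sum(nets[[w]]$weights[upper.tri(nets[[w]]$weights)] != 0))
    files <- c(files, write_run_csv(
      as.data.frame(nets[[w]]$weights), out, paste0("network_", w, ".csv")))
    export_graphml(nets[[w]], file.path(out, paste0("network_", w, ".graphml")))
    export_json(nets[[w]], file.path(out, paste0("network_", w, ".json")))
    files <- c(files, paste0("network_", w, c(".graphml", ".json")))
  }
  avg <- average_edges(nets$t1, nets$t2)
  files <- c(files, write_run_csv(avg, out, "edge_table_average.csv"))

  # -- stage: temporal network --------------------------------------------
  waves <- split_waves(res)
  clpn <- fit_clpn(waves$t1, waves$t2, seed = derive_seed(config$seed %||% 0L, 101L),
                   folds = config$cv_folds)
  say("clpn: per-node lambda in [%.4g, %.4g]", min(clpn$lambda_per_node),
      max(clpn$lambda_per_node))
  files <- c(files, write_run_csv(temporal_edge_table(clpn), out,
                                  "temporal_edges.csv"))
  files <- c(files, write_run_csv(filter_edges(clpn), out,
                                  "temporal_edges_filtered.csv"))
  export_graphml(clpn, file.path(out, "temporal.graphml"))
  files <- c(files, "temporal.graphml")

  # -- stage: centralities -------------------------------------------------
  cent_c <- rbind(cbind(wave = "t1", expected_influence(nets$t1)),
                  cbind(wave = "t2", expected_influence(nets$t2)))
  files <- c(files, write_run_csv(cent_c, out, "centrality_contemporaneous.csv"))
  cent_t <- rbind(
    in_prediction(clpn, "cross_lagged"), in_prediction(clpn, "cross_construct"),
    out_prediction(clpn, "cross_lagged"), out_prediction(clpn, "cross_construct"),
    variance_explained_prediction(clpn, waves$t1, waves$t2, "cross_lagged"),
    variance_explained_prediction(clpn, waves$t1, waves$t2, "cross_construct")
  )
  files <- c(files, write_run_csv(cent_t, out, "centrality_temporal.csv"))

  # -- stage: layout -------------------------------------------------------
  lay <- average_layout(nets$t1, nets$t2, seed = derive_seed(config$seed %||% 1L, 202L))
  files <- c(files, write_run_csv(lay, out, "layout.csv"))

  # -- stage: bootstrap stability -----------------------------------------
  stability <- NULL
  if (config$bootstrap) {
    ggm_est <- ggm_estimator(config)
    boot_t1 <- bootstrap_edges(waves$t1, ggm_est, n_boot = config$n_boot_edges,
                               seed = derive_seed(config$seed, 301L))
    boot_t2 <- bootstrap_edges(waves$t2, ggm_est, n_boot = config$n_boot_edges,
                               seed = derive_seed(config$seed, 302L))
    boot_cl <- bootstrap_edges(res, clpn_estimator(config),
                               n_boot = config$n_boot_edges,
                               seed = derive_seed(config$seed, 303L))
    files <- c(files,
               write_run_csv(as.data.frame(boot_t1), out, "bootstrap_edges_t1.csv"),
               write_run_csv(as.data.frame(boot_t2), out, "bootstrap_edges_t2.csv"),
               write_run_csv(as.data.frame(boot_cl), out, "bootstrap_edges_temporal.csv"))
    ei_fn <- function(data, seed) {
      est <- ggm_est(data, seed)
      W <- matrix(0, ncol(data), ncol(data))
      W[upper.tri(W)] <- est
      rowSums(W + t(W))
    }
    cs_t1 <- case_drop_cs(waves$t1, ei_fn, n_boot = config$n_boot_casedrop,
                          seed = derive_seed(config$seed, 311L))
    cs_t2 <- case_drop_cs(waves$t2, ei_fn, n_boot = config$n_boot_casedrop,
                          seed = derive_seed(config$seed, 312L))
    say("stability: CS(EI) t1 = %.2f, t2 = %.2f", cs_t1$cs, cs_t2$cs)
    files <- c(files, write_run_csv(
      data.frame(index = c("EI_t1", "EI_t2"), cs = c(cs_t1$cs, cs_t2$cs)),
      out, "cs_coefficients.csv"))
    for (nm in c("t1", "t2")) {
      b <- if (nm == "t1") boot_t1 else boot_t2
      files <- c(files, write_run_csv(
        as.data.frame(difference_matrix(b)), out,
        paste0("edge_difference_", nm, ".csv")))
    }
    stability <- list(boot_t1 = boot_t1, boot_t2 = boot_t2, boot_clpn = boot_cl,
                      cs_t1 = cs_t1, cs_t2 = cs_t2)
  }

  # -- manifest ------------------------------------------------------------
  writeLines(log_lines, file.path(out, "log.txt"))
  cfg_echo <- unclass(config)
  cfg_echo$scale_defs <- lapply(config$scale_defs, unclass)
  cfg_echo$input <- if (inherits(config$input, "simulation_spec"))
    list(kind = "simulation", spec_file = "sim_spec.yaml")
  else list(kind = "file", path = config$input,
            md5 = unname(tools::md5sum(config$input)))
  cfg_echo$output_dir <- NULL
  manifest <- list(
    package = "panelnet",
    package_version = as.character(utils::packageVersion("panelnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg_echo,
    outputs = as.list(tools::md5sum(file.path(out, sort(unique(files)))))
  )
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = pd, descriptives = descr, retained = retained,
                 residuals = res, networks = nets, average_edges = avg,
                 clpn = clpn, centrality_contemporaneous = cent_c,
                 centrality_temporal = cent_t, layout = lay,
                 stability = stability, dir = out))
}

#' Replay a run from its manifest and diff the outputs
#'
#' Re-executes the pipeline from the configuration echoed in a
#' `manifest.json` and compares every output file's checksum against the
#' original run. A faithful manifest yields an empty diff.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param output_dir where to re-run (default: a fresh temporary directory).
#' @return data frame with columns file, match; attribute `"identical"` is
#'   TRUE when every file matches.
#' @export
replay_run <- function(manifest_path, output_dir = tempfile("replay")) {
  man <- jsonlite::read_json(manifest_path)
  cfg <- man$config
  orig_dir <- dirname(manifest_path)
  input <- if (identical(cfg$input$kind, "simulation"))
    read_spec(file.path(orig_dir, cfg$input$spec_file))
  else cfg$input$path
  defs <- lapply(cfg$scale_defs, function(d)
    scale_definition(d$name, d$construct, unlist(d$item_ids),
                     unlist(d$response_range), unlist(d$reverse_keyed)))
  names(defs) <- vapply(defs, function(d) d$name, character(1))
  config <- run_config(
    input = input, output_dir = output_dir, seed = cfg$seed,
    scale_defs = defs, covariates = unlist(cfg$covariates),
    ebic_gamma = cfg$ebic_gamma, nlambda = cfg$nlambda,
    lambda_min_ratio = cfg$lambda_min_ratio, cv_folds = cfg$cv_folds,
    cv_lambda_min_ratio = cfg$cv_lambda_min_ratio,
    n_boot_edges = cfg$n_boot_edges, n_boot_casedrop = cfg$n_boot_casedrop,
    bootstrap = cfg$bootstrap, alpha_threshold = cfg$alpha_threshold,
    score_min_prop = cfg$score_min_prop)
  run_pipeline(config)
  orig <- unlist(man$outputs)
  new <- tools::md5sum(file.path(output_dir, names(orig)))
  out <- data.frame(file = names(orig),
                    match = unname(new == orig))
  attr(out, "identical") <- all(out$match)
  out
}
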