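#' Pipeline configuration
#'
#' One configuration object drives the whole pipeline; a single master
#' `seed` deterministically derives every stage's seed, so a config fully
#' reproduces a run. Defaults mirror the study conditions: 12 components,
#' 4 donor blocks with 3 replicates, the 3 x 3 candidate model grid with
#' 10-fold CV, a 1e5-formulation search with `c02` fixed at its medium
#' level, top-40 pooling, 6 k-means clusters with 25 restarts, 2 selected
#' consensus media, 6 pooled-model baseline media and 4 test donors.
#'
#' @param k Number of components.
#' @param n_blocks Training donor blocks.
#' @param replicates Technical replicates per run.
#' @param scenario Scenario name (`"default"` or `"planted"`) or a
#'   [donor_scenario()] object.
#' @param algorithms,equations,folds Model-zoo grid and CV folds.
#' @param n_search,n_top In-silico sample size and per-model pool depth.
#' @param constraints Constraint tibble; default fixes `c02` at 0.
#' @param k_clusters,n_restarts,hopkins_fraction Clustering settings.
#' @param elbow_range Candidate `k` values for the elbow curve.
#' @param n_select Consensus media carried to confirmation.
#' @param n_baseline,baseline_min_sep Pooled-baseline media count and
#'   diversity separation.
#' @param baseline_equation Stepwise scope for the pooled baseline model.
#' @param n_test_donors Fresh donors for the confirmation experiment.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL` = in-memory only).
#' @param ... Extra [zoo_config()] arguments (grids).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k = 12, n_blocks = 4, replicates = 3,
                            scenario = "default",
                            algorithms = c("ols_stepwise", "random_forest", "elastic_net"),
                            equations = c("eq1", "eq2", "eq3"), folds = 10,
                            n_search = 1e5, n_top = 40,
                            constraints = constraint("c02", "fix", 0),
                            k_clusters = 6, n_restarts = 25,
                            hopkins_fraction = 0.1, elbow_range = 1:10,
                            n_select = 2, n_baseline = 6,
                            baseline_min_sep = 0.5, baseline_equation = "eq3",
                            n_test_donors = 4, seed = 1L, out_dir = NULL, ...) {
  structure(list(
    k = k, n_blocks = n_blocks, replicates = replicates, scenario = scenario,
    algorithms = algorithms, equations = equations, folds = folds,
    n_search = n_search, n_top = n_top, constraints = constraints,
    k_clusters = k_clusters, n_restarts = n_restarts,
    hopkins_fraction = hopkins_fraction, elbow_range = elbow_range,
    n_select = n_select, n_baseline = n_baseline,
    baseline_min_sep = baseline_min_sep, baseline_equation = baseline_equation,
    n_test_donors = n_test_donors,
    seed = as.integer(seed), out_dir = out_dir,
    zoo = zoo_config(folds = folds, ...)), class = "pipeline_config")
}

resolve_scenario <- function(config) {
  sc <- config$scenario
  if (inherits(sc, "donor_scenario")) return(sc)
  switch(as.character(sc),
         default = default_scenario(config$k),
         planted = planted_scenario(config$k),
         abort(paste0("unknown scenario: ", sc)))
}

#' Write / read a pipeline config as YAML
#'
#' Round-trips losslessly for configs whose `scenario` is a name (scenario
#' objects stay in R).
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$constraints <- if (is.null(x$constraints)) list() else
    purrr::transpose(as.list(x$constraints))
  if (inherits(x$scenario, "donor_scenario")) {
    abort("only named scenarios can be serialised to YAML")
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cons <- if (length(x$constraints) == 0) NULL else
    bind_rows(lapply(x$constraints, as_tibble))
  cfg <- pipeline_config(
    k = x$k, n_blocks = x$n_blocks, replicates = x$replicates,
    scenario = x$scenario, algorithms = unlist(x$algorithms),
    equations = unlist(x$equations), folds = x$folds,
    n_search = x$n_search, n_top = x$n_top, constraints = cons,
    k_clusters = x$k_clusters, n_restarts = x$n_restarts,
    hopkins_fraction = x$hopkins_fraction,
    elbow_range = unlist(x$elbow_range), n_select = x$n_select,
    n_baseline = x$n_baseline, baseline_min_sep = x$baseline_min_sep,
    baseline_equation = x$baseline_equation %||% "eq3",
    n_test_donors = x$n_test_donors, seed = x$seed, out_dir = x$out_dir)
  cfg$zoo <- utils::modifyList(cfg$zoo, x$zoo[!vapply(x$zoo, is.null, TRUE)])
  cfg
}

#' Validate and ingest a measured response table
#'
#' Reads (or validates) a long response CSV with columns `donor_id`,
#' `run_id`, `replicate`, `response`, `value` (optional `block_id`), so real
#' laboratory measurements can replace the simulator. Schema violations are
#' reported with row numbers; viability values outside \[0, 100\] and
#' negative expansion are rejected.
#'
#' @param path CSV path, or a data frame to validate in place.
#' @return A validated response tibble.
#' @export
ingest_responses <- function(path) {
  df <- if (is.data.frame(path)) as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE)
  required <- c("donor_id", "run_id", "replicate", "response", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing required columns: ", paste(missing, collapse = ", ")))
  }
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))
    abort(paste0("non-numeric `value` at rows: ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (!"block_id" %in% names(df)) df$block_id <- df$donor_id
  bad_v <- which(df$response == "viability_d3" &
                 (df$value < 0 | df$value > 100))
  if (length(bad_v) > 0) {
    abort(paste0("viability outside [0, 100] at rows: ",
                 paste(utils::head(bad_v, 10), collapse = ", ")))
  }
  bad_e <- which(df$response == "expansion_d6" & df$value < 0)
  if (length(bad_e) > 0) {
    abort(paste0("negative expansion at rows: ",
                 paste(utils::head(bad_e, 10), collapse = ", ")))
  }
  if (dplyr::n_distinct(df$response) == 1) {
    warn(paste0("responses present for only `", df$response[1],
                "`; only that response's models can be fit"))
  }
  df[, c("donor_id", "block_id", "run_id", "replicate", "response", "value")]
}

#' Run the full optimization pipeline
#'
#' Executes design -> simulate (or ingest) -> fit -> search -> cluster ->
#' select -> baselines -> confirmation from one config, with every stage
#' seeded from the master seed. Rerunning with an identical config
#' reproduces identical outputs. If `config$out_dir` is set, all tabular
#' artifacts are written as CSV, the stage report as JSON, and an
#' md5-hashed manifest covering every emitted file.
#'
#' @param config A [pipeline_config()].
#' @param responses Optional measured response tibble (replaces the
#'   simulator; see [ingest_responses()]).
#' @return A `media_pipeline` result list (design, responses, zoo, pool,
#'   clustering, selection, baselines, evaluation, manifest).
#' @export
run_pipeline <- function(config, responses = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(nm) derive_seed(seed, nm)
  scenario <- resolve_scenario(config)

  # design
  design <- generate_dsd(config$k)
  blocks <- dsd_blocks(design, config$n_blocks, seed = stage("design"))

  # simulate or ingest
  profiles <- sample_donor_profiles(config$n_blocks, scenario,
                                    seed = stage("profiles"))
  if (is.null(responses)) {
    responses <- simulate_responses(profiles, blocks,
                                    replicates = config$replicates,
                                    seed = stage("simulate"))
  } else {
    responses <- ingest_responses(responses)
  }

  # fit
  zoo <- fit_model_zoo(blocks, responses, algorithms = config$algorithms,
                       equations = config$equations, config = config$zoo,
                       seed = stage("fit"))

  # search
  formulations <- sample_formulations(config$n_search, config$k,
                                      constraints = config$constraints,
                                      factor_ids = design_factors(design),
                                      seed = stage("search"))
  pool <- top_n_pool(zoo$finals, formulations, n_top = config$n_top)

  # cluster
  scaled <- scale_pool(pool)
  hopkins <- hopkins_statistic(scaled, config$hopkins_fraction,
                               seed = stage("hopkins"))
  elbow <- elbow_curve(scaled, config$elbow_range,
                       n_restarts = config$n_restarts, seed = stage("elbow"))
  solution <- kmeans_cluster(scaled, config$k_clusters,
                             n_restarts = config$n_restarts,
                             seed = stage("cluster"))
  composition <- cluster_composition(pool, solution)
  media <- cluster_media(pool, solution)

  # select
  backeval <- back_evaluate(media, zoo$finals)
  selection <- select_cluster_media(composition, backeval, media,
                                    n_select = config$n_select)

  # baselines (the pooled arm needs at least two donor blocks)
  naive <- naive_ensemble(pool)
  naive_media <- bind_cols(tibble(cluster = 0L, n_members = nrow(pool)), naive)
  attr(naive_media, "factor_ids") <- design_factors(design)
  naive_backeval <- back_evaluate(naive_media, zoo$finals)
  if (config$n_blocks >= 2) {
    pooled_model <- fit_pooled_ols(blocks, responses,
                                   equation = config$baseline_equation,
                                   config = config$zoo,
                                   seed = stage("pooled"))
    baseline_media <- select_baseline_media(pooled_model, formulations,
                                            n = config$n_baseline,
                                            min_sep = config$baseline_min_sep)
    confirmation <- run_confirmation(config, scenario, selection, backeval,
                                     baseline_media, pooled_model, stage)
  } else {
    warn("single donor block: skipping the pooled baseline and confirmation stages")
    pooled_model <- NULL
    baseline_media <- NULL
    confirmation <- NULL
  }

  result <- structure(list(
    config = config, scenario = scenario, design = design, blocks = blocks,
    profiles = profiles, responses = responses, zoo = zoo,
    formulations = formulations, pool = pool, hopkins = hopkins,
    elbow = elbow, solution = solution, composition = composition,
    media = media, back_eval = backeval, selection = selection,
    pooled_model = pooled_model, baseline_media = baseline_media,
    naive = naive, naive_back_eval = naive_backeval,
    confirmation = confirmation, manifest = NULL), class = "media_pipeline")
  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config$out_dir)
  }
  result
}

# confirmation experiment: selected cluster media + baseline media +
# reference, simulated in every fresh test donor as one randomized block
run_confirmation <- function(config, scenario, selection, backeval,
                             baseline_media, pooled_model, stage) {
  ids <- scenario$factor_ids
  cluster_rows <- selection$selected
  conf_design <- bind_rows(
    bind_cols(tibble(run_id = paste0("Cluster", cluster_rows$cluster),
                     run_role = "confirmation"),
              cluster_rows[, ids]),
    bind_cols(tibble(run_id = baseline_media$formulation_id,
                     run_role = "confirmation"),
              baseline_media[, ids]),
    tibble(run_id = "ref", run_role = "reference"))
  conf_design$block_id <- NA_character_

  test_profiles <- sample_donor_profiles(
    config$n_test_donors, scenario, seed = stage("test_donors"),
    donor_ids = sprintf("t%02d", seq_len(config$n_test_donors)))
  test_responses <- map(test_profiles, function(p) {
    d <- conf_design
    d$block_id <- p$donor_id
    simulate_block(p, d, replicates = config$replicates,
                   seed = stage(paste0("confirm_", p$donor_id)))
  }) |> bind_rows()

  # predictions: individual-model median/IQR for cluster media,
  # single pooled-model value for the baseline media
  pred_cluster <- backeval$summary |>
    filter(.data$cluster %in% cluster_rows$cluster) |>
    mutate(formulation_id = paste0("Cluster", .data$cluster),
           arm = "individual_models") |>
    select("formulation_id", "response", predicted = "predicted_median",
           predicted_iqr = "predicted_iqr", "arm")
  pred_baseline <- tibble(
    formulation_id = baseline_media$formulation_id,
    response = pooled_model$response,
    predicted = baseline_media$predicted,
    predicted_iqr = NA_real_, arm = "pooled_model")
  predictions <- bind_rows(pred_cluster, pred_baseline)

  evaluation <- evaluate_on_test_set(
    distinct(predictions, .data$formulation_id), test_responses, predictions)

  list(design = conf_design, test_profiles = test_profiles,
       responses = test_responses, predictions = predictions,
       evaluation = evaluation,
       n_runs = nrow(conf_design) * length(test_profiles))
}

#' @export
print.media_pipeline <- function(x, ...) {
  cat("<media_pipeline>\n")
  cat(sprintf("  %d-factor DSD, %d blocks, %d training runs\n",
              x$config$k, x$config$n_blocks, nrow(x$blocks)))
  cat(sprintf("  models: %d candidates -> %d finals\n",
              nrow(x$zoo$candidates), nrow(x$zoo$finals)))
  cat(sprintf("  pool: %d candidates; hopkins %.3f; k = %d clusters, avg silhouette %.3f\n",
              nrow(x$pool), x$hopkins, x$solution$k, x$solution$avg_silhouette))
  cat(sprintf("  selected clusters: %s\n",
              paste(x$selection$selected$cluster, collapse = ", ")))
  if (!is.null(x$confirmation)) {
    cat(sprintf("  confirmation: %d runs on %d test donors\n",
                x$confirmation$n_runs, x$config$n_test_donors))
  }
  invisible(x)
}

# write all tabular artifacts + JSON report, return hash manifest
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_design_csv(result$blocks, p("design.csv"))
  readr::write_csv(result$responses, p("responses.csv"))
  readr::write_csv(zoo_metrics(result$zoo), p("model_metrics.csv"))
  readr::write_csv(as_tibble(result$pool), p("pool.csv"))
  readr::write_csv(tibble(idx = seq_along(result$solution$assignments),
                          cluster = result$solution$assignments),
                   p("cluster_assignments.csv"))
  readr::write_csv(result$media, p("cluster_media.csv"))
  readr::write_csv(result$composition$by_response, p("cluster_composition.csv"))
  readr::write_csv(result$back_eval$summary, p("back_evaluation.csv"))
  if (!is.null(result$baseline_media)) {
    readr::write_csv(result$baseline_media, p("baseline_media.csv"))
    readr::write_csv(result$confirmation$evaluation, p("evaluation.csv"))
  }
  report <- list(
    version = as.character(utils::packageVersion("mediaforge")),
    seed = result$config$seed,
    hopkins = result$hopkins,
    avg_silhouette = result$solution$avg_silhouette,
    tot_withinss = result$solution$tot_withinss,
    selected_clusters = result$selection$selected$cluster,
    rationale = result$selection$rationale,
    pooled_model = if (is.null(result$pooled_model)) NULL else
      result$pooled_model$metrics,
    final_models = purrr::transpose(as.list(zoo_metrics(result$zoo))))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(
    list(created = format(Sys.time(), tz = "UTC"),
         version = as.character(utils::packageVersion("mediaforge")),
         seed = result$config$seed,
         files = purrr::transpose(as.list(manifest))),
    p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  manifest
}
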