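#' Fit the competitive per-donor model zoo
#'
#' For every donor block and every response, fits one candidate model per
#' (algorithm, equation) combination — with the default three algorithms and
#' three nested equations that is 9 candidates per cell, 72 for a four-donor
#' two-response study — and selects one final model per cell with
#' [rank_and_select()]. Reference runs are excluded (their coded levels are
#' outside the factor space). Candidate ids follow the pattern
#' `b<block>.model<n><e|v>` with `n` enumerating OLS (eq1-3), random forest
#' (eq4-6 positions) and elastic net (7-9), and the suffix the response's
#' first letter.
#'
#' @param blocks Assembled design blocks ([dsd_blocks()]).
#' @param responses Long response tibble ([simulate_responses()] or
#'   [ingest_responses()]).
#' @param algorithms,equations Candidate grid.
#' @param config [zoo_config()] tuning settings.
#' @param seed Master seed for fold assignment and forests.
#' @return A `media_zoo`: list with `candidates` (tibble of all fitted
#'   candidates with metrics and a `model` list-column) and `finals`
#'   (the selected winner per donor and response).
#' @export
fit_model_zoo <- function(blocks, responses,
                          algorithms = c("ols_stepwise", "random_forest", "elastic_net"),
                          equations = c("eq1", "eq2", "eq3"),
                          config = zoo_config(), seed = 1L) {
  ids <- design_factors(blocks)
  dsd <- blocks[blocks$run_role == "dsd_formulation", , drop = FALSE]
  dat <- dplyr::inner_join(
    responses,
    dsd[, c("block_id", "run_id", ids)],
    by = c("block_id", "run_id"))
  if (nrow(dat) == 0) abort("no response rows match the design's dsd runs")

  cells <- distinct(dat, .data$donor_id, .data$block_id, .data$response)
  specs <- tidyr::expand_grid(algorithm = algorithms, equation = equations)
  specs$spec_index <- seq_len(nrow(specs))

  candidates <- pmap(cells, function(donor_id, block_id, response) {
    cell <- dat[dat$donor_id == donor_id & dat$response == response, ]
    block_n <- as.integer(sub("^b", "", block_id))
    pmap(specs, function(algorithm, equation, spec_index) {
      model_id <- sprintf("b%d.model%d%s", block_n, spec_index,
                          substr(response, 1, 1))
      m <- fit_model_impl(
        cell[, ids], cell$value, algorithm, equation,
        run_id = if (identical(config$fold_by, "run")) cell$run_id else NULL,
        config = config,
        seed = derive_seed(seed, model_id), cv = TRUE,
        donor_id = donor_id, response = response, model_id = model_id)
      tibble(donor_id = donor_id, response = response, model_id = model_id,
             algorithm = algorithm, equation = equation,
             cv_rmse = m$metrics$cv_rmse, cv_r2 = m$metrics$cv_r2,
             train_rmse = m$metrics$train_rmse, train_r2 = m$metrics$train_r2,
             model = list(m))
    }) |> bind_rows()
  }) |> bind_rows()

  structure(list(candidates = candidates,
                 finals = rank_and_select(candidates)),
            class = "media_zoo")
}

#' @export
print.media_zoo <- function(x, ...) {
  cat(sprintf("<media_zoo: %d candidate models, %d finals>\n",
              nrow(x$candidates), nrow(x$finals)))
  print(select(x$finals, -"model"))
  invisible(x)
}

#' Rank candidates and select one final model per donor and response
#'
#' Candidates are ranked by ascending cross-validated RMSE with ties broken
#' by descending cross-validated R-squared. The selection is restricted to
#' elastic-net and random-forest candidates: regularised and ensemble models
#' are preferred over stepwise OLS for prediction because of their greater
#' robustness to overfitting, even when an OLS candidate scores better.
#'
#' @param candidates Candidate tibble from [fit_model_zoo()].
#' @param eligible Algorithms eligible for final selection.
#' @return Tibble of winners, one row per (donor, response).
#' @export
rank_and_select <- function(candidates,
                            eligible = c("elastic_net", "random_forest")) {
  pool <- candidates[candidates$algorithm %in% eligible, , drop = FALSE]
  if (nrow(pool) == 0) abort("no eligible candidate models to select from")
  pool |>
    group_by(.data$donor_id, .data$response) |>
    arrange(.data$cv_rmse, desc(.data$cv_r2), .data$model_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Final-model metrics table
#'
#' The per-donor, per-response metric table of the selected finals (train
#' and cross-validated RMSE and R-squared), suitable for CSV export.
#'
#' @param zoo A `media_zoo`.
#' @return A tibble without model objects.
#' @export
zoo_metrics <- function(zoo) {
  select(zoo$finals, "donor_id", "response", "model_id", "algorithm",
         "equation", "train_rmse", "train_r2", "cv_rmse", "cv_r2")
}
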