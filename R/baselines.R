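#' Pooled single-response OLS baseline
#'
#' The traditional comparison arm: all donors' expansion data are pooled
#' (donor identity discarded) and one stepwise-AIC OLS model is fitted on
#' centred/scaled features, with cross-validated and train metrics recorded.
#' Pooling across heterogeneous donors typically costs predictive accuracy
#' relative to the per-donor models.
#'
#' @param blocks Assembled design blocks.
#' @param responses Long response tibble (all donors).
#' @param response Which response to pool (default day-6 expansion).
#' @param equation Model equation for the stepwise scope.
#' @param config [zoo_config()].
#' @param seed Integer seed.
#' @return A `media_model` with `donor_id = "pooled"`.
#' @export
fit_pooled_ols <- function(blocks, responses, response = "expansion_d6",
                           equation = "eq3", config = zoo_config(), seed = 1L) {
  ids <- design_factors(blocks)
  dsd <- blocks[blocks$run_role == "dsd_formulation", , drop = FALSE]
  dat <- dplyr::inner_join(responses[responses$response == response, ],
                           dsd[, c("block_id", "run_id", ids)],
                           by = c("block_id", "run_id"))
  if (dplyr::n_distinct(dat$donor_id) < 2) {
    abort("pooled baseline needs blocks from at least 2 donors")
  }
  fit_model_impl(dat[, ids], dat$value, "ols_stepwise", equation,
                 run_id = if (identical(config$fold_by, "run"))
                   paste(dat$block_id, dat$run_id) else NULL,
                 config = config,
                 seed = seed, cv = TRUE, donor_id = "pooled",
                 response = response, model_id = "pooled.ols")
}

#' Select diverse baseline media from the pooled model
#'
#' Greedy selection of `n` formulations maximising the pooled model's
#' predicted response subject to a minimum pairwise Chebyshev (L-infinity)
#' separation, so the baseline media differ in component composition. If the
#' separation makes `n` selections infeasible it is halved with a warning
#' until enough candidates qualify.
#'
#' @param model The pooled `media_model`.
#' @param candidates Coded candidate tibble (the in-silico sample under the
#'   study constraints).
#' @param n Number of media to select.
#' @param min_sep Minimum pairwise L-infinity distance (coded units);
#'   `0` reduces to the top-`n` ranked candidates.
#' @return Tibble of `n` formulations with `formulation_id` (`T01 ...`) and
#'   `predicted`.
#' @export
select_baseline_media <- function(model, candidates, n = 6, min_sep = 0.5) {
  p <- predict(model, candidates)
  ord <- order(-p, seq_along(p))
  X <- coded_matrix(candidates, design_factors(candidates))
  sep <- min_sep
  repeat {
    chosen <- integer(0)
    for (i in ord) {
      if (length(chosen) == 0 ||
          all(apply(abs(X[chosen, , drop = FALSE] -
                        matrix(X[i, ], nrow = length(chosen), ncol = ncol(X),
                               byrow = TRUE)), 1, max) >= sep)) {
        chosen <- c(chosen, i)
        if (length(chosen) == n) break
      }
    }
    if (length(chosen) == n || sep < 1e-8) break
    warn(sprintf("separation %.3g infeasible for %d media; relaxing to %.3g",
                 sep, n, sep / 2))
    sep <- sep / 2
  }
  out <- bind_cols(
    tibble(formulation_id = sprintf("T%02d", seq_along(chosen))),
    candidates[chosen, , drop = FALSE],
    tibble(predicted = p[chosen]))
  out
}

#' Naive component-wise median ensemble
#'
#' The ablation baseline: the component-wise median over the (optionally
#' response-filtered) pooled top formulations, with no clustering step —
#' equivalent to [cluster_median_formulation()] applied to the whole pool as
#' a single cluster.
#'
#' @param pool A `candidate_pool`.
#' @param response Response filter (default: expansion-derived candidates
#'   only); `NULL` uses the whole pool.
#' @return One-row coded tibble.
#' @export
naive_ensemble <- function(pool, response = "expansion_d6") {
  if (!is.null(response)) pool <- pool[pool$response == response, , drop = FALSE]
  if (nrow(pool) == 0) abort("pool is empty after response filtering")
  med <- cluster_median_formulation(pool)
  as_tibble(as.list(med))
}

#' Compare predictions against a confirmation test set
#'
#' For every formulation and response: averages replicates within each test
#' donor, summarises across donors by median and IQR, and pairs the result
#' with the supplied predictions, reporting the absolute prediction error.
#'
#' @param formulations Tibble with a `formulation_id` column (coded columns
#'   optional; identification is by id).
#' @param test_responses Long response tibble for the confirmation runs,
#'   with `run_id` equal to the formulation id.
#' @param predictions Tibble with `formulation_id`, `response`, `predicted`
#'   (and optionally `predicted_iqr`).
#' @return Evaluation tibble: one row per formulation x response with
#'   `predicted`, `experimental_median`, `experimental_iqr`, `abs_error`.
#' @export
evaluate_on_test_set <- function(formulations, test_responses, predictions) {
  needed <- tidyr::expand_grid(
    formulation_id = formulations$formulation_id,
    donor_id = unique(test_responses$donor_id))
  have <- distinct(test_responses, formulation_id = .data$run_id, .data$donor_id)
  gaps <- dplyr::anti_join(needed, have, by = c("formulation_id", "donor_id"))
  if (nrow(gaps) > 0) {
    abort(paste0("test responses missing for: ",
                 paste(paste(gaps$formulation_id, gaps$donor_id, sep = "/"),
                       collapse = ", ")))
  }
  experimental <- test_responses |>
    filter(.data$run_id %in% formulations$formulation_id) |>
    group_by(formulation_id = .data$run_id, .data$donor_id, .data$response) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    group_by(.data$formulation_id, .data$response) |>
    summarise(experimental_median = stats::median(.data$value),
              experimental_iqr = stats::IQR(.data$value),
              n_donors = dplyr::n(), .groups = "drop")
  dplyr::inner_join(predictions, experimental,
                    by = c("formulation_id", "response")) |>
    mutate(abs_error = abs(.data$predicted - .data$experimental_median))
}
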