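#' Component constraints for the in-silico search
#'
#' A constraint fixes a component at a coded value or bounds it from above
#' or below; the study's own constraint fixes `c02` at its medium level
#' (coded 0) because that component was to be kept low-cost.
#'
#' @param factor_id Component label.
#' @param kind `"fix"`, `"upper_bound"` or `"lower_bound"`.
#' @param value Coded value in `[-1, 1]`.
#' @return A one-row constraint tibble; combine with `bind_rows()`.
#' @export
constraint <- function(factor_id, kind = c("fix", "upper_bound", "lower_bound"),
                       value) {
  kind <- match.arg(kind)
  if (abs(value) > 1) abort("constraint value must lie in [-1, 1]")
  tibble(factor_id = factor_id, kind = kind, value = as.numeric(value))
}

# resolve constraints into per-column [lo, hi] sampling ranges
constraint_ranges <- function(constraints, factor_ids) {
  lo <- stats::setNames(rep(-1, length(factor_ids)), factor_ids)
  hi <- stats::setNames(rep(1, length(factor_ids)), factor_ids)
  if (!is.null(constraints) && nrow(constraints) > 0) {
    unknown <- setdiff(constraints$factor_id, factor_ids)
    if (length(unknown) > 0) {
      abort(paste0("constraints on unknown factors: ", paste(unknown, collapse = ", ")))
    }
    for (i in seq_len(nrow(constraints))) {
      f <- constraints$factor_id[i]
      v <- constraints$value[i]
      switch(constraints$kind[i],
        fix = { lo[f] <- max(lo[f], v); hi[f] <- min(hi[f], v) },
        upper_bound = hi[f] <- min(hi[f], v),
        lower_bound = lo[f] <- max(lo[f], v))
    }
    bad <- lo > hi
    if (any(bad)) {
      abort(paste0("conflicting constraints on: ",
                   paste(factor_ids[bad], collapse = ", ")))
    }
  }
  list(lo = lo, hi = hi)
}

#' Sample random in-silico formulations
#'
#' Draws `n` formulations over the experimental space: every free component
#' is independent continuous uniform on `[-1, 1]`; fixed components sit
#' exactly at their constraint value; bounded components are uniform on the
#' restricted interval.
#'
#' @param n Number of formulations.
#' @param k Number of components.
#' @param constraints Constraint tibble ([constraint()]) or `NULL`.
#' @param factor_ids Component labels.
#' @param seed Integer seed (identical draws at identical seed).
#' @return Tibble of `n` coded formulations.
#' @export
sample_formulations <- function(n, k, constraints = NULL,
                                factor_ids = default_factor_ids(k), seed = 1L) {
  stopifnot(n >= 1)
  rng <- constraint_ranges(constraints, factor_ids)
  X <- withr::with_seed(seed, {
    m <- matrix(stats::runif(n * k), nrow = n)
    sweep(sweep(m, 2, rng$hi - rng$lo, "*"), 2, rng$lo, "+")
  })
  colnames(X) <- factor_ids
  as_tibble(X)
}

#' Pool the top-ranked formulations of every final model
#'
#' Ranks the shared formulation set under each final model (predictions
#' sorted descending; both responses are maximised), takes the first
#' `n_top` per model with ties broken by formulation row index, and
#' concatenates them with full provenance. Duplicates across models are
#' retained, so with 8 final models and `n_top = 40` the pool has 320
#' members.
#'
#' @param finals Finals tibble from [fit_model_zoo()] (with `model`
#'   list-column), or a list of `media_model`s.
#' @param formulations Coded formulation tibble ([sample_formulations()]).
#' @param n_top Candidates kept per model.
#' @return A `candidate_pool` tibble: coded columns plus `donor_id`,
#'   `response`, `model_id`, `predicted`, `rank`.
#' @export
top_n_pool <- function(finals, formulations, n_top = 40) {
  models <- if (is.data.frame(finals)) finals$model else finals
  if (n_top > nrow(formulations)) abort("n_top exceeds number of formulations")
  pool <- map(models, function(m) {
    p <- predict(m, formulations)
    idx <- order(-p, seq_along(p))[seq_len(n_top)]
    bind_cols(
      formulations[idx, , drop = FALSE],
      tibble(donor_id = m$donor_id, response = m$response,
             model_id = m$model_id, predicted = p[idx],
             rank = seq_len(n_top)))
  }) |> bind_rows()
  structure(pool, class = c("candidate_pool", class(pool)))
}

#' Coded columns of a candidate pool
#' @param pool A `candidate_pool` or any tibble with coded columns.
#' @return Numeric matrix of coded levels.
#' @export
pool_matrix <- function(pool) {
  coded_matrix(pool, design_factors(pool))
}
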