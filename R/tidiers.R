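#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted media model
#'
#' Linear models (stepwise OLS, elastic net) return one row per retained
#' coefficient (scaled-feature units); random forests return impurity
#' variable importance.
#'
#' @param x A `media_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy media_model
#' @export
tidy.media_model <- function(x, ...) {
  if (x$core$kind == "linear") {
    cf <- x$core$coef
    out <- tibble(term = c("(Intercept)", names(cf)),
                  estimate = c(x$core$intercept, unname(cf)))
    out[out$term == "(Intercept)" | out$estimate != 0, ]
  } else {
    imp <- ranger::importance(x$core$forest)
    if (length(imp) == 0) {
      tibble(term = names(x$scaler$mean), importance = NA_real_)
    } else {
      tibble(term = names(imp), importance = unname(imp))
    }
  }
}

#' One-row model summary
#'
#' @param x A `media_model`.
#' @param ... Unused.
#' @return Tibble with ids, algorithm, equation and train/CV metrics.
#' @method glance media_model
#' @export
glance.media_model <- function(x, ...) {
  tibble(model_id = x$model_id, donor_id = x$donor_id, response = x$response,
         algorithm = x$algorithm, equation = x$equation,
         cv_rmse = x$metrics$cv_rmse, cv_r2 = x$metrics$cv_r2,
         train_rmse = x$metrics$train_rmse, train_r2 = x$metrics$train_r2)
}

#' Candidate metric table of a model zoo
#' @param x A `media_zoo`.
#' @param ... Unused.
#' @return Tibble of all candidates' metrics (no model objects).
#' @method tidy media_zoo
#' @export
tidy.media_zoo <- function(x, ...) select(x$candidates, -"model")

#' Final-model summary of a model zoo
#' @param x A `media_zoo`.
#' @param ... Unused.
#' @method glance media_zoo
#' @export
glance.media_zoo <- function(x, ...) zoo_metrics(x)

#' Per-point cluster assignments and silhouette widths
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  out <- tibble(idx = seq_along(x$assignments), cluster = x$assignments)
  if (!is.null(x$silhouette)) out$sil_width <- x$silhouette$width
  out
}

#' One-row clustering summary
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble(k = x$k, n = length(x$assignments), tot_withinss = x$tot_withinss,
         avg_silhouette = x$avg_silhouette)
}
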