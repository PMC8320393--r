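#' Hopkins statistic of clustering tendency
#'
#' Compares nearest-neighbour distances of `m` uniform pseudo-points
#' (sampled in the data's bounding box) against those of `m` sampled real
#' points: `H = sum(u) / (sum(u) + sum(w))`, where `u` are pseudo-point to
#' nearest-data distances and `w` are sampled-point to nearest-other-data
#' distances. Values near 0.5 indicate spatial uniformity (no structure);
#' values toward 1 indicate clustering.
#'
#' @param points Numeric matrix (rows = observations).
#' @param sample_fraction Fraction of points sampled, default 0.1
#'   (`m = ceiling(fraction * n)`).
#' @param seed Integer seed.
#' @return A single value in (0, 1).
#' @export
hopkins_statistic <- function(points, sample_fraction = 0.1, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  m <- ceiling(sample_fraction * n)
  if (n < 2 * m || m < 1) abort("too few points for the Hopkins statistic")
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  withr::with_seed(seed, {
    pseudo <- sweep(sweep(matrix(stats::runif(m * ncol(points)), nrow = m),
                          2, hi - lo, "*"), 2, lo, "+")
    idx <- sample(n, m)
    du <- cross_dist(pseudo, points)
    u <- apply(du, 1, min)
    dw <- cross_dist(points[idx, , drop = FALSE], points)
    dw[cbind(seq_len(m), idx)] <- Inf  # exclude self
    w <- apply(dw, 1, min)
    sum(u) / (sum(u) + sum(w))
  })
}

#' Cluster scaled points with k-means
#'
#' Best-of-`n_restarts` k-means (Hartigan-Wong) under a fixed seed on
#' centred and scaled coordinates. Use [scale_pool()] to scale a candidate
#' pool first.
#'
#' @param points_scaled Numeric matrix of centred/scaled points.
#' @param k Number of clusters (`1 <= k <= n`).
#' @param n_restarts Random restarts; the solution with the lowest total
#'   within-cluster sum of squares is kept.
#' @param max_iter Iteration cap per restart.
#' @param seed Integer seed.
#' @return A `cluster_solution`: `k`, `assignments`, `centers` (scaled
#'   space), `withinss`, `tot_withinss`, `sizes`, and (for `k >= 2`)
#'   per-point `silhouette` widths and their `avg_silhouette`.
#' @export
kmeans_cluster <- function(points_scaled, k, n_restarts = 25, max_iter = 100,
                           seed = 1L) {
  points_scaled <- as.matrix(points_scaled)
  n <- nrow(points_scaled)
  if (k > n) abort("k exceeds the number of points")
  km <- if (k == n) {
    # every point its own cluster: exact zero-WSS solution
    list(cluster = seq_len(n), centers = points_scaled,
         withinss = rep(0, n), tot.withinss = 0, size = rep(1L, n))
  } else {
    withr::with_seed(seed,
      stats::kmeans(points_scaled, centers = k, nstart = n_restarts,
                    iter.max = max_iter))
  }
  sil <- if (k >= 2) silhouette_widths(points_scaled, km$cluster) else NULL
  structure(list(
    k = k, assignments = unname(km$cluster), centers = km$centers,
    withinss = km$withinss, tot_withinss = km$tot.withinss,
    sizes = unname(km$size),
    silhouette = sil,
    avg_silhouette = if (is.null(sil)) NA_real_ else attr(sil, "average")),
    class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution: k = %d, n = %d, tot WSS = %.2f, avg silhouette = %.3f>\n",
              x$k, length(x$assignments), x$tot_withinss, x$avg_silhouette))
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Within-cluster sum of squares across candidate k (elbow curve)
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate numbers of clusters.
#' @return Tibble of class `elbow_curve` with columns `k`, `tot_withinss`.
#' @export
elbow_curve <- function(points_scaled, k_range = 1:10, n_restarts = 25,
                        seed = 1L) {
  out <- map(k_range, function(kk) {
    sol <- kmeans_cluster(points_scaled, kk, n_restarts = n_restarts,
                          seed = derive_seed(seed, paste0("elbow", kk)))
    tibble(k = kk, tot_withinss = sol$tot_withinss)
  }) |> bind_rows()
  structure(out, class = c("elbow_curve", class(out)))
}

#' Per-point silhouette widths
#'
#' Silhouette width `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the
#' mean within-cluster distance and `b` the mean distance to the nearest
#' other cluster (Euclidean); points in singleton clusters score 0.
#'
#' @param points_scaled Numeric matrix.
#' @param assignments Integer cluster labels (at least 2 clusters).
#' @return Tibble with `cluster`, `neighbor`, `width`; attribute `average`.
#' @export
silhouette_widths <- function(points_scaled, assignments) {
  if (length(unique(assignments)) < 2) {
    abort("silhouette requires at least 2 clusters")
  }
  assignments <- as.integer(assignments)
  sizes <- table(assignments)
  if (all(sizes == 1L)) {
    # every cluster a singleton: widths are 0 by convention
    out <- tibble(cluster = assignments, neighbor = NA_integer_,
                  width = rep(0, length(assignments)))
    attr(out, "average") <- 0
    return(out)
  }
  sil <- cluster::silhouette(assignments,
                             stats::dist(as.matrix(points_scaled)))
  out <- tibble(cluster = as.integer(sil[, "cluster"]),
                neighbor = as.integer(sil[, "neighbor"]),
                width = as.numeric(sil[, "sil_width"]))
  attr(out, "average") <- mean(out$width)
  out
}

#' Centre and scale a candidate pool for clustering
#'
#' Column mean/SD scaling of the coded components, with the scaler recorded
#' so centroids can be mapped back exactly; constant columns (e.g. a fixed
#' constrained component) are centred but not divided.
#'
#' @param pool A `candidate_pool` or coded tibble/matrix.
#' @return Scaled matrix with attribute `scaler`.
#' @export
scale_pool <- function(pool) {
  X <- if (is.data.frame(pool)) pool_matrix(pool) else as.matrix(pool)
  sc <- fit_scaler(X)
  out <- scaler_apply(sc, X)
  attr(out, "scaler") <- sc
  out
}

#' Cluster composition profiles
#'
#' Tallies each cluster's members by response of origin (count and
#' percentage, summing to 100 within a cluster) and by donor of origin,
#' including which donors contribute expansion-response members — the
#' eligibility information used for consensus selection.
#'
#' @param pool The `candidate_pool` that was clustered.
#' @param solution The matching `cluster_solution`.
#' @return A `cluster_profiles` list: `by_response`, `by_donor`, `sizes`.
#' @export
cluster_composition <- function(pool, solution) {
  if (nrow(pool) != length(solution$assignments)) {
    abort("pool and cluster assignments are not aligned")
  }
  df <- tibble(cluster = solution$assignments,
               response = pool$response, donor_id = pool$donor_id)
  by_response <- df |>
    dplyr::count(.data$cluster, .data$response, name = "n") |>
    group_by(.data$cluster) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  by_donor <- df |>
    dplyr::count(.data$cluster, .data$response, .data$donor_id, name = "n")
  sizes <- df |> dplyr::count(.data$cluster, name = "n")
  structure(list(by_response = by_response, by_donor = by_donor,
                 sizes = sizes), class = "cluster_profiles")
}

#' Component-wise median consensus formulation
#'
#' The prototypic formulation of a cluster: the component-wise median of its
#' member formulations (even member counts use the midpoint of the two
#' central order statistics). Each component of the result lies within the
#' members' range for that component.
#'
#' @param members Coded matrix or tibble of member formulations (>= 1 row).
#' @return Named numeric vector, one value per component.
#' @export
cluster_median_formulation <- function(members) {
  X <- if (is.data.frame(members)) pool_matrix(members) else as.matrix(members)
  if (nrow(X) == 0) abort("empty cluster has no median formulation")
  apply(X, 2, stats::median)
}

#' Derive all cluster medium formulations
#'
#' @param pool The clustered `candidate_pool`.
#' @param solution The `cluster_solution`.
#' @return A `cluster_media` tibble: `cluster`, `n_members`, coded columns.
#' @export
cluster_media <- function(pool, solution) {
  ids <- design_factors(pool)
  out <- map(sort(unique(solution$assignments)), function(cl) {
    members <- pool[solution$assignments == cl, , drop = FALSE]
    med <- cluster_median_formulation(members)
    bind_cols(tibble(cluster = cl, n_members = nrow(members)),
              as_tibble(as.list(med)))
  }) |> bind_rows()
  structure(out, class = c("cluster_media", class(out)), factor_ids = ids)
}

#' Back-evaluate consensus formulations in every donor model
#'
#' Predicts each cluster medium formulation's responses with all final
#' per-donor models and summarises per cluster and response by the median
#' and interquartile range across donors — the cross-donor robustness check
#' applied before selecting formulations for confirmation.
#'
#' @param media A `cluster_media` tibble (or any tibble with a `cluster`
#'   column plus coded columns).
#' @param finals Finals tibble (with `model` list-column) or model list
#'   covering every (donor, response).
#' @return A `back_eval` list: `predictions` (cluster x donor x response)
#'   and `summary` (median and IQR per cluster and response).
#' @export
back_evaluate <- function(media, finals) {
  models <- if (is.data.frame(finals)) finals$model else finals
  ids <- attr(media, "factor_ids") %||% design_factors(media)
  X <- media[, ids, drop = FALSE]
  predictions <- map(models, function(m) {
    tibble(cluster = media$cluster, donor_id = m$donor_id,
           response = m$response, model_id = m$model_id,
           predicted = predict(m, X))
  }) |> bind_rows()
  summary <- predictions |>
    group_by(.data$cluster, .data$response) |>
    summarise(predicted_median = stats::median(.data$predicted),
              predicted_iqr = stats::IQR(.data$predicted),
              n_models = dplyr::n(), .groups = "drop")
  structure(list(predictions = predictions, summary = summary),
            class = "back_eval")
}

#' Select consensus formulations for confirmation
#'
#' Eligibility first: clusters whose expansion-response members come from
#' all training donors (full donor representation signals a formulation
#' family every donor's model favours) outrank all others; within each
#' eligibility tier clusters are ranked by back-evaluated median expansion,
#' descending, and the top `n_select` cluster media are returned. If fewer
#' than `n_select` clusters are eligible the selection is filled from the
#' best-ranked remaining clusters with a warning (flagged in the result when
#' none is eligible).
#'
#' @param profiles [cluster_composition()] output.
#' @param back_eval [back_evaluate()] output.
#' @param media [cluster_media()] output.
#' @param n_select Number of formulations to carry forward.
#' @param donors All training donor ids (defaults to those in `profiles`).
#' @param expansion_response Name of the expansion response.
#' @return A `media_selection` list: `selected` (cluster media rows),
#'   `ranking` (per-cluster table with eligibility and rank), `rationale`
#'   (text records) and `warning_no_eligible`.
#' @export
select_cluster_media <- function(profiles, back_eval, media, n_select = 2,
                                 donors = NULL,
                                 expansion_response = "expansion_d6") {
  donors <- donors %||% sort(unique(profiles$by_donor$donor_id))
  coverage <- profiles$by_donor |>
    filter(.data$response == expansion_response) |>
    group_by(.data$cluster) |>
    summarise(n_donors = dplyr::n_distinct(.data$donor_id), .groups = "drop")
  ranking <- back_eval$summary |>
    filter(.data$response == expansion_response) |>
    left_join(coverage, by = "cluster") |>
    mutate(n_donors = dplyr::coalesce(.data$n_donors, 0L),
           eligible = .data$n_donors == length(donors)) |>
    arrange(desc(.data$eligible), desc(.data$predicted_median)) |>
    mutate(rank = row_number())
  n_eligible <- sum(ranking$eligible)
  no_eligible <- n_eligible == 0
  chosen <- ranking$cluster[seq_len(min(n_select, nrow(ranking)))]
  if (n_eligible < n_select) {
    warn(sprintf(paste0("only %d cluster(s) contain expansion formulations ",
                        "from all donors; filling the selection from the ",
                        "best-ranked remaining clusters"), n_eligible))
  }
  rationale <- sprintf(
    "cluster %d selected: expansion members from %d/%d donors, predicted median expansion %.2f",
    chosen,
    ranking$n_donors[match(chosen, ranking$cluster)], length(donors),
    ranking$predicted_median[match(chosen, ranking$cluster)])
  structure(list(
    selected = media[match(chosen, media$cluster), , drop = FALSE],
    ranking = ranking, rationale = rationale, n_eligible = n_eligible,
    warning_no_eligible = no_eligible), class = "media_selection")
}
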