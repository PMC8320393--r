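# toy pool: coded tibble + provenance columns, aligned fake solution
toy_pool <- function() {
  X <- sample_formulations(20, 3, factor_ids = c("c01", "c02", "c03"), seed = 1)
  pool <- dplyr::bind_cols(X, tibble::tibble(
    donor_id = rep(c("d01", "d02"), each = 10),
    response = rep(c("expansion_d6", "viability_d3"), 10),
    model_id = "m", predicted = 1, rank = 1))
  class(pool) <- c("candidate_pool", class(tibble::tibble()))
  pool
}

test_that("hopkins flags tight blobs as clustered and is scale-stable under duplication", {
  blobs <- withr::with_seed(2, rbind(
    matrix(stats::rnorm(400 * 2, 0, 0.01), ncol = 2),
    matrix(stats::rnorm(400 * 2, 1, 0.01), ncol = 2)))
  h <- hopkins_statistic(blobs, seed = 3)
  expect_gt(h, 0.8)
  h_dup <- hopkins_statistic(rbind(blobs, blobs), seed = 3)
  expect_gt(h_dup, 0.8)  # conclusion direction unchanged when points repeat
  expect_error(hopkins_statistic(blobs[1:3, ], sample_fraction = 0.5),
               "too few points")
})

test_that("k-means covers the degenerate k = 1 and k = n limits", {
  X <- withr::with_seed(4, matrix(stats::rnorm(30 * 2), 30))
  s1 <- kmeans_cluster(X, 1, seed = 1)
  tss <- sum(sweep(X, 2, colMeans(X))^2)
  expect_equal(s1$tot_withinss, tss, tolerance = 1e-9)
  sn <- kmeans_cluster(X, 30, n_restarts = 5, seed = 1)
  expect_equal(sn$tot_withinss, 0, tolerance = 1e-12)
  expect_error(kmeans_cluster(X, 31), "exceeds")
})

test_that("best-of-restarts k-means matches the exhaustive partition optimum on a 12-point toy", {
  X <- withr::with_seed(5, rbind(matrix(stats::rnorm(6 * 2, 0, 0.3), ncol = 2),
                                 matrix(stats::rnorm(6 * 2, 3, 0.3), ncol = 2)))
  sol <- kmeans_cluster(X, 2, n_restarts = 20, seed = 6)
  # brute force: all 2^11 assignments of points 2..12 (point 1 fixed in cluster 1)
  best <- Inf; best_assign <- NULL
  for (mask in 0:(2^11 - 1)) {
    a <- c(1L, as.integer(intToBits(mask))[1:11] + 1L)
    if (length(unique(a)) < 2) next
    wss <- sum(vapply(1:2, function(cl) {
      pts <- X[a == cl, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    if (wss < best) { best <- wss; best_assign <- a }
  }
  expect_equal(sol$tot_withinss, best, tolerance = 1e-9)
  agree <- mean(sol$assignments == best_assign)
  expect_true(agree == 1 || agree == 0)  # identical up to label swap
})

test_that("the elbow curve is monotone and locates planted blob structure", {
  X <- withr::with_seed(7, rbind(
    cbind(stats::rnorm(40, 0, 0.15), stats::rnorm(40, 0, 0.15)),
    cbind(stats::rnorm(40, 4, 0.15), stats::rnorm(40, 0, 0.15)),
    cbind(stats::rnorm(40, 0, 0.15), stats::rnorm(40, 4, 0.15))))
  ec <- elbow_curve(X, 1:6, n_restarts = 10, seed = 8)
  expect_true(all(diff(ec$tot_withinss) <= 1e-9))
  drops <- -diff(ec$tot_withinss) / ec$tot_withinss[-nrow(ec)]
  expect_equal(ec$k[which.max(drops) + 1L], 3)
  expect_equal(elbow_curve(X, nrow(X), n_restarts = 2, seed = 1)$tot_withinss,
               0, tolerance = 1e-12)
})

test_that("silhouette widths follow the definition, conventions and an O(n^2) oracle", {
  # two singleton clusters score zero by convention
  two <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  s2 <- silhouette_widths(two, c(1, 2))
  expect_equal(s2$width, c(0, 0))
  expect_error(silhouette_widths(two, c(1, 1)), "at least 2 clusters")

  blobs <- withr::with_seed(9, rbind(
    matrix(stats::rnorm(30 * 2, 0, 0.05), ncol = 2),
    matrix(stats::rnorm(30 * 2, 5, 0.05), ncol = 2)))
  sb <- silhouette_widths(blobs, rep(1:2, each = 30))
  expect_gt(attr(sb, "average"), 0.9)

  X <- withr::with_seed(10, matrix(stats::rnorm(15 * 3), 15))
  a <- withr::with_seed(11, sample(1:3, 15, replace = TRUE))
  while (length(unique(a)) < 3) a <- sample(1:3, 15, replace = TRUE)
  sw <- silhouette_widths(X, a)
  D <- as.matrix(stats::dist(X))
  for (i in 1:15) {
    d_by_cl <- vapply(1:3, function(cl) {
      others <- setdiff(which(a == cl), i)
      if (length(others) == 0) NA_real_ else mean(D[i, others])
    }, numeric(1))
    own <- sum(a == a[i])
    if (own == 1) {
      expect_equal(sw$width[i], 0)
    } else {
      ai <- d_by_cl[a[i]]
      bi <- min(d_by_cl[-a[i]], na.rm = TRUE)
      expect_equal(sw$width[i], (bi - ai) / max(ai, bi), tolerance = 1e-12)
    }
  }
  expect_true(all(sw$width >= -1 & sw$width <= 1))
})

test_that("pool scaling records an exactly invertible transform with constant columns", {
  pool <- toy_pool()
  pool$c02 <- 0  # constrained component: zero variance
  Xs <- scale_pool(pool)
  sc <- attr(Xs, "scaler")
  expect_true(sc$constant["c02"])
  expect_true(all(Xs[, "c02"] == 0))
  back <- sweep(sweep(Xs, 2, sc$sd, "*"), 2, sc$mean, "+")
  expect_equal(back, pool_matrix(pool), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("cluster composition tallies counts, percentages and donor coverage", {
  pool <- toy_pool()
  sol <- list(assignments = rep(1:2, each = 10))
  prof <- cluster_composition(pool, sol)
  expect_equal(sum(prof$sizes$n), 20)
  pct_sums <- tapply(prof$by_response$pct, prof$by_response$cluster, sum)
  expect_equal(as.numeric(pct_sums), c(100, 100))
  # hand tally: cluster 1 = rows 1:10 (d01), alternating responses
  c1 <- prof$by_response[prof$by_response$cluster == 1, ]
  expect_equal(sort(c1$n), c(5L, 5L))
  d1 <- prof$by_donor[prof$by_donor$cluster == 1, ]
  expect_equal(unique(d1$donor_id), "d01")
  expect_error(cluster_composition(pool, list(assignments = 1:5)),
               "not aligned")

  one_resp <- pool
  one_resp$response <- "expansion_d6"
  p2 <- cluster_composition(one_resp, sol)
  expect_true(all(p2$by_response$pct == 100))
})

test_that("cluster medians are component-wise order statistics", {
  m <- matrix(c(-1, 0, 1, 0.5), 4, 3, dimnames = list(NULL, paste0("c0", 1:3)))
  expect_equal(unname(cluster_median_formulation(m)),
               rep(stats::median(c(-1, 0, 1, 0.5)), 3))
  same <- matrix(0.3, 5, 2, dimnames = list(NULL, c("c01", "c02")))
  expect_equal(unname(cluster_median_formulation(same)), c(0.3, 0.3))
  expect_equal(unname(cluster_median_formulation(
    matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "c01")))), 0)
  # even counts: midpoint of the two central order statistics (sort oracle)
  X <- withr::with_seed(12, matrix(stats::runif(4 * 6, -1, 1), 4,
                                   dimnames = list(NULL, default_factor_ids(6))))
  med <- cluster_median_formulation(X)
  for (j in 1:6) {
    srt <- sort(X[, j])
    expect_equal(unname(med[j]), (srt[2] + srt[3]) / 2)
  }
  expect_true(all(med >= apply(X, 2, min) & med <= apply(X, 2, max)))
  expect_error(cluster_median_formulation(X[0, , drop = FALSE]), "empty cluster")
})

test_that("cluster media inherit member ranges and back-evaluation matches quantile oracles", {
  pool <- toy_pool()
  sol <- list(assignments = rep(1:2, each = 10))
  media <- cluster_media(pool, sol)
  expect_equal(nrow(media), 2)
  expect_equal(media$n_members, c(10L, 10L))

  # four donor models for one response: median/IQR across donors
  models <- purrr::map(1:4, function(i) {
    X <- sample_formulations(30, 3, factor_ids = c("c01", "c02", "c03"),
                             seed = 20 + i)
    y <- withr::with_seed(30 + i, 2 * X$c01 + i + stats::rnorm(30, 0, 0.1))
    fit_elastic_net(X, y, equation = "eq1", cv = FALSE,
                    config = zoo_config(enet_lambda = 0),
                    donor_id = paste0("d0", i), response = "expansion_d6",
                    model_id = paste0("m", i))
  })
  be <- back_evaluate(media, models)
  expect_equal(nrow(be$predictions), 2 * 4)
  expect_equal(nrow(be$summary), 2)
  for (cl in 1:2) {
    v <- be$predictions$predicted[be$predictions$cluster == cl]
    expect_equal(be$summary$predicted_median[be$summary$cluster == cl],
                 stats::median(v))
    expect_equal(be$summary$predicted_iqr[be$summary$cluster == cl],
                 stats::IQR(v))
  }

  # identical donor models give zero IQR
  same <- purrr::map(1:4, function(i) {
    m <- models[[1]]; m$donor_id <- paste0("d0", i); m
  })
  be0 <- back_evaluate(media, same)
  expect_equal(be0$summary$predicted_iqr, rep(0, 2))
})

test_that("consensus selection filters on donor coverage then ranks by expansion", {
  media <- tibble::tibble(cluster = 1:4, n_members = 10,
                          c01 = 0, c02 = 0, c03 = 0)
  attr(media, "factor_ids") <- paste0("c0", 1:3)
  profiles <- list(by_donor = tibble::tibble(
    cluster = c(1, 1, 1, 1, 2, 2, 3, 3, 3, 3, 4),
    response = c(rep("expansion_d6", 4), rep("expansion_d6", 2),
                 rep("expansion_d6", 4), "expansion_d6"),
    donor_id = c("d01", "d02", "d03", "d04", "d01", "d02",
                 "d01", "d02", "d03", "d04", "d01"),
    n = 1))
  back_eval <- list(summary = tibble::tibble(
    cluster = rep(1:4, each = 2),
    response = rep(c("expansion_d6", "viability_d3"), 4),
    predicted_median = c(28, 85, 33, 84, 30, 83, 35, 82),
    predicted_iqr = 1, n_models = 4))
  sel <- select_cluster_media(profiles, back_eval, media, n_select = 2,
                              donors = paste0("d0", 1:4))
  # clusters 1 and 3 are fully covered; 3 outranks 1 on expansion (30 > 28);
  # clusters 2 and 4 predict higher but lack donor coverage
  expect_equal(sort(sel$selected$cluster), c(1, 3))
  expect_false(sel$warning_no_eligible)
  ranked <- sel$ranking[sel$ranking$eligible, ]
  expect_true(all(ranked$predicted_median[1:2] >=
                  max(0, ranked$predicted_median[-(1:2)])))

  # no eligible cluster: best-ranked returned with a warning flag
  profiles2 <- list(by_donor = profiles$by_donor[5:6, ])
  expect_warning(sel2 <- select_cluster_media(profiles2, back_eval, media,
                                              n_select = 1,
                                              donors = paste0("d0", 1:4)),
                 "0 cluster")
  expect_true(sel2$warning_no_eligible)
  expect_equal(sel2$selected$cluster, 4)  # highest predicted expansion

  # a single eligible cluster is selected regardless of rank
  profiles3 <- list(by_donor = profiles$by_donor[1:4, ])
  expect_warning(
    sel3 <- select_cluster_media(profiles3, back_eval, media, n_select = 2,
                                 donors = paste0("d0", 1:4)),
    "filling the selection")
  expect_equal(sel3$ranking$cluster[sel3$ranking$eligible], 1)
  # the single eligible cluster leads the selection; the shortfall is filled
  expect_equal(sel3$selected$cluster[1], 1)
  expect_equal(nrow(sel3$selected), 2)
})
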