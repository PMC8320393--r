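#' Tuning and cross-validation settings for the model zoo
#'
#' Hyperparameter grids and fold settings shared by all fitting functions.
#' Elastic-net mixing `alpha` runs over \{0, 0.25, 0.5, 0.75, 1\} with 50
#' log-spaced penalties derived from the data (overridable via
#' `enet_lambda`); the random forest tunes the fraction of candidate features
#' per split over \{1/3, 1/2, 2/3, 1\} at a fixed 500 trees.
#'
#' @param folds Cross-validation folds (capped at the number of runs; if
#'   fewer runs than folds, leave-one-out is used with a warning).
#' @param enet_alpha,enet_nlambda,enet_lambda Elastic-net grid.
#' @param rf_mtry_frac,rf_num_trees Random-forest grid.
#' @param stepwise_direction Direction for stepwise-AIC search.
#' @param fold_by `"observation"` (default; replicates are separate
#'   observations, matching a standard tenfold CV on the training table) or
#'   `"run"` (all replicates of a design run share a fold; a stricter,
#'   more pessimistic protocol that guards against replicate leakage).
#' @return A named list of settings.
#' @export
zoo_config <- function(folds = 10, enet_alpha = c(0, 0.25, 0.5, 0.75, 1),
                       enet_nlambda = 50, enet_lambda = NULL,
                       rf_mtry_frac = c(1 / 3, 1 / 2, 2 / 3, 1),
                       rf_num_trees = 500, stepwise_direction = "both",
                       fold_by = c("observation", "run")) {
  list(folds = folds, enet_alpha = enet_alpha, enet_nlambda = enet_nlambda,
       enet_lambda = enet_lambda, rf_mtry_frac = rf_mtry_frac,
       rf_num_trees = rf_num_trees, stepwise_direction = stepwise_direction,
       fold_by = match.arg(fold_by))
}

# run-level fold assignment: all replicates of a run share a fold
make_folds <- function(run_id, folds, seed) {
  runs <- unique(run_id)
  n <- length(runs)
  if (folds > n) {
    warn(sprintf("only %d runs; reducing %d-fold CV to leave-one-out", n, folds))
    folds <- n
  }
  fold_of_run <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  names(fold_of_run) <- runs
  unname(fold_of_run[as.character(run_id)])
}

# ---- per-algorithm fitting on already-scaled features ----------------------

# bidirectional stepwise from the intercept-only model, minimising
# AIC = n log(RSS/n) + 2p with p counting coefficients incl. the intercept;
# rank-deficient candidate fits are rejected, and RSS is floored so a
# numerically exact fit cannot justify further additions
fit_stepwise_core <- function(Xs, y, direction = "both") {
  n <- length(y)
  all_terms <- colnames(Xs)
  aic_of <- function(tms) {
    X1 <- cbind(1, Xs[, tms, drop = FALSE])
    fit <- stats::lm.fit(X1, y)
    if (fit$rank < ncol(X1)) return(Inf)
    rss <- sum(fit$residuals^2)
    n * log(max(rss, n * 1e-12) / n) + 2 * ncol(X1)
  }
  terms <- character(0)
  cur <- aic_of(terms)
  repeat {
    moves <- list()
    if (direction %in% c("both", "forward")) {
      for (t in setdiff(all_terms, terms)) moves[[paste0("+", t)]] <- c(terms, t)
    }
    if (direction %in% c("both", "backward")) {
      for (t in terms) moves[[paste0("-", t)]] <- setdiff(terms, t)
    }
    if (length(moves) == 0) break
    aics <- vapply(moves, aic_of, numeric(1))
    if (min(aics) < cur - 1e-10) {
      cur <- min(aics)
      terms <- moves[[which.min(aics)]]
    } else break
  }
  fit <- stats::lm.fit(cbind(1, Xs[, terms, drop = FALSE]), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(kind = "linear", intercept = unname(cf[1]),
       coef = stats::setNames(cf[-1], terms))
}

# glmnet needs >= 2 columns; pad a zero column for single-feature inputs
glmnet_fit <- function(X, y, alpha, lambda) {
  padded <- ncol(X) < 2
  if (padded) X <- cbind(X, .pad = 0)
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e6)
  attr(fit, "padded") <- padded
  fit
}

glmnet_predict <- function(fit, X, s) {
  if (isTRUE(attr(fit, "padded"))) X <- cbind(X, .pad = 0)
  stats::predict(fit, newx = X, s = s)
}

enet_lambda_grid <- function(Xs, y, config) {
  if (!is.null(config$enet_lambda)) return(sort(config$enet_lambda, decreasing = TRUE))
  if (stats::sd(y) < 1e-12) abort("degenerate response: zero variance")
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / length(y)
  lmax <- max(lmax, 1e-8)
  exp(seq(log(lmax * 1.05), log(lmax * 1e-4), length.out = config$enet_nlambda))
}

fit_enet_core <- function(Xs, y, alpha, lambda_grid, lambda) {
  if (lambda <= 0) {
    # unpenalised limit: exact least squares rather than coordinate descent
    cf <- stats::lm.fit(cbind(1, Xs), y)$coefficients
    cf[is.na(cf)] <- 0
    return(list(kind = "linear", intercept = unname(cf[1]),
                coef = stats::setNames(cf[-1], colnames(Xs))))
  }
  fit <- glmnet_fit(Xs, y, alpha, lambda_grid)
  cf <- as.matrix(stats::coef(fit, s = lambda))
  cf <- cf[c(TRUE, rownames(cf)[-1] != ".pad"), , drop = FALSE]
  list(kind = "linear", intercept = cf[1, 1], coef = cf[-1, 1])
}

predict_linear_core <- function(core, Xs) {
  nm <- names(core$coef)
  drop(core$intercept + Xs[, nm, drop = FALSE] %*% core$coef)
}

rf_mtry_grid <- function(p, config) {
  sort(unique(pmax(1L, floor(config$rf_mtry_frac * p))))
}

fit_rf_core <- function(Xs, y, mtry, num_trees, seed) {
  fit <- ranger::ranger(x = as.data.frame(Xs), y = y, num.trees = num_trees,
                        mtry = mtry, seed = seed, num.threads = 1,
                        importance = "impurity")
  list(kind = "forest", forest = fit)
}

predict_core <- function(core, Xs) {
  if (core$kind == "linear") predict_linear_core(core, Xs)
  else stats::predict(core$forest, data = as.data.frame(Xs),
                      num.threads = 1)$predictions
}

# ---- cross-validation ------------------------------------------------------

#' Cross-validate a model specification
#'
#' Seeded k-fold cross-validation, over observations by default or over
#' design runs when `run_id` groups are supplied (replicates of a run then
#' share a fold). Within every training fold the feature scaler is re-fit
#' (no leakage of held-out information), the algorithm is trained, and
#' held-out points are predicted. For tunable
#' algorithms the hyperparameter grid is evaluated on the same folds and the
#' reported metrics belong to the selected hyperparameters (elastic-net ties
#' break toward larger penalty then larger `alpha`, i.e. the sparser model).
#'
#' Metrics are pooled over held-out points:
#' `cv_rmse = sqrt(mean((obs - pred)^2))` and `cv_r2 = 1 - SSE/SST` with the
#' total sum of squares taken about the mean of the held-out observations.
#'
#' @param formulations Coded matrix/tibble of model inputs.
#' @param y Response vector.
#' @param algorithm `"ols_stepwise"`, `"elastic_net"` or `"random_forest"`.
#' @param equation Model equation (see [build_features()]).
#' @param run_id Grouping vector so replicates of a run share a fold
#'   (default: every row its own run).
#' @param config A [zoo_config()].
#' @param seed Seed for the fold assignment (and forest fits).
#' @return List with `cv_rmse`, `cv_r2`, `hyper` (selected hyperparameters),
#'   and `predictions` (tibble of obs/pred/fold).
#' @export
cross_validate <- function(formulations, y,
                           algorithm = c("ols_stepwise", "elastic_net", "random_forest"),
                           equation = "eq3", run_id = NULL,
                           config = zoo_config(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  F <- build_features(formulations, equation)
  run_id <- run_id %||% seq_len(nrow(F))
  fold <- make_folds(run_id, config$folds, seed)
  nfold <- max(fold)
  split <- map(seq_len(nfold), function(f) {
    sc <- fit_scaler(F[fold != f, , drop = FALSE])
    list(test = which(fold == f),
         Xtr = scaler_apply(sc, F[fold != f, , drop = FALSE]),
         Xte = scaler_apply(sc, F[fold == f, , drop = FALSE]),
         ytr = y[fold != f])
  })

  if (algorithm == "ols_stepwise") {
    pred <- numeric(length(y))
    for (s in split) {
      core <- fit_stepwise_core(s$Xtr, s$ytr, config$stepwise_direction)
      pred[s$test] <- predict_linear_core(core, s$Xte)
    }
    hyper <- list()
  } else if (algorithm == "elastic_net") {
    sc_full <- fit_scaler(F)
    lambda_grid <- enet_lambda_grid(scaler_apply(sc_full, F), y, config)
    alphas <- config$enet_alpha
    # held-out prediction for every (alpha, lambda) combination
    preds <- array(NA_real_,
                   dim = c(length(y), length(alphas), length(lambda_grid)))
    for (s in split) {
      for (a in seq_along(alphas)) {
        fit <- glmnet_fit(s$Xtr, s$ytr, alphas[a], lambda_grid)
        p <- glmnet_predict(fit, s$Xte, lambda_grid)
        preds[s$test, a, ] <- as.matrix(p)
      }
    }
    grid_rmse <- apply(preds, c(2, 3), function(p) rmse(y, p))
    best <- min(grid_rmse)
    cand <- which(grid_rmse <= best + 1e-12, arr.ind = TRUE)
    # sparser first: larger lambda, then larger alpha
    cand <- cand[order(-lambda_grid[cand[, 2]], -alphas[cand[, 1]]), , drop = FALSE]
    a_i <- cand[1, 1]; l_i <- cand[1, 2]
    pred <- preds[, a_i, l_i]
    hyper <- list(alpha = alphas[a_i], lambda = lambda_grid[l_i],
                  lambda_grid = lambda_grid)
  } else {
    p <- ncol(F)
    mtry_grid <- rf_mtry_grid(p, config)
    preds <- matrix(NA_real_, nrow = length(y), ncol = length(mtry_grid))
    for (s in split) {
      for (m in seq_along(mtry_grid)) {
        core <- fit_rf_core(s$Xtr, s$ytr, mtry_grid[m], config$rf_num_trees,
                            seed = derive_seed(seed, paste0("rf", m)))
        preds[s$test, m] <- predict_core(core, s$Xte)
      }
    }
    grid_rmse <- apply(preds, 2, function(p) rmse(y, p))
    m_i <- which.min(grid_rmse)
    pred <- preds[, m_i]
    hyper <- list(mtry = mtry_grid[m_i], num_trees = config$rf_num_trees)
  }

  list(cv_rmse = rmse(y, pred), cv_r2 = rsq(y, pred), hyper = hyper,
       predictions = tibble(obs = y, pred = pred, fold = fold))
}

# ---- fitted-model container ------------------------------------------------

new_media_model <- function(algorithm, equation, factor_ids, scaler, core,
                            hyper, metrics, y_range, donor_id = NA_character_,
                            response = NA_character_, model_id = NA_character_) {
  structure(list(
    model_id = model_id, donor_id = donor_id, response = response,
    algorithm = algorithm, equation = equation, factor_ids = factor_ids,
    scaler = scaler, core = core, hyper = hyper, metrics = metrics,
    y_range = y_range), class = "media_model")
}

#' @export
print.media_model <- function(x, ...) {
  cat(sprintf("<media_model %s: %s / %s, donor %s, response %s>\n",
              x$model_id, x$algorithm, x$equation, x$donor_id, x$response))
  cat(sprintf("  cv_rmse %.3f  cv_r2 %.3f  train_rmse %.3f  train_r2 %.3f\n",
              x$metrics$cv_rmse, x$metrics$cv_r2,
              x$metrics$train_rmse, x$metrics$train_r2))
  invisible(x)
}

#' Predict responses for coded formulations
#'
#' Applies the model's own feature expansion and scaler, then its fitted
#' state. Deterministic for a fitted model; random-forest predictions are
#' bounded by the training response range by construction.
#'
#' @param object A `media_model`.
#' @param newdata Coded matrix or tibble (columns = the model's factors).
#' @param ... Unused.
#' @return Numeric predictions, one per row.
#' @export
predict.media_model <- function(object, newdata, ...) {
  F <- build_features(newdata, object$equation, factor_ids = object$factor_ids)
  if (ncol(F) != length(object$scaler$mean)) abort("formulation width mismatch")
  predict_core(object$core, scaler_apply(object$scaler, F))
}

#' @rdname predict.media_model
#' @param model A `media_model`.
#' @param formulations Coded matrix or tibble.
#' @export
predict_batch <- function(model, formulations) predict(model, formulations)

# shared full-data fitting path
fit_model_impl <- function(formulations, y, algorithm, equation, run_id,
                           config, seed, cv, donor_id, response, model_id) {
  F <- build_features(formulations, equation)
  if (length(y) != nrow(F)) abort("response length does not match formulations")
  cv_res <- if (cv) {
    cross_validate(formulations, y, algorithm, equation, run_id, config, seed)
  } else {
    list(cv_rmse = NA_real_, cv_r2 = NA_real_, hyper = NULL)
  }
  scaler <- fit_scaler(F)
  Xs <- scaler_apply(scaler, F)
  core <- switch(algorithm,
    ols_stepwise = fit_stepwise_core(Xs, y, config$stepwise_direction),
    elastic_net = {
      hy <- cv_res$hyper
      if (is.null(hy)) {
        lambda_grid <- enet_lambda_grid(Xs, y, config)
        hy <- list(alpha = config$enet_alpha[1], lambda = min(lambda_grid),
                   lambda_grid = lambda_grid)
      }
      fit_enet_core(Xs, y, hy$alpha, hy$lambda_grid, hy$lambda)
    },
    random_forest = {
      hy <- cv_res$hyper
      mtry <- hy$mtry %||% rf_mtry_grid(ncol(F), config)[1]
      fit_rf_core(Xs, y, mtry, config$rf_num_trees,
                  seed = derive_seed(seed, "rf_final"))
    })
  train_pred <- predict_core(core, Xs)
  metrics <- list(cv_rmse = cv_res$cv_rmse, cv_r2 = cv_res$cv_r2,
                  train_rmse = rmse(y, train_pred), train_r2 = rsq(y, train_pred))
  new_media_model(algorithm, equation, colnames(coded_or_self(formulations)),
                  scaler, core, cv_res$hyper, metrics, range(y),
                  donor_id, response, model_id)
}

coded_or_self <- function(formulations) {
  if (is.data.frame(formulations)) {
    ids <- design_factors(formulations)
    as.matrix(formulations[, ids, drop = FALSE])
  } else {
    m <- as.matrix(formulations)
    if (is.null(colnames(m))) colnames(m) <- default_factor_ids(ncol(m))
    m
  }
}

#' Fit a single model
#'
#' `fit_ols_stepwise()` runs bidirectional stepwise selection from the
#' intercept-only model over the equation's term set, minimising
#' `AIC = n log(RSS/n) + 2p` (`p` counting coefficients incl. the
#' intercept); `fit_elastic_net()` grid-searches `(alpha, lambda)` by
#' cross-validated RMSE and refits on all data at the winner;
#' `fit_random_forest()` cross-validates the per-split candidate-feature
#' count at 500 trees. Features are centred and scaled before fitting.
#'
#' @inheritParams cross_validate
#' @param cv Compute cross-validated metrics (default `TRUE`; `FALSE` skips
#'   CV and fits with default hyperparameters).
#' @param donor_id,response,model_id Optional provenance labels.
#' @return A `media_model`.
#' @export
fit_ols_stepwise <- function(formulations, y, equation = "eq3", run_id = NULL,
                             config = zoo_config(), seed = 1L, cv = TRUE,
                             donor_id = NA, response = NA, model_id = NA) {
  fit_model_impl(formulations, y, "ols_stepwise", equation, run_id, config,
                 seed, cv, donor_id, response, model_id)
}

#' @rdname fit_ols_stepwise
#' @export
fit_elastic_net <- function(formulations, y, equation = "eq3", run_id = NULL,
                            config = zoo_config(), seed = 1L, cv = TRUE,
                            donor_id = NA, response = NA, model_id = NA) {
  fit_model_impl(formulations, y, "elastic_net", equation, run_id, config,
                 seed, cv, donor_id, response, model_id)
}

#' @rdname fit_ols_stepwise
#' @export
fit_random_forest <- function(formulations, y, equation = "eq3", run_id = NULL,
                              config = zoo_config(), seed = 1L, cv = TRUE,
                              donor_id = NA, response = NA, model_id = NA) {
  fit_model_impl(formulations, y, "random_forest", equation, run_id, config,
                 seed, cv, donor_id, response, model_id)
}
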