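#' Expand coded formulations into model features
#'
#' The three nested model equations of the screening analysis:
#' `eq1` = main effects only; `eq2` = mains + quadratics; `eq3` = the full
#' second-order set (mains, quadratics, all two-factor interactions).
#' Columns are ordered mains by factor index, then quadratics
#' (`<id>_sq`), then interactions lexicographic by factor-index pair
#' (`<id1>_x_<id2>`), so the expansion is deterministic given factor order.
#' For `k = 12`, `eq3` has 12 + 12 + 66 = 90 columns.
#'
#' @param formulations Coded matrix or tibble (columns = factors).
#' @param equation `"eq1"`, `"eq2"` or `"eq3"`.
#' @param factor_ids Factor labels; defaults to the coded columns found.
#' @return Numeric feature matrix with named columns.
#' @export
build_features <- function(formulations, equation = c("eq3", "eq1", "eq2"),
                           factor_ids = NULL) {
  equation <- match.arg(equation)
  if (is.data.frame(formulations)) {
    factor_ids <- factor_ids %||% design_factors(formulations)
    X <- coded_matrix(formulations, factor_ids)
  } else {
    X <- as.matrix(formulations)
    factor_ids <- factor_ids %||% colnames(X) %||% default_factor_ids(ncol(X))
    colnames(X) <- factor_ids
  }
  if (!all(is.finite(X))) abort("coded entries must be finite")
  out <- X
  if (equation %in% c("eq2", "eq3")) {
    Q <- X^2
    colnames(Q) <- paste0(factor_ids, "_sq")
    out <- cbind(out, Q)
  }
  if (equation == "eq3" && ncol(X) >= 2) {
    pairs <- utils::combn(ncol(X), 2)
    tfi <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(tfi) <- paste0(factor_ids[pairs[1, ]], "_x_", factor_ids[pairs[2, ]])
    out <- cbind(out, tfi)
  }
  out
}

# --- centring/scaling state learned on training data ------------------------

# Columns with zero variance are recorded and mapped to 0 after centring
# (never divided by a zero SD); transform o inverse-transform is identity on
# the retained columns.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  constant <- !is.finite(sd) | sd < 1e-12
  sd[constant] <- 1
  structure(list(mean = mu, sd = sd, constant = constant), class = "mf_scaler")
}

scaler_apply <- function(scaler, X) {
  sweep(sweep(X[, names(scaler$mean), drop = FALSE], 2, scaler$mean, "-"),
        2, scaler$sd, "/")
}

scaler_invert <- function(scaler, Xs) {
  sweep(sweep(Xs, 2, scaler$sd, "*"), 2, scaler$mean, "+")
}
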