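#' Define a multi-donor response-surface scenario
#'
#' A scenario describes the population of donor response surfaces the
#' simulator draws from: for each response, a second-order surface in coded
#' units (intercept, main, quadratic and two-factor-interaction coefficients)
#' given as population means plus between-donor standard deviations per
#' coefficient class, a replicate noise SD, response bounds, and the
#' reference-medium performance (a constant outside the coded space).
#'
#' @param k Number of components.
#' @param responses Named list, one element per response, each a list with
#'   `beta0`, `main` (length `k`), `quad` (length `k`), `int` (`k x k`
#'   strictly upper-triangular matrix, or NULL), `sd_beta0`, `sd_main`,
#'   `sd_quad`, `sd_int`, `replicate_sd`, `bounds` (length-2), `reference`
#'   (mean performance of the reference medium).
#' @param factor_ids Coded component labels.
#' @return A `donor_scenario` object.
#' @seealso [default_scenario()], [planted_scenario()]
#' @export
donor_scenario <- function(k, responses, factor_ids = default_factor_ids(k)) {
  stopifnot(length(factor_ids) == k)
  responses <- imap(responses, function(r, nm) {
    r$int <- r$int %||% matrix(0, k, k)
    stopifnot(
      length(r$main) == k, length(r$quad) == k,
      all(dim(r$int) == c(k, k)),
      all(r$int[lower.tri(r$int, diag = TRUE)] == 0)
    )
    for (f in c("sd_beta0", "sd_main", "sd_quad", "sd_int", "replicate_sd")) {
      if (is.null(r[[f]]) || r[[f]] < 0 || !is.finite(r[[f]])) {
        abort(paste0("scenario field `", f, "` for response ", nm,
                     " must be a finite non-negative number"))
      }
    }
    if (r$replicate_sd <= 0) abort("replicate_sd must be > 0")
    r$bounds <- r$bounds %||% c(-Inf, Inf)
    r
  })
  structure(list(k = k, factor_ids = factor_ids, responses = responses),
            class = "donor_scenario")
}

#' Default screening scenario
#'
#' The simulator's default study conditions: 12 components, two responses.
#' Day-6 expansion (abstract "expansion units") is centred at 24 with a
#' handful of strong main effects, negative curvature on the dominant
#' components and weak interactions, spanning roughly 15-32 units over the
#' design with the reference medium near the top of that range. Day-3
#' viability (%) is centred at 82 with one designated toxic-at-high-level
#' component (`c06`, strong negative main effect plus curvature) so that runs
#' split into a <75% and a >75% mode. Replicate noise is 1 unit / 1
#' percentage point, so a well-specified model can reach RMSE near 1.
#'
#' @param k Number of components (the defaults assume `k >= 6`; coefficient
#'   vectors are zero-padded or truncated for other `k`).
#' @return A `donor_scenario`.
#' @export
default_scenario <- function(k = 12) {
  pad <- function(x) { out <- numeric(k); n <- min(k, length(x)); out[seq_len(n)] <- x[seq_len(n)]; out }
  int_exp <- matrix(0, k, k)
  if (k >= 5) { int_exp[1, 3] <- 0.8; int_exp[4, 5] <- -0.5 }
  donor_scenario(k, list(
    expansion_d6 = list(
      beta0 = 25,
      main = pad(c(2.8, 0, 2.2, -1.8, 1.4, 0, 0.9, 0, 0, 0, 0, 0)),
      quad = pad(c(-1.8, 0, -1.2, 0, -0.8, 0, 0, 0, 0, 0, 0, 0)),
      int = int_exp,
      sd_beta0 = 1.5, sd_main = 0.6, sd_quad = 0.2, sd_int = 0.05,
      replicate_sd = 1, bounds = c(0, Inf), reference = 30),
    viability_d3 = list(
      beta0 = 82,
      main = pad(c(1.5, 0, 0.8, 0, 0, -10, 0, 2.0, 0, 0, -1.2, 0)),
      quad = pad(c(0, 0, 0, 0, 0, -3, 0, 0, 0, 0, 0, 0)),
      int = NULL,
      sd_beta0 = 2, sd_main = 0.6, sd_quad = 0.2, sd_int = 0.03,
      replicate_sd = 1, bounds = c(0, 100), reference = 90)
  ))
}

#' Scenario with a planted shared optimum
#'
#' Both responses are concave quadratic surfaces whose unconstrained argmax
#' sits at `x_star` on the components where `x_star` is non-zero (via
#' `main = -2 * quad * x_star`). Between-donor deviations are kept small
#' relative to the curvature so that every donor's true optimum stays within
#' a few hundredths of `x_star` — the premise of a genuinely shared optimum.
#' Used for end-to-end parameter-recovery checks.
#'
#' @param k Number of components.
#' @param x_star Coded optimum (length `k`, entries in `[-1, 1]`). The
#'   default keeps `c02` at 0, consistent with the study's constraint of
#'   that component to its medium level.
#' @param strength Curvature magnitude on the active components.
#' @param sd_scale Multiplier on the (small) between-donor SDs.
#' @return A `donor_scenario` with attribute `x_star`.
#' @export
planted_scenario <- function(k = 12,
                             x_star = c(0.6, 0, -0.5, 0.7, -0.4, 0.5, rep(0, max(0, k - 6)))[seq_len(k)],
                             strength = 2, sd_scale = 1) {
  stopifnot(length(x_star) == k, all(abs(x_star) <= 1))
  active <- seq_len(min(k, 6))
  quad_e <- numeric(k); quad_e[active] <- -strength
  main_e <- -2 * quad_e * x_star
  quad_v <- numeric(k); quad_v[active] <- -strength * 0.75
  main_v <- -2 * quad_v * x_star
  sc <- donor_scenario(k, list(
    expansion_d6 = list(
      beta0 = 24, main = main_e, quad = quad_e, int = NULL,
      sd_beta0 = 0.8, sd_main = 0.1 * sd_scale, sd_quad = 0.05 * sd_scale,
      sd_int = 0, replicate_sd = 1, bounds = c(0, Inf), reference = 26),
    viability_d3 = list(
      beta0 = 85, main = main_v, quad = quad_v, int = NULL,
      sd_beta0 = 1, sd_main = 0.1 * sd_scale, sd_quad = 0.05 * sd_scale,
      sd_int = 0, replicate_sd = 1, bounds = c(0, 100), reference = 88)
  ))
  attr(sc, "x_star") <- x_star
  sc
}
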