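#' Draw donor effect profiles from a scenario population
#'
#' Each donor's surface coefficients are the scenario's population means plus
#' independent Gaussian donor-specific deviations (per coefficient class).
#' With all between-donor SDs zero the donors are identical.
#'
#' @param n_donors Number of donors.
#' @param scenario A [donor_scenario()].
#' @param seed Integer seed; draws are reproducible bitwise.
#' @param donor_ids Optional labels (default `d01 ...`).
#' @return A list of `donor_profile` objects, each holding per-response
#'   `beta0`, `main`, `quad`, `int` and the scenario's noise model.
#' @export
sample_donor_profiles <- function(n_donors, scenario, seed = 1L,
                                  donor_ids = sprintf("d%02d", seq_len(n_donors))) {
  stopifnot(inherits(scenario, "donor_scenario"))
  k <- scenario$k
  iu <- upper.tri(matrix(0, k, k))
  withr::with_seed(seed, {
    map(seq_len(n_donors), function(i) {
      responses <- map(scenario$responses, function(r) {
        int <- r$int
        int[iu] <- int[iu] + stats::rnorm(sum(iu), 0, r$sd_int)
        list(
          beta0 = r$beta0 + stats::rnorm(1, 0, r$sd_beta0),
          main = r$main + stats::rnorm(k, 0, r$sd_main),
          quad = r$quad + stats::rnorm(k, 0, r$sd_quad),
          int = int,
          replicate_sd = r$replicate_sd, bounds = r$bounds,
          reference = r$reference
        )
      })
      structure(list(donor_id = donor_ids[i], k = k,
                     factor_ids = scenario$factor_ids, responses = responses),
                class = "donor_profile")
    })
  })
}

#' Noiseless response of a donor surface at a formulation
#'
#' Evaluates the donor's second-order surface
#' \eqn{\beta_0 + \sum \beta_i x_i + \sum \beta_{ii} x_i^2 +
#' \sum_{i<j} \beta_{ij} x_i x_j} and clamps the value to the response
#' bounds (viability to \[0, 100\], expansion to non-negative).
#'
#' @param profile A `donor_profile`.
#' @param formulation Coded vector of length `k` (entries in `[-1, 1]`) or a
#'   matrix/tibble of such rows.
#' @param response Response name, e.g. `"expansion_d6"`.
#' @return Numeric value(s), one per formulation row.
#' @export
true_response <- function(profile, formulation, response) {
  r <- profile$responses[[response]]
  if (is.null(r)) abort(paste0("unknown response: ", response))
  X <- if (is.matrix(formulation)) formulation
       else if (is.data.frame(formulation)) coded_matrix(formulation, profile$factor_ids)
       else matrix(formulation, nrow = 1)
  if (ncol(X) != profile$k) abort("formulation length does not match k")
  val <- r$beta0 + X %*% r$main + (X^2) %*% r$quad +
    rowSums((X %*% r$int) * X)
  pmin(pmax(drop(val), r$bounds[1]), r$bounds[2])
}

#' Simulate noisy measurements for one donor block
#'
#' For every design run and replicate the measured value is the donor's
#' noiseless surface response plus Gaussian replicate noise, clamped to the
#' response bounds. Reference runs use the scenario's fixed reference
#' performance (the reference medium lies outside the coded space) plus the
#' same noise.
#'
#' @param profile A `donor_profile`.
#' @param design A design block (may include the reference run).
#' @param replicates Technical replicates per run.
#' @param seed Integer seed.
#' @param responses Which responses to simulate (default: all in profile).
#' @return A long response tibble with columns `donor_id`, `block_id`,
#'   `run_id`, `replicate`, `response`, `value`.
#' @export
simulate_block <- function(profile, design, replicates = 3, seed = 1L,
                           responses = names(profile$responses)) {
  stopifnot(replicates >= 1)
  ids <- profile$factor_ids
  is_ref <- design$run_role == "reference"
  X <- coded_matrix(design[!is_ref, , drop = FALSE], ids)
  out <- withr::with_seed(seed, {
    map(responses, function(resp) {
      r <- profile$responses[[resp]]
      mu <- numeric(nrow(design))
      mu[!is_ref] <- true_response(profile, X, resp)
      mu[is_ref] <- r$reference
      map(seq_len(replicates), function(rep_i) {
        tibble(
          donor_id = profile$donor_id,
          block_id = design$block_id,
          run_id = design$run_id,
          replicate = rep_i,
          response = resp,
          value = pmin(pmax(mu + stats::rnorm(length(mu), 0, r$replicate_sd),
                            r$bounds[1]), r$bounds[2])
        )
      }) |> bind_rows()
    }) |> bind_rows()
  })
  arrange(out, .data$response, .data$run_id, .data$replicate)
}

#' Simulate the full multi-donor training set
#'
#' Pairs donor `i` with block `b<i>` of the assembled design and simulates
#' each block with its own derived seed.
#'
#' @param profiles List of `donor_profile`s.
#' @param blocks Stacked blocks from [dsd_blocks()] (one block per donor).
#' @inheritParams simulate_block
#' @return A long response tibble covering all donors.
#' @export
simulate_responses <- function(profiles, blocks, replicates = 3, seed = 1L) {
  block_ids <- unique(blocks$block_id)
  if (length(block_ids) != length(profiles)) {
    abort("number of blocks must equal number of donor profiles")
  }
  map2(profiles, block_ids, function(p, b) {
    simulate_block(p, blocks[blocks$block_id == b, , drop = FALSE],
                   replicates = replicates,
                   seed = derive_seed(seed, paste0("sim_", b)))
  }) |> bind_rows()
}
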