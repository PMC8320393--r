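#' Define the screened components of a study
#'
#' Builds the factor-specification table for a screen of `k` media components
#' at three coded levels (-1 = low, 0 = medium, +1 = high). Real-unit
#' concentrations are optional; all downstream modelling happens in coded
#' units.
#'
#' @param k Number of components.
#' @param factor_id Character vector of unique short labels; defaults to
#'   `c01 ... c<k>`.
#' @param name Optional free-text component names.
#' @param low,mid,high Optional real-unit concentrations, one per factor,
#'   with `low < mid < high`.
#' @return A tibble with one row per component.
#' @export
factor_specs <- function(k, factor_id = default_factor_ids(k), name = factor_id,
                         low = NA_real_, mid = NA_real_, high = NA_real_) {
  spec <- tibble(
    factor_id = as.character(factor_id), name = as.character(name),
    low = as.numeric(low), mid = as.numeric(mid), high = as.numeric(high)
  )
  if (nrow(spec) != k) abort("`factor_id` must have length k")
  if (anyDuplicated(spec$factor_id)) abort("factor_id values must be unique")
  has_units <- stats::complete.cases(spec[, c("low", "mid", "high")])
  bad <- has_units & !(spec$low < spec$mid & spec$mid < spec$high)
  if (any(bad)) {
    abort(paste0("low < mid < high violated for: ",
                 paste(spec$factor_id[bad], collapse = ", ")))
  }
  spec
}

#' Generate a definitive screening design
#'
#' Builds the 2k + 1 run three-level definitive screening design for `k`
#' factors by stacking the fold-over pairs of a conference matrix `C`
#' (rows of `C` interleaved with their negations) and one overall centre run.
#' Main effects of such a design are orthogonal to every quadratic and
#' two-factor-interaction column.
#'
#' @param k Number of factors (even; a conference matrix of order `k` must be
#'   constructible, see [build_conference_matrix()]).
#' @param specs Optional factor-specification tibble from [factor_specs()];
#'   defaults to coded labels `c01 ... c<k>`.
#' @param randomize Randomize run order (the design rows, not their labels).
#' @param seed Seed used when `randomize = TRUE`.
#' @return A design tibble of class `dsd_design`: columns `run_id`,
#'   `run_role` (all `"dsd_formulation"`), `block_id` (`NA` until blocks are
#'   assembled) and one coded column per factor.
#' @examples
#' d <- generate_dsd(12)
#' nrow(d) # 25 formulations
#' @export
generate_dsd <- function(k, specs = NULL, randomize = FALSE, seed = NULL) {
  C <- build_conference_matrix(k)
  if (is.null(specs)) specs <- factor_specs(k)
  if (nrow(specs) != k) abort("`specs` must describe exactly k factors")
  # interleave fold-over pairs: rows 2i-1 and 2i negate each other
  rows <- matrix(0L, nrow = 2L * k + 1L, ncol = k)
  rows[seq(1L, 2L * k, by = 2L), ] <- C
  rows[seq(2L, 2L * k, by = 2L), ] <- -C
  colnames(rows) <- specs$factor_id
  design <- bind_cols(
    tibble(
      run_id = sprintf("r%02d", seq_len(nrow(rows))),
      run_role = "dsd_formulation",
      block_id = NA_character_
    ),
    as_tibble(rows)
  )
  if (randomize) {
    design <- withr::with_seed(seed %||% 1L, design[sample(nrow(design)), ])
  }
  new_dsd_design(design, specs)
}

new_dsd_design <- function(df, specs) {
  structure(df,
    class = c("dsd_design", class(tibble())),
    factor_ids = specs$factor_id, specs = specs)
}

#' Extract the coded factor labels of a design or pool
#' @param x A design, pool or plain tibble with coded `c..` columns.
#' @return Character vector of factor ids.
#' @export
design_factors <- function(x) {
  attr(x, "factor_ids") %||% grep("^c[0-9]+$", names(x), value = TRUE)
}

#' Assemble one experimental block
#'
#' Stamps a block (donor) id on all runs of a design and appends the
#' reference-medium run. The reference medium is a control with known
#' performance outside the coded component space, so its coded levels are
#' recorded as `NA` and it is excluded from model features.
#'
#' @param design A `dsd_design` tibble.
#' @param block_id Block label, e.g. `"b1"`.
#' @param include_reference Append the reference run (default `TRUE`).
#' @param randomize,seed Optionally randomize run order within the block.
#' @return The block as a `dsd_design` tibble (2k + 2 rows with reference).
#' @export
assemble_block <- function(design, block_id, include_reference = TRUE,
                           randomize = FALSE, seed = NULL) {
  ids <- design_factors(design)
  block <- design
  block$block_id <- as.character(block_id)
  if (include_reference) {
    ref <- block[1, ]
    ref$run_id <- "ref"
    ref$run_role <- "reference"
    ref[, ids] <- NA_real_
    block <- bind_rows(block, ref)
  }
  if (randomize) {
    block <- withr::with_seed(seed %||% 1L, block[sample(nrow(block)), ])
  }
  new_dsd_design(block, attr(design, "specs"))
}

#' Assemble the full multi-donor block structure
#'
#' Replicates a design into `n_blocks` randomized complete blocks (one per
#' donor), each with its own run-order randomization and reference run.
#'
#' @inheritParams assemble_block
#' @param n_blocks Number of donor blocks.
#' @param seed Master seed for per-block run-order randomization.
#' @return All blocks stacked into one `dsd_design` tibble.
#' @examples
#' blocks <- dsd_blocks(generate_dsd(12), n_blocks = 4, seed = 1)
#' nrow(blocks) # 104 training runs
#' @export
dsd_blocks <- function(design, n_blocks, include_reference = TRUE,
                       randomize = TRUE, seed = 1L) {
  out <- map(seq_len(n_blocks), function(b) {
    assemble_block(design, sprintf("b%d", b), include_reference,
                   randomize = randomize, seed = derive_seed(seed, paste0("block", b)))
  })
  new_dsd_design(bind_rows(out), attr(design, "specs"))
}

#' Check the design-class properties of a definitive screening design
#'
#' Reports, over the `dsd_formulation` rows: coded levels in \{-1, 0, +1\},
#' run count 2k + 1, fold-over closure (the row multiset maps onto itself
#' under negation, with a single self-paired centre run), per-column zero
#' counts (exactly 3) and zero column sums, and exact integer orthogonality
#' of every main-effect column with every quadratic and two-factor
#' interaction column.
#'
#' @param design A design tibble (single block or the bare design).
#' @return A tibble of class `dsd_validation` with columns `check`, `pass`,
#'   `detail`; attribute `all_pass` summarises it.
#' @export
validate_design <- function(design) {
  ids <- design_factors(design)
  dsd <- design[design$run_role %in% "dsd_formulation", , drop = FALSE]
  X <- coded_matrix(dsd, ids)
  k <- length(ids)
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble(check = check, pass = pass, detail = detail)
  }

  add("levels_coded", all(X %in% c(-1, 0, 1)), "all entries in {-1, 0, +1}")
  add("run_count", nrow(X) == 2L * k + 1L,
      sprintf("%d dsd rows (expect %d)", nrow(X), 2L * k + 1L))

  key <- apply(X, 1, paste, collapse = ",")
  neg_key <- apply(-X, 1, paste, collapse = ",")
  add("foldover_closure",
      identical(sort(key), sort(neg_key)) && sum(key == neg_key) == 1L,
      "row multiset closed under negation with one centre run")

  zeros <- colSums(X == 0)
  add("zeros_per_column", all(zeros == 3L),
      paste0("zeros per column: ", paste(unique(zeros), collapse = "/")))
  add("column_sums_zero", all(colSums(X) == 0), "each column sums to 0")

  quad <- X^2
  pairs <- utils::combn(k, 2)
  tfi <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
  mq <- crossprod(X, quad)
  mi <- crossprod(X, tfi)
  add("main_x_quadratic_orthogonal", all(mq == 0),
      sprintf("max |X'Q| = %g", max(abs(mq))))
  add("main_x_interaction_orthogonal", all(mi == 0),
      sprintf("max |X'I| = %g", max(abs(mi))))

  out <- bind_rows(checks)
  structure(out, class = c("dsd_validation", class(out)),
            all_pass = all(out$pass))
}

#' Write / read a design as CSV
#'
#' Plain-text interchange for designs: `run_id`, `run_role`, `block_id`
#' followed by the coded factor columns (reference rows have empty cells).
#'
#' @param design A design tibble.
#' @param path File path.
#' @return `read_design_csv` returns a `dsd_design` tibble.
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(design, path, na = "")
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          run_id = "c", run_role = "c", block_id = "c",
                          .default = "d"))
  ids <- grep("^c[0-9]+$", names(df), value = TRUE)
  new_dsd_design(df, factor_specs(length(ids), factor_id = ids))
}
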