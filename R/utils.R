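# internal helpers shared across modules

#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows bind_cols left_join across n row_number desc slice pull distinct
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2 imap pmap list_rbind
NULL

# deterministic per-stage seed derived from one master seed; stays < 2^31
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  offset <- sum(utf8ToInt(stage)) %% 9973L
  as.integer((abs(master_seed) * 7919 + offset * 104729) %% 2147483647)
}

# default coded component labels c01, c02, ...
default_factor_ids <- function(k) sprintf("c%02d", seq_len(k))

# pull the coded-level columns of a design/pool tibble as a numeric matrix
coded_matrix <- function(df, factor_ids) {
  missing <- setdiff(factor_ids, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing coded columns: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(df[, factor_ids, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# squared-distance based cross-distance matrix (rows of a vs rows of b)
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

rsq <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}
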