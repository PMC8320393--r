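#' Construct a conference matrix
#'
#' A conference matrix of order \eqn{k} is a square matrix \eqn{C} with zero
#' diagonal and off-diagonal entries in \eqn{\{-1, +1\}} satisfying
#' \eqn{C^T C = (k - 1) I}. It is the combinatorial core of the definitive
#' screening design: the design's fold-over pairs are the rows of \eqn{C} and
#' \eqn{-C}.
#'
#' Orders `k = q + 1` with `q` an odd prime use the Paley construction
#' (a bordered Jacobsthal matrix of quadratic-residue characters, with the
#' border sign chosen so the skew case `q = 3 mod 4` also satisfies the Gram
#' identity). Order 10 uses a stored GF(9) Paley matrix and order 16 is built
#' by skew-Hadamard doubling of the order-8 matrix.
#'
#' @param k Order of the matrix; must be even and >= 4, and a supported
#'   construction must exist (any `k` with `k - 1` an odd prime, plus 10
#'   and 16).
#' @return An integer `k x k` matrix with zero diagonal and
#'   `crossprod(C) == (k - 1) * diag(k)`.
#' @examples
#' C <- build_conference_matrix(12)
#' all(crossprod(C) == 11 * diag(12))
#' @export
build_conference_matrix <- function(k) {
  if (length(k) != 1L || !is.numeric(k) || k != round(k)) {
    abort("`k` must be a single integer")
  }
  k <- as.integer(k)
  if (k %% 2L != 0L || k < 4L) {
    abort(paste0("no conference-matrix construction available for k = ", k,
                 ": order must be even and >= 4"))
  }
  q <- k - 1L
  if (is_odd_prime(q)) {
    C <- paley_conference(q)
  } else if (k == 10L) {
    C <- gf9_conference()
  } else if (k == 16L) {
    C <- skew_double(build_conference_matrix(8L))
  } else {
    abort(paste0("no conference-matrix construction available for k = ", k))
  }
  storage.mode(C) <- "integer"
  C
}

is_odd_prime <- function(q) {
  if (q < 3L || q %% 2L == 0L) return(FALSE)
  all(q %% seq(3L, max(3L, floor(sqrt(q))), by = 2L) != 0L) || q == 3L
}

# Paley construction for prime q. Jacobsthal matrix Q[i, j] = chi(i - j) with
# chi the quadratic character mod q; border sign -1 in the skew case
# (q = 3 mod 4) so that C^T C = q I holds with a zero diagonal either way.
paley_conference <- function(q) {
  residues <- unique((seq_len(q - 1)^2) %% q)
  chi <- rep(-1L, q)
  chi[residues + 1L] <- 1L
  chi[1L] <- 0L
  idx <- 0:(q - 1)
  Q <- outer(idx, idx, function(i, j) chi[((i - j) %% q) + 1L])
  s <- if (q %% 4L == 1L) 1L else -1L
  rbind(c(0L, rep(1L, q)), cbind(rep(s, q), Q))
}

# order-10 Paley matrix over GF(9); stored because GF(p^2) arithmetic is not
# worth carrying for a single order. Gram identity is asserted in tests.
gf9_conference <- function() {
  matrix(c(
    0,  1,  1,  1,  1,  1,  1,  1,  1,  1,
    1,  0,  1,  1,  1, -1, -1,  1, -1, -1,
    1,  1,  0,  1, -1,  1, -1, -1,  1, -1,
    1,  1,  1,  0, -1, -1,  1, -1, -1,  1,
    1,  1, -1, -1,  0,  1,  1,  1, -1, -1,
    1, -1,  1, -1,  1,  0,  1, -1,  1, -1,
    1, -1, -1,  1,  1,  1,  0, -1, -1,  1,
    1,  1, -1, -1,  1, -1, -1,  0,  1,  1,
    1, -1,  1, -1, -1,  1, -1,  1,  0,  1,
    1, -1, -1,  1, -1, -1,  1,  1,  1,  0), nrow = 10, byrow = TRUE)
}

# doubling: if I + C is skew-Hadamard of order n, [[H, H], [-H^T, H^T]] is
# skew-Hadamard of order 2n; subtracting the identity recovers a conference
# matrix. Used for order 16 from the order-8 Paley (q = 7, skew type).
skew_double <- function(C) {
  H <- diag(nrow(C)) + C
  H2 <- rbind(cbind(H, H), cbind(-t(H), t(H)))
  H2 - diag(nrow(H2))
}
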