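`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 65011 * 7919 + as.double(k) * 104729 + 17) %% 2147483629)
}

symmetrize <- function(S) (S + t(S)) / 2

# Lower-triangular Cholesky factor: S = L %*% t(L).
lower_chol <- function(S) t(chol(symmetrize(S)))

is_spd <- function(S, tol = 1e-10) {
  is.matrix(S) && nrow(S) == ncol(S) &&
    max(abs(S - t(S))) <= tol * max(1, max(abs(S))) &&
    min(eigen(symmetrize(S), symmetric = TRUE, only.values = TRUE)$values) > 0
}

check_spd <- function(S, name) {
  if (!is_spd(S)) stop(sprintf("`%s` must be a symmetric positive-definite matrix", name),
                       call. = FALSE)
  invisible(S)
}

#' Draw from an inverse-Wishart distribution
#'
#' Samples `Sigma ~ IW(nu, S)` under the parameterization with density
#' proportional to `|Sigma|^-(nu + p + 1)/2 * exp(-tr(S Sigma^-1)/2)`, so that
#' `E[Sigma] = S / (nu - p - 1)` for `nu > p + 1`. This is the conjugate update
#' used for every covariance matrix in the Gibbs sampler: if the rows of a
#' `J x p` effect matrix `B` have column covariance `Sigma` and row covariance
#' `G`, then `Sigma | B ~ IW(nu + J, S + t(B) G^-1 B)`.
#'
#' @param nu Degrees of freedom (must exceed `p - 1`).
#' @param S Positive-definite `p x p` scale matrix.
#' @param n Number of draws.
#' @return A `p x p x n` array (or a `p x p` matrix when `n = 1`).
#' @examples
#' draws <- riw(12, diag(2) * 5, n = 500)
#' apply(draws, 1:2, mean)     # close to diag(2) * 5 / (12 - 2 - 1)
#' @export
riw <- function(nu, S, n = 1L) {
  p <- nrow(S)
  if (nu <= p - 1) stop("inverse-Wishart requires nu > p - 1", call. = FALSE)
  Sinv <- chol2inv(chol(symmetrize(S)))
  W <- stats::rWishart(n, df = nu, Sigma = Sinv)
  out <- array(apply(W, 3L, function(w) symmetrize(chol2inv(chol(w)))), dim = c(p, p, n))
  if (n == 1L) out[, , 1L, drop = TRUE] else out
}

# Effective sample size via the initial monotone positive-sequence truncation
# of the empirical autocorrelation function.
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(n)
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 1L, 500L), plot = FALSE)$acf)[-1L]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  max(1, n / (1 + 2 * s))
}
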