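# small shared helpers

logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# log(mean(exp(x))) without overflow
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Gauss-Hermite rule for E[f(Z)], Z ~ N(0,1) (probabilists' weight), via
# Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
gauss_hermite <- function(n = 15L) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i)
  J <- J + t(J)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1L, ]^2)
}

# derive a per-stage 31-bit seed from a global seed (stable, collision-poor)
derive_seed <- function(seed, stage) {
  s <- (as.numeric(seed) * 69069 + 12345 + 97 * as.numeric(stage)) %% 2147483647
  as.integer(s) + 1L
}

stamp <- function() format(Sys.time(), "%Y-%m-%d %H:%M:%S")
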