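# Independent maximum-likelihood oracle for the crossed random-intercept LMM:
# direct optimisation of the marginal multivariate-normal likelihood, with
# GLS-profiled fixed effects. Deliberately shares no code with the package's
# lme4-based fit.

mvn_lmm_oracle <- function(y, X, female, year, start = c(1, 1, 2)) {
  Za <- stats::model.matrix(~ 0 + factor(female))
  Ze <- stats::model.matrix(~ 0 + factor(year))
  n <- length(y)
  profile <- function(logsd) {
    s <- exp(logsd)
    Sigma <- s[1]^2 * tcrossprod(Za) + s[2]^2 * tcrossprod(Ze) +
      s[3]^2 * diag(n)
    ch <- chol(Sigma)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    beta <- solve(crossprod(Xi), crossprod(Xi, yi))
    r <- yi - Xi %*% beta
    ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
    list(nll = -ll, beta = drop(beta))
  }
  o <- stats::optim(log(start), function(ls) profile(ls)$nll,
                    method = "Nelder-Mead",
                    control = list(maxit = 4000, reltol = 1e-14))
  o <- stats::optim(o$par, function(ls) profile(ls)$nll,
                    method = "Nelder-Mead",
                    control = list(maxit = 4000, reltol = 1e-14))
  fin <- profile(o$par)
  list(beta = fin$beta, sd = exp(o$par), loglik = -fin$nll)
}
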