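# Multistate mark-recapture model of breeding probability: mixed-effects
# logistic transitions over latent states F/B/N, imperfect detection of
# breeders, exact marginal likelihood by the forward algorithm, and a
# brute-force enumeration oracle.

STATE_LEVELS <- c("F", "B", "N")

#' Breeding probability from the logistic transition model
#'
#' Evaluates \eqn{\psi^{kB}}, the probability of being in the breeder state
#' next season given the previous state `k` and covariates, under a given
#' model variant. With `sigma_omega > 0` the observation-level logit-normal
#' term is marginalised by Gauss-Hermite quadrature.
#'
#' @param params a [transition_params()] object.
#' @param prev_state previous state, one of `"F"`, `"B"`, `"N"`.
#' @param std_age standardised female age.
#' @param std_lw standardised weaning length.
#' @param variant one of `"null"`, `"linear"`, `"quadratic"`, `"parity"`,
#'   `"cohort"`.
#' @param parity prior-birth parity group (1, 2 or 3), parity variant only.
#' @param cohort 1-based cohort index (cohort variant only).
#' @param beta,theta female and year random effects (default 0).
#' @return probability in (0, 1); vectorised over `std_age`/`std_lw`.
#' @export
breeding_probability <- function(params, prev_state, std_age, std_lw = 0,
                                 variant = "linear", parity = 1L,
                                 cohort = 1L, beta = 0, theta = 0) {
  variant <- check_variant(variant)
  if (!all(prev_state %in% STATE_LEVELS))
    stop("prev_state must be one of F, B, N")
  lp <- params$mu + params$lambda1 * std_age + params$lambda2 * std_age^2 +
    params$lambda3[prev_state] + beta + theta
  lp <- lp + switch(variant,
    null = 0,
    linear = params$lambda5 * std_lw,
    quadratic = params$lambda5 * std_lw + params$lambda6 * std_lw^2,
    parity = params$lambda5 * std_lw +
      ifelse(parity == 1L, params$lambda6 * std_lw, 0),
    cohort = {
      lc <- params$lambda_cohort %||% 0
      params$lambda5 * std_lw + c(0, lc)[pmin(cohort, length(lc) + 1L)]
    })
  lp <- unname(lp)
  if (params$sigma_omega > 0) {
    gh <- gauss_hermite(15L)
    vapply(lp, function(e)
      sum(gh$weights * invlogit(e + params$sigma_omega * gh$nodes)),
      numeric(1))
  } else {
    invlogit(lp)
  }
}

check_forward_inputs <- function(sightings, std_age, theta) {
  if (anyNA(sightings) || !all(sightings %in% c(0L, 1L)))
    stop("sightings must be 0/1 from the recruitment occasion onward")
  if (sightings[1L] != 1L)
    stop("first element must be the recruitment sighting (1)")
  if (length(std_age) != length(sightings))
    stop("std_age must match sightings in length")
  if (length(theta) != length(sightings))
    stop("theta must match sightings in length")
}

#' Exact marginal log-likelihood of one female's sighting history
#'
#' Computes the log probability of the post-recruitment sighting vector,
#' summing over all latent breeder/nonbreeder sequences with the forward
#' recursion, conditioned on first capture (state `F` with probability 1 at
#' the recruitment occasion). Emissions: a breeder is sighted with probability
#' `detection_p`; a nonbreeder is never sighted.
#'
#' @param sightings 0/1 vector starting at the recruitment occasion (the
#'   first element must be 1).
#' @param params a [transition_params()] object (must have finite entries).
#' @param std_age standardised age at each occasion of `sightings`.
#' @param std_lw standardised weaning length of the female.
#' @param variant model variant, see [breeding_probability()].
#' @param cohort 1-based cohort index.
#' @param beta female random effect.
#' @param theta year random effects aligned with `sightings` (default 0).
#' @param parity_obs optional observed parity groups (1/2/3) aligned with
#'   `sightings`; when supplied the parity variant uses them instead of
#'   tracking parity through the latent states.
#' @return the log-likelihood (0 for a history of length one, since the
#'   conditioned recruitment event has probability 1).
#' @export
forward_loglik <- function(sightings, params, std_age = rep(0, length(sightings)),
                           std_lw = 0, variant = "linear", cohort = 1L,
                           beta = 0, theta = rep(0, length(sightings)),
                           parity_obs = NULL) {
  variant <- check_variant(variant)
  sightings <- as.integer(sightings)
  check_forward_inputs(sightings, std_age, theta)
  flat <- unlist(params[c("mu", "lambda1", "lambda2", "lambda3", "lambda5",
                          "lambda6", "sigma_omega", "detection_p")])
  if (any(!is.finite(flat))) stop("non-finite parameters")
  use_obs <- !is.null(parity_obs)
  gh <- if (params$sigma_omega > 0) gauss_hermite(15L) else
    list(nodes = numeric(0), weights = numeric(0))
  msms_forward_loglik_cpp(
    obs = sightings, zage = as.numeric(std_age), zlw = std_lw,
    pars = list(mu = params$mu, lambda1 = params$lambda1,
                lambda2 = params$lambda2,
                lambda3F = unname(params$lambda3["F"]),
                lambda3B = unname(params$lambda3["B"]),
                lambda3N = unname(params$lambda3["N"]),
                lambda5 = params$lambda5, lambda6 = params$lambda6,
                p = params$detection_p, sigma_omega = params$sigma_omega,
                lambda_cohort = c(0, params$lambda_cohort %||% numeric(0))),
    theta = as.numeric(theta), beta = beta, variant = variant_code(variant),
    cohort = cohort - 1L,
    n_cohort = length(params$lambda_cohort %||% numeric(0)) + 1L,
    parity_obs = if (use_obs) as.integer(parity_obs) else
      rep(1L, length(sightings)),
    use_obs_parity = use_obs, gh_x = gh$nodes, gh_w = gh$weights)
}

#' Brute-force marginal log-likelihood (verification oracle)
#'
#' Enumerates every latent breeder/nonbreeder sequence over the
#' post-recruitment occasions and sums path probability times emission
#' probability. Exponential in the history length; refuse beyond 12
#' post-recruitment occasions. Used to verify [forward_loglik()].
#'
#' @inheritParams forward_loglik
#' @return the log-likelihood.
#' @export
brute_force_loglik <- function(sightings, params,
                               std_age = rep(0, length(sightings)),
                               std_lw = 0, variant = "linear", cohort = 1L,
                               beta = 0, theta = rep(0, length(sightings)),
                               parity_obs = NULL) {
  variant <- check_variant(variant)
  sightings <- as.integer(sightings)
  check_forward_inputs(sightings, std_age, theta)
  Tn <- length(sightings) - 1L # post-recruitment transitions
  if (Tn > 12L) stop("history too long for enumeration (cap 12)")
  if (Tn == 0L) return(0)
  p <- params$detection_p
  total <- 0
  for (code in 0:(2^Tn - 1L)) {
    states <- ifelse(bitwAnd(code, 2L^(seq_len(Tn) - 1L)) > 0L, "B", "N")
    prob <- 1
    prev <- "F"
    births <- 1L # the recruitment birth
    for (s in seq_len(Tn)) {
      t <- s + 1L
      par_s <- if (!is.null(parity_obs)) parity_obs[t] else min(births, 3L)
      psi <- breeding_probability(params, prev, std_age[t], std_lw,
                                  variant = variant, parity = par_s,
                                  cohort = cohort, beta = beta,
                                  theta = theta[t])
      prob <- prob * if (states[s] == "B") psi else 1 - psi
      # emission
      prob <- prob * if (states[s] == "B") {
        if (sightings[t] == 1L) p else 1 - p
      } else {
        if (sightings[t] == 1L) 0 else 1
      }
      if (states[s] == "B") births <- births + 1L
      prev <- states[s]
    }
    total <- total + prob
  }
  log(total)
}
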