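# Bayesian fitting of the multistate model: design-data builder, MCMC
# configuration, the fit wrapper around the C++ adaptive
# Metropolis-within-Gibbs sampler, and posterior containers.

#' Posterior samples container
#'
#' @param chains list of numeric matrices (one per chain), equal dimensions,
#'   identical column names; rows are kept draws.
#' @param burn_in,thin bookkeeping for how the draws were produced.
#' @return object of class `posterior_samples`.
#' @export
posterior_samples <- function(chains, burn_in = NA_integer_,
                              thin = NA_integer_) {
  if (!length(chains)) stop("need at least one chain")
  dims <- vapply(chains, dim, integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop("chains must have equal numbers of draws and parameters")
  structure(list(chains = chains, burn_in = burn_in, thin = thin,
                 parameters = colnames(chains[[1]])),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]), " draws x ", ncol(x$chains[[1]]),
      " parameters\n", sep = "")
  invisible(x)
}

#' Stack chains into a single draws matrix
#' @param samples a `posterior_samples` object (or an `msms_fit`).
#' @return numeric matrix, all chains row-bound.
#' @export
draws_matrix <- function(samples) {
  if (inherits(samples, "msms_fit")) samples <- samples$samples
  do.call(rbind, samples$chains)
}

#' MCMC configuration
#'
#' Defaults mirror the study protocol for this model class: 3 chains, 10,000
#' burn-in sweeps, 100,000 further sweeps thinned by 100 (3,000 retained
#' draws). Tests and examples use much shorter profiles.
#'
#' @param n_chains number of independent chains.
#' @param n_iter post-burn-in sweeps per chain.
#' @param burn_in adaptation/burn-in sweeps (discarded).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; chain c uses a seed derived from `seed` and `c`.
#' @param prior_sd_fixed sd of the diffuse normal prior N(0, prior_sd^2) on
#'   the regression parameters (default sqrt(1000)).
#' @param sigma_upper upper bound of the Uniform(0, upper) priors on the
#'   random-effect sds.
#' @param p_bounds support of the uniform prior on detection probability.
#' @param parity_mode for the parity variant: `"latent"` tracks parity
#'   exactly through the latent states (expanded state space); `"observed"`
#'   uses parity groups computed from recorded births.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 100000L, burn_in = 10000L,
                        thin = 100L, seed = 1L,
                        prior_sd_fixed = sqrt(1000), sigma_upper = 10,
                        p_bounds = c(0, 1), parity_mode = c("latent", "observed")) {
  parity_mode <- match.arg(parity_mode)
  stopifnot(n_chains >= 1L, n_iter >= thin, burn_in >= 0L, thin >= 1L,
            prior_sd_fixed > 0, sigma_upper > 0,
            length(p_bounds) == 2L, p_bounds[1] >= 0, p_bounds[2] <= 1,
            p_bounds[1] < p_bounds[2])
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), prior_sd_fixed = prior_sd_fixed,
                 sigma_upper = sigma_upper, p_bounds = p_bounds,
                 parity_mode = parity_mode),
            class = "mcmc_config")
}

# Assemble the flat design data consumed by the C++ routines.
# histories: encounter_histories; females: female covariate table aligned by
# female_id; pups needed only for parity_mode = "observed".
build_msms_data <- function(histories, females, variant,
                            parity_mode = "latent", pups = NULL,
                            age_std = NULL, lw_std = NULL) {
  variant <- check_variant(variant)
  idx <- match(histories$female_id, females$female_id)
  if (anyNA(idx))
    stop("females table is missing ids present in the encounter histories")
  females <- females[idx, , drop = FALSE]
  years <- histories$years
  nF <- length(histories$female_id)
  nT <- length(years)

  age <- outer(females$cohort, years, function(c, y) y - c)
  post <- col(age) >= histories$recruit # post-recruitment cells
  if (is.null(age_std)) age_std <- fit_standardizer(age[post])
  zage <- matrix(std_transform(age_std, age), nF, nT)
  if (is.null(lw_std)) lw_std <- fit_standardizer(females$weaning_length_cm)
  zlw <- std_transform(lw_std, females$weaning_length_cm)

  cohort_levels <- sort(unique(females$cohort))
  cohort_idx <- match(females$cohort, cohort_levels) - 1L

  obs <- histories$sightings
  obs[is.na(obs)] <- -1L

  parity_obs <- matrix(1L, nF, nT)
  if (identical(parity_mode, "observed")) {
    if (is.null(pups)) stop("parity_mode='observed' needs a pup table")
    for (i in seq_len(nF)) {
      byears <- sort(pups$year[pups$female_id == histories$female_id[i]])
      for (t in seq_len(nT))
        parity_obs[i, t] <- max(1L, min(3L, sum(byears < years[t])))
    }
  }

  list(obs = obs, recruit = histories$recruit - 1L, zage = zage, zlw = zlw,
       cohort = cohort_idx, n_cohort = length(cohort_levels),
       parity_obs = parity_obs,
       use_obs_parity = identical(parity_mode, "observed"),
       variant = variant_code(variant),
       gh_x = numeric(0), gh_w = numeric(0),
       # bookkeeping (ignored by C++)
       female_id = histories$female_id, years = years,
       cohort_levels = cohort_levels,
       age_std = age_std, lw_std = lw_std, variant_name = variant)
}

# per-female log-likelihood vector for a transition_params object
colony_loglik <- function(data, params, beta = NULL, theta = NULL) {
  nF <- nrow(data$obs); nT <- ncol(data$obs)
  gh <- if (params$sigma_omega > 0) gauss_hermite(15L) else
    list(nodes = numeric(0), weights = numeric(0))
  d <- data
  d$gh_x <- gh$nodes; d$gh_w <- gh$weights
  msms_colony_loglik_cpp(d, list(
    mu = params$mu, lambda1 = params$lambda1, lambda2 = params$lambda2,
    lambda3F = unname(params$lambda3["F"]),
    lambda3B = unname(params$lambda3["B"]),
    lambda3N = unname(params$lambda3["N"]),
    lambda5 = params$lambda5, lambda6 = params$lambda6,
    p = params$detection_p, sigma_omega = params$sigma_omega,
    lambda_cohort = c(0, params$lambda_cohort %||% rep(0, data$n_cohort - 1L)),
    beta = beta %||% rep(0, nF), theta = theta %||% rep(0, nT)))
}

msms_param_names <- function(data) {
  variant <- data$variant_name
  nm <- c("mu", "lambda1", "lambda2", "lambda3_F", "lambda3_B")
  if (variant != "null") nm <- c(nm, "lambda5")
  if (variant %in% c("quadratic", "parity")) nm <- c(nm, "lambda6")
  if (variant == "cohort")
    nm <- c(nm, paste0("lambda_cohort_", data$cohort_levels[-1L]))
  c(nm, "p", "lambda3_N", "sigma_beta", "sigma_theta",
    paste0("beta[", data$female_id, "]"),
    paste0("theta[", data$years, "]"))
}

#' Fit the multistate mark-recapture model by MCMC
#'
#' Samples the posterior of the mixed-effects logistic transition model under
#' diffuse N(0, 1000) priors on the regression parameters, Uniform(0, 10)
#' priors on the random-effect sds and a Uniform(0, 1) prior on detection
#' probability. The target density is the exact marginal likelihood (forward
#' algorithm, latent states summed out) plus log-priors; sampling is by an
#' adaptive Metropolis-within-Gibbs scheme (multivariate adaptive block for
#' the fixed effects and detection, joint block for year effects,
#' componentwise vectorised updates for female effects, Gibbs updates of the
#' variance components, plus likelihood-invariant translation moves between
#' the intercept and the random-effect means). Adaptation runs only during
#' burn-in.
#'
#' @param colony a colony object (see [simulate_colony()]) or a list with
#'   elements `encounters` ([encounter_histories()]) and `females`
#'   (covariate table); a pup table is required for
#'   `parity_mode = "observed"`.
#' @param variant model variant, see [breeding_probability()].
#' @param mcmc an [mcmc_config()].
#' @return object of class `msms_fit`: posterior samples, design data with
#'   standardisers, acceptance rates, and split-chain R-hat for the
#'   top-level parameters (a warning is emitted if any exceeds 1.05).
#' @export
fit_multistate <- function(colony, variant = "linear", mcmc = mcmc_config()) {
  variant <- check_variant(variant)
  histories <- colony$encounters
  if (is.null(histories) || length(histories$female_id) == 0L)
    stop("zero-length data: no encounter histories")
  data <- build_msms_data(histories, colony$females, variant,
                          parity_mode = mcmc$parity_mode,
                          pups = colony$pups)
  nF <- nrow(data$obs); nT <- ncol(data$obs)
  d_fixed <- 5L + switch(variant, null = 0L, linear = 1L, quadratic = 2L,
                         parity = 2L, cohort = data$n_cohort) + 1L
  # crude empirical resight rate for the intercept start
  post_cells <- sweep(col(data$obs), 1, data$recruit + 1L, ">")
  raw_rate <- mean(data$obs[post_cells] == 1L)
  if (!is.finite(raw_rate)) raw_rate <- 0.5 # no post-recruitment occasions
  raw_rate <- min(max(raw_rate, 0.05), 0.95)

  chains <- vector("list", mcmc$n_chains)
  acc <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(derive_seed(mcmc$seed, ch))
    init_fixed <- rnorm(d_fixed, 0, 0.3)
    init_fixed[1L] <- logit(raw_rate) + rnorm(1, 0, 0.5)
    p0 <- 0.9 + 0.08 * runif(1)
    p0 <- min(max(p0, mcmc$p_bounds[1] + 1e-3), mcmc$p_bounds[2] - 1e-3)
    init_fixed[d_fixed] <- logit(p0)
    res <- msms_sampler_cpp(data, list(
      n_burn = mcmc$burn_in, n_iter = mcmc$n_iter, thin = mcmc$thin,
      prior_sd = mcmc$prior_sd_fixed, sigma_upper = mcmc$sigma_upper,
      p_lo = mcmc$p_bounds[1], p_hi = mcmc$p_bounds[2],
      init_fixed = init_fixed,
      init_beta = rnorm(nF, 0, 0.3), init_theta = rnorm(nT, 0, 0.3),
      init_sigma_beta = 0.5, init_sigma_theta = 0.5))
    m <- res$draws
    colnames(m) <- msms_param_names(data)
    chains[[ch]] <- m
    acc[[ch]] <- c(fixed = res$acc_fixed, beta = res$acc_beta,
                   theta = res$acc_theta)
  }
  samples <- posterior_samples(chains, burn_in = mcmc$burn_in,
                               thin = mcmc$thin)
  top <- setdiff(samples$parameters,
                 grep("^(beta|theta)\\[", samples$parameters, value = TRUE))
  rh <- if (mcmc$n_chains >= 2L)
    vapply(top, function(pp) rhat(samples, pp), numeric(1)) else NULL
  if (!is.null(rh) && any(rh > 1.05, na.rm = TRUE))
    warning("possible non-convergence: max split R-hat = ",
            format(max(rh, na.rm = TRUE), digits = 4))
  structure(list(samples = samples, variant = variant, data = data,
                 config = mcmc, acceptance = acc, rhat = rh),
            class = "msms_fit")
}

#' @export
print.msms_fit <- function(x, ...) {
  cat("<msms_fit> variant:", x$variant, "|", length(x$samples$chains),
      "chain(s) x", nrow(x$samples$chains[[1]]), "draws\n")
  if (!is.null(x$rhat))
    cat("  max split R-hat (top-level):",
        format(max(x$rhat, na.rm = TRUE), digits = 4), "\n")
  print(transition_summary(x))
  invisible(x)
}

# extract psi^{kB} draws at given covariates from a draws matrix
psi_draws <- function(m, at = list()) {
  a <- at$std_age %||% 0
  z <- at$std_lw %||% 0
  parity <- at$parity %||% 1L
  gcol <- function(nm) if (nm %in% colnames(m)) m[, nm] else 0
  base <- m[, "mu"] + gcol("lambda1") * a + gcol("lambda2") * a^2 +
    gcol("lambda5") * z
  if ("lambda6" %in% colnames(m)) {
    # quadratic variant: z^2 term; parity variant: z x I(parity == 1)
    base <- base + if (isTRUE(at$lambda6_is_parity))
      ifelse(parity == 1L, m[, "lambda6"] * z, 0)
    else m[, "lambda6"] * z^2
  }
  list(FB = invlogit(base + m[, "lambda3_F"]),
       BB = invlogit(base + m[, "lambda3_B"]),
       NB = invlogit(base + m[, "lambda3_N"]))
}

#' Posterior summaries of the transition probabilities
#'
#' Posterior mean, sd and 2.5/50/97.5% quantiles of \eqn{\psi^{FB}},
#' \eqn{\psi^{BB}} and \eqn{\psi^{NB}} evaluated at stated covariates
#' (default: mean age and mean weaning length, i.e. standardised 0, random
#' effects 0).
#'
#' @param object an `msms_fit` or `posterior_samples` containing columns
#'   `mu`, `lambda3_F`, `lambda3_B`, `lambda3_N` (plus any variant terms).
#' @param at list with `std_age`, `std_lw` (and `parity` for the parity
#'   variant).
#' @return data frame, one row per transition.
#' @export
transition_summary <- function(object, at = list(std_age = 0, std_lw = 0)) {
  m <- draws_matrix(if (inherits(object, "msms_fit")) object$samples else object)
  if (inherits(object, "msms_fit") && object$variant == "parity")
    at$lambda6_is_parity <- TRUE
  ps <- psi_draws(m, at)
  out <- do.call(rbind, lapply(c("FB", "BB", "NB"), function(k) {
    x <- ps[[k]]
    data.frame(transition = paste0("psi_", k), mean = mean(x), sd = sd(x),
               q2.5 = unname(quantile(x, 0.025)),
               q50 = unname(quantile(x, 0.5)),
               q97.5 = unname(quantile(x, 0.975)))
  }))
  rownames(out) <- NULL
  out
}
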