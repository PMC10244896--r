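# Linear mixed models for pup weaning mass: variant menu, ML fitting via
# lme4, likelihood-ratio tests, variance partitioning, and the predicted
# mass spread across the weaning-length range.

mass_formula <- function(variant) {
  base <- "weaning_mass_kg ~ z_age + z_age2 + pup_sex"
  rhs <- switch(variant,
    null = paste(base, "+ parity_group"),
    linear = paste(base, "+ parity_group + z_lw"),
    quadratic = paste(base, "+ parity_group + z_lw + z_lw2"),
    # parity drops the parity main effects and lets the length effect vary
    parity = paste(base, "+ z_lw + z_lw:parity_group"),
    cohort = paste(base, "+ parity_group + z_lw + cohort_f"))
  stats::as.formula(paste(rhs, "+ (1 | female_id) + (1 | year_f)"))
}

# shared covariate construction so the simulator and the fit agree on the
# standardisation convention: age over pup records, weaning length over
# females
build_mass_frame <- function(pups, females, age_std = NULL, lw_std = NULL) {
  need <- c("female_id", "year", "pup_sex", "weaning_mass_kg",
            "maternal_age_yr")
  if (!all(need %in% names(pups)))
    stop("pup table needs columns: ", paste(need, collapse = ", "))
  dat <- merge(pups, females[, c("female_id", "cohort", "weaning_length_cm")],
               by = "female_id", sort = FALSE)
  if (nrow(dat) < nrow(pups))
    stop("pup records reference females missing from the female table")
  dat <- dat[order(dat$female_id, dat$year), ]
  if (!"parity_group" %in% names(dat)) {
    dat$parity_group <- derive_parity(dat)
  } else {
    dat$parity_group <- factor(dat$parity_group, levels = c("1", "2", "3+"))
  }
  # age on a 2-sd scale: keeps the quadratic age profile of weaning mass
  # positive over the observed maternal age span
  if (is.null(age_std))
    age_std <- fit_standardizer(dat$maternal_age_yr, scale = 2)
  if (is.null(lw_std))
    lw_std <- fit_standardizer(
      females$weaning_length_cm[females$female_id %in% dat$female_id])
  dat$z_age <- std_transform(age_std, dat$maternal_age_yr)
  dat$z_age2 <- dat$z_age^2
  dat$z_lw <- std_transform(lw_std, dat$weaning_length_cm)
  dat$z_lw2 <- dat$z_lw^2
  dat$year_f <- factor(dat$year)
  dat$pup_sex <- factor(dat$pup_sex, levels = c("male", "female"))
  dat$cohort_f <- factor(dat$cohort)
  attr(dat, "age_std") <- age_std
  attr(dat, "lw_std") <- lw_std
  dat
}

#' Fit a pup weaning-mass mixed model
#'
#' Fits one variant of the provisioning model
#' \eqn{mass_{j,t} = \pi_1 z(age) + \pi_2 z(age)^2 + \pi_{3,m} +
#' \pi_4 I(sex=female) [+ L_w terms] + \alpha_i + \eta_t + \upsilon_{i,t}}
#' with crossed random intercepts for female and year, by maximum likelihood
#' (default, so likelihood-ratio tests between fixed-effect structures are
#' valid) or REML. Fitting is delegated to [lme4::lmer()].
#'
#' @param pups pup table (`female_id`, `year`, `pup_sex`, `weaning_mass_kg`,
#'   `maternal_age_yr`).
#' @param females female table (`female_id`, `cohort`, `weaning_length_cm`).
#' @param variant one of `"null"`, `"linear"`, `"quadratic"`, `"parity"`,
#'   `"cohort"`.
#' @param reml use REML instead of ML.
#' @param age_std,lw_std optional pre-fitted [fit_standardizer()] constants;
#'   by default they are computed from the analysis sample and stored on the
#'   fit.
#' @return object of class `mass_fit`: lme4 fit, coefficient table,
#'   variance components (sd scale), log-likelihood, AIC, standardisers.
#' @export
fit_mass_model <- function(pups, females, variant = "linear", reml = FALSE,
                           age_std = NULL, lw_std = NULL) {
  variant <- check_variant(variant)
  dat <- build_mass_frame(pups, females, age_std, lw_std)
  if (length(unique(dat$female_id)) < 2L || nlevels(dat$year_f) < 2L)
    stop("need at least two females and two years")
  missing_par <- setdiff(levels(dat$parity_group),
                         unique(as.character(dat$parity_group)))
  if (length(missing_par) && variant != "parity")
    stop("singular design: no records for parity group ",
         paste(missing_par, collapse = ", "))
  fml <- mass_formula(variant)
  fit <- lme4::lmer(fml, data = dat, REML = reml,
                    control = lme4::lmerControl(optimizer = "bobyqa",
                                                calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sdof <- function(g) vc$sdcor[match(g, vc$grp)]
  ll <- as.numeric(logLik(fit))
  k <- length(fe) + 3L # fixed effects + three variance components
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  structure(list(
    variant = variant, fit = fit,
    coefficients = data.frame(term = names(fe), estimate = unname(fe),
                              se = unname(se)),
    sigma_alpha = sdof("female_id"), sigma_eta = sdof("year_f"),
    sigma_resid = sdof("Residual"),
    loglik = ll, n_par = k, AIC = 2 * k - 2 * ll,
    n_obs = nrow(dat), reml = reml, convergence = conv,
    age_std = attr(dat, "age_std"), lw_std = attr(dat, "lw_std"),
    lw_range = range(dat$weaning_length_cm)),
    class = "mass_fit")
}

#' @export
print.mass_fit <- function(x, ...) {
  cat("<mass_fit> variant:", x$variant,
      if (x$reml) "(REML)" else "(ML)",
      "| n =", x$n_obs, "| AIC =", format(x$AIC, digits = 7), "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("  sd components: female", format(x$sigma_alpha, digits = 4),
      "| year", format(x$sigma_eta, digits = 4),
      "| residual", format(x$sigma_resid, digits = 4), "\n")
  invisible(x)
}

# nesting partial order of the variant menu (by fixed-effect structure)
NESTED_IN <- list(null = c("linear", "quadratic", "cohort"),
                  linear = c("quadratic", "cohort"))

#' Likelihood-ratio test between nested mass-model variants
#'
#' @param fit_nested,fit_full `mass_fit` objects fitted by ML to the same
#'   data, with the nested variant's fixed effects a subset of the full
#'   one's.
#' @return list with `statistic` (2 x loglik difference), `df` and `p`
#'   (chi-square upper tail).
#' @export
likelihood_ratio_test <- function(fit_nested, fit_full) {
  if (fit_nested$n_obs != fit_full$n_obs)
    stop("fits use different numbers of observations")
  if (fit_nested$reml || fit_full$reml)
    stop("likelihood-ratio tests require ML fits")
  same <- fit_nested$variant == fit_full$variant
  ok <- same || fit_full$variant %in% (NESTED_IN[[fit_nested$variant]] %||%
                                         character(0))
  if (!ok)
    stop("variants '", fit_nested$variant, "' and '", fit_full$variant,
         "' are not nested")
  stat <- max(0, 2 * (fit_full$loglik - fit_nested$loglik))
  df <- fit_full$n_par - fit_nested$n_par
  p <- if (df == 0L) as.numeric(stat <= 0) else
    pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Variance partition of a fitted mass model
#'
#' Shares of the female, year and residual components in the total
#' \eqn{\sigma_\alpha^2 + \sigma_\eta^2 + \sigma_\upsilon^2}.
#'
#' @param fit a `mass_fit` (or any list with the three sd components).
#' @return named numeric vector of shares summing to 1.
#' @export
variance_partition <- function(fit) {
  v <- c(female = fit$sigma_alpha, year = fit$sigma_eta,
         residual = fit$sigma_resid)^2
  if (sum(v) <= 0) stop("all variance components are zero")
  v / sum(v)
}

#' Predicted weaning-mass spread across the weaning-length range
#'
#' Expected pup-mass difference between mothers at two weaning lengths, at
#' stated covariates, with a Wald interval from the fixed-effect covariance.
#' For the linear variant this is exactly
#' \eqn{\pi_5 (z(L_{high}) - z(L_{low}))}.
#'
#' @param fit a `mass_fit` whose variant contains a weaning-length term.
#' @param lw_low,lw_high weaning lengths (cm) to contrast.
#' @param at covariates at which to evaluate (parity group, for the parity
#'   variant).
#' @param level confidence level of the interval.
#' @return list with `spread_kg`, `se`, `lower`, `upper`.
#' @export
predict_mass_spread <- function(fit, lw_low = 90, lw_high = 132,
                                at = list(parity = "1"), level = 0.95) {
  if (fit$variant == "null")
    stop("model has no weaning-length term")
  if (lw_low < fit$lw_range[1] || lw_high > fit$lw_range[2])
    warning("contrast evaluated outside the observed weaning-length range (",
            paste(format(fit$lw_range, digits = 4), collapse = "-"), " cm)")
  zl <- std_transform(fit$lw_std, lw_low)
  zh <- std_transform(fit$lw_std, lw_high)
  fe <- lme4::fixef(fit$fit)
  cvec <- setNames(numeric(length(fe)), names(fe))
  add <- function(term, w) {
    if (!term %in% names(cvec)) stop("term not in model: ", term)
    cvec[term] <<- cvec[term] + w
  }
  dz <- zh - zl
  if ("z_lw" %in% names(fe)) add("z_lw", dz)
  if (fit$variant == "quadratic") add("z_lw2", zh^2 - zl^2)
  if (fit$variant == "parity") {
    g <- as.character(at$parity %||% "1")
    term <- paste0("z_lw:parity_group", g)
    if (term %in% names(fe)) add(term, dz)
  }
  est <- sum(cvec * fe)
  V <- as.matrix(vcov(fit$fit))
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  zq <- qnorm(1 - (1 - level) / 2)
  list(spread_kg = est, se = se, lower = est - zq * se,
       upper = est + zq * se)
}
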