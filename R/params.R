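# Parameter containers for the two model families.

#' Transition-model parameters
#'
#' Parameters of the mixed-effects logistic model for the probability that a
#' female is in the breeder state `B` in year `t`, given her previous state
#' `k` (first-time breeder `F`, breeder `B`, nonbreeder `N`):
#'
#' \deqn{logit \psi^{kB}_{i,t} = \mu + \lambda_1 z(age) + \lambda_2 z(age)^2 +
#'   \lambda_{3,k} + \lambda_5 z(L_w) [+ variant terms] + \beta_i + \theta_t}
#'
#' with sum-to-zero previous-state effects \eqn{\sum_k \lambda_{3,k} = 0},
#' female effects \eqn{\beta_i \sim N(0, \sigma_\beta^2)}, year effects
#' \eqn{\theta_t \sim N(0, \sigma_\theta^2)}, and detection probability `p`
#' applying to breeders only (nonbreeders are never sighted). Defaults are the
#' posterior means reported for this model class in long-term gray seal
#' colony monitoring, used as generating truth by the simulator.
#'
#' @param mu intercept on the logit scale.
#' @param lambda1,lambda2 linear and quadratic standardised-age effects.
#' @param lambda3 named length-3 vector of previous-state effects
#'   (`F`, `B`, `N`), must sum to zero (tolerance 1e-12).
#' @param lambda5 standardised weaning-length effect.
#' @param lambda6 second weaning-length term: coefficient of \eqn{z(L_w)^2}
#'   (quadratic variant) or of \eqn{z(L_w) I(parity = 1)} (parity variant).
#' @param lambda_cohort per-cohort offsets (cohort variant), first cohort is
#'   the baseline 0.
#' @param sigma_beta,sigma_theta random-effect standard deviations (logit
#'   scale).
#' @param sigma_omega optional observation-level logit-normal overdispersion
#'   sd; 0 disables it.
#' @param detection_p probability a breeding female is sighted at least once
#'   in a season.
#' @return object of class `transition_params`.
#' @export
transition_params <- function(mu = 1.685698,
                              lambda1 = 0.385, lambda2 = -0.355,
                              lambda3 = c(F = -0.4258498, B = 0.1379224,
                                          N = 0.2879274),
                              lambda5 = 0.549, lambda6 = 0,
                              lambda_cohort = NULL,
                              sigma_beta = sqrt(0.895),
                              sigma_theta = sqrt(1.310),
                              sigma_omega = 0,
                              detection_p = 0.975) {
  if (length(lambda3) != 3L || is.null(names(lambda3)) ||
      !setequal(names(lambda3), c("F", "B", "N")))
    stop("lambda3 must be a length-3 vector named F, B, N")
  lambda3 <- lambda3[c("F", "B", "N")]
  if (abs(sum(lambda3)) > 1e-12)
    stop("lambda3 must sum to zero (got ", format(sum(lambda3)), ")")
  if (sigma_beta < 0 || sigma_theta < 0 || sigma_omega < 0)
    stop("random-effect sds must be >= 0")
  if (detection_p < 0 || detection_p > 1)
    stop("detection_p must be in [0, 1]")
  structure(list(mu = mu, lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, lambda5 = lambda5, lambda6 = lambda6,
                 lambda_cohort = lambda_cohort,
                 sigma_beta = sigma_beta, sigma_theta = sigma_theta,
                 sigma_omega = sigma_omega, detection_p = detection_p),
            class = "transition_params")
}

#' Provisioning-model parameters
#'
#' Generating values of the linear mixed model for pup weaning mass
#' \eqn{mass_{j,t} = \pi_0 + \pi_1 z(age) + \pi_2 z(age)^2 + \pi_{3,m} +
#' \pi_4 I(sex = female) + \pi_5 z(L_w) [+ variant terms] + \alpha_i +
#' \eta_t + \upsilon_{i,t}}. Random intercepts: female
#' \eqn{\alpha_i \sim N(0, \sigma_\alpha^2)} and year
#' \eqn{\eta_t \sim N(0, \sigma_\eta^2)}, residual
#' \eqn{\upsilon \sim N(0, \sigma_\upsilon^2)}. Defaults are the reported
#' estimates for this system; the printed variance components (4.67, 1.29,
#' 5.45) are interpreted as variances in kg^2.
#'
#' @param intercept expected mass (kg) at baseline covariates (first parity,
#'   male pup, mean age, mean weaning length).
#' @param pi1,pi2 linear and quadratic standardised maternal-age effects (kg).
#' @param pi3 named effects of parity groups `2` and `3+` relative to parity
#'   1 (kg).
#' @param pi4 effect of a female pup relative to male (kg, negative: female
#'   pups wean lighter).
#' @param pi5 standardised weaning-length effect (kg per sd of L_w).
#' @param pi6,pi7 variant terms: quadratic `z(L_w)^2` coefficient, or the
#'   `z(L_w) x parity` interaction coefficients.
#' @param pi_cohort per-cohort offsets (cohort variant), baseline first.
#' @param sigma_alpha,sigma_eta,sigma_resid female, year and residual
#'   standard deviations (kg).
#' @return object of class `mass_params`.
#' @export
mass_params <- function(intercept = 49.22,
                        pi1 = 14.46, pi2 = -11.88,
                        pi3 = c(`2` = 4.01, `3+` = 6.23),
                        pi4 = -2.26, pi5 = 1.07, pi6 = 0, pi7 = 0,
                        pi_cohort = NULL,
                        sigma_alpha = sqrt(4.67),
                        sigma_eta = sqrt(1.29),
                        sigma_resid = sqrt(5.45)) {
  if (sigma_alpha < 0 || sigma_eta < 0 || sigma_resid < 0)
    stop("standard deviations must be >= 0")
  if (length(pi3) != 2L) stop("pi3 must have effects for groups 2 and 3+")
  structure(list(intercept = intercept, pi1 = pi1, pi2 = pi2, pi3 = pi3,
                 pi4 = pi4, pi5 = pi5, pi6 = pi6, pi7 = pi7,
                 pi_cohort = pi_cohort,
                 sigma_alpha = sigma_alpha, sigma_eta = sigma_eta,
                 sigma_resid = sigma_resid),
            class = "mass_params")
}

# canonical variant names shared by both families
MSMS_VARIANTS <- c("null", "linear", "quadratic", "parity", "cohort")

check_variant <- function(variant) {
  match.arg(variant, MSMS_VARIANTS)
}

variant_code <- function(variant) {
  match(check_variant(variant), MSMS_VARIANTS) - 1L
}
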