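# Synthetic colony generator: encounter histories, female covariates and pup
# weaning-mass records with the statistical structure the two model families
# assume, so every downstream stage is testable by parameter recovery.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is designed around:
#' 363 branded females from the 1998-2002 cohorts followed over the 19
#' breeding seasons 2002-2020, weaning lengths averaging 112.7 cm (sd
#' 4.28, truncated to 90-132 cm, with a longer 2002 cohort), recruitment
#' concentrated at ages 5-7, latent F/B/N breeding dynamics at the reported
#' transition-model posterior means and detection of breeders at 0.975.
#'
#' @param n_females number of females surviving to recruitment.
#' @param n_occasions number of breeding seasons observed.
#' @param start_year calendar year of the first season.
#' @param cohorts birth years of the marked cohorts.
#' @param cohort_probs probability a female belongs to each cohort.
#' @param cohort_mean_cm per-cohort mean weaning length (cm).
#' @param cohort_sd_cm within-cohort sd of weaning length (cm).
#' @param lw_range_cm truncation range for weaning length (cm).
#' @param recruit_ages,recruit_age_probs support and probabilities of age at
#'   first breeding.
#' @param transition a [transition_params()] object (generating truth).
#' @param mass a [mass_params()] object (generating truth).
#' @param detection_p probability a breeding female is sighted; overrides the
#'   value in `transition`.
#' @param survival optional annual survival thinning (1 = no mortality, the
#'   model's assumption; adult survival in this system is ~0.99).
#' @param transition_variant which variant generates the breeding dynamics.
#' @param mass_variant which variant generates pup masses.
#' @param seed default seed used by [simulate_colony()] when none is given.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_females = 363L, n_occasions = 19L,
                       start_year = 2002L, cohorts = 1998:2002,
                       cohort_probs = rep(1 / 5, 5),
                       cohort_mean_cm = c(112.0, 112.3, 112.5, 112.6, 114.1),
                       cohort_sd_cm = 4.28, lw_range_cm = c(90, 132),
                       recruit_ages = 4:8,
                       recruit_age_probs = c(0.025, 0.314, 0.245, 0.286, 0.130),
                       transition = transition_params(),
                       mass = mass_params(),
                       detection_p = transition$detection_p,
                       survival = 1.0,
                       transition_variant = "linear",
                       mass_variant = "linear",
                       seed = 1L) {
  stopifnot(n_females >= 1L, n_occasions >= 2L,
            length(cohort_probs) == length(cohorts),
            length(cohort_mean_cm) == length(cohorts),
            cohort_sd_cm > 0,
            length(recruit_age_probs) == length(recruit_ages),
            detection_p > 0, detection_p <= 1, survival > 0, survival <= 1)
  if (abs(sum(cohort_probs) - 1) > 1e-12) stop("cohort_probs must sum to 1")
  if (abs(sum(recruit_age_probs) - 1) > 1e-12)
    stop("recruit_age_probs must sum to 1")
  transition$detection_p <- detection_p
  structure(list(n_females = as.integer(n_females),
                 n_occasions = as.integer(n_occasions),
                 start_year = as.integer(start_year),
                 cohorts = as.integer(cohorts), cohort_probs = cohort_probs,
                 cohort_mean_cm = cohort_mean_cm,
                 cohort_sd_cm = cohort_sd_cm, lw_range_cm = lw_range_cm,
                 recruit_ages = as.integer(recruit_ages),
                 recruit_age_probs = recruit_age_probs,
                 transition = transition, mass = mass,
                 detection_p = detection_p, survival = survival,
                 transition_variant = check_variant(transition_variant),
                 mass_variant = check_variant(mass_variant),
                 seed = as.integer(seed)),
            class = "sim_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- rnorm(length(todo), mean[todo], sd)
    todo <- todo[out[todo] < lo | out[todo] > hi]
  }
  out
}

#' Simulate a breeding colony
#'
#' Generates, per female: a cohort and truncated-normal weaning length; an
#' age at recruitment; a latent state sequence starting in `F` at recruitment
#' (conditioning on first capture, sighting 1) and thereafter switching
#' between `B` and `N` with probability given by the logistic transition
#' model (female and year random effects drawn from their generating
#' normals); sightings of breeders with probability `detection_p`; and one
#' pup record per *sighted* breeding occasion, with weaning mass from the
#' provisioning model (true parity, random pup sex). Latent states and the
#' drawn random effects are returned for truth-checking only.
#'
#' @param config a [sim_config()].
#' @param seed integer; overrides `config$seed`.
#' @return list of class `seal_colony` with elements `females`, `encounters`,
#'   `pups`, `latent` (state matrix), `truth` (generating parameters, random
#'   effects and standardisers) and `manifest`.
#' @export
simulate_colony <- function(config = sim_config(), seed = NULL) {
  set.seed(seed %||% config$seed)
  nF <- config$n_females
  nT <- config$n_occasions
  years <- config$start_year + seq_len(nT) - 1L
  tp <- config$transition
  mp <- config$mass
  tvar <- config$transition_variant
  mvar <- config$mass_variant

  # cohort, weaning length, recruitment age (joint redraw when the implied
  # recruitment year falls outside the study window)
  cohort <- recruit_year <- integer(nF)
  todo <- seq_len(nF)
  guard <- 0L
  while (length(todo)) {
    cohort[todo] <- sample(config$cohorts, length(todo), replace = TRUE,
                           prob = config$cohort_probs)
    age_r <- sample(config$recruit_ages, length(todo), replace = TRUE,
                    prob = config$recruit_age_probs)
    recruit_year[todo] <- cohort[todo] + age_r
    todo <- todo[recruit_year[todo] < years[1L] |
                   recruit_year[todo] > years[nT]]
    guard <- guard + 1L
    if (guard > 1000L)
      stop("n_occasions too small for any female to recruit")
  }
  ci <- match(cohort, config$cohorts)
  lw <- rtrunc_norm(nF, config$cohort_mean_cm[ci], config$cohort_sd_cm,
                    config$lw_range_cm[1], config$lw_range_cm[2])
  recruit <- recruit_year - config$start_year + 1L

  females <- data.frame(
    female_id = sprintf("F%04d", seq_len(nF)),
    cohort = cohort, weaning_length_cm = lw,
    recruit_occasion = recruit, recruit_year = recruit_year,
    stringsAsFactors = FALSE)

  # standardisers: age over the post-recruitment female-occasion grid,
  # weaning length over females (constants recorded in the manifest)
  age <- outer(cohort, years, function(c, y) y - c)
  post <- col(age) >= recruit
  age_std <- fit_standardizer(age[post])
  lw_std <- fit_standardizer(lw)
  zage <- matrix(std_transform(age_std, age), nF, nT)
  zlw <- std_transform(lw_std, lw)

  beta <- rnorm(nF, 0, tp$sigma_beta)
  theta <- rnorm(nT, 0, tp$sigma_theta)

  states <- matrix(NA_character_, nF, nT,
                   dimnames = list(females$female_id, years))
  sight <- matrix(NA_integer_, nF, nT)
  alive <- rep(TRUE, nF)
  for (i in seq_len(nF)) states[i, recruit[i]] <- "F"
  sight[cbind(seq_len(nF), recruit)] <- 1L

  tp0 <- tp
  tp0$sigma_omega <- 0 # per-transition omega is drawn, not marginalised
  for (t in seq_len(nT)) {
    active <- which(recruit < t & alive)
    if (!length(active)) next
    prev <- states[cbind(active, t - 1L)]
    # prior births (recruitment included), discretised to groups 1/2/3+
    prior_b <- vapply(active, function(ii)
      sum(states[ii, seq_len(t - 1L)] %in% c("F", "B")), integer(1))
    lp <- logit(breeding_probability(tp0, prev, zage[cbind(active, t)],
                                     zlw[active], variant = tvar,
                                     parity = pmin(prior_b, 3L),
                                     cohort = ci[active],
                                     beta = beta[active], theta = theta[t]))
    if (tp$sigma_omega > 0)
      lp <- lp + rnorm(length(active), 0, tp$sigma_omega)
    psi <- invlogit(lp)
    b <- rbinom(length(active), 1L, psi) == 1L
    states[cbind(active, t)] <- ifelse(b, "B", "N")
    sight[cbind(active, t)] <- ifelse(
      b, rbinom(length(active), 1L, tp$detection_p), 0L)
    if (config$survival < 1) {
      dead <- runif(length(active)) > config$survival
      alive[active[dead]] <- FALSE
    }
  }
  # survival thinning < 1: dead females remain unobservable (state D, 0s)
  gone <- is.na(sight) & col(sight) > recruit[row(sight)]
  states[gone] <- "D"
  sight[gone] <- 0L

  encounters <- encounter_histories(sight, years, females$female_id)

  # pup records at every sighted breeding occasion (recruitment included)
  breeding <- !is.na(states) & states %in% c("F", "B")
  birth_idx <- which(breeding & sight == 1L, arr.ind = TRUE)
  birth_idx <- birth_idx[order(birth_idx[, 1L], birth_idx[, 2L]), ,
                         drop = FALSE]
  i <- birth_idx[, 1L]; t <- birth_idx[, 2L]
  # true parity: count of breeding occasions (sighted or not) up to t
  cum_births <- t(apply(breeding, 1L, cumsum))
  par_grp <- pmin(cum_births[birth_idx], 3L)

  mass_age_std <- fit_standardizer(years[t] - cohort[i], scale = 2)
  za <- std_transform(mass_age_std, years[t] - cohort[i])
  zl <- zlw[i]
  alpha <- rnorm(nF, 0, mp$sigma_alpha)
  eta <- rnorm(nT, 0, mp$sigma_eta)
  sex <- ifelse(runif(length(i)) < 0.5, "female", "male")
  pi3v <- c(0, mp$pi3)[par_grp]
  lwterm <- switch(mvar,
    null = 0,
    linear = mp$pi5 * zl,
    quadratic = mp$pi5 * zl + mp$pi6 * zl^2,
    parity = mp$pi5 * zl + mp$pi6 * zl * (par_grp == 2L) +
      mp$pi7 * zl * (par_grp == 3L),
    cohort = mp$pi5 * zl + c(0, mp$pi_cohort %||% rep(0, length(config$cohorts) - 1L))[ci[i]])
  if (mvar == "parity") pi3v <- 0 # parity mains replaced by the interaction
  mass <- mp$intercept + mp$pi1 * za + mp$pi2 * za^2 + pi3v +
    mp$pi4 * (sex == "female") + lwterm + alpha[i] + eta[t] +
    rnorm(length(i), 0, mp$sigma_resid)

  pups <- data.frame(
    female_id = females$female_id[i], year = years[t], pup_sex = sex,
    weaning_mass_kg = mass, maternal_age_yr = years[t] - cohort[i],
    stringsAsFactors = FALSE)

  manifest <- list(
    generator = "sealcarry::simulate_colony",
    package_version = as.character(packageVersion("sealcarry")),
    seed = seed %||% config$seed,
    n_females = nF, n_occasions = nT,
    years = paste(range(years), collapse = "-"),
    transition_variant = tvar, mass_variant = mvar,
    detection_p = tp$detection_p,
    age_std_mean = age_std$mean, age_std_sd = age_std$sd,
    lw_std_mean = lw_std$mean, lw_std_sd = lw_std$sd,
    mass_age_std_mean = mass_age_std$mean, mass_age_std_sd = mass_age_std$sd,
    n_pup_records = nrow(pups))

  structure(list(females = females, encounters = encounters, pups = pups,
                 latent = states,
                 truth = list(transition = tp, mass = mp, beta = beta,
                              theta = theta, alpha = alpha, eta = eta,
                              age_std = age_std, lw_std = lw_std,
                              mass_age_std = mass_age_std),
                 config = config, manifest = manifest),
            class = "seal_colony")
}

#' @export
print.seal_colony <- function(x, ...) {
  cat("<seal_colony> ", nrow(x$females), " females, ",
      length(x$encounters$years), " occasions, ", nrow(x$pups),
      " pup records\n", sep = "")
  invisible(x)
}

#' Descriptive summary of a colony
#'
#' Reports sample sizes, pups per female, weaning-length moments, the
#' recruitment-age distribution and the raw post-recruitment resight rate
#' (plus the latent breeding rate when latent states are available).
#'
#' @param colony a `seal_colony` (simulated, or assembled from read tables
#'   with elements `females`, `encounters`, `pups`).
#' @return named list of summaries.
#' @export
summary_statistics <- function(colony) {
  if (is.null(colony$females) || nrow(colony$females) == 0L)
    stop("empty colony")
  enc <- colony$encounters
  pupn <- table(factor(colony$pups$female_id, levels = enc$female_id))
  post <- col(enc$sightings) > enc$recruit
  resgt <- enc$sightings[post]
  out <- list(
    n_females = nrow(colony$females),
    n_pups = nrow(colony$pups),
    pups_per_female = c(mean = mean(pupn), sd = sd(pupn),
                        min = min(pupn), max = max(pupn)),
    weaning_length_cm = c(mean = mean(colony$females$weaning_length_cm),
                          sd = sd(colony$females$weaning_length_cm),
                          min = min(colony$females$weaning_length_cm),
                          max = max(colony$females$weaning_length_cm)),
    recruit_age = table(colony$females$recruit_year - colony$females$cohort),
    resight_rate = mean(resgt == 1L, na.rm = TRUE))
  if (!is.null(colony$latent)) {
    lat <- colony$latent[col(colony$latent) > enc$recruit]
    out$latent_breeding_rate <- mean(lat == "B", na.rm = TRUE)
  }
  out
}

#' Write / read a colony as a directory of CSV tables
#'
#' Writes `encounters.csv` (wide 0/1 matrix), `females.csv`, `pups.csv`, the
#' latent-truth matrix (`latent_states.csv`, simulated colonies only) and a
#' `manifest.txt`. `read_colony()` restores the analysable parts (latent
#' truth is reloaded when present).
#'
#' @param colony a `seal_colony`.
#' @param dir directory (created if missing).
#' @return `dir` (write) / a `seal_colony` (read).
#' @export
write_colony <- function(colony, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_encounter_matrix(colony$encounters, file.path(dir, "encounters.csv"))
  write_female_table(colony$females, file.path(dir, "females.csv"))
  write_pup_table(colony$pups, file.path(dir, "pups.csv"))
  if (!is.null(colony$latent))
    write.csv(data.frame(female_id = rownames(colony$latent), colony$latent,
                         check.names = FALSE),
              file.path(dir, "latent_states.csv"), row.names = FALSE, na = "")
  if (!is.null(colony$manifest))
    write_manifest(colony$manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_colony
#' @export
read_colony <- function(dir) {
  enc <- read_encounter_matrix(file.path(dir, "encounters.csv"))
  females <- read_female_table(file.path(dir, "females.csv"))
  pups <- read_pup_table(file.path(dir, "pups.csv"))
  latent <- NULL
  lp <- file.path(dir, "latent_states.csv")
  if (file.exists(lp)) {
    ldf <- read.csv(lp, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character") # keep "F" from becoming FALSE
    latent <- as.matrix(ldf[, -1L, drop = FALSE])
    latent[latent == ""] <- NA
    rownames(latent) <- ldf$female_id
  }
  manifest <- if (file.exists(file.path(dir, "manifest.txt")))
    read_manifest(file.path(dir, "manifest.txt")) else NULL
  structure(list(females = females, encounters = enc, pups = pups,
                 latent = latent, manifest = manifest),
            class = "seal_colony")
}
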