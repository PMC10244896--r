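# shared fixtures: small colonies and random parameter draws

small_config <- function(n_females = 40L, n_occasions = 8L, seed = 1L, ...) {
  sim_config(n_females = n_females, n_occasions = n_occasions, seed = seed,
             ...)
}

# random transition parameters with a valid sum-to-zero lambda3
random_tparams <- function(sd = 0.6, sigma_omega = 0, detection_p = NULL) {
  x <- rnorm(2, 0, sd)
  transition_params(
    mu = rnorm(1, 0, sd), lambda1 = rnorm(1, 0, sd),
    lambda2 = rnorm(1, 0, sd),
    lambda3 = c(F = x[1], B = x[2], N = -sum(x)),
    lambda5 = rnorm(1, 0, sd), lambda6 = rnorm(1, 0, sd),
    sigma_omega = sigma_omega,
    detection_p = detection_p %||% runif(1, 0.3, 1))
}

# three-female toy encounter matrix
toy_histories <- function() {
  m <- rbind(c(NA, 1L, 0L, 1L, 0L),
             c(1L, 0L, 0L, 1L, 1L),
             c(NA, NA, 1L, 1L, 0L))
  encounter_histories(m, 2002:2006, c("A", "B", "C"))
}

# filtered analysis colony, mirroring the pipeline's filter stage
filtered_colony <- function(colony, quiet = TRUE) {
  enc <- filter_single_season(colony$encounters, quiet = quiet)
  keep <- colony$females$female_id %in% enc$female_id
  out <- colony
  out$encounters <- enc
  out$females <- colony$females[keep, , drop = FALSE]
  out$pups <- colony$pups[colony$pups$female_id %in% enc$female_id, ,
                          drop = FALSE]
  out
}
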