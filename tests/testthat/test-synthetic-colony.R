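test_that("simulation is deterministic given the seed", {
  a <- simulate_colony(small_config(seed = 11L))
  b <- simulate_colony(small_config(seed = 11L))
  expect_identical(a$encounters$sightings, b$encounters$sightings)
  expect_identical(a$pups, b$pups)
  expect_identical(a$latent, b$latent)
  c2 <- simulate_colony(small_config(seed = 12L))
  expect_false(identical(a$encounters$sightings, c2$encounters$sightings))
})

test_that("no sightings before recruitment; recruitment is always sighted", {
  col <- simulate_colony(small_config(n_females = 80L, seed = 2L))
  enc <- col$encounters
  for (i in seq_along(enc$female_id)) {
    r <- enc$recruit[i]
    if (r > 1L) expect_true(all(is.na(enc$sightings[i, seq_len(r - 1L)])))
    expect_equal(enc$sightings[i, r], 1L)
    expect_equal(col$latent[i, r], "F")
  }
})

test_that("perfect detection makes sightings equal the breeding indicator", {
  col <- simulate_colony(small_config(n_females = 60L, seed = 5L,
                                      detection_p = 1))
  post <- col(col$latent) >= col$encounters$recruit
  b <- col$latent[post] %in% c("F", "B")
  expect_identical(col$encounters$sightings[post] == 1L, b)
  s <- summary_statistics(col)
  expect_equal(s$resight_rate, s$latent_breeding_rate)
})

test_that("pup records pair one-to-one with sighted occasions", {
  col <- simulate_colony(small_config(n_females = 70L, seed = 9L))
  enc <- col$encounters
  sighted <- which(enc$sightings == 1L, arr.ind = TRUE)
  expect_equal(nrow(col$pups), nrow(sighted))
  key_s <- paste(enc$female_id[sighted[, 1]], enc$years[sighted[, 2]])
  key_p <- paste(col$pups$female_id, col$pups$year)
  expect_setequal(key_p, key_s)
  expect_false(anyDuplicated(key_p) > 0)
  expect_true(all(col$pups$weaning_mass_kg > 0))
})

test_that("constant transition probability is recovered by the raw rate", {
  # all covariate effects zero, no random effects: breeding is Bernoulli(0.8)
  tp <- transition_params(mu = logit(0.8), lambda1 = 0, lambda2 = 0,
                          lambda3 = c(F = 0, B = 0, N = 0), lambda5 = 0,
                          sigma_beta = 0, sigma_theta = 0, detection_p = 1)
  col <- simulate_colony(sim_config(n_females = 700L, n_occasions = 17L,
                                    transition = tp, detection_p = 1,
                                    seed = 21L))
  post <- col(col$latent) > col$encounters$recruit
  n <- sum(post)
  rate <- mean(col$latent[post] == "B")
  expect_gt(n, 5000)
  expect_lt(abs(rate - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("homogeneous latent dynamics form the analytic 2-state Markov chain", {
  tp <- transition_params(mu = 0.9, lambda1 = 0, lambda2 = 0,
                          lambda3 = c(F = -0.2, B = 0.3, N = -0.1),
                          lambda5 = 0, sigma_beta = 0, sigma_theta = 0,
                          detection_p = 1)
  col <- simulate_colony(sim_config(n_females = 9000L, n_occasions = 20L,
                                    transition = tp, detection_p = 1,
                                    seed = 33L))
  lat <- col$latent
  n_obs <- matrix(0, 2, 2, dimnames = list(c("B", "N"), c("B", "N")))
  for (t in 2:ncol(lat)) {
    prev <- lat[, t - 1L]
    cur <- lat[, t]
    ok <- prev %in% c("B", "N") & cur %in% c("B", "N")
    n_obs <- n_obs + table(factor(prev[ok], c("B", "N")),
                           factor(cur[ok], c("B", "N")))
  }
  expect_gt(sum(n_obs), 1e5)
  psiB <- invlogit(0.9 + 0.3)
  psiN <- invlogit(0.9 - 0.1)
  for (k in 1:2) {
    p_expect <- if (k == 1) c(psiB, 1 - psiB) else c(psiN, 1 - psiN)
    gof <- suppressWarnings(stats::chisq.test(n_obs[k, ], p = p_expect))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("breeding fraction increases across weaning-length deciles", {
  col <- simulate_colony(sim_config(n_females = 2500L, n_occasions = 12L,
                                    detection_p = 1, seed = 8L))
  post <- col(col$latent) > col$encounters$recruit
  b_rate <- vapply(seq_len(nrow(col$females)), function(i) {
    cells <- which(post[i, ])
    if (!length(cells)) return(NA_real_)
    mean(col$latent[i, cells] == "B")
  }, numeric(1))
  dec <- cut(col$females$weaning_length_cm,
             quantile(col$females$weaning_length_cm, seq(0, 1, 0.1)),
             include.lowest = TRUE)
  means <- tapply(b_rate, dec, mean, na.rm = TRUE)
  expect_true(all(diff(means) > 0))
})

test_that("summary statistics report the expected descriptives", {
  col <- simulate_colony(small_config(n_females = 40L, seed = 14L))
  one <- list(females = col$females[1, , drop = FALSE],
              encounters = encounter_histories(
                col$encounters$sightings[1, , drop = FALSE],
                col$encounters$years, col$encounters$female_id[1]),
              pups = col$pups[col$pups$female_id ==
                                col$females$female_id[1], , drop = FALSE])
  s1 <- summary_statistics(one)
  expect_equal(unname(s1$pups_per_female["mean"]), s1$n_pups)
  expect_equal(unname(s1$pups_per_female["min"]),
               unname(s1$pups_per_female["max"]))
  expect_error(summary_statistics(list(females = data.frame())), "empty")

  big <- simulate_colony(sim_config(seed = 4L)) # default 363 females
  s <- summary_statistics(big)
  expect_equal(s$n_females, 363L)
  # L_w mean within 3 standard errors of the configured 112.7 cm
  expect_lt(abs(unname(s$weaning_length_cm["mean"]) - 112.7),
            3 * 4.28 / sqrt(363))
})

test_that("colony directories round-trip", {
  col <- simulate_colony(small_config(seed = 6L))
  dir <- withr::local_tempdir()
  write_colony(col, dir)
  got <- read_colony(dir)
  expect_identical(got$encounters$sightings, col$encounters$sightings)
  expect_equal(got$females$weaning_length_cm, col$females$weaning_length_cm)
  expect_equal(got$pups$weaning_mass_kg, col$pups$weaning_mass_kg)
  expect_identical(got$latent, col$latent)
})
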