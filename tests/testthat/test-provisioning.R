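test_that("noiseless data are recovered exactly (degenerates to least squares)", {
  mp <- mass_params(sigma_alpha = 0, sigma_eta = 0, sigma_resid = 1e-7)
  col <- simulate_colony(small_config(n_females = 50L, n_occasions = 9L,
                                      seed = 12L, mass = mp,
                                      detection_p = 1))
  fit <- suppressMessages(suppressWarnings(
    fit_mass_model(col$pups, col$females, "linear")))
  fe <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(fe["(Intercept)"]), 49.22, tolerance = 1e-5)
  expect_equal(unname(fe["z_age"]), 14.46, tolerance = 1e-5)
  expect_equal(unname(fe["z_age2"]), -11.88, tolerance = 1e-5)
  expect_equal(unname(fe["parity_group2"]), 4.01, tolerance = 1e-5)
  expect_equal(unname(fe["parity_group3+"]), 6.23, tolerance = 1e-5)
  expect_equal(unname(fe["pup_sexfemale"]), -2.26, tolerance = 1e-5)
  expect_equal(unname(fe["z_lw"]), 1.07, tolerance = 1e-5)
})

test_that("duplicating every row changes the loglik, barely moves estimates", {
  # exact invariance holds only without random effects; with crossed random
  # intercepts the re-estimated variance ratios reweight the GLS fit a little
  col <- simulate_colony(sim_config(n_females = 120L, n_occasions = 10L,
                                    seed = 19L))
  pups <- col$pups
  pups$parity_group <- derive_parity(pups) # fix parity before duplicating
  f1 <- fit_mass_model(pups, col$females, "linear")
  f2 <- fit_mass_model(rbind(pups, pups), col$females, "linear")
  expect_false(isTRUE(all.equal(f1$loglik, f2$loglik)))
  expect_true(all(abs(f2$coefficients$estimate - f1$coefficients$estimate) <
                    0.75 * f1$coefficients$se))
})

test_that("fixed effects match a direct marginal-MVN maximum-likelihood oracle", {
  set.seed(5)
  for (r in 1:3) {
    col <- simulate_colony(small_config(n_females = 22L, n_occasions = 6L,
                                        seed = 40L + r))
    fit <- fit_mass_model(col$pups, col$females, "linear")
    lmm <- fit$fit
    orc <- mvn_lmm_oracle(y = lme4::getME(lmm, "y"),
                          X = as.matrix(lme4::getME(lmm, "X")),
                          female = lmm@frame$female_id,
                          year = lmm@frame$year_f)
    expect_equal(unname(lme4::fixef(lmm)), unname(orc$beta),
                 tolerance = 1e-4)
    expect_equal(fit$loglik, orc$loglik, tolerance = 1e-6)
  }
})

test_that("refitting fixed effects at the estimated variances reproduces them", {
  col <- simulate_colony(small_config(n_females = 30L, seed = 23L))
  fit <- fit_mass_model(col$pups, col$females, "linear")
  lmm <- fit$fit
  X <- as.matrix(lme4::getME(lmm, "X"))
  y <- lme4::getME(lmm, "y")
  Za <- stats::model.matrix(~ 0 + factor(lmm@frame$female_id))
  Ze <- stats::model.matrix(~ 0 + factor(lmm@frame$year_f))
  Sigma <- fit$sigma_alpha^2 * tcrossprod(Za) +
    fit$sigma_eta^2 * tcrossprod(Ze) + fit$sigma_resid^2 * diag(length(y))
  gls <- solve(t(X) %*% solve(Sigma, X), t(X) %*% solve(Sigma, y))
  expect_equal(unname(lme4::fixef(lmm)), unname(drop(gls)), tolerance = 1e-6)
})

test_that("the fuller model never has lower log-likelihood", {
  col <- simulate_colony(small_config(n_females = 45L, seed = 27L))
  f0 <- fit_mass_model(col$pups, col$females, "null")
  f1 <- fit_mass_model(col$pups, col$females, "linear")
  f2 <- fit_mass_model(col$pups, col$females, "quadratic")
  expect_gte(f1$loglik, f0$loglik - 1e-8)
  expect_gte(f2$loglik, f1$loglik - 1e-8)
})

test_that("estimates are invariant to row order and relabeling", {
  col <- simulate_colony(small_config(n_females = 35L, seed = 29L))
  f1 <- fit_mass_model(col$pups, col$females, "linear")
  perm <- sample(nrow(col$pups))
  pups2 <- col$pups[perm, ]
  map <- setNames(paste0("Z", seq_len(nrow(col$females))),
                  col$females$female_id)
  pups2$female_id <- unname(map[pups2$female_id])
  fem2 <- col$females
  fem2$female_id <- unname(map[fem2$female_id])
  f2 <- fit_mass_model(pups2, fem2, "linear")
  expect_equal(sort(f2$coefficients$estimate), sort(f1$coefficients$estimate),
               tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("likelihood-ratio test behaves on identical, nested and invalid pairs", {
  col <- simulate_colony(small_config(n_females = 40L, seed = 31L))
  f0 <- fit_mass_model(col$pups, col$females, "null")
  f1 <- fit_mass_model(col$pups, col$females, "linear")
  same <- likelihood_ratio_test(f0, f0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1L)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
  fp <- fit_mass_model(col$pups, col$females, "parity")
  expect_error(likelihood_ratio_test(f0, fp), "not nested")
  half <- col$pups[seq_len(nrow(col$pups) - 5L), ]
  f0b <- fit_mass_model(half, col$females, "null")
  expect_error(likelihood_ratio_test(f0b, f1), "different numbers")
})

test_that("variance partition is simple share arithmetic", {
  fake <- list(sigma_alpha = 2, sigma_eta = 1, sigma_resid = 1)
  expect_equal(unname(variance_partition(fake)), c(4, 1, 1) / 6)
  tab3 <- list(sigma_alpha = sqrt(4.67), sigma_eta = sqrt(1.29),
               sigma_resid = sqrt(5.45))
  expect_equal(sum(variance_partition(tab3)), 1)
  expect_error(variance_partition(list(sigma_alpha = 0, sigma_eta = 0,
                                       sigma_resid = 0)), "zero")
})

test_that("mass spread is exact linear algebra on the weaning-length terms", {
  col <- simulate_colony(small_config(n_females = 40L, seed = 37L))
  fit <- fit_mass_model(col$pups, col$females, "linear")
  pi5 <- fit$coefficients$estimate[fit$coefficients$term == "z_lw"]
  dz <- std_transform(fit$lw_std, 132) - std_transform(fit$lw_std, 90)
  sp <- suppressWarnings(predict_mass_spread(fit, 90, 132))
  expect_equal(sp$spread_kg, pi5 * dz, tolerance = 1e-12)
  expect_true(sp$lower < sp$spread_kg & sp$spread_kg < sp$upper)
  expect_warning(predict_mass_spread(fit, 80, 140), "outside")
  f0 <- fit_mass_model(col$pups, col$females, "null")
  expect_error(predict_mass_spread(f0), "no weaning-length term")
})
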