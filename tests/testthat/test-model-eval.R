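# small real fit reused across WAIC / contrast checks
local_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      col <- simulate_colony(small_config(n_females = 25L, n_occasions = 7L,
                                          seed = 55L))
      fit <<- fit_multistate(col, "linear",
                             mcmc_config(n_chains = 1L, n_iter = 300L,
                                         burn_in = 150L, thin = 10L,
                                         seed = 6L))
    }
    fit
  }
})

# transition_params equivalent of one posterior draw, for the manual oracle
draw_to_params <- function(m, s) {
  g <- function(nm) unname(m[s, nm])
  l3 <- c(F = g("lambda3_F"), B = g("lambda3_B"), N = g("lambda3_N"))
  transition_params(
    mu = g("mu"), lambda1 = g("lambda1"), lambda2 = g("lambda2"),
    lambda3 = l3 - sum(l3) / 3, # exact sum-to-zero despite rounding
    lambda5 = g("lambda5"), detection_p = g("p"),
    sigma_beta = g("sigma_beta"), sigma_theta = g("sigma_theta"))
}

test_that("waic matches a hand computation on a few draws", {
  fit <- local_fit()
  m <- draws_matrix(fit)[1:3, , drop = FALSE]
  toy <- fit
  toy$samples <- posterior_samples(list(m))
  got <- waic(toy)

  d <- fit$data
  ll <- sapply(1:3, function(s)
    sealcarry:::colony_loglik(
      d, draw_to_params(m, s),
      beta = m[s, paste0("beta[", d$female_id, "]")],
      theta = m[s, paste0("theta[", d$years, "]")]))
  # ll: females x draws; WAIC formula computed longhand
  lppd <- sum(log(rowMeans(exp(ll))))
  p_waic <- sum(apply(ll, 1, var))
  expect_equal(got$lppd, lppd, tolerance = 1e-10)
  expect_equal(got$p_waic, p_waic, tolerance = 1e-10)
  expect_equal(got$waic, -2 * (lppd - p_waic), tolerance = 1e-10)
  expect_equal(sum(got$contributions$lppd), got$lppd, tolerance = 1e-8)
  expect_equal(sum(got$contributions$p_waic), got$p_waic, tolerance = 1e-8)
})

test_that("a degenerate posterior has p_waic 0 and waic = -2 loglik", {
  fit <- local_fit()
  m <- draws_matrix(fit)
  md <- m[rep(1L, 5L), , drop = FALSE]
  toy <- fit
  toy$samples <- posterior_samples(list(md))
  got <- waic(toy)
  d <- fit$data
  ll1 <- sum(sealcarry:::colony_loglik(
    d, draw_to_params(m, 1L),
    beta = m[1L, paste0("beta[", d$female_id, "]")],
    theta = m[1L, paste0("theta[", d$years, "]")]))
  expect_equal(got$p_waic, 0, tolerance = 1e-12)
  expect_equal(got$waic, -2 * ll1, tolerance = 1e-8)
  expect_error({toy$samples <- posterior_samples(list(m[1L, , drop = FALSE]))
                waic(toy)}, "2 posterior draws")
})

test_that("per-occasion pointwise unit enumerates every transition", {
  fit <- local_fit()
  got <- waic(fit, pointwise = "occasion")
  d <- fit$data
  n_units <- sum(pmax(0L, ncol(d$obs) - 1L - d$recruit))
  expect_equal(nrow(got$contributions), n_units)
  expect_true(is.finite(got$waic))
})

test_that("rhat separates mixed from unmixed chains", {
  set.seed(10)
  iid <- lapply(1:3, function(i) rnorm(1000))
  expect_lt(rhat(iid), 1.01)
  expect_gt(rhat(list(rnorm(100, 0, 0.01), rnorm(100, 5, 0.01))), 2)
  one <- rnorm(200)
  expect_lt(abs(rhat(list(one, one)) - 1), 0.05)
  expect_error(rhat(list(one)), "2 chains")
  expect_true(is.nan(rhat(list(rep(1, 50), rep(1, 50)))))
})

test_that("cost contrast: zero case, antisymmetry and the point-mass anchor", {
  set.seed(11)
  base <- cbind(mu = rnorm(200, 1.5, 0.3), lambda3_F = 0,
                lambda3_B = rnorm(200, 0.2, 0.1), lambda3_N = 0)
  equal <- base; equal[, "lambda3_N"] <- equal[, "lambda3_B"]
  cc0 <- cost_contrast(posterior_samples(list(equal)))
  expect_true(all(cc0$draws == 0))
  expect_equal(cc0$mean, 0)

  swapped <- base[, c("mu", "lambda3_F", "lambda3_N", "lambda3_B")]
  colnames(swapped) <- c("mu", "lambda3_F", "lambda3_B", "lambda3_N")
  c1 <- cost_contrast(posterior_samples(list(base)))
  c2 <- cost_contrast(posterior_samples(list(swapped)))
  expect_equal(c1$draws, -c2$draws)

  # point mass at the reported transition means: contrast = 0.861 - 0.878
  pm <- cbind(mu = 1.685698, lambda3_F = -0.4258498, lambda3_B = 0.1379224,
              lambda3_N = 0.2879274)[rep(1, 10), ]
  cc <- cost_contrast(posterior_samples(list(pm)))
  expect_equal(cc$mean, 0.861 - 0.878, tolerance = 1e-3)
  expect_equal(cc$p_negative, 1)
})

test_that("the report writes coherent comparison tables", {
  col <- simulate_colony(small_config(n_females = 35L, seed = 61L))
  colf <- filtered_colony(col)
  mass <- list(null = fit_mass_model(colf$pups, colf$females, "null"),
               linear = fit_mass_model(colf$pups, colf$females, "linear"))
  mc <- mcmc_config(n_chains = 1L, n_iter = 400L, burn_in = 200L, thin = 4L,
                    seed = 13L)
  msms <- list(null = fit_multistate(colf, "null", mc),
               linear = fit_multistate(colf, "linear", mc))
  dir <- withr::local_tempdir()
  rep_tabs <- build_report(msms, mass, out_dir = dir)
  expect_true(file.exists(file.path(dir, "mass_model_comparison.csv")))
  expect_true(file.exists(file.path(dir, "multistate_model_comparison.csv")))
  expect_true(file.exists(file.path(dir, "transition_summary.csv")))
  expect_true(file.exists(file.path(dir, "cost_contrast.csv")))
  tab <- rep_tabs$msms_comparison
  expect_equal(tab$dWAIC, tab$waic - min(tab$waic))
  expect_equal(min(tab$dWAIC), 0)
  mt <- rep_tabs$mass_comparison
  expect_equal(mt$dAIC, mt$AIC - min(mt$AIC))
  expect_true(is.na(mt$lrt_p_vs_null[mt$variant == "null"]))
  expect_false(is.na(mt$lrt_p_vs_null[mt$variant == "linear"]))
  # single-variant input: one-row tables
  one <- build_report(msms["linear"], mass["linear"],
                      out_dir = withr::local_tempdir())
  expect_equal(nrow(one$msms_comparison), 1L)
  expect_equal(nrow(one$mass_comparison), 1L)
})
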