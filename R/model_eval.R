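# Cross-cutting posterior machinery: WAIC, split-chain R-hat, the
# cost-of-reproduction contrast, and the run report.

#' Widely Applicable Information Criterion for a multistate fit
#'
#' Computes WAIC from pointwise log-likelihoods across posterior draws:
#' `lppd = sum_i log mean_s exp(ll_is)`, `p_waic = sum_i var_s(ll_is)`,
#' `waic = -2 (lppd - p_waic)`. The default pointwise unit is one female's
#' whole post-recruitment history, since occasions within a female are
#' dependent through her random effect; `pointwise = "occasion"` uses the
#' forward-algorithm increments `log P(y_t | y_before)` instead, for
#' sensitivity.
#'
#' @param fit an `msms_fit`.
#' @param pointwise `"female"` or `"occasion"`.
#' @return object of class `waic_result` with `lppd`, `p_waic`, `waic` and
#'   the per-unit contributions.
#' @export
waic <- function(fit, pointwise = c("female", "occasion")) {
  pointwise <- match.arg(pointwise)
  if (!inherits(fit, "msms_fit")) stop("waic expects an msms_fit")
  m <- draws_matrix(fit)
  if (nrow(m) < 2L) stop("need at least 2 posterior draws")
  ll <- msms_pointwise_loglik(fit, m, per_occasion = pointwise == "occasion")
  lppd_i <- apply(ll, 2L, log_mean_exp)
  p_i <- apply(ll, 2L, var)
  structure(list(lppd = sum(lppd_i), p_waic = sum(p_i),
                 waic = -2 * (sum(lppd_i) - sum(p_i)),
                 pointwise_unit = pointwise,
                 contributions = data.frame(lppd = lppd_i, p_waic = p_i)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat("WAIC:", format(x$waic, digits = 6),
      "(lppd", format(x$lppd, digits = 6),
      ", p_waic", format(x$p_waic, digits = 4),
      ", unit:", x$pointwise_unit, ")\n")
  invisible(x)
}

# draws matrix -> canonical parameter matrices for the C++ pointwise loglik
msms_pointwise_loglik <- function(fit, m, per_occasion = FALSE) {
  data <- fit$data
  S <- nrow(m)
  gcol <- function(nm) if (nm %in% colnames(m)) m[, nm] else rep(0, S)
  fixed <- cbind(m[, "mu"], gcol("lambda1"), gcol("lambda2"),
                 m[, "lambda3_F"], m[, "lambda3_B"], m[, "lambda3_N"],
                 gcol("lambda5"), gcol("lambda6"), m[, "p"], rep(0, S))
  lcoh <- matrix(0, S, data$n_cohort)
  if (fit$variant == "cohort")
    for (j in seq_len(data$n_cohort - 1L))
      lcoh[, j + 1L] <- m[, paste0("lambda_cohort_", data$cohort_levels[j + 1L])]
  beta <- m[, paste0("beta[", data$female_id, "]"), drop = FALSE]
  theta <- m[, paste0("theta[", data$years, "]"), drop = FALSE]
  msms_loglik_draws_cpp(data, fixed, lcoh, beta, theta, per_occasion)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Brooks-Gelman-Rubin convergence diagnostic: each chain is split in half,
#' and the ratio of pooled to within-sequence variance is returned. Values
#' near 1 indicate convergence; this package flags fits with R-hat > 1.05.
#'
#' @param x an `msms_fit`, a `posterior_samples`, or a list of numeric
#'   vectors (one per chain).
#' @param parameter parameter name (ignored when `x` is a list of vectors).
#' @return R-hat (>= 1 up to numerical tolerance; `NaN` when all draws are
#'   identical).
#' @export
rhat <- function(x, parameter = NULL) {
  if (inherits(x, "msms_fit")) x <- x$samples
  chains <- if (inherits(x, "posterior_samples")) {
    if (is.null(parameter)) stop("give a parameter name")
    lapply(x$chains, function(ch) ch[, parameter])
  } else {
    x
  }
  if (length(chains) < 2L) stop("need at least 2 chains")
  halves <- unlist(lapply(chains, function(v) {
    n <- length(v) %/% 2L
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  n <- min(lengths(halves))
  if (n < 5L) stop("need at least 10 draws per chain")
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) NaN else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior cost-of-reproduction contrast
#'
#' Draw-wise difference \eqn{\psi^{BB} - \psi^{NB}} at stated covariates.
#' A negative contrast means females that bred last year are *less* likely
#' to breed this year than females that skipped: a cost of reproduction
#' expressed in breeding rate.
#'
#' @param object an `msms_fit` or `posterior_samples` (see
#'   [transition_summary()]).
#' @param at covariate point (standardised age and weaning length; default
#'   0, i.e. sample means, random effects 0).
#' @return object of class `contrast_result`: draws, posterior mean, 95%
#'   equal-tailed credible interval, and `P(contrast < 0)`.
#' @export
cost_contrast <- function(object, at = list(std_age = 0, std_lw = 0)) {
  m <- draws_matrix(if (inherits(object, "msms_fit")) object$samples else object)
  if (inherits(object, "msms_fit") && object$variant == "parity")
    at$lambda6_is_parity <- TRUE
  ps <- psi_draws(m, at)
  d <- ps$BB - ps$NB
  structure(list(draws = d, mean = mean(d),
                 cri = unname(quantile(d, c(0.025, 0.975))),
                 p_negative = mean(d < 0)),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("psi^BB - psi^NB: mean", format(x$mean, digits = 4),
      " 95% CRI [", format(x$cri[1], digits = 4), ",",
      format(x$cri[2], digits = 4), "]  P(<0) =",
      format(x$p_negative, digits = 3), "\n")
  invisible(x)
}

#' Build the run report
#'
#' Writes the comparison and coefficient tables (CSV) and summary figures
#' (PDF) for a set of fitted models: the mass-model menu with AIC and LRT
#' against the null, the multistate menu with WAIC and delta WAIC, the
#' transition-probability summary and the cost-of-reproduction contrast of
#' the preferred multistate model, and effect plots for weaning length.
#'
#' @param msms_fits named list of `msms_fit` objects (names = variants).
#' @param mass_fits named list of `mass_fit` objects fitted to the same data.
#' @param out_dir output directory (created if needed).
#' @param waic_pointwise pointwise unit passed to [waic()].
#' @return invisibly, a list with the comparison tables.
#' @export
build_report <- function(msms_fits = list(), mass_fits = list(),
                         out_dir = ".", waic_pointwise = "female") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  if (length(mass_fits)) {
    tab <- do.call(rbind, lapply(names(mass_fits), function(v) {
      f <- mass_fits[[v]]
      p <- if (!identical(v, "null") && "null" %in% names(mass_fits) &&
               v %in% NESTED_IN[["null"]])
        likelihood_ratio_test(mass_fits[["null"]], f)$p else NA_real_
      data.frame(variant = v, n_par = f$n_par, loglik = f$loglik,
                 AIC = f$AIC, lrt_p_vs_null = p)
    }))
    tab$dAIC <- tab$AIC - min(tab$AIC)
    out$mass_comparison <- tab
    write.csv(tab, file.path(out_dir, "mass_model_comparison.csv"),
              row.names = FALSE)
    best <- mass_fits[[which.min(tab$AIC)]]
    coefs <- best$coefficients
    coefs <- rbind(coefs,
                   data.frame(term = c("sd_female", "sd_year", "sd_residual"),
                              estimate = c(best$sigma_alpha, best$sigma_eta,
                                           best$sigma_resid), se = NA))
    out$mass_coefficients <- coefs
    write.csv(coefs, file.path(out_dir, "mass_coefficients.csv"),
              row.names = FALSE)
    if (best$variant != "null") {
      grDevices::pdf(file.path(out_dir, "mass_vs_weaning_length.pdf"),
                     width = 6, height = 4.5)
      plot_mass_effect(best)
      grDevices::dev.off()
    }
  }

  if (length(msms_fits)) {
    ws <- lapply(msms_fits, waic, pointwise = waic_pointwise)
    tab <- do.call(rbind, lapply(names(msms_fits), function(v)
      data.frame(variant = v, waic = ws[[v]]$waic, p_waic = ws[[v]]$p_waic,
                 lppd = ws[[v]]$lppd)))
    tab$dWAIC <- tab$waic - min(tab$waic)
    out$msms_comparison <- tab
    write.csv(tab, file.path(out_dir, "multistate_model_comparison.csv"),
              row.names = FALSE)
    best <- msms_fits[[which.min(tab$waic)]]
    ts <- transition_summary(best)
    out$transition_summary <- ts
    write.csv(ts, file.path(out_dir, "transition_summary.csv"),
              row.names = FALSE)
    cc <- cost_contrast(best)
    out$cost_contrast <- data.frame(mean = cc$mean, cri_lo = cc$cri[1],
                                    cri_hi = cc$cri[2],
                                    p_negative = cc$p_negative)
    write.csv(out$cost_contrast, file.path(out_dir, "cost_contrast.csv"),
              row.names = FALSE)
    if (!is.null(best$rhat)) {
      rh <- data.frame(parameter = names(best$rhat),
                       rhat = unname(best$rhat))
      write.csv(rh, file.path(out_dir, "rhat.csv"), row.names = FALSE)
      out$rhat <- rh
    }
    grDevices::pdf(file.path(out_dir, "breeding_vs_weaning_length.pdf"),
                   width = 6, height = 4.5)
    plot_breeding_effect(best)
    grDevices::dev.off()
    grDevices::pdf(file.path(out_dir, "cost_contrast.pdf"),
                   width = 6, height = 4.5)
    plot_contrast(cc)
    grDevices::dev.off()
  }
  invisible(out)
}

# effect of weaning length on expected pup mass (population level)
plot_mass_effect <- function(fit) {
  lw <- seq(fit$lw_range[1], fit$lw_range[2], length.out = 50)
  z <- std_transform(fit$lw_std, lw)
  fe <- lme4::fixef(fit$fit)
  y <- unname(fe["(Intercept)"]) + unname(fe["z_lw"]) * z
  if (fit$variant == "quadratic") y <- y + unname(fe["z_lw2"]) * z^2
  graphics::plot(lw, y, type = "l", lwd = 2,
                 xlab = "weaning length of mother (cm)",
                 ylab = "expected pup weaning mass (kg)",
                 main = "Provisioning vs maternal weaning length")
}

# posterior mean curve (with CRI band) of breeding probability vs L_w
plot_breeding_effect <- function(fit, n_grid = 40) {
  lw_std <- fit$data$lw_std
  lw <- seq(std_inverse(lw_std, -2.5), std_inverse(lw_std, 2.5),
            length.out = n_grid)
  z <- std_transform(lw_std, lw)
  m <- draws_matrix(fit)
  qs <- sapply(z, function(zz) {
    d <- psi_draws(m, list(std_age = 0, std_lw = zz))$BB
    quantile(d, c(0.025, 0.5, 0.975))
  })
  graphics::plot(lw, qs[2, ], type = "l", lwd = 2, ylim = c(0, 1),
                 xlab = "weaning length (cm)",
                 ylab = expression(psi^{BB}),
                 main = "Breeding probability vs weaning length")
  graphics::lines(lw, qs[1, ], lty = 2)
  graphics::lines(lw, qs[3, ], lty = 2)
}

plot_contrast <- function(cc) {
  dens <- stats::density(cc$draws)
  graphics::plot(dens, main = "Cost of reproduction",
                 xlab = expression(psi^{BB} - psi^{NB}))
  graphics::abline(v = 0, lty = 2)
  graphics::abline(v = cc$mean, col = "grey40")
}
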