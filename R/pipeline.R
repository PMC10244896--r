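# End-to-end orchestration: simulate -> write/read -> filter -> fit both
# model families -> compare -> report, with per-stage derived seeds and a
# manifest tying the artifact tree together.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the colony to simulate (or `NULL`
#'   to analyse an existing colony directory via `colony_dir`).
#' @param mcmc an [mcmc_config()] for the multistate fits.
#' @param mass_variants,msms_variants variants to fit in each family.
#' @param out_dir output directory for the artifact tree.
#' @param colony_dir optional directory with an existing colony (read with
#'   [read_colony()]) instead of simulating.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param waic_pointwise pointwise unit for WAIC.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), mcmc = mcmc_config(),
                       mass_variants = c("null", "linear"),
                       msms_variants = c("null", "linear"),
                       out_dir = "sealcarry-run", colony_dir = NULL,
                       seed = 1L, waic_pointwise = "female") {
  mass_variants <- vapply(mass_variants, check_variant, character(1))
  msms_variants <- vapply(msms_variants, check_variant, character(1))
  structure(list(sim = sim, mcmc = mcmc, mass_variants = mass_variants,
                 msms_variants = msms_variants, out_dir = out_dir,
                 colony_dir = colony_dir, seed = as.integer(seed),
                 waic_pointwise = waic_pointwise),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate a colony (or read one), write its tables, re-read them,
#' drop single-season females, fit the requested mass-model variants (ML)
#' with AIC/LRT comparison, fit the requested multistate variants by MCMC
#' with WAIC comparison, summarise transitions and the cost-of-reproduction
#' contrast, and write the report and a run manifest. Deterministic given
#' the seed.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the colony, fits, report tables and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  t0 <- Sys.time()
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    line <- paste0("[", stamp(), "] ", ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }

  stage <- function(name, idx, expr) {
    logf("stage ", name, " (seed ", derive_seed(config$seed, idx), ")")
    set.seed(derive_seed(config$seed, idx))
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # 1. obtain colony
  colony <- if (is.null(config$colony_dir)) {
    stage("simulate", 1L,
          simulate_colony(config$sim, seed = derive_seed(config$seed, 1L)))
  } else {
    stage("read-colony", 1L, read_colony(config$colony_dir))
  }
  colony_dir <- file.path(out_dir, "colony")
  write_colony(colony, colony_dir)
  colony <- stage("reread", 2L, {
    cc <- read_colony(colony_dir)
    cc$truth <- colony$truth
    cc
  })

  # 2. study filter
  enc_f <- stage("filter", 3L, filter_single_season(colony$encounters,
                                                    quiet = quiet))
  keep <- colony$females$female_id %in% enc_f$female_id
  analysis <- colony
  analysis$encounters <- enc_f
  analysis$females <- colony$females[keep, , drop = FALSE]
  analysis$pups <- colony$pups[colony$pups$female_id %in% enc_f$female_id, ,
                               drop = FALSE]
  logf("analysis sample: ", nrow(analysis$females), " females, ",
       nrow(analysis$pups), " pup records")

  # 3. provisioning models
  mass_fits <- list()
  for (v in config$mass_variants)
    mass_fits[[v]] <- stage(paste0("fit-mass-", v), 10L + match(v, MSMS_VARIANTS),
                            fit_mass_model(analysis$pups, analysis$females,
                                           variant = v))

  # 4. multistate models
  msms_fits <- list()
  for (v in config$msms_variants) {
    mc <- config$mcmc
    mc$seed <- derive_seed(config$seed, 20L + match(v, MSMS_VARIANTS))
    msms_fits[[v]] <- stage(paste0("fit-multistate-", v),
                            20L + match(v, MSMS_VARIANTS),
                            fit_multistate(analysis, variant = v, mcmc = mc))
  }

  # 5. comparison + report
  report <- stage("report", 40L,
                  build_report(msms_fits, mass_fits, out_dir = out_dir,
                               waic_pointwise = config$waic_pointwise))

  files <- c("colony/encounters.csv", "colony/females.csv", "colony/pups.csv",
             "colony/manifest.txt", "pipeline.log",
             list.files(out_dir, pattern = "\\.(csv|pdf)$"))
  manifest <- list(
    package_version = as.character(packageVersion("sealcarry")),
    seed = config$seed,
    n_females_simulated = nrow(colony$females),
    n_females_analysed = nrow(analysis$females),
    n_removed_single_season = attr(enc_f, "n_removed"),
    mass_variants = paste(config$mass_variants, collapse = ","),
    msms_variants = paste(config$msms_variants, collapse = ","),
    mcmc_chains = config$mcmc$n_chains,
    mcmc_iter = config$mcmc$n_iter,
    mcmc_burn_in = config$mcmc$burn_in,
    mcmc_thin = config$mcmc$thin,
    waic_pointwise = config$waic_pointwise,
    files = paste(unique(files), collapse = ";"))
  if (length(mass_fits)) {
    b <- mass_fits[[which.min(vapply(mass_fits, `[[`, numeric(1), "AIC"))]]
    manifest$mass_age_std <- paste(b$age_std$mean, b$age_std$sd, sep = ",")
    manifest$mass_lw_std <- paste(b$lw_std$mean, b$lw_std$sd, sep = ",")
  }
  if (length(msms_fits)) {
    d <- msms_fits[[1]]$data
    manifest$msms_age_std <- paste(d$age_std$mean, d$age_std$sd, sep = ",")
    manifest$msms_lw_std <- paste(d$lw_std$mean, d$lw_std$sd, sep = ",")
  }
  write_manifest(manifest, file.path(out_dir, "run_manifest.txt"))
  logf("done in ", format(round(difftime(Sys.time(), t0, units = "secs"), 1)))

  invisible(list(colony = colony, analysis = analysis, mass_fits = mass_fits,
                 msms_fits = msms_fits, report = report, manifest = manifest))
}
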