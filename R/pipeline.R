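# End-to-end orchestration: simulate (optional) -> derive phenotypes ->
# descriptives -> fit ACE and AE -> compare -> bootstrap, with a manifest
# recording everything needed to reproduce the run.

#' Validate a pipeline run configuration
#'
#' A configuration is a list (or a YAML file holding one) with exactly one
#' input source:
#' \describe{
#'   \item{input}{list with `trials` and `participants` CSV paths, or}
#'   \item{generator}{list with `seed` and optionally `preset = "fear"`
#'     (the default, [fear_generating_model()]) and `trial_level`
#'     (default TRUE: simulate ratings and run the full derivation
#'     pipeline; FALSE simulates the phenotype table directly).}
#' }
#' plus `models` (default `c("ACE", "AE")`), `bootstrap` (list with
#' `n_iter` >= 1, `seed`, `level`), `output_dir` and `verbose`.
#'
#' @param config list or path to a YAML file.
#' @return the normalized configuration list.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generator)
  if (has_input == has_gen) {
    stop("configuration must set exactly one of 'input' and 'generator'")
  }
  if (has_input &&
      (is.null(config$input$trials) || is.null(config$input$participants))) {
    stop("'input' needs 'trials' and 'participants' paths")
  }
  if (has_gen) {
    if (is.null(config$generator$seed)) stop("'generator' needs a 'seed'")
    config$generator$preset <- config$generator$preset %||% "fear"
    config$generator$trial_level <- config$generator$trial_level %||% TRUE
    # optional sample-plan override: either sample_plan() arguments or a
    # fully resolved plan (as echoed into a manifest)
    pl <- config$generator$plan
    if (!is.null(pl)) {
      if (!is.null(pl$n_mz_singletons)) {
        plan <- sample_plan(pl$n_mz_pairs, pl$n_dz_pairs, 0)
        plan$n_mz_singletons <- as.integer(pl$n_mz_singletons)
        plan$n_dz_singletons <- as.integer(pl$n_dz_singletons)
        config$generator$plan <- plan
      } else {
        config$generator$plan <- do.call(sample_plan, pl)
      }
    }
  }
  config$models <- config$models %||% c("ACE", "AE")
  stopifnot(all(config$models %in% c("ACE", "AE")))
  bs <- config$bootstrap %||% list()
  bs$n_iter <- bs$n_iter %||% 100
  bs$level <- bs$level %||% 0.95
  if (bs$n_iter < 1) stop("bootstrap n_iter must be >= 1")
  config$bootstrap <- bs
  if (is.null(config$output_dir)) stop("configuration needs 'output_dir'")
  config$verbose <- isTRUE(config$verbose)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_stage <- function(name, verbose, expr) {
  if (verbose) {
    t0 <- Sys.time()
    message("[twinfear] stage ", name, " ...")
  }
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (verbose) {
    message("[twinfear] stage ", name, " done (",
            round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
            " s)")
  }
  out
}

fit_to_list <- function(fit) {
  list(variant = fit$variant,
       params = list(mu = fit$params$mu, L_A = fit$params$L_A,
                     L_C = fit$params$L_C, L_E = fit$params$L_E),
       minus2LL = fit$minus2LL, n_params = fit$n_params, AIC = fit$AIC,
       converged = fit$converged, iterations = fit$iterations,
       grad_norm = fit$grad_norm,
       data_summary = list(n_families = fit$data_summary$n_families,
                           n_mz = fit$data_summary$n_mz,
                           n_dz = fit$data_summary$n_dz),
       solution = unclass(correlated_factors(fit))[
         c("a2", "c2", "e2", "rA", "rC", "rE", "r_phenotypic",
           "contrib_A", "contrib_C", "contrib_E")])
}

#' Run the full twin-analysis pipeline
#'
#' Executes (optionally) the simulator, the phenotype derivation, twin
#' descriptives, ACE and AE model fits, the nested model comparison and the
#' bootstrap for the selected final model, writing to `output_dir`:
#' `phenotypes.csv`, `descriptives.csv` and `descriptives.txt`,
#' `fit_<variant>.json` per fitted model, `model_comparison.csv`,
#' `solution_ci.json` (bootstrap CIs) and `manifest.json` (config echo,
#' seeds, package version, input checksums). Re-running with an identical
#' configuration reproduces every numeric output byte-for-byte.
#'
#' @param config configuration list or YAML path; see [run_config()].
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$output_dir, f)
  vb <- config$verbose
  checksums <- list()

  if (!is.null(config$generator)) {
    gen <- config$generator
    model <- switch(gen$preset, fear = fear_generating_model(),
                    stop("unknown generator preset: ", gen$preset))
    if (!is.null(gen$plan)) model$plan <- gen$plan
    if (isTRUE(gen$trial_level)) {
      sim <- pipeline_stage("simulate", vb,
                            simulate_trial_level(model, seed = gen$seed))
      phen <- pipeline_stage("phenotypes", vb,
                             derive_phenotypes(sim$trials, sim$roster))
    } else {
      phen <- pipeline_stage("simulate", vb,
                             simulate_twin_phenotypes(model, gen$seed))
    }
  } else {
    dat <- pipeline_stage("load", vb,
                          load_trial_data(config$input$trials,
                                          config$input$participants))
    checksums <- as.list(tools::md5sum(c(config$input$trials,
                                         config$input$participants)))
    phen <- pipeline_stage("phenotypes", vb,
                           derive_phenotypes(dat$trials, dat$roster))
  }
  write_phenotypes(phen, out_path("phenotypes.csv"))

  desc <- pipeline_stage("describe", vb,
                         twin_descriptives(phen,
                                           n_boot = config$bootstrap$n_iter,
                                           seed = config$bootstrap$seed,
                                           level = config$bootstrap$level))
  desc_df <- data.frame(quantity = names(desc$estimates),
                        estimate = unname(desc$estimates),
                        lower = unname(desc$lower),
                        upper = unname(desc$upper))
  write.csv(desc_df, out_path("descriptives.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(desc)), out_path("descriptives.txt"))

  fits <- list()
  for (variant in config$models) {
    fits[[variant]] <- pipeline_stage(paste0("fit_", variant), vb,
                                      fit_ace(phen, variant))
    jsonlite::write_json(fit_to_list(fits[[variant]]),
                         out_path(paste0("fit_", variant, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  comparison <- NULL
  if (all(c("ACE", "AE") %in% names(fits))) {
    comparison <- pipeline_stage("compare", vb,
                                 compare_models(fits$ACE, fits$AE))
    write.csv(data.frame(chi2 = comparison$chi2, df = comparison$df,
                         p = comparison$p,
                         delta_AIC = comparison$delta_AIC),
              out_path("model_comparison.csv"), row.names = FALSE)
  }

  final_variant <- if ("AE" %in% names(fits)) "AE" else config$models[1]
  ci <- pipeline_stage("bootstrap", vb,
                       bootstrap_model_ci(phen, final_variant,
                                          n_iter = config$bootstrap$n_iter,
                                          seed = config$bootstrap$seed,
                                          level = config$bootstrap$level,
                                          fit = fits[[final_variant]]))
  jsonlite::write_json(list(variant = final_variant,
                            estimates = as.list(ci$estimates),
                            lower = as.list(setNames(ci$lower,
                                                     names(ci$estimates))),
                            upper = as.list(setNames(ci$upper,
                                                     names(ci$estimates))),
                            n_boot = ci$n_boot, n_failed = ci$n_failed,
                            seed = ci$seed, level = ci$level),
                       out_path("solution_ci.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  config_echo <- config[setdiff(names(config), "verbose")]
  if (!is.null(config_echo$generator$plan)) {
    config_echo$generator$plan <- unclass(config_echo$generator$plan)
  }
  manifest <- list(
    package = "twinfear",
    version = as.character(utils::packageVersion("twinfear")),
    created = format(Sys.time(), tz = "UTC"),
    config = config_echo,
    input_checksums = checksums,
    outputs = list("phenotypes.csv", "descriptives.csv", "descriptives.txt",
                   paste0("fit_", names(fits), ".json"),
                   if (!is.null(comparison)) "model_comparison.csv",
                   "solution_ci.json"))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(phenotypes = phen, descriptives = desc, fits = fits,
                 comparison = comparison, ci = ci,
                 output_dir = config$output_dir))
}
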