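#' Read and validate a pipeline run configuration
#'
#' The configuration is one YAML document.  Recognised keys (all optional
#' except \code{seed}): \code{seed}, \code{out_dir},
#' \code{attribute_space} (path to a space definition file),
#' \code{design} (\code{n_blocks}, \code{sets_per_block},
#' \code{filter_dominated}), \code{population} (\code{n_scotland},
#' \code{n_sweden}), \code{model} (\code{cluster_se}, \code{restriction}),
#' \code{forecast} (\code{interactions}, \code{alpha}, \code{apply_scale}).
#' Unknown keys are rejected.
#'
#' @param path YAML file path, or \code{NULL} for all defaults.
#' @param seed Overrides the config's seed if given.
#' @param out_dir Overrides the config's output directory if given.
#' @return A validated \code{run_config} list.
#' @export
read_run_config <- function(path = NULL, seed = NULL, out_dir = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop(sprintf("unknown config key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")))
  }
  check_keys(cfg, c("seed", "out_dir", "attribute_space", "design",
                    "population", "model", "forecast"), "top level")
  check_keys(cfg$design %||% list(),
             c("n_blocks", "sets_per_block", "filter_dominated"), "design")
  check_keys(cfg$population %||% list(),
             c("n_scotland", "n_sweden"), "population")
  check_keys(cfg$model %||% list(), c("cluster_se", "restriction"), "model")
  check_keys(cfg$forecast %||% list(),
             c("interactions", "alpha", "apply_scale"), "forecast")
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$seed))
    stop("a seed is mandatory for any stochastic pipeline command")
  cfg$seed <- as.integer(cfg$seed)
  d <- cfg$design %||% list()
  if (!is.null(d$sets_per_block) && d$sets_per_block < 1)
    stop("config error: design.sets_per_block must be >= 1")
  if (!is.null(d$n_blocks) && d$n_blocks < 1)
    stop("config error: design.n_blocks must be >= 1")
  cfg$design <- list(n_blocks = d$n_blocks %||% 40L,
                     sets_per_block = d$sets_per_block %||% 6L,
                     filter_dominated = d$filter_dominated %||% TRUE)
  p <- cfg$population %||% list()
  cfg$population <- list(n_scotland = p$n_scotland %||% 1004L,
                         n_sweden = p$n_sweden %||% 974L)
  m <- cfg$model %||% list()
  cfg$model <- list(cluster_se = m$cluster_se %||% FALSE,
                    restriction = m$restriction %||% "auto")
  f <- cfg$forecast %||% list()
  cfg$forecast <- list(interactions = f$interactions %||% "significant_only",
                       alpha = f$alpha %||% 0.05,
                       apply_scale = f$apply_scale %||% FALSE)
  cfg$out_dir <- cfg$out_dir %||% "."
  class(cfg) <- "run_config"
  cfg
}

config_space <- function(cfg) {
  if (is.null(cfg$attribute_space)) default_attribute_space()
  else read_attribute_space(cfg$attribute_space)
}

pipe_log <- function(fmt, ...) message(sprintf(paste0("[dcelink] ", fmt), ...))

#' Pipeline stage: generate and export a design
#'
#' Generates the blocked design, writes \code{design.csv} and a
#' \code{design_diagnostics.yaml} into the output directory, and logs the
#' profile/pair/set counts.
#'
#' @param config A [read_run_config()] result.
#' @return The design, invisibly.
#' @export
cmd_design <- function(config) {
  space <- config_space(config)
  n_prof <- nrow(enumerate_profiles(space))
  pipe_log("%d profiles, %s possible choice pairs", n_prof,
           format(count_choice_pairs(n_prof), big.mark = ","))
  des <- generate_design(space, config$design$n_blocks,
                         config$design$sets_per_block,
                         config$design$filter_dominated,
                         seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_design_csv(des, file.path(config$out_dir, "design.csv"))
  dg <- design_diagnostics(des, space)
  yaml::write_yaml(list(balance_ratio = as.list(dg$balance_ratio),
                        overlap_counts = as.list(dg$overlap_counts),
                        d_efficiency = dg$d_efficiency),
                   file.path(config$out_dir, "design_diagnostics.yaml"))
  pipe_log("design: %d sets written; D-efficiency %.4f",
           des$n_blocks * des$sets_per_block, dg$d_efficiency)
  invisible(des)
}

#' Pipeline stage: simulate screening and a choice dataset
#'
#' Simulates invited panels, applies route-out screening (summary written
#' to \code{screening_summary.csv}), builds quota completer panels of the
#' configured sizes, simulates their choices over the design and writes
#' \code{choices.csv}.
#'
#' @param config A [read_run_config()] result.
#' @param design Optionally a pre-built design; defaults to regenerating
#'   from the config seed.
#' @return The choice dataset, invisibly.
#' @export
cmd_simulate <- function(config, design = NULL) {
  space <- config_space(config)
  if (is.null(design))
    design <- generate_design(space, config$design$n_blocks,
                              config$design$sets_per_block,
                              config$design$filter_dominated,
                              seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # screening illustration on invited-sized panels
  invited <- simulate_population(
    default_population_spec(1465, 1487), seed = config$seed + 1L)
  scr <- simulate_screening(invited, default_screening_spec(),
                            seed = config$seed + 2L)
  summ <- as.data.frame(table(scr$routed_out$country,
                              scr$routed_out$exit_question),
                        stringsAsFactors = FALSE)
  names(summ) <- c("country", "exit_question", "n_routed_out")
  utils::write.csv(summ, file.path(config$out_dir, "screening_summary.csv"),
                   row.names = FALSE)
  pipe_log("screening: %d of %d invited routed out",
           nrow(scr$routed_out), nrow(invited))

  pop <- simulate_population(
    default_population_spec(config$population$n_scotland,
                            config$population$n_sweden),
    seed = config$seed + 3L)
  prefs <- list(Scotland = default_preferences("Scotland"),
                Sweden = default_preferences("Sweden"))
  dat <- simulate_choices(pop, design, prefs, space,
                          seed = config$seed + 4L)
  write_choice_data(dat, file.path(config$out_dir, "choices.csv"))
  pipe_log("choice dataset: %d rows (%d respondents)", nrow(dat), nrow(pop))
  invisible(dat)
}

#' Pipeline stage: fit the three choice models
#'
#' Fits per-country, pooled-interaction and heteroskedastic conditional
#' logit models and writes a report plus a serialised fit for each.
#'
#' @param config A [read_run_config()] result.
#' @param data_path Path to a choice dataset CSV; defaults to
#'   \code{choices.csv} in the output directory.
#' @return Named list of the three \code{dce_fit} objects, invisibly.
#' @export
cmd_fit <- function(config, data_path = NULL) {
  space <- config_space(config)
  if (is.null(data_path))
    data_path <- file.path(config$out_dir, "choices.csv")
  if (!file.exists(data_path)) stop("choice data file not found: ", data_path)
  dat <- read_choice_data(data_path)
  fits <- list()
  for (cn in unique(dat$country)) {
    fits[[tolower(cn)]] <- fit_clogit(dat, space, country = cn,
                                      cluster_se = config$model$cluster_se)
  }
  fits$pooled <- fit_pooled_interactions(dat, space,
                                         cluster_se = config$model$cluster_se)
  restr <- config$model$restriction
  if (identical(restr, "auto")) {
    restr <- select_restriction_attribute(fits$pooled)
    pipe_log("scale identification: restricting attribute '%s'", restr)
  }
  fits$heteroskedastic <- fit_hetclogit(dat, space,
                                        restricted_attribute = restr,
                                        cluster_se = config$model$cluster_se)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fits)) {
    write_fit_report(fits[[nm]],
                     file.path(config$out_dir, paste0("fit_", nm, ".tsv")))
    write_dce_fit(fits[[nm]],
                  file.path(config$out_dir, paste0("fit_", nm, ".json")))
  }
  pipe_log("fits written: %s", paste(names(fits), collapse = ", "))
  invisible(fits)
}

#' Pipeline stage: forecast scenario acceptance
#'
#' Forecasts the built-in scenarios from a fitted (or bundled reference)
#' model and writes \code{forecasts.csv} plus a what-if grid per country.
#'
#' @param config A [read_run_config()] result.
#' @param fit_path Path to a serialised fit (from [write_dce_fit()]);
#'   \code{NULL} uses the bundled published heteroskedastic estimates.
#' @return The forecast table, invisibly.
#' @export
cmd_forecast <- function(config, fit_path = NULL) {
  fit <- if (is.null(fit_path)) reference_estimates("heteroskedastic")
         else {
           if (!file.exists(fit_path)) stop("fit file not found: ", fit_path)
           read_dce_fit(fit_path)
         }
  rule <- forecast_rule(config$forecast$interactions, config$forecast$alpha,
                        config$forecast$apply_scale)
  fc <- forecast_scenarios(fit, rule)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_forecast_csv(fc, file.path(config$out_dir, "forecasts.csv"))
  space <- signature_to_space(fit$space)
  typ <- builtin_scenarios(space)$typical
  for (cn in unique(fc$country)) {
    grid <- whatif_grid(typ, fit, cn, rule)
    utils::write.csv(grid,
                     file.path(config$out_dir,
                               sprintf("whatif_typical_%s.csv", tolower(cn))),
                     row.names = FALSE)
  }
  pipe_log("forecasts written for %d scenario x country cells", nrow(fc))
  invisible(fc)
}

#' Run the full pipeline: design, simulate, fit, forecast
#'
#' Orchestrates the four stages end to end under one seed.  All outputs are
#' written into the configured output directory.
#'
#' @param config A [read_run_config()] result (or \code{NULL} with
#'   \code{seed} given).
#' @param seed,out_dir Convenience overrides, passed to
#'   [read_run_config()].
#' @return A list with the design, dataset, fits and forecast table.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, out_dir = NULL) {
  if (is.null(config) || is.character(config))
    config <- read_run_config(config, seed = seed, out_dir = out_dir)
  des <- cmd_design(config)
  dat <- cmd_simulate(config, design = des)
  fits <- cmd_fit(config)
  fc <- cmd_forecast(config,
                     file.path(config$out_dir, "fit_heteroskedastic.json"))
  list(design = des, data = dat, fits = fits, forecasts = fc)
}
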