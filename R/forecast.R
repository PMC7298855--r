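#' Define a named scenario
#'
#' A scenario is one full profile: a level label for every attribute.
#'
#' @param name Scenario name.
#' @param levels Named character vector mapping each attribute to one of
#'   its level labels.
#' @param space The [attribute_space()] the labels must resolve in.
#' @return An object of class \code{dce_scenario}.
#' @seealso [builtin_scenarios()]
#' @export
scenario <- function(name, levels, space = default_attribute_space()) {
  an <- names(space$attributes)
  if (is.null(names(levels)) || !setequal(names(levels), an))
    stop("'levels' must name every attribute of the space")
  levels <- levels[an]
  for (a in an) {
    if (!levels[[a]] %in% space$attributes[[a]]$levels)
      stop(sprintf("scenario '%s': level '%s' does not resolve in attribute '%s'",
                   name, levels[[a]], a))
  }
  structure(list(name = name, levels = levels), class = "dce_scenario")
}

#' The three built-in forecasting scenarios
#'
#' \describe{
#'   \item{typical}{university researchers or health-service staff use
#'     linked health records for general public benefit; profit is invested
#'     in public services; the relevant public service oversees the
#'     process.}
#'   \item{best_case}{the most risk-averse scenario: only university
#'     researchers, primary care linked to other health records, direct
#'     benefits for the people whose data are used, nobody profits,
#'     oversight by a non-governmental independent body.}
#'   \item{worst_case}{every attribute at its base ("worst") level.}
#' }
#'
#' @param space The [attribute_space()].
#' @return Named list of [scenario()] objects.
#' @export
builtin_scenarios <- function(space = default_attribute_space()) {
  list(
    typical = scenario("typical", c(
      researchers = "university_health",
      data_type = "primary_care_other_health",
      purpose = "public_benefits",
      profit = "invested_public_services",
      oversight = "relevant_public_service"), space),
    best_case = scenario("best_case", c(
      researchers = "university_only",
      data_type = "primary_care_other_health",
      purpose = "direct_benefits",
      profit = "nobody_profits",
      oversight = "independent_body"), space),
    worst_case = scenario("worst_case", vapply(space$attributes, function(a)
      a$levels[a$base], character(1)), space))
}

#' Forecast rule: how fitted coefficients map to scenario utilities
#'
#' Controls which nationality-interaction terms enter a non-reference
#' country's utility and whether the estimated scale multiplies utilities.
#' The default -- only interactions significant at the 5% level, scale not
#' applied -- is the configuration that reproduces the published headline
#' probabilities from the published pooled heteroskedastic coefficients.
#'
#' @param interactions \code{"significant_only"}, \code{"all"} or
#'   \code{"none"}.
#' @param alpha Significance level for \code{"significant_only"} (Wald z
#'   test), in (0,1).
#' @param apply_scale Multiply non-reference-country utilities by the
#'   fitted scale \eqn{e^{\theta}}?  Default \code{FALSE}.
#' @return An object of class \code{forecast_rule}.
#' @export
forecast_rule <- function(interactions = c("significant_only", "all", "none"),
                          alpha = 0.05, apply_scale = FALSE) {
  interactions <- match.arg(interactions)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0,1)")
  structure(list(interactions = interactions, alpha = alpha,
                 apply_scale = apply_scale), class = "forecast_rule")
}

# coefficient for a term under the rule, including any interaction share
rule_coef <- function(fit, term, country, rule) {
  cf <- coef(fit)
  base <- if (term %in% names(cf)) cf[[term]] else 0
  if (identical(country, fit$nonref_country) && fit$model != "country") {
    iterm <- paste0(tolower(fit$nonref_country), ":", term)
    if (iterm %in% names(cf)) {
      use <- switch(rule$interactions,
        all = TRUE,
        none = FALSE,
        significant_only = {
          z <- cf[[iterm]] / fit$se[[iterm]]
          2 * stats::pnorm(-abs(z)) < rule$alpha
        })
      if (use) base <- base + cf[[iterm]]
    }
  }
  base
}

#' Observable utility of a scenario under a fitted model
#'
#' Sums the fitted part-worths of the scenario's non-base levels (base
#' levels contribute zero).  For the non-reference country, nationality
#' interactions are added according to the [forecast_rule()]; the opt-out
#' constant is never part of a scenario's utility (it belongs to the
#' opt-out alternative).
#'
#' @param scen A [scenario()].
#' @param fit A \code{dce_fit} (estimated or a [reference_estimates()]
#'   fixture).
#' @param country Country to forecast for.
#' @param rule A [forecast_rule()].
#' @return The utility V (numeric scalar).
#' @export
scenario_utility <- function(scen, fit, country,
                             rule = forecast_rule()) {
  stopifnot(inherits(scen, "dce_scenario"), inherits(fit, "dce_fit"))
  space <- signature_to_space(fit$space)
  V <- 0
  for (a in names(space$attributes)) {
    at <- space$attributes[[a]]
    lv <- scen$levels[[a]]
    li <- match(lv, at$levels)
    if (is.na(li))
      stop(sprintf("level '%s' does not resolve in attribute '%s'", lv, a))
    if (li == at$base) next
    V <- V + rule_coef(fit, paste0(a, ":", lv), country, rule)
  }
  if (isTRUE(rule$apply_scale) && identical(country, fit$nonref_country) &&
      "log_scale" %in% names(coef(fit)))
    V <- V * exp(coef(fit)[["log_scale"]])
  V
}

#' Acceptance probability of a scenario against the opt-out
#'
#' The probability that a scenario with observable utility \code{V} is
#' chosen over opting out, whose utility is the constant \code{delta}:
#' \deqn{P = \frac{e^V}{e^V + e^\delta}}
#' computed overflow-safely.
#'
#' @param V Scenario utility.
#' @param delta Opt-out constant.
#' @return Probability in (0,1).
#' @export
#' @examples
#' acceptance_probability(2.411, 0.620)  # ~0.857
acceptance_probability <- function(V, delta) {
  stopifnot(is.finite(V), is.finite(delta))
  stats::plogis(V - delta)
}

optout_delta <- function(fit, country, rule) {
  d <- rule_coef(fit, "optout", country, rule)
  if (isTRUE(rule$apply_scale) && identical(country, fit$nonref_country) &&
      "log_scale" %in% names(coef(fit)))
    d <- d * exp(coef(fit)[["log_scale"]])
  d
}

#' Forecast acceptance probabilities for a set of scenarios
#'
#' @param fit A \code{dce_fit}.
#' @param rule A [forecast_rule()].
#' @param scenarios Named list of [scenario()] objects (default the
#'   built-in trio).
#' @param countries Countries to forecast for; defaults to both study
#'   countries for pooled fits, the fit's own country otherwise.
#' @return A data.frame with columns \code{scenario}, \code{country},
#'   \code{V}, \code{delta}, \code{P}.
#' @export
#' @examples
#' forecast_scenarios(reference_estimates("heteroskedastic"))
forecast_scenarios <- function(fit, rule = forecast_rule(),
                               scenarios = NULL, countries = NULL) {
  stopifnot(inherits(fit, "dce_fit"))
  space <- signature_to_space(fit$space)
  if (is.null(scenarios)) scenarios <- builtin_scenarios(space)
  if (is.null(countries)) {
    countries <- if (fit$model == "country" && !is.null(fit$country))
      fit$country else c("Sweden", "Scotland")
  }
  grid <- expand.grid(scenario = names(scenarios), country = countries,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- scenarios[[grid$scenario[i]]]
    cn <- grid$country[i]
    V <- scenario_utility(sc, fit, cn, rule)
    d <- optout_delta(fit, cn, rule)
    data.frame(scenario = sc$name, country = cn, V = V, delta = d,
               P = acceptance_probability(V, d), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' What-if analysis: change one attribute of a scenario
#'
#' Recomputes a scenario's acceptance probability after substituting one
#' attribute level, and reports the change in percentage points (computed
#' from unrounded probabilities, reported to one decimal).
#'
#' @param base_scenario A [scenario()].
#' @param attribute Attribute to change.
#' @param new_level Replacement level label.
#' @param fit A \code{dce_fit}.
#' @param country Country to forecast for.
#' @param rule A [forecast_rule()].
#' @return A list with \code{P_before}, \code{P_after}, \code{drop_pp}
#'   (percentage-point decrease, one decimal; negative values mean an
#'   increase).
#' @export
delta_analysis <- function(base_scenario, attribute, new_level, fit, country,
                           rule = forecast_rule()) {
  stopifnot(inherits(base_scenario, "dce_scenario"))
  space <- signature_to_space(fit$space)
  if (!attribute %in% names(space$attributes))
    stop(sprintf("unknown attribute '%s'", attribute))
  lv <- base_scenario$levels
  lv[[attribute]] <- new_level
  changed <- scenario(paste0(base_scenario$name, "_modified"), lv, space)
  P0 <- acceptance_probability(
    scenario_utility(base_scenario, fit, country, rule),
    optout_delta(fit, country, rule))
  P1 <- acceptance_probability(
    scenario_utility(changed, fit, country, rule),
    optout_delta(fit, country, rule))
  list(P_before = P0, P_after = P1,
       drop_pp = round((P0 - P1) * 100, 1))
}

#' Split-sample subgroup forecasts
#'
#' Splits the choice data by a demographic key, fits a plain conditional
#' logit per subgroup, and forecasts the scenarios from each subgroup's own
#' coefficients.
#'
#' @param data Long-format choice data.
#' @param space The [attribute_space()].
#' @param grouping Column name in \code{data} to split by.
#' @param scenarios Named list of scenarios (default built-ins).
#' @param rule A [forecast_rule()] (interactions are irrelevant for plain
#'   per-group fits).
#' @param min_sets Minimum choice sets a group must retain (default 30).
#' @return A data.frame: \code{group}, \code{scenario}, \code{V}, \code{P}.
#' @export
subgroup_forecasts <- function(data, space = default_attribute_space(),
                               grouping, scenarios = NULL,
                               rule = forecast_rule("none"), min_sets = 30) {
  if (!grouping %in% names(data))
    stop(sprintf("grouping column '%s' not present in data", grouping))
  if (is.null(scenarios)) scenarios <- builtin_scenarios(space)
  groups <- split(data, data[[grouping]], drop = FALSE)
  res <- lapply(names(groups), function(g) {
    gd <- groups[[g]]
    n_sets <- nrow(gd) / 3
    if (nrow(gd) == 0L || n_sets < min_sets)
      stop(sprintf("subgroup '%s' has too few choice sets (%d < %d)",
                   g, floor(n_sets), min_sets))
    fit <- dce_clogit(gd, space, model = "country")
    do.call(rbind, lapply(scenarios, function(sc) {
      V <- scenario_utility(sc, fit, country = NULL, rule)
      data.frame(group = g, scenario = sc$name, V = V,
                 P = acceptance_probability(V, coef(fit)[["optout"]]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a forecast report and a what-if grid
#'
#' \code{write_forecast_csv} writes the scenario/country table from
#' [forecast_scenarios()].  \code{whatif_grid} computes, for one scenario
#' and country, the acceptance probability after every possible single
#' attribute-level substitution -- the grid behind an interactive what-if
#' explorer.
#'
#' @param forecasts Result of [forecast_scenarios()].
#' @param path Output CSV path.
#' @export
write_forecast_csv <- function(forecasts, path) {
  utils::write.csv(forecasts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_forecast_csv
#' @inheritParams delta_analysis
#' @param base_scenario The scenario whose levels are varied one at a time.
#' @export
whatif_grid <- function(base_scenario, fit, country,
                        rule = forecast_rule()) {
  space <- signature_to_space(fit$space)
  rows <- list()
  for (a in names(space$attributes)) {
    for (lv in space$attributes[[a]]$levels) {
      da <- delta_analysis(base_scenario, a, lv, fit, country, rule)
      rows[[length(rows) + 1L]] <- data.frame(
        attribute = a, level = lv, P = da$P_after,
        change_pp = -da$drop_pp, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
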