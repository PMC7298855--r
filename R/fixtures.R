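#' Published reference coefficient estimates
#'
#' Bundled, read-only coefficient fixtures transcribed from the published
#' results of the original Scotland--Sweden linked-data preference survey:
#' the per-country conditional logit estimates, the pooled model with
#' nationality interactions, and the pooled heteroskedastic model with the
#' country scale term.  They serve two purposes: true values for the choice
#' simulator (parameter-recovery studies) and coefficient inputs for
#' scenario forecasting, independent of any estimation step.  Standard
#' errors are as printed; the covariance is diagonal (the full matrix was
#' not published), which suffices for the Wald z tests the forecast rules
#' use.
#'
#' @param which One of \code{"scotland"}, \code{"sweden"},
#'   \code{"pooled_interactions"}, \code{"heteroskedastic"}.
#' @return A \code{dce_fit} object (with \code{logLik = NA}: these are
#'   transcribed numbers, not an in-session fit).
#' @export
#' @examples
#' coef(reference_estimates("sweden"))[["optout"]]        # 0.620
#' coef(reference_estimates("heteroskedastic"))[["log_scale"]]
reference_estimates <- function(which = c("scotland", "sweden",
                                          "pooled_interactions",
                                          "heteroskedastic")) {
  which <- match.arg(which)
  space <- default_attribute_space()
  nb <- dummy_names(space)

  # part-worths in dummy_names order: researchers (3), data_type (3),
  # purpose (2), profit (3), oversight (government, independent_body,
  # relevant_public_service)
  scot_beta <- c(0.214, 0.500, 0.445, 0.918, 0.664, 0.407, 0.322, 0.548,
                 0.326, 0.579, 0.739, 0.066, 0.346, 0.265)
  swed_beta <- c(0.168, 0.312, 0.337, 0.706, 0.403, 0.171, 0.254, 0.430,
                 0.171, 0.397, 0.506, 0.289, 0.420, 0.457)
  beta_se <- c(rep(0.05, 6), 0.04, 0.04, rep(0.05, 6))
  inter <- c(0.047, 0.188, 0.108, 0.212, 0.261, 0.236, 0.068, 0.118,
             0.156, 0.182, 0.233, -0.223, -0.074, -0.192)
  inter_se <- c(rep(0.07, 6), 0.06, 0.06, rep(0.07, 6))
  het_beta <- c(0.168, 0.312, 0.337, 0.706, 0.403, 0.171, 0.253, 0.430,
                0.171, 0.397, 0.506, 0.289, 0.420, 0.457)
  het_beta_se <- c(rep(0.05, 6), 0.03, 0.04, rep(0.05, 6))
  # purpose interactions restricted to zero for scale identification,
  # hence absent from the heteroskedastic parameter vector
  het_inter <- c(0.001, 0.080, 0.012, 0.014, 0.118, 0.148,
                 0.086, 0.057, 0.074, -0.238, -0.148, -0.249)
  het_inter_se <- c(0.07, 0.08, 0.08, 0.11, 0.09, 0.08,
                    0.07, 0.08, 0.09, 0.07, 0.07, 0.07)

  px <- "scotland:"
  build <- function(est, se, model, country = NULL, n_obs,
                    restricted = NULL) {
    V <- diag(se^2)
    rownames(V) <- colnames(V) <- names(est)
    structure(list(
      coefficients = est, se = stats::setNames(se, names(est)), vcov = V,
      logLik = NA_real_, converged = TRUE, max_grad = NA_real_,
      unstable = character(0),
      model = model, country = country,
      restricted_attribute = restricted,
      nonref_country = "Scotland", cluster_se = FALSE,
      n_obs = n_obs, n_sets = n_obs / 3L, n_dropped = 0L,
      space = space_signature(space),
      call = NULL, reference = TRUE),
      class = "dce_fit")
  }

  switch(which,
    scotland = build(
      stats::setNames(c(scot_beta, 0.886), c(nb, "optout")),
      c(beta_se, 0.08), "country", "Scotland", 18072L),
    sweden = build(
      stats::setNames(c(swed_beta, 0.620), c(nb, "optout")),
      c(beta_se, 0.08), "country", "Sweden", 17532L),
    pooled_interactions = build(
      stats::setNames(c(swed_beta, 0.620, inter, 0.266),
                      c(nb, "optout", paste0(px, nb), paste0(px, "optout"))),
      c(beta_se, 0.08, inter_se, 0.12), "pooled", NULL, 35604L),
    heteroskedastic = {
      keep <- !startsWith(nb, "purpose:")
      build(
        stats::setNames(
          c(het_beta, 0.620, het_inter, 0.076, 0.242),
          c(nb, "optout", paste0(px, nb[keep]), paste0(px, "optout"),
            "log_scale")),
        c(het_beta_se, 0.08, het_inter_se, 0.11, 0.12),
        "heteroskedastic", NULL, 35604L, restricted = "purpose")
    })
}
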