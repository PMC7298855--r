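#' @export
coef.dce_fit <- function(object, ...) object$coefficients

#' @export
vcov.dce_fit <- function(object, ...) object$vcov

#' @export
logLik.dce_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n_sets, class = "logLik")
}

sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.dce_fit <- function(x, ...) {
  tag <- switch(x$model, country = "conditional logit",
                pooled = "pooled conditional logit with nationality interactions",
                heteroskedastic = "heteroskedastic conditional logit")
  cat(sprintf("DCE %s fit%s\n", tag,
              if (!is.null(x$country)) paste0(" (", x$country, ")") else ""))
  cat(sprintf("  %d observations in %d choice sets; log-likelihood %.3f\n",
              x$n_obs, x$n_sets, x$logLik))
  if (!is.null(x$restricted_attribute))
    cat(sprintf("  interactions restricted to zero for attribute '%s'\n",
                x$restricted_attribute))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summarise a fitted DCE choice model
#'
#' @param object A \code{dce_fit}.
#' @param ... Unused.
#' @return A \code{summary.dce_fit}: coefficient table with estimates,
#'   standard errors, Wald z statistics, p-values and significance stars
#'   (* p<0.05, ** p<0.01, *** p<0.001).
#' @export
summary.dce_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(term = names(est), estimate = est, std_error = se,
                    z = z, p_value = p, stars = sig_stars(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, model = object$model, country = object$country,
                 logLik = object$logLik, n_obs = object$n_obs,
                 n_sets = object$n_sets,
                 restricted_attribute = object$restricted_attribute,
                 cluster_se = object$cluster_se),
            class = "summary.dce_fit")
}

#' @export
print.summary.dce_fit <- function(x, ...) {
  cat(sprintf("Model: %s%s   (SEs: %s)\n", x$model,
              if (!is.null(x$country)) paste0(" / ", x$country) else "",
              if (isTRUE(x$cluster_se)) "respondent-clustered" else "classical"))
  tab <- x$table
  tab$estimate <- sprintf("%8.3f", tab$estimate)
  tab$std_error <- sprintf("(%.3f)", tab$std_error)
  tab$p_value <- sprintf("%.4f", tab$p_value)
  print(tab, right = FALSE)
  cat(sprintf("Log-likelihood: %.3f   observations: %d   choice sets: %d\n",
              x$logLik, x$n_obs, x$n_sets))
  cat("Signif.: * p<0.05  ** p<0.01  *** p<0.001\n")
  invisible(x)
}

# linear predictor eta for new data under a fit
fit_eta <- function(object, bundle) {
  model <- object$model
  restricted <- if (is.null(object$restricted_attribute)) character(0)
                else object$restricted_attribute
  lay <- param_layout(bundle, model, restricted)
  par <- object$coefficients[lay$names]
  if (anyNA(par)) stop("fit coefficients do not match this data's layout")
  X <- bundle$X; nat <- bundle$nat
  if (model == "country") return(drop(X %*% par))
  Z <- cbind(X, X[, lay$inter_cols, drop = FALSE] * nat)
  nb <- ncol(Z)
  v <- drop(Z %*% par[seq_len(nb)])
  if (model == "heteroskedastic") exp(par[nb + 1L] * nat) * v else v
}

#' Predict within-set choice probabilities
#'
#' @param object A \code{dce_fit}.
#' @param newdata Long-format choice data; defaults to an error (the fit
#'   does not store its data).
#' @param ... Unused.
#' @return Numeric vector of choice probabilities, one per row of
#'   \code{newdata} (rows reordered group-major as in
#'   [build_design_matrix()]); probabilities sum to 1 within each choice
#'   set.
#' @export
predict.dce_fit <- function(object, newdata, ...) {
  if (missing(newdata)) stop("'newdata' is required: the fit stores no data")
  space <- signature_to_space(object$space)
  bundle <- build_design_matrix(newdata, space, object$nonref_country)
  eta <- fit_eta(object, bundle)
  set_probs(eta, bundle$group, bundle$n_sets)$p
}

#' @export
residuals.dce_fit <- function(object, newdata, ...) {
  if (missing(newdata)) stop("'newdata' is required: the fit stores no data")
  space <- signature_to_space(object$space)
  bundle <- build_design_matrix(newdata, space, object$nonref_country)
  eta <- fit_eta(object, bundle)
  bundle$chosen - set_probs(eta, bundle$group, bundle$n_sets)$p
}

#' Simulate choice outcomes from a fitted model
#'
#' Draws, for each choice set in \code{newdata}, a chosen alternative from
#' the fitted multinomial choice probabilities.
#'
#' @param object A \code{dce_fit}.
#' @param nsim Number of replicate chosen-flag vectors.
#' @param seed Optional integer seed.
#' @param newdata Long-format choice data.
#' @param ... Unused.
#' @return A data.frame with \code{nsim} columns of simulated 0/1 chosen
#'   flags, rows aligned to \code{newdata} sorted group-major.
#' @export
simulate.dce_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (missing(newdata)) stop("'newdata' is required: the fit stores no data")
  if (!is.null(seed)) set.seed(seed)
  space <- signature_to_space(object$space)
  bundle <- build_design_matrix(newdata, space, object$nonref_country)
  eta <- fit_eta(object, bundle)
  p <- set_probs(eta, bundle$group, bundle$n_sets)$p
  out <- replicate(nsim, {
    chosen <- numeric(length(p))
    for (ix in split(seq_along(p), bundle$group)) {
      chosen[sample(ix, 1L, prob = p[ix])] <- 1
    }
    chosen
  })
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
plot.dce_fit <- function(x, ...) {
  est <- x$coefficients
  se <- x$se
  ord <- seq_along(est)
  graphics::dotchart(est[ord], labels = names(est)[ord],
                     xlim = range(c(est - 1.96 * se, est + 1.96 * se)),
                     xlab = "estimate (95% CI)", ...)
  graphics::segments(est - 1.96 * se, ord, est + 1.96 * se, ord)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Write a human-readable fit report
#'
#' Tab-delimited table mirroring the conventional DCE results layout:
#' term, estimate, standard error, significance stars.
#'
#' @param fit A \code{dce_fit} (or a summary of one).
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  s <- if (inherits(fit, "summary.dce_fit")) fit else summary(fit)
  tab <- s$table
  out <- data.frame(term = tab$term,
                    estimate = sprintf("%.3f", tab$estimate),
                    std_error = sprintf("%.3f", tab$std_error),
                    stars = tab$stars, stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("term", "estimate", "std_error", "stars"),
                   collapse = "\t"), con)
  writeLines(do.call(paste, c(out, sep = "\t")), con)
  writeLines(sprintf("# log-likelihood\t%.6f", s$logLik), con)
  writeLines(sprintf("# n_observations\t%d", s$n_obs), con)
  invisible(path)
}

#' Serialise or restore a fitted model as structured text
#'
#' Uses a lossless JSON encoding, so a round trip restores the fit exactly.
#'
#' @param fit A \code{dce_fit}.
#' @param path File path.
#' @return \code{read_dce_fit} returns the restored \code{dce_fit}.
#' @export
write_dce_fit <- function(fit, path) {
  stopifnot(inherits(fit, "dce_fit"))
  fit$call <- NULL  # calls are session-bound, not data
  writeLines(jsonlite::serializeJSON(fit, digits = 17), path)
  invisible(path)
}

#' @rdname write_dce_fit
#' @export
read_dce_fit <- function(path) {
  fit <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                         collapse = "\n"))
  stopifnot(inherits(fit, "dce_fit"))
  fit
}
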