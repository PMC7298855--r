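#' Build the estimation design matrix from long-format choice data
#'
#' Dummy-codes every attribute relative to its base level (14 indicators for
#' the default five-attribute space), adds the opt-out indicator that
#' carries the alternative-specific constant, and records the choice-set
#' grouping.  Opt-out rows have all attribute dummies zero.
#'
#' @param data Long-format choice data (see [simulate_choices()] /
#'   [read_choice_data()]): one row per alternative per choice set.
#' @param space The [attribute_space()] used for coding.
#' @param nonref_country Country coded 1 in the nationality indicator
#'   (default \code{"Scotland"}; the other country is the reference).
#' @return A list of class \code{dce_bundle}: design matrix \code{X}
#'   (attribute dummies plus \code{optout} column), \code{nat} (nationality
#'   indicator per row), \code{chosen}, \code{group} (choice-set id, rows
#'   sorted group-major), \code{resp} (respondent id), \code{country},
#'   \code{attr_of_col} (attribute owning each dummy column),
#'   \code{n_obs}, \code{n_sets}, and \code{n_dropped} (degenerate sets
#'   removed).
#' @export
build_design_matrix <- function(data, space, nonref_country = "Scotland") {
  stopifnot(is.data.frame(data), inherits(space, "attribute_space"))
  an <- names(space$attributes)
  need <- c("respondent_id", "set", "opt_out", "chosen", an)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("choice data is missing columns: ",
                         paste(miss, collapse = ", "))
  for (i in seq_along(an)) {
    bad <- which(data[[an[i]]] < 1 | data[[an[i]]] > space$n_levels[i] |
                   data[[an[i]]] != floor(data[[an[i]]]))
    if (length(bad))
      stop(sprintf("unknown level index for attribute '%s' at data row %d",
                   an[i], bad[1L]))
  }
  key <- interaction(data$respondent_id, data$set, drop = TRUE, lex.order = TRUE)
  ord <- order(key)
  data <- data[ord, , drop = FALSE]
  group <- as.integer(interaction(data$respondent_id, data$set,
                                  drop = TRUE, lex.order = TRUE))

  prof <- as.matrix(data[, an, drop = FALSE])
  X <- profile_dummies(prof, space)
  X[data$opt_out == 1L, ] <- 0
  X <- cbind(X, optout = as.numeric(data$opt_out))
  attr_of_col <- c(rep(an, space$n_levels - 1L), "optout")

  chosen <- as.numeric(data$chosen)
  one <- rowsum(chosen, group)
  if (any(one != 1))
    stop("every choice set must have exactly one chosen alternative")
  sizes <- tabulate(group)
  if (any(sizes < 2L)) stop("every choice set needs at least two alternatives")

  # degenerate sets (identical coding across all alternatives) carry no
  # information; drop them.  Detected via zero within-set sum of squares.
  nat <- as.numeric(data$country == nonref_country)
  gs <- rowsum(X, group)
  gss <- rowsum(X^2, group)
  within_ss <- rowSums(gss - gs^2 / sizes)
  degenerate <- within_ss < 1e-12
  n_dropped <- sum(degenerate)
  if (n_dropped > 0L) {
    keep <- !degenerate[group]
    X <- X[keep, , drop = FALSE]; chosen <- chosen[keep]; nat <- nat[keep]
    data <- data[keep, , drop = FALSE]
    group <- as.integer(factor(group[keep]))
    message(sprintf("dropped %d degenerate choice set(s) with no variation",
                    n_dropped))
  }
  structure(list(
    X = X, nat = nat, chosen = chosen, group = group,
    resp = data$respondent_id, country = data$country,
    attr_of_col = attr_of_col, nonref_country = nonref_country,
    n_obs = nrow(X), n_sets = length(unique(group)), n_dropped = n_dropped),
    class = "dce_bundle")
}

# log-sum-exp and within-set choice probabilities; rows are group-major
set_probs <- function(eta, group, n_sets) {
  sizes <- tabulate(group, nbins = n_sets)
  if (length(unique(sizes)) == 1L) {
    J <- sizes[1L]
    E <- matrix(eta, nrow = J)
    m <- E[1L, ]
    for (j in seq_len(J)[-1L]) m <- pmax(m, E[j, ])
    lse <- m + log(colSums(exp(E - rep(m, each = J))))
  } else {
    m <- vapply(split(eta, group), max, numeric(1))
    lse <- m + log(vapply(split(exp(eta - m[group]), group), sum, numeric(1)))
  }
  list(lse = lse, p = exp(eta - lse[group]))
}

# parameter layout per model tag; restricted = attribute names whose
# interactions are fixed at zero (heteroskedastic identification)
param_layout <- function(bundle, model, restricted = character(0)) {
  main <- colnames(bundle$X)
  px <- tolower(bundle$nonref_country)
  switch(model,
    country = list(names = main, n_main = length(main)),
    pooled = ,
    heteroskedastic = {
      free <- !(bundle$attr_of_col %in% restricted)
      inter <- paste0(px, ":", main[free])
      nm <- c(main, inter)
      if (model == "heteroskedastic") nm <- c(nm, "log_scale")
      list(names = nm, n_main = length(main), inter_cols = which(free))
    })
}

#' Conditional logit log-likelihood and analytic gradient
#'
#' \eqn{LL = \sum_s [\eta_{chosen} - \log \sum_j e^{\eta_j}]} over choice
#' sets, where the linear predictor \eqn{\eta_j} is \eqn{x_j'\beta +
#' optout_j\,\delta}, plus nationality-interaction terms for pooled models,
#' all multiplied by the scale \eqn{\lambda = e^{\theta \cdot nat}} for the
#' heteroskedastic model.
#'
#' @param params Numeric parameter vector in the layout of the model tag.
#' @param bundle A [build_design_matrix()] result.
#' @param model \code{"country"}, \code{"pooled"} or
#'   \code{"heteroskedastic"}.
#' @param restricted For the heteroskedastic model, attribute name(s) whose
#'   interaction terms are restricted to zero.
#' @return The log-likelihood, with the analytic gradient attached as
#'   attribute \code{"gradient"}.
#' @export
clogit_loglik <- function(params, bundle, model = "country",
                          restricted = character(0)) {
  stopifnot(inherits(bundle, "dce_bundle"))
  if (any(!is.finite(params))) stop("non-finite parameter values")
  lay <- param_layout(bundle, model, restricted)
  if (length(params) != length(lay$names))
    stop(sprintf("expected %d parameters for model '%s', got %d",
                 length(lay$names), model, length(params)))
  X <- bundle$X; nat <- bundle$nat
  nm <- lay$n_main
  if (model == "country") {
    Z <- X
    b <- params
    v <- drop(Z %*% b)
    lam <- rep(1, length(v)); theta <- NULL
  } else {
    Z <- cbind(X, X[, lay$inter_cols, drop = FALSE] * nat)
    nb <- nm + length(lay$inter_cols)
    b <- params[seq_len(nb)]
    v <- drop(Z %*% b)
    if (model == "heteroskedastic") {
      theta <- params[nb + 1L]
      lam <- exp(theta * nat)
    } else {
      lam <- rep(1, length(v)); theta <- NULL
    }
  }
  eta <- lam * v
  sp <- set_probs(eta, bundle$group, bundle$n_sets)
  ll <- sum(eta[bundle$chosen == 1]) - sum(sp$lse)
  r <- bundle$chosen - sp$p
  g <- drop(crossprod(Z, r * lam))
  if (!is.null(theta)) g <- c(g, sum(r * lam * nat * v))
  attr(ll, "gradient") <- g
  ll
}

fit_mle <- function(bundle, model, restricted = character(0),
                    cluster = FALSE, control = list()) {
  lay <- param_layout(bundle, model, restricted)
  k <- length(lay$names)
  negll <- function(p) -as.numeric(clogit_loglik(p, bundle, model, restricted))
  neggr <- function(p) -attr(clogit_loglik(p, bundle, model, restricted),
                             "gradient")
  maxit <- control$maxit %||% 500L
  gtol <- control$gtol %||% 1e-6
  opt <- stats::optim(rep(0, k), negll, neggr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  par <- opt$par
  # Newton polish to the gradient tolerance
  H <- NULL
  for (it in seq_len(25L)) {
    g <- neggr(par)
    if (max(abs(g)) < gtol) break
    H <- stats::optimHess(par, negll, neggr)
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-8, k), g))
    cand <- par - step
    if (negll(cand) > negll(par) + 1e-8) {  # halve until improving
      for (h in 1:20) {
        step <- step / 2
        cand <- par - step
        if (negll(cand) <= negll(par)) break
      }
    }
    par <- cand
  }
  g <- neggr(par)
  if (max(abs(g)) > 1e-3)
    stop(sprintf("MLE did not converge: max |gradient| = %.3g after %d BFGS iterations",
                 max(abs(g)), maxit))
  H <- stats::optimHess(par, negll, neggr)
  V <- tryCatch(solve(H), error = function(e) {
    warning("observed information is singular; using pseudo-inverse")
    MASS_ginv(H)
  })
  V <- (V + t(V)) / 2
  if (cluster) {
    # respondent-clustered sandwich
    S <- score_by_cluster(par, bundle, model, restricted)
    V <- V %*% crossprod(S) %*% V
    V <- (V + t(V)) / 2
  }
  se <- sqrt(pmax(diag(V), 0))
  names(par) <- names(se) <- rownames(V) <- colnames(V) <- lay$names
  unstable <- abs(par) > 15 | se > 100
  if (any(unstable))
    warning("possible separation: unstable coefficient(s) ",
            paste(lay$names[unstable], collapse = ", "))
  list(coefficients = par, se = se, vcov = V,
       logLik = -negll(par), converged = max(abs(g)) < gtol,
       max_grad = max(abs(g)), unstable = lay$names[unstable])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal Moore-Penrose fallback (avoids a MASS dependency for a rare path)
MASS_ginv <- function(M) {
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

score_by_cluster <- function(par, bundle, model, restricted) {
  lay <- param_layout(bundle, model, restricted)
  X <- bundle$X; nat <- bundle$nat
  if (model == "country") {
    Z <- X; v <- drop(Z %*% par); lam <- rep(1, length(v)); theta <- NULL
  } else {
    Z <- cbind(X, X[, lay$inter_cols, drop = FALSE] * nat)
    nb <- ncol(Z)
    v <- drop(Z %*% par[seq_len(nb)])
    if (model == "heteroskedastic") {
      theta <- par[nb + 1L]; lam <- exp(theta * nat)
    } else { lam <- rep(1, length(v)); theta <- NULL }
  }
  eta <- lam * v
  sp <- set_probs(eta, bundle$group, bundle$n_sets)
  r <- bundle$chosen - sp$p
  Srow <- Z * (r * lam)
  if (!is.null(theta)) Srow <- cbind(Srow, r * lam * nat * v)
  rowsum(Srow, bundle$resp)
}

#' Fit a conditional logit model to DCE choice data
#'
#' The package's central fitting function.  Estimates, by maximum
#' likelihood, one of three random-utility models for choices among two
#' scenario alternatives and an opt-out:
#' \describe{
#'   \item{\code{"country"}}{plain conditional logit on one country's data
#'     (or all data pooled without interactions): part-worths \eqn{\beta}
#'     per non-base attribute level plus the opt-out constant \eqn{\delta}.}
#'   \item{\code{"pooled"}}{both countries with nationality interaction
#'     terms \eqn{\gamma} on every level and on the constant
#'     (indicator 1 = non-reference country).}
#'   \item{\code{"heteroskedastic"}}{the pooled model with a scale
#'     parameter \eqn{\lambda = e^{\theta}} multiplying the systematic
#'     utility of non-reference-country respondents.  Identification
#'     requires restricting one attribute's interactions to zero
#'     (\code{restriction}, default \code{"auto"} selects the attribute
#'     with the jointly least significant interactions in a pooled fit).}
#' }
#' Optimisation starts from zero, uses BFGS with the analytic gradient and
#' Newton polishing to gradient max-norm below \code{1e-6}; standard errors
#' come from the inverse observed information (optionally a
#' respondent-clustered sandwich).
#'
#' @param data Long-format choice data (see [simulate_choices()]).
#' @param space The [attribute_space()]; default the built-in linked-data
#'   space.
#' @param model \code{"country"}, \code{"pooled"} or
#'   \code{"heteroskedastic"}.
#' @param country For \code{model = "country"}: restrict to this country's
#'   respondents (\code{NULL} fits all rows).
#' @param restriction Heteroskedastic only: attribute name whose
#'   interactions are fixed at zero, or \code{"auto"}.
#' @param cluster_se Use respondent-clustered sandwich standard errors?
#'   Default classical inverse-information.
#' @param nonref_country Country coded 1 in interactions and scale.
#' @param control Optional list: \code{maxit}, \code{gtol}.
#' @return An object of class \code{dce_fit} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{vcov}, \code{logLik},
#'   \code{predict}, \code{fitted}, \code{residuals}, \code{simulate} and
#'   \code{plot}.
#' @export
#' @examples
#' \donttest{
#' sp <- default_attribute_space()
#' des <- generate_design(sp, n_blocks = 5, sets_per_block = 6, seed = 1)
#' pop <- simulate_population(default_population_spec(150, 150), seed = 1)
#' dat <- simulate_choices(pop, des,
#'   list(Scotland = default_preferences("Scotland"),
#'        Sweden = default_preferences("Sweden")), sp, seed = 2)
#' fit <- dce_clogit(dat, sp, model = "country", country = "Sweden")
#' coef(fit)["optout"]
#' }
dce_clogit <- function(data, space = default_attribute_space(),
                       model = c("country", "pooled", "heteroskedastic"),
                       country = NULL, restriction = "auto",
                       cluster_se = FALSE, nonref_country = "Scotland",
                       control = list()) {
  model <- match.arg(model)
  if (!is.null(country)) {
    if (model != "country")
      stop("'country' subsetting applies only to model = \"country\"")
    data <- data[data$country == country, , drop = FALSE]
    if (nrow(data) == 0L) stop(sprintf("no data for country '%s'", country))
  }
  bundle <- build_design_matrix(data, space, nonref_country)
  restricted <- character(0)
  if (model %in% c("pooled", "heteroskedastic")) {
    if (length(unique(bundle$country)) < 2L)
      stop("pooled models require data from both countries")
  }
  if (model == "heteroskedastic") {
    if (identical(restriction, "auto")) {
      pooled <- dce_clogit(data, space, model = "pooled",
                           cluster_se = FALSE,
                           nonref_country = nonref_country, control = control)
      restriction <- select_restriction_attribute(pooled)
    }
    if (!restriction %in% names(space$attributes))
      stop(sprintf("unknown restriction attribute '%s'", restriction))
    restricted <- restriction
  }
  res <- fit_mle(bundle, model, restricted, cluster = cluster_se,
                 control = control)
  structure(c(res, list(
    model = model, country = country,
    restricted_attribute = if (model == "heteroskedastic") restriction else NULL,
    nonref_country = nonref_country,
    cluster_se = cluster_se,
    n_obs = bundle$n_obs, n_sets = bundle$n_sets,
    n_dropped = bundle$n_dropped,
    space = space_signature(space),
    call = match.call())),
    class = "dce_fit")
}

# compact, serialisable description of the space a fit was coded against
space_signature <- function(space) {
  list(attributes = lapply(space$attributes, function(a)
    list(name = a$name, levels = a$levels, base = a$base)))
}

signature_to_space <- function(sig) {
  attribute_space(lapply(sig$attributes, function(a)
    list(levels = a$levels, base = a$base)))
}

#' Per-country conditional logit fit
#'
#' Thin wrapper over [dce_clogit()] with \code{model = "country"}.
#' @inheritParams dce_clogit
#' @param country Country label to fit.
#' @return A \code{dce_fit}.
#' @export
fit_clogit <- function(data, space = default_attribute_space(), country = NULL,
                       ...) {
  dce_clogit(data, space, model = "country", country = country, ...)
}

#' Pooled conditional logit with nationality interactions
#'
#' Thin wrapper over [dce_clogit()] with \code{model = "pooled"}.
#' @inheritParams dce_clogit
#' @return A \code{dce_fit}.
#' @export
fit_pooled_interactions <- function(data, space = default_attribute_space(),
                                    ...) {
  dce_clogit(data, space, model = "pooled", ...)
}

#' Pooled heteroskedastic conditional logit with a country scale term
#'
#' Thin wrapper over [dce_clogit()] with \code{model = "heteroskedastic"}.
#' @inheritParams dce_clogit
#' @param restricted_attribute Attribute whose interactions are fixed at
#'   zero to identify the scale term, or \code{"auto"}.
#' @return A \code{dce_fit} including the \code{log_scale} parameter
#'   \eqn{\theta}.
#' @export
fit_hetclogit <- function(data, space = default_attribute_space(),
                          restricted_attribute = "auto", ...) {
  dce_clogit(data, space, model = "heteroskedastic",
             restriction = restricted_attribute, ...)
}

#' Select the attribute to restrict for scale identification
#'
#' Returns the attribute whose nationality-interaction terms are jointly
#' least significant in a pooled fit, measured by the Wald statistic
#' \eqn{\gamma' V_\gamma^{-1} \gamma} per degree of freedom.  Ties break by
#' smaller Wald value then attribute order.
#'
#' @param pooled_fit A \code{dce_fit} with \code{model = "pooled"}.
#' @return The attribute name.
#' @export
select_restriction_attribute <- function(pooled_fit) {
  stopifnot(inherits(pooled_fit, "dce_fit"))
  if (pooled_fit$model != "pooled")
    stop("restriction selection needs a pooled fit with interaction terms")
  px <- paste0(tolower(pooled_fit$nonref_country), ":")
  cf <- pooled_fit$coefficients
  V <- pooled_fit$vcov
  attrs <- vapply(pooled_fit$space$attributes, `[[`, character(1), "name")
  wald_per_df <- vapply(attrs, function(a) {
    sig <- pooled_fit$space$attributes[[a]]
    nb <- sig$levels[setdiff(seq_along(sig$levels), sig$base)]
    terms <- paste0(px, a, ":", nb)
    if (!all(terms %in% names(cf))) return(NA_real_)
    g <- cf[terms]
    Vg <- V[terms, terms, drop = FALSE]
    w <- tryCatch(drop(t(g) %*% solve(Vg, g)), error = function(e) NA_real_)
    w / length(terms)
  }, numeric(1))
  if (all(is.na(wald_per_df)))
    stop("no attribute has estimable interaction terms")
  attrs[which.min(wald_per_df)]
}
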