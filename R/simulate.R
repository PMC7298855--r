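#' Population specification with demographic quotas
#'
#' Describes, per country, the panel size and quota targets for gender,
#' age band (18-34, 35-54, 55+) and working status.  Quota proportions for
#' each dimension must sum to 1.
#'
#' @param countries Named list: one element per country, each a list with
#'   \code{n} (respondent count) and named proportion vectors \code{gender},
#'   \code{age_band}, \code{working}.
#' @return An object of class \code{population_spec}.
#' @seealso [default_population_spec()], [simulate_population()]
#' @export
population_spec <- function(countries) {
  stopifnot(is.list(countries), length(countries) >= 1L)
  for (cn in names(countries)) {
    co <- countries[[cn]]
    if (is.null(co$n) || co$n < 1) stop(sprintf("country '%s': invalid n", cn))
    for (dim in c("gender", "age_band", "working")) {
      p <- co[[dim]]
      if (is.null(p) || is.null(names(p)) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-9)
        stop(sprintf("country '%s': quota '%s' must be named proportions summing to 1",
                     cn, dim))
    }
  }
  structure(list(countries = countries), class = "population_spec")
}

#' Default two-country quota specification
#'
#' Quota targets matching the realised demographic composition of the
#' two completer samples: Scotland n = 1004, Sweden n = 974.  Working-status
#' proportions are renormalised over the two observed categories (a handful
#' of respondents did not report employment).
#'
#' @param n_scotland,n_sweden Panel sizes (defaults 1004 and 974).
#' @return A [population_spec()].
#' @export
default_population_spec <- function(n_scotland = 1004, n_sweden = 974) {
  population_spec(list(
    Scotland = list(
      n = n_scotland,
      gender = c(male = 421 / 1004, female = 583 / 1004),
      age_band = c("18-34" = 275 / 1004, "35-54" = 358 / 1004,
                   "55+" = 371 / 1004),
      working = c(working = 557 / 1001, not_working = 444 / 1001)),
    Sweden = list(
      n = n_sweden,
      gender = c(male = 499 / 974, female = 475 / 974),
      age_band = c("18-34" = 354 / 974, "35-54" = 411 / 974,
                   "55+" = 209 / 974),
      working = c(working = 627 / 968, not_working = 341 / 968))
  ))
}

# largest-remainder apportionment of n into round(n*p) counts summing to n
quota_counts <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Simulate a respondent panel under demographic quotas
#'
#' Quotas are filled deterministically (largest-remainder apportionment of
#' \code{n * p} to whole respondents) and assignments shuffled under the
#' seed, so realised proportions match the targets to rounding.  Quota
#' dimensions are assigned independently of one another.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A data.frame with columns \code{respondent_id}, \code{country},
#'   \code{gender}, \code{age_band}, \code{working}.
#' @export
#' @examples
#' pop <- simulate_population(default_population_spec(), seed = 1)
#' prop.table(table(pop$gender[pop$country == "Scotland"]))
simulate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(spec$countries), function(cn) {
    co <- spec$countries[[cn]]
    n <- as.integer(co$n)
    cols <- lapply(c("gender", "age_band", "working"), function(dim) {
      p <- co[[dim]]
      sample(rep(names(p), quota_counts(n, p)))
    })
    data.frame(country = cn, gender = cols[[1]], age_band = cols[[2]],
               working = cols[[3]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- cbind(respondent_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Screening specification for sequential route-out questions
#'
#' Respondents answer the screening questions in order; the first question
#' at which they answer that data linkage should never be permitted routes
#' them out of the survey, recording that question as their exit point.
#'
#' @param questions Character vector of question labels, in asked order.
#' @param probabilities Either a numeric vector (one route-out probability
#'   per question, used for every country) or a named list of such vectors
#'   keyed by country.
#' @return An object of class \code{screening_spec}.
#' @export
screening_spec <- function(questions, probabilities) {
  stopifnot(is.character(questions), length(questions) >= 1L)
  check_p <- function(p) {
    if (length(p) != length(questions) || any(p < 0) || any(p > 1))
      stop("each probability vector needs one value in [0,1] per question")
    p
  }
  if (is.list(probabilities)) {
    probabilities <- lapply(probabilities, check_p)
  } else {
    probabilities <- check_p(probabilities)
  }
  structure(list(questions = questions, probabilities = probabilities),
            class = "screening_spec")
}

#' Default screening specification calibrated to the observed route-out flow
#'
#' Six questions, one per survey topic, in the order asked.  Per-question
#' route-out hazards are calibrated so that the expected exits at each
#' question match the observed counts given the invited totals
#' (1465 Scotland, 1487 Sweden): hazard = exits / respondents still at risk.
#' Expected completers are then 1004 and 974.
#'
#' @return A [screening_spec()] with country-specific hazards.
#' @export
default_screening_spec <- function() {
  questions <- c("purposes_of_research", "who_are_the_researchers",
                 "types_of_information_linked", "management_of_profits",
                 "oversight_monitoring", "public_involvement")
  exits <- list(Scotland = c(67, 104, 135, 145, 8, 2),
                Sweden = c(51, 186, 128, 140, 5, 3))
  invited <- c(Scotland = 1465, Sweden = 1487)
  hazards <- lapply(names(exits), function(cn) {
    e <- exits[[cn]]
    at_risk <- invited[[cn]] - cumsum(c(0, e[-length(e)]))
    e / at_risk
  })
  names(hazards) <- names(exits)
  screening_spec(questions, hazards)
}

#' Simulate sequential route-out screening
#'
#' @param respondents Data.frame with a \code{country} column (e.g. from
#'   [simulate_population()]).
#' @param spec A [screening_spec()].
#' @param seed Integer seed.
#' @return A list with \code{completers} (rows passing every question) and
#'   \code{routed_out} (rows with an added \code{exit_question} column).
#' @export
simulate_screening <- function(respondents, spec, seed = NULL) {
  stopifnot(inherits(spec, "screening_spec"), is.data.frame(respondents))
  if (!is.null(seed)) set.seed(seed)
  nq <- length(spec$questions)
  n <- nrow(respondents)
  probs_for <- function(cn) {
    if (is.list(spec$probabilities)) {
      p <- spec$probabilities[[cn]]
      if (is.null(p)) stop(sprintf("no screening probabilities for country '%s'", cn))
      p
    } else spec$probabilities
  }
  pmat <- t(vapply(respondents$country, probs_for, numeric(nq)))
  u <- matrix(stats::runif(n * nq), n, nq)
  hit <- u < pmat
  exit_q <- apply(hit, 1L, function(h) {
    w <- which(h)
    if (length(w)) w[1L] else NA_integer_
  })
  routed <- !is.na(exit_q)
  routed_out <- respondents[routed, , drop = FALSE]
  if (any(routed)) routed_out$exit_question <- spec$questions[exit_q[routed]]
  else routed_out$exit_question <- character(0)
  list(completers = respondents[!routed, , drop = FALSE],
       routed_out = routed_out)
}

#' Preference profile: the true coefficients of a choice simulator
#'
#' Holds the part-worth utilities of the random-utility model used to
#' generate choices: \code{beta} (one coefficient per non-base attribute
#' level, in attribute-then-level listing order), \code{delta} (the
#' alternative-specific constant on the opt-out) and \code{theta} (log-scale
#' offset applied to respondents of the non-reference country; scale
#' \eqn{\lambda = e^{\theta \cdot scot}}, with the reference country at
#' \eqn{\lambda = 1}).
#'
#' @param beta Named numeric vector of part-worths (names
#'   \code{"attribute:level"} matching the space's non-base levels).
#' @param delta Opt-out constant.
#' @param theta Log-scale offset for the non-reference country (default 0).
#' @param space The [attribute_space()] the profile is dimensioned to.
#' @return An object of class \code{preference_profile}.
#' @seealso [default_preferences()]
#' @export
preference_profile <- function(beta, delta, theta = 0,
                               space = default_attribute_space()) {
  expected <- dummy_names(space)
  if (length(beta) != length(expected))
    stop(sprintf("beta must have %d entries (one per non-base level)",
                 length(expected)))
  if (is.null(names(beta))) names(beta) <- expected
  if (!identical(names(beta), expected))
    beta <- beta[expected]
  if (anyNA(beta)) stop("beta names do not match the space's non-base levels")
  structure(list(beta = beta, delta = as.numeric(delta),
                 theta = as.numeric(theta)),
            class = "preference_profile")
}

dummy_names <- function(space) {
  unlist(lapply(space$attributes, function(a) {
    paste0(a$name, ":", a$levels[setdiff(seq_along(a$levels), a$base)])
  }), use.names = FALSE)
}

#' True preference coefficients for a country's choice simulator
#'
#' Returns the bundled published per-country conditional-logit estimates
#' (see [reference_estimates()]) as the simulator's true part-worths.
#'
#' @param country \code{"Scotland"} or \code{"Sweden"}.
#' @return A [preference_profile()].
#' @export
#' @examples
#' default_preferences("Sweden")$delta  # 0.620
default_preferences <- function(country) {
  fit <- switch(country,
                Scotland = reference_estimates("scotland"),
                Sweden = reference_estimates("sweden"),
                stop(sprintf("unknown country '%s'", country)))
  cf <- coef(fit)
  preference_profile(beta = cf[setdiff(names(cf), "optout")],
                     delta = cf[["optout"]])
}

#' Simulate choices from a random-utility model with opt-out
#'
#' Each respondent is assigned one block of the design (round-robin) and
#' answers its choice sets.  For each set, utilities are
#' \eqn{U_j = \lambda_i V_j + \epsilon_j} with iid standard Gumbel errors,
#' where \eqn{V} of a scenario alternative is the sum of \code{beta} over
#' its non-base levels, \eqn{V} of the opt-out is \code{delta}, and
#' \eqn{\lambda_i = e^{\theta}} for non-reference-country respondents
#' (1 otherwise).  The maximum-utility alternative is chosen.
#'
#' @param completers Respondent data.frame (needs \code{respondent_id} and
#'   \code{country}; demographics are carried through if present).
#' @param design A [generate_design()] result.
#' @param prefs A [preference_profile()], or a named list of them keyed by
#'   country.
#' @param space The [attribute_space()].
#' @param seed Integer seed.
#' @param nonref_country Country whose respondents get the \code{theta}
#'   scale offset (default \code{"Scotland"}).
#' @return A long-format choice data.frame: 3 rows (A, B, optout) per
#'   respondent and choice set, with attribute level indices (base levels on
#'   opt-out rows), \code{opt_out} and \code{chosen} flags.
#' @export
simulate_choices <- function(completers, design, prefs, space, seed = NULL,
                             nonref_country = "Scotland") {
  stopifnot(is.data.frame(completers), inherits(design, "dce_design"),
            inherits(space, "attribute_space"))
  if (!is.null(seed)) set.seed(seed)
  if (inherits(prefs, "preference_profile")) prefs <- list(.all = prefs)
  n_resp <- nrow(completers)
  n_blk <- design$n_blocks
  spb <- design$sets_per_block
  an <- names(space$attributes)
  blocks <- ((seq_len(n_resp) - 1L) %% n_blk) + 1L

  # design rows must be ordered block-major for positional set lookup
  ord <- order(design$block, design$set)
  alt_a <- design$alt_a[ord, , drop = FALSE]
  alt_b <- design$alt_b[ord, , drop = FALSE]
  set_lab <- design$set[ord]
  Xa <- profile_dummies(alt_a, space)
  Xb <- profile_dummies(alt_b, space)

  # per-country systematic utilities of every design set
  ctry <- completers$country
  prof_of <- function(cn) {
    pp <- if (!is.null(prefs$.all)) prefs$.all else prefs[[cn]]
    if (is.null(pp)) stop(sprintf("no preference profile for country '%s'", cn))
    if (length(pp$beta) != ncol(Xa))
      stop("preference profile not dimensioned to the attribute space")
    pp
  }
  u_ctry <- unique(ctry)
  Va_c <- matrix(vapply(u_ctry, function(cn) drop(Xa %*% prof_of(cn)$beta),
                        numeric(nrow(Xa))), nrow = nrow(Xa))
  Vb_c <- matrix(vapply(u_ctry, function(cn) drop(Xb %*% prof_of(cn)$beta),
                        numeric(nrow(Xb))), nrow = nrow(Xb))
  delta_c <- vapply(u_ctry, function(cn) prof_of(cn)$delta, numeric(1))
  lam_c <- vapply(u_ctry, function(cn) {
    if (identical(cn, nonref_country)) exp(prof_of(cn)$theta) else 1
  }, numeric(1))

  n_rs <- n_resp * spb                        # respondent-set tasks
  ridx <- rep(seq_len(n_resp), each = spb)    # respondent of each task
  gset <- (blocks[ridx] - 1L) * spb + rep(seq_len(spb), n_resp)  # design row
  ci <- match(ctry, u_ctry)[ridx]
  Va <- Va_c[cbind(gset, ci)]
  Vb <- Vb_c[cbind(gset, ci)]
  Vo <- delta_c[ci]
  lam <- lam_c[ci]
  eps <- matrix(-log(-log(stats::runif(3L * n_rs))), n_rs, 3L)
  U <- cbind(lam * Va, lam * Vb, lam * Vo) + eps
  pick <- max.col(U)                          # 1 = A, 2 = B, 3 = opt-out

  base_profile <- vapply(space$attributes, `[[`, integer(1), "base")
  attr_mat <- rbind(alt_a[gset, , drop = FALSE],
                    alt_b[gset, , drop = FALSE],
                    matrix(base_profile, n_rs, length(an), byrow = TRUE))
  out <- data.frame(
    respondent_id = completers$respondent_id[rep(ridx, 3L)],
    country = ctry[rep(ridx, 3L)],
    block = blocks[rep(ridx, 3L)],
    set = rep(set_lab[gset], 3L),
    alt = rep(c("A", "B", "optout"), each = n_rs),
    attr_mat,
    opt_out = rep(c(0L, 0L, 1L), each = n_rs),
    chosen = as.integer(rep(pick, 3L) == rep(1:3, each = n_rs)),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[6:(5 + length(an))] <- an
  demo_cols <- intersect(c("gender", "age_band", "working"), names(completers))
  for (dc in demo_cols) out[[dc]] <- completers[[dc]][rep(ridx, 3L)]
  out <- out[order(out$respondent_id, out$set, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Write or read a long-format choice dataset CSV
#'
#' Comma-separated with header, UTF-8: \code{respondent_id}, \code{country},
#' demographics, \code{block}, \code{set}, \code{alt}, one column per
#' attribute (1-based level index; base level on opt-out rows),
#' \code{opt_out}, \code{chosen}.
#'
#' @param data Choice dataset from [simulate_choices()].
#' @param path File path.
#' @export
write_choice_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choice_data
#' @export
read_choice_data <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
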