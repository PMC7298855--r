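test_that("design-matrix construction follows the dummy-coding rules", {
  sp <- default_space()
  dat <- small_dataset()
  b <- build_design_matrix(dat, sp)
  expect_equal(ncol(b$X), 15L)  # 14 level dummies + opt-out indicator
  expect_equal(b$n_obs, nrow(dat))
  expect_equal(b$n_sets, nrow(dat) / 3L)
  # opt-out rows: all dummies zero, indicator one
  oo <- b$X[, "optout"] == 1
  expect_true(all(b$X[oo, 1:14] == 0))
  # scenario rows: at most one indicator per attribute block
  for (a in names(sp$attributes)) {
    cols <- which(b$attr_of_col == a)
    expect_true(all(rowSums(b$X[, cols, drop = FALSE]) <= 1))
  }
  # a profile at all base levels codes like the opt-out minus its indicator
  base_row <- one_set_data(a = c(4L, 4L, 3L, 4L, 4L), b = c(1L, 1L, 1L, 1L, 1L))
  bb <- build_design_matrix(base_row, sp)
  all_base <- which(bb$X[, "optout"] == 0 & rowSums(bb$X[, 1:14]) == 0)
  expect_length(all_base, 1L)
  # bad level index errors with the offending row
  bad <- dat; bad$purpose[5] <- 9L
  expect_error(build_design_matrix(bad, sp), "purpose")
})

test_that("log-likelihood at zero parameters is -n_sets * log(3)", {
  sp <- default_space()
  dat <- small_dataset()
  b <- build_design_matrix(dat, sp)
  ll <- clogit_loglik(rep(0, 15), b, "country")
  expect_equal(as.numeric(ll), -b$n_sets * log(3), tolerance = 1e-12)
})

test_that("the likelihood is invariant to a constant added to every alternative", {
  sp <- default_space()
  dat <- small_dataset()[1:180, ]
  b <- build_design_matrix(dat, sp)
  set.seed(1)
  par <- rnorm(15, sd = 0.4)
  ll1 <- as.numeric(clogit_loglik(par, b, "country"))
  # appending an all-ones column with coefficient c shifts every eta by c
  b2 <- b
  b2$X <- cbind(b$X, shift = 1)
  b2$attr_of_col <- c(b$attr_of_col, "shift")
  ll2 <- as.numeric(clogit_loglik(c(par, 2.7), b2, "country"))
  expect_equal(ll2, ll1, tolerance = 1e-10)
})

test_that("single-set likelihood equals the hand computation", {
  sp <- default_space()
  dat <- one_set_data(a = c(1L, 1L, 2L, 2L, 2L), b = c(2L, 3L, 1L, 3L, 1L),
                      chosen_alt = "B")
  b <- build_design_matrix(dat, sp)
  set.seed(2)
  par <- rnorm(15, sd = 0.5)
  eta <- drop(b$X %*% par)
  by_hand <- eta[b$chosen == 1] - log(sum(exp(eta)))
  expect_equal(as.numeric(clogit_loglik(par, b, "country")), by_hand,
               tolerance = 1e-12)
  expect_error(clogit_loglik(c(par[-1], NaN), b, "country"), "non-finite")
})

test_that("analytic gradients match central finite differences", {
  sp <- default_space()
  dat <- small_dataset()[1:540, ]
  b <- build_design_matrix(dat, sp)
  fd_grad <- function(f, par, h = 1e-5) {
    vapply(seq_along(par), function(i) {
      e <- numeric(length(par)); e[i] <- h
      (f(par + e) - f(par - e)) / (2 * h)
    }, numeric(1))
  }
  set.seed(3)
  for (model in c("country", "pooled", "heteroskedastic")) {
    restricted <- if (model == "heteroskedastic") "purpose" else character(0)
    k <- length(dcelink:::param_layout(b, model, restricted)$names)
    for (rep in 1:3) {
      par <- rnorm(k, sd = 0.3)
      ll <- clogit_loglik(par, b, model, restricted)
      g <- attr(ll, "gradient")
      g_fd <- fd_grad(function(p)
        as.numeric(clogit_loglik(p, b, model, restricted)), par)
      expect_equal(unname(g), g_fd, tolerance = 1e-6)
    }
  }
})

test_that("the MLE agrees with an independent conditional-logit fit", {
  skip_if_not_installed("survival")
  library(survival)  # clogit internally dispatches to an attached coxph
  sp <- default_space()
  dat <- small_dataset()
  fit <- fit_clogit(dat, sp, country = "Sweden")
  b <- build_design_matrix(dat[dat$country == "Sweden", ], sp)
  df <- as.data.frame(b$X)
  names(df) <- paste0("x", seq_len(ncol(b$X)))
  df$chosen <- b$chosen
  df$grp <- b$group
  fml <- stats::as.formula(paste("chosen ~",
    paste(names(df)[1:15], collapse = "+"), "+ survival::strata(grp)"))
  ref <- survival::clogit(fml, data = df)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
  expect_equal(as.numeric(logLik(fit)), as.numeric(logLik(ref)),
               tolerance = 1e-6)
})

test_that("optimum log-likelihood improves on the null and probabilities sum to 1", {
  sp <- default_space()
  dat <- small_dataset()
  fit <- fit_clogit(dat, sp, country = "Scotland")
  expect_gt(fit$logLik, -(fit$n_sets) * log(3))
  p <- predict(fit, newdata = dat[dat$country == "Scotland", ])
  sums <- rowsum(p, rep(seq_len(length(p) / 3), each = 3))
  expect_equal(unname(sums[, 1]), rep(1, nrow(sums)), tolerance = 1e-10)
})

test_that("fully interacted pooled fit reproduces the separate country fits", {
  sp <- default_space()
  dat <- small_dataset()
  f_sw <- fit_clogit(dat, sp, country = "Sweden")
  f_sc <- fit_clogit(dat, sp, country = "Scotland")
  f_p <- fit_pooled_interactions(dat, sp)
  cf <- coef(f_p)
  main <- names(coef(f_sw))
  # reference-country coefficients equal the Sweden-only fit
  expect_equal(cf[main], coef(f_sw), tolerance = 1e-4)
  # main + interaction equals the Scotland-only fit
  expect_equal(unname(cf[main] + cf[paste0("scotland:", main)]),
               unname(coef(f_sc)), tolerance = 1e-4)
  # log-likelihood decomposes exactly
  expect_equal(f_p$logLik, f_sw$logLik + f_sc$logLik, tolerance = 1e-6)
  expect_error(fit_pooled_interactions(dat[dat$country == "Sweden", ], sp),
               "both countries")
})

test_that("heteroskedastic fit nests the pooled model at zero scale", {
  sp <- default_space()
  dat <- small_dataset()
  f_p <- fit_pooled_interactions(dat, sp)
  b <- build_design_matrix(dat, sp)
  par_p <- coef(f_p)
  # evaluate the heteroskedastic likelihood at the pooled optimum, theta = 0
  ll_h <- clogit_loglik(c(par_p, 0), b, "heteroskedastic",
                        restricted = character(0))
  expect_equal(as.numeric(ll_h), f_p$logLik, tolerance = 1e-9)
  # lambda at theta = 0 is exactly 1
  expect_identical(exp(0), 1)
})

test_that("restriction selection picks the least-different attribute", {
  sp <- default_space()
  # simulate with a cross-country difference on every attribute except
  # purpose (identical purpose part-worths)
  sc <- default_preferences("Scotland")
  sw <- default_preferences("Sweden")
  sc$beta[c("purpose:direct_benefits", "purpose:public_benefits")] <-
    sw$beta[c("purpose:direct_benefits", "purpose:public_benefits")]
  pop <- simulate_population(default_population_spec(400, 400), seed = 31)
  hits <- 0L
  for (s in 1:3) {
    dat <- simulate_choices(pop, small_design(),
                            list(Scotland = sc, Sweden = sw), sp,
                            seed = 310 + s)
    f_p <- fit_pooled_interactions(dat, sp)
    if (select_restriction_attribute(f_p) == "purpose") hits <- hits + 1L
  }
  expect_gte(hits, 2L)
  f_ct <- fit_clogit(small_dataset(), sp, country = "Sweden")
  expect_error(select_restriction_attribute(f_ct), "pooled fit")
})

test_that("a single choice set never yields silent garbage", {
  sp <- default_space()
  dat <- one_set_data()
  flagged <- tryCatch({
    fit <- suppressWarnings(fit_clogit(dat, sp))
    length(fit$unstable) > 0 || !fit$converged
  }, warning = function(w) TRUE, error = function(e) TRUE)
  expect_true(flagged)
})

test_that("clustered sandwich standard errors are available and sane", {
  sp <- default_space()
  dat <- small_dataset()
  f0 <- fit_clogit(dat, sp, country = "Sweden")
  f1 <- fit_clogit(dat, sp, country = "Sweden", cluster_se = TRUE)
  expect_equal(coef(f0), coef(f1))
  expect_false(identical(f0$se, f1$se))
  expect_true(all(f1$se > 0))
  expect_lt(max(abs(log(f1$se / f0$se))), log(2))  # same order of magnitude
})

test_that("fit reports and serialised fits round-trip", {
  sp <- default_space()
  fit <- fit_clogit(small_dataset(), sp, country = "Sweden")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fit_report(fit, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "term\testimate")
  expect_equal(length(lines), 1L + 15L + 2L)
  js <- withr::local_tempfile(fileext = ".json")
  write_dce_fit(fit, js)
  fit2 <- read_dce_fit(js)
  expect_identical(coef(fit2), coef(fit))
  expect_identical(fit2$vcov, fit$vcov)
  expect_identical(fit2$logLik, fit$logLik)
})

test_that("summary tables carry estimates, SEs and significance stars", {
  fit <- reference_estimates("sweden")
  s <- summary(fit)
  tab <- s$table
  expect_equal(nrow(tab), 15L)
  row <- tab[tab$term == "data_type:primary_care_other_health", ]
  expect_equal(row$estimate, 0.706)
  expect_equal(row$stars, "***")
  gov <- tab[tab$term == "oversight:government", ]
  expect_equal(gov$stars, "***")
})
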