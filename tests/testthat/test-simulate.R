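test_that("quota panels realise the target demographic proportions", {
  pop <- simulate_population(default_population_spec(), seed = 1)
  sc <- pop[pop$country == "Scotland", ]
  sw <- pop[pop$country == "Sweden", ]
  expect_equal(nrow(sc), 1004L)
  expect_equal(nrow(sw), 974L)
  # realised shares match targets well within 2 percentage points
  expect_equal(mean(sc$gender == "female"), 583 / 1004, tolerance = 0.002)
  expect_equal(mean(sw$gender == "male"), 499 / 974, tolerance = 0.002)
  expect_equal(mean(sc$age_band == "55+"), 371 / 1004, tolerance = 0.002)
  expect_equal(mean(sw$working == "working"), 627 / 968, tolerance = 0.002)
})

test_that("population simulation is deterministic and validates quotas", {
  p1 <- simulate_population(default_population_spec(100, 100), seed = 5)
  p2 <- simulate_population(default_population_spec(100, 100), seed = 5)
  expect_identical(p1, p2)
  all_male <- population_spec(list(X = list(
    n = 50, gender = c(male = 1), age_band = c("18-34" = 1),
    working = c(working = 1))))
  expect_true(all(simulate_population(all_male, seed = 1)$gender == "male"))
  expect_error(population_spec(list(X = list(
    n = 10, gender = c(male = 0.6, female = 0.5),
    age_band = c("18-34" = 1), working = c(working = 1)))), "summing to 1")
})

test_that("screening routes respondents out at their first refusal", {
  pop <- simulate_population(default_population_spec(200, 200), seed = 2)
  zero <- screening_spec(paste0("q", 1:6), rep(0, 6))
  scr <- simulate_screening(pop, zero, seed = 1)
  expect_equal(nrow(scr$routed_out), 0L)
  expect_equal(nrow(scr$completers), nrow(pop))
  first <- screening_spec(paste0("q", 1:6), c(1, rep(0, 5)))
  scr1 <- simulate_screening(pop, first, seed = 1)
  expect_equal(nrow(scr1$completers), 0L)
  expect_true(all(scr1$routed_out$exit_question == "q1"))
})

test_that("calibrated hazards reproduce the expected route-out flow", {
  # hazards are calibrated so expected Scottish exits total 461 of 1465
  spec <- default_screening_spec()
  h <- spec$probabilities$Scotland
  at_risk <- 1465
  expected_exits <- numeric(6)
  for (q in 1:6) {
    expected_exits[q] <- at_risk * h[q]
    at_risk <- at_risk - expected_exits[q]
  }
  expect_equal(expected_exits, c(67, 104, 135, 145, 8, 2), tolerance = 1e-9)
  # Monte-Carlo realisation within 3 binomial SEs of the expectation
  invited <- data.frame(respondent_id = 1:1465, country = "Scotland")
  scr <- simulate_screening(invited, spec, seed = 9)
  p <- 461 / 1465
  se3 <- 3 * sqrt(1465 * p * (1 - p))
  expect_lt(abs(nrow(scr$routed_out) - 461), se3)
  expect_true(all(scr$routed_out$exit_question %in% spec$questions))
})

test_that("simulated choice datasets satisfy the long-format invariants", {
  dat <- small_dataset()
  key <- paste(dat$respondent_id, dat$set)
  expect_true(all(table(key) == 3L))
  chosen_per_set <- tapply(dat$chosen, key, sum)
  expect_true(all(chosen_per_set == 1L))
  # each respondent sees the 6 sets of exactly one block
  per_resp <- tapply(dat$block, dat$respondent_id,
                     function(b) length(unique(b)))
  expect_true(all(per_resp == 1L))
  expect_true(all(tapply(dat$set, dat$respondent_id,
                         function(s) length(unique(s))) == 6L))
  # opt-out rows sit at the base profile
  sp <- default_space()
  base <- vapply(sp$attributes, `[[`, integer(1), "base")
  oo <- dat[dat$opt_out == 1L, names(sp$attributes)]
  expect_true(all(t(oo) == base))
})

test_that("choice simulation is deterministic and validates dimensions", {
  pop <- simulate_population(default_population_spec(30, 30), seed = 3)
  prefs <- default_preferences("Sweden")
  d1 <- simulate_choices(pop, small_design(), prefs, default_space(), seed = 4)
  d2 <- simulate_choices(pop, small_design(), prefs, default_space(), seed = 4)
  expect_identical(d1, d2)
  bad <- preference_profile(rep(0, 14), 0)
  bad$beta <- bad$beta[-1]
  expect_error(simulate_choices(pop, small_design(), bad, default_space(),
                                seed = 1), "dimensioned")
})

test_that("an overwhelming part-worth drives the choice share to one", {
  sp <- default_space()
  # alternative A uniquely holds a level with a huge coefficient
  des <- fixed_set_design(c(1L, 4L, 3L, 4L, 4L), c(4L, 1L, 3L, 4L, 4L))
  beta <- stats::setNames(rep(0, 14), NULL)
  prefs <- preference_profile(beta, delta = 0)
  prefs$beta[["researchers:university_only"]] <- 50
  prefs$beta[["data_type:primary_care_other_health"]] <- 0
  pop <- data.frame(respondent_id = 1:2000, country = "Sweden")
  dat <- simulate_choices(pop, des, prefs, sp, seed = 6)
  share_a <- mean(dat$chosen[dat$alt == "A"])
  expect_gt(share_a, 0.99)
})

test_that("null preferences give uniform one-third choice shares", {
  sp <- default_space()
  des <- fixed_set_design(c(1L, 2L, 1L, 2L, 1L), c(2L, 1L, 2L, 1L, 2L))
  prefs <- preference_profile(rep(0, 14), delta = 0)
  pop <- data.frame(respondent_id = 1:30000, country = "Sweden")
  dat <- simulate_choices(pop, des, prefs, sp, seed = 7)
  shares <- tapply(dat$chosen, dat$alt, mean)
  se3 <- 3 * sqrt((1 / 3) * (2 / 3) / 30000)
  expect_true(all(abs(shares - 1 / 3) < se3))
})

test_that("simulated shares match closed-form logit probabilities", {
  sp <- default_space()
  a <- c(2L, 1L, 2L, 3L, 3L)  # typical-like alternative
  b <- c(1L, 2L, 1L, 1L, 2L)
  des <- fixed_set_design(a, b)
  prefs <- default_preferences("Sweden")
  # closed-form oracle computed from first principles
  util <- function(prof) {
    v <- 0
    for (i in seq_along(prof)) {
      at <- sp$attributes[[i]]
      if (prof[i] != at$base)
        v <- v + prefs$beta[[paste0(at$name, ":", at$levels[prof[i]])]]
    }
    v
  }
  V <- c(util(a), util(b), prefs$delta)
  p_true <- exp(V) / sum(exp(V))
  n <- 50000
  pop <- data.frame(respondent_id = seq_len(n), country = "Sweden")
  dat <- simulate_choices(pop, des, prefs, sp, seed = 8)
  shares <- tapply(dat$chosen, dat$alt, mean)[c("A", "B", "optout")]
  se3 <- 3 * sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(shares - p_true) < se3))
})

test_that("the scale parameter sharpens or flattens simulated choices", {
  sp <- default_space()
  des <- fixed_set_design(c(1L, 1L, 1L, 1L, 1L), c(3L, 3L, 2L, 3L, 3L))
  pop <- data.frame(respondent_id = 1:4000, country = "Scotland")
  base_prefs <- default_preferences("Sweden")
  sharp <- base_prefs; sharp$theta <- 4     # lambda >> 1
  flat <- base_prefs; flat$theta <- -8      # lambda ~ 0
  dat_s <- simulate_choices(pop, des, sharp, sp, seed = 10)
  dat_f <- simulate_choices(pop, des, flat, sp, seed = 10)
  # best alternative approaches certainty under a large scale
  best <- names(which.max(tapply(dat_s$chosen, dat_s$alt, mean)))
  expect_gt(mean(dat_s$chosen[dat_s$alt == best]), 0.95)
  # shares approach uniform as the scale vanishes
  shares_f <- tapply(dat_f$chosen, dat_f$alt, mean)
  expect_true(all(abs(shares_f - 1 / 3) < 0.03))
})

test_that("default preference profiles carry the published true values", {
  sw <- default_preferences("Sweden")
  expect_equal(sw$beta[["data_type:primary_care_other_health"]], 0.706)
  expect_equal(sw$delta, 0.620)
  sc <- default_preferences("Scotland")
  expect_equal(sc$delta, 0.886)
  expect_error(default_preferences("Norway"), "unknown country")
})

test_that("choice datasets round-trip through CSV", {
  dat <- small_dataset()[1:90, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_choice_data(dat, path)
  dat2 <- read_choice_data(path)
  expect_equal(dat2$chosen, dat$chosen)
  expect_equal(dat2$purpose, dat$purpose)
})
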