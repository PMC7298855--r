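# shared small fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

default_space <- function() fixture("space", default_attribute_space)

small_design <- function() fixture("design", function()
  generate_design(default_space(), n_blocks = 5, sets_per_block = 6,
                  seed = 11, n_iter = 50))

# two-country simulated dataset, 120 respondents per country
small_dataset <- function() fixture("dataset", function() {
  pop <- simulate_population(default_population_spec(120, 120), seed = 21)
  simulate_choices(pop, small_design(),
                   list(Scotland = default_preferences("Scotland"),
                        Sweden = default_preferences("Sweden")),
                   default_space(), seed = 22)
})

# a single hand-checkable choice set as a long-format data.frame
one_set_data <- function(a = c(1L, 1L, 1L, 1L, 1L),
                         b = c(4L, 4L, 3L, 4L, 4L),
                         chosen_alt = "A", country = "Sweden") {
  sp <- default_space()
  an <- names(sp$attributes)
  base <- vapply(sp$attributes, `[[`, integer(1), "base")
  m <- rbind(a, b, base)
  df <- data.frame(respondent_id = 1L, country = country, block = 1L,
                   set = 1L, alt = c("A", "B", "optout"), m,
                   opt_out = c(0L, 0L, 1L),
                   chosen = as.integer(c("A", "B", "optout") == chosen_alt),
                   row.names = NULL, check.names = FALSE)
  names(df)[6:10] <- an
  df
}

# random attribute space for property tests
random_space <- function() {
  n_attr <- sample(1:5, 1)
  defs <- lapply(seq_len(n_attr), function(i) {
    k <- sample(2:5, 1)
    list(levels = paste0("l", seq_len(k)))
  })
  names(defs) <- paste0("attr", seq_len(n_attr))
  attribute_space(defs)
}

# single-choice-set design around two fixed profiles
fixed_set_design <- function(a, b) {
  sp <- default_space()
  structure(list(
    alt_a = matrix(a, 1, 5, dimnames = list(NULL, names(sp$attributes))),
    alt_b = matrix(b, 1, 5, dimnames = list(NULL, names(sp$attributes))),
    block = 1L, set = 1L, n_blocks = 1L, sets_per_block = 1L,
    attribute_names = names(sp$attributes)), class = "dce_design")
}
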