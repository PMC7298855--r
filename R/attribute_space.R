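#' Define an attribute space for a discrete choice experiment
#'
#' An attribute space is the universe of attributes and levels from which
#' choice-scenario profiles are built.  Each attribute designates one level
#' as the base (reference) level for dummy coding -- conventionally the
#' "worst" level -- and may carry a quality order used by dominance checks.
#'
#' @param attributes A named list.  Each element describes one attribute and
#'   is itself a list with components \code{levels} (character vector of
#'   unique level labels), optional \code{base} (label or index of the base
#'   level; defaults to the last listed level) and optional
#'   \code{quality_order} (integer rank per level, higher = better; defaults
#'   to base level worst, remaining levels ranked by listing position with
#'   the first-listed level best).
#'
#' @return An object of class \code{attribute_space}: a list with components
#'   \code{attributes} (the validated per-attribute definitions),
#'   \code{n_attributes}, and \code{n_levels} (integer vector of level
#'   counts).
#' @seealso [default_attribute_space()], [enumerate_profiles()],
#'   [read_attribute_space()]
#' @export
#' @examples
#' sp <- attribute_space(list(
#'   size  = list(levels = c("small", "large")),
#'   speed = list(levels = c("slow", "medium", "fast"), base = "slow")
#' ))
#' sp$n_levels
attribute_space <- function(attributes) {
  if (!is.list(attributes) || length(attributes) == 0L)
    stop("'attributes' must be a non-empty named list of attribute definitions")
  nm <- names(attributes)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("attributes must have unique non-empty names")
  attrs <- lapply(seq_along(attributes), function(i) {
    a <- attributes[[i]]
    if (is.character(a)) a <- list(levels = a)
    lv <- a$levels
    if (!is.character(lv) || length(lv) < 2L)
      stop(sprintf("attribute '%s' must have at least two character levels", nm[i]))
    if (anyDuplicated(lv))
      stop(sprintf("attribute '%s' has duplicated level labels", nm[i]))
    base <- a$base
    if (is.null(base)) base <- length(lv)
    if (is.character(base)) base <- match(base, lv)
    base <- as.integer(base)
    if (is.na(base) || base < 1L || base > length(lv))
      stop(sprintf("attribute '%s': base level not found among its levels", nm[i]))
    qo <- a$quality_order
    if (!is.null(qo)) {
      qo <- as.numeric(qo)
      if (length(qo) != length(lv))
        stop(sprintf("attribute '%s': quality_order must rank every level", nm[i]))
    }
    list(name = nm[i], levels = lv, base = base, quality_order = qo)
  })
  names(attrs) <- nm
  structure(
    list(attributes = attrs,
         n_attributes = length(attrs),
         n_levels = vapply(attrs, function(a) length(a$levels), integer(1))),
    class = "attribute_space")
}

#' @export
print.attribute_space <- function(x, ...) {
  cat(sprintf("Attribute space: %d attributes, %s profiles\n",
              x$n_attributes, format(prod(x$n_levels), big.mark = ",")))
  for (a in x$attributes) {
    cat(sprintf("  %s (%d levels, base = '%s')\n",
                a$name, length(a$levels), a$levels[a$base]))
  }
  invisible(x)
}

#' The five-attribute linked-data space used throughout the package
#'
#' The default study design describes hypothetical data-linkage scenarios by
#' five attributes: who the researchers are, what type of data is linked,
#' the purpose of the research, what happens to any profit, and who oversees
#' the process.  Level counts are (4, 4, 3, 4, 4); each attribute's base
#' level -- the one dummy coding measures against -- is its last-listed,
#' least restrictive ("worst") level.
#'
#' @return An [attribute_space()] with 5 attributes and 768 possible
#'   profiles.
#' @export
#' @examples
#' sp <- default_attribute_space()
#' prod(sp$n_levels)  # 768
default_attribute_space <- function() {
  attribute_space(list(
    researchers = list(levels = c(
      "university_only",
      "university_health",
      "university_health_gov",
      "university_health_gov_commercial")),
    data_type = list(levels = c(
      "primary_care_other_health",
      "health_social_education",
      "health_social_edu_emp_benefits",
      "health_all_incl_private_sector")),
    purpose = list(levels = c(
      "direct_benefits",
      "public_benefits",
      "any_reason")),
    profit = list(levels = c(
      "nobody_profits",
      "shared_with_public",
      "invested_public_services",
      "kept_by_researchers")),
    oversight = list(levels = c(
      "government",
      "independent_body",
      "relevant_public_service",
      "research_organisation"))
  ))
}

default_quality_order <- function(attr) {
  # base level worst (rank 0); remaining levels ranked by listing position,
  # first-listed best
  k <- length(attr$levels)
  qo <- numeric(k)
  non_base <- setdiff(seq_len(k), attr$base)
  qo[non_base] <- rev(seq_along(non_base))
  qo[attr$base] <- 0
  qo
}

quality_ranks <- function(space) {
  lapply(space$attributes, function(a) {
    if (is.null(a$quality_order)) default_quality_order(a) else a$quality_order
  })
}

#' Enumerate all profiles of an attribute space
#'
#' Generates the full factorial of level combinations.  A profile is one
#' level index per attribute.
#'
#' @param space An [attribute_space()].
#' @return An integer matrix with one row per profile and one column per
#'   attribute (1-based level indices); \code{nrow} equals the product of
#'   the level counts.
#' @export
#' @examples
#' nrow(enumerate_profiles(default_attribute_space()))  # 768
enumerate_profiles <- function(space) {
  stopifnot(inherits(space, "attribute_space"))
  if (space$n_attributes == 0L) stop("attribute space has no attributes")
  grid <- expand.grid(lapply(space$n_levels, seq_len), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(NULL, names(space$attributes))
  m
}

#' Number of unordered pairs of distinct profiles
#'
#' The number of possible two-alternative choice tasks that can be formed
#' from \code{n_profiles} distinct profiles: \eqn{n(n-1)/2}.
#'
#' @param n_profiles Number of distinct profiles (>= 2).
#' @return The pair count as a double (counts exceed integer range quickly).
#' @export
#' @examples
#' count_choice_pairs(768)  # 294528
count_choice_pairs <- function(n_profiles) {
  n_profiles <- as.numeric(n_profiles)
  if (length(n_profiles) != 1L || is.na(n_profiles) || n_profiles < 2)
    stop("'n_profiles' must be a single number >= 2")
  n_profiles * (n_profiles - 1) / 2
}

#' Is a choice set a dominated pair?
#'
#' A pair is dominated when one alternative is at least as good as the other
#' on every attribute (under each attribute's quality order) and strictly
#' better on at least one.  Dominated pairs carry no preference information
#' and are removed from designs when filtering is enabled.
#'
#' @param a,b Integer vectors of level indices, one per attribute.
#' @param space An [attribute_space()] whose attributes all have a quality
#'   order (the default ordering is used where none is declared).
#' @return \code{TRUE} if either alternative dominates the other.
#' @export
is_dominated_pair <- function(a, b, space) {
  stopifnot(inherits(space, "attribute_space"))
  if (length(a) != space$n_attributes || length(b) != space$n_attributes)
    stop("profiles must have one level index per attribute")
  qr <- quality_ranks(space)
  qa <- vapply(seq_along(qr), function(i) qr[[i]][a[i]], numeric(1))
  qb <- vapply(seq_along(qr), function(i) qr[[i]][b[i]], numeric(1))
  if (anyNA(qa) || anyNA(qb)) stop("level index out of range for its attribute")
  (all(qa >= qb) && any(qa > qb)) || (all(qb >= qa) && any(qb > qa))
}

#' Orme's rule-of-thumb minimum sample size for a DCE
#'
#' The heuristic \eqn{N \ge 500 c / (t a)} where \eqn{c} is the largest
#' number of levels of any attribute, \eqn{t} the number of choice tasks per
#' respondent and \eqn{a} the number of alternatives per task.
#'
#' @param max_levels Largest number of levels across attributes.
#' @param tasks_per_respondent Choice tasks answered by each respondent.
#' @param alternatives_per_task Alternatives per task (excluding opt-out).
#' @return The minimum sample size, rounded up.
#' @export
#' @examples
#' orme_minimum_n(4, 6, 2)  # 167
orme_minimum_n <- function(max_levels, tasks_per_respondent,
                           alternatives_per_task) {
  vals <- c(max_levels, tasks_per_respondent, alternatives_per_task)
  if (any(!is.finite(vals)) || any(vals < 1))
    stop("all inputs must be >= 1")
  as.integer(ceiling(500 * max_levels /
                       (tasks_per_respondent * alternatives_per_task)))
}

#' Read or write an attribute space definition file
#'
#' The file is a single YAML document: a mapping from attribute name to
#' \code{levels}, optional \code{base}, and optional \code{quality_order}.
#'
#' @param path File path.
#' @return \code{read_attribute_space} returns an [attribute_space()];
#'   \code{write_attribute_space} invisibly returns \code{path}.
#' @export
read_attribute_space <- function(path) {
  doc <- yaml::read_yaml(path)
  attribute_space(doc)
}

#' @rdname read_attribute_space
#' @param space An [attribute_space()] to serialise.
#' @export
write_attribute_space <- function(space, path) {
  stopifnot(inherits(space, "attribute_space"))
  doc <- lapply(space$attributes, function(a) {
    out <- list(levels = a$levels, base = a$levels[a$base])
    if (!is.null(a$quality_order)) out$quality_order <- a$quality_order
    out
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}
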