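#' Generate a blocked main-effects choice-set design
#'
#' Builds a design of \code{n_blocks} blocks, each containing
#' \code{sets_per_block} choice sets.  A choice set pairs two distinct
#' scenario profiles (an opt-out alternative is always implied at analysis
#' time).  Sets are drawn by a seeded random-swap heuristic: an initial
#' random design is improved by proposing single-set replacements and
#' accepting those that raise the D-efficiency of the main-effects dummy
#' coding under null coefficients.  With \code{filter_dominated = TRUE}
#' (default) no set is a dominated pair under the space's quality order.
#'
#' @param space An [attribute_space()].
#' @param n_blocks Number of blocks (default 40).
#' @param sets_per_block Choice sets per block (default 6).
#' @param filter_dominated Remove dominated pairs? Default \code{TRUE}.
#' @param seed Integer seed; fixed seeds give identical designs.
#' @param n_iter Improvement iterations for the swap heuristic.
#' @return An object of class \code{dce_design}: list with integer matrices
#'   \code{alt_a}, \code{alt_b} (one row per choice set, one column per
#'   attribute, 1-based level indices), vectors \code{block} and \code{set},
#'   and counts \code{n_blocks}, \code{sets_per_block}.
#' @export
#' @examples
#' d <- generate_design(default_attribute_space(), n_blocks = 2,
#'                      sets_per_block = 3, seed = 1)
#' d$n_blocks * d$sets_per_block
generate_design <- function(space, n_blocks = 40, sets_per_block = 6,
                            filter_dominated = TRUE, seed = NULL,
                            n_iter = 300) {
  stopifnot(inherits(space, "attribute_space"))
  n_blocks <- as.integer(n_blocks); sets_per_block <- as.integer(sets_per_block)
  if (n_blocks < 1L || sets_per_block < 1L)
    stop("n_blocks and sets_per_block must be positive")
  n_sets <- n_blocks * sets_per_block
  profiles <- enumerate_profiles(space)
  np <- nrow(profiles)
  if (n_sets > count_choice_pairs(np))
    stop("requested more choice sets than distinct profile pairs exist")
  if (!is.null(seed)) set.seed(seed)

  qr <- quality_ranks(space)
  qmat <- vapply(seq_along(qr), function(i) qr[[i]][profiles[, i]],
                 numeric(np))  # np x A quality ranks per profile

  dominated <- function(i, j) {
    d <- qmat[i, ] - qmat[j, ]
    (all(d >= 0) && any(d > 0)) || (all(d <= 0) && any(d < 0))
  }
  draw_pair <- function() {
    for (k in seq_len(1000L)) {
      ij <- sample.int(np, 2L)
      if (!filter_dominated || !dominated(ij[1L], ij[2L]))
        return(sort(ij))
    }
    stop("could not find a non-dominated pair; design request infeasible")
  }

  pair_key <- function(p) p[1L] * (np + 1) + p[2L]
  pairs <- matrix(0L, n_sets, 2L)
  used <- new.env(hash = TRUE, parent = emptyenv())
  i <- 1L; tries <- 0L
  while (i <= n_sets) {
    p <- draw_pair()
    key <- as.character(pair_key(p))
    if (is.null(used[[key]])) {
      used[[key]] <- TRUE
      pairs[i, ] <- p
      i <- i + 1L
    }
    tries <- tries + 1L
    if (tries > 200L * n_sets)
      stop("could not assemble enough distinct choice sets; request infeasible")
  }

  # D-efficiency criterion under null coefficients (choice sets of 3
  # alternatives incl. opt-out; 14 level dummies + opt-out constant)
  X_all <- profile_dummies(profiles, space)
  k_par <- ncol(X_all) + 1L
  set_info <- function(ia, ib) {
    xa <- c(X_all[ia, ], 0); xb <- c(X_all[ib, ], 0)
    xo <- c(numeric(ncol(X_all)), 1)
    xbar <- (xa + xb + xo) / 3
    (tcrossprod(xa) + tcrossprod(xb) + tcrossprod(xo)) / 3 - tcrossprod(xbar)
  }
  info <- matrix(0, k_par, k_par)
  for (s in seq_len(n_sets)) info <- info + set_info(pairs[s, 1L], pairs[s, 2L])
  logdet <- function(M) {
    d <- determinant(M, logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }
  crit <- logdet(info)

  for (it in seq_len(n_iter)) {
    s <- sample.int(n_sets, 1L)
    cand <- draw_pair()
    key <- as.character(pair_key(cand))
    if (!is.null(used[[key]])) next
    old <- pairs[s, ]
    info_new <- info - set_info(old[1L], old[2L]) + set_info(cand[1L], cand[2L])
    crit_new <- logdet(info_new)
    if (crit_new > crit) {
      rm(list = as.character(pair_key(old)), envir = used)
      used[[key]] <- TRUE
      pairs[s, ] <- cand
      info <- info_new
      crit <- crit_new
    }
  }

  ord <- sample.int(n_sets)  # random allocation of sets to blocks
  pairs <- pairs[ord, , drop = FALSE]
  structure(list(
    alt_a = profiles[pairs[, 1L], , drop = FALSE],
    alt_b = profiles[pairs[, 2L], , drop = FALSE],
    block = rep(seq_len(n_blocks), each = sets_per_block),
    set = rep(seq_len(sets_per_block), times = n_blocks),
    n_blocks = n_blocks, sets_per_block = sets_per_block,
    attribute_names = names(space$attributes)),
    class = "dce_design")
}

#' @export
print.dce_design <- function(x, ...) {
  cat(sprintf("Blocked DCE design: %d blocks x %d choice sets (%d total)\n",
              x$n_blocks, x$sets_per_block, x$n_blocks * x$sets_per_block))
  cat("Each set: two scenario alternatives + opt-out\n")
  invisible(x)
}

# dummy coding of profile rows: one column per non-base level, listing order
profile_dummies <- function(profiles, space) {
  cols <- list()
  for (i in seq_along(space$attributes)) {
    a <- space$attributes[[i]]
    for (l in setdiff(seq_along(a$levels), a$base)) {
      cols[[paste0(a$name, ":", a$levels[l])]] <-
        as.numeric(profiles[, i] == l)
    }
  }
  do.call(cbind, cols)
}

#' Diagnostics for a blocked choice design
#'
#' Reports per-attribute level balance (max/min frequency ratio over all
#' scenario alternatives), within-set attribute-level overlap counts, and
#' the D-efficiency of the main-effects coding under null coefficients
#' (geometric-mean information per parameter, opt-out included).
#'
#' @param design A [generate_design()] result.
#' @param space The [attribute_space()] the design was built from.
#' @return A list with \code{level_frequencies}, \code{balance_ratio}
#'   (per attribute), \code{overlap_counts} (per attribute) and
#'   \code{d_efficiency}.
#' @export
design_diagnostics <- function(design, space) {
  stopifnot(inherits(design, "dce_design"), inherits(space, "attribute_space"))
  alts <- rbind(design$alt_a, design$alt_b)
  freqs <- lapply(seq_along(space$attributes), function(i) {
    tabulate(alts[, i], nbins = space$n_levels[i])
  })
  names(freqs) <- names(space$attributes)
  balance <- vapply(freqs, function(f) {
    if (min(f) == 0) Inf else max(f) / min(f)
  }, numeric(1))
  overlap <- vapply(seq_along(space$attributes), function(i) {
    sum(design$alt_a[, i] == design$alt_b[, i])
  }, numeric(1))
  names(overlap) <- names(space$attributes)

  Xa <- cbind(profile_dummies(design$alt_a, space), optout = 0)
  Xb <- cbind(profile_dummies(design$alt_b, space), optout = 0)
  k <- ncol(Xa)
  xo <- c(numeric(k - 1L), 1)
  n_sets <- nrow(Xa)
  info <- matrix(0, k, k)
  for (s in seq_len(n_sets)) {
    xs <- rbind(Xa[s, ], Xb[s, ], xo)
    xbar <- colMeans(xs)
    info <- info + crossprod(xs) / 3 - tcrossprod(xbar)
  }
  info <- info / n_sets
  d <- determinant(info, logarithm = TRUE)
  d_eff <- if (d$sign <= 0) 0 else exp(as.numeric(d$modulus) / k)
  list(level_frequencies = freqs, balance_ratio = balance,
       overlap_counts = overlap, d_efficiency = d_eff)
}

#' Export or import a design as CSV
#'
#' Long format: columns \code{block}, \code{set}, \code{alternative}
#' (\code{"A"}/\code{"B"}) and one column per attribute holding the 0-based
#' level index.
#'
#' @param design A \code{dce_design}.
#' @param path Output file path.
#' @export
write_design_csv <- function(design, path) {
  stopifnot(inherits(design, "dce_design"))
  long <- rbind(
    data.frame(block = design$block, set = design$set, alternative = "A",
               design$alt_a - 1L, check.names = FALSE),
    data.frame(block = design$block, set = design$set, alternative = "B",
               design$alt_b - 1L, check.names = FALSE))
  long <- long[order(long$block, long$set, long$alternative), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param space The [attribute_space()] the design refers to.
#' @export
read_design_csv <- function(path, space) {
  long <- utils::read.csv(path, check.names = FALSE)
  an <- names(space$attributes)
  if (!all(c("block", "set", "alternative", an) %in% names(long)))
    stop("design CSV is missing required columns")
  a_rows <- long[long$alternative == "A", ]
  b_rows <- long[long$alternative == "B", ]
  a_rows <- a_rows[order(a_rows$block, a_rows$set), ]
  b_rows <- b_rows[order(b_rows$block, b_rows$set), ]
  alt_a <- as.matrix(a_rows[, an]) + 1L
  alt_b <- as.matrix(b_rows[, an]) + 1L
  storage.mode(alt_a) <- "integer"; storage.mode(alt_b) <- "integer"
  dimnames(alt_a) <- dimnames(alt_b) <- list(NULL, an)
  structure(list(
    alt_a = alt_a, alt_b = alt_b,
    block = a_rows$block, set = a_rows$set,
    n_blocks = length(unique(a_rows$block)),
    sets_per_block = length(unique(a_rows$set)),
    attribute_names = an),
    class = "dce_design")
}
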