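#' Describe a study-extension problem
#'
#' An existing study of `n` case-units assayed at hit rate `v` is to be
#' extended with a fixed additional budget, by one of two strategies:
#' \describe{
#'   \item{A}{assay new case-units with the original assay (price `price_A`
#'     each), raising n to \eqn{n_A};}
#'   \item{B}{apply an additional assay (price `price_B` each) to the
#'     existing case-units, raising the hit rate to \eqn{v_B}.}
#' }
#' The augmented hit rate can be given directly (`augmented_hit_rate`) or as
#' the hit rate of the second assay (`extra_hit_rate`), added to `v` under
#' the no-overlap assumption of [combine_assays()].
#'
#' @param n Existing number of case-units, >= 1.
#' @param hit_rate Original assay hit rate \eqn{v}.
#' @param price_A Price per case-unit of the original assay.
#' @param price_B Price per case-unit of the additional assay.
#' @param complexity Disease complexity \eqn{c \ge 1} (or [disease_model()]).
#' @param budget Funds available for the extension; defaults to the cost of
#'   strategy B, `n * price_B`, the equal-cost comparison.
#' @param augmented_hit_rate Combined hit rate \eqn{v_B} after strategy B.
#' @param extra_hit_rate Alternative to `augmented_hit_rate`: hit rate of the
#'   additional assay, combined with `hit_rate` assuming zero overlap.
#' @param overlap Shared coverage subtracted when combining via
#'   `extra_hit_rate`; default 0.
#' @return An object of class `"extension_scenario"`.
#' @examples
#' # 4 exome-sequenced trios; add a 5th trio, or chip-genotype the existing 4?
#' extension_scenario(n = 4, hit_rate = 0.27, price_A = 4, price_B = 1,
#'                    complexity = 2, extra_hit_rate = 0.12)
#' @export
extension_scenario <- function(n, hit_rate, price_A, price_B, complexity,
                               budget = NULL, augmented_hit_rate = NULL,
                               extra_hit_rate = NULL, overlap = 0) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1")
  check_hit_rate(hit_rate)
  check_price(price_A, "price_A")
  check_price(price_B, "price_B")
  complexity <- as_complexity(complexity)
  if (is.null(augmented_hit_rate) == is.null(extra_hit_rate))
    stop("give exactly one of 'augmented_hit_rate' or 'extra_hit_rate'")
  if (!is.null(extra_hit_rate)) {
    combined <- combine_assays(
      list(assay("base", hit_rate, price_A),
           assay("extra", extra_hit_rate, price_B)),
      overlap = overlap)
    augmented_hit_rate <- combined$hit_rate
  }
  check_hit_rate(augmented_hit_rate, "augmented_hit_rate")
  if (augmented_hit_rate < hit_rate)
    stop("'augmented_hit_rate' cannot be below the original hit rate: ",
         "re-assaying cannot lose coverage")
  if (is.null(budget)) budget <- n * price_B
  if (!is.numeric(budget) || length(budget) != 1L || is.na(budget) ||
      budget < 0)
    stop("'budget' must be a single non-negative number")
  structure(list(
    n = as.integer(n), hit_rate = hit_rate,
    augmented_hit_rate = augmented_hit_rate,
    complexity = complexity,
    price_A = price_A, price_B = price_B,
    budget = budget
  ), class = "extension_scenario")
}

#' @export
print.extension_scenario <- function(x, ...) {
  cat(sprintf(
    "Extension scenario: n = %d, v = %g -> v_B = %g, c = %g, P_A = %g, P_B = %g, budget = %g\n",
    x$n, x$hit_rate, x$augmented_hit_rate, x$complexity,
    x$price_A, x$price_B, x$budget))
  invisible(x)
}

# relative-tolerance tie classification used for A/B/equivalent verdicts
.equiv_rtol <- 1e-9

classify_yields <- function(yield_A, yield_B, rtol = .equiv_rtol) {
  scale <- max(abs(yield_A), abs(yield_B), 1e-300)
  if (abs(yield_A - yield_B) <= rtol * scale) "equivalent"
  else if (yield_A > yield_B) "A" else "B"
}

#' Compare the two extension strategies
#'
#' Computes the expected yields \eqn{E[m_A] = n_A v^c} (strategy A, with
#' \eqn{n_A = n + \lfloor budget / P_A \rfloor} new case-units on the
#' original assay) and \eqn{E[m_B] = n v_B^c} (strategy B, re-assaying the
#' existing case-units), and declares the favoured strategy. Yields within a
#' relative tolerance of 1e-9 are declared equivalent. Strategy B is flagged
#' infeasible when its cost \eqn{n P_B} exceeds the budget. The breakeven
#' quantities of [min_extra_hit_rate()] and [required_base_hit_rate()] are
#' attached for context.
#'
#' @param scenario An [extension_scenario()].
#' @param continuous_n Use the continuous equal-budget convention
#'   \eqn{n_A = n + budget / P_A} instead of whole case-units. The breakeven
#'   algebra assumes this; concrete advice should use the default `FALSE`.
#' @return An object of class `"strategy_verdict"`: list with `yield_A`,
#'   `yield_B`, `n_A`, `favoured` (one of `"A"`, `"B"`, `"equivalent"`,
#'   `"infeasible"`), `breakeven_delta`, `breakeven_base_hit_rate`, and
#'   `feasibility_notes`.
#' @examples
#' sc <- extension_scenario(n = 4, hit_rate = 0.27, price_A = 4, price_B = 1,
#'                          complexity = 2, extra_hit_rate = 0.12)
#' extension_yields(sc)   # strategy B wins: 0.61 vs 0.365
#' @export
extension_yields <- function(scenario, continuous_n = FALSE) {
  stopifnot(inherits(scenario, "extension_scenario"))
  s <- scenario
  notes <- character(0)

  extra_units <- s$budget / s$price_A
  if (!continuous_n) extra_units <- floor(extra_units)
  n_A <- s$n + extra_units
  yield_A <- n_A * s$hit_rate^s$complexity

  cost_B <- s$n * s$price_B
  feasible_B <- cost_B <= s$budget * (1 + .equiv_rtol)
  yield_B <- s$n * s$augmented_hit_rate^s$complexity
  if (!feasible_B)
    notes <- c(notes, sprintf(
      "strategy B costs %g, exceeding the extension budget %g",
      cost_B, s$budget))
  if (extra_units == 0)
    notes <- c(notes,
               "budget does not cover one additional case-unit for strategy A")

  favoured <- if (!feasible_B && extra_units == 0) "infeasible"
  else if (!feasible_B) "A"
  else classify_yields(yield_A, yield_B)

  delta <- min_extra_hit_rate(s$hit_rate, s$price_B, s$price_A, s$complexity)
  req_v <- required_base_hit_rate(s$augmented_hit_rate - s$hit_rate,
                                  s$price_B, s$price_A, s$complexity)

  structure(list(
    scenario = s,
    n_A = n_A,
    yield_A = yield_A,
    yield_B = yield_B,
    favoured = favoured,
    breakeven_delta = delta,
    breakeven_base_hit_rate = req_v,
    feasibility_notes = notes
  ), class = "strategy_verdict")
}

#' @export
print.strategy_verdict <- function(x, digits = 3, ...) {
  s <- x$scenario
  cat("Study extension verdict\n")
  cat(sprintf("  strategy A (n %d -> %g at v = %g): E[m_A] = %s (%.6g)\n",
              s$n, x$n_A, s$hit_rate,
              format(round_half_up(x$yield_A, digits)), x$yield_A))
  cat(sprintf("  strategy B (v %g -> %g at n = %d): E[m_B] = %s (%.6g)\n",
              s$hit_rate, s$augmented_hit_rate, s$n,
              format(round_half_up(x$yield_B, digits)), x$yield_B))
  cat(sprintf("  favoured: %s\n", x$favoured))
  cat(sprintf(
    "  breakeven: strategy B must add at least %.3g to the hit rate%s\n",
    as.numeric(x$breakeven_delta),
    if (isTRUE(attr(x$breakeven_delta, "infeasible")))
      " (infeasible: exceeds 1)" else ""))
  cat(sprintf(
    "  breakeven: strategy A ties only if the base hit rate were %.3g%s\n",
    as.numeric(x$breakeven_base_hit_rate),
    if (isTRUE(attr(x$breakeven_base_hit_rate, "infeasible")))
      " (infeasible: exceeds 1)" else ""))
  for (note in x$feasibility_notes) cat("  note:", note, "\n")
  invisible(x)
}

#' Sample-size multiple needed for strategy A to match strategy B
#'
#' \eqn{n_A / n = (v_B / v)^c}: how many times the original sample strategy A
#' must reach for its expected yield to equal strategy B's.
#'
#' @param base_hit_rate Original hit rate \eqn{v > 0}.
#' @param augmented_hit_rate Hit rate \eqn{v_B} after the additional assay.
#' @param complexity Disease complexity \eqn{c \ge 1}.
#' @return The ratio \eqn{n_A / n}.
#' @examples
#' extension_sample_ratio(0.27, 0.39, 2)  # ~2.09x the trios
#' @export
extension_sample_ratio <- function(base_hit_rate, augmented_hit_rate,
                                   complexity) {
  check_hit_rate(base_hit_rate, "base_hit_rate")
  check_hit_rate(augmented_hit_rate, "augmented_hit_rate")
  complexity <- as_complexity(complexity)
  if (base_hit_rate == 0)
    stop("'base_hit_rate' must be positive")
  (augmented_hit_rate / base_hit_rate)^complexity
}

#' Hit-rate ratio at which the two extension strategies tie
#'
#' Under the equal-budget constraint \eqn{(n_A - n) P_A = n P_B}, the two
#' strategies give the same expected yield exactly when
#' \eqn{v_B / v = (P_B / P_A + 1)^{1/c}}. The boundary is independent of
#' sample size, falls as complexity rises, and tends to 1 as
#' \eqn{c \to \infty} (handled analytically for `complexity = Inf`): for a
#' very complex disease, any genuine gain in hit rate beats more subjects.
#'
#' @param price_B Price per case-unit of the additional assay, > 0.
#' @param price_A Price per case-unit of the original assay, > 0.
#' @param complexity Disease complexity \eqn{c \ge 1}; may be `Inf`.
#' @return The breakeven ratio \eqn{v_B / v}.
#' @examples
#' equivalence_hit_ratio(1, 4, 2)  # ~1.118
#' @export
equivalence_hit_ratio <- function(price_B, price_A, complexity) {
  check_price(price_B, "price_B")
  check_price(price_A, "price_A")
  if (is.infinite(complexity)) return(1)
  complexity <- as_complexity(complexity)
  (price_B / price_A + 1)^(1 / complexity)
}

#' Minimum extra hit rate strategy B must confer
#'
#' \eqn{\Delta_{v_B} = v [ (P_B/P_A + 1)^{1/c} - 1 ]}: the smallest hit-rate
#' increment the additional assay must contribute for strategy B to match
#' strategy A at equal budget. If \eqn{v + \Delta_{v_B} > 1} no assay can
#' achieve it and the result carries attribute `infeasible = TRUE`.
#'
#' @param base_hit_rate Original hit rate \eqn{v}.
#' @inheritParams equivalence_hit_ratio
#' @return The increment \eqn{\Delta_{v_B}}, with logical attribute
#'   `infeasible`.
#' @examples
#' min_extra_hit_rate(0.27, 1, 4, 2)  # ~0.032
#' @export
min_extra_hit_rate <- function(base_hit_rate, price_B, price_A, complexity) {
  check_hit_rate(base_hit_rate, "base_hit_rate")
  delta <- base_hit_rate * (equivalence_hit_ratio(price_B, price_A,
                                                  complexity) - 1)
  structure(delta, infeasible = base_hit_rate + delta > 1)
}

#' Base hit rate at which strategy A ties strategy B
#'
#' The inverse of [min_extra_hit_rate()]:
#' \eqn{v = \Delta_{v_B} / [ (P_B/P_A + 1)^{1/c} - 1 ]}. Given the hit-rate
#' increment the additional assay actually offers, this is the original hit
#' rate that would make adding subjects exactly as good as re-assaying.
#' Values above 1 are returned with attribute `infeasible = TRUE` -- no real
#' assay could have such a hit rate, so strategy B dominates outright.
#'
#' @param delta Hit-rate increment \eqn{\Delta_{v_B} \ge 0} of the
#'   additional assay.
#' @inheritParams equivalence_hit_ratio
#' @return The base hit rate \eqn{v}, with logical attribute `infeasible`.
#' @examples
#' required_base_hit_rate(0.12, 1, 4, 2)  # ~1.02, infeasible
#' @export
required_base_hit_rate <- function(delta, price_B, price_A, complexity) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("'delta' must be a single non-negative number")
  denom <- equivalence_hit_ratio(price_B, price_A, complexity) - 1
  if (denom == 0)
    stop("degenerate boundary: the price ratio or infinite complexity ",
         "makes any positive increment decisive")
  v <- delta / denom
  structure(v, infeasible = v > 1)
}

#' Partition the price-ratio / hit-rate-ratio plane by favoured strategy
#'
#' Lays a rectangular grid over the plane of price ratio \eqn{P_B / P_A}
#' (x) and hit-rate ratio \eqn{v_B / v} (y) and labels every cell, for each
#' requested complexity, with the favoured extension strategy: `"B"` above
#' the breakeven curve \eqn{v_B/v = (P_B/P_A + 1)^{1/c}}, `"A"` below it,
#' `"equivalent"` on it (relative tolerance 1e-9), and `"infeasible"` where
#' \eqn{v_B / v < 1} (an additional assay cannot lower coverage). The axes
#' are ratios, so the picture is scale-free and independent of n and v.
#' `Inf` is an allowed complexity; its boundary is the constant line
#' \eqn{v_B / v = 1}.
#'
#' @param price_ratio_range Length-2 positive numeric, limits of
#'   \eqn{P_B / P_A}.
#' @param hit_ratio_range Length-2 positive numeric, limits of
#'   \eqn{v_B / v}.
#' @param complexities Numeric vector of complexities (each >= 1, `Inf`
#'   allowed).
#' @param resolution Grid points per axis, >= 2. Default 101.
#' @return An object of class `"strategy_partition"`: a data frame in long
#'   form with columns `price_ratio`, `hit_ratio`, `complexity`, `label`,
#'   plus attributes `price_ratio` / `hit_ratio` (axis grids) and
#'   `boundary` (data frame of the equivalence curves per complexity).
#' @examples
#' pg <- partition_parameter_space(c(0.05, 2), c(0.9, 2), c(1, 2, 4, Inf),
#'                                 resolution = 41)
#' head(as.data.frame(pg))
#' @export
partition_parameter_space <- function(price_ratio_range, hit_ratio_range,
                                      complexities, resolution = 101) {
  check_range <- function(r, what) {
    if (!is.numeric(r) || length(r) != 2L || any(is.na(r)) || any(r <= 0) ||
        r[1] >= r[2])
      stop(sprintf("'%s' must be an increasing pair of positive numbers",
                   what))
  }
  check_range(price_ratio_range, "price_ratio_range")
  check_range(hit_ratio_range, "hit_ratio_range")
  if (!is.numeric(complexities) || length(complexities) < 1L ||
      any(is.na(complexities)) || any(complexities < 1))
    stop("'complexities' must be numeric values >= 1 (Inf allowed)")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution < 2)
    stop("'resolution' must be a single number >= 2")
  resolution <- as.integer(resolution)

  rp <- seq(price_ratio_range[1], price_ratio_range[2],
            length.out = resolution)
  rv <- seq(hit_ratio_range[1], hit_ratio_range[2], length.out = resolution)

  cells <- expand.grid(price_ratio = rp, hit_ratio = rv,
                       complexity = complexities,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  boundary_at <- vapply(seq_len(nrow(cells)), function(i)
    equivalence_hit_ratio(cells$price_ratio[i], 1, cells$complexity[i]),
    numeric(1))
  lab <- character(nrow(cells))
  scale <- pmax(cells$hit_ratio, boundary_at)
  on_boundary <- abs(cells$hit_ratio - boundary_at) <= .equiv_rtol * scale
  lab[cells$hit_ratio > boundary_at] <- "B"
  lab[cells$hit_ratio < boundary_at] <- "A"
  lab[on_boundary] <- "equivalent"
  lab[cells$hit_ratio < 1] <- "infeasible"
  cells$label <- lab

  boundary <- do.call(rbind, lapply(complexities, function(cc)
    data.frame(complexity = cc, price_ratio = rp,
               hit_ratio = vapply(rp, equivalence_hit_ratio, numeric(1),
                                  price_A = 1, complexity = cc))))

  structure(cells,
            class = c("strategy_partition", "data.frame"),
            price_ratio = rp, hit_ratio = rv,
            complexities = complexities,
            boundary = boundary)
}

#' @export
print.strategy_partition <- function(x, ...) {
  rp <- attr(x, "price_ratio"); rv <- attr(x, "hit_ratio")
  cat(sprintf(
    "Strategy partition: %d x %d grid, P_B/P_A in [%g, %g], v_B/v in [%g, %g]\n",
    length(rp), length(rv), min(rp), max(rp), min(rv), max(rv)))
  cat("complexities:", paste(attr(x, "complexities"), collapse = ", "), "\n")
  tab <- table(x$complexity, x$label)
  print(tab)
  invisible(x)
}

#' Plot a strategy partition
#'
#' Shades the feasible plane by favoured strategy for the first complexity
#' (dark: strategy B, light: strategy A) and overlays the equivalence curves
#' for every complexity in the grid.
#'
#' @param x A `"strategy_partition"`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.strategy_partition <- function(x, ...) {
  rp <- attr(x, "price_ratio"); rv <- attr(x, "hit_ratio")
  ccs <- attr(x, "complexities")
  first <- x[x$complexity == ccs[1], ]
  z <- matrix(NA_real_, nrow = length(rp), ncol = length(rv))
  code <- c(infeasible = 0, A = 1, equivalent = 1.5, B = 2)
  z[cbind(match(first$price_ratio, rp), match(first$hit_ratio, rv))] <-
    code[first$label]
  graphics::image(rp, rv, z, col = c("white", "grey85", "grey60", "grey40"),
                  breaks = c(-0.5, 0.5, 1.25, 1.75, 2.5),
                  xlab = expression(P[B] / P[A]),
                  ylab = expression(v[B] / v),
                  main = sprintf("Favoured extension strategy (c = %g)",
                                 ccs[1]), ...)
  bnd <- attr(x, "boundary")
  cols <- grDevices::hcl.colors(length(ccs), "Dark 3")
  for (i in seq_along(ccs)) {
    b <- bnd[bnd$complexity == ccs[i], ]
    graphics::lines(b$price_ratio, b$hit_ratio, lty = 3, lwd = 2,
                    col = cols[i])
  }
  graphics::legend("topleft", bty = "n", lty = 3, lwd = 2, col = cols,
                   legend = paste("c =", ccs))
  invisible(x)
}
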