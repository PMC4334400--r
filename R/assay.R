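#' Define a genetic assay
#'
#' An assay is characterised by its hit rate \eqn{v} -- the probability that
#' any given disease risk mutation lies within the loci the assay covers --
#' and its price \eqn{P} per case-unit. A case-unit is whatever sampling unit
#' is priced: a singleton case, or a parent-offspring trio in trio designs;
#' nothing downstream assumes family structure. Currency is an abstract
#' positive unit, since every decision quantity depends on price ratios only.
#'
#' @param name Character label, e.g. `"WES"`.
#' @param hit_rate Probability in \[0, 1\] that a risk mutation is covered.
#' @param price Price per case-unit, > 0, in arbitrary currency units.
#' @return An object of class `"assay"`: a list with elements `name`,
#'   `hit_rate`, `price`.
#' @examples
#' wes <- assay("WES", hit_rate = 0.27, price = 4)
#' chip <- assay("chip-CNV", hit_rate = 0.12, price = 1)
#' @seealso [assay_utility()], [combine_assays()], [disease_model()]
#' @export
assay <- function(name, hit_rate, price) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a single non-empty character string")
  check_hit_rate(hit_rate)
  check_price(price)
  structure(list(name = name, hit_rate = hit_rate, price = price),
            class = "assay")
}

#' @export
print.assay <- function(x, ...) {
  cat(sprintf("Assay %s: hit rate v = %g, price P = %g per case-unit\n",
              x$name, x$hit_rate, x$price))
  invisible(x)
}

#' Define a disease model
#'
#' The disease model is a single parameter: the complexity \eqn{c}, the
#' number of risk mutations that must jointly be present to cause the disease
#' in one case (the component causes of a sufficient cause). Integer values
#' are the typical use; any real \eqn{c \ge 1} is accepted, since all the
#' closed forms are well defined for real exponents and the decision
#' boundaries are usefully swept continuously in \eqn{c}.
#'
#' @param complexity Number of risk mutations per causal mechanism, >= 1.
#' @return An object of class `"disease_model"`.
#' @examples
#' disease_model(2)
#' @export
disease_model <- function(complexity) {
  check_complexity(complexity)
  structure(list(complexity = complexity), class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf("Disease model: complexity c = %g risk mutations per mechanism\n",
              x$complexity))
  invisible(x)
}

# -- parameter validation helpers (shared across modules) --------------------

check_hit_rate <- function(v, what = "hit_rate") {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1], got %s",
                 what, format(v)))
  invisible(v)
}

check_price <- function(p, what = "price") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0)
    stop(sprintf("'%s' must be a single positive number, got %s",
                 what, format(p)))
  invisible(p)
}

check_complexity <- function(c, what = "complexity") {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 1)
    stop(sprintf("'%s' must be a single number >= 1, got %s",
                 what, format(c)))
  invisible(c)
}

# Accept an assay object or coerce from (hit_rate, price) fields of a list.
as_assay <- function(x) {
  if (inherits(x, "assay")) return(x)
  if (is.list(x) && all(c("name", "hit_rate", "price") %in% names(x)))
    return(assay(x$name, x$hit_rate, x$price))
  stop("expected an 'assay' object or a list with name, hit_rate, price")
}

as_complexity <- function(x) {
  if (inherits(x, "disease_model")) return(x$complexity)
  check_complexity(x)
  x
}

#' Per-case discoverability of a complete disease mechanism
#'
#' Probability \eqn{d = v^c} that all \eqn{c} risk mutations of a case lie
#' within the assayed loci, under the rare-disease assumptions that causal
#' mutations do not overlap across cases and each case carries exactly
#' \eqn{c} of them, each covered independently with probability \eqn{v}.
#'
#' @param hit_rate Assay hit rate \eqn{v} in \[0, 1\].
#' @param complexity Disease complexity \eqn{c \ge 1} (or a
#'   [disease_model()]).
#' @return Probability in \[0, 1\].
#' @examples
#' discoverability(0.27, 2)  # 0.0729
#' @export
discoverability <- function(hit_rate, complexity) {
  check_hit_rate(hit_rate)
  complexity <- as_complexity(complexity)
  hit_rate^complexity
}

#' Expected number of completely observed disease mechanisms
#'
#' \eqn{E[m] = n v^c}: the mean of the binomial count of cases whose full
#' causal mechanism is observed, over \eqn{n} assayed case-units.
#'
#' @param n Number of case-units assayed, >= 0.
#' @inheritParams discoverability
#' @return Expected count (non-negative real).
#' @examples
#' expected_mechanisms(4, 0.27, 2)   # 0.2916, the exome-sequencing arm
#' expected_mechanisms(16, 0.12, 2)  # 0.2304, the chip-genotyping arm
#' @export
expected_mechanisms <- function(n, hit_rate, complexity) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("'n' must be a single non-negative number")
  n * discoverability(hit_rate, complexity)
}

#' Distribution of the number of completely observed mechanisms
#'
#' The count \eqn{m} of cases whose complete mechanism is observed is
#' binomial, \eqn{m \sim Bin(n, d)} with \eqn{d = v^c}. Returns the full
#' distribution over the support \eqn{0..n} together with its analytic mean.
#'
#' @param n Integer number of case-units assayed, >= 0.
#' @inheritParams discoverability
#' @return An object of class `"mechanism_distribution"`: list with `n`, `d`,
#'   `mean`, and vectors `pmf` / `cdf` over counts `0:n`.
#' @examples
#' md <- mechanism_distribution(4, 0.27, 2)
#' md$mean                    # 0.2916
#' prob_at_least(md, 1)       # chance of seeing at least one mechanism
#' @seealso [prob_at_least()]
#' @export
mechanism_distribution <- function(n, hit_rate, complexity) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != round(n))
    stop("'n' must be a single non-negative integer")
  n <- as.integer(n)
  d <- discoverability(hit_rate, complexity)
  support <- 0:n
  structure(list(
    n = n, d = d,
    mean = n * d,
    support = support,
    pmf = stats::dbinom(support, size = n, prob = d),
    cdf = stats::pbinom(support, size = n, prob = d)
  ), class = "mechanism_distribution")
}

#' @export
print.mechanism_distribution <- function(x, ...) {
  cat(sprintf(
    "Completely observed mechanisms: m ~ Bin(n = %d, d = %.6g), E[m] = %.4g\n",
    x$n, x$d, x$mean))
  cat(sprintf("P(m >= 1) = %.4g\n", prob_at_least(x, 1)))
  invisible(x)
}

#' @export
mean.mechanism_distribution <- function(x, ...) x$mean

#' Upper-tail probability of the mechanism count
#'
#' \eqn{P(m \ge k)} for a [mechanism_distribution()]; e.g. the chance a study
#' observes at least one complete disease mechanism.
#'
#' @param dist A `"mechanism_distribution"` object.
#' @param k Integer threshold, 0 <= k.
#' @return Probability.
#' @export
prob_at_least <- function(dist, k) {
  stopifnot(inherits(dist, "mechanism_distribution"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k != round(k))
    stop("'k' must be a single non-negative integer")
  if (k == 0) return(1)
  stats::pbinom(k - 1, size = dist$n, prob = dist$d, lower.tail = FALSE)
}

#' Cost-effectiveness (utility) of an assay
#'
#' \eqn{U = E[m] / (nP) = v^c / P}: expected completely observed mechanisms
#' per currency unit spent. Independent of the sample size, so it ranks
#' assays for any budget. Only ratios of utilities are meaningful across
#' currencies.
#'
#' @param assay An [assay()] (or list with `hit_rate` and `price`).
#' @param disease A [disease_model()] or bare complexity value.
#' @return Utility in expected mechanisms per currency unit.
#' @examples
#' assay_utility(assay("WES", 0.27, 4), disease_model(2))  # 0.018225
#' @export
assay_utility <- function(assay, disease) {
  assay <- as_assay(assay)
  complexity <- as_complexity(disease)
  discoverability(assay$hit_rate, complexity) / assay$price
}

#' Price ratio at which two assays are equally cost-effective
#'
#' Setting the utilities of two assays equal gives
#' \eqn{P_2 / P_1 = (v_2 / v_1)^c}: the maximum price multiple at which the
#' second assay remains at least as cost-effective as the first. E.g. with
#' genome sequencing at four times the price of exome sequencing, a hit-rate
#' ratio of 2 makes the two break even exactly at complexity 2, and the
#' dearer assay wins for any higher complexity.
#'
#' @param hit_rate_1 Hit rate of the reference assay, > 0.
#' @param hit_rate_2 Hit rate of the comparison assay.
#' @param complexity Disease complexity \eqn{c \ge 1}.
#' @return The breakeven price ratio \eqn{P_2 / P_1}.
#' @examples
#' equivalent_price_ratio(0.27, 0.54, 2)  # 4: twice the hit rate is worth 4x
#' @export
equivalent_price_ratio <- function(hit_rate_1, hit_rate_2, complexity) {
  check_hit_rate(hit_rate_1, "hit_rate_1")
  check_hit_rate(hit_rate_2, "hit_rate_2")
  complexity <- as_complexity(complexity)
  if (hit_rate_1 == 0)
    stop("'hit_rate_1' must be positive: the reference assay covers nothing")
  (hit_rate_2 / hit_rate_1)^complexity
}

#' Combine several assays into one composite assay
#'
#' Running a set of assays on the same case-unit acts as a single assay whose
#' hit rate is the summed hit rate minus any shared coverage, and whose price
#' is the summed price. With `overlap = 0` (the default) hit rates are purely
#' additive -- the assumption appropriate when the assays cover disjoint
#' mutation classes, e.g. exome point mutations plus chip-detected copy-number
#' variants. `overlap` is a single probability mass subtracted from the sum;
#' no finer model of shared coverage is attempted.
#'
#' @param assays A list of [assay()] objects (length >= 1).
#' @param overlap Probability mass of coverage shared among the assays,
#'   subtracted from the summed hit rates. Default 0.
#' @param name Name for the composite; default joins the parts with `"+"`.
#' @return An [assay()] with the combined hit rate and price.
#' @examples
#' combine_assays(list(assay("WES", 0.27, 4), assay("chip-CNV", 0.12, 1)))
#' @export
combine_assays <- function(assays, overlap = 0, name = NULL) {
  if (!is.list(assays) || length(assays) < 1L)
    stop("'assays' must be a non-empty list of assay objects")
  if (inherits(assays, "assay")) assays <- list(assays)
  assays <- lapply(assays, as_assay)
  if (!is.numeric(overlap) || length(overlap) != 1L || is.na(overlap) ||
      overlap < 0)
    stop("'overlap' must be a single non-negative probability mass")
  v <- sum(vapply(assays, `[[`, numeric(1), "hit_rate")) - overlap
  if (v < 0 || v > 1)
    stop(sprintf(
      "infeasible combination: combined hit rate %.4g is outside [0, 1]", v))
  if (is.null(name))
    name <- paste(vapply(assays, `[[`, character(1), "name"), collapse = "+")
  assay(name, hit_rate = v,
        price = sum(vapply(assays, `[[`, numeric(1), "price")))
}

# Display rounding that never uses round-half-to-even: reports in this field
# quote 2-dp figures and half-way cases must round away from zero.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
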