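#' Number of case-units affordable under a budget
#'
#' `floor(budget / price)`: whole case-units only; any remainder is reported
#' by [evaluate_design()] as leftover budget.
#'
#' @param budget Available funds, >= 0, in the same currency as `price`.
#' @param price Price per case-unit, > 0.
#' @return Integer count of affordable case-units.
#' @examples
#' affordable_sample_size(16, 4)  # 4 exome-sequenced trios
#' affordable_sample_size(16, 1)  # 16 chip-genotyped trios
#' @export
affordable_sample_size <- function(budget, price) {
  if (!is.numeric(budget) || length(budget) != 1L || is.na(budget) ||
      budget < 0)
    stop("'budget' must be a single non-negative number")
  check_price(price)
  as.integer(floor(budget / price))
}

#' Evaluate one assay against a fixed budget
#'
#' Resolves a (budget, assay, disease) triple into the affordable sample size
#' n, per-case discoverability d = v^c, expected yield E\[m\] = n v^c, and
#' utility U = v^c / P.
#'
#' @param budget Available funds, >= 0.
#' @param assay An [assay()].
#' @param disease A [disease_model()] or bare complexity.
#' @return An object of class `"design_evaluation"`: list with `assay`, `n`,
#'   `discoverability`, `expected_yield`, `utility`, `budget_spent`,
#'   `budget_left`.
#' @examples
#' evaluate_design(16, assay("WES", 0.27, 4), disease_model(2))
#' @export
evaluate_design <- function(budget, assay, disease) {
  assay <- as_assay(assay)
  complexity <- as_complexity(disease)
  n <- affordable_sample_size(budget, assay$price)
  d <- discoverability(assay$hit_rate, complexity)
  structure(list(
    assay = assay,
    complexity = complexity,
    n = n,
    discoverability = d,
    expected_yield = n * d,
    utility = d / assay$price,
    budget_spent = n * assay$price,
    budget_left = budget - n * assay$price
  ), class = "design_evaluation")
}

#' @export
print.design_evaluation <- function(x, digits = 2, ...) {
  cat(sprintf("Design: %d x %s (c = %g)\n", x$n, x$assay$name, x$complexity))
  cat(sprintf("  E[m] = %s expected complete mechanisms (%.6g full precision)\n",
              format(round_half_up(x$expected_yield, digits)),
              x$expected_yield))
  cat(sprintf("  utility U = v^c / P = %.6g per currency unit\n", x$utility))
  if (x$budget_left > 0)
    cat(sprintf("  leftover budget: %g\n", x$budget_left))
  invisible(x)
}

#' Rank an assay catalog by cost-effectiveness under a fixed budget
#'
#' Evaluates every assay in the catalog at the given budget and disease
#' complexity and ranks by utility \eqn{U = v^c / P} (descending), with ties
#' broken by lower price, then name. Because n is the integer number of
#' affordable case-units, ranking by realised expected yield n v^c can
#' disagree with the utility ranking when a budget does not divide evenly;
#' any disagreement is flagged on the returned object.
#'
#' @param budget Available funds, >= 0.
#' @param catalog A non-empty list of [assay()] objects, or an
#'   `"assay_catalog"` from [load_catalog()].
#' @param disease A [disease_model()] or bare complexity.
#' @return An object of class `"design_ranking"`: a data frame with one row
#'   per assay (columns `assay`, `hit_rate`, `price`, `n`, `discoverability`,
#'   `expected_yield`, `utility`, `budget_left`), sorted by utility, with
#'   attributes `budget`, `complexity`, `yield_ratio` (full-precision and
#'   2-dp pairwise ratio of the top two expected yields) and
#'   `rank_disagreement`.
#' @examples
#' cat2 <- list(assay("WES", 0.27, 4), assay("chip-CNV", 0.12, 1))
#' rank_assays(16, cat2, disease_model(2))
#' @export
rank_assays <- function(budget, catalog, disease) {
  if (!is.list(catalog) || length(catalog) == 0L)
    stop("'catalog' must be a non-empty list of assays")
  if (inherits(catalog, "assay")) catalog <- list(catalog)
  evals <- lapply(catalog, function(a) evaluate_design(budget, a, disease))
  df <- data.frame(
    assay = vapply(evals, function(e) e$assay$name, character(1)),
    hit_rate = vapply(evals, function(e) e$assay$hit_rate, numeric(1)),
    price = vapply(evals, function(e) e$assay$price, numeric(1)),
    n = vapply(evals, function(e) e$n, integer(1)),
    discoverability = vapply(evals, function(e) e$discoverability, numeric(1)),
    expected_yield = vapply(evals, function(e) e$expected_yield, numeric(1)),
    utility = vapply(evals, function(e) e$utility, numeric(1)),
    budget_left = vapply(evals, function(e) e$budget_left, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-df$utility, df$price, df$assay)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL

  yield_ord <- order(-df$expected_yield, df$price, df$assay)
  rank_disagreement <- !identical(yield_ord, seq_len(nrow(df)))

  yield_ratio <- NULL
  if (nrow(df) >= 2L && df$expected_yield[2L] > 0) {
    top2 <- round_half_up(df$expected_yield[1:2], 2)
    yield_ratio <- list(
      full = df$expected_yield[1L] / df$expected_yield[2L],
      rounded_2dp = if (top2[2L] > 0)
        round_half_up(top2[1L] / top2[2L], 2) else NA_real_
    )
  }

  structure(df,
            class = c("design_ranking", "data.frame"),
            budget = budget,
            complexity = as_complexity(disease),
            yield_ratio = yield_ratio,
            rank_disagreement = rank_disagreement)
}

#' @export
print.design_ranking <- function(x, digits = 2, ...) {
  cat(sprintf("Assay ranking at budget %g, complexity c = %g\n\n",
              attr(x, "budget"), attr(x, "complexity")))
  shown <- as.data.frame(x)
  shown$discoverability <- signif(shown$discoverability, 4)
  shown$expected_yield <- round_half_up(shown$expected_yield, digits)
  shown$utility <- signif(shown$utility, 4)
  print(shown, row.names = FALSE)
  yr <- attr(x, "yield_ratio")
  if (!is.null(yr)) {
    top2 <- round_half_up(x$expected_yield[1:2], digits)
    cat(sprintf(
      "\n%s yields %g%% more expected mechanisms than %s (%s/%s = %s; full precision %.4g)\n",
      x$assay[1L], round_half_up(100 * (yr$rounded_2dp - 1), 0), x$assay[2L],
      format(top2[1L]), format(top2[2L]), format(yr$rounded_2dp), yr$full))
  }
  if (isTRUE(attr(x, "rank_disagreement")))
    cat("\nNote: ranking by realised expected yield (integer n) disagrees",
        "with the utility ranking; leftover budget differs across assays.\n")
  invisible(x)
}

#' @export
summary.design_ranking <- function(object, ...) {
  cat(sprintf("Best assay: %s (utility %.6g, E[m] = %.4g at n = %d)\n",
              object$assay[1L], object$utility[1L],
              object$expected_yield[1L], object$n[1L]))
  invisible(object)
}
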