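#' Simulate the generative model of mechanism discovery
#'
#' Simulates the assumptions behind the closed forms directly: each of
#' `n_cases` cases carries `complexity` private risk mutations (no overlap
#' across cases), and each mutation independently falls inside the assayed
#' loci with probability `hit_rate`. A case's complete disease mechanism is
#' observed only when all of its mutations are captured. The per-replicate
#' count `m` of such cases is the empirical counterpart of the
#' Bin(n, v^c) model and its mean estimates \eqn{n v^c}, so the simulator is
#' an independent check on every closed form in the package.
#'
#' Optionally, a fraction `prop_extra` of cases carries one additional causal
#' mutation (complexity c + 1), probing the direction and size of the bias
#' incurred by treating \eqn{d = v^c} as exact; off by default, as the
#' proportion of such cases is negligible for rare diseases.
#'
#' @param n_cases Number of cases per replicate, >= 0 integer.
#' @param hit_rate Assay hit rate \eqn{v} in \[0, 1\].
#' @param complexity Integer disease complexity \eqn{c \ge 1}; the simulator
#'   draws whole mutations, so real-valued c is not supported here.
#' @param n_replicates Number of replicate studies, >= 1. Default 1e5, small
#'   enough to run in seconds yet giving a standard error fine enough to
#'   resolve example-scale differences.
#' @param seed Optional integer; fixes the whole output stream.
#' @param prop_extra Proportion of cases carrying one extra causal mutation.
#'   Default 0 (the exact-c model).
#' @return An object of class `"assay_simulation"`: list with the integer
#'   vector `m` of per-replicate counts and summaries `mean`, `var`, `se`
#'   (standard error of the mean), plus the configuration.
#' @examples
#' sim <- simulate_study(4, 0.27, 2, n_replicates = 1e4, seed = 1)
#' sim$mean                       # close to 4 * 0.27^2 = 0.2916
#' @seealso [simulate_extension()], [mechanism_distribution()]
#' @export
simulate_study <- function(n_cases, hit_rate, complexity,
                           n_replicates = 1e5, seed = NULL,
                           prop_extra = 0) {
  if (!is.numeric(n_cases) || length(n_cases) != 1L || is.na(n_cases) ||
      n_cases < 0 || n_cases != round(n_cases))
    stop("'n_cases' must be a single non-negative integer")
  check_hit_rate(hit_rate)
  check_complexity(complexity)
  if (complexity != round(complexity) || is.infinite(complexity))
    stop("'complexity' must be a finite integer for simulation")
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      n_replicates < 1 || n_replicates != round(n_replicates))
    stop("'n_replicates' must be a single integer >= 1")
  if (!is.numeric(prop_extra) || length(prop_extra) != 1L ||
      is.na(prop_extra) || prop_extra < 0 || prop_extra > 1)
    stop("'prop_extra' must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_cases <- as.integer(n_cases)
  n_replicates <- as.integer(n_replicates)

  m <- draw_mechanism_counts(n_cases, hit_rate, as.integer(complexity),
                             n_replicates, prop_extra)
  structure(list(
    n_cases = n_cases, hit_rate = hit_rate,
    complexity = as.integer(complexity),
    n_replicates = n_replicates, seed = seed, prop_extra = prop_extra,
    m = m,
    mean = mean(m),
    var = stats::var(m),
    se = stats::sd(m) / sqrt(n_replicates)
  ), class = "assay_simulation")
}

# One draw of m per replicate: per case, count how many of its c (or c+1)
# causal mutations the assay captures; the case counts iff all are captured.
draw_mechanism_counts <- function(n_cases, hit_rate, complexity,
                                  n_replicates, prop_extra) {
  if (n_cases == 0L) return(integer(n_replicates))
  total <- n_cases * n_replicates
  n_mut <- complexity + stats::rbinom(total, 1L, prop_extra)
  captured <- stats::rbinom(total, n_mut, hit_rate)
  complete <- as.integer(captured == n_mut)
  as.integer(colSums(matrix(complete, nrow = n_cases)))
}

#' @export
print.assay_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated %d studies of %d cases (v = %g, c = %d%s)\n",
    x$n_replicates, x$n_cases, x$hit_rate, x$complexity,
    if (x$prop_extra > 0)
      sprintf(", %.3g of cases carry an extra mutation", x$prop_extra)
    else ""))
  analytic <- x$n_cases * x$hit_rate^x$complexity
  cat(sprintf("  mean m = %.4f (SE %.4f); analytic n v^c = %.4f\n",
              x$mean, x$se, analytic))
  cat(sprintf("  var m  = %.4f; binomial n d (1 - d) = %.4f\n",
              x$var, analytic * (1 - x$hit_rate^x$complexity)))
  invisible(x)
}

#' Simulate both extension strategies on a common random stream
#'
#' Runs the generative simulation for strategy A (\eqn{n_A} cases at the
#' original hit rate) and strategy B (the original n cases at the augmented
#' hit rate \eqn{v_B}) from a single seeded random stream, and summarises the
#' paired difference in yields.
#'
#' @param scenario An [extension_scenario()].
#' @param n_replicates Replicate studies per strategy. Default 1e5.
#' @param seed Optional integer seed for the common stream.
#' @param continuous_n Passed to [extension_yields()] to determine
#'   \eqn{n_A}; the simulator needs whole cases, so a continuous \eqn{n_A}
#'   is rounded down with a warning.
#' @return An object of class `"extension_simulation"`: list with the two
#'   `"assay_simulation"` results `A` and `B`, the per-replicate yield
#'   difference summary (`diff_mean`, `diff_se`), and the analytic verdict.
#' @examples
#' sc <- extension_scenario(n = 4, hit_rate = 0.27, price_A = 4, price_B = 1,
#'                          complexity = 2, extra_hit_rate = 0.12)
#' simulate_extension(sc, n_replicates = 1e4, seed = 1)
#' @export
simulate_extension <- function(scenario, n_replicates = 1e5, seed = NULL,
                               continuous_n = FALSE) {
  stopifnot(inherits(scenario, "extension_scenario"))
  verdict <- extension_yields(scenario, continuous_n = continuous_n)
  n_A <- verdict$n_A
  if (n_A != floor(n_A)) {
    warning("rounding continuous n_A down to whole cases for simulation")
    n_A <- floor(n_A)
  }
  if (!is.null(seed)) set.seed(seed)
  sim_A <- simulate_study(n_A, scenario$hit_rate, scenario$complexity,
                          n_replicates = n_replicates)
  sim_B <- simulate_study(scenario$n, scenario$augmented_hit_rate,
                          scenario$complexity, n_replicates = n_replicates)
  d <- sim_B$m - sim_A$m
  structure(list(
    A = sim_A, B = sim_B,
    diff_mean = mean(d),
    diff_se = stats::sd(d) / sqrt(n_replicates),
    verdict = verdict
  ), class = "extension_simulation")
}

#' @export
print.extension_simulation <- function(x, ...) {
  cat("Paired simulation of extension strategies\n")
  cat(sprintf("  A: mean m = %.4f (SE %.4f), analytic %.4f\n",
              x$A$mean, x$A$se, x$verdict$yield_A))
  cat(sprintf("  B: mean m = %.4f (SE %.4f), analytic %.4f\n",
              x$B$mean, x$B$se, x$verdict$yield_B))
  cat(sprintf("  empirical yield difference (B - A): %.4f (SE %.4f)\n",
              x$diff_mean, x$diff_se))
  cat(sprintf("  analytic favoured strategy: %s\n", x$verdict$favoured))
  invisible(x)
}
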