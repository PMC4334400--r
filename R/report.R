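#' Render a result object as a serialized report
#'
#' Serializes any of the package's result objects deterministically:
#' `"json"` carries full numeric precision (no rounding), `"tsv"` is the
#' object's tabular form, and `"text"` is the object's printed summary,
#' which rounds for display only. Identical inputs always produce identical
#' output strings.
#'
#' @param results A result object (`design_ranking`, `design_evaluation`,
#'   `strategy_verdict`, `strategy_partition`, `assay_simulation`,
#'   `extension_simulation`, `assay_catalog`) or a plain data frame / list.
#' @param format One of `"tsv"`, `"json"`, `"text"`.
#' @return A single character string, the serialized report.
#' @examples
#' rk <- rank_assays(16, list(assay("WES", 0.27, 4), assay("chip", 0.12, 1)), 2)
#' cat(render_report(rk, "tsv"))
#' @seealso [write_report()]
#' @export
render_report <- function(results, format = c("tsv", "json", "text")) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("unknown report format: use tsv, json or text"))
  switch(format,
    text = paste(utils::capture.output(print(results)), collapse = "\n"),
    tsv = {
      df <- as.data.frame(report_table(results))
      tc <- textConnection("out", "w", local = TRUE)
      utils::write.table(df, tc, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(tc)
      paste0(paste(out, collapse = "\n"), "\n")
    },
    json = jsonlite::toJSON(report_body(results), auto_unbox = TRUE,
                            digits = NA, pretty = TRUE, null = "null")
  )
}

#' Write a rendered report to a file
#'
#' @inheritParams render_report
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json", "text")) {
  writeLines(render_report(results, format), path)
  invisible(path)
}

# Tabular view of each result type, used for TSV export.
report_table <- function(x) UseMethod("report_table")

#' @export
report_table.data.frame <- function(x) x

#' @export
report_table.assay_catalog <- function(x) as.data.frame(x)

#' @export
report_table.design_evaluation <- function(x) {
  data.frame(assay = x$assay$name, hit_rate = x$assay$hit_rate,
             price = x$assay$price, complexity = x$complexity, n = x$n,
             discoverability = x$discoverability,
             expected_yield = x$expected_yield, utility = x$utility,
             budget_left = x$budget_left, stringsAsFactors = FALSE)
}

#' @export
report_table.strategy_verdict <- function(x) {
  s <- x$scenario
  data.frame(
    n = s$n, hit_rate = s$hit_rate,
    augmented_hit_rate = s$augmented_hit_rate,
    complexity = s$complexity, price_A = s$price_A, price_B = s$price_B,
    budget = s$budget, n_A = x$n_A,
    yield_A = x$yield_A, yield_B = x$yield_B, favoured = x$favoured,
    breakeven_delta = as.numeric(x$breakeven_delta),
    breakeven_delta_infeasible = isTRUE(attr(x$breakeven_delta,
                                             "infeasible")),
    breakeven_base_hit_rate = as.numeric(x$breakeven_base_hit_rate),
    breakeven_base_infeasible = isTRUE(attr(x$breakeven_base_hit_rate,
                                            "infeasible")),
    stringsAsFactors = FALSE)
}

#' @export
report_table.assay_simulation <- function(x) {
  data.frame(n_cases = x$n_cases, hit_rate = x$hit_rate,
             complexity = x$complexity, n_replicates = x$n_replicates,
             prop_extra = x$prop_extra, mean_m = x$mean, var_m = x$var,
             se_mean = x$se,
             analytic_mean = x$n_cases * x$hit_rate^x$complexity,
             stringsAsFactors = FALSE)
}

#' @export
report_table.extension_simulation <- function(x) {
  rbind(cbind(strategy = "A", report_table(x$A)),
        cbind(strategy = "B", report_table(x$B)))
}

#' @export
report_table.default <- function(x) as.data.frame(x)

# Structured view of each result type, used for JSON export. Attribute-laden
# data frames flatten to records plus a metadata block.
report_body <- function(x) UseMethod("report_body")

#' @export
report_body.default <- function(x) x

#' @export
report_body.design_ranking <- function(x) {
  list(budget = attr(x, "budget"), complexity = attr(x, "complexity"),
       yield_ratio = attr(x, "yield_ratio"),
       rank_disagreement = attr(x, "rank_disagreement"),
       ranking = as.data.frame(x))
}

#' @export
report_body.strategy_partition <- function(x) {
  list(price_ratio_grid = attr(x, "price_ratio"),
       hit_ratio_grid = attr(x, "hit_ratio"),
       complexities = attr(x, "complexities"),
       cells = as.data.frame(x),
       boundary = attr(x, "boundary"))
}

#' @export
report_body.strategy_verdict <- function(x) report_table(x)

#' @export
report_body.design_evaluation <- function(x) report_table(x)

#' @export
report_body.assay_simulation <- function(x) report_table(x)

#' @export
report_body.extension_simulation <- function(x) report_table(x)

#' @export
report_body.assay_catalog <- function(x) as.data.frame(x)
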