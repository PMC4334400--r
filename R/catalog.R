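#' Load an assay catalog from a YAML or JSON file
#'
#' The schema is a list of records `{name, hit_rate, price}`, either at the
#' top level or under a top-level `assays` key. Validation reports every
#' offending field; duplicate assay names are rejected.
#'
#' The package ships a default catalog
#' (`system.file("extdata", "assay_catalog.yaml", package = "assaychoice")`)
#' with chip-CNV, WES and WGS hit rates of 0.12, 0.27 and 0.62. These are
#' diagnostic rates observed for severe intellectual disability under the
#' respective assays; because those diagnoses reflect a disease of
#' complexity about 1, they are lower bounds on the assays' hit rates, and
#' should be replaced with disease-specific estimates where available.
#' Prices are in chip-units: WES at 4x and WGS at 16x the chip price.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` catalog file.
#' @return An object of class `"assay_catalog"`: a list of [assay()]
#'   objects.
#' @examples
#' path <- system.file("extdata", "assay_catalog.yaml",
#'                     package = "assaychoice")
#' load_catalog(path)
#' @export
load_catalog <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("catalog file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop("unsupported catalog format '.", ext, "': use YAML or JSON"))
  if (is.list(raw) && !is.null(raw$assays)) raw <- raw$assays
  if (!is.list(raw) || length(raw) == 0L)
    stop("catalog is empty: expected a list of {name, hit_rate, price} records")

  problems <- character(0)
  assays <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    rec <- raw[[i]]
    missing <- setdiff(c("name", "hit_rate", "price"), names(rec))
    if (length(missing)) {
      problems <- c(problems, sprintf("record %d: missing field(s) %s",
                                      i, paste(missing, collapse = ", ")))
      next
    }
    a <- tryCatch(assay(rec$name, rec$hit_rate, rec$price),
                  error = function(e)
                    sprintf("record %d (%s): %s", i,
                            if (is.character(rec$name)) rec$name else "?",
                            conditionMessage(e)))
    if (is.character(a)) problems <- c(problems, a) else assays[[i]] <- a
  }
  if (length(problems))
    stop("invalid catalog:\n  ", paste(problems, collapse = "\n  "))
  nms <- vapply(assays, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate assay names in catalog: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  structure(assays, class = c("assay_catalog", "list"))
}

#' Default bundled assay catalog
#'
#' Convenience wrapper around [load_catalog()] for the shipped catalog of
#' lower-bound hit rates (chip-CNV 0.12, WES 0.27, WGS 0.62).
#'
#' @return An `"assay_catalog"`.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "assay_catalog.yaml",
                           package = "assaychoice"))
}

#' @export
print.assay_catalog <- function(x, ...) {
  cat("Assay catalog (", length(x), " assays)\n", sep = "")
  for (a in x) print(a)
  invisible(x)
}

#' @export
as.data.frame.assay_catalog <- function(x, ...) {
  data.frame(
    name = vapply(x, `[[`, character(1), "name"),
    hit_rate = vapply(x, `[[`, numeric(1), "hit_rate"),
    price = vapply(x, `[[`, numeric(1), "price"),
    stringsAsFactors = FALSE
  )
}
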