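#' Convert a composition table between as-fed and dry-matter bases
#'
#' Feed composition tables are reported either per kg of feed as consumed
#' ("as-fed") or per kg of its dry matter. Conversion is a single common
#' rescaling: every energy or mass-fraction analyte is multiplied by
#' `100 / dm` going to the dry-matter basis and by `dm / 100` going back,
#' where `dm` is the dry-matter percentage of the sample. `dm` itself is
#' basis-free and is never rescaled, so the conversion preserves all ratios
#' between analytes and round-trips exactly.
#'
#' @param comp A data frame with a `basis` column (`"as_fed"` or
#'   `"dry_matter"`), a `dm` column (dry matter, percent, in `(0, 100]`),
#'   and any number of numeric analyte columns (e.g. `ge` in MJ/kg and
#'   mass fractions in percent). Non-numeric columns are carried through
#'   untouched.
#' @param target `"dry_matter"` or `"as_fed"`.
#'
#' @return A tibble with the same columns, analytes rescaled to `target`
#'   and `basis` set to it. Rows already on `target` are no-ops.
#' @examples
#' comp <- feedval_fixture("table6")
#' convert_basis(comp, "dry_matter")
#' @export
convert_basis <- function(comp, target = c("dry_matter", "as_fed")) {
  target <- match.arg(target)
  comp <- tibble::as_tibble(comp)
  if (!all(c("basis", "dm") %in% names(comp))) {
    abort("`comp` must have `basis` and `dm` columns.", class = "feedval_invalid_composition")
  }
  bad <- !is.finite(comp$dm) | comp$dm <= 0 | comp$dm > 100
  if (any(bad)) {
    abort(
      paste0("`dm` must lie in (0, 100]; offending rows: ",
             paste(which(bad), collapse = ", ")),
      class = "feedval_invalid_composition"
    )
  }
  if (!all(comp$basis %in% c("as_fed", "dry_matter"))) {
    abort("`basis` must be 'as_fed' or 'dry_matter'.", class = "feedval_invalid_composition")
  }
  full_scale <- if (target == "dry_matter") 100 / comp$dm else comp$dm / 100
  scale <- ifelse(comp$basis == target, 1, full_scale)
  value_cols <- setdiff(names(comp)[vapply(comp, is.numeric, logical(1))], "dm")
  comp <- dplyr::mutate(comp, dplyr::across(dplyr::all_of(value_cols), ~ .x * scale))
  comp$basis <- target
  comp
}

#' Summarize one analyte across samples
#'
#' Mean, range and coefficient of variation for a vector of analyte values
#' measured on several samples of the same ingredient class. The CV uses the
#' population standard deviation (denominator `n`) by default, which is the
#' convention the packaged reference tables follow; the sample convention
#' (`n - 1`) is available via `cv`.
#'
#' @param values Numeric vector, length at least 2.
#' @param cv `"population"` (default) or `"sample"` standard deviation in the
#'   CV numerator.
#' @return One-row tibble: `n`, `mean`, `min`, `max`, `cv_pct`.
#' @examples
#' summarize_analyte(c(18.16, 18.07, 17.74))
#' @export
summarize_analyte <- function(values, cv = c("population", "sample")) {
  cv <- match.arg(cv)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    abort("At least 2 non-missing values are needed.", class = "feedval_insufficient_data")
  }
  m <- mean(values)
  if (m == 0) {
    abort("CV is undefined when the mean is 0.", class = "feedval_undefined_cv")
  }
  s <- if (cv == "population") sqrt(mean((values - m)^2)) else sd(values)
  tibble::tibble(n = n, mean = m, min = min(values), max = max(values),
                 cv_pct = 100 * s / m)
}

#' Variability summary of a composition table
#'
#' Applies [summarize_analyte()] to every numeric column of a composition
#' table (including `dm`), mirroring the Mean/CV columns of an ingredient
#' survey table.
#'
#' @param comp Composition data frame (one row per sample).
#' @param analytes Optional character vector restricting which columns are
#'   summarized; default all numeric columns.
#' @inheritParams summarize_analyte
#' @return Tibble with one row per analyte: `analyte`, `n`, `mean`, `min`,
#'   `max`, `cv_pct`.
#' @examples
#' summarize_composition(feedval_fixture("table6"))
#' @export
summarize_composition <- function(comp, analytes = NULL,
                                  cv = c("population", "sample")) {
  cv <- match.arg(cv)
  comp <- tibble::as_tibble(comp)
  num <- names(comp)[vapply(comp, is.numeric, logical(1))]
  if (is.null(analytes)) analytes <- num
  missing <- setdiff(analytes, names(comp))
  if (length(missing)) {
    abort(paste0("Unknown analytes: ", paste(missing, collapse = ", ")),
          class = "feedval_schema_error")
  }
  purrr::map_dfr(analytes, function(a) {
    dplyr::bind_cols(tibble::tibble(analyte = a),
                     summarize_analyte(comp[[a]], cv = cv))
  })
}
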