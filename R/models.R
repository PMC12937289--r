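#' Pearson correlation matrix with significance stars
#'
#' Pairwise Pearson correlations between the selected variables, with
#' two-sided p-values from the exact t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom, and a
#' star annotation. Two conventions are supported, matching the two table
#' styles in feed-evaluation reports:
#' \describe{
#'   \item{`"p05_p01"`}{`*` for 0.01 <= p < 0.05, `**` for p < 0.01.}
#'   \item{`"p10_p05"`}{`*` for 0.05 <= p < 0.10 (tendency), `**` for
#'     p < 0.05.}
#' }
#'
#' @param data Data frame with at least 3 complete rows.
#' @param vars Character vector of column names to correlate; default all
#'   numeric columns.
#' @param stars Star convention, see above.
#' @return An object of class `feedval_cor`: list with `r`, `p` and `stars`
#'   matrices, `n`, and the convention. Use [tidy()] for a long tibble or
#'   [autoplot()] for a heatmap.
#' @examples
#' correlate_variables(feedval_fixture("table6"), c("ge", "cp", "ash"))
#' @export
correlate_variables <- function(data, vars = NULL,
                                stars = c("p05_p01", "p10_p05")) {
  stars <- match.arg(stars)
  data <- tibble::as_tibble(data)
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort(paste0("Unknown variables: ", paste(missing, collapse = ", ")),
          class = "feedval_schema_error")
  }
  m <- as.matrix(data[stats::complete.cases(data[vars]), vars])
  n <- nrow(m)
  if (n < 3) abort("At least 3 complete rows are required.",
                   class = "feedval_insufficient_data")
  degenerate <- vars[apply(m, 2, function(x) var(x) == 0)]
  if (length(degenerate)) {
    abort(paste0("Zero-variance variable(s): ",
                 paste(degenerate, collapse = ", ")),
          class = "feedval_degenerate_variable")
  }
  r <- cor(m)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  diag(p) <- 0
  star <- matrix(star_label(p, stars), nrow = nrow(p), dimnames = dimnames(p))
  diag(star) <- ""
  structure(list(r = r, p = p, stars = star, n = n, convention = stars),
            class = "feedval_cor")
}

star_label <- function(p, convention) {
  if (convention == "p05_p01") {
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  } else {
    ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", ""))
  }
}

#' @export
print.feedval_cor <- function(x, digits = 2, ...) {
  cat("Pearson correlations (n = ", x$n, ", stars: ", x$convention, ")\n",
      sep = "")
  out <- matrix(paste0(formatC(x$r, format = "f", digits = digits),
                       ifelse(x$stars == "", "", " "), x$stars),
                nrow = nrow(x$r), dimnames = dimnames(x$r))
  out[upper.tri(out)] <- ""
  print(noquote(out))
  invisible(x)
}

#' @rdname correlate_variables
#' @param x A `feedval_cor` object.
#' @param ... Unused.
#' @export
tidy.feedval_cor <- function(x, ...) {
  vars <- colnames(x$r)
  expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::filter(match(.data$var1, vars) > match(.data$var2, vars)) |>
    dplyr::mutate(
      r = x$r[cbind(.data$var1, .data$var2)],
      p.value = x$p[cbind(.data$var1, .data$var2)],
      stars = x$stars[cbind(.data$var1, .data$var2)]
    )
}

#' Fit a linear prediction equation
#'
#' Ordinary least squares of a nutritional response (e.g. ingredient DE, or
#' the SID of an amino acid) on chemical-composition predictors, with the
#' diagnostics feed-evaluation tables report: \eqn{R^2}, the root mean
#' square error on residual degrees of freedom \eqn{n - k - 1}, and the
#' overall F-test p-value. The intercept is always included.
#'
#' @param data Data frame holding the response and predictors, typically
#'   ingredient-level means on the dry-matter basis.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names (>= 1).
#' @return An object of class `prediction_equation`: intercept, named
#'   `coefficients`, `r2`, `rmse`, `model_p`, `n`, plus the underlying data
#'   for plotting. Supports [tidy()], [glance()], [predict()] and
#'   [autoplot()].
#' @examples
#' comp <- convert_basis(feedval_fixture("table6"), "dry_matter")
#' comp$de <- 21 - 0.7 * comp$ash + rnorm(10, 0, 0.5)
#' fit_prediction_equation(comp, "de", "ash")
#' @export
fit_prediction_equation <- function(data, response, predictors) {
  data <- tibble::as_tibble(data)
  if (length(predictors) < 1) {
    abort("At least one predictor is required.", class = "feedval_config_error")
  }
  missing <- setdiff(c(response, predictors), names(data))
  if (length(missing)) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")),
          class = "feedval_schema_error")
  }
  d <- data[stats::complete.cases(data[c(response, predictors)]),
            c(response, predictors)]
  n <- nrow(d)
  k <- length(predictors)
  if (n <= k + 1) {
    abort("Need n > k + 1 observations.", class = "feedval_insufficient_data")
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- lm(fml, data = d)
  if (fit$rank < k + 1) {
    abort("Predictors are rank deficient (collinear).",
          class = "feedval_collinearity_error")
  }
  sse <- sum(fit$residuals^2)
  sst <- sum((d[[response]] - mean(d[[response]]))^2)
  r2 <- 1 - sse / sst
  rmse <- sqrt(sse / (n - k - 1))
  f <- (sst - sse) / k / (sse / (n - k - 1))
  model_p <- pf(f, k, n - k - 1, lower.tail = FALSE)
  structure(
    list(response = response,
         intercept = unname(coef(fit)[1]),
         coefficients = coef(fit)[-1],
         r2 = r2, rmse = rmse, model_p = model_p,
         n = n, k = k,
         fitted = unname(fit$fitted.values),
         observed = d[[response]],
         data = d),
    class = "prediction_equation"
  )
}

#' @export
print.prediction_equation <- function(x, digits = 2, ...) {
  terms <- paste0(
    ifelse(x$coefficients < 0, " - ", " + "),
    "(", formatC(abs(x$coefficients), format = "f", digits = digits),
    " x ", names(x$coefficients), ")", collapse = "")
  cat(x$response, " = ", formatC(x$intercept, format = "f", digits = digits),
      terms, "\n", sep = "")
  cat("R2 = ", formatC(x$r2, format = "f", digits = 2),
      ", RMSE = ", formatC(x$rmse, format = "f", digits = 2),
      ", p = ", format.pval(x$model_p, digits = 2),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @rdname fit_prediction_equation
#' @param x,object A `prediction_equation`.
#' @param ... Unused.
#' @export
tidy.prediction_equation <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname fit_prediction_equation
#' @export
glance.prediction_equation <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, rmse = x$rmse, p.value = x$model_p,
                 n = x$n, df.residual = x$n - x$k - 1)
}

#' @rdname fit_prediction_equation
#' @param newdata Data frame (dry-matter basis) with all predictor columns.
#' @export
predict.prediction_equation <- function(object, newdata, ...) {
  missing <- setdiff(names(object$coefficients), names(newdata))
  if (length(missing)) {
    abort(paste0("Missing predictor(s): ", paste(missing, collapse = ", ")),
          class = "feedval_schema_error")
  }
  vals <- as.matrix(tibble::as_tibble(newdata)[names(object$coefficients)])
  drop(object$intercept + vals %*% object$coefficients)
}

#' Equation selection by best subset or forward stepwise
#'
#' Develops candidate prediction equations for one response. The default
#' strategy fits every subset of the candidate predictors up to `max_terms`
#' terms and ranks the fits by \eqn{R^2} (descending) then RMSE
#' (ascending) — the literal reading of "maximize R2, minimize RMSE". Ties
#' are broken by fewer terms, then lexicographically on the term names. A
#' classical forward-stepwise selector with entry/stay p-value thresholds is
#' available for fidelity to conventional stepwise software.
#'
#' @param data Data frame with the response and candidates.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor names.
#' @param max_terms Maximum number of predictors per equation (default 2).
#' @param method `"best_subset"` (default) or `"forward"`.
#' @param p_enter,p_stay Entry/stay thresholds for `method = "forward"`
#'   (defaults 0.15, the conventional stepwise defaults).
#' @return Tibble ranked best-first: `rank`, `terms` (collapsed `+` string),
#'   `n_terms`, `r2`, `rmse`, `model_p`, and `equation` (list column of
#'   [fit_prediction_equation()] objects). For `"forward"`, the single
#'   selected model.
#' @export
select_equations <- function(data, response, candidates, max_terms = 2,
                             method = c("best_subset", "forward"),
                             p_enter = 0.15, p_stay = 0.15) {
  method <- match.arg(method)
  if (length(candidates) < 1) {
    abort("At least one candidate predictor is required.",
          class = "feedval_config_error")
  }
  if (method == "forward") {
    sel <- forward_stepwise(data, response, candidates, max_terms,
                            p_enter, p_stay)
    subsets <- list(sel)
  } else {
    subsets <- unlist(
      lapply(seq_len(min(max_terms, length(candidates))),
             function(sz) combn(sort(candidates), sz, simplify = FALSE)),
      recursive = FALSE)
  }
  fits <- purrr::map(subsets, function(terms) {
    tryCatch(fit_prediction_equation(data, response, terms),
             feedval_collinearity_error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  if (!length(fits)) {
    abort("No candidate subset could be fitted.", class = "feedval_config_error")
  }
  out <- tibble::tibble(
    terms = vapply(fits, function(f) paste(names(f$coefficients), collapse = " + "), ""),
    n_terms = vapply(fits, function(f) f$k, 0L),
    r2 = vapply(fits, function(f) f$r2, 0),
    rmse = vapply(fits, function(f) f$rmse, 0),
    model_p = vapply(fits, function(f) f$model_p, 0),
    equation = fits
  )
  out <- out[order(-out$r2, out$rmse, out$n_terms, out$terms), ]
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

# Conventional forward selection: add the predictor with the smallest
# partial-F p-value while it is below p_enter; drop any whose p rises
# above p_stay. Returns the selected term set.
forward_stepwise <- function(data, response, candidates, max_terms,
                             p_enter, p_stay) {
  current <- character(0)
  repeat {
    remaining <- setdiff(candidates, current)
    if (!length(remaining) || length(current) >= max_terms) break
    pvals <- vapply(remaining, function(cand) {
      partial_f_p(data, response, current, cand)
    }, 0)
    best <- names(which.min(pvals))
    if (pvals[best] >= p_enter) break
    current <- c(current, best)
    # backward check
    repeat {
      if (length(current) < 2) break
      drop_p <- vapply(current, function(term) {
        partial_f_p(data, response, setdiff(current, term), term)
      }, 0)
      worst <- names(which.max(drop_p))
      if (drop_p[worst] <= p_stay) break
      current <- setdiff(current, worst)
    }
  }
  if (!length(current)) {
    # fall back to the single best predictor so a model is always reported
    r2s <- vapply(candidates, function(cand) {
      fit_prediction_equation(data, response, cand)$r2
    }, 0)
    current <- names(which.max(r2s))
  }
  sort(current)
}

partial_f_p <- function(data, response, base_terms, new_term) {
  d <- tibble::as_tibble(data)
  d <- d[stats::complete.cases(d[c(response, base_terms, new_term)]), ]
  null_fml <- if (length(base_terms)) {
    stats::reformulate(base_terms, response = response)
  } else {
    stats::reformulate("1", response = response)
  }
  full <- lm(stats::reformulate(c(base_terms, new_term), response = response),
             data = d)
  null <- lm(null_fml, data = d)
  stats::anova(null, full)[2, "Pr(>F)"]
}
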