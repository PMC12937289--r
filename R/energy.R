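#' Diet digestible and metabolizable energy from balance records
#'
#' For each pig-period total-collection observation, digestible energy is
#' gross-energy intake minus fecal gross energy per kg of dry-matter intake,
#' and metabolizable energy additionally subtracts urinary gross energy:
#' \deqn{DE_d = (GE_i - GE_f)/F, \qquad ME_d = (GE_i - GE_f - GE_u)/F}
#' with \eqn{F} the feed intake (kg DM) over the collection window.
#'
#' @param records Data frame of balance records with columns
#'   `feed_intake_kg_dm` (> 0), `ge_intake_mj` (> 0), `fecal_ge_mj` and
#'   `urine_ge_mj` (both >= 0), in MJ over the window. Identifier columns
#'   (`pig_id`, `period`, `diet_id`, ...) are carried through.
#' @return The input tibble with `de_d`, `me_d` (MJ/kg DM) and
#'   `me_de_ratio_pct` appended. Fecal energy exceeding intake yields a
#'   negative digestibility: the value is returned with a warning, never
#'   clipped.
#' @examples
#' diet_energy(tibble::tibble(
#'   diet_id = "a", feed_intake_kg_dm = 5,
#'   ge_intake_mj = 100, fecal_ge_mj = 20, urine_ge_mj = 5
#' ))
#' @export
diet_energy <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("feed_intake_kg_dm", "ge_intake_mj", "fecal_ge_mj", "urine_ge_mj")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", ")),
          class = "feedval_schema_error")
  }
  if (any(records$feed_intake_kg_dm <= 0)) {
    abort("`feed_intake_kg_dm` must be > 0.", class = "feedval_invalid_record")
  }
  if (any(records$ge_intake_mj <= 0)) {
    abort("`ge_intake_mj` must be > 0.", class = "feedval_invalid_record")
  }
  if (any(records$fecal_ge_mj < 0) || any(records$urine_ge_mj < 0)) {
    abort("Fecal and urinary GE must be >= 0.", class = "feedval_invalid_record")
  }
  if (any(records$fecal_ge_mj > records$ge_intake_mj)) {
    warn("Fecal GE exceeds GE intake for some records; negative digestibility returned.")
  }
  dplyr::mutate(
    records,
    de_d = (.data$ge_intake_mj - .data$fecal_ge_mj) / .data$feed_intake_kg_dm,
    me_d = (.data$ge_intake_mj - .data$fecal_ge_mj - .data$urine_ge_mj) /
      .data$feed_intake_kg_dm,
    me_de_ratio_pct = 100 * .data$me_d / .data$de_d
  )
}

#' Correct basal-diet energy for its non-energy-supplying fraction
#'
#' The basal diet contributes energy only through its energy-supplying
#' ingredients (corn plus oil etc.), which make up a fraction
#' `energy_fraction` of the diet (default 0.97; minerals, premix and salt
#' supply none). The corrected basal values \eqn{DE_{dc} = DE_d / 0.97}
#' (and likewise ME) are what the difference method subtracts.
#'
#' @param e Numeric vector of diet energies (MJ/kg), or a data frame with
#'   `de_d`/`me_d` columns, in which case `de_dc`/`me_dc` are appended.
#' @param energy_fraction Proportion of energy-supplying ingredients in the
#'   basal diet, in `(0, 1]`.
#' @return Same shape as `e`, corrected.
#' @examples
#' correct_basal(13.41)
#' @export
correct_basal <- function(e, energy_fraction = 0.97) {
  if (!is.numeric(energy_fraction) || length(energy_fraction) != 1 ||
      energy_fraction <= 0 || energy_fraction > 1) {
    abort("`energy_fraction` must be a single number in (0, 1].",
          class = "feedval_config_error")
  }
  if (is.data.frame(e)) {
    for (col in intersect(c("de_d", "me_d"), names(e))) {
      e[[sub("_d$", "_dc", col)]] <- e[[col]] / energy_fraction
    }
    return(tibble::as_tibble(e))
  }
  e / energy_fraction
}

#' Ingredient energy by the difference (substitution) method
#'
#' A test diet replaces a fraction `x` of the basal diet's energy-supplying
#' portion with the test ingredient. Its energy is recovered by subtracting
#' the basal contribution:
#' \deqn{DE_{ing} = [DE_d - DE_{dc}(1 - x)]/x}
#' The relation is affine in the test-diet energy with slope `1/x`, so any
#' error in the diet measurement is amplified by `1/x`.
#'
#' @param test_de Numeric: test-diet energy (MJ/kg), vectorized.
#' @param basal_de_c Numeric: corrected basal energy on the same basis (see
#'   [correct_basal()]).
#' @param x Substitution fraction, strictly between 0 and 1 (default 0.30).
#' @return Ingredient energy, MJ/kg, same basis as the inputs.
#' @examples
#' ingredient_energy_by_difference(15.02, 13.824, x = 0.30)
#' @export
ingredient_energy_by_difference <- function(test_de, basal_de_c, x = 0.30) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 1) {
    abort("`x` must be a single fraction strictly between 0 and 1.",
          class = "feedval_invalid_substitution")
  }
  (test_de - basal_de_c * (1 - x)) / x
}

#' Per-observation ingredient energies from a balance trial
#'
#' Runs the full difference-method chain on a set of balance records:
#' per-observation diet DE/ME (kg DM basis), conversion to the as-fed basis
#' with the analyzed diet dry matter, correction of the basal diet by
#' `energy_fraction`, subtraction of the basal contribution at substitution
#' fraction `x`, and (when ingredient dry matter is supplied) conversion of
#' the ingredient values to its own dry-matter basis. The basal estimate is
#' the mean over all basal-diet observations.
#'
#' @param records Balance records (see [diet_energy()]) including
#'   observations on the basal diet.
#' @param diet_dm Data frame `diet_id`, `dm` — analyzed diet dry matter, %.
#' @param ingredient_dm Optional data frame `diet_id`, `dm` — dry matter of
#'   the ingredient fed in each test diet, %; enables the
#'   `de_ingredient_dm`/`me_ingredient_dm` columns.
#' @param basal_diet Identifier of the basal diet in `records`.
#' @param x Substitution fraction of the test ingredient (default 0.30).
#' @param energy_fraction See [correct_basal()].
#' @return Tibble of test-diet observations with diet energies (`de_d`,
#'   `me_d`, DM basis; `de_d_asfed`, `me_d_asfed`) and ingredient energies
#'   (`de_ingredient_asfed`, `me_ingredient_asfed`, and `_dm` variants when
#'   `ingredient_dm` is given). The basal estimate used is attached as the
#'   `"basal"` attribute.
#' @export
estimate_ingredient_energy <- function(records, diet_dm, ingredient_dm = NULL,
                                       basal_diet = "basal", x = 0.30,
                                       energy_fraction = 0.97) {
  en <- diet_energy(records)
  if (!basal_diet %in% en$diet_id) {
    abort(paste0("No observations for basal diet '", basal_diet, "'."),
          class = "feedval_missing_treatment")
  }
  en <- dplyr::left_join(en, dplyr::select(diet_dm, "diet_id", diet_dm_pct = "dm"),
                         by = "diet_id")
  if (any(is.na(en$diet_dm_pct))) {
    abort("Every diet in `records` needs a `diet_dm` entry.",
          class = "feedval_schema_error")
  }
  en <- dplyr::mutate(en,
                      de_d_asfed = .data$de_d * .data$diet_dm_pct / 100,
                      me_d_asfed = .data$me_d * .data$diet_dm_pct / 100)
  basal <- dplyr::filter(en, .data$diet_id == basal_diet)
  basal_c <- c(
    de_dc = correct_basal(mean(basal$de_d_asfed), energy_fraction),
    me_dc = correct_basal(mean(basal$me_d_asfed), energy_fraction)
  )
  out <- en |>
    dplyr::filter(.data$diet_id != basal_diet) |>
    dplyr::mutate(
      de_ingredient_asfed = ingredient_energy_by_difference(
        .data$de_d_asfed, basal_c[["de_dc"]], x),
      me_ingredient_asfed = ingredient_energy_by_difference(
        .data$me_d_asfed, basal_c[["me_dc"]], x)
    )
  if (!is.null(ingredient_dm)) {
    out <- dplyr::left_join(
      out, dplyr::select(ingredient_dm, "diet_id", ing_dm_pct = "dm"),
      by = "diet_id")
    if (any(is.na(out$ing_dm_pct))) {
      abort("Every test diet needs an `ingredient_dm` entry.",
            class = "feedval_schema_error")
    }
    out <- dplyr::mutate(
      out,
      de_ingredient_dm = .data$de_ingredient_asfed * 100 / .data$ing_dm_pct,
      me_ingredient_dm = .data$me_ingredient_asfed * 100 / .data$ing_dm_pct
    )
  }
  attr(out, "basal") <- basal_c
  out
}

#' Treatment means and pooled SEM
#'
#' Per-diet arithmetic means of one or more response columns, with a
#' standard error of the mean computed from the pooled residual standard
#' deviation: \eqn{SEM = s_{pooled}/\sqrt{n}} where
#' \eqn{s_{pooled}^2 = SSE/(N - g)} pools the within-diet variance across
#' all \eqn{g} diets and \eqn{n} is the replicate count of the diet.
#' Multiple-comparison letter groupings are deliberately not produced.
#'
#' @param data Data frame of per-observation results.
#' @param ... <[`tidy-select`][dplyr::select]> response columns to summarize.
#' @param group Grouping column (default `diet_id`).
#' @return Tibble: `diet_id` (or `group`), `measure`, `n`, `mean`, `sem`.
#' @examples
#' treatment_energy_summary(
#'   tibble::tibble(diet_id = c("a", "a", "b", "b"), de = c(1, 3, 2, 4)), de
#' )
#' @export
treatment_energy_summary <- function(data, ..., group = "diet_id") {
  data <- tibble::as_tibble(data)
  long <- data |>
    dplyr::select(dplyr::all_of(group), ...) |>
    tidyr::pivot_longer(-dplyr::all_of(group),
                        names_to = "measure", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  if (nrow(long) == 0) {
    abort("No observations to summarize.", class = "feedval_missing_treatment")
  }
  pooled <- long |>
    dplyr::group_by(.data$measure) |>
    dplyr::mutate(.gmean = stats::ave(.data$value, .data[[group]])) |>
    dplyr::summarise(
      sse = sum((.data$value - .data$.gmean)^2),
      df = dplyr::n() - dplyr::n_distinct(.data[[group]]),
      s_pooled = if (.data$df[1] > 0) sqrt(.data$sse / .data$df) else 0,
      .groups = "drop"
    )
  long |>
    dplyr::group_by(.data[[group]], .data$measure) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value), .groups = "drop") |>
    dplyr::left_join(dplyr::select(pooled, "measure", "s_pooled"), by = "measure") |>
    dplyr::mutate(sem = .data$s_pooled / sqrt(.data$n), s_pooled = NULL) |>
    dplyr::arrange(.data$measure, .data[[group]])
}
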