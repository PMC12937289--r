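#' Packaged reference tables
#'
#' Verbatim CSV copies of the reference study's printed tables, shipped
#' with the package: diet formulations and analyzed nutrients for both
#' experiments, the ten-sample ingredient composition survey (with minerals
#' and anti-nutritional factors), the treatment-mean energy table, and the
#' standardized ileal digestibility table with its basal endogenous-loss
#' column. The basal diet's own energy is not printed anywhere; the
#' `"basal_energy"` fixture is back-solved from the treatment means and is
#' flagged as synthetic in its file name and `source` column.
#'
#' @param name One of `"table2"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"table6"`, `"table7"`, `"table8"`, `"table9"`, `"table12"`,
#'   `"table12_iaa"`, `"basal_energy"`.
#' @return The parsed tibble.
#' @examples
#' feedval_fixture("table6")
#' @export
feedval_fixture <- function(name) {
  files <- c(
    table2 = "table2_diet_formulation_exp1.csv",
    table3 = "table3_diet_nutrients_exp1.csv",
    table4 = "table4_diet_formulation_exp2.csv",
    table5 = "table5_diet_amino_acids_exp2.csv",
    table6 = "table6_esbm_composition.csv",
    table7 = "table7_esbm_minerals.csv",
    table8 = "table8_esbm_anf.csv",
    table9 = "table9_energy_means.csv",
    table12 = "table12_sid.csv",
    table12_iaa = "table12_iaa.csv",
    basal_energy = "derived_basal_energy_synthetic.csv"
  )
  if (length(name) != 1 || !name %in% names(files)) {
    abort(paste0("Unknown fixture '", paste(name, collapse = ","),
                 "'. Available: ", paste(names(files), collapse = ", ")),
          class = "feedval_lookup_error")
  }
  path <- system.file("extdata", files[[name]], package = "feedval",
                      mustWork = TRUE)
  read_study_csv(path)
}

# Shared CSV ingestion: UTF-8, header row, Unicode minus / en-dash
# normalized to ASCII minus before parsing.
read_study_csv <- function(path) {
  txt <- readr::read_file(path)
  txt <- gsub("−|–", "-", txt)
  readr::read_csv(I(txt), show_col_types = FALSE, progress = FALSE)
}

#' Read and write study tables
#'
#' Thin CSV readers with schema checks for each record type the pipeline
#' consumes, and a matching writer. All files are UTF-8 CSV with a header
#' row; Unicode minus signs are normalized on ingest.
#'
#' @param path File path.
#' @return A tibble.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_composition <- function(path) {
  check_columns(read_study_csv(path), c("ingredient_id", "basis", "dm"))
}

#' @rdname study_io
#' @export
read_balance_records <- function(path) {
  check_columns(read_study_csv(path),
                c("pig_id", "period", "diet_id", "feed_intake_kg_dm",
                  "ge_intake_mj", "fecal_ge_mj", "urine_ge_mj"))
}

#' @rdname study_io
#' @export
read_digesta_records <- function(path) {
  check_columns(read_study_csv(path),
                c("pig_id", "period", "diet_id", "marker_mg_kg"))
}

#' @rdname study_io
#' @export
read_diet_profiles <- function(path) {
  check_columns(read_study_csv(path), c("diet_id", "dm", "marker_mg_kg"))
}

#' @rdname study_io
#' @param data Data frame to write.
#' @export
write_study_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

check_columns <- function(data, need) {
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "feedval_schema_error")
  }
  data
}

#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one list with the defaults
#' used throughout: substitution fraction 0.30, basal energy-supplying
#' fraction 0.97, population-SD coefficients of variation, regressions on
#' ingredient-level dry-matter means, endogenous losses used verbatim.
#'
#' @param substitution_x Substitution fraction of the test ingredient.
#' @param energy_fraction Energy-supplying fraction of the basal diet.
#' @param cv_denominator `"population"` or `"sample"`.
#' @param regression_unit `"ingredient_means"` or `"observations"`.
#' @param stars_energy,stars_sid Star conventions for the two correlation
#'   tables (see [correlate_variables()]).
#' @param iaa_scale_factor Multiplier on the endogenous-loss table.
#' @param seed Optional integer seed.
#' @return A named list of class `feedval_config`.
#' @export
feedval_config <- function(substitution_x = 0.30, energy_fraction = 0.97,
                           cv_denominator = c("population", "sample"),
                           regression_unit = c("ingredient_means", "observations"),
                           stars_energy = "p05_p01", stars_sid = "p10_p05",
                           iaa_scale_factor = 1, seed = NULL) {
  if (substitution_x <= 0 || substitution_x >= 1) {
    abort("`substitution_x` must be in (0, 1).", class = "feedval_config_error")
  }
  structure(list(
    substitution_x = substitution_x, energy_fraction = energy_fraction,
    cv_denominator = match.arg(cv_denominator),
    regression_unit = match.arg(regression_unit),
    stars_energy = stars_energy, stars_sid = stars_sid,
    iaa_scale_factor = iaa_scale_factor, seed = seed
  ), class = "feedval_config")
}

#' Rebuild the study's result tables from the packaged fixtures
#'
#' Drives the whole pipeline end to end on the packaged reference tables:
#' composition variability summaries, ingredient-energy grand means with
#' the cross-row difference-method consistency check, the
#' composition-energy correlation matrix, energy and SID prediction
#' equations, and the SID grand means. Optionally writes each result as a
#' CSV.
#'
#' @param out_dir Optional directory for CSV output.
#' @param config A [feedval_config()].
#' @return Named list of tibbles/objects: `composition_summary`,
#'   `mineral_summary`, `anf_summary`, `energy_summary`,
#'   `basal_consistency`, `energy_correlations`, `energy_equations`,
#'   `sid_summary`, `sid_correlations`, `sid_equations`.
#' @export
reproduce_tables <- function(out_dir = NULL, config = feedval_config()) {
  comp <- feedval_fixture("table6")
  cvd <- config$cv_denominator

  composition_summary <- summarize_composition(
    comp, setdiff(names(comp)[vapply(comp, is.numeric, logical(1))], NULL),
    cv = cvd)
  mineral_summary <- summarize_composition(feedval_fixture("table7"), cv = cvd)
  anf_summary <- summarize_composition(feedval_fixture("table8"), cv = cvd)

  t9 <- feedval_fixture("table9")
  energy_summary <- t9 |>
    dplyr::group_by(.data$item, .data$basis, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value), min = min(.data$value),
                     max = max(.data$value), .groups = "drop")
  basal_consistency <- difference_method_consistency(t9, config$substitution_x)

  # correlations and equations are computed from the DM-basis composition at
  # 2 decimals, the precision at which analyzed-composition tables are
  # reported (this is what makes the reference equations reproduce exactly)
  comp_dm <- convert_basis(comp, "dry_matter") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric) & !dplyr::all_of("dm"),
                                ~ round(.x, 2)))
  ing_dm <- t9 |>
    dplyr::filter(.data$item == "ingredient", .data$basis == "dry_matter",
                  .data$measure != "me_de_ratio") |>
    tidyr::pivot_wider(id_cols = "sample", names_from = "measure",
                       values_from = "value") |>
    dplyr::rename(ingredient_id = "sample")
  energy_data <- dplyr::inner_join(comp_dm, ing_dm, by = "ingredient_id")
  energy_correlations <- correlate_variables(
    energy_data, c("de", "me", "cp", "ee", "cf", "ndf", "adf", "ash", "ge"),
    stars = config$stars_energy)
  energy_candidates <- c("ge", "cp", "ash", "ee", "cf", "ndf", "adf")
  energy_equations <- dplyr::bind_rows(
    de = select_equations(energy_data, "de", energy_candidates, max_terms = 2),
    me = select_equations(energy_data, "me", energy_candidates, max_terms = 2),
    .id = "response")

  t12 <- feedval_fixture("table12") |>
    tidyr::pivot_longer(-"aa", names_to = "diet_id", values_to = "sid_pct")
  sid_summary <- sid_grand_means(t12)
  sid_wide <- t12 |>
    dplyr::filter(.data$aa %in% c("lys", "met", "trp", "thr", "val", "taa")) |>
    tidyr::pivot_wider(names_from = "aa", values_from = "sid_pct",
                       names_prefix = "sid_") |>
    dplyr::rename(ingredient_id = "diet_id")
  sid_data <- dplyr::inner_join(comp_dm, sid_wide, by = "ingredient_id")
  sid_correlations <- correlate_variables(
    sid_data, c("ash", "trp", paste0("sid_", c("lys", "met", "trp", "thr",
                                               "val", "taa"))),
    stars = config$stars_sid)
  sid_candidates <- c("trp", "ash", "cf", "adf", "cp", "ge")
  sid_equations <- purrr::map_dfr(
    c("sid_lys", "sid_met", "sid_trp", "sid_thr", "sid_val", "sid_taa"),
    function(resp) {
      dplyr::mutate(
        select_equations(sid_data, resp, sid_candidates, max_terms = 2),
        response = resp, .before = 1)
    })

  out <- list(
    composition_summary = composition_summary,
    mineral_summary = mineral_summary,
    anf_summary = anf_summary,
    energy_summary = energy_summary,
    basal_consistency = basal_consistency,
    energy_correlations = energy_correlations,
    energy_equations = energy_equations,
    sid_summary = sid_summary,
    sid_correlations = sid_correlations,
    sid_equations = sid_equations
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      obj <- out[[nm]]
      tbl <- if (inherits(obj, "feedval_cor")) {
        tidy(obj)
      } else if (is.data.frame(obj)) {
        dplyr::select(obj, -dplyr::any_of("equation"))
      } else {
        next
      }
      write_study_csv(tbl, file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  out
}

#' Cross-row consistency of the difference method
#'
#' Back-solves the corrected basal energy from every test-diet /
#' ingredient pair of an energy table,
#' \eqn{DE_{dc} = (DE_d - x \cdot DE_{ing})/(1 - x)}; if the printed diet
#' and ingredient values are mutually consistent, all rows must agree on
#' the same basal value.
#'
#' @param t9 Energy table in the layout of `feedval_fixture("table9")`.
#' @param x Substitution fraction.
#' @return Tibble: `measure`, `sample`, `basal_backsolved`, plus the
#'   across-row `spread` (max minus min) per measure.
#' @export
difference_method_consistency <- function(t9, x = 0.30) {
  wide <- t9 |>
    dplyr::filter(.data$basis == "as_fed", .data$measure %in% c("de", "me")) |>
    tidyr::pivot_wider(names_from = "item", values_from = "value")
  wide |>
    dplyr::mutate(
      basal_backsolved = (.data$diet - x * .data$ingredient) / (1 - x)) |>
    dplyr::group_by(.data$measure) |>
    dplyr::mutate(spread = max(.data$basal_backsolved) -
                    min(.data$basal_backsolved)) |>
    dplyr::ungroup() |>
    dplyr::select("measure", "sample", "basal_backsolved", "spread")
}
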