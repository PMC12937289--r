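#' Apparent ileal digestibility from marker ratios
#'
#' With an indigestible marker (here TiO2) included in the diet, the
#' apparent ileal digestibility of an amino acid follows from the change in
#' its concentration relative to the marker between diet and digesta:
#' \deqn{AID = [1 - (AA_1/AA_2)(IM_2/IM_1)] \times 100}
#' where subscript 1 is digesta and 2 is diet (both per kg DM). The ratio
#' form makes the result invariant to rescaling all concentrations of one
#' sample by a common factor, so no digesta-flow measurement is needed.
#'
#' @param aa_digesta,aa_diet Amino acid concentration in digesta / diet
#'   (same units, e.g. mg/kg DM). `aa_diet` must be > 0.
#' @param marker_digesta,marker_diet Marker concentration in digesta / diet
#'   (mg/kg DM), both > 0.
#' @return AID in percent, vectorized. May be negative (returned with a
#'   warning, never clipped); equals 100 exactly when `aa_digesta` is 0.
#' @examples
#' apparent_ileal_digestibility(3000, 10000, 6000, 2000)
#' @export
apparent_ileal_digestibility <- function(aa_digesta, aa_diet,
                                         marker_digesta, marker_diet) {
  if (any(aa_diet <= 0)) {
    abort("Diet amino acid concentration must be > 0.",
          class = "feedval_undefined_digestibility")
  }
  if (any(marker_digesta <= 0) || any(marker_diet <= 0)) {
    abort("Marker concentrations must be > 0.",
          class = "feedval_marker_recovery_error")
  }
  if (any(aa_digesta < 0)) {
    abort("Digesta amino acid concentration must be >= 0.",
          class = "feedval_invalid_record")
  }
  aid <- 100 * (1 - (aa_digesta / aa_diet) * (marker_diet / marker_digesta))
  if (any(aid < 0)) {
    warn("Negative apparent ileal digestibility computed; value returned unclipped.")
  }
  aid
}

#' Basal endogenous amino-acid loss from a nitrogen-free diet
#'
#' Digesta collected on a protein-free diet contains only endogenous amino
#' acids; the marker ratio converts their digesta concentration to a loss
#' per kg of dry-matter intake:
#' \deqn{IAA = AA_3 \times (IM_4/IM_3)}
#' with subscript 3 the N-free digesta and 4 the N-free diet. The result is
#' returned in g/kg DMI (inputs are mg/kg DM).
#'
#' @param aa_digesta Amino acid concentration in N-free digesta, mg/kg DM.
#' @param marker_digesta Marker in N-free digesta, mg/kg DM, > 0.
#' @param marker_diet Marker in the N-free diet, mg/kg DM.
#' @return Basal endogenous loss, g/kg dry-matter intake.
#' @examples
#' basal_endogenous_loss(6000, 4000, 2000)
#' @export
basal_endogenous_loss <- function(aa_digesta, marker_digesta, marker_diet) {
  if (any(marker_digesta <= 0)) {
    abort("N-free digesta marker concentration must be > 0.",
          class = "feedval_marker_recovery_error")
  }
  aa_digesta * (marker_diet / marker_digesta) / 1000
}

#' Standardized ileal digestibility
#'
#' Corrects apparent digestibility upward for the basal endogenous loss,
#' which is a property of the animal, not the feed:
#' \deqn{SID = AID + (IAA/AA_2) \times 100}
#' with `IAA` in g/kg DMI and the diet concentration `AA_2` in g/kg DM.
#' Values above 100% are legal and occur for amino acids (notably proline)
#' whose endogenous secretion is stimulated by the N-free diet itself.
#'
#' @param aid_pct Apparent ileal digestibility, percent.
#' @param iaa Basal endogenous loss, g/kg DMI, >= 0.
#' @param aa_diet Diet amino acid concentration, g/kg DM, > 0.
#' @return SID in percent, vectorized; never clipped.
#' @examples
#' standardized_ileal_digestibility(70, 0.63, 1.26)
#' @export
standardized_ileal_digestibility <- function(aid_pct, iaa, aa_diet) {
  if (any(aa_diet <= 0)) {
    abort("Diet amino acid concentration must be > 0.",
          class = "feedval_undefined_digestibility")
  }
  if (any(iaa < 0)) {
    abort("Endogenous losses must be >= 0.", class = "feedval_invalid_record")
  }
  aid_pct + 100 * iaa / aa_diet
}

#' Per-diet apparent and standardized ileal digestibility table
#'
#' Computes AID and SID for every amino acid and every pig-period digesta
#' observation, then averages by diet. Diet amino-acid profiles follow the
#' convention of analyzed diet tables: as-fed percent plus a `dm` column;
#' they are converted to g/kg DM internally before the marker-ratio and
#' endogenous-correction steps.
#'
#' @param digesta Data frame of digesta observations: `pig_id`, `period`,
#'   `diet_id`, `marker_mg_kg` (TiO2, mg/kg DM) and one column per amino
#'   acid (mg/kg DM), including `taa` for the total if available.
#' @param diet_profiles Data frame: `diet_id`, `dm` (%), `marker_mg_kg`
#'   (mg/kg DM) and amino-acid columns in as-fed percent.
#' @param endogenous Data frame `aa`, `iaa_g_per_kg_dmi` — basal endogenous
#'   losses per kg DMI (e.g. `feedval_fixture("table12_iaa")`).
#' @param iaa_scale_factor Multiplier applied to the endogenous table before
#'   the SID correction (default 1: values used verbatim).
#' @return Tibble, one row per diet and amino acid: `diet_id`, `aa`, `n`,
#'   `aid_pct`, `sid_pct`.
#' @seealso [sid_grand_means()] for the across-diet summary.
#' @export
digestibility_table <- function(digesta, diet_profiles, endogenous,
                                iaa_scale_factor = 1) {
  digesta <- tibble::as_tibble(digesta)
  diet_profiles <- tibble::as_tibble(diet_profiles)
  ids <- c("pig_id", "period", "diet_id", "marker_mg_kg")
  aas <- setdiff(names(digesta)[vapply(digesta, is.numeric, logical(1))],
                 c(ids, "period"))
  missing_diet <- setdiff(unique(digesta$diet_id), diet_profiles$diet_id)
  if (length(missing_diet)) {
    abort(paste0("No diet profile for: ", paste(missing_diet, collapse = ", ")),
          class = "feedval_schema_error")
  }
  missing_aa <- setdiff(aas, names(diet_profiles))
  if (length(missing_aa)) {
    abort(paste0("Amino acids in digesta but not in diet profiles: ",
                 paste(missing_aa, collapse = ", ")),
          class = "feedval_schema_error")
  }
  endo <- setNames(endogenous$iaa_g_per_kg_dmi, endogenous$aa)
  missing_endo <- setdiff(aas, names(endo))
  if (length(missing_endo)) {
    abort(paste0("Amino acids missing from the endogenous table: ",
                 paste(missing_endo, collapse = ", ")),
          class = "feedval_schema_error")
  }

  long_dig <- digesta |>
    tidyr::pivot_longer(dplyr::all_of(aas), names_to = "aa",
                        values_to = "aa_digesta")
  long_diet <- diet_profiles |>
    tidyr::pivot_longer(dplyr::all_of(aas), names_to = "aa",
                        values_to = "aa_diet_pct_asfed") |>
    dplyr::mutate(
      # as-fed % -> g/kg DM: x10 to g/kg as-fed, then x100/dm to DM basis
      aa_diet_g_kg_dm = .data$aa_diet_pct_asfed * 10 * 100 / .data$dm
    ) |>
    dplyr::select("diet_id", diet_marker_mg_kg = "marker_mg_kg",
                  "aa", "aa_diet_g_kg_dm")

  obs <- dplyr::inner_join(long_dig, long_diet, by = c("diet_id", "aa")) |>
    dplyr::mutate(
      aid_pct = apparent_ileal_digestibility(
        .data$aa_digesta, .data$aa_diet_g_kg_dm * 1000,
        .data$marker_mg_kg, .data$diet_marker_mg_kg),
      sid_pct = standardized_ileal_digestibility(
        .data$aid_pct, endo[.data$aa] * iaa_scale_factor,
        .data$aa_diet_g_kg_dm)
    )
  obs |>
    dplyr::group_by(.data$diet_id, .data$aa) |>
    dplyr::summarise(n = dplyr::n(), aid_pct = mean(.data$aid_pct),
                     sid_pct = mean(.data$sid_pct), .groups = "drop")
}

#' Across-diet grand means of digestibility values
#'
#' Unweighted mean, minimum and maximum of the per-diet values for each
#' amino acid — the "Mean" column of a digestibility table over the tested
#' ingredient set.
#'
#' @param sid_table Long data frame with `aa` and a per-diet value column.
#' @param value Name of the value column (default `"sid_pct"`).
#' @return Tibble: `aa`, `n_diets`, `mean`, `min`, `max`.
#' @examples
#' tbl <- feedval_fixture("table12") |>
#'   tidyr::pivot_longer(-aa, names_to = "diet_id", values_to = "sid_pct")
#' sid_grand_means(tbl)
#' @export
sid_grand_means <- function(sid_table, value = "sid_pct") {
  sid_table |>
    dplyr::group_by(.data$aa) |>
    dplyr::summarise(n_diets = dplyr::n(),
                     mean = mean(.data[[value]]),
                     min = min(.data[[value]]),
                     max = max(.data[[value]]), .groups = "drop")
}
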