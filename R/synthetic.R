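#' Incomplete Latin-square trial design
#'
#' Allocates diets to pig-period cells by a cyclic Youden-square
#' construction — pig \eqn{i}, period \eqn{j} receives diet
#' \eqn{(i + j) \bmod n_{diets}} — then randomizes by seeded shuffles of the
#' pig and diet labels. The construction guarantees the two contractual
#' design invariants: no pig ever repeats a diet, and every diet reaches
#' exactly the target replicate count.
#'
#' @param n_pigs,n_diets,n_periods,reps_per_diet Design counts. Feasibility
#'   requires `n_pigs * n_periods == n_diets * reps_per_diet`, `n_pigs` a
#'   multiple of `n_diets`, and `n_periods <= n_diets`.
#' @param diet_ids Optional character vector of diet labels (length
#'   `n_diets`); default `"diet1"`, `"diet2"`, ...
#' @param seed Optional integer seed for the label shuffles.
#' @return Tibble: `pig_id`, `period`, `diet_id`, one row per cell.
#' @examples
#' generate_design(22, 11, 3, 6, seed = 1)
#' @export
generate_design <- function(n_pigs, n_diets, n_periods, reps_per_diet,
                            diet_ids = NULL, seed = NULL) {
  if (n_pigs * n_periods != n_diets * reps_per_diet ||
      n_pigs %% n_diets != 0 || n_periods > n_diets) {
    abort(paste0("Infeasible design: need n_pigs * n_periods == ",
                 "n_diets * reps_per_diet, n_pigs a multiple of n_diets, ",
                 "and n_periods <= n_diets."),
          class = "feedval_design_error")
  }
  if (is.null(diet_ids)) diet_ids <- paste0("diet", seq_len(n_diets))
  if (length(diet_ids) != n_diets) {
    abort("`diet_ids` must have length `n_diets`.", class = "feedval_design_error")
  }
  if (!is.null(seed)) set.seed(seed)
  diet_perm <- sample(diet_ids)
  pig_perm <- sample(seq_len(n_pigs))
  grid <- tidyr::expand_grid(pig = seq_len(n_pigs), period = seq_len(n_periods))
  tibble::tibble(
    pig_id = sprintf("pig%02d", pig_perm[grid$pig]),
    period = grid$period,
    diet_id = diet_perm[(grid$pig - 1 + grid$period - 1) %% n_diets + 1]
  ) |>
    dplyr::arrange(.data$period, .data$pig_id)
}

#' Noise settings for the trial simulators
#'
#' Measurement noise is multiplicative lognormal (energy outputs and
#' concentrations are positive), parameterized by coefficients of variation
#' in percent and corrected to unit mean so the simulated estimators stay
#' unbiased. A CV of 0 switches the corresponding noise off exactly.
#'
#' @param fecal_ge_cv,urine_ge_cv CV of the fecal / urinary energy outputs,
#'   percent (default 2).
#' @param digesta_conc_cv CV of digesta concentrations, percent (default 5).
#' @param seed Optional integer seed; the simulators draw from one global
#'   stream seeded here.
#' @return A `noise_model` list.
#' @export
noise_model <- function(fecal_ge_cv = 2, urine_ge_cv = 2,
                        digesta_conc_cv = 5, seed = NULL) {
  cvs <- c(fecal_ge_cv, urine_ge_cv, digesta_conc_cv)
  if (any(cvs < 0)) abort("Noise CVs must be >= 0.", class = "feedval_config_error")
  structure(list(fecal_ge_cv = fecal_ge_cv, urine_ge_cv = urine_ge_cv,
                 digesta_conc_cv = digesta_conc_cv, seed = seed),
            class = "noise_model")
}

# unit-mean lognormal factors; exactly 1 when cv_pct == 0
lognormal_factor <- function(n, cv_pct) {
  if (cv_pct == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Ground truth for the synthetic study
#'
#' Bundles everything the forward simulators need: per-ingredient as-fed
#' DE/ME and dry matter, analyzed diet dry matter and gross energy for the
#' energy trial, diet amino-acid profiles and true SID values for the ileal
#' trial, a basal endogenous-loss table, and the structural constants
#' (substitution fraction, basal energy fraction, marker inclusion, digesta
#' flow). Defaults are seeded from the packaged reference tables so the
#' synthetic trials resemble the original study; the default endogenous
#' table is the packaged one scaled to physiologically plausible magnitudes
#' (see `iaa_scale`), restricted to the five first-limiting amino acids.
#'
#' @param aa_set Amino acids carried by the ileal simulator (default the
#'   five first-limiting: lys, met, thr, trp, val).
#' @param iaa_scale Factor applied to the packaged endogenous-loss table to
#'   obtain the simulator's true basal losses (default 0.1, which brings
#'   them to the magnitude reported for growing pigs elsewhere, e.g. Lys
#'   about 0.5 g/kg DMI).
#' @param digesta_flow_frac kg of ileal digesta DM per kg of DM intake
#'   (default 0.30).
#' @param x,energy_fraction,marker_pct Structural constants: substitution
#'   fraction (0.30), basal energy-supplying fraction (0.97), TiO2
#'   inclusion as-fed % (0.20).
#' @param bw_kg Initial body weight driving feed intake (default 36.47).
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(aa_set = c("lys", "met", "thr", "trp", "val"),
                            iaa_scale = 0.1, digesta_flow_frac = 0.30,
                            x = 0.30, energy_fraction = 0.97,
                            marker_pct = 0.20, bw_kg = 36.47) {
  comp <- feedval_fixture("table6")
  t9 <- feedval_fixture("table9")
  ing_e <- t9 |>
    dplyr::filter(.data$item == "ingredient", .data$basis == "as_fed") |>
    tidyr::pivot_wider(id_cols = "sample", names_from = "measure",
                       values_from = "value") |>
    dplyr::rename(ingredient_id = "sample", de_asfed = "de", me_asfed = "me")
  ingredients <- comp |>
    dplyr::select("ingredient_id", "dm") |>
    dplyr::inner_join(ing_e, by = "ingredient_id")
  basal <- feedval_fixture("basal_energy")
  t12 <- feedval_fixture("table12") |>
    dplyr::filter(.data$aa %in% aa_set) |>
    tidyr::pivot_longer(-"aa", names_to = "diet_id", values_to = "sid_pct")
  endo <- feedval_fixture("table12_iaa") |>
    dplyr::filter(.data$aa %in% aa_set) |>
    dplyr::mutate(iaa_g_per_kg_dmi = .data$iaa_g_per_kg_dmi * iaa_scale)
  diet_aa <- feedval_fixture("table5") |>
    dplyr::select("diet_id", "dm", dplyr::all_of(aa_set))
  structure(
    list(ingredients = ingredients,
         basal_de_asfed = basal$de_d, basal_me_asfed = basal$me_d,
         diet_nutrients = dplyr::select(feedval_fixture("table3"),
                                        "diet_id", "dm", "ge"),
         diet_aa = diet_aa, true_sid = t12, endogenous = endo,
         x = x, energy_fraction = energy_fraction,
         marker_pct = marker_pct, digesta_flow_frac = digesta_flow_frac,
         bw_kg = bw_kg),
    class = "synthetic_truth"
  )
}

#' True diet energies implied by a synthetic truth
#'
#' Composes the true as-fed diet DE/ME for every diet the truth knows:
#' the basal diet's own value for `basal`, and
#' \eqn{x \cdot E_{ing} + (1 - x) \cdot E_{basal}/0.97} for test diets
#' (the forward form whose inverse is the difference method).
#'
#' @param truth A [synthetic_truth()].
#' @return Tibble: `diet_id`, `de_asfed`, `me_asfed`.
#' @export
true_diet_energy <- function(truth) {
  test <- truth$ingredients |>
    dplyr::transmute(
      diet_id = .data$ingredient_id,
      de_asfed = truth$x * .data$de_asfed +
        (1 - truth$x) * truth$basal_de_asfed / truth$energy_fraction,
      me_asfed = truth$x * .data$me_asfed +
        (1 - truth$x) * truth$basal_me_asfed / truth$energy_fraction
    )
  dplyr::bind_rows(
    tibble::tibble(diet_id = "basal", de_asfed = truth$basal_de_asfed,
                   me_asfed = truth$basal_me_asfed),
    test
  )
}

#' Simulate a total-collection energy balance trial
#'
#' Forward model of the metabolism trial: feed intake is 4% of initial body
#' weight per day over the collection window; gross-energy intake follows
#' from the analyzed diet GE; fecal and urinary energy outputs are the
#' deterministic values implied by the true diet DE/ME, each multiplied by
#' unit-mean lognormal noise. With all CVs zero the difference-method
#' estimator recovers the true ingredient energies exactly.
#'
#' @param truth A [synthetic_truth()].
#' @param plan A design from [generate_design()] whose diet ids are covered
#'   by the truth (test diets named like its ingredients, plus `"basal"`).
#' @param noise A [noise_model()].
#' @param bw_kg Initial body weight, kg (default from the truth).
#' @param days Collection days (default 5).
#' @return Tibble of balance records ready for [diet_energy()] /
#'   [estimate_ingredient_energy()].
#' @export
simulate_balance_trial <- function(truth, plan, noise = noise_model(),
                                   bw_kg = truth$bw_kg, days = 5) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  diets <- true_diet_energy(truth)
  missing <- setdiff(unique(plan$diet_id), diets$diet_id)
  if (length(missing)) {
    abort(paste0("Truth does not cover diet(s): ",
                 paste(missing, collapse = ", ")),
          class = "feedval_config_error")
  }
  obs <- plan |>
    dplyr::left_join(diets, by = "diet_id") |>
    dplyr::left_join(truth$diet_nutrients, by = "diet_id")
  if (any(is.na(obs$dm))) {
    abort("Truth `diet_nutrients` must cover every diet in the plan.",
          class = "feedval_config_error")
  }
  n <- nrow(obs)
  obs |>
    dplyr::mutate(
      feed_asfed_kg = 0.04 * bw_kg * days,
      feed_intake_kg_dm = .data$feed_asfed_kg * .data$dm / 100,
      ge_dm = .data$ge * 100 / .data$dm,
      de_dm = .data$de_asfed * 100 / .data$dm,
      me_dm = .data$me_asfed * 100 / .data$dm,
      ge_intake_mj = .data$ge_dm * .data$feed_intake_kg_dm,
      fecal_ge_mj = (.data$ge_dm - .data$de_dm) * .data$feed_intake_kg_dm *
        lognormal_factor(n, noise$fecal_ge_cv),
      urine_ge_mj = (.data$de_dm - .data$me_dm) * .data$feed_intake_kg_dm *
        lognormal_factor(n, noise$urine_ge_cv)
    ) |>
    dplyr::select("pig_id", "period", "diet_id", "feed_intake_kg_dm",
                  "ge_intake_mj", "fecal_ge_mj", "urine_ge_mj")
}

#' Simulate an ileal digesta collection trial
#'
#' Forward model of the marker-ratio measurement: for each amino acid the
#' true apparent digestibility is recovered from the true SID and the basal
#' endogenous loss (\eqn{AID = SID - 100 \cdot IAA/AA_2}); the undigested
#' flow plus a fixed digesta-flow fraction then fixes the digesta amino
#' acid and marker concentrations, each multiplied by unit-mean lognormal
#' noise. A true AID above 100% would imply a negative flow and raises a
#' truth-inconsistency error.
#'
#' @inheritParams simulate_balance_trial
#' @return Tibble of digesta records (`pig_id`, `period`, `diet_id`,
#'   `marker_mg_kg`, one column per amino acid, mg/kg DM) ready for
#'   [digestibility_table()].
#' @export
simulate_ileal_trial <- function(truth, plan, noise = noise_model()) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  missing <- setdiff(unique(plan$diet_id), truth$diet_aa$diet_id)
  if (length(missing)) {
    abort(paste0("Truth does not cover diet(s): ",
                 paste(missing, collapse = ", ")),
          class = "feedval_config_error")
  }
  aa_set <- truth$endogenous$aa
  endo <- setNames(truth$endogenous$iaa_g_per_kg_dmi, aa_set)
  q <- truth$digesta_flow_frac
  long <- plan |>
    dplyr::left_join(truth$diet_aa, by = "diet_id") |>
    tidyr::pivot_longer(dplyr::all_of(aa_set), names_to = "aa",
                        values_to = "aa_pct_asfed") |>
    dplyr::left_join(truth$true_sid, by = c("diet_id", "aa")) |>
    dplyr::mutate(
      aa_diet_g_kg_dm = .data$aa_pct_asfed * 10 * 100 / .data$dm,
      marker_diet_mg_kg = truth$marker_pct * 10000 * 100 / .data$dm,
      aid_true = .data$sid_pct - 100 * endo[.data$aa] / .data$aa_diet_g_kg_dm
    )
  if (any(long$aid_true > 100)) {
    bad <- unique(long$aa[long$aid_true > 100])
    abort(paste0("True AID > 100% (negative undigested flow) for: ",
                 paste(bad, collapse = ", ")),
          class = "feedval_truth_inconsistency")
  }
  long <- long |>
    dplyr::mutate(
      flow_mg_kg_dmi = .data$aa_diet_g_kg_dm * 1000 * (1 - .data$aid_true / 100),
      aa_digesta = .data$flow_mg_kg_dmi / q *
        lognormal_factor(dplyr::n(), noise$digesta_conc_cv)
    )
  markers <- plan |>
    dplyr::left_join(dplyr::select(truth$diet_aa, "diet_id", "dm"),
                     by = "diet_id") |>
    dplyr::mutate(
      marker_mg_kg = truth$marker_pct * 10000 * 100 / .data$dm / q *
        lognormal_factor(dplyr::n(), noise$digesta_conc_cv)
    ) |>
    dplyr::select("pig_id", "period", "diet_id", "marker_mg_kg")
  long |>
    dplyr::select("pig_id", "period", "diet_id", "aa", "aa_digesta") |>
    tidyr::pivot_wider(names_from = "aa", values_from = "aa_digesta") |>
    dplyr::left_join(markers, by = c("pig_id", "period", "diet_id")) |>
    dplyr::relocate("marker_mg_kg", .after = "diet_id")
}

#' Simulate nitrogen-free-diet digesta for endogenous-loss estimation
#'
#' Emits one digesta record per pig on a protein-free diet whose amino-acid
#' content is purely endogenous, so that [basal_endogenous_loss()] applied
#' to the records recovers the truth's endogenous table (exactly at zero
#' noise).
#'
#' @inheritParams simulate_balance_trial
#' @param pigs Character vector of pig ids.
#' @param period Period number recorded (default 1).
#' @return Tibble: `pig_id`, `period`, `diet_id = "nfree"`,
#'   `marker_diet_mg_kg`, `marker_mg_kg`, one column per amino acid
#'   (mg/kg DM).
#' @export
simulate_nfree_digesta <- function(truth, pigs, noise = noise_model(),
                                   period = 1) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  q <- truth$digesta_flow_frac
  im4 <- truth$marker_pct * 10000
  grid <- tidyr::expand_grid(pig_id = pigs, aa = truth$endogenous$aa) |>
    dplyr::left_join(truth$endogenous, by = "aa") |>
    dplyr::mutate(
      aa_digesta = 1000 * .data$iaa_g_per_kg_dmi / q *
        lognormal_factor(dplyr::n(), noise$digesta_conc_cv)
    )
  grid |>
    dplyr::select("pig_id", "aa", "aa_digesta") |>
    tidyr::pivot_wider(names_from = "aa", values_from = "aa_digesta") |>
    dplyr::mutate(period = period, diet_id = "nfree",
                  marker_diet_mg_kg = im4, marker_mg_kg = im4 / q) |>
    dplyr::relocate("period", "diet_id", "marker_diet_mg_kg",
                    "marker_mg_kg", .after = "pig_id")
}

#' Parameter-recovery report
#'
#' Joins estimates to ground truth by a key column and reports, for every
#' quantity present in both tables, the mean bias and the root mean square
#' error. If the estimates carry interval columns (`<quantity>_lo`,
#' `<quantity>_hi`), the empirical coverage of the truth is added.
#'
#' @param estimates,truth Data frames sharing a key column and one or more
#'   numeric quantity columns.
#' @param by Key column name (default `"ingredient_id"`).
#' @return Tibble: `quantity`, `n`, `bias`, `rmse` (and `coverage` when
#'   intervals are present).
#' @examples
#' recovery_report(
#'   tibble::tibble(ingredient_id = c("a", "b"), de = c(16, 17)),
#'   tibble::tibble(ingredient_id = c("a", "b"), de = c(15, 16))
#' )
#' @export
recovery_report <- function(estimates, truth, by = "ingredient_id") {
  estimates <- tibble::as_tibble(estimates)
  truth <- tibble::as_tibble(truth)
  if (!setequal(estimates[[by]], truth[[by]])) {
    abort("Estimate and truth keys do not match.", class = "feedval_schema_error")
  }
  is_interval <- function(nm) grepl("_(lo|hi)$", nm)
  quantities <- intersect(
    setdiff(names(estimates)[vapply(estimates, is.numeric, logical(1))], by),
    setdiff(names(truth)[vapply(truth, is.numeric, logical(1))], by)
  )
  quantities <- quantities[!is_interval(quantities)]
  if (!length(quantities)) {
    abort("No shared numeric quantities between estimates and truth.",
          class = "feedval_schema_error")
  }
  joined <- dplyr::inner_join(estimates, truth, by = by,
                              suffix = c("_est", "_true"))
  purrr::map_dfr(quantities, function(qn) {
    est <- joined[[paste0(qn, "_est")]]
    tru <- joined[[paste0(qn, "_true")]]
    out <- tibble::tibble(quantity = qn, n = length(est),
                          bias = mean(est - tru),
                          rmse = sqrt(mean((est - tru)^2)))
    lo <- estimates[[paste0(qn, "_lo")]]
    hi <- estimates[[paste0(qn, "_hi")]]
    if (!is.null(lo) && !is.null(hi)) {
      ord <- match(joined[[by]], estimates[[by]])
      out$coverage <- mean(lo[ord] <= tru & tru <= hi[ord])
    }
    out
  })
}
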