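# Shared joins of the packaged tables onto the dry-matter basis, and a
# reusable Monte-Carlo driver for the energy-recovery tests.
#
# The DM-converted analytes are carried at 2 decimals, the precision at
# which analyzed-composition tables are reported (and the table the
# reference regressions were evidently fitted on).

comp_dm_2dp <- function() {
  convert_basis(feedval_fixture("table6"), "dry_matter") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric) & !dm,
                                ~ round(.x, 2)))
}

# printed-value comparison: agreement within half a unit of the last
# printed digit (the tables round half-up; round() rounds half-to-even)
expect_printed <- function(actual, printed, digits = 2) {
  expect_lt(max(abs(actual - printed)), 0.5 * 10^-digits + 1e-9)
}

energy_dm_data <- function() {
  comp_dm <- comp_dm_2dp()
  ing <- feedval_fixture("table9") |>
    dplyr::filter(item == "ingredient", basis == "dry_matter",
                  measure != "me_de_ratio") |>
    tidyr::pivot_wider(id_cols = sample, names_from = measure,
                       values_from = value) |>
    dplyr::rename(ingredient_id = sample)
  dplyr::inner_join(comp_dm, ing, by = "ingredient_id")
}

sid_dm_data <- function() {
  comp_dm <- comp_dm_2dp()
  sid_wide <- feedval_fixture("table12") |>
    tidyr::pivot_longer(-aa, names_to = "ingredient_id",
                        values_to = "sid_pct") |>
    dplyr::filter(aa %in% c("lys", "met", "trp", "thr", "val", "taa")) |>
    tidyr::pivot_wider(names_from = aa, values_from = sid_pct,
                       names_prefix = "sid_")
  dplyr::inner_join(comp_dm, sid_wide, by = "ingredient_id")
}

exp1_diet_ids <- function() c("basal", paste0("esbm", 1:10))

# Per-seed mean ingredient DE estimates from simulated energy trials.
# Returns a matrix: seeds x ingredients (columns in truth order).
run_energy_recovery <- function(n_seeds, truth, plan, fecal_cv = 2,
                                urine_cv = 2, seed_offset = 0) {
  ing_dm <- dplyr::select(truth$ingredients, diet_id = ingredient_id, dm)
  ids <- truth$ingredients$ingredient_id
  out <- matrix(NA_real_, nrow = n_seeds, ncol = length(ids),
                dimnames = list(NULL, ids))
  for (s in seq_len(n_seeds)) {
    rec <- simulate_balance_trial(
      truth, plan, noise_model(fecal_cv, urine_cv, 0, seed = s + seed_offset))
    est <- estimate_ingredient_energy(rec, truth$diet_nutrients,
                                      ingredient_dm = ing_dm)
    means <- tapply(est$de_ingredient_asfed, est$diet_id, mean)
    out[s, ] <- means[ids]
  }
  out
}
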