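check_design <- function(plan, n_cells, reps) {
  expect_equal(nrow(plan), n_cells)
  expect_true(all(table(plan$diet_id) == reps))
  repeats <- dplyr::count(plan, pig_id, diet_id) |> dplyr::filter(n > 1)
  expect_equal(nrow(repeats), 0)
}

test_that("both study designs satisfy the incomplete Latin-square invariants", {
  check_design(generate_design(22, 11, 3, 6, seed = 1), 66, 6)
  check_design(generate_design(10, 10, 6, 6, seed = 1), 60, 6)
  tiny <- generate_design(2, 2, 1, 1, seed = 1)
  expect_equal(nrow(tiny), 2)
  expect_equal(sort(unique(tiny$diet_id)), c("diet1", "diet2"))
})

test_that("design invariants hold across 100 seeds", {
  for (s in 1:100) {
    p1 <- generate_design(22, 11, 3, 6, seed = s)
    expect_true(all(table(p1$diet_id) == 6))
    expect_equal(nrow(dplyr::distinct(p1, pig_id, diet_id)), 66)
    p2 <- generate_design(10, 10, 6, 6, seed = s)
    expect_true(all(table(p2$diet_id) == 6))
    expect_equal(nrow(dplyr::distinct(p2, pig_id, diet_id)), 60)
  }
})

test_that("infeasible design counts are rejected", {
  expect_error(generate_design(22, 11, 3, 5), class = "feedval_design_error")
  expect_error(generate_design(21, 11, 3, 6), class = "feedval_design_error")
  expect_error(generate_design(10, 5, 6, 12), class = "feedval_design_error")
  expect_error(generate_design(10, 10, 6, 6, diet_ids = "a"),
               class = "feedval_design_error")
})

test_that("the same seed reproduces simulations exactly", {
  truth <- synthetic_truth()
  plan <- generate_design(22, 11, 3, 6, diet_ids = exp1_diet_ids(), seed = 4)
  plan_again <- generate_design(22, 11, 3, 6, diet_ids = exp1_diet_ids(),
                                seed = 4)
  expect_identical(plan, plan_again)
  r1 <- simulate_balance_trial(truth, plan, noise_model(seed = 9))
  r2 <- simulate_balance_trial(truth, plan, noise_model(seed = 9))
  expect_identical(r1, r2)
  d1 <- simulate_ileal_trial(truth,
                             generate_design(10, 10, 6, 6,
                                             diet_ids = paste0("esbm", 1:10),
                                             seed = 4),
                             noise_model(seed = 9))
  d2 <- simulate_ileal_trial(truth,
                             generate_design(10, 10, 6, 6,
                                             diet_ids = paste0("esbm", 1:10),
                                             seed = 4),
                             noise_model(seed = 9))
  expect_identical(d1, d2)
})

test_that("feed intake follows 4% of initial body weight", {
  truth <- synthetic_truth()
  plan <- generate_design(22, 11, 3, 6, diet_ids = exp1_diet_ids(), seed = 2)
  rec <- simulate_balance_trial(truth, plan, noise_model(0, 0, 0),
                                bw_kg = 36.47, days = 5)
  dm <- setNames(truth$diet_nutrients$dm, truth$diet_nutrients$diet_id)
  daily_asfed <- rec$feed_intake_kg_dm / (dm[rec$diet_id] / 100) / 5
  expect_equal(unname(daily_asfed), rep(0.04 * 36.47, nrow(rec)),
               tolerance = 1e-12)
})

test_that("zero-noise energy trial round-trips the true ingredient DE and ME", {
  truth <- synthetic_truth()
  plan <- generate_design(22, 11, 3, 6, diet_ids = exp1_diet_ids(), seed = 8)
  rec <- simulate_balance_trial(truth, plan, noise_model(0, 0, 0, seed = 8))
  est <- estimate_ingredient_energy(
    rec, truth$diet_nutrients,
    ingredient_dm = dplyr::select(truth$ingredients,
                                  diet_id = ingredient_id, dm))
  per_diet <- treatment_energy_summary(est, de_ingredient_asfed,
                                       me_ingredient_asfed)
  wide <- tidyr::pivot_wider(per_diet[, c("diet_id", "measure", "mean")],
                             names_from = measure, values_from = mean)
  chk <- dplyr::inner_join(wide, truth$ingredients,
                           by = c(diet_id = "ingredient_id"))
  expect_lt(max(abs(chk$de_ingredient_asfed - chk$de_asfed)), 1e-9)
  expect_lt(max(abs(chk$me_ingredient_asfed - chk$me_asfed)), 1e-9)
  # ME never exceeds DE anywhere in the chain
  expect_true(all(est$me_d <= est$de_d + 1e-12))
  expect_true(all(est$me_ingredient_asfed <= est$de_ingredient_asfed + 1e-12))
})

test_that("zero-noise ileal trial round-trips the true SID", {
  truth <- synthetic_truth()
  plan <- generate_design(10, 10, 6, 6, diet_ids = paste0("esbm", 1:10),
                          seed = 8)
  dig <- simulate_ileal_trial(truth, plan, noise_model(0, 0, 0, seed = 8))
  profiles <- dplyr::mutate(
    truth$diet_aa, marker_mg_kg = truth$marker_pct * 10000 * 100 / dm)
  tab <- digestibility_table(dig, profiles, truth$endogenous)
  chk <- dplyr::inner_join(tab, truth$true_sid, by = c("diet_id", "aa"),
                           suffix = c("_est", "_true"))
  expect_equal(nrow(chk), 50)
  expect_lt(max(abs(chk$sid_pct_est - chk$sid_pct_true)), 1e-9)
})

test_that("zero-noise N-free digesta recover the endogenous-loss table", {
  truth <- synthetic_truth()
  rec <- simulate_nfree_digesta(truth, paste0("pig", 1:3),
                                noise_model(0, 0, 0, seed = 1))
  aa <- truth$endogenous$aa
  for (a in aa) {
    est <- basal_endogenous_loss(rec[[a]], rec$marker_mg_kg,
                                 rec$marker_diet_mg_kg)
    expect_equal(est,
                 rep(truth$endogenous$iaa_g_per_kg_dmi[match(a, aa)], 3),
                 tolerance = 1e-12)
  }
})

test_that("a truth implying negative undigested flow is rejected", {
  truth <- synthetic_truth()
  truth$true_sid$sid_pct[truth$true_sid$aa == "lys"] <- 120
  plan <- generate_design(10, 10, 1, 1, diet_ids = paste0("esbm", 1:10),
                          seed = 3)
  expect_error(simulate_ileal_trial(truth, plan, noise_model(0, 0, 0)),
               class = "feedval_truth_inconsistency")
})

test_that("recovery report computes bias, RMSE and optional coverage", {
  est <- tibble::tibble(ingredient_id = c("a", "b"), de = c(16, 17))
  tru <- tibble::tibble(ingredient_id = c("a", "b"), de = c(16, 17))
  r <- recovery_report(est, tru)
  expect_equal(r$bias, 0)
  expect_equal(r$rmse, 0)
  offset <- dplyr::mutate(est, de = de + 1)
  r1 <- recovery_report(offset, tru)
  expect_equal(r1$bias, 1)
  expect_equal(r1$rmse, 1)
  with_ci <- dplyr::mutate(est, de_lo = de - 0.5, de_hi = de + 0.5)
  expect_equal(recovery_report(with_ci, tru)$coverage, 1)
  expect_error(
    recovery_report(est, dplyr::mutate(tru, ingredient_id = c("a", "c"))),
    class = "feedval_schema_error")
})

test_that("simulated-measurement spread matches error propagation over 1000 seeds", {
  truth <- synthetic_truth()
  plan <- generate_design(22, 11, 3, 6, diet_ids = exp1_diet_ids(), seed = 10)
  cv <- 2
  mat <- run_energy_recovery(1000, truth, plan, fecal_cv = cv, urine_cv = cv)
  emp_se <- apply(mat, 2, sd)
  # delta method: DE_af = GE_af - (GE_af - DE_af_true) * eps, averaged over 6
  # replicate pigs; ingredient = [diet - (1-x)/0.97 * basal] / x
  diets <- true_diet_energy(truth)
  nut <- truth$diet_nutrients
  sd_diet <- (nut$ge - diets$de_asfed[match(nut$diet_id, diets$diet_id)]) *
    (cv / 100) / sqrt(6)
  names(sd_diet) <- nut$diet_id
  var_basal <- sd_diet[["basal"]]^2
  x <- truth$x
  ana_se <- sqrt(sd_diet[truth$ingredients$ingredient_id]^2 +
                   ((1 - x) / truth$energy_fraction)^2 * var_basal) / x
  expect_lt(max(abs(emp_se - ana_se[colnames(mat)]) /
                  ana_se[colnames(mat)]), 0.10)
})
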