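test_that("correlation matrix has unit diagonal and reproduces table entries", {
  cc <- correlate_variables(energy_dm_data(),
                            c("de", "me", "cp", "ee", "cf", "ndf", "adf",
                              "ash", "ge"))
  expect_equal(unname(diag(cc$r)), rep(1, 9))
  expect_equal(round(cc$r["ash", "de"], 2), -0.75)
  expect_equal(round(cc$r["cf", "adf"], 2), 0.91)
  expect_equal(round(cc$r["ge", "ash"], 2), -0.87)
  expect_equal(cc$r, t(cc$r))
  expect_equal(cc$p, t(cc$p))
  # stars under the 0.05/0.01 convention
  expect_equal(cc$stars["ash", "de"], "*")
  expect_equal(cc$stars["cf", "adf"], "**")
})

test_that("the two star conventions split the same p-values differently", {
  expect_equal(feedval:::star_label(c(0.005, 0.03, 0.07, 0.2), "p05_p01"),
               c("**", "*", "", ""))
  expect_equal(feedval:::star_label(c(0.005, 0.03, 0.07, 0.2), "p10_p05"),
               c("**", "**", "*", ""))
})

test_that("t-based correlation p agrees with a permutation oracle at n = 10", {
  set.seed(31)
  x <- rnorm(10)
  y <- 0.7 * x + rnorm(10)
  cc <- correlate_variables(tibble::tibble(x = x, y = y))
  r0 <- cor(x, y)
  b <- 1e5
  perm <- matrix(0, nrow = 10, ncol = b)
  for (j in seq_len(b)) perm[, j] <- sample(y)
  r_perm <- drop(cor(x, perm))
  p_perm <- (1 + sum(abs(r_perm) >= abs(r0))) / (b + 1)
  expect_lt(abs(cc$p["x", "y"] - p_perm), 0.02)
})

test_that("zero-variance variables are rejected by name", {
  d <- tibble::tibble(a = 1:5, b = rep(2, 5))
  expect_error(correlate_variables(d), class = "feedval_degenerate_variable")
  expect_error(correlate_variables(d), "b")
})

test_that("tidy() of a correlation object gives each unordered pair once", {
  cc <- correlate_variables(energy_dm_data(), c("de", "me", "ash"))
  td <- tidy(cc)
  expect_equal(nrow(td), 3)
  expect_true(all(c("r", "p.value", "stars") %in% names(td)))
})

test_that("a single-ash equation reproduces the printed DE equation exactly", {
  eq <- fit_prediction_equation(energy_dm_data(), "de", "ash")
  expect_printed(eq$intercept, 21.71)
  expect_equal(round(unname(eq$coefficients["ash"]), 2), -0.68)
  expect_equal(round(eq$r2, 2), 0.57)
  expect_equal(round(eq$rmse, 2), 1.06)
  expect_lt(eq$model_p, 0.05)
  g <- glance(eq)
  expect_equal(g$r.squared, eq$r2)
  expect_equal(g$df.residual, 8)
})

test_that("an exactly affine response gives R2 = 1 and RMSE = 0", {
  d <- tibble::tibble(x = 1:10, y = 3 + 2 * (1:10))
  eq <- fit_prediction_equation(d, "y", "x")
  expect_equal(eq$r2, 1)
  expect_equal(eq$rmse, 0, tolerance = 1e-10)
})

test_that("single-predictor R2 equals the squared Pearson correlation", {
  d <- energy_dm_data()
  for (p in c("ash", "ge", "ndf")) {
    eq <- fit_prediction_equation(d, "de", p)
    cc <- correlate_variables(d, c("de", p))
    expect_equal(eq$r2, cc$r["de", p]^2, tolerance = 1e-12)
  }
})

test_that("model diagnostics match the standard least-squares summary", {
  d <- energy_dm_data()
  eq <- fit_prediction_equation(d, "de", c("ge", "cp"))
  ref <- summary(lm(de ~ ge + cp, data = d))
  expect_equal(eq$r2, ref$r.squared, tolerance = 1e-12)
  expect_equal(eq$rmse, ref$sigma, tolerance = 1e-12)
  expect_equal(eq$model_p,
               pf(ref$fstatistic[1], ref$fstatistic[2], ref$fstatistic[3],
                  lower.tail = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("degenerate fits raise typed errors", {
  d <- tibble::tibble(y = c(1, 2, 3), x1 = c(1, 2, 3), x2 = c(2, 4, 6))
  expect_error(fit_prediction_equation(d, "y", c("x1", "x2")),
               class = "feedval_insufficient_data")
  d2 <- tibble::tibble(y = rnorm(8), x1 = 1:8, x2 = 2 * (1:8), x3 = rnorm(8))
  expect_error(fit_prediction_equation(d2, "y", c("x1", "x2", "x3")),
               class = "feedval_collinearity_error")
})

test_that("prediction applies the equation and checks predictors", {
  eq <- fit_prediction_equation(energy_dm_data(), "de", "ash")
  expect_equal(round(predict(eq, tibble::tibble(ash = 9.17)), 2), 15.47,
               tolerance = 0.015)
  at_zero <- predict(eq, tibble::tibble(ash = 0))
  expect_equal(at_zero, eq$intercept)
  expect_error(predict(eq, tibble::tibble(ge = 18)),
               class = "feedval_schema_error")
})

test_that("best-subset selection equals an explicit enumeration oracle", {
  d <- energy_dm_data()
  candidates <- c("ge", "cp", "ash", "ndf", "cf", "ee")
  sel <- select_equations(d, "de", candidates, max_terms = 2)
  # oracle: brute-force all subsets with plain lm
  subsets <- c(as.list(candidates), combn(candidates, 2, simplify = FALSE))
  oracle <- lapply(subsets, function(tr) {
    f <- summary(lm(stats::reformulate(tr, "de"), data = d))
    list(terms = paste(sort(tr), collapse = " + "), r2 = f$r.squared,
         rmse = f$sigma)
  })
  r2s <- vapply(oracle, `[[`, 0, "r2")
  best <- oracle[[which.max(r2s)]]
  expect_equal(sel$terms[1], best$terms)
  expect_equal(sel$r2[1], best$r2, tolerance = 1e-12)
  expect_equal(nrow(sel), length(subsets))
  # ranking is monotone in r2
  expect_true(all(diff(sel$r2) <= 1e-12))
})

test_that("the top two-term energy model uses GE and CP", {
  sel <- select_equations(energy_dm_data(), "de",
                          c("ge", "cp", "ash", "ndf", "cf", "adf", "ee"),
                          max_terms = 2)
  expect_equal(sel$terms[1], "cp + ge")
  expect_equal(round(sel$r2[1], 2), 0.76)
})

test_that("selection degenerates gracefully", {
  d <- energy_dm_data()
  single <- select_equations(d, "de", "ash")
  direct <- fit_prediction_equation(d, "de", "ash")
  expect_equal(single$r2[1], direct$r2)
  expect_equal(nrow(single), 1)
  # max_terms = 1 returns the predictor with max |r|
  sel1 <- select_equations(d, "de", c("ge", "cp", "ash", "ndf"), max_terms = 1)
  cc <- correlate_variables(d, c("de", "ge", "cp", "ash", "ndf"))
  expect_equal(sel1$terms[1],
               names(which.max(abs(cc$r["de", c("ge", "cp", "ash", "ndf")]))))
  expect_error(select_equations(d, "de", character(0)),
               class = "feedval_config_error")
})

test_that("forward stepwise selects a nested model consistent with best subset", {
  d <- energy_dm_data()
  fw <- select_equations(d, "de", c("ge", "cp", "ash", "ndf", "cf", "adf"),
                         max_terms = 2, method = "forward")
  expect_equal(nrow(fw), 1)
  expect_true(fw$n_terms[1] >= 1)
  expect_true(all(strsplit(fw$terms[1], " \\+ ")[[1]] %in%
                    c("ge", "cp", "ash", "ndf", "cf", "adf")))
})
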