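test_that("a noise-free fixed effect is recovered to machine tolerance", {
  tab <- withr::with_seed(1, {
    tibble::tibble(
      patient = rep(c("p1", "p2", "p3"), each = 40),
      ec_degree = stats::rnorm(120),
      sc_degree = 0.4 * ec_degree + rep(c(-1, 0, 1), each = 40) +
        stats::rnorm(120, sd = 1e-5)
    )
  })
  fit <- suppressWarnings(suppressMessages(  # optimizer warns near zero residual variance
    fit_multilevel(tab, predictors = "ec_degree", standardize = FALSE)))
  expect_equal(fit$fixed$estimate[fit$fixed$term == "ec_degree"], 0.4,
               tolerance = 1e-4)
})

test_that("ICC hits its limits for degenerate variance structures", {
  # no between-patient variance
  tab0 <- withr::with_seed(2, {
    tibble::tibble(patient = rep(sprintf("p%d", 1:10), each = 50),
                   sc_degree = stats::rnorm(500))
  })
  f0 <- suppressMessages(fit_intercept_only(tab0))
  expect_lt(f0$icc, 0.05)
  # identical values within patients, different means across
  tab1 <- tibble::tibble(patient = rep(sprintf("p%d", 1:6), each = 20),
                         sc_degree = rep(c(1, 3, 5, 7, 9, 11), each = 20))
  f1 <- suppressWarnings(fit_intercept_only(tab1))  # roundoff warning at the ICC=1 boundary
  expect_gt(f1$icc, 0.99)
  expect_error(fit_intercept_only(tab1[tab1$patient == "p1", ]),
               "at least 2 patients")
})

test_that("the intercept-only ICC tracks the generative variance ratio", {
  cfg <- sim_config(n_patients = 50, nodes_per_patient = 66, seed = 6)
  tab <- simulate_cohort(cfg)
  fit <- fit_intercept_only(tab)
  expect_equal(fit$icc, 0.37, tolerance = 0.08)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
})

test_that("cohort tables have the configured structure and missing-SOZ patients", {
  cfg <- sim_config(n_patients = 13, nodes_per_patient = 66,
                    n_soz_undetermined = 2, seed = 3)
  tab <- simulate_cohort(cfg)
  expect_equal(nrow(tab), 13 * 66)
  expect_equal(dplyr::n_distinct(tab$patient), 13)
  na_pat <- unique(tab$patient[is.na(tab$soz)])
  expect_equal(length(na_pat), 2)
  expect_identical(simulate_cohort(cfg), tab)  # seeded determinism
})

test_that("the full multilevel fit recovers planted coefficients with sane CIs", {
  cfg <- sim_config(n_patients = 13, nodes_per_patient = 66, seed = 11)
  tab <- simulate_cohort(cfg)
  fit <- suppressMessages(fit_multilevel(
    tab, predictors = c("ec_degree", "proximity_mm", "vea_mm3", "soz")))
  fx <- fit$fixed
  b_ecd <- fx[fx$term == "ec_degree", ]
  b_np <- fx[fx$term == "proximity_mm", ]
  expect_lt(abs(b_ecd$estimate - 0.13), 3 * b_ecd$std_error)
  expect_lt(abs(b_np$estimate + 0.13), 3 * b_np$std_error)
  expect_true(all(fx$conf_low < fx$estimate & fx$estimate < fx$conf_high))
  # residual df convention: rows - fixed effects - patients (11 SOZ patients)
  n_rows <- sum(!is.na(tab$soz))
  expect_equal(unique(fx$df), n_rows - 5 - 11)
})

test_that("Satterthwaite degrees of freedom are available as an option", {
  cfg <- sim_config(n_patients = 6, nodes_per_patient = 30, seed = 12)
  tab <- simulate_cohort(cfg)
  f1 <- fit_multilevel(tab, predictors = "ec_degree")
  f2 <- fit_multilevel(tab, predictors = "ec_degree",
                       df_method = "satterthwaite")
  expect_false(isTRUE(all.equal(f1$fixed$df, f2$fixed$df)))
  expect_equal(f1$fixed$estimate, f2$fixed$estimate)
})

test_that("backward elimination drops null predictors and keeps true ones", {
  cfg <- sim_config(n_patients = 13, nodes_per_patient = 66, seed = 5)
  tab <- simulate_cohort(cfg)
  fit <- backward_eliminate(tab)
  expect_setequal(fit$retained, c("ec_degree", "proximity_mm"))
  expect_true(all(c("vea_mm3", "soz") %in% fit$path$dropped[!is.na(fit$path$dropped)]))
  # elimination path records one row per step, ending with no drop
  expect_true(is.na(fit$path$p_dropped[nrow(fit$path)]))
  # final fit uses all patients once SOZ left the model
  expect_equal(fit$n_obs, nrow(tab))
  expect_equal(fit$n_patients, 13)
})

test_that("all-null predictors collapse to the intercept-only model", {
  tab <- withr::with_seed(8, {
    tibble::tibble(
      patient = rep(sprintf("p%d", 1:8), each = 40),
      sc_degree = stats::rnorm(320) + rep(stats::rnorm(8), each = 40),
      x1 = stats::rnorm(320), x2 = stats::rnorm(320)
    )
  })
  fit <- backward_eliminate(tab, predictors = c("x1", "x2"))
  if (fit$all_eliminated) {
    expect_length(fit$retained, 0)
  } else {
    # a false retention is possible; it must then be nominally significant
    expect_true(all(fit$fixed$p_value[fit$fixed$term %in% fit$retained] <= 0.05))
  }
})

test_that("tidy and glance expose the fit in broom style", {
  cfg <- sim_config(n_patients = 5, nodes_per_patient = 25, seed = 9)
  tab <- simulate_cohort(cfg)
  fit <- fit_multilevel(tab, predictors = c("ec_degree", "proximity_mm"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf_low", "conf_high", "p_value")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$icc, fit$icc)
  expect_equal(gl$n_obs, 125)
})
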