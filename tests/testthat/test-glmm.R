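test_that("intercept-only fit on constant k/n = 1/2 gives logit(0.5) and zero RE", {
  df <- data.frame(k = rep(10L, 12), n = rep(20L, 12),
                   subject_id = rep(sprintf("s%d", 1:4), each = 3),
                   timepoint = factor(rep(c("S", "A", "W"), 4),
                                      c("S", "A", "W")))
  fit <- fit_glmm(df, include_timepoint = FALSE)
  expect_lt(abs(fit$coefficients$estimate[1]), 1e-5)
  expect_lt(fit$ranef_sd, 1e-3)
  expect_true(fit$converged)
})

test_that("AIC identity and invariances hold", {
  df <- sim_glmm_data(3, beta_x = 0.5)
  fit <- fit_glmm(df, fixed_terms = "x")
  expect_equal(fit$aic, 2 * fit$n_par - 2 * fit$loglik, tolerance = 1e-8)

  # observation order invariance
  set.seed(1); ord <- sample(nrow(df))
  fit2 <- fit_glmm(df[ord, ], fixed_terms = "x")
  expect_equal(fit$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)

  # subject relabeling invariance
  df3 <- df; df3$subject_id <- paste0("zz_", df3$subject_id)
  fit3 <- fit_glmm(df3, fixed_terms = "x")
  expect_equal(fit$coefficients$estimate, fit3$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("zero between-subject variance reduces to a plain binomial GLM", {
  df <- sim_glmm_data(11, n_subjects = 40, beta_x = 0.6, sd_subject = 0)
  fit <- fit_glmm(df, fixed_terms = "x")
  ref <- stats::glm(cbind(k, n - k) ~ timepoint + x, data = df,
                    family = stats::binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-3)
})

test_that("input validation: marginality, missing columns, NA, bad response", {
  df <- sim_glmm_data(2)
  expect_error(fit_glmm(df, interactions = "x"),
               "marginality|main effect")
  expect_error(fit_glmm(df, fixed_terms = "ghost"), "lacks columns")
  df_na <- df; df_na$x[1] <- NA
  expect_error(fit_glmm(df_na, fixed_terms = "x"), "missing values")
  df_bad <- df; df_bad$k[1] <- df_bad$n[1] + 1L
  expect_error(fit_glmm(df_bad, fixed_terms = "x"), "k <= n")
  expect_error(fit_glmm(df[df$subject_id == "s001", ], fixed_terms = "x"),
               "2 subjects")
})

test_that("interaction screening keeps a true interaction and drops a null one", {
  d_int <- sim_glmm_data(5, n_subjects = 50, beta_x = 0.3,
                         beta_int = c(A = 0, W = 1.0))
  sc <- screen_interaction(d_int, "x")
  expect_true(sc$keep_interaction)
  expect_lt(sc$interaction_p, 0.05)
  expect_true(any(grepl("x:timepoint|timepoint.*:x", deparse(sc$model$formula))))

  d_null <- sim_glmm_data(6, n_subjects = 50, beta_x = 0.3)
  sc2 <- screen_interaction(d_null, "x")
  expect_false(sc2$keep_interaction)
  expect_false(any(grepl(":", vapply(sc2$model$coefficients$term,
                                     identity, character(1)))))

  d_one_tp <- sim_glmm_data(7, timepoints = "S")
  expect_error(screen_interaction(d_one_tp, "x"), "one timepoint")
  expect_error(screen_interaction(d_null[1:5, ], "x"), "complete rows")
})

test_that("forward selection enters a strong candidate and gates a null model", {
  d_strong <- sim_glmm_data(8, n_subjects = 40, beta_x = 1.5)
  res <- forward_select(d_strong, "x")
  expect_identical(res$selected, "x")
  expect_identical(res$trace[[1]]$phase, "p_gate")
  expect_match(res$trace[[1]]$decision, "enter 'x'")

  # timepoint-only model when nothing passes the gate (a fixed null seed
  # picked before looking at outcomes; operating characteristics are tested
  # in the acceptance suite)
  d_null <- sim_glmm_data(1002, n_subjects = 40, beta_x = 0)
  res2 <- forward_select(d_null, "x")
  if (length(res2$selected) == 0) {
    expect_match(res2$trace[[1]]$decision, "timepoint-only")
    expect_identical(res2$model$fixed_terms, character(0))
  } else {
    succeed("null candidate entered (5% event under the gate)")
  }
})

test_that("a duplicated collinear candidate never enters twice", {
  df <- sim_glmm_data(9, n_subjects = 40, beta_x = 1.2)
  df$x2 <- df$x  # perfect copy
  res <- forward_select(df, c("x", "x2"))
  expect_identical(res$selected, "x")
  expect_match(res$trace[[2]]$decision, "stop")
})

test_that("selection respects per-phase missing-data handling", {
  df <- sim_glmm_data(10, n_subjects = 40, beta_x = 1.5)
  df$z <- rnorm(nrow(df))
  df$z[1:10] <- NA         # missing only in a null candidate
  res <- forward_select(df, c("x", "z"))
  expect_identical(res$selected, "x")
  # step 1 used all x-complete rows; phase 2 only z-complete rows
  expect_identical(res$trace[[1]]$candidates$x$n_used, nrow(df))
  expect_identical(res$trace[[2]]$n_used, nrow(df) - 10L)
  # final refit back on all rows complete for the selected variable only
  expect_identical(res$model$n_obs, nrow(df))
})

test_that("per-timepoint models drop timepoint, keep the random intercept, and skip small strata", {
  df <- sim_glmm_data(12, n_subjects = 30, beta_x = 1.5)
  res <- per_timepoint_models(df, "x")
  expect_identical(sort(names(res)), c("A", "S", "W"))
  for (tp in names(res)) {
    expect_false(isTRUE(res[[tp]]$skipped))
    expect_false(res[[tp]]$model$include_timepoint)
  }
  small <- rbind(df[df$timepoint != "W", ], df[df$timepoint == "W", ][1:5, ])
  res2 <- per_timepoint_models(small, "x")
  expect_true(res2$W$skipped)
  expect_match(res2$W$reason, "only 5")
})

test_that("scaled residual diagnostics are calibrated on self-simulated data", {
  df <- sim_glmm_data(13, n_subjects = 40, beta_x = 0.5)
  fit <- fit_glmm(df, fixed_terms = "x")
  diag <- simulate_residuals(fit, df, n_sim = 200, seed = 4)
  expect_true(all(diag$scaled_residuals >= 0 & diag$scaled_residuals <= 1))
  expect_gt(diag$ks_p, 0.01)
  expect_gt(diag$dispersion_ratio, 0.7)
  expect_lt(diag$dispersion_ratio, 1.3)

  expect_error(simulate_residuals(fit, df, n_sim = 99), ">= 100")

  # deterministic given seed
  diag2 <- simulate_residuals(fit, df, n_sim = 200, seed = 4)
  expect_identical(diag$scaled_residuals, diag2$scaled_residuals)
})

test_that("overdispersed responses are flagged by the dispersion test", {
  df <- sim_glmm_data(14, n_subjects = 40, beta_x = 0)
  # beta-binomial contamination: strong extra-binomial noise
  set.seed(99)
  p <- plogis(-2 + rnorm(nrow(df), 0, 1.5))
  df$k <- rbinom(nrow(df), df$n, p)
  fit <- fit_glmm(df)
  diag <- simulate_residuals(fit, df, n_sim = 200, seed = 5)
  expect_gt(diag$dispersion_ratio, 1.2)
  expect_lt(diag$dispersion_p, 0.05)
})

test_that("prepare_model_data joins covariates, codes factors, drops antibiotics", {
  study <- generate_study(small_config(seed = 31, antibiotics_rate = 0.3))
  filt <- filter_pipeline(study$table, study$taxonomy, study$metadata$samples,
                          seed = 1)
  shared <- shared_table(filt$table, filt$records)
  d <- prepare_model_data(shared, study$metadata$subjects, "saliva")
  expect_true(all(c("k", "n", "built", "gardening") %in% names(d)))
  expect_identical(levels(d$timepoint), c("S", "A", "W"))
  expect_identical(levels(d$gardening), c("rarely", "at_least_monthly"))
  d_all <- prepare_model_data(shared, study$metadata$subjects, "saliva",
                              exclude_antibiotics = FALSE)
  expect_gt(nrow(d_all), nrow(d))
  expect_error(prepare_model_data(shared, study$metadata$subjects, "plasma"))
})
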