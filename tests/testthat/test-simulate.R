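test_that("covariate drawing honors strata, missingness, and the configured means", {
  cfg <- small_config(seed = 3, proportion_urban = 1, missingness_fraction = 0)
  covs <- draw_covariates(cfg)
  expect_true(all(covs$urban == "u"))
  expect_false(anyNA(covs))

  cfg2 <- small_config(seed = 3, missingness_fraction = 0.1)
  covs2 <- draw_covariates(cfg2)
  expect_gt(sum(is.na(covs2$gardening), is.na(covs2$number_of_persons)), 0)
  expect_true(all(covs2$built >= 0 & covs2$built <= 100))
  expect_true(all(covs2$outdoor >= 0 & covs2$outdoor <= 4))
  expect_true(all(covs2$number_of_persons %in% c(1:5, NA)))

  # law of large numbers: empirical built mean near the urban/rural mixture
  cfg3 <- small_config(seed = 8, n_subjects = 5000, timepoints = "S",
                       proportion_urban = 0.4)
  covs3 <- draw_covariates(cfg3)
  expect_lt(abs(mean(covs3$built) - (0.4 * 70 + 0.6 * 15)), 3)
})

test_that("true_dispersal matches the logistic closed form", {
  covs <- data.frame(subject_id = "a", timepoint = "S", built = 50,
                     stringsAsFactors = FALSE)
  b <- list(intercept = -2, built = 0.02, timepoint = c(A = 0, W = 0))
  expect_equal(true_dispersal(covs, b), plogis(-1), tolerance = 1e-12)
  expect_equal(true_dispersal(covs, list(intercept = 0,
                                         timepoint = c(A = 0, W = 0))), 0.5)
  expect_lt(true_dispersal(covs, list(intercept = -50,
                                      timepoint = c(A = 0, W = 0))), 1e-12)
  covs$built <- NA
  expect_error(true_dispersal(covs, b), "missing.*built")
})

test_that("simulate_sample restricts support as the mixture dictates", {
  core <- c(0.5, 0.5, 0, 0)
  env <- c(0, 0, 0.3, 0.7)
  set.seed(2)
  h0 <- simulate_sample("saliva", core, env, d = 0, library_size = 500)
  expect_identical(sum(h0[3:4]), 0L)
  m0 <- simulate_sample("mat", core, env, h = 0, library_size = 500)
  expect_identical(sum(m0[1:2]), 0L)

  s <- simulate_sample("saliva", core, env, d = 0.3, library_size = 10000)
  expect_lt(abs(sum(s[3:4]) / 10000 - 0.3), 0.02)
  expect_identical(sum(s), 10000L)

  expect_error(simulate_sample("saliva", core * 0, env, d = 0,
                               library_size = 10), "empty")
  expect_error(simulate_sample("saliva", core, env, library_size = 0), ">= 1")
})

test_that("generate_study is deterministic and structurally complete", {
  cfg <- small_config(seed = 19, n_subjects = 2, timepoints = "S",
                      n_mat_replicates = 2, n_negative_controls = 3)
  st <- generate_study(cfg)
  # 2 subjects x (3 human types + 2 mat replicates) + 3 controls
  expect_identical(nrow(st$table), 2L * 5L + 3L)
  expect_identical(nrow(st$truth), 2L)

  st2 <- generate_study(cfg)
  expect_identical(unclass(st$table), unclass(st2$table))
  expect_identical(st$metadata, st2$metadata)

  # winter skin absent
  cfg_w <- small_config(seed = 19, n_subjects = 2, timepoints = c("S", "W"))
  st_w <- generate_study(cfg_w)
  smp <- st_w$metadata$samples
  expect_identical(sum(smp$sample_type == "skin" & smp$timepoint == "W"), 0L)
  expect_gt(sum(smp$sample_type == "skin" & smp$timepoint == "S"), 0L)
})

test_that("contamination reaches every control; real taxa never do", {
  st <- generate_study(small_config(seed = 23))
  m <- unclass(st$table)
  ctrl <- st$metadata$samples$sample_id[
    st$metadata$samples$sample_type == "negative_control"]
  ctrl_m <- m[ctrl, , drop = FALSE]
  contam <- names(st$origin)[st$origin == "contaminant"]
  # every contaminant in >= 1 control; here by construction in all
  expect_true(all(colSums(ctrl_m[, contam, drop = FALSE] > 0) >= 1))
  # controls carry ONLY contaminant taxa
  non_contam <- names(st$origin)[st$origin != "contaminant"]
  expect_identical(sum(ctrl_m[, non_contam]), 0L)

  # zero-contaminant config leaves controls empty
  st0 <- generate_study(small_config(seed = 23, n_contaminant_taxa = 0))
  m0 <- unclass(st0$table)
  ctrl0 <- st0$metadata$samples$sample_id[
    st0$metadata$samples$sample_type == "negative_control"]
  expect_identical(sum(m0[ctrl0, ]), 0L)
})

test_that("the strict control filter eliminates all injected contaminants", {
  st <- generate_study(small_config(seed = 29))
  filt <- filter_pipeline(st$table, st$taxonomy, st$metadata$samples, seed = 1)
  expect_identical(sum(st$origin[asv_ids(filt$table)] == "contaminant"), 0L)
  # contamination inflates naive sharing: shared count before >= after filter
  merged <- merge_replicates(st$table, st$metadata$samples)
  pr <- pair_samples(merged$records)$pairs[1, ]
  k_before <- shared_statistic(presence_set(merged$table, pr$human_sample_id),
                               presence_set(merged$table, pr$mat_sample_id))$k
  pr2 <- pair_samples(filt$records)$pairs
  pr2 <- pr2[pr2$subject_id == pr$subject_id & pr2$timepoint == pr$timepoint &
               pr2$human_type == pr$human_type, ]
  k_after <- shared_statistic(presence_set(filt$table, pr2$human_sample_id),
                              presence_set(filt$table, pr2$mat_sample_id))$k
  expect_gte(k_before, k_after)
})

test_that("built coefficient induces a positive built-dispersal association", {
  cfg <- small_config(seed = 37, n_subjects = 40, timepoints = "S",
                      beta = list(intercept = -3.5, built = 0.02,
                                  timepoint = c(A = 0, W = 0)))
  st <- generate_study(cfg)
  covs <- st$metadata$subjects
  expect_gt(cor(covs$built, st$truth$d), 0.9)
})

test_that("write_study emits files the readers round-trip", {
  st <- generate_study(small_config(seed = 41, n_subjects = 3,
                                    timepoints = "S"))
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  tab <- read_count_table(paths["counts"])
  expect_identical(unclass(tab), unclass(st$table))
  md <- read_metadata(paths["metadata"])
  expect_identical(md$samples, st$metadata$samples)
  tax <- read_taxonomy(paths["taxonomy"])
  expect_identical(tax$asv_id, st$taxonomy$asv_id)
  expect_identical(tax$lineage[[1]], st$taxonomy$lineage[[1]])
})
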