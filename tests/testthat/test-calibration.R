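test_that("anchored calibration recovers generating thresholds from simulated data", {
  bank <- study_bank()
  sim <- simulate_cohort(cohort_spec(800, 2.30, 1.99, seed = 402), bank)
  res <- jmle_calibrate(sim$responses, anchors = bank)
  expect_true(res$converged)
  err <- res$bank$scale$thresholds - c(-4.16, -1.50, 2.66)
  expect_lt(sqrt(mean(err^2)), 0.2)   # looser than the n = 2000 regime
  # anchored difficulties are passed through untouched
  cal <- calibrated_items(bank)
  got <- res$bank$items$difficulty[match(cal$item_id, res$bank$items$item_id)]
  expect_equal(got, cal$difficulty)
})

test_that("unanchored calibration is identified and agrees with truth up to location", {
  bank <- study_bank()
  sim <- simulate_cohort(cohort_spec(800, 2.30, 1.99, seed = 402), bank)
  res <- jmle_calibrate(sim$responses)
  expect_equal(mean(res$bank$items$difficulty), 0, tolerance = 1e-10)
  expect_equal(sum(res$bank$scale$thresholds), 0, tolerance = 1e-10)
  cal <- calibrated_items(bank)
  got <- res$bank$items$difficulty[match(cal$item_id, res$bank$items$item_id)]
  expect_gt(stats::cor(got, cal$difficulty), 0.99)
  # mild spread inflation (order J/(J-1)) plus sampling noise bounds the
  # per-item error once locations are aligned
  shifted <- got + mean(cal$difficulty)
  expect_lt(max(abs(shifted - cal$difficulty)), 0.35)

  # identification invariance: anchoring difficulties at the unanchored
  # solution shifted by a constant must reproduce the same thresholds and
  # shift every person measure by that constant
  off <- 0.7
  anchors2 <- item_bank(transform(res$bank$items, difficulty = difficulty + off),
                        res$bank$scale)
  resA <- jmle_calibrate(sim$responses, anchors = anchors2)
  expect_equal(resA$bank$scale$thresholds, res$bank$scale$thresholds,
               tolerance = 1e-3)
  thU <- vapply(res$person_measures, function(a) a$theta, 0)
  thA <- vapply(resA$person_measures, function(a) a$theta, 0)
  keep <- abs(thU) < 9
  expect_equal(mean(thA[keep] - thU[keep]), off, tolerance = 1e-3)
})

test_that("calibration is deterministic and symmetric for duplicated items", {
  bank <- toy_bank()
  sim <- simulate_cohort(cohort_spec(250, 0, 1.5, seed = 9), bank)
  X <- sim$responses
  X2 <- cbind(X, X[, 2, drop = FALSE])
  colnames(X2) <- c(colnames(X), "6")
  res <- jmle_calibrate(X2)
  d <- res$bank$items$difficulty
  expect_equal(d[res$bank$items$item_id == 2L], d[res$bank$items$item_id == 6L],
               tolerance = 1e-6)
  # bitwise determinism
  res2 <- jmle_calibrate(X2)
  expect_identical(res$bank$items$difficulty, res2$bank$items$difficulty)
  expect_identical(res$bank$scale$thresholds, res2$bank$scale$thresholds)
})

test_that("zero-variance items are dropped with a warning", {
  bank <- toy_bank()
  sim <- simulate_cohort(cohort_spec(150, 0, 1.5, seed = 10), bank)
  X <- sim$responses
  X[, 3] <- 2L
  expect_warning(res <- jmle_calibrate(X), "no response variance")
  expect_false(3L %in% res$bank$items$item_id)
})

test_that("fit statistics are centred near 1 for model-consistent data", {
  bank <- study_bank()
  sim <- simulate_cohort(cohort_spec(1000, 2.30, 1.99, seed = 77), bank)
  pm <- estimate_persons(sim$responses, bank)
  fs <- fit_statistics(sim$responses, bank, pm)
  expect_gt(mean(fs$item$outfit), 0.9)
  expect_lt(mean(fs$item$outfit), 1.1)
  expect_gt(mean(fs$item$infit), 0.9)
  expect_lt(mean(fs$item$infit), 1.1)
  # with measures held at truth the Wilson-Hilferty Z is close to standard
  # normal: most items inside +/- 1.96
  pm_true <- lapply(sim$theta, function(t) ability_estimate(t, 0.1, 24))
  fs_true <- fit_statistics(sim$responses, bank, pm_true)
  expect_gt(mean(abs(fs_true$item$infit_z) < 1.96), 0.85)
  expect_lt(abs(mean(fs_true$item$infit_z)), 1)
})

test_that("outfit is zero when responses equal integer-valued expected scores", {
  sc <- rating_scale(c(0, 0))            # E = 1 exactly at theta = delta
  bank <- item_bank(data.frame(item_id = 1:3, label = letters[1:3],
                               difficulty = 0, se = NA, infit = NA,
                               outfit = NA, status = "calibrated"), sc)
  X <- matrix(1L, nrow = 4, ncol = 3, dimnames = list(NULL, 1:3))
  pm <- lapply(1:4, function(i) ability_estimate(0, 1, 3))
  fs <- fit_statistics(X, bank, pm)
  expect_equal(fs$item$outfit, rep(0, 3))
  expect_equal(fs$person$outfit, rep(0, 4))
})

test_that("misfit filter retains the closed infit interval and the fixture's 24 items", {
  flt <- misfit_filter(study_bank())
  expect_equal(nrow(flt$bank$items), 24L)
  expect_equal(length(flt$misfit_item_ids), 13L)
  # boundary values are retained (closed interval)
  sc <- rating_scale(c(-1, 1))
  bb <- item_bank(data.frame(item_id = 1:4, label = letters[1:4],
                             difficulty = 0, se = NA,
                             infit = c(0.5, 1.5, 0.49, 1.51),
                             outfit = 1, status = "calibrated"), sc)
  flt2 <- misfit_filter(bb)
  expect_setequal(flt2$bank$items$item_id, c(1L, 2L))
  # degenerate bounds act as the identity
  flt3 <- misfit_filter(bb, lower = 0, upper = Inf)
  expect_equal(nrow(flt3$bank$items), 4L)
  expect_error(misfit_filter(bb, lower = 0.51, upper = 0.52), "all items misfit")
})

test_that("separation reliability behaves at its closed-form limits", {
  mk <- function(theta, se) lapply(seq_along(theta), function(i)
    ability_estimate(theta[i], se[i], 10))
  expect_equal(separation_reliability(mk(c(-1, 0, 1, 2), rep(0, 4))), 1)
  v <- stats::var(c(-1, 0, 1, 2))
  expect_equal(separation_reliability(mk(c(-1, 0, 1, 2), rep(sqrt(v), 4))), 0)
  expect_warning(r0 <- separation_reliability(mk(c(1, 1, 1), rep(0.3, 3))),
                 "zero observed variance")
  expect_equal(r0, 0)
  expect_error(separation_reliability(list(ability_estimate(0, 1, 5))), ">= 2")
})

test_that("reliability grows with test length on nested item subsets", {
  bank <- study_bank()
  sim <- simulate_cohort(cohort_spec(400, 2.30, 1.99, seed = 55), bank)
  rel_for <- function(k) {
    X <- sim$responses[, 1:k, drop = FALSE]
    separation_reliability(estimate_persons(X, bank))
  }
  rels <- vapply(c(6, 12, 24), rel_for, 0)
  expect_true(all(diff(rels) > 0))
})

test_that("SEM stop value follows the reference SD and reliability", {
  expect_equal(sem_stop_value(1.99, 0.88), 1.99 * sqrt(0.12))
  expect_equal(floor(sem_stop_value(1.99, 0.88) * 100) / 100, 0.68)
  expect_equal(sem_stop_value(1.99, 1), 0)
  expect_equal(sem_stop_value(1.99, 0), 1.99)
  expect_error(sem_stop_value(1.99, 1.2), "reliability")
  expect_error(sem_stop_value(-1, 0.5), "positive")
})

test_that("residual PCA sees noise-level structure in unidimensional data", {
  bank <- study_bank()
  sim <- simulate_cohort(cohort_spec(1000, 2.30, 1.99, seed = 31), bank)
  pm <- estimate_persons(sim$responses, bank)
  dp <- residual_pca(sim$responses, bank, pm)
  expect_lt(dp$first_contrast_eigenvalue, 3)
  expect_lt(dp$first_contrast_variance, 5)
  expect_gt(dp$variance_explained_by_measures, 0)
  expect_lt(dp$variance_explained_by_measures, 100)
  # eigenvalues of near-independent residuals concentrate near 1 (one
  # near-null direction is expected: residuals at the fitted measure are
  # linearly constrained within persons)
  expect_lt(max(dp$eigenvalues), 1.6)
  expect_gt(sort(dp$eigenvalues)[2L], 0.4)
})

test_that("a pasted second trait inflates the first residual contrast", {
  bank <- study_bank()
  cal <- calibrated_items(bank)
  half_a <- item_bank(cal[1:12, ], bank$scale)
  half_b0 <- cal[13:24, ]
  half_b <- item_bank(half_b0, bank$scale)
  set.seed(64)
  simA <- simulate_cohort(cohort_spec(600, 2.3, 1.99, seed = 640), half_a)
  simB <- simulate_cohort(cohort_spec(600, 2.3, 1.99, seed = 641), half_b)
  X2 <- cbind(simA$responses, simB$responses)   # two independent traits
  pm2 <- estimate_persons(X2, bank)
  two <- residual_pca(X2, bank, pm2)
  sim1 <- simulate_cohort(cohort_spec(600, 2.3, 1.99, seed = 642), bank)
  pm1 <- estimate_persons(sim1$responses, bank)
  one <- residual_pca(sim1$responses, bank, pm1)
  expect_gt(two$first_contrast_eigenvalue, one$first_contrast_eigenvalue)
  expect_gt(two$first_contrast_eigenvalue, 3)   # clear second dimension
})

test_that("category diagnostics apply the four rating-scale guidelines", {
  bank <- study_bank()
  sim <- simulate_cohort(cohort_spec(600, 2.30, 1.99, seed = 21), bank)
  pm <- estimate_persons(sim$responses, bank)
  cd <- category_diagnostics(sim$responses, bank, pm)
  expect_equal(cd$threshold_advances, c(2.66, 4.16))
  expect_true(all(cd$guideline_flags[c("steps_advance", "advance_at_least_1.4",
                                       "advance_less_than_5")]))
  expect_true(cd$guideline_flags[["monotone_average_measures"]])
  expect_true(all(diff(cd$average_measures_per_category) > 0))

  # narrow steps violate the 1.4-logit advance rule
  bank2 <- toy_bank(tau = c(0, 0.5))
  sim2 <- simulate_cohort(cohort_spec(300, 0, 1.5, seed = 22), bank2)
  cd2 <- category_diagnostics(sim2$responses, bank2,
                              estimate_persons(sim2$responses, bank2))
  expect_false(cd2$guideline_flags[["advance_at_least_1.4"]])
  expect_true(cd2$guideline_flags[["steps_advance"]])

  # a 6-logit advance violates the upper guideline
  bank3 <- toy_bank(tau = c(-3, 3))
  sim3 <- simulate_cohort(cohort_spec(300, 0, 1.5, seed = 23), bank3)
  cd3 <- category_diagnostics(sim3$responses, bank3,
                              estimate_persons(sim3$responses, bank3))
  expect_equal(cd3$threshold_advances, 6)
  expect_false(cd3$guideline_flags[["advance_less_than_5"]])
})

test_that("empty categories leave the average-measure guideline undetermined", {
  bank <- toy_bank(tau = c(-1, 0, 1))
  X <- matrix(c(1L, 2L, 1L, 2L, 3L, 2L, 1L, 3L, 2L, 1L,
                2L, 1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 2L), 4, 5,
              dimnames = list(NULL, 1:5))   # category 0 never used
  pm <- estimate_persons(X, bank)
  expect_warning(cd <- category_diagnostics(X, bank, pm), "empty rating category")
  expect_true(is.na(cd$guideline_flags[["monotone_average_measures"]]))
})
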