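small_cohort <- function(n = 103, seed = 21, ...) {
  generate_cohort(generation_config(n_samples = n, seed = seed, ...))
}

test_that("stratified_kfold partitions with balanced strata", {
  cohort <- small_cohort()
  fp <- stratified_kfold(cohort, k = 5, seed = 2)
  ids <- unlist(fp$folds)
  expect_setequal(ids, cohort$profiles$respondent_id)  # a partition
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(sort(lengths(fp$folds), decreasing = TRUE),
               c(21, 21, 21, 20, 20))
  # each fold matches the cohort within +/-1 respondent per stratum
  for (s in unique(fp$strata)) {
    members <- names(fp$strata)[fp$strata == s]
    per_fold <- vapply(fp$folds, function(f) sum(f %in% members), 1L)
    expect_lte(diff(range(per_fold)), 1L)
  }
  # deterministic under seed
  fp2 <- stratified_kfold(cohort, k = 5, seed = 2)
  expect_identical(fp$folds, fp2$folds)

  expect_error(stratified_kfold(cohort, k = 1), ">= 2")
  expect_error(stratified_kfold(cohort, k = 104), "cohort size")
  # k = n: leave-one-out
  tiny <- small_cohort(n = 8, seed = 3)
  expect_true(all(lengths(stratified_kfold(tiny, k = 8)$folds) == 1))
})

test_that("confusion_metrics matches hand arithmetic and a counting oracle", {
  pred <- c(rep(TRUE, 50), rep(FALSE, 10), rep(FALSE, 30), rep(TRUE, 10))
  truth <- c(rep(TRUE, 60), rep(FALSE, 40))
  m <- confusion_metrics(pred, truth)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 50 / 60)
  expect_equal(m$specificity, 0.75)

  set.seed(5)
  for (i in 1:5) {
    p <- runif(200) > 0.5; t <- runif(200) > 0.4
    m <- confusion_metrics(p, t)
    # independent elementwise enumeration
    expect_equal(m$accuracy, mean(p == t))
    expect_equal(m$sensitivity, sum(p & t) / sum(t))
    expect_equal(m$specificity, sum(!p & !t) / sum(!t))
  }

  # degenerate denominator: NA with a warning, never silently zero
  expect_warning(m0 <- confusion_metrics(c(FALSE, TRUE), c(FALSE, FALSE)),
                 "sensitivity")
  expect_true(is.na(m0$sensitivity))
})

test_that("level-matched truth reduces to the stored annotations at level 2", {
  cohort <- small_cohort()
  lt <- screentree:::level_truth(cohort, 2L)
  expect_equal(lt$positive, cohort$truth$positive)
  # level 4 has no latent stratum: only flipped-in positives remain
  lt4 <- screentree:::level_truth(cohort, 4L)
  key4 <- paste(lt4$respondent_id, lt4$label)
  fkey <- paste(cohort$noise_flips$respondent_id, cohort$noise_flips$label)
  expect_true(all(key4[lt4$positive] %in% fkey))
})

test_that("a noiseless moderate-or-worse cohort is classified perfectly", {
  cohort <- small_cohort(
    n = 60, seed = 31,
    severity_mix = c(mild = 0, moderate = 0.7, severe = 0.3),
    noise_rate = 0,
    response_style = list(jitter = 0, minimize = 0, endorse_absent = 0))
  rep <- evaluate_variant(cohort, n_trials = 1, k = 3, seed = 1)
  expect_equal(rep$metrics$accuracy, 1.0)
  expect_equal(rep$metrics$sensitivity, 1.0)
})

test_that("evaluate_variant is deterministic and macro-averages its folds", {
  cohort <- small_cohort(n = 80, seed = 8)
  a <- evaluate_variant(cohort, n_trials = 2, k = 3, seed = 9)
  b <- evaluate_variant(cohort, n_trials = 2, k = 3, seed = 9)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$per_fold, b$per_fold)
  # single trial: reported metrics equal the unweighted fold mean
  c1 <- evaluate_variant(cohort, n_trials = 1, k = 4, seed = 5)
  expect_equal(c1$metrics$accuracy, mean(c1$per_fold$accuracy))
  expect_equal(c1$metrics$mean_questions, mean(c1$per_fold$mean_questions))
})

test_that("severity sweep reproduces the negative time-severity correlation", {
  cohort <- small_cohort(n = 150, seed = 41)
  sweep <- severity_sweep(cohort, n_trials = 3, k = 5, seed = 6)
  expect_equal(sweep$level, c("mild", "moderate", "severe", "extreme"))
  # question count falls as the screening level rises (positive-rich cohort)
  expect_true(all(diff(sweep$mean_questions) <= 0))
  expect_true(all(sweep$accuracy >= 0 & sweep$accuracy <= 1))
  # the mild criterion is the least accurate screening condition
  expect_equal(which.min(sweep$accuracy), 1L)
  # one-level sweep reduces to evaluate_variant
  folds <- stratified_kfold(cohort, k = 5, seed = 6)
  one <- severity_sweep(cohort, levels = c(moderate = 2L), n_trials = 2,
                        k = 5, seed = 6)
  direct <- evaluate_variant(cohort, n_trials = 2, seed = 6, folds = folds)
  expect_equal(one$accuracy, direct$metrics$accuracy)
})

test_that("question count grows with the number of forced positives", {
  sweep <- positives_sweep(template = "MSSMHS", n_positive = c(0, 3, 10),
                           n_per_cell = 60, n_trials = 2, seed = 4)
  # no positives: exactly the comprehensive item count, nothing else
  expect_equal(sweep$mean_questions[[1]], 60)
  expect_true(all(diff(sweep$mean_questions) > 0))
  expect_equal(which.max(sweep$mean_questions), nrow(sweep))
})

test_that("ablation study orders variants as expected", {
  cohort <- generate_cohort(generation_config(
    n_samples = 150, age_mix = c(adult = 0, adolescent = 1, child = 0),
    seed = 17))
  tab <- ablation_study(cohort, n_trials = 2, seed = 17)
  tab2 <- ablation_study(cohort, n_trials = 2, seed = 17)
  expect_identical(tab, tab2)                       # determinism
  expect_equal(tab$variant,
               c("full", "no_sorting", "comprehensive_only", "no_indices"))
  qc <- setNames(tab$mean_questions, tab$variant)
  expect_equal(which.min(qc), c(comprehensive_only = 3L))
  acc <- setNames(tab$accuracy, tab$variant)
  # sorting changes order only: identical classifications, identical accuracy
  expect_equal(acc[["full"]], acc[["no_sorting"]])
  expect_true(all(acc[["full"]] >= acc - 1e-12))    # full is never beaten
  # always-descend asks every item of every single scale
  expect_equal(qc[["no_indices"]], 60 + 10 * 10)
})
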