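test_that("preset_threshold is the minimum-over-total score ratio", {
  expect_equal(preset_threshold(1, 2), 0.5)   # the worked 50% preset
  expect_equal(preset_threshold(3, 3), 1.0)
  expect_equal(preset_threshold(1, 4), 0.25)
  expect_error(preset_threshold(1, 0), "nonzero")
  expect_error(preset_threshold(3, 2), "s_min")
})

test_that("first_order_rate and the first-tier rule use an inclusive boundary", {
  expect_equal(first_order_rate(3, 5), 0.6)
  expect_equal(first_order_rate(0, 7), 0)
  expect_equal(first_order_rate(7, 7), 1)
  expect_error(first_order_rate(1, 0), "zero denominator")
  expect_error(first_order_rate(6, 5), "0..denominator")

  th <- screen_thresholds(p1 = 0.5, p2 = 0.5)
  expect_equal(classify_first_order(0.6, th), "positive")
  expect_equal(classify_first_order(0.5, th), "positive")    # boundary: >=
  expect_equal(classify_first_order(0.499, th), "non-positive")
  expect_equal(classify_first_order(0, th), "non-positive")
})

test_that("second_order_step stops early on the fixed-denominator rate", {
  # 10-item scale, preset 0.5: five positives in five answers -> stop at 5
  st <- new_second_order_state(10, p2 = 0.5)
  for (i in 1:4) {
    st <- second_order_step(st, 4L)
    expect_equal(st$status, "continue")
  }
  st <- second_order_step(st, 4L)
  expect_equal(st$status, "positive-stop")
  expect_equal(st$n_answered, 5L)
  expect_error(second_order_step(st, 0L), "already finished")

  # four positives over all ten answers -> negative only at the end
  st <- new_second_order_state(10, p2 = 0.5)
  resp <- c(rep(4L, 4), rep(0L, 6))
  for (i in 1:9) {
    st <- second_order_step(st, resp[[i]])
    expect_equal(st$status, "continue")
  }
  st <- second_order_step(st, resp[[10]])
  expect_equal(st$status, "negative-done")
  expect_equal(st$rate, 0.4)
})

test_that("administer handles the all-none and all-extreme respondents", {
  tree <- toy_tree()
  n_comp <- sum(lengths(tree$blocks))

  res0 <- administer(tree, function(id) 0L)
  expect_true(all(res0$classification == "negative"))
  expect_equal(res0$question_count, n_comp)           # no single items asked
  expect_equal(nrow(res0$log), n_comp)

  # all-extreme, presets 0.5: each second tier stops after ceil(0.5 * NSi)
  res4 <- administer(tree, function(id) 4L)
  expect_true(all(res4$classification == "positive"))
  expected <- n_comp + sum(vapply(tree$singles,
                                  function(s) ceiling(0.5 * length(s)), 1))
  expect_equal(res4$question_count, expected)
})

test_that("early-stop verdicts equal full administration, exhaustively", {
  # every positivity pattern of the 2x(3+4)-item toy system
  tree <- toy_tree()
  item_ids <- c(unlist(tree$blocks), unlist(tree$singles))
  n <- length(item_ids)
  grid <- as.matrix(expand.grid(rep(list(c(0L, 3L)), n)))
  colnames(grid) <- item_ids
  agree <- logical(nrow(grid))
  bounded <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    responses <- grid[i, ]
    res <- administer(tree, responses, keep_log = FALSE)
    want <- full_administration_oracle(tree, responses)
    agree[i] <- identical(unname(res$classification[tree$label_order]),
                          unname(want$classification[tree$label_order]))
    bounded[i] <- res$question_count <= want$question_count
  }
  expect_true(all(agree))
  expect_true(all(bounded))
})

test_that("question counts are bounded by the no-early-stop reference", {
  tree <- toy_tree()
  item_ids <- c(unlist(tree$blocks), unlist(tree$singles))
  total <- length(item_ids)
  set.seed(42)
  for (i in 1:50) {
    responses <- setNames(sample(0:4, total, replace = TRUE), item_ids)
    res <- administer(tree, responses, keep_log = FALSE)
    want <- full_administration_oracle(tree, responses)
    expect_lte(res$question_count, want$question_count)
    expect_lte(want$question_count, total)
    # the callback path and the vectorized path are the same engine
    res_fn <- administer(tree, function(id) responses[[id]])
    expect_identical(res_fn$classification, res$classification)
    expect_identical(res_fn$question_count, res$question_count)
  }
})

test_that("classifications are monotone in option values", {
  tree <- toy_tree()
  item_ids <- c(unlist(tree$blocks), unlist(tree$singles))
  set.seed(7)
  for (i in 1:30) {
    responses <- setNames(sample(0:4, length(item_ids), replace = TRUE),
                          item_ids)
    base <- administer(tree, responses, keep_log = FALSE)$classification
    bump <- sample(which(responses < 4), 1)
    responses[bump] <- responses[bump] + 1L
    raised <- administer(tree, responses, keep_log = FALSE)$classification
    expect_false(any(base == "positive" & raised == "negative"))
  }
})

test_that("classification ignores comprehensive item order within a block", {
  tree <- toy_tree()
  item_ids <- c(unlist(tree$blocks), unlist(tree$singles))
  set.seed(11)
  responses <- setNames(sample(0:4, length(item_ids), replace = TRUE),
                        item_ids)
  base <- administer(tree, responses, keep_log = FALSE)$classification
  shuffled <- tree
  shuffled$blocks <- lapply(tree$blocks, rev)
  again <- administer(shuffled, responses, keep_log = FALSE)$classification
  expect_equal(again, base)
})

test_that("ablation variants alter ordering, descent and stopping as stated", {
  tree <- toy_tree()
  n_comp <- sum(lengths(tree$blocks))
  expect_error(ablation_variant("bogus"))

  # all-none: comprehensive_only is identical to full (no descent anyway)
  full0 <- administer(tree, function(id) 0L, variant = "full")
  comp0 <- administer(tree, function(id) 0L, variant = "comprehensive_only")
  expect_equal(comp0$classification[tree$label_order],
               full0$classification[tree$label_order])
  expect_equal(comp0$question_count, full0$question_count)

  # all-extreme: counts differ by exactly the second-tier items asked
  full4 <- administer(tree, function(id) 4L, variant = "full")
  comp4 <- administer(tree, function(id) 4L, variant = "comprehensive_only")
  second_tier <- sum(vapply(tree$singles,
                            function(s) ceiling(0.5 * length(s)), 1))
  expect_equal(full4$question_count - comp4$question_count, second_tier)
  expect_equal(comp4$question_count, n_comp)

  # no_sorting agrees with full when every item is answered the same way
  # regardless of order (complete-administration order invariance)
  item_ids <- c(unlist(tree$blocks), unlist(tree$singles))
  set.seed(3)
  responses <- setNames(sample(0:4, length(item_ids), replace = TRUE),
                        item_ids)
  a <- administer(tree, responses, variant = "full", keep_log = FALSE)
  b <- administer(tree, responses, variant = "no_sorting", keep_log = FALSE)
  expect_equal(b$classification[tree$label_order],
               a$classification[tree$label_order])

  # no_indices always descends and never stops early
  c0 <- administer(tree, function(id) 0L, variant = "no_indices")
  expect_equal(c0$question_count,
               n_comp + sum(lengths(tree$singles)))
})

test_that("a failing respondent aborts the session but preserves the log", {
  tree <- toy_tree()
  flaky <- local({
    n <- 0L
    function(id) {
      n <<- n + 1L
      if (n > 4L) stop("respondent walked away")
      2L
    }
  })
  err <- tryCatch(administer(tree, flaky), error = function(e) e)
  expect_s3_class(err, "screentree_session_error")
  expect_equal(nrow(err$log), 4)
})

test_that("severity-restricted screening moves the positivity criterion", {
  tree <- toy_tree()
  mild_only <- administer(tree, function(id) 1L, positivity_min = 1L,
                          keep_log = FALSE)
  expect_true(all(mild_only$classification == "positive"))
  strict <- administer(tree, function(id) 3L, positivity_min = 4L,
                       keep_log = FALSE)
  expect_true(all(strict$classification == "negative"))
})
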