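# Classification metrics, booster fitting, tuning, config combination.

test_that("evaluate reproduces the worked confusion-matrix arithmetic", {
  # confusion counts: 15 predicted active of which 13 true positives, and 43
  # actives missed; fill in enough negatives to complete the matrix
  tp <- 13; fp <- 2; fn <- 43; tn <- 200
  probs <- c(rep(0.9, tp), rep(0.9, fp), rep(0.1, fn), rep(0.1, tn))
  labels <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  rep <- evaluate(probs, labels)
  expect_equal(rep$precision, 13 / 15)
  expect_equal(round(rep$precision, 2), 0.87)
  expect_equal(rep$f1, 2 * 13 / (2 * 13 + 2 + 43))
  expect_equal(round(rep$f1, 2), 0.37)
  expect_equal(unname(rep$confusion), c(13, 2, 43, 200))
})

test_that("evaluate handles the degenerate conventions", {
  perfect <- evaluate(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  allneg <- evaluate(c(0.1, 0.2, 0.3), c(1, 0, 1))
  expect_equal(allneg$precision, 0)
  expect_equal(allneg$f1, 0)
  expect_equal(allneg$mcc, 0)
  expect_error(evaluate(numeric(0), numeric(0)), "Empty")
  expect_error(evaluate(c(1.2), c(1)), "\\[0, 1\\]")
})

test_that("ROC-AUC equals the brute-force pairwise comparison", {
  set.seed(6)
  for (k in 1:5) {
    n <- 150
    scores <- round(runif(n), 2)       # ties on purpose
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    brute <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(scores, labels), brute, tolerance = 1e-12)
  }
})

test_that("average precision matches a direct curve computation", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  labels <- c(1, 0, 1, 1, 0)
  # descending: precisions at the positives: 1/1, 2/3, 3/4
  expect_equal(average_precision(scores, labels),
               (1 / 3) * (1 + 2 / 3 + 3 / 4))
  expect_equal(average_precision(scores, rep(0, 5)), 0)
})

test_that("booster fit separates a separable toy and validates columns", {
  set.seed(1)
  x <- matrix(c(rnorm(20, -2), rnorm(20, 2)), ncol = 1,
              dimnames = list(NULL, "f"))
  x <- cbind(x, noise = rnorm(40))
  rownames(x) <- paste0("r", 1:40)
  y <- rep(c(0, 1), each = 20)
  fmx <- feature_matrix(x, "DESCRIPTOR")
  fit <- fit_booster(fmx, y, booster_config(n_trees = 50, seed = 1))
  expect_equal(roc_auc(predict_booster(fit, fmx), y), 1)
  expect_error(fit_booster(fmx, rep(1, 40)), "constant labels")
  wrong <- feature_matrix(matrix(rnorm(40), 20, 2,
                                 dimnames = list(NULL, c("a", "b"))),
                          "DESCRIPTOR")
  expect_error(predict_booster(fit, wrong), "do not match")
})

test_that("booster tuning returns the argmax configuration deterministically", {
  set.seed(5)
  n <- 120
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.5) > 0)
  groups <- rep(1:30, each = 4)
  fmx <- feature_matrix(x, "DESCRIPTOR")
  tuned <- tune_booster(fmx, y, groups, n_iter = 4L, seed = 2)
  expect_equal(nrow(tuned$trials), 4L)
  expect_equal(max(tuned$trials$mean_ap),
               tuned$trials$mean_ap[which(
                 tuned$trials$n_trees == tuned$config$n_trees &
                 tuned$trials$max_depth == tuned$config$max_depth)][1])
  tuned2 <- tune_booster(fmx, y, groups, n_iter = 4L, seed = 2)
  expect_identical(tuned$trials, tuned2$trials)
  one <- tune_booster(fmx, y, groups, n_iter = 1L, seed = 3)
  expect_equal(nrow(one$trials), 1L)
  # sampled configurations respect the search ranges
  expect_true(all(tuned$trials$n_trees >= 100 & tuned$trials$n_trees <= 400))
  expect_true(all(tuned$trials$learning_rate >= 0.01 &
                    tuned$trials$learning_rate <= 0.2))
  expect_true(all(tuned$trials$max_depth >= 3 & tuned$trials$max_depth <= 10))
  expect_true(all(tuned$trials$colsample_bytree >= 0.1 &
                    tuned$trials$colsample_bytree <= 0.9))
})

test_that("median hyperparameter combination follows the stated rules", {
  cfgs <- list(booster_config(n_trees = 100, max_depth = 3, learning_rate = 0.02),
               booster_config(n_trees = 200, max_depth = 4, learning_rate = 0.05),
               booster_config(n_trees = 400, max_depth = 5, learning_rate = 0.2))
  med <- tdpscreen:::median_config(cfgs)
  expect_equal(med$n_trees, 200L)
  expect_equal(med$max_depth, 4L)
  expect_equal(med$learning_rate, 0.05)
  # identical configurations are returned unchanged
  same <- tdpscreen:::median_config(cfgs[c(1, 1, 1)])
  expect_equal(same$n_trees, 100L)
  # even count: ties resolved downwards for integer fields
  two <- tdpscreen:::median_config(cfgs[1:2])
  expect_equal(two$max_depth, 3L)
})
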