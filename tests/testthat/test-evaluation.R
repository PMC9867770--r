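test_that("confusion counts match a brute-force tally on random vectors", {
  classes <- c("A", "B", "C")
  for (seed in 1:5) {
    y_true <- random_labels(200, classes, seed)
    y_pred <- random_labels(200, classes, seed + 100)
    got <- confusion(y_true, y_pred, classes)
    want <- oracle_confusion(y_true, y_pred, classes)
    expect_equal(got$TP, want$TP)
    expect_equal(got$FP, want$FP)
    expect_equal(got$TN, want$TN)
    expect_equal(got$FN, want$FN)
    expect_equal(got$support, want$support)
    # conservation: every class's counts sum to the total
    expect_true(all(got$TP + got$FP + got$TN + got$FN == 200))
  }
  expect_error(confusion(c("A", "B"), c("A"), classes), "length")
  expect_error(confusion(c("A", "Z"), c("A", "A"), classes), "vocabulary")
})

test_that("degenerate confusion cases count as specified", {
  classes <- c("A", "B")
  perfect <- confusion(rep(classes, 5), rep(classes, 5), classes)
  expect_true(all(perfect$FP == 0) && all(perfect$FN == 0))
  wrong <- confusion(c("A", "B"), c("B", "A"), classes)
  expect_true(all(wrong$TP == 0) && all(wrong$TN == 0))
})

test_that("precision, recall, F1 and accuracy follow their definitions", {
  # one class with TP=8, FP=2, FN=2: Pr = Re = F1 = 0.8
  cm <- structure(data.frame(class = "A", TP = 8L, FP = 2L, TN = 8L, FN = 2L,
                             support = 10L),
                  class = c("exohar_confusion", "data.frame"))
  r <- metrics_from_counts(cm)
  expect_equal(r$per_class$precision, 0.8)
  expect_equal(r$per_class$recall, 0.8)
  expect_equal(r$per_class$f1, 0.8)

  # degenerate: TP=0, FP=0, FN=5 -> Re = 0, F1 = 0, flagged
  cm0 <- structure(data.frame(class = "A", TP = 0L, FP = 0L, TN = 5L, FN = 5L,
                              support = 5L),
                   class = c("exohar_confusion", "data.frame"))
  r0 <- metrics_from_counts(cm0)
  expect_equal(r0$per_class$recall, 0)
  expect_equal(r0$per_class$f1, 0)
  expect_true(r0$per_class$degenerate)
})

test_that("weighted averages use class support", {
  # supports (10, 20, 30) with F1 (1.0, 0.5, 0.8) -> weighted F1 = 0.7333
  y_true <- c(rep("A", 10), rep("B", 20), rep("C", 30))
  # craft predictions: A perfect; B recall 10/20 with precision 1;
  # C as filler
  y_pred <- c(rep("A", 10), rep("B", 10), rep("C", 10), rep("C", 30))
  r <- score_labels(y_true, y_pred, c("A", "B", "C"))
  f1 <- r$per_class$f1
  manual <- sum(c(10, 20, 30) / 60 * f1)
  expect_equal(r$weighted_f1, manual)
  # spec'd arithmetic on the quoted example values
  expect_equal((10 * 1.0 + 20 * 0.5 + 30 * 0.8) / 60, 0.73333, tolerance = 1e-4)
})

test_that("metric invariants hold on random label vectors", {
  classes <- c("A", "B", "C", "D")
  for (seed in 1:20) {
    y_true <- random_labels(100, classes, seed)
    y_pred <- random_labels(100, classes, seed + 1000)
    r <- score_labels(y_true, y_pred, classes)
    pc <- r$per_class
    expect_true(all(pc$precision >= 0 & pc$precision <= 1))
    expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
    expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-12))
    # micro-averaged recall equals accuracy for single-label problems
    expect_equal(r$accuracy, mean(y_true == y_pred))
    # support-weighted recall also equals accuracy
    expect_equal(r$weighted_recall, mean(y_true == y_pred))
  }
})

test_that("subject aggregation matches an independent quartile computation", {
  expect_equal(aggregate_subjects(c(0.8, 0.9, 1.0))$median, 0.9)
  one <- aggregate_subjects(0.7)
  expect_equal(one$q1, 0.7)
  expect_equal(one$q3, 0.7)
  for (seed in 1:10) {
    x <- withr::with_seed(seed, runif(12))
    agg <- aggregate_subjects(x)
    want <- oracle_quartiles(x, c(0.25, 0.5, 0.75))
    expect_equal(c(agg$q1, agg$median, agg$q3), want)
    expect_true(agg$q1 <= agg$median && agg$median <= agg$q3)
  }
})

test_that("configuration comparison routes tests by normality and corrects p", {
  # identical scores: degenerate, flagged, not significant
  s <- rep(0.9, 8)
  r0 <- compare_configurations(s, s)
  expect_true(r0$degenerate)
  expect_false(r0$significant)

  # Bonferroni threshold for 3 comparisons at family alpha 0.05
  a <- withr::with_seed(1, runif(12, 0.85, 0.95))
  b <- a - withr::with_seed(2, runif(12, 0.01, 0.05))
  r <- compare_configurations(a, b)
  expect_equal(r$threshold, 0.05 / 3, tolerance = 1e-12)
  expect_equal(r$p_star, 3 * r$p)
  expect_identical(r$significant, r$p < 0.05 / 3)
  # routing agrees with an independent Shapiro-Wilk decision
  expect_identical(r$test,
                   if (stats::shapiro.test(a - b)$p.value >= 0.05) "paired-t"
                   else "wilcoxon-signed-rank")

  # heavy-tailed differences route to the signed-rank test
  d <- c(0.001, 0.002, 0.001, 0.002, 0.001, 0.3, 0.001, 0.002, 0.001, 0.25)
  x <- rep(0.9, 10)
  r2 <- compare_configurations(x, x - d)
  expect_identical(r2$test, "wilcoxon-signed-rank")

  # identical inputs always route identically
  expect_identical(compare_configurations(a, b)$test,
                   compare_configurations(a, b)$test)
  expect_error(compare_configurations(1:3, 1:2), "paired")
  expect_error(compare_configurations(c(1, 2), c(1, 2)), "at least 3")
})

test_that("all pairwise comparisons over three configurations", {
  m <- withr::with_seed(4, matrix(runif(36, 0.7, 0.95), 12, 3,
                                  dimnames = list(NULL,
                                                  c("FULL_5", "REDUCED_3", "CHEST_1"))))
  res <- compare_all_configurations(m)
  expect_length(res, 3)
  for (r in res) expect_equal(r$p_star, 3 * r$p)
})
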