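test_that("confusion matrix counts (true row, predicted column) pairs", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(truth = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = "class")

  perfect <- confusion_matrix(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
  expect_equal(sum(diag(perfect)), 10L)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)

  expect_error(confusion_matrix(c("A"), c("C"), levels = c("A", "B")), "C")
  expect_error(confusion_matrix(c("A", "B"), c("A")), "equal length")
})

test_that("row sums equal class supports for random label vectors", {
  withr::local_seed(8)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(20:100, 1)
    truth <- sample(LETTERS[1:k], n, replace = TRUE)
    pred <- sample(LETTERS[1:k], n, replace = TRUE)
    cm <- confusion_matrix(truth, pred, levels = LETTERS[1:k])
    expect_equal(unname(rowSums(cm)),
                 unname(vapply(LETTERS[1:k], function(l) sum(truth == l),
                               numeric(1))))
    expect_equal(accuracy(cm), sum(truth == pred) / n)
  }
})

test_that("per-class metrics reproduce the published shank-IMU table", {
  cm <- reference_cm_homemade()
  m <- per_class_metrics(cm)
  # exact fractions from the printed counts
  expect_equal(m$recall[1], 65 / 75)
  expect_equal(m$precision[3], 97 / 106)
  # the full two-decimal readout matches the printed PRC/RCL/F1S entries
  expect_equal(round_half_up2(m$recall), reference_homemade_printed$recall)
  expect_equal(round_half_up2(m$precision), reference_homemade_printed$precision)
  expect_equal(round_half_up2(m$f1), reference_homemade_printed$f1)
  expect_equal(sum(m$weight), 1)
})

test_that("accuracy is trace over total", {
  expect_equal(accuracy(reference_cm_homemade()),
               (65 + 112 + 97 + 328 + 77 + 75) / 780)
  ident <- as_confusion_matrix(diag(3) * 5)
  expect_equal(accuracy(ident), 1)
  expect_equal(accuracy(as_confusion_matrix(matrix(1, 2, 2))), 0.5)
  expect_error(accuracy(as_confusion_matrix(matrix(0L, 2, 2))), "empty")
})

test_that("weighted F1 is the support-weighted mean of per-class F1", {
  expect_equal(weighted_f1(reference_cm_homemade()), 0.9663418373,
               tolerance = 1e-9)
  ident <- as_confusion_matrix(diag(4) * 3)
  expect_equal(weighted_f1(ident), 1)
  two <- tibble::tibble(class = c("x", "y"), f1 = c(1, 0),
                        weight = c(0.25, 0.75))
  expect_equal(weighted_f1(two), 0.25)
})

test_that("weighted F1 lies between the extreme per-class F1 values", {
  withr::local_seed(21)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    cm <- as_confusion_matrix(matrix(rpois(k * k, 5) + diag(k) * 20, k))
    m <- suppressWarnings(per_class_metrics(cm))
    if (anyNA(m$f1)) next
    fw <- weighted_f1(cm)
    expect_gte(fw, min(m$f1)); expect_lte(fw, max(m$f1))
  }
})

test_that("class order permutation leaves accuracy and weighted F1 unchanged", {
  withr::local_seed(13)
  truth <- sample(c("a", "b", "c"), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth, sample(c("a", "b", "c"), 200, TRUE))
  cm1 <- confusion_matrix(truth, pred, levels = c("a", "b", "c"))
  cm2 <- confusion_matrix(truth, pred, levels = c("c", "a", "b"))
  expect_equal(unclass(cm2), unclass(cm1)[c("c", "a", "b"), c("c", "a", "b")],
               ignore_attr = TRUE)
  expect_equal(accuracy(cm1), accuracy(cm2))
  expect_equal(weighted_f1(cm1), weighted_f1(cm2))
})

test_that("undefined metrics surface as NA with a warning, never silent zeros", {
  # class B never predicted: precision undefined
  cm <- confusion_matrix(c("A", "B", "A"), c("A", "A", "A"),
                         levels = c("A", "B"))
  expect_warning(m <- per_class_metrics(cm), "B")
  expect_true(is.na(m$precision[2]))
  expect_error(weighted_f1(cm), "B")
})

test_that("the formatted report carries PRC/RCL/F1S in table layout", {
  tab <- format_metric_table(reference_cm_homemade())
  expect_equal(rownames(tab), c(paste0("HA", 1:6), "PRC"))
  expect_equal(colnames(tab), c(paste0("HA", 1:6), "RCL", "F1S"))
  expect_equal(tab["HA1", "RCL"], "0.87")
  expect_equal(tab["PRC", "HA3"], "0.92")
  expect_equal(tab["HA5", "F1S"], "0.94")
})
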