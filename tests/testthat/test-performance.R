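fx_objects <- function(pairs) {
  tibble::tibble(manual = pairs[[1]], predicted = pairs[[2]])
}

test_that("the confusion matrix cross-tabulates manual vs predicted labels", {
  vocab <- c("A", "B")
  diagonal <- fx_objects(list(c("A", "B", "A"), c("A", "B", "A")))
  cm <- build_confusion_matrix(diagonal, vocab)
  expect_equal(sum(diag(cm)), 3)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  mixed <- fx_objects(list(c("A", "A", "B"), c("A", "B", "B")))
  cm <- build_confusion_matrix(mixed, vocab)
  expect_equal(cm["A", "A"], 1L)
  expect_equal(cm["A", "B"], 1L)
  expect_equal(cm["B", "B"], 1L)
  expect_equal(cm["B", "A"], 0L)
  expect_equal(sum(cm), nrow(mixed)) # conservation
})

test_that("objects without manual labels or outside the vocabulary are tallied", {
  obj <- fx_objects(list(c("A", NA, "Zed", "B"), c("A", "A", "A", "Zed")))
  expect_warning(cm <- build_confusion_matrix(obj, c("A", "B")),
                 "manual label")
  expect_equal(sum(cm), 1) # only (A, A) survives
  expect_equal(attr(cm, "n_missing_manual"), 1)
  expect_equal(sum(attr(cm, "excluded_labels")), 2) # Zed seen twice
})

test_that("binary decomposition matches the worked quadruple", {
  obj <- fx_objects(list(
    c(rep("A", 100), rep("B", 100)),
    c(rep("A", 85), rep("Varia", 15), rep("A", 5), rep("B", 95))
  ))
  cm <- build_confusion_matrix(obj, c("A", "B", "Varia"))
  bd <- binary_decompose(cm, "A")
  expect_equal(bd$tp, 85)
  expect_equal(bd$fn, 15)
  expect_equal(bd$fp, 5)
  expect_equal(bd$tn, 95)
})

test_that("binary counts always sum to the matrix total", {
  withr::local_seed(8)
  vocab <- paste0("L", 1:5)
  obj <- fx_objects(list(sample(vocab, 400, replace = TRUE),
                         sample(vocab, 400, replace = TRUE)))
  cm <- build_confusion_matrix(obj, vocab)
  for (lab in vocab) {
    bd <- binary_decompose(cm, lab)
    expect_equal(bd$tp + bd$fp + bd$fn + bd$tn, sum(cm))
  }
})

test_that("sensitivity and PPV follow their defining ratios", {
  obj <- fx_objects(list(
    c(rep("A", 100), rep("B", 7)),
    c(rep("A", 90), rep("Varia", 10), rep("A", 7))
  ))
  cm <- build_confusion_matrix(obj, c("A", "B", "Varia"))
  scores <- performance_scores(cm)
  a <- scores[scores$label == "A", ]
  expect_equal(a$sensitivity, 90 / 100)
  expect_equal(a$ppv, 90 / 97)
  b <- scores[scores$label == "B", ]
  expect_equal(b$sensitivity, 0) # TP=0, FN=7 -> 0, defined
  expect_true(is.na(b$ppv)) # nothing predicted B -> undefined, not 0
  expect_true(all(scores$sensitivity >= 0 & scores$sensitivity <= 1,
                  na.rm = TRUE))
  expect_true(all(scores$ppv >= 0 & scores$ppv <= 1, na.rm = TRUE))
})

test_that("micro accuracy is trace over total and permutation-invariant", {
  withr::local_seed(9)
  vocab <- c("A", "B", "C", "Varia")
  obj <- fx_objects(list(sample(vocab, 500, replace = TRUE),
                         sample(vocab, 500, replace = TRUE)))
  cm <- build_confusion_matrix(obj, vocab)
  g <- glance(cm)
  expect_equal(g$micro_accuracy, sum(diag(cm)) / sum(cm))
  # permuting the vocabulary must not change the overall accuracy
  cm2 <- build_confusion_matrix(obj, rev(vocab))
  expect_equal(glance(cm2)$micro_accuracy, g$micro_accuracy)
  expect_equal(g$n_objects, 500)
})

test_that("an all-zero confusion matrix is an error", {
  cm <- build_confusion_matrix(fx_objects(list("A", "A")), c("A", "B"))
  cm[1, 1] <- 0L
  expect_error(performance_scores(cm), "empty")
  expect_error(glance(cm), "empty")
})

test_that("scores recover a known generator row within binomial error", {
  dev <- fx_pomo(seed = 51)
  dev$confusion <- fx_confusion()
  n <- 10000
  obj <- generate_labeled_objects(setNames(rep(n, 3), rownames(fx_confusion())),
                                  dev)
  cm <- build_confusion_matrix(obj, colnames(fx_confusion()))
  scores <- performance_scores(cm)
  sens_a <- scores$sensitivity[scores$label == "Alpha"]
  expect_lt(abs(sens_a - 0.85), 2 * sqrt(0.85 * 0.15 / n))
})

test_that("the non-pollen breakdown reproduces constructed proportions", {
  obj <- fx_objects(list(
    c(rep("NoPollen", 870), rep("Spores", 90), rep("Betula", 17),
      rep("Varia", 23)),
    rep("NoPollen", 1000)
  ))
  bd <- particle_breakdown(obj)
  get <- function(group) bd$proportion[bd$manual_group == group]
  expect_equal(get("NoPollen"), 0.870)
  expect_equal(get("Spores"), 0.090)
  expect_equal(get("Pollen"), 0.017)
  expect_equal(get("Other"), 0.023)
  expect_equal(sum(bd$proportion), 1)

  # perfect classification -> single group with proportion 1
  clean <- fx_objects(list(rep("NoPollen", 10), rep("NoPollen", 10)))
  expect_equal(particle_breakdown(clean)$proportion, 1)

  # empty selection is an error
  pollen_only <- fx_objects(list("Betula", "Betula"))
  expect_error(particle_breakdown(pollen_only), "no objects")
})

test_that("tidy() flattens the matrix losslessly", {
  obj <- fx_objects(list(c("A", "A", "B"), c("A", "B", "B")))
  cm <- build_confusion_matrix(obj, c("A", "B"))
  td <- tidy(cm)
  expect_equal(sum(td$n), sum(cm))
  expect_equal(nrow(td), 4)
  back <- tidyr::pivot_wider(td, names_from = "predicted",
                             values_from = "n")
  expect_equal(back$A, as.integer(cm[, "A"]))
})
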