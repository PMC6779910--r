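test_that("stratified folds partition samples with balanced class proportions", {
  set.seed(100)
  labels <- rep(c("A", "B"), each = 5)
  E <- synthetic_embedding(matrix(rnorm(10 * 3), 10, 3), labels)
  ev <- cross_validate(E, k = 5, seed = 0)
  expect_equal(sort(unique(ev$fold_of)), 0:4)
  expect_equal(as.vector(table(ev$fold_of)), rep(2L, 5))   # each fold size 2
  expect_true(all(nchar(ev$predicted_labels) > 0))          # everyone predicted
  # per-class proportions within +-1 sample of global
  for (f in 0:4) {
    per_class <- table(factor(labels[ev$fold_of == f], levels = c("A", "B")))
    expect_true(all(abs(per_class - 1) <= 1))
  }
})

test_that("cross-validation on separable data is perfect and deterministic", {
  E <- separable_embedding(n_per_class = 10, d = 4, gap = 8, seed = 7)
  ev1 <- cross_validate(E, k = 5, seed = 3)
  ev2 <- cross_validate(E, k = 5, seed = 3)
  expect_identical(ev1$fold_of, ev2$fold_of)
  expect_identical(ev1$probabilities, ev2$probabilities)
  expect_equal(ev1$predicted_labels, ev1$true_labels)
  cm <- confusion_matrix(ev1)
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  m <- compute_metrics(ev1)
  expect_equal(m$CA, 1)
  expect_equal(m$F1, 1)
  expect_equal(m$AUC_macro_ovr, 1)
})

test_that("too-small classes produce a stratification error with guidance", {
  E <- synthetic_embedding(matrix(rnorm(7 * 2), 7, 2),
                           c(rep("A", 4), rep("B", 3)))
  expect_error(cross_validate(E, k = 5, seed = 0), regexp = "reduce",
               class = "imagemine_input_error")
  E_unlab <- synthetic_embedding(matrix(rnorm(10), 5, 2), NULL)
  expect_error(cross_validate(E_unlab, k = 2), regexp = "label",
               class = "imagemine_input_error")
})

test_that("confusion counts are conserved and indexed [true, predicted]", {
  ev <- structure(list(
    true_labels = c("A", "A", "A", "B", "B", "C"),
    predicted_labels = c("A", "B", "A", "B", "C", "C"),
    classes = c("A", "B", "C")
  ), class = "cv_result")
  cm <- confusion_matrix(ev)
  expect_equal(sum(cm), 6L)
  expect_equal(unclass(cm)[cbind(c("A", "A", "B", "B", "C"),
                                 c("A", "B", "B", "C", "C"))],
               c(2L, 1L, 1L, 1L, 1L))
  expect_equal(cm["C", "A"], 0L, ignore_attr = TRUE)
})

test_that("metrics match hand-computed values on the printed oocyte table", {
  cm <- as_confusion_matrix(rbind(c(65, 4), c(1, 61)), c("SN", "NSN"))
  m <- compute_metrics(cm)
  expect_equal(m$n, 131L)
  expect_equal(m$CA, 126 / 131)                   # 96% to the nearest percent
  expect_equal(round(100 * m$CA), 96)
  expect_equal(sum(cm) - sum(diag(cm)), 5L)       # five misclassified
  # hand-computed one-vs-rest F1
  expect_equal(m$F1_per_class[["SN"]], 2 * (65 / 66) * (65 / 69) / (65 / 66 + 65 / 69))
  expect_equal(m$F1_per_class[["NSN"]], 2 * (61 / 65) * (61 / 62) / (61 / 65 + 61 / 62))
  expect_true(is.na(m$AUC_macro_ovr))             # no probabilities available
})

test_that("metrics match hand-computed oracles on small confusion matrices", {
  # symmetric uninformative 2x2
  m <- compute_metrics(as_confusion_matrix(rbind(c(2, 2), c(2, 2)), c("A", "B")))
  expect_equal(m$CA, 0.5)
  expect_equal(m$F1_macro, 0.5)
  expect_equal(m$F1_weighted, 0.5)

  # worked 3x3: precision/recall by hand
  cm3 <- rbind(c(5, 1, 0), c(2, 3, 1), c(0, 0, 4))
  m3 <- compute_metrics(as_confusion_matrix(cm3, c("A", "B", "C")))
  expect_equal(m3$CA, 12 / 16)
  pr <- c(5 / 7, 3 / 4, 4 / 5)   # column sums
  rc <- c(5 / 6, 3 / 6, 4 / 4)   # row sums
  f1 <- 2 * pr * rc / (pr + rc)
  expect_equal(unname(m3$F1_per_class), f1)
  expect_equal(m3$F1_macro, mean(f1))
  expect_equal(m3$F1_weighted, sum(f1 * c(6, 6, 4)) / 16)
  expect_equal(m3$F1, m3$F1_weighted) # multiclass headline = weighted

  # a class never predicted: F1 defined as 0
  cm0 <- as_confusion_matrix(rbind(c(3, 0), c(2, 0)), c("A", "B"))
  expect_equal(compute_metrics(cm0)$F1_per_class[["B"]], 0)
})

test_that("AUC agrees with an independent rank-based oracle", {
  set.seed(110)
  for (rep in 1:5) {
    n <- 40
    truth <- sample(c("A", "B"), n, replace = TRUE, prob = c(0.6, 0.4))
    pA <- ifelse(truth == "A", rbeta(n, 4, 2), rbeta(n, 2, 4))
    probs <- cbind(A = pA, B = 1 - pA)
    ev <- structure(list(true_labels = truth,
                         predicted_labels = ifelse(pA > 0.5, "A", "B"),
                         probabilities = probs, classes = c("A", "B")),
                    class = "cv_result")
    m <- compute_metrics(ev)
    oracle <- mean(c(rank_auc(truth == "A", probs[, "A"]),
                     rank_auc(truth == "B", probs[, "B"])))
    expect_equal(m$AUC_macro_ovr, oracle, tolerance = 1e-12)
    # CA always equals the mean agreement
    expect_equal(m$CA, mean(truth == ev$predicted_labels))
  }
})

test_that("uninformative probabilities give AUC 0.5", {
  ev <- structure(list(true_labels = rep(c("A", "B"), each = 4),
                       predicted_labels = rep(c("A", "B"), 4),
                       probabilities = matrix(0.5, 8, 2,
                                              dimnames = list(NULL, c("A", "B"))),
                       classes = c("A", "B")),
                  class = "cv_result")
  expect_equal(compute_metrics(ev)$AUC_macro_ovr, 0.5)
})

test_that("confusion-cell selection returns exactly the cell's images", {
  set.seed(120)
  E <- separable_embedding(n_per_class = 6, d = 3, gap = 6)
  ev <- cross_validate(E, k = 3, seed = 1)
  expect_equal(ev$predicted_labels, ev$true_labels) # separable
  aa <- select_cell(ev, "A", "A")
  expect_equal(nrow(aa), 6L)
  expect_equal(aa$path, ev$table$path[ev$table$label == "A"])
  expect_equal(nrow(select_cell(ev, "A", "B")), 0L)
  # conservation over all cells
  total <- sum(vapply(c("A", "B"), function(tc) {
    sum(vapply(c("A", "B"), function(pc) nrow(select_cell(ev, tc, pc)), numeric(1)))
  }, numeric(1)))
  expect_equal(total, 12)
  expect_error(select_cell(ev, "A", "Z"), class = "imagemine_input_error")
})

test_that("metrics JSON and confusion CSV are written faithfully", {
  E <- separable_embedding(n_per_class = 5, d = 3, gap = 6)
  ev <- cross_validate(E, k = 5, seed = 0)
  metrics <- compute_metrics(ev)
  mj <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(metrics, mj, ev)
  got <- jsonlite::read_json(mj, simplifyVector = TRUE)
  expect_equal(got$CA, metrics$CA)
  expect_equal(got$folds, 5)
  expect_equal(got$learner$C, 1)
  cc <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(confusion_matrix(ev), cc)
  back <- as.matrix(read.csv(cc, row.names = 1))
  expect_equal(unname(back), unclass(unname(confusion_matrix(ev))), ignore_attr = TRUE)
})
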