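pop100 <- simulate_cell_population(population_config(n_per_line = 100),
                                   seed = 71)

test_that("stratified splitting preserves class proportions and is reproducible", {
  parts <- split_train_test(pop100, 0.7, seed = 1)
  tab <- table(parts$label, parts$split)
  for (line in rownames(tab)) {
    expect_equal(unname(tab[line, "train"]), 70)
    expect_equal(unname(tab[line, "test"]), 30)
  }
  expect_identical(split_train_test(pop100, 0.7, seed = 1)$split,
                   parts$split)
  expect_false(identical(split_train_test(pop100, 0.7, seed = 2)$split,
                         parts$split))

  expect_warning(all_train <- split_train_test(pop100, 1, seed = 1),
                 "test set is empty")
  expect_equal(sum(all_train$split == "test"), 0)

  lone <- dplyr::bind_rows(pop100, pop100[1, ] |>
                             dplyr::mutate(label = "rare"))
  expect_error(split_train_test(lone, 0.7), "rare")
})

test_that("the forest separates the synthetic lines and is deterministic", {
  model <- train_forest(pop100, seed = 5)
  on_train <- classification_report(pop100$label, predict(model, pop100))
  expect_equal(on_train$accuracy, 1)

  again <- train_forest(pop100, seed = 5)
  expect_identical(predict(again, pop100), predict(model, pop100))

  # identical feature vectors with different labels are tolerated
  degen <- pop100[c(1, 1, 101, 101), ]
  degen$label <- c("MM231", "MCF7", "MM231", "MCF7")
  expect_s3_class(train_forest(degen, seed = 1), "sers_forest")

  expect_error(train_forest(pop100[pop100$label == "MM231", ]),
               "at least 2 classes")
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(f1_from_pre_rec(1, 1), 1)
  for (p in c(0, 0.25, 0.5, 0.9)) {
    expect_equal(f1_from_pre_rec(p, p), p)
  }
  expect_equal(f1_from_pre_rec(0.8, 0.6), 24 / 35)
  expect_equal(f1_from_pre_rec(0, 0), 0)
  expect_error(f1_from_pre_rec(1.2, 0.5), "\\[0, 1\\]")
  expect_error(f1_from_pre_rec(0.5, -0.1), "\\[0, 1\\]")
})

test_that("classification reports follow the confusion-matrix arithmetic", {
  labs <- c("MM231", "MCF7", "SKBR3")
  perfect <- classification_report(rep(labs, each = 10),
                                   rep(labs, each = 10))
  expect_equal(perfect$confusion_fractions, diag(3), ignore_attr = TRUE)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$accuracy, 1)

  collapsed <- classification_report(rep(labs, each = 10),
                                     rep("MM231", 30), levels = labs)
  expect_equal(collapsed$accuracy, 1 / 3)

  # class A: TP = 9, FN = 3, FP = 1
  actual <- c(rep("A", 12), rep("B", 5))
  predicted <- c(rep("A", 9), rep("B", 3), "A", rep("B", 4))
  rep_ab <- classification_report(actual, predicted)
  a <- rep_ab$per_class[rep_ab$per_class$class == "A", ]
  expect_equal(a$precision, 0.9)
  expect_equal(a$recall, 0.75)
  expect_equal(a$f1, 2 * 0.9 * 0.75 / 1.65)
})

test_that("confusion counts and fractions satisfy their row constraints", {
  parts <- split_train_test(pop100, seed = 31)
  report <- evaluate_classifier(train_forest(parts, seed = 32), parts)
  test_counts <- table(parts$label[parts$split == "test"])
  expect_equal(rowSums(report$confusion_counts),
               as.vector(test_counts), ignore_attr = TRUE)
  expect_equal(unname(rowSums(report$confusion_fractions)), rep(1, 3),
               tolerance = 1e-12)
  expect_error(
    evaluate_classifier(train_forest(parts, seed = 1),
                        tibble::tibble(label = "HeLa", alpha3 = 1, beta1 = 1,
                                       beta3 = 1, beta4 = 1, beta5 = 1)),
    "unknown label")
})

test_that("one protocol iteration equals a single split/fit/evaluate run", {
  protocol <- repeat_training(pop100, n_iterations = 1, seed = 17)
  manual_parts <- split_train_test(pop100, 0.7,
                                   seed = protocol$summary$split_seed[[1]])
  manual <- evaluate_classifier(
    train_forest(manual_parts, seed = protocol$summary$fit_seed[[1]]),
    manual_parts)
  expect_equal(protocol$mean_macro_f1, manual$macro_f1)
  expect_equal(protocol$mean_accuracy, manual$accuracy)
})

test_that("the whole protocol is deterministic under one top-level seed", {
  a <- repeat_training(pop100, n_iterations = 5, seed = 99)
  b <- repeat_training(pop100, n_iterations = 5, seed = 99)
  expect_identical(a$summary, b$summary)
})

test_that("label-permuted data scores at chance level", {
  shuffled <- pop100
  shuffled$label <- withr::with_seed(8, sample(shuffled$label))
  protocol <- repeat_training(shuffled, n_iterations = 20, seed = 8)
  expect_lt(abs(protocol$mean_accuracy - 1 / 3), 0.05)
})

test_that("population prediction conserves counts and finds the source line", {
  pop300 <- simulate_cell_population(population_config(), seed = 40)
  parts <- split_train_test(pop300, seed = 41)
  model <- train_forest(parts, seed = 42)

  mm_only <- simulate_cell_population(
    population_config(n_per_line = 200), seed = 43, lines = "MM231")
  pred <- predict_population(model, mm_only)
  expect_equal(sum(pred$counts), pred$n_total)
  expect_equal(pred$n_total, 200)
  expect_gte(pred$counts[["MM231"]] / pred$n_total, 0.95)

  td <- tidy(pred)
  expect_true(all(c("predicted", "count", "alpha3") %in% names(td)))
})

test_that("predicted-population profiles correlate with training means", {
  parts <- split_train_test(pop100, seed = 51)
  model <- train_forest(parts, seed = 52)
  mixed <- simulate_cell_population(population_config(n_per_line = 80),
                                    seed = 53)
  pred <- predict_population(model, mixed)
  res <- profile_correlation(pred, parts[parts$split == "train", ])
  expect_equal(res$n, 15)
  expect_gt(res$r, 0.98)
})
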