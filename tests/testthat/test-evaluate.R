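test_that("metrics reproduce hand-computed binary values", {
  cm <- matrix(c(8, 5, 2, 85), 2, 2,
    dimnames = list(c("pos", "neg"), c("pos", "neg"))
  )
  m <- compute_metrics(cm)
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$sens, 0.800, tolerance = 1e-12)
  expect_equal(pos$spec, 85 / 90, tolerance = 1e-12)
  expect_equal(pos$mcc, 670 / sqrt(13 * 10 * 90 * 87), tolerance = 1e-12)
  expect_equal(m$oa, 93 / 100, tolerance = 1e-12)
})

test_that("a diagonal confusion matrix gives perfect metrics", {
  cm <- diag(c(5L, 9L, 3L))
  dimnames(cm) <- list(letters[1:3], letters[1:3])
  m <- compute_metrics(cm)
  expect_true(all(m$per_class$sens == 1))
  expect_true(all(m$per_class$spec == 1))
  expect_true(all(m$per_class$mcc == 1))
  expect_identical(m$oa, 1)
})

test_that("zero-denominator metrics are reported as 0 and flagged", {
  # every sample predicted into class a, balanced 10 + 10
  cm <- matrix(c(10, 10, 0, 0), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b"))
  )
  m <- compute_metrics(cm)
  a <- m$per_class[m$per_class$class == "a", ]
  b <- m$per_class[m$per_class$class == "b", ]
  expect_identical(a$sens, 1)
  expect_identical(a$spec, 0)
  expect_identical(a$mcc, 0)
  expect_true(a$degenerate)
  expect_identical(b$sens, 0)
  expect_true(b$degenerate)
})

test_that("metrics agree with a one-vs-rest tally oracle", {
  set.seed(31)
  for (rep in 1:50) {
    cm <- random_confusion(sample(2:6, 1))
    m <- compute_metrics(cm)
    for (j in seq_len(nrow(cm))) {
      expect_equal(
        unlist(m$per_class[j, c("sens", "spec", "mcc")]),
        ovr_oracle(cm, j),
        tolerance = 1e-12, ignore_attr = TRUE
      )
    }
    expect_equal(m$oa, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("malformed confusion matrices are rejected", {
  expect_error(compute_metrics(matrix(0, 2, 3)), "square")
  cm <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(compute_metrics(cm), "empty")
  cm[1, 1] <- -1L
  expect_error(compute_metrics(cm), "non-negative")
})

test_that("a linear SVM separates separable toy data", {
  feats <- tibble::tibble(
    id = paste0("s", 1:4), f1 = c(0, 0.1, 1, 0.9), f2 = c(0, 0.2, 1, 0.8)
  )
  y <- c("lo", "lo", "hi", "hi")
  model <- train_svm(feats, y)
  pred <- predict(model, feats)
  expect_identical(pred$predicted, y)
  expect_error(train_svm(feats, rep("lo", 4)), "2 classes")
})

test_that("jackknife tests each sample exactly once, deterministically", {
  set.seed(32)
  prof <- class_profiles(c("A", "B", "C"), informative_strength = 0.6)
  spec <- synthetic_spec(12L, prof, length_range = c(30L, 80L), seed = 5)
  d <- suppressMessages(generate_dataset(spec))
  feats <- encode_trigrams(d)
  r1 <- jackknife_evaluate(feats, d$class,
    k = 50L, mode = "paper", rfe_step = 200L, seed = 2
  )
  expect_identical(r1$n, nrow(d))
  expect_identical(sum(r1$confusion), nrow(d))
  expect_identical(rownames(r1$confusion), c("A", "B", "C"))
  r2 <- jackknife_evaluate(feats, d$class,
    k = 50L, mode = "paper", rfe_step = 200L, seed = 2
  )
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(glance(r1)$oa, r1$oa)
})

test_that("singleton classes are rejected unless explicitly allowed", {
  feats <- tibble::tibble(
    id = paste0("s", 1:5),
    f1 = c(0, 0.1, 1, 0.9, 0.5), f2 = c(0, 0.2, 1, 0.8, 0.5)
  )
  y <- c("a", "a", "b", "b", "c")
  expect_error(
    jackknife_evaluate(feats, y, k = 2L),
    "fewer than 2"
  )
})

test_that("selection protocols behave as expected on separable data", {
  # both protocols recover well-separated classes; fold-internal selection
  # cannot do meaningfully better than rank-once selection when the signal
  # is real
  spec <- synthetic_spec(
    30L, class_profiles(c("A", "B", "C", "D"), informative_strength = 0.5),
    length_range = c(50L, 200L), seed = 9
  )
  d <- suppressMessages(generate_dataset(spec))
  feats <- encode_trigrams(d)
  paper <- jackknife_evaluate(feats, d$class,
    k = 120L, mode = "paper", rfe_step = 440L, seed = 1
  )
  leakfree <- jackknife_evaluate(feats, d$class,
    k = 120L, mode = "leak_free", rfe_step = 440L, seed = 1
  )
  expect_gte(paper$oa, 0.90)
  expect_gte(leakfree$oa, 0.90)
  expect_lte(leakfree$oa, paper$oa + 0.05)
})

test_that("sweep_top_k returns one OA per k and the smallest argmax", {
  spec <- synthetic_spec(
    10L, class_profiles(c("A", "B"), informative_strength = 0.7),
    length_range = c(30L, 60L), seed = 3
  )
  d <- suppressMessages(generate_dataset(spec))
  feats <- encode_trigrams(d)
  sw <- sweep_top_k(feats, d$class,
    k_values = c(20L, 60L, 120L), mode = "paper", rfe_step = 300L, seed = 1
  )
  expect_identical(sw$k, c(20L, 60L, 120L))
  expect_true(all(sw$oa >= 0 & sw$oa <= 1))
  expect_identical(attr(sw, "best_k"), sw$k[which.max(sw$oa)])
  expect_error(
    sweep_top_k(feats, d$class, k_values = integer(0)),
    "non-empty"
  )
})

test_that("evaluation reports serialize to JSON with full structure", {
  cm <- matrix(c(8, 5, 2, 85), 2, 2,
    dimnames = list(c("pos", "neg"), c("pos", "neg"))
  )
  m <- compute_metrics(cm)
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(m, path)
  back <- jsonlite::read_json(path)
  expect_identical(unlist(back$classes), c("pos", "neg"))
  expect_equal(back$oa, 0.93, tolerance = 1e-12)
  expect_identical(
    unlist(back$confusion), c(8L, 2L, 5L, 85L),
    ignore_attr = TRUE
  )
})

test_that("autoplot methods return ggplot objects", {
  cm <- diag(c(4L, 6L))
  dimnames(cm) <- list(c("a", "b"), c("a", "b"))
  expect_s3_class(autoplot(compute_metrics(cm)), "ggplot")
  sw <- structure(
    tibble::tibble(k = c(10L, 20L), oa = c(0.5, 0.8)),
    class = c("topk_sweep", class(tibble::tibble())), best_k = 20L
  )
  expect_s3_class(autoplot(sw), "ggplot")
})
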