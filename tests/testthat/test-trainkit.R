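# Loss, metrics, schedule and the training/evaluation loops.

test_that("cross-entropy matches its closed forms and the loop oracle", {
  expect_equal(cross_entropy(matrix(c(1, 0, 0, 0), 1), 1L), 0)
  # uniform prediction over 4 classes -> ln 4
  expect_equal(cross_entropy(matrix(0.25, 3, 4), c(1L, 2L, 4L)), log(4),
               tolerance = 1e-12)
  set.seed(1)
  p <- matrix(rexp(10 * 4), 10, 4); p <- p / rowSums(p)
  y <- sample(4, 10, replace = TRUE)
  oracle <- 0
  for (i in 1:10) {
    onehot <- numeric(4); onehot[y[i]] <- 1
    oracle <- oracle - sum(onehot * log(p[i, ]))
  }
  expect_equal(cross_entropy(p, y), oracle / 10, tolerance = 1e-7)
  # logits are normalized internally when requested
  logits <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(cross_entropy(logits, y, from_logits = TRUE),
               cross_entropy(ilvit:::softmax_rows(logits), y), tolerance = 1e-12)
  # zero probability on the true class is clamped, not infinite
  expect_true(is.finite(cross_entropy(matrix(c(0, 1, 0, 0), 1), 1L)))
})

test_that("micro accuracy and per-class metrics match hand computations", {
  cm <- diag(c(5L, 3L, 7L))
  expect_equal(micro_accuracy(cm), 1.0)
  rep1 <- per_class_metrics(cm)
  expect_true(all(rep1$per_class$precision == 1))
  expect_true(all(rep1$per_class$recall == 1))

  cm2 <- matrix(c(8L, 2L, 1L, 9L), 2, 2, byrow = TRUE)
  expect_equal(micro_accuracy(cm2), 0.85)
  r2 <- per_class_metrics(cm2)
  expect_equal(r2$per_class$precision[1], 8 / 9)
  expect_equal(r2$per_class$recall[1], 0.8)
  # the literal errors-in-the-denominator form double-counts mistakes
  expect_equal(micro_accuracy(cm2, literal = TRUE), 17 / 23)
  expect_warning(per_class_metrics(matrix(c(2L, 0L, 1L, 0L), 2, 2)), "zero")
})

test_that("micro-averaged recall equals micro accuracy on any confusion matrix", {
  set.seed(2)
  for (rep in 1:10) {
    C <- sample(2:6, 1)
    cm <- matrix(rpois(C * C, 5), C, C)
    tp <- diag(cm); fn <- rowSums(cm) - tp
    micro_recall <- sum(tp) / sum(tp + fn)
    expect_equal(micro_recall, micro_accuracy(cm))
  }
})

test_that("the cosine schedule hits its anchors and the closed form", {
  total <- 1000L; warm <- 100L
  # warmup start and linear ramp
  expect_equal(cosine_lr(1, total, warm), 1e-6)
  expect_equal(cosine_lr(warm + 1, total, warm), 1e-4)        # peak
  expect_equal(cosine_lr(total, total, warm), 1e-6)           # floor
  for (s in c(150L, 400L, 900L)) {
    prog <- (s - warm - 1) / (total - warm - 1)
    closed <- 1e-6 + 0.5 * (1e-4 - 1e-6) * (1 + cos(pi * prog))
    expect_equal(cosine_lr(s, total, warm), closed, tolerance = 1e-9)
  }
  # without warmup the first step is at the peak
  expect_equal(cosine_lr(1, total, 0L), 1e-4)
})

test_that("evaluate is deterministic, side-effect-free, and perfect on a pure batch", {
  set.seed(3)
  cfg <- tiny_model_config("V1")
  m <- build_model(cfg, seed = 1)
  ds <- generate_synthetic(synthetic_spec(per_class_count = 3, image_size = 32,
                                          seed = 5))
  b <- dataset_to_batch(ds, size = 32)
  suppressWarnings({
    r1 <- evaluate(m, b$x, b$y, class_names = ds$class_names)
    r2 <- evaluate(m, b$x, b$y, class_names = ds$class_names)
  })
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(sum(r1$confusion), length(b$y))

  # a one-class set predicted perfectly reports all metrics = 1
  pred_cls <- model_predict(m, b$x[, , , 1:3, drop = FALSE], type = "class")
  cm <- confusion_matrix(pred_cls, pred_cls, 4L)
  suppressWarnings(rep1 <- per_class_metrics(cm))
  expect_equal(rep1$accuracy, 1.0)
  expect_true(all(rep1$per_class$recall[unique(pred_cls)] == 1))
})

test_that("training logs a decreasing loss and a faithful learning-rate trace", {
  set.seed(4)
  b <- smoke_dataset(per_class = 4L, size = 32L)
  cfg <- tiny_model_config("V1")
  m <- build_model(cfg, seed = 2)
  tc <- train_config(steps = 30L, epochs = 500L, warmup_epochs = 20L, seed = 7L,
                     batch_size = 8L)
  log_file <- tempfile(fileext = ".jsonl")
  res <- train(m, b$x, b$y, tc, log_file = log_file)
  expect_equal(nrow(res$log), 30L)
  # lr trace matches the schedule anchors: warmup starts at 1e-6
  expect_equal(res$log$lr[1], 1e-6)
  expect_true(all(diff(res$log$lr[1:30]) > 0))        # still in warmup
  expect_true(all(is.finite(res$log$loss)))
  # loss trends downward over the run (median of thirds decreases)
  expect_lt(median(res$log$loss[21:30]), median(res$log$loss[1:10]) + 0.05)
  # JSON-lines log parses back
  lines <- readLines(log_file)
  expect_equal(length(lines), 30L)
  rec <- jsonlite::fromJSON(lines[5])
  expect_equal(rec$step, 5L)
})
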