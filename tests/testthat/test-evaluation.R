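test_that("confusion matrices tally correctly and expose accuracy", {
  # perfect predictions -> diagonal, 100%
  truth <- rep(eye_classes(), each = 3)
  cm <- confusion(truth, truth)
  expect_equal(sum(cm$counts) , 18)
  expect_equal(sum(diag(cm$counts)), 18)
  expect_equal(accuracy(cm), 100)

  # everything predicted center
  pred <- rep("center", length(truth))
  cm2 <- confusion(truth, pred)
  expect_equal(sum(cm2$counts[, "center"]), 18)
  expect_equal(accuracy(cm2), mean(truth == "center") * 100)

  expect_error(confusion(c("left"), c("left", "right")), "equal length")
  expect_error(confusion("left", "sideways", classes = eye_classes()),
               "unknown label")
})

test_that("random 6x6 tallies match a brute-force pair-counting oracle", {
  set.seed(31)
  for (rep_i in 1:3) {
    truth <- sample(eye_classes(), 200, replace = TRUE)
    pred <- sample(eye_classes(), 200, replace = TRUE)
    cm <- confusion(truth, pred, classes = eye_classes())
    brute <- matrix(0L, 6, 6, dimnames = list(eye_classes(), eye_classes()))
    for (i in seq_along(truth))
      brute[truth[i], pred[i]] <- brute[truth[i], pred[i]] + 1L
    expect_equal(unname(cm$counts), unname(brute))
    # row-normalized percentages sum to 100 per non-empty row
    pct <- tidy(cm, percent = TRUE)
    sums <- tapply(pct$percent, pct$truth, sum)
    expect_equal(as.numeric(sums[rowSums(brute) > 0]),
                 rep(100, sum(rowSums(brute) > 0)))
    # accuracy equals trace/total
    expect_equal(accuracy(cm), sum(diag(brute)) / 200 * 100)
  }
})

test_that("one-vs-rest metrics implement the precision/sensitivity/specificity formulas", {
  # TP=1, FP=0, FN=0, TN=1 -> all 100%
  cm <- confusion(c("left", "right"), c("left", "right"))
  m <- class_metrics(cm)
  expect_equal(m$precision, c(100, 100))
  expect_equal(m$sensitivity, c(100, 100))
  expect_equal(m$specificity, c(100, 100))

  # TP=9, FP=1, FN=0, TN=10 -> 90 / 100 / ~90.9
  truth <- c(rep("left", 9), rep("right", 11))
  pred <- c(rep("left", 9), "left", rep("right", 10))
  m2 <- class_metrics(confusion(truth, pred))
  left <- m2[m2$class == "left", ]
  expect_equal(left$TP, 9); expect_equal(left$FP, 1)
  expect_equal(left$FN, 0); expect_equal(left$TN, 10)
  expect_equal(left$precision, 90)
  expect_equal(left$sensitivity, 100)
  expect_equal(left$specificity, 10 / 11 * 100, tolerance = 1e-9)

  # identity collapse equals direct computation
  ident <- stats::setNames(c("left", "right"), c("left", "right"))
  expect_equal(class_metrics(confusion(truth, pred), collapse = ident), m2)

  # empty positive class warns and yields NaN sensitivity
  cm3 <- confusion(rep("left", 4), c("left", "left", "right", "left"),
                   classes = c("left", "right"))
  expect_warning(m3 <- class_metrics(cm3), "no positive")
  expect_true(is.nan(m3$sensitivity[m3$class == "right"]))
})

test_that("the game collapse reduces six classes to right/idle/left", {
  set.seed(32)
  truth <- sample(eye_classes(), 120, replace = TRUE)
  pred <- sample(eye_classes(), 120, replace = TRUE)
  m <- class_metrics(confusion(truth, pred), collapse = game_collapse())
  expect_setequal(m$class, c("left", "right", "idle"))
  idle <- m[m$class == "idle", ]
  truth_c <- game_collapse()[truth]; pred_c <- game_collapse()[pred]
  expect_equal(idle$TP, sum(truth_c == "idle" & pred_c == "idle"))
})

test_that("chance levels are 100/k and uniform guessing attains them", {
  expect_equal(chance_level(6), 100 / 6, tolerance = 1e-12)
  expect_equal(round(chance_level(6), 2), 16.67)
  expect_equal(chance_level(5), 20)
  expect_equal(chance_level(2), 50)
  expect_error(chance_level(1), "at least 2")

  set.seed(123)
  n <- 1e5
  for (k in c(6, 5)) {
    cls <- eye_classes()[1:k]
    acc <- mean(sample(cls, n, TRUE) == sample(cls, n, TRUE)) * 100
    p <- 1 / k
    se <- sqrt(p * (1 - p) / n) * 100
    expect_lt(abs(acc - chance_level(k)), 3 * se)
  }
})

test_that("bit-rate accounting matches the 1-s block contract", {
  r <- bit_rates(60, 60, 2)
  expect_equal(r$classification_rate, 60)
  expect_equal(r$control_rate, 30)
  expect_equal(bit_rates(30, 60, 1)$control_rate, 30)
  expect_error(bit_rates(10, 0), "positive")

  # counting oracle on a simulated stream: commands consumed by the controller
  decisions <- rep(c("left", "center"), 30)   # 60 decisions over 60 s
  res <- simulate_game(decisions, seed = 1, control_decimation = 2)
  expect_equal(nrow(res$log), 30)             # controller consumed half
  expect_equal(res$rates$classification_rate, 60)
  expect_equal(res$rates$control_rate, 30)
})

test_that("score_decisions summarises a labeled stream", {
  d <- tibble::tibble(block_index = 0:3,
                      decision = c("center", "left", "left", "blink"),
                      label = c("center", "left", "right", "blink"))
  sc <- score_decisions(d)
  expect_equal(sc$block_accuracy, 75)
  expect_equal(sc$summary$n, 4)
  expect_error(score_decisions(d[, 1:2]), "labels")
})
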