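# Confusion counts, metric formulas, ROC/AUC and multi-run summaries.

test_that("confusion counts match a brute-force tally", {
  pred <- rep(c("SENESCENT", "CONTROL"), c(30, 24))
  cc <- confusion_counts(pred, pred)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 30, TN = 24, FP = 0, FN = 0))
  cc2 <- confusion_counts(rep("CONTROL", 5), rep("SENESCENT", 5))
  expect_equal(cc2$FN, 5)
  expect_equal(cc2$TP + cc2$TN + cc2$FP, 0)
  set.seed(13)
  for (rep in 1:5) {
    n <- 50
    pr <- sample(c("SENESCENT", "CONTROL"), n, replace = TRUE)
    tr <- sample(c("SENESCENT", "CONTROL"), n, replace = TRUE)
    cc <- confusion_counts(pr, tr)
    tally <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    for (i in seq_len(n)) {
      cell <- if (tr[i] == "SENESCENT") {
        if (pr[i] == "SENESCENT") "TP" else "FN"
      } else {
        if (pr[i] == "SENESCENT") "FP" else "TN"
      }
      tally[cell] <- tally[cell] + 1
    }
    expect_equal(unlist(cc[names(tally)]), tally)
    expect_equal(sum(unlist(cc[names(tally)])), n)
  }
  expect_error(confusion_counts("SENESCENT", c("SENESCENT", "CONTROL")),
               "equal-length")
})

test_that("metric formulas agree with hand evaluation and identities", {
  m <- compute_metrics(list(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 0.5, precision = 0.5, recall = 0.5, f1 = 0.5))
  perfect <- compute_metrics(list(TP = 30, TN = 24, FP = 0, FN = 0))
  expect_true(all(unlist(perfect) == 1))
  hand <- compute_metrics(list(TP = 9, FP = 1, FN = 3, TN = 7))
  expect_equal(hand$accuracy, 0.8)
  expect_equal(hand$precision, 0.9)
  expect_equal(hand$recall, 0.75)
  expect_equal(hand$f1, 18 / 22, tolerance = 1e-12)
  # zero denominators are NA, not silently zero
  degen <- compute_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(degen$precision))
  expect_true(is.na(degen$recall))
})

test_that("F1 is the harmonic mean of precision and recall wherever defined", {
  grid <- expand.grid(TP = 0:4, TN = 0:4, FP = 0:4, FN = 0:4)
  grid <- grid[rowSums(grid) > 0, ]
  for (r in sample(nrow(grid), 200)) {
    cc <- as.list(grid[r, ])
    m <- compute_metrics(cc)
    if (!is.na(m$precision) && !is.na(m$recall) &&
        (m$precision + m$recall) > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
    }
    expect_equal(m$accuracy, (cc$TP + cc$TN) / sum(unlist(cc)))
  }
})

test_that("trapezoidal AUC equals the pairwise concordance statistic", {
  concordance <- function(p, truth) {
    s <- p[truth == "SENESCENT"]; c <- p[truth == "CONTROL"]
    tot <- 0
    for (a in s) for (b in c) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(s) * length(c))
  }
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(6:50, 1)
    truth <- c("SENESCENT", "CONTROL",
               sample(c("SENESCENT", "CONTROL"), n - 2, replace = TRUE))
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    roc <- roc_curve(p, truth)
    expect_equal(roc$auc, concordance(p, truth), tolerance = 1e-10)
  }
  # degenerate cases
  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                   c("SENESCENT", "SENESCENT", "CONTROL", "CONTROL"))
  expect_equal(sep$auc, 1)
  tie <- roc_curve(rep(0.5, 6), rep(c("SENESCENT", "CONTROL"), 3))
  expect_equal(tie$auc, 0.5)
  expect_error(roc_curve(runif(4), rep("SENESCENT", 4)), "both classes")
})

test_that("ROC curves agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  truth <- sample(c("SENESCENT", "CONTROL"), 40, replace = TRUE,
                  prob = c(0.55, 0.45))
  p <- plogis(rnorm(40) + 2 * (truth == "SENESCENT"))
  ours <- roc_curve(p, truth)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = p, levels = c("CONTROL", "SENESCENT"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("run summaries report mean, sample SD and max AUC", {
  ms <- function(acc) list(accuracy = acc, precision = acc, recall = acc,
                           f1 = acc)
  nine <- summarize_runs(rep(list(ms(0.9)), 9), aucs = rep(0.95, 9))
  expect_true(all(nine$sd == 0))
  expect_equal(nine$n_runs, 9)
  two <- summarize_runs(list(ms(0.8), ms(1.0)), aucs = c(0.91, 0.96))
  expect_equal(unname(two$mean[["accuracy"]]), 0.9)
  expect_equal(unname(two$sd[["accuracy"]]), sd(c(0.8, 1.0)))
  expect_equal(two$max_auc, 0.96)
  expect_equal(summarize_runs(list(ms(0.7)),
                              aucs = c(0.91, 0.96, 0.93))$max_auc, 0.96)
})
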