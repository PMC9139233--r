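# Published per-class count cells and the derived ratios printed with
# them, used as golden tests for the metric arithmetic. `printed` holds
# the table strings; comparisons honor each cell's printed precision
# (half-up rounding).
fdnn_table <- data.frame(
  population = c("CLL_cells", "B_cells", "hematogones", "plasma_cells",
                 "T_cells", "aggregates", "debris", "Other"),
  TP = c(1316803, 195925, 93642, 11033, 2697327, 1739028, 3611475, 15297918),
  TN = c(24331391, 25464627, 25569274, 25654446, 22909067, 23610304,
         21611955, 9841675),
  FP = c(13539, 6582, 5298, 2914, 37470, 149637, 185744, 307263),
  FN = c(9865, 4464, 3384, 3205, 27734, 172629, 262424, 224742),
  accuracy = c("0.9991", "0.9996", "0.9997", "0.9998", "0.9975", "0.9874",
               "0.9825", "0.9793"),
  sensitivity = c("0.9926", "0.9777", "0.9651", "0.7749", "0.9898",
                  "0.9097", "0.9323", "0.9855"),
  specificity = c("0.9994", "0.9997", "0.9998", "0.9999", "0.9984",
                  "0.9937", "0.9915", "0.9697"),
  ppv = c("0.9898", "0.9675", "0.9465", "0.7911", "0.9863", "0.9208",
          "0.9511", "0.9803"),
  npv = c("0.9996", "0.9998", "0.9999", "0.9999", "0.9988", "0.9927",
          "0.988", "0.9777"),
  f1 = c("0.9912", "0.9726", "0.9557", "0.7829", "0.9881", "0.9152",
         "0.9416", "0.9829"),
  stringsAsFactors = FALSE
)

ldnn_table <- data.frame(
  population = fdnn_table$population,
  TP = c(1358, 177419, 70908, 10749, 1943032, 1213909, 2585138, 11750260),
  TN = c(18210402, 18027561, 18135313, 18196392, 16226465, 16810440,
         15324944, 6094852),
  FP = c(184, 4405, 3494, 2426, 23739, 82813, 145941, 196491),
  FN = c(322, 2881, 2551, 2699, 19030, 105104, 156243, 170663),
  accuracy = c("1.0000", "0.9996", "0.9997", "0.9997", "0.9977", "0.9897",
               "0.9834", "0.9798"),
  sensitivity = c("0.8083", "0.9840", "0.9653", "0.7993", "0.9903",
                  "0.9203", "0.9430", "0.9857"),
  specificity = c("1.0000", "0.9998", "0.9998", "0.9999", "0.9985",
                  "0.9951", "0.9906", "0.9688"),
  ppv = c("0.8807", "0.9758", "0.9530", "0.8159", "0.9879", "0.9361",
          "0.9466", "0.9836"),
  npv = c("1.0000", "0.9998", "0.9999", "0.9999", "0.9988", "0.9938",
          "0.9899", "0.9728"),
  f1 = c("0.8430", "0.9799", "0.9591", "0.8075", "0.9891", "0.9281",
         "0.9448", "0.9846"),
  stringsAsFactors = FALSE
)

# Compare a computed ratio against a printed string at its own precision.
# F1 cells get an extra half-digit of slack: the published F1 values were
# derived from the already-rounded sensitivity and PPV (visible in the
# L-DNN aggregates row, 0.9281 printed vs 0.92816 from raw counts), so
# they can differ from the raw-count value in the fourth decimal.
expect_matches_printed <- function(computed, printed, f1 = FALSE) {
  digits <- nchar(sub("^[^.]*\\.", "", printed))
  slack <- if (f1) 10^-digits else 0.5 * 10^-digits
  expect_lte(abs(computed - as.numeric(printed)), slack + 1e-12)
}

test_that("per-class metrics reproduce the published F-DNN table", {
  m <- class_metrics(fdnn_table[, c("population", "TP", "TN", "FP", "FN")])
  for (i in seq_len(nrow(m))) {
    for (col in c("accuracy", "sensitivity", "specificity", "ppv",
                  "npv", "f1")) {
      expect_matches_printed(m[[col]][i], fdnn_table[[col]][i],
                             f1 = col == "f1")
    }
  }
})

test_that("per-class metrics reproduce the published L-DNN table", {
  m <- class_metrics(ldnn_table[, c("population", "TP", "TN", "FP", "FN")])
  for (i in seq_len(nrow(m))) {
    for (col in c("accuracy", "sensitivity", "specificity", "ppv",
                  "npv", "f1")) {
      expect_matches_printed(m[[col]][i], ldnn_table[[col]][i],
                             f1 = col == "f1")
    }
  }
})

test_that("confusion counts match hand enumeration and conserve events", {
  cm <- confusion(c("CLL_cells", "T_cells", "debris"),
                  c("CLL_cells", "CLL_cells", "debris"))
  cll <- cm[cm$population == "CLL_cells", ]
  expect_equal(c(cll$TP, cll$FP, cll$FN, cll$TN), c(1, 1, 0, 1))
  expect_true(all(rowSums(cm[, c("TP", "TN", "FP", "FN")]) == 3))

  labels <- sample(cll_classes(), 200, replace = TRUE)
  perfect <- confusion(labels, labels, group_other = FALSE)
  expect_true(all(perfect$FP == 0) && all(perfect$FN == 0))
  expect_equal(sum(perfect$TP), 200L)

  # grouping folds the seven minor classes into Other
  g <- confusion(c("granulocytes", "unknown", "NK_cells"),
                 c("monocytes", "blasts", "T_cells"))
  other <- g[g$population == "Other", ]
  expect_equal(other$TP, 2L)  # cross-minor-class confusions vanish
  expect_equal(other$FN, 1L)
  expect_error(confusion("CLL_cells", c("CLL_cells", "T_cells")), "length")
})

test_that("degenerate ratios propagate as NA, perfect counts as 1", {
  m <- class_metrics(data.frame(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(unlist(m[1, c("accuracy", "sensitivity", "specificity",
                             "ppv", "npv", "f1")]),
               rep(1, 6), ignore_attr = TRUE)
  m0 <- class_metrics(data.frame(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m0$sensitivity))
  expect_true(is.na(m0$ppv))
  expect_equal(m0$specificity, 1)
  expect_error(class_metrics(data.frame(TP = -1, TN = 1, FP = 0, FN = 0)),
               "non-negative")
})

test_that("status table reproduces the published 2x2 case comparison", {
  st <- status_table_from_counts(tp = 25, tn = 8, fp = 1, fn = 0)
  m <- st$metrics
  get <- function(metric, col) m[m$metric == metric, col]
  expect_equal(get("accuracy", "percent"), 97.1, tolerance = 5e-3)
  expect_equal(get("sensitivity", "percent"), 100.0)
  expect_equal(get("specificity", "percent"), 88.9, tolerance = 5e-3)
  expect_equal(get("ppv", "percent"), 96.2, tolerance = 5e-3)
  expect_equal(get("npv", "percent"), 100.0)
  # the same numbers flow from per-case status vectors
  dnn <- rep(c("MRD_positive", "MRD_negative", "MRD_positive"),
             c(25, 8, 1))
  expert <- rep(c("MRD_positive", "MRD_negative", "MRD_negative"),
                c(25, 8, 1))
  st2 <- status_table(dnn, expert)
  expect_identical(st2$table, st$table)
  # all-correct and swapped-prediction enumeration oracle
  all_ok <- status_table(expert, expert)
  expect_equal(all_ok$metrics$percent[1], 100)
  flip <- ifelse(expert == "MRD_positive", "MRD_negative", "MRD_positive")
  swapped <- status_table(flip, expert)
  expect_equal(swapped$metrics$percent[1], 0)
})

test_that("exact binomial intervals match the published CIs", {
  # printed to 0.1 percentage point
  expect_ci_close <- function(ci, printed) {
    expect_true(all(abs(100 * ci - printed) <= 0.05 + 1e-9))
  }
  expect_ci_close(exact_binomial_ci(25, 25), c(86.3, 100.0))
  expect_ci_close(exact_binomial_ci(8, 8), c(63.1, 100.0))
  expect_ci_close(exact_binomial_ci(33, 34), c(84.7, 99.9))
  expect_ci_close(exact_binomial_ci(8, 9), c(51.8, 99.7))
  expect_ci_close(exact_binomial_ci(25, 26), c(80.4, 99.9))
  # closed-form beta-quantile cases
  expect_equal(unname(exact_binomial_ci(0, 1)), c(0, 0.975))
  expect_equal(unname(exact_binomial_ci(3, 3))[2], 1)
  expect_error(exact_binomial_ci(5, 4), "k <= n")
})

test_that("rank AUC equals the pair-counting oracle and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  toy <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  toy_truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(toy, toy_truth), auc_oracle(toy, toy_truth))
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) truth[1:2] <- c(TRUE, FALSE)
    scores <- round(runif(n), 2)  # coarse grid forces ties
    expect_equal(roc_auc(scores, truth), auc_oracle(scores, truth))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- c(rnorm(60, 1), rnorm(80, 0))
  truth <- rep(c(TRUE, FALSE), c(60, 80))
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                         quiet = TRUE))))
  expect_equal(roc_auc(scores, truth), ref, tolerance = 1e-12)
})

test_that("Passing-Bablok recovers exact lines and matches the oracle", {
  x <- 1:10
  fit <- passing_bablok(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_true(fit$slope_ci[1] <= 1 && 1 <= fit$slope_ci[2])
  expect_true(fit$intercept_ci[1] <= 0 && 0 <= fit$intercept_ci[2])

  fit2 <- passing_bablok(x, 2 * x + 3)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 3)

  set.seed(12)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    xx <- round(runif(n, 0, 50), 1)
    if (length(unique(xx)) < 2) next
    yy <- round(1.4 * xx + rnorm(n, 0, 4), 1)
    fit <- try(passing_bablok(xx, yy), silent = TRUE)
    if (inherits(fit, "try-error")) next
    expect_equal(fit$slope, pb_slope_oracle(xx, yy))
  }
  expect_error(passing_bablok(rep(2, 5), 1:5), "identical")
  expect_error(passing_bablok(1:2, 2:3), "at least 3")
})

test_that("swapping the axes inverts the Passing-Bablok slope", {
  set.seed(3)
  x <- sort(runif(7, 1, 20))
  y <- sort(runif(7, 5, 40))  # strictly monotone pairing
  a <- passing_bablok(x, y)
  b <- passing_bablok(y, x)
  expect_equal(a$slope, 1 / b$slope, tolerance = 1e-8)
})

test_that("Pearson correlation matches the covariance formula", {
  expect_equal(pearson_r(1:8, 1:8), 1)
  expect_equal(pearson_r(1:8, -(1:8)), -1)
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(0.8, 2.9, 2.5, 4.0, 4.6)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), direct)
  expect_error(pearson_r(rep(1, 4), 1:4), "variance")
})

test_that("dilution errors switch rule at 1000 expert events", {
  d <- dilution_errors(
    expert_count = c(1132442, 492, 750, 2000),
    dnn_count = c(1096836, 11, 750, 2000),
    expert_pct = c(88.878, 0.024, 0.05, 0.1),
    dnn_pct = c(88.521, 0.001, 0.05, 0.1)
  )
  expect_equal(round(d$error[1], 3), -3.144)
  expect_identical(d$error_type[1], "proportionate")
  expect_equal(d$error[2], -481)
  expect_identical(d$error_type[2], "absolute")
  expect_equal(d$error[3:4], c(0, 0))
  expect_equal(round(d$abs_error_pct_wbc[1], 3), -0.357)
  expect_equal(round(d$abs_error_pct_wbc[2], 3), -0.023)
})
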