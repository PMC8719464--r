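test_that("trapezoidal ROC equals the pairwise Mann-Whitney statistic", {
  expect_equal(roc_from_poms(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_from_poms(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(101)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, TRUE)   # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    r <- roc_from_poms(scores, labels)
    expect_equal(r$auc, mw_auc(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
  }
  expect_error(roc_from_poms(runif(5), rep(1, 5)), "undefined-ROC")
})

test_that("AUC is invariant under strictly monotone transforms of the POMs", {
  skip_if_not_installed("pROC")
  set.seed(102)
  for (i in 1:8) {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    a <- roc_from_poms(scores, labels)$auc
    expect_equal(roc_from_poms(qlogis(scores / 1.0001 + 1e-5), labels)$auc, a)
    expect_equal(roc_from_poms(scores^3, labels)$auc, a)
    # independent reference implementation
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                   direction = "<",
                                                   quiet = TRUE))))
  }
})

test_that("reader-averaged AUC is the arithmetic mean over readers", {
  obs <- make_observer_records(n_cases = 30, n_readers = 4, seed = 7)
  res <- reader_average_auc(obs$records, obs$truth, "unaided")
  expect_length(res$per_reader, 4L)
  expect_equal(res$average, mean(res$per_reader), tolerance = 1e-15)
  one <- reader_average_auc(obs$records[obs$records$reader_id == "R1", ],
                            obs$truth, "unaided")
  expect_equal(one$average, unname(one$per_reader))
  # missing reader x case cell -> design error listing the gap
  broken <- obs$records[-5, ]
  expect_error(reader_average_auc(broken, obs$truth, "unaided"),
               "design error")
})

test_that("bootstrap AUC comparison finds planted aiding and not its absence", {
  obs <- make_observer_records(n_cases = 40, n_readers = 3,
                               sd_unaided = 0.45, sd_aided = 0.18, seed = 8)
  res <- auc_difference_test(obs$records, obs$truth, n_boot = 500, seed = 9)
  expect_gt(res$difference, 0)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$ci[1], res$difference); expect_gt(res$ci[2], res$difference)
  # identical sessions: zero difference, p ~ 1
  same <- obs$records
  same$pom[same$session == "aided"] <-
    same$pom[same$session == "unaided"][match(
      paste(same$reader_id, same$case_id)[same$session == "aided"],
      paste(same$reader_id, same$case_id)[same$session == "unaided"])]
  res0 <- auc_difference_test(same, obs$truth, n_boot = 200, seed = 9)
  expect_equal(res0$difference, 0)
  expect_gt(res0$p_value, 0.9)
  expect_message(auc_difference_test(same, obs$truth, n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("binary metrics and rate-based confusion reconstruction invert each other", {
  m <- binary_metrics(confusion_counts(tp = 12, fp = 2, tn = 27, fn = 10))
  expect_equal(unname(m$rounded),
               c(0.545, 0.931, 0.857, 0.730))
  perfect <- binary_metrics(confusion_counts(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_true(all(perfect$raw == 1))
  undef <- binary_metrics(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_true(is.na(undef$raw[["ppv"]]))

  cc <- confusion_from_rates(0.545, 0.931, 22, 29)
  expect_equal(unlist(cc[c("tp", "fn", "tn", "fp")]),
               c(tp = 12, fn = 10, tn = 27, fp = 2))
  cc2 <- confusion_from_rates(1, 1, 10, 10)
  expect_equal(unlist(cc2[c("tp", "tn", "fp", "fn")]),
               c(tp = 10, tn = 10, fp = 0, fn = 0))
  cc3 <- confusion_from_rates(0.773, 0.793, 22, 29)
  expect_equal(cc3$tp, 17)
  expect_equal(cc3$tn, 23)
  expect_equal(binary_metrics(cc3)$rounded[["ppv"]], 0.739)
  expect_error(confusion_counts(tp = -1, fp = 0, tn = 0, fn = 0), "nonnegative")
})

test_that("BI-RADS change tabulation counts direction and biopsy concordance", {
  truth <- c(c1 = "malignant", c2 = "benign", c3 = "benign")
  un <- data.frame(reader_id = "R1", case_id = c("c1", "c2", "c3"),
                   birads = c("3", "4a", "2"), stringsAsFactors = FALSE)
  ai <- data.frame(reader_id = "R1", case_id = c("c1", "c2", "c3"),
                   birads = c("4b", "4a", "2"), stringsAsFactors = FALSE)
  tab <- birads_changes(un, ai, truth)
  expect_equal(tab$per_reader$n_increase, 1)
  expect_equal(tab$per_reader$n_decrease, 0)
  expect_equal(tab$per_reader$n_closer_to_biopsy, 1)
  # decrease toward benign truth is also "closer"
  ai2 <- ai; ai2$birads <- c("4b", "3", "2")
  tab2 <- birads_changes(un, ai2, truth)
  expect_equal(tab2$per_reader$n_decrease, 1)
  expect_equal(tab2$per_reader$n_closer_to_biopsy, 2)
  # identical sessions: all zero
  tab0 <- birads_changes(un, un, truth)
  expect_true(all(tab0$per_reader[, -1] == 0))
  # plain 4 sits between 3 and 4a
  un4 <- un; un4$birads <- c("4", "4", "4")
  ai4 <- un; ai4$birads <- c("4a", "3", "4")
  tab4 <- birads_changes(un4, ai4, truth)
  expect_equal(tab4$per_reader$n_increase, 1)
  expect_equal(tab4$per_reader$n_decrease, 1)
  expect_error(birads_changes(un[1:2, ], ai, truth), "design error")
  expect_error(perceptcad:::birads_rank("6"), "unknown")
})

test_that("time comparison reports means, differences, percent change and pairing", {
  un <- data.frame(reader_id = "R1", case_id = sprintf("c%d", 1:10),
                   time_s = seq(40, 58, by = 2), stringsAsFactors = FALSE)
  ai <- un; ai$time_s <- un$time_s + 5
  tc <- time_comparison(un, ai)
  expect_equal(tc$difference, 5)
  same <- time_comparison(un, un)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  shift <- time_comparison(un, within(ai, time_s <- time_s + rnorm(10, 0, 0.1)))
  expect_lt(shift$p_value, 0.01)
  expect_error(time_comparison(un[1, , drop = FALSE], ai[1, , drop = FALSE]),
               ">= 2")
  ch <- time_change(56.96, 43.96)
  expect_equal(unname(ch["difference"]), -13)
  expect_equal(round(-ch[["pct_change"]], 1), 22.8)
})

test_that("packaged observer tables are internally consistent", {
  aucs <- observer_fixture("reader_aucs")
  expect_equal(nrow(aucs), 6L)
  times <- observer_fixture("reader_times")
  expect_equal(round_half_up(times$mean_aided - times$mean_unaided, 2),
               times$difference)
  mix <- observer_case_mix()
  expect_equal(unname(mix["n_benign"] + mix["n_malignant"]), 51L)
})
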