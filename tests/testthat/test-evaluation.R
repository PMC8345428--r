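test_that("confusion counts match a hand-enumerated 4x4 case", {
  truth <- matrix(0L, 4, 4); truth[c(1, 2, 3, 5, 6, 9)] <- 2L   # 6 positives
  pred <- matrix(0L, 4, 4)
  pred[c(1, 2, 3, 5, 6)] <- 2L                 # 5 true positives, misses 9
  pred[c(10, 11)] <- 2L                        # 2 false positives
  cc <- confusion_counts(pred, truth)
  expect_identical(cc$tp, 5); expect_identical(cc$fp, 2)
  expect_identical(cc$fn, 1); expect_identical(cc$tn, 8)
  m <- seg_metrics(cc)
  expect_equal(m$precision, 5 / 7)
  expect_equal(m$recall, 5 / 6)
  expect_equal(m$jaccard, 5 / 8)
  expect_equal(m$accuracy, 13 / 16)
  expect_equal(m$f1, 10 / 13)
})

test_that("degenerate prediction patterns follow the stated conventions", {
  t1 <- matrix(c(rep(2L, 100), rep(0L, 9900)), 100, 100)
  m1 <- seg_metrics(confusion_counts(t1, t1))
  expect_true(all(unlist(m1[c("accuracy", "precision", "recall", "f1",
                              "jaccard")]) == 1))

  cc <- confusion_counts(matrix(0L, 100, 100), t1)
  expect_identical(cc$tp, 0); expect_identical(cc$fn, 100)

  # empty-positive convention: perfect all-background slide scores 1
  m0 <- seg_metrics(list(tp = 0, fp = 0, fn = 0, tn = 100))
  expect_true(all(unlist(m0[-1]) == 1))
  # positives predicted where none exist: precision collapses to 0
  mfp <- seg_metrics(list(tp = 0, fp = 5, fn = 0, tn = 95))
  expect_equal(mfp$precision, 0)
  expect_equal(mfp$recall, 0)

  expect_error(seg_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)), "no pixels")
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "differ in dimensions")
})

test_that("f1 equals 2*jaccard/(1+jaccard) on random confusion tables", {
  set.seed(5)
  for (k in 1:50) {
    cc <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
               fn = sample(0:50, 1), tn = sample(1:50, 1))
    m <- seg_metrics(cc)
    expect_equal(m$f1, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-12)
  }
})

test_that("streamed block counting equals dense counting", {
  set.seed(9)
  pred <- matrix(sample(0:2, 300 * 200, TRUE), 200, 300)
  truth <- matrix(sample(0:2, 300 * 200, TRUE), 200, 300)
  small <- confusion_counts(pred, truth, block_px = 64L)
  dense <- confusion_counts(pred, truth, block_px = 100000L)
  expect_identical(small[c("tp", "fp", "fn", "tn")],
                   dense[c("tp", "fp", "fn", "tn")])
  expect_equal(small$tp + small$fp + small$fn + small$tn, 200 * 300)
})

test_that("LSD test matches the hand-computed two-group ANOVA", {
  out <- lsd_test(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  ab <- out[out$group_i == "A" & out$group_j == "B", ]
  expect_equal(ab$mean_diff, -3)
  expect_equal(ab$std_error, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ab$t, -3.674235, tolerance = 1e-6)
  expect_identical(ab$df, 4L)
  expect_equal(ab$p_value, 0.02131164, tolerance = 1e-6)
  # pair swap: negated difference, same p, mirrored interval
  ba <- out[out$group_i == "B" & out$group_j == "A", ]
  expect_equal(ba$mean_diff, -ab$mean_diff)
  expect_equal(ba$p_value, ab$p_value)
  expect_equal(ba$ci_low, -ab$ci_high)
  expect_equal(ba$ci_high, -ab$ci_low)
})

test_that("LSD test agrees with a brute-force oracle on random groups", {
  set.seed(13)
  for (k in 1:10) {
    ns <- sample(2:6, 3, replace = TRUE)
    g <- rep(c("m1", "m2", "m3"), times = ns)
    v <- rnorm(sum(ns), mean = rep(runif(3), times = ns))
    out <- lsd_test(v, g)
    # oracle: explicit within-group sums of squares and Student t
    means <- tapply(v, g, mean)
    ssw <- sum((v - means[g])^2)
    df <- length(v) - 3
    mse <- ssw / df
    for (r in seq_len(nrow(out))) {
      i <- out$group_i[r]; j <- out$group_j[r]
      se <- sqrt(mse * (1 / ns[match(i, c("m1", "m2", "m3"))] +
                          1 / ns[match(j, c("m1", "m2", "m3"))]))
      diff <- means[[i]] - means[[j]]
      p <- 2 * pt(-abs(diff / se), df)
      expect_equal(out$mean_diff[r], diff, tolerance = 1e-10)
      expect_equal(out$std_error[r], se, tolerance = 1e-10)
      expect_equal(out$p_value[r], p, tolerance = 1e-10)
      expect_equal(out$ci_low[r], diff - qt(0.975, df) * se,
                   tolerance = 1e-10)
    }
  }
})

test_that("identical groups give zero difference and p of one", {
  out <- lsd_test(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(out$mean_diff, c(0, 0))
  expect_equal(out$p_value, c(1, 1))
  expect_warning(lsd_test(c(1, 1, 2, 2), rep(c("A", "B"), each = 2)),
                 "degenerate")
  expect_error(lsd_test(1:3, c("A", "A", "B")), "at least two values")
})

test_that("cohort evaluation summarizes per-slide metrics and methods", {
  t1 <- matrix(0L, 50, 50); t1[1:10, 1:10] <- 2L
  t2 <- matrix(0L, 50, 50); t2[20:40, 20:40] <- 2L
  truths <- list(s1 = t1, s2 = t2)
  perfect <- list(s1 = t1, s2 = t2)
  blind <- list(s1 = matrix(0L, 50, 50), s2 = matrix(0L, 50, 50))
  # the perfect-vs-blind toy has zero within-group variance, so the LSD
  # rows are legitimately degenerate here
  ev <- suppressWarnings(
    evaluate_cohort(list(good = perfect, bad = blind), truths,
                    slide_type = c(s1 = "FNA", s2 = "TP")))
  expect_identical(nrow(ev$per_slide), 4L)
  good_all <- ev$summary[ev$summary$method == "good" &
                           ev$summary$cohort == "All", ]
  expect_equal(good_all$f1, 1)
  expect_true(all(c("FNA", "TP") %in% ev$summary$cohort))
  # summary is the macro average of per-slide records
  bad_rows <- ev$per_slide[ev$per_slide$method == "bad", ]
  bad_all <- ev$summary[ev$summary$method == "bad" &
                          ev$summary$cohort == "All", ]
  expect_equal(bad_all$accuracy, mean(bad_rows$accuracy))
  expect_false(is.null(ev$lsd))
  expect_true(all(ev$lsd$metric %in%
                    c("accuracy", "precision", "recall", "f1", "jaccard")))

  # single perfect slide, no grouping: an "All" summary row of ones
  ev1 <- evaluate_cohort(list(s1 = t1), list(s1 = t1))
  expect_identical(ev1$summary$cohort, "All")
  expect_true(all(unlist(ev1$summary[c("accuracy", "precision", "recall",
                                       "f1", "jaccard")]) == 1))
  expect_error(evaluate_cohort(list(m = list(s1 = t1)), truths), "missing")
})
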