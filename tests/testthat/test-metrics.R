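# Overlap metrics, dice loss, aggregation.

test_that("soft dice matches hand evaluations and conventions", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(dice_coefficient_soft(a, a), 1)
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(dice_coefficient_soft(a, b), 0)
  # sum(pg) = 2, sum(p^2) = sum(g^2) = 4
  p <- matrix(0, 4, 4); p[1, 1:4] <- 1
  g <- matrix(0, 4, 4); g[1, 3:4] <- 1; g[2, 1:2] <- 1
  expect_equal(dice_coefficient_soft(p, g), 0.5)
  z <- matrix(0, 3, 3)
  expect_equal(dice_coefficient_soft(z, z), 1)
  expect_equal(dice_coefficient_soft(z, z, empty_value = 0), 0)
  expect_error(dice_coefficient_soft(matrix(2, 2, 2), matrix(1, 2, 2)),
               "\\[0, 1\\]")
})

test_that("dice loss endpoints and analytic gradient", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(dice_loss(a, a), 0)
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(dice_loss(a, b), 1)
  set.seed(12)
  p <- matrix(stats::runif(16, 0.05, 0.95), 4, 4)
  g <- matrix(sample(0:1, 16, replace = TRUE), 4, 4)
  an <- dice_loss_grad(p, g)
  fd <- numeric_grad_at(function(pp) dice_loss(pp, g), p, seq_len(16), 1e-6)
  expect_lt(max(abs(an - fd) / pmax(abs(fd), 1e-6)), 1e-2)
})

test_that("confusion counts and metric formulas", {
  g <- matrix(0, 10, 10); g[1, 1:8] <- 1          # 8 foreground
  p <- matrix(0, 10, 10); p[1, 3:8] <- 1; p[2, 1:2] <- 1  # TP 6, FP 2, FN 2
  cc <- confusion(p, g)
  expect_equal(unclass(cc)[c("TP", "FP", "FN", "TN")],
               list(TP = 6L, FP = 2L, FN = 2L, TN = 90L))
  expect_equal(accuracy_score(cc), 0.96)
  expect_equal(iou_score(cc), 0.6)
  expect_equal(dsc_score(cc), 0.75)

  same <- confusion(g, g)
  expect_equal(same$TP, 8L)
  expect_equal(same$FP + same$FN, 0L)
  allpos <- confusion(matrix(1, 5, 5), matrix(0, 5, 5))
  expect_equal(allpos$FP, 25L)

  empty <- confusion(matrix(0, 5, 5), matrix(0, 5, 5))
  expect_equal(iou_score(empty), 1)
  expect_equal(dsc_score(empty), 1)
  expect_equal(accuracy_score(empty), 1)
})

test_that("DSC equals 2 IoU / (1 + IoU) and binary soft dice equals count dice", {
  set.seed(2024)
  for (r in 1:200) {
    cc <- structure(list(TP = sample(0:50, 1), TN = sample(0:50, 1),
                         FP = sample(0:50, 1), FN = sample(0:50, 1)),
                    class = "confusion_counts")
    if (cc$TP + cc$TN + cc$FP + cc$FN == 0) next
    i <- iou_score(cc)
    expect_equal(dsc_score(cc), 2 * i / (1 + i), tolerance = 1e-12)
  }
  for (r in 1:20) {
    p <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
    g <- matrix(sample(0:1, 64, replace = TRUE), 8, 8)
    expect_identical(dice_coefficient_soft(p, g), dsc_score(confusion(p, g)))
  }
})

test_that("aggregation: CI half-widths, zero-dice counts, permutation invariance", {
  df <- data.frame(sample_id = 1:3, dsc = c(1, 1, 1), iou = c(1, 1, 1),
                   accuracy = c(1, 1, 1))
  r <- aggregate_metrics(df)
  expect_equal(unname(r$mean["dsc"]), 1)
  expect_equal(unname(r$ci_halfwidth["dsc"]), 0)

  df2 <- data.frame(sample_id = 1:4, dsc = c(0, 0.5, 0, 1),
                    iou = c(0, 0.5, 0, 1), accuracy = rep(0.9, 4))
  expect_equal(aggregate_metrics(df2)$zero_dice_count, 2L)

  df3 <- data.frame(sample_id = 1:2, dsc = c(0.6, 0.8), iou = c(0.6, 0.8),
                    accuracy = c(0.6, 0.8))
  r3 <- aggregate_metrics(df3)
  expect_equal(unname(r3$mean["dsc"]), 0.7)
  expect_equal(unname(r3$ci_halfwidth["dsc"]),
               1.96 * stats::sd(c(0.6, 0.8)) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(r3$ci_halfwidth["dsc"]), 0.196, tolerance = 1e-3)

  perm <- df2[c(3, 1, 4, 2), ]
  rp <- aggregate_metrics(perm)
  expect_equal(rp$mean, aggregate_metrics(df2)$mean)
  expect_equal(rp$zero_dice_count, 2L)

  expect_error(aggregate_metrics(df2[0, ]), "nrow")
})

test_that("reports serialise to CSV and JSON", {
  df <- data.frame(sample_id = 1:3, dsc = c(0, 0.5, 1), iou = c(0, 1 / 3, 1),
                   accuracy = c(0.9, 0.95, 1))
  r <- aggregate_metrics(df)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metric_report(r, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$dsc, df$dsc)
  j <- jsonlite::read_json(js)
  expect_equal(j$zero_dice_count, 1L)
  expect_equal(j$mean$dsc, 0.5)
})
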