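test_that("reference averaging interpolates linearly in log rate", {
  # single subject already on the grid: identity
  ref1 <- tibble::tibble(condition = "c1", subject = "s1",
                         rate_hz = c(4, 8, 16), threshold_db = c(-20, -15, -10))
  out <- average_reference(ref1, c(4, 8, 16))
  expect_equal(out$threshold_db, c(-20, -15, -10))
  expect_false(any(out$clamped))
  # two subjects offset by 4 dB: mean is the midpoint
  ref2 <- dplyr::bind_rows(ref1, dplyr::mutate(ref1, subject = "s2",
                                               threshold_db = threshold_db + 4))
  out2 <- average_reference(ref2, c(4, 8, 16))
  expect_equal(out2$threshold_db, c(-18, -13, -8))
  # off-grid target: brute-force piecewise-linear oracle in log2(rate)
  tgt <- c(5, 11)
  oracle <- vapply(tgt, function(r) {
    xs <- log2(c(4, 8, 16)); ys <- c(-20, -15, -10); xr <- log2(r)
    i <- max(which(xs <= xr))
    ys[i] + (ys[i + 1] - ys[i]) * (xr - xs[i]) / (xs[i + 1] - xs[i])
  }, numeric(1))
  out3 <- average_reference(ref1, tgt)
  expect_equal(out3$threshold_db, oracle, tolerance = 1e-9)
  # no extrapolation: outside rates are clamped and flagged
  out4 <- average_reference(ref1, c(1, 64))
  expect_equal(out4$threshold_db, c(-20, -10))
  expect_true(all(out4$clamped))
  expect_error(average_reference(ref1[0, ], c(4)), "empty")
})

test_that("similarity indices match their definitions and identity", {
  h <- c(-30, -25, -20, -18, -22, -28)
  expect_equal(pattern_similarity(h, h), 1.0)
  expect_equal(pattern_similarity(-(h - mean(h)) + mean(h), h), -1.0)
  expect_equal(discrepancy(h, h), 0)
  expect_equal(discrepancy(h + 6, h), 6)
  expect_equal(net_difference(h + 6, h), 6)
  # sign cancellation: net difference 0, discrepancy 2
  expect_equal(net_difference(c(2, -2) + c(0, 0), c(0, 0)), 0)
  expect_equal(discrepancy(c(2, -2), c(0, 0)), 2)
  # hand-computed covariance-ratio oracle on a 6-point toy vector
  m <- c(-28, -26, -21, -15, -20, -30)
  r_oracle <- sum((m - mean(m)) * (h - mean(h))) /
    sqrt(sum((m - mean(m))^2) * sum((h - mean(h))^2))
  expect_equal(pattern_similarity(m, h), r_oracle, tolerance = 1e-12)
  # degenerate variance is reported as missing
  expect_true(is.na(pattern_similarity(rep(1, 6), h)))
  expect_error(discrepancy(1:3, 1:4), "length")
})

test_that("discrepancy^2 = net_difference^2 + population variance of diffs", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(48, -20, 6); b <- rnorm(48, -22, 5)
    d <- a - b
    vpop <- mean((d - mean(d))^2)
    expect_equal(discrepancy(a, b)^2, net_difference(a, b)^2 + vpop,
                 tolerance = 1e-9)
  }
})

test_that("pooling order does not change the indices", {
  set.seed(3)
  tbl <- tidyr::expand_grid(condition = paste0("c", 1:3), rate_hz = c(4, 8, 16))
  tbl$layer <- 1
  tbl$threshold_db <- rnorm(9, -20, 5)
  ref <- dplyr::mutate(dplyr::select(tbl, -"layer", -"threshold_db"),
                       subject = "s1", threshold_db = rnorm(9, -22, 5))
  r1 <- compare_tmtf(tbl, ref)
  r2 <- compare_tmtf(tbl[sample(9), ], ref)
  expect_equal(r1$pattern_similarity, r2$pattern_similarity)
  expect_equal(r1$discrepancy_db, r2$discrepancy_db)
  expect_equal(r1$net_difference_db, r2$net_difference_db)
  expect_identical(r1$n_points, 9L)
  expect_gte(r1$discrepancy_db, abs(r1$net_difference_db))
})

test_that("accuracy-similarity correlations are Bonferroni corrected", {
  accs <- tibble::tibble(model = paste0("m", 1:5),
                         accuracy = c(0.1, 0.2, 0.3, 0.4, 0.5))
  # layer 1: perfectly linear; layer 2: toy set with a closed-form r
  idx <- dplyr::bind_rows(
    tibble::tibble(model = accs$model, layer = 1, index = 2 * accs$accuracy + 1),
    tibble::tibble(model = accs$model, layer = 2,
                   index = c(0.3, 0.1, 0.4, 0.2, 0.5)))
  out <- accuracy_similarity_correlation(accs, idx)
  expect_equal(out$r[out$layer == 1], 1.0, tolerance = 1e-9)
  r_oracle <- stats::cor(accs$accuracy, c(0.3, 0.1, 0.4, 0.2, 0.5))
  expect_equal(out$r[out$layer == 2], r_oracle, tolerance = 1e-12)
  expect_equal(out$p_bonferroni,
               pmin(1, out$p_raw * 2), tolerance = 1e-12)
  # identical accuracies: undefined, reported missing
  accs0 <- dplyr::mutate(accs, accuracy = 0.5)
  out0 <- accuracy_similarity_correlation(accs0, idx)
  expect_true(all(is.na(out0$r)))
  expect_error(accuracy_similarity_correlation(accs[1:2, ], idx), "3 models")
})

test_that("the synthetic human reference has the qualitative TMTF shapes", {
  ref <- synthetic_human_reference()
  conds <- am_conditions()
  targets <- purrr::map_dfr(seq_len(nrow(conds)), function(i)
    tibble::tibble(condition = conds$condition[i],
                   rate_hz = condition_rates(conds[i, ])))
  avg <- average_reference(ref, targets)
  # broadband: low-pass (threshold rises with rate);
  # narrowband: high-pass (threshold falls with rate)
  bb <- avg[avg$condition == "bb_long", ]
  expect_gt(bb$threshold_db[which.max(bb$rate_hz)],
            bb$threshold_db[which.min(bb$rate_hz)])
  nb <- avg[avg$condition == "nb31", ]
  expect_lt(nb$threshold_db[which.max(nb$rate_hz)],
            nb$threshold_db[which.min(nb$rate_hz)])
})
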