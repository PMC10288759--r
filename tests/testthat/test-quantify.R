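test_that("specificity index follows the on/(on+off) definition", {
  tbl <- data.frame(site = c("s1", "s1_off"),
                    kind = c("on_target", "off_target"),
                    reads = c(98, 2))
  expect_identical(specificityIndex(tbl), 0.98)
  noOff <- data.frame(site = "s1", kind = "on_target", reads = 50)
  expect_identical(specificityIndex(noOff), 1.0)
  zero <- data.frame(site = c("s1", "o1"),
                     kind = c("on_target", "off_target"), reads = c(0, 0))
  expect_error(specificityIndex(zero), "zero total reads")
  # condition slicing and the per-site mode
  multi <- data.frame(condition = rep(c("A", "B"), each = 2),
                      site = c("s1", "o1", "s1", "o1"),
                      kind = rep(c("on_target", "off_target"), 2),
                      reads = c(90, 10, 50, 50))
  expect_identical(specificityIndex(multi, "A"), 0.9)
  expect_identical(specificityIndex(multi, "B"), 0.5)
  expect_identical(unname(specificityIndex(multi, "A", perSite = TRUE)),
                   0.9)
})

test_that("specificity index is scale-invariant and decreasing in off-target reads", {
  set.seed(11)
  for (i in 1:200) {
    on <- sample(1:5000, 3); off <- sample(0:500, 2)
    tbl <- data.frame(site = paste0("s", 1:5),
                      kind = c(rep("on_target", 3), rep("off_target", 2)),
                      reads = c(on, off))
    si <- specificityIndex(tbl)
    expect_gte(si, 0); expect_lte(si, 1)
    # independent arithmetic
    expect_equal(si, sum(on) / (sum(on) + sum(off)))
    scaled <- tbl; scaled$reads <- scaled$reads * 7
    expect_equal(specificityIndex(scaled), si)
    worse <- tbl; worse$reads[4] <- worse$reads[4] + 1
    expect_lt(specificityIndex(worse), si)
  }
})

test_that("cleavage efficiency is the mNeonGreen-negative fraction of transfected cells", {
  expect_identical(
    cleavageEfficiency(data.frame(total = 5000, mcherry_pos = 1000,
                                  neon_neg_mcherry_pos = 400)), 0.4)
  expect_identical(
    cleavageEfficiency(data.frame(total = 5000, mcherry_pos = 1000,
                                  neon_neg_mcherry_pos = 0)), 0)
  expect_error(
    cleavageEfficiency(data.frame(total = 5000, mcherry_pos = 0,
                                  neon_neg_mcherry_pos = 0)),
    "zero transfected")
  expect_error(
    cleavageEfficiency(data.frame(total = 100, mcherry_pos = 50,
                                  neon_neg_mcherry_pos = 60)),
    "invalid FACS counts")
  set.seed(12)
  for (i in 1:200) {
    tot <- sample(1000:10000, 1)
    mc <- sample(1:tot, 1)
    nn <- sample(0:mc, 1)
    e <- cleavageEfficiency(data.frame(total = tot, mcherry_pos = mc,
                                       neon_neg_mcherry_pos = nn))
    expect_gte(e, 0); expect_lte(e, 1)
    expect_equal(e, nn / mc)
  }
})

test_that("fold change is the ratio of means, with a 2^-ddCt helper", {
  expect_identical(foldChange(10, 2), 5)
  x <- c(1.2, 0.8, 1.0)
  expect_identical(foldChange(x, x), 1)
  expect_error(foldChange(1, 0), "positive")
  expect_identical(foldChangeDDCt(20, 21, 15, 15), 2)
  expect_identical(foldChangeDDCt(21, 21, 15, 15), 1)
  set.seed(13)
  for (i in 1:100) {
    test <- runif(3, 0.1, 50); ctrl <- runif(3, 0.1, 50)
    expect_equal(foldChange(test, ctrl), mean(test) / mean(ctrl))
  }
})

test_that("half-life is exact on noiseless exponential decay", {
  tp <- c(1, 3, 6, 9, 18)
  fit <- decayHalfLife(tp, exp(-0.231 * tp))
  expect_equal(fit$k, 0.231, tolerance = 1e-9)
  expect_equal(fit$tHalf, log(2) / 0.231, tolerance = 1e-9)
  expect_equal(fit$tHalf, 3.0, tolerance = 1e-2)
  expect_false(fit$stable)

  flat <- decayHalfLife(tp, rep(2, 5))
  expect_equal(flat$k, 0, tolerance = 1e-12)
  expect_true(flat$stable)
  expect_identical(flat$tHalf, Inf)

  expect_error(decayHalfLife(c(1, 2), c(1, 0.5)), "at least 3")
  expect_error(decayHalfLife(c(1, 2, 2), c(1, 0.5, 0.4)),
               "strictly increasing")
  expect_error(decayHalfLife(c(1, 2, 3), c(1, 0, -1)), "positive")
})

test_that("half-life recovery from noisy decay is unbiased within 5%", {
  set.seed(2024)
  tp <- c(1, 3, 6, 9, 18)
  kTrue <- 0.231
  est <- replicate(100, {
    ab <- exp(-kTrue * tp) * exp(rnorm(length(tp), 0, 0.05))
    decayHalfLife(tp, ab)$tHalf
  })
  truth <- log(2) / kTrue
  expect_lt(abs(median(est) - truth) / truth, 0.05)
})
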