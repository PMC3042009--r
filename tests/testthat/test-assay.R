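test_that("blot normalization divides by loading and by the time average", {
  b <- data.frame(replicate = 1, time_min = c(0, 60),
                  target_signal = c(2, 4), loading_signal = c(1, 1))
  out <- blot_normalize(b)
  expect_equal(out$value, c(2 / 3, 4 / 3))   # ratios [2,4], mean 3

  # loading proportional to target -> flat series of ones
  b2 <- data.frame(replicate = 1, time_min = c(0, 30, 60),
                   target_signal = c(2, 6, 10),
                   loading_signal = c(1, 3, 5))
  expect_equal(blot_normalize(b2)$value, c(1, 1, 1))
})

test_that("blot normalization matches the direct formula and ignores gain", {
  set.seed(21)
  b <- data.frame(replicate = rep(1:3, each = 5), time_min = rep(0:4 * 60, 3),
                  target_signal = stats::runif(15, 1, 9),
                  loading_signal = stats::runif(15, 0.5, 2))
  out <- blot_normalize(b)
  for (r in 1:3) {
    sel <- b$replicate == r
    ratio <- b$target_signal[sel] / b$loading_signal[sel]
    expect_equal(out$value[sel], ratio / mean(ratio), tolerance = 1e-12)
  }
  # multiplying all loading signals of a replicate by a constant cancels
  b3 <- b
  b3$loading_signal <- b3$loading_signal * 17
  expect_equal(blot_normalize(b3)$value, out$value, tolerance = 1e-12)

  expect_error(blot_normalize(transform(b, loading_signal = 0)),
               "loading")
})

test_that("replicate summaries give the textbook mean and SEM", {
  df <- data.frame(observable = "x", dose_ng_ml = 100,
                   time_min = rep(c(0, 60), each = 4),
                   value = c(1, 1, 1, 1, 0, 2, 0, 2))
  s <- summarize_replicates(df)
  expect_equal(s$mean, c(1, 1))
  expect_equal(s$sem[1], 0)
  expect_equal(s$sem[2], stats::sd(c(0, 2, 0, 2)) / 2)

  two <- data.frame(observable = "x", dose_ng_ml = 1, time_min = 0,
                    value = c(0, 2))
  s2 <- summarize_replicates(two)
  expect_equal(s2$mean, 1)
  expect_equal(s2$sem, 1)   # sd = sqrt(2), / sqrt(2)

  expect_error(summarize_replicates(
    data.frame(observable = "x", dose_ng_ml = 1, time_min = 0, value = 1)),
    "< 2 replicates")
})

test_that("replicate summaries match an independent two-pass computation", {
  set.seed(31)
  df <- data.frame(observable = "x", dose_ng_ml = 10,
                   time_min = rep(c(0, 30, 60), each = 6),
                   value = stats::runif(18))
  s <- summarize_replicates(df)
  for (i in seq_along(s$time_min)) {
    v <- df$value[df$time_min == s$time_min[i]]
    m <- sum(v) / length(v)
    ss <- sqrt(sum((v - m)^2) / (length(v) - 1)) / sqrt(length(v))
    expect_equal(s$mean[i], m, tolerance = 1e-12)
    expect_equal(s$sem[i], ss, tolerance = 1e-12)
  }
})

test_that("qPCR relative expression follows the exponential Ct identities", {
  expect_equal(qpcr_relative_expression(20, 20), 1)
  expect_equal(qpcr_relative_expression(21, 20), 0.5)
  expect_equal(qpcr_relative_expression(19, 20), 2)
  set.seed(41)
  ct_t <- stats::runif(10, 18, 30)
  ct_h <- stats::runif(10, 18, 22)
  expect_equal(qpcr_relative_expression(ct_t, ct_h),
               exp(-(ct_t - ct_h) * log(2)), tolerance = 1e-12)
  expect_error(qpcr_relative_expression(Inf, 20), "finite")
  # strictly monotone in both Ct arguments
  expect_true(qpcr_relative_expression(21, 20) <
                qpcr_relative_expression(20.5, 20))
  expect_true(qpcr_relative_expression(20, 20) <
                qpcr_relative_expression(20, 20.5))
})

test_that("qPCR preprocessing averages technical replicates in Ct domain", {
  q <- data.frame(gene = "SOCS1", replicate = 1,
                  time_min = rep(c(30, 60), each = 2),
                  ct_target = c(24, 26, 22, 22), ct_hprt = 20)
  out <- qpcr_normalize(q)                 # mean dCt: 5 and 2
  raw <- 2^(-c(5, 2))
  expect_equal(out$value, raw / mean(raw), tolerance = 1e-12)
  out_lin <- qpcr_normalize(q, technical = "linear")
  raw_lin <- c(mean(2^(-c(4, 6))), 2^(-2))
  expect_equal(out_lin$value, raw_lin / mean(raw_lin), tolerance = 1e-12)
})

test_that("per-cell RSNC is an area-normalized concentration ratio", {
  one <- data.frame(nuc_sum = 10, nuc_area = 10, cyt_sum = 10, cyt_area = 10)
  expect_equal(rsnc_from_cells(one)$mean, 1)
  # halving nuclear area and summed signal leaves the concentration ratio
  half <- data.frame(nuc_sum = 5, nuc_area = 5, cyt_sum = 10, cyt_area = 10)
  expect_equal(rsnc_from_cells(half)$mean, 1)

  set.seed(51)
  cells <- data.frame(nuc_sum = stats::runif(35, 5, 50),
                      nuc_area = stats::runif(35, 5, 20),
                      cyt_sum = stats::runif(35, 5, 50),
                      cyt_area = stats::runif(35, 5, 20))
  r <- rsnc_from_cells(cells)
  ratios <- (cells$nuc_sum / cells$nuc_area) / (cells$cyt_sum / cells$cyt_area)
  expect_equal(r$mean, sum(ratios) / 35, tolerance = 1e-12)
  expect_equal(r$sem, stats::sd(ratios) / sqrt(35), tolerance = 1e-12)
  # global brightness rescaling cancels
  bright <- transform(cells, nuc_sum = 3 * nuc_sum, cyt_sum = 3 * cyt_sum)
  expect_equal(rsnc_from_cells(bright)$mean, r$mean, tolerance = 1e-12)
  expect_error(rsnc_from_cells(transform(cells, cyt_sum = 0)), "cell")
})

test_that("tumor volume follows the ellipsoid approximation", {
  expect_equal(tumor_volume(1, 1), 0.52)
  expect_equal(tumor_volume(2, 3), 4 * 3 * 0.52)
  expect_error(tumor_volume(0, 1), "positive")
  expect_warning(v <- tumor_volume(3, 2), "swapping")
  expect_equal(v, tumor_volume(2, 3))
  # homogeneous of degree 3 under isotropic scaling
  expect_equal(tumor_volume(2 * 1.7, 3 * 1.7), 1.7^3 * tumor_volume(2, 3))
})
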