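test_that("low-pass filter passes constants, damps noise, kills Nyquist", {
  expect_lt(max(abs(lowpass_filter(rep(3.7, 97)) - 3.7)), 1e-8)
  set.seed(4)
  noise <- rnorm(200)
  f <- lowpass_filter(noise)
  expect_lt(var(f), var(noise))
  # alternating +-1 sits at the Nyquist frequency: essentially erased
  nyq <- rep(c(1, -1), 60)
  fn <- lowpass_filter(nyq)
  expect_lt(max(abs(fn[20:100])), 0.05)
  expect_error(lowpass_filter(rnorm(8)), "12")
  expect_error(lowpass_filter(rnorm(50), cutoff = 1.5), "cutoff")
  # NaN gaps are interpolated for filtering and re-masked afterwards
  x <- sin(seq(0, 4 * pi, length.out = 80))
  x[c(10, 41)] <- NA
  fx <- lowpass_filter(x)
  expect_true(all(is.na(fx[c(10, 41)])))
  expect_false(anyNA(fx[-c(10, 41)]))
})

test_that("normalization subtracts controls and applies NaN rules", {
  n <- 20
  od <- seq(0.2, 1.2, length.out = n)
  blank <- rep(0.1, n)
  yfp <- 100 + 50 * od
  ref <- rep(100, n)
  norm <- normalize_expression(yfp, od, ref, blank)
  expect_equal(norm, (yfp - ref) / (od - blank), tolerance = 1e-12)
  # identical signal and reference: all zeros -> masked as near-zero
  expect_true(all(is.na(normalize_expression(ref, od, ref, blank))))
  # denominator at or below blank becomes NaN
  od2 <- od; od2[3] <- 0.05
  expect_true(is.na(normalize_expression(yfp, od2, ref, blank)[3]))
  # ratio invariance: scaling both differences by 2 changes nothing
  norm2 <- normalize_expression(2 * yfp - ref, 2 * od - blank, ref, blank)
  expect_equal(norm2, norm, tolerance = 1e-12)
  expect_error(normalize_expression(yfp, od, ref, blank[-1]), "time grid")
})

test_that("self-crossing SNR matches known component magnitudes", {
  t <- 0:95
  slow <- sin(2 * pi * t / 96)
  slow <- slow / sd(slow) * 10            # signal sd exactly 10
  set.seed(7)
  noise <- rnorm(96)
  noise <- noise / sd(noise) * 2          # residual sd exactly 2
  expect_equal(compute_snr(slow + noise, slow), 5, tolerance = 1e-12)
  # through the filter, the separation is recovered approximately
  raw <- slow + noise
  snr <- compute_snr(raw, lowpass_filter(raw))
  expect_gt(snr, 3)
  # degenerate cases
  expect_identical(compute_snr(slow, slow), Inf)
  expect_equal(compute_snr(rep(1, 20) + rnorm(20), rep(1, 20)), 0)
  expect_true(is.na(compute_snr(rep(NA_real_, 10), rep(NA_real_, 10))))
})

test_that("SNR is invariant to positive rescaling of the trace", {
  set.seed(9)
  raw <- cumsum(rnorm(50)) + rnorm(50)
  f <- lowpass_filter(raw)
  for (k in c(0.1, 3, 1000))
    expect_equal(compute_snr(k * raw, k * f), compute_snr(raw, f),
                 tolerance = 1e-10)
})

test_that("spliced call combines the SNR threshold and the NaN-majority rule", {
  expect_false(classify_spliced(snr = 100, nan_fraction = 0.6))
  expect_false(classify_spliced(snr = 5, nan_fraction = 0))   # strict >
  expect_true(classify_spliced(snr = Inf, nan_fraction = 0))
  expect_true(classify_spliced(snr = 5.01, nan_fraction = 0.5))
  expect_false(classify_spliced(snr = NA, nan_fraction = 0))
  # monotone in SNR, antitone in NaN fraction
  for (s in c(1, 5, 10, 100)) for (nf in c(0, 0.25, 0.5, 0.75)) {
    if (classify_spliced(s, nf)) {
      expect_true(classify_spliced(s + 1, nf))
      expect_true(classify_spliced(s, max(0, nf - 0.25)))
    }
  }
})

test_that("replicate merging follows the majority rule", {
  mk <- function(spliced, m = 1) list(mean_expr = m, max_expr = 2 * m,
                                      snr = 10, nan_fraction = 0,
                                      spliced = spliced)
  expect_true(merge_replicates(list(mk(TRUE), mk(TRUE), mk(TRUE),
                                    mk(FALSE)))$spliced)
  expect_false(merge_replicates(list(mk(TRUE), mk(TRUE), mk(FALSE),
                                     mk(FALSE)))$spliced)
  m <- merge_replicates(rep(list(mk(TRUE, 3)), 4))
  expect_identical(m$mean_expr, 3)
  expect_identical(m$max_expr, 6)
  # single replicate: threshold is 1
  expect_true(merge_replicates(list(mk(TRUE)))$spliced)
  expect_error(merge_replicates(list()), "no replicates")
})

test_that("splicing efficiency is a ratio against the reference strain", {
  wt <- list(mean_expr = 10, max_expr = 14)
  expect_identical(unname(splicing_efficiency(wt, wt)), c(1, 1))
  s <- list(mean_expr = 5, max_expr = 7)
  expect_identical(unname(splicing_efficiency(s, wt)), c(0.5, 0.5))
  expect_error(splicing_efficiency(s, list(mean_expr = 0, max_expr = 1)),
               "positive")
})

test_that("noise outliers are flagged by studentized residual sign", {
  x <- exp(seq(1, 3, length.out = 20))
  y <- exp(2 - 0.5 * log(x))       # exactly on a line in log-log space
  none <- noise_outlier_detection(x, y)
  expect_length(none$low, 0)
  expect_length(none$high, 0)
  # plant one point far above the trend
  y2 <- y; y2[7] <- y[7] * 20
  out <- noise_outlier_detection(x, y2)
  expect_true(7 %in% out$high)
  expect_false(7 %in% out$low)
  expect_length(noise_outlier_detection(x, y2, alpha = 0)$high, 0)
  expect_error(noise_outlier_detection(x[1:3], y[1:3]), "5 points")
  expect_error(noise_outlier_detection(rep(2, 6), y[1:6]), "degenerate")
})

test_that("measured efficiencies track the simulated ground truth", {
  eff <- c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.65, 0.8, 0.95, 1.1)
  plate <- tiny_plate(eff, n_replicates = 2, seed = 31)
  res <- process_plate(plate)
  lib <- res[res$role == "YiFP", ]
  lib <- lib[order(lib$strain), ]
  expect_true(all(lib$spliced))
  expect_gt(suppressWarnings(
    cor(lib$splicing_efficiency, eff, method = "spearman")), 0.95)
  # absolute recovery is also close
  expect_lt(max(abs(lib$splicing_efficiency - eff) / eff), 0.2)
})

test_that("plates without required control roles are rejected", {
  plate <- tiny_plate(c(0.5), n_replicates = 1, seed = 2)
  expect_error(process_plate(plate[plate$role != "blank", ]), "blank")
  expect_error(process_plate(plate[plate$role != "cherry_only", ]),
               "cherry_only")
})
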