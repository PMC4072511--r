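# Raw OD/YFP plate traces -> per-strain splicing-efficiency indices.
#
# Processing follows the reporter-library scheme: Butterworth low-pass
# filtering of each channel, subtraction of medium (OD) and background
# (no-YFP) signals, NaN-masking of near-zero values, a self-crossing
# signal-to-noise ratio computed over the first hours of growth to call a
# strain "spliced", replicate merging by majority, and expression indices
# relative to the intron-less reference strain.

# steady-state initial filter state for a unit-step input (direct form II
# transposed), so a constant series passes through the filter unchanged
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  comp <- matrix(0, n - 1, n - 1)       # companion matrix of a
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# zero-phase IIR filtering: odd-reflection padding at both ends plus
# steady-state initial conditions, applied forward and backward
.filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  b <- b / a[1]; a <- a / a[1]
  zi <- .lfilter_zi(b, a)
  p <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 3L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- .iir_filter(b, a, xp, zi * xp[1])
  y <- rev(.iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(p + 1):(p + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-4 Butterworth IIR filter at the given normalized cutoff (1 =
#' Nyquist), applied forward and backward so peaks are not time-shifted.
#' NaN gaps are linearly interpolated before filtering and re-masked
#' afterwards. The DC gain is exactly 1: constants pass through unchanged.
#'
#' @param series numeric series (NaN/NA-capable).
#' @param cutoff normalized cutoff frequency in (0, 1); default 0.15.
#' @param order filter order.
#' @return filtered series of the same length, original NA positions masked.
#' @export
lowpass_filter <- function(series, cutoff = 0.15, order = 4) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  ok <- is.finite(series)
  if (sum(ok) < 12)
    stop("series too short: need at least 12 non-NaN points")
  x <- series
  if (!all(ok)) {
    idx <- seq_along(x)
    x <- approx(idx[ok], x[ok], xout = idx, rule = 2)$y
  }
  bf <- signal::butter(order, cutoff, type = "low")
  out <- .filtfilt_ss(bf$b, bf$a, x)
  out[!ok] <- NA_real_
  out
}

#' Normalize reporter expression against background and medium
#'
#' `norm(t) = (yfp_i(t) - yfp_ref(t)) / (od_i(t) - od_blank(t))`; any time
#' point where the numerator or the denominator is at or below epsilon
#' (a small fraction of that channel's dynamic range) becomes NaN, following
#' the rule that near-zero or negative values are ignored.
#'
#' @param yfp_i strain fluorescence series.
#' @param od_i strain absorbance series.
#' @param yfp_ref fluorescence of the matched no-YFP control.
#' @param od_blank absorbance of the medium-only control.
#' @param eps_frac epsilon as a fraction of each channel's dynamic range.
#' @return normalized series with NaN where either channel is unusable.
#' @export
normalize_expression <- function(yfp_i, od_i, yfp_ref, od_blank,
                                 eps_frac = 1e-3) {
  lens <- lengths(list(yfp_i, od_i, yfp_ref, od_blank))
  if (length(unique(lens)) != 1L)
    stop("series must share a time grid (equal lengths)")
  num <- yfp_i - yfp_ref
  den <- od_i - od_blank
  eps_num <- eps_frac * diff(range(c(yfp_i, yfp_ref), finite = TRUE))
  eps_den <- eps_frac * diff(range(c(od_i, od_blank), finite = TRUE))
  out <- num / den
  out[!is.finite(num) | !is.finite(den) |
        num <= eps_num | den <= eps_den] <- NA_real_
  out
}

#' Self-crossing signal-to-noise ratio
#'
#' `SNR = sd(filtered) / sd(raw - filtered)` over the early-growth window,
#' comparing a trace's smooth component with its residual. NaN pairs are
#' dropped pairwise.
#'
#' @param raw unfiltered series.
#' @param filtered low-pass-filtered version of the same series.
#' @param time_h optional time axis; when given, only `time_h <=
#'   window_end_h` enters the computation.
#' @param window_end_h end of the evaluation window (hours, default 6).
#' @return non-negative real; `Inf` when the residual is exactly zero and
#'   the signal is not; `NA` when fewer than 4 points are usable.
#' @export
compute_snr <- function(raw, filtered, time_h = NULL, window_end_h = 6) {
  stopifnot(length(raw) == length(filtered))
  keep <- rep(TRUE, length(raw))
  if (!is.null(time_h)) keep <- time_h <= window_end_h
  r <- raw[keep]; f <- filtered[keep]
  ok <- is.finite(r) & is.finite(f)
  if (sum(ok) < 4) return(NA_real_)
  s_sig <- sd(f[ok])
  s_res <- sd(r[ok] - f[ok])
  if (s_res == 0) return(if (s_sig > 0) Inf else NA_real_)
  s_sig / s_res
}

#' Call a strain spliced from SNR and NaN fraction
#'
#' Spliced iff the NaN fraction of the normalized series is at most one half
#' and the SNR is strictly above the threshold within the early window.
#'
#' @param snr self-crossing SNR over the first `window_end_h` hours.
#' @param nan_fraction fraction of NaN values in the normalized series.
#' @param snr_threshold default 5.
#' @return logical.
#' @export
classify_spliced <- function(snr, nan_fraction, snr_threshold = 5) {
  if (is.na(nan_fraction) || nan_fraction > 0.5) return(FALSE)
  !is.na(snr) && snr > snr_threshold
}

#' Merge per-replicate expression results
#'
#' Means and maxima are averaged NaN-aware across replicates; the merged
#' spliced call follows the majority rule (at least `ceiling((n+1)/2)`
#' replicates spliced, i.e. 3 of 4 in the standard design).
#'
#' @param per_replicate list of per-replicate result lists with elements
#'   `mean_expr`, `max_expr`, `snr`, `nan_fraction`, `spliced`.
#' @return single merged result list with an `n_replicates` field.
#' @export
merge_replicates <- function(per_replicate) {
  n <- length(per_replicate)
  if (n == 0) stop("no replicates to merge")
  g <- function(field) vapply(per_replicate, function(r)
    as.numeric(r[[field]]), 0)
  spliced_n <- sum(vapply(per_replicate, function(r) isTRUE(r$spliced),
                          TRUE))
  list(mean_expr = mean(g("mean_expr"), na.rm = TRUE),
       max_expr = mean(g("max_expr"), na.rm = TRUE),
       snr = mean(g("snr"), na.rm = TRUE),
       nan_fraction = mean(g("nan_fraction"), na.rm = TRUE),
       spliced = spliced_n >= ceiling((n + 1) / 2),
       n_replicates = n)
}

#' Splicing-efficiency indices relative to the intron-less reference
#'
#' @param strain merged result for the intron strain.
#' @param wt merged result for the intron-less reference strain.
#' @return named numeric: `splicing_efficiency` (ratio of mean expression)
#'   and `max_splicing_efficiency` (ratio of maximal expression).
#' @export
splicing_efficiency <- function(strain, wt) {
  if (!is.finite(wt$mean_expr) || wt$mean_expr <= 0 ||
      !is.finite(wt$max_expr) || wt$max_expr <= 0)
    stop("reference strain expression must be positive")
  c(splicing_efficiency = strain$mean_expr / wt$mean_expr,
    max_splicing_efficiency = strain$max_expr / wt$max_expr)
}

#' Expression-noise outliers from a mean-CV^2 regression
#'
#' Fits `log(cv2) ~ log(mean_expr)` and flags points whose externally
#' studentized residual has a two-sided p-value below `alpha`, split by
#' residual sign (high = noisier than the trend, low = quieter).
#'
#' @param mean_expr positive mean expression per strain.
#' @param cv2 squared coefficient of variation per strain.
#' @param alpha significance level (default 0.1).
#' @return list with integer index vectors `low` and `high`.
#' @export
noise_outlier_detection <- function(mean_expr, cv2, alpha = 0.1) {
  stopifnot(length(mean_expr) == length(cv2))
  if (length(mean_expr) < 5) stop("need at least 5 points")
  if (any(mean_expr <= 0) || any(cv2 <= 0))
    stop("mean_expr and cv2 must be positive")
  x <- log(mean_expr)
  if (diff(range(x)) == 0) stop("degenerate fit: all mean_expr equal")
  fit <- lm(log(cv2) ~ x)
  # a numerically perfect fit has no outliers (studentization degenerates)
  if (suppressWarnings(summary(fit)$sigma) <=
        1e-10 * (sd(log(cv2)) + 1e-300))
    return(list(low = integer(0), high = integer(0)))
  tr <- rstudent(fit)
  p <- 2 * pt(-abs(tr), df = fit$df.residual - 1)
  hit <- is.finite(p) & p < alpha
  list(low = which(hit & tr < 0), high = which(hit & tr > 0))
}

# process one well's traces against its matched controls
.process_well <- function(time_h, yfp, od, yfp_ref_f, od_blank_f,
                          cutoff, snr_threshold, window_end_h) {
  yfp_f <- lowpass_filter(yfp, cutoff)
  od_f <- lowpass_filter(od, cutoff)
  norm <- normalize_expression(yfp_f, od_f, yfp_ref_f, od_blank_f)
  nan_fraction <- mean(!is.finite(norm))
  snr <- compute_snr(yfp, yfp_f, time_h = time_h,
                     window_end_h = window_end_h)
  list(mean_expr = if (all(!is.finite(norm))) NA_real_ else
         mean(norm, na.rm = TRUE),
       max_expr = if (all(!is.finite(norm))) NA_real_ else
         max(norm, na.rm = TRUE),
       snr = snr, nan_fraction = nan_fraction,
       spliced = classify_spliced(snr, nan_fraction, snr_threshold))
}

# plate geometry: "A01" -> (row, col); falls back to a 1-D index
.well_coords <- function(wells) {
  m <- regmatches(wells, regexec("^([A-P])([0-9]{1,2})$", wells))
  bad <- lengths(m) != 3L
  row <- ifelse(bad, NA_integer_, match(vapply(m, function(z)
    if (length(z) == 3) z[2] else "", ""), LETTERS))
  col <- ifelse(bad, NA_integer_, as.integer(vapply(m, function(z)
    if (length(z) == 3) z[3] else "0", "")))
  if (anyNA(row)) { row <- seq_along(wells); col <- rep(1L, length(wells)) }
  cbind(row = row, col = col)
}

#' Process a plate table into per-strain splicing-efficiency results
#'
#' Runs the full trace-processing chain: per well, both channels are
#' low-pass filtered; expression is normalized against the nearest no-YFP
#' well and the nearest blank well on the same replicate plate (Euclidean
#' row/column distance, ties to the lowest well index); the self-crossing
#' SNR over the first `window_end_h` hours and the NaN fraction yield a
#' spliced call; wells of a strain are merged by majority; and expression is
#' expressed relative to the merged intron-less reference.
#'
#' @param plate tibble/data.frame with columns
#'   `well,strain,role,replicate,time_h,od,yfp`.
#' @param snr_threshold spliced-call SNR threshold (default 5).
#' @param window_end_h SNR window end in hours (default 6).
#' @param cutoff normalized Butterworth cutoff (default 0.15).
#' @return tibble with one row per strain:
#'   `strain,role,n_replicates,snr,nan_fraction,spliced,mean_expr,max_expr,`
#'   `splicing_efficiency,max_splicing_efficiency`.
#' @export
process_plate <- function(plate, snr_threshold = 5, window_end_h = 6,
                          cutoff = 0.15) {
  need <- c("well", "strain", "role", "replicate", "time_h", "od", "yfp")
  if (!all(need %in% names(plate)))
    stop("plate table must have columns ", paste(need, collapse = ","))
  roles <- unique(plate$role)
  for (r in c("YFP_wt", "cherry_only", "blank"))
    if (!r %in% roles) stop("plate is missing a required control role: ", r)

  res <- list()
  for (rep_i in sort(unique(plate$replicate))) {
    pp <- plate[plate$replicate == rep_i, , drop = FALSE]
    wells <- unique(pp$well)
    info <- pp[!duplicated(pp$well), c("well", "strain", "role")]
    coords <- .well_coords(info$well)
    cherry_idx <- which(info$role == "cherry_only")
    blank_idx <- which(info$role == "blank")
    if (!length(cherry_idx) || !length(blank_idx))
      stop("replicate ", rep_i, " lacks cherry_only or blank wells")
    # filter each control well once
    ctl_cache <- new.env(parent = emptyenv())
    get_ctl <- function(i, channel) {
      key <- paste0(channel, "_", info$well[i])
      if (!is.null(ctl_cache[[key]])) return(ctl_cache[[key]])
      tr <- pp[pp$well == info$well[i], , drop = FALSE]
      tr <- tr[order(tr$time_h), ]
      ctl_cache[[key]] <- lowpass_filter(tr[[channel]], cutoff)
      ctl_cache[[key]]
    }
    nearest <- function(i, cand) {
      d <- sqrt((coords[cand, "row"] - coords[i, "row"])^2 +
                  (coords[cand, "col"] - coords[i, "col"])^2)
      cand[order(d, cand)][1]
    }
    for (i in seq_len(nrow(info))) {
      if (!info$role[i] %in% c("YiFP", "YFP_wt")) next
      tr <- pp[pp$well == info$well[i], , drop = FALSE]
      tr <- tr[order(tr$time_h), ]
      ci <- nearest(i, cherry_idx)
      bi <- nearest(i, blank_idx)
      r <- .process_well(tr$time_h, tr$yfp, tr$od,
                         get_ctl(ci, "yfp"), get_ctl(bi, "od"),
                         cutoff, snr_threshold, window_end_h)
      res[[length(res) + 1L]] <- c(list(strain = info$strain[i],
                                        role = info$role[i]), r)
    }
  }
  strains <- unique(vapply(res, `[[`, "", "strain"))
  merged <- lapply(strains, function(s)
    merge_replicates(res[vapply(res, function(r) r$strain == s, TRUE)]))
  names(merged) <- strains
  role_of <- vapply(strains, function(s)
    res[[which(vapply(res, function(r) r$strain == s, TRUE))[1]]]$role, "")
  wt_strains <- strains[role_of == "YFP_wt"]
  if (!length(wt_strains)) stop("no intron-less reference strain found")
  wt <- merge_replicates(merged[wt_strains])  # pool reference wells
  out <- lapply(strains, function(s) {
    m <- merged[[s]]
    se <- splicing_efficiency(m, wt)
    tibble::tibble(strain = s, role = role_of[[s]],
                   n_replicates = m$n_replicates, snr = m$snr,
                   nan_fraction = m$nan_fraction, spliced = m$spliced,
                   mean_expr = m$mean_expr, max_expr = m$max_expr,
                   splicing_efficiency = se[["splicing_efficiency"]],
                   max_splicing_efficiency =
                     se[["max_splicing_efficiency"]])
  })
  do.call(rbind, out)
}
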