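# Beat-level feature extraction feeding subsystem 1.
#
# R peaks are found with a derivative-emphasis detector in the Pan-Tompkins
# tradition: first difference -> squaring -> 150 ms moving-window integration
# -> adaptive threshold at 0.5x the running mean of accepted integrated peak
# heights, with a 200 ms refractory period; the reported index is the local
# maximum of the raw trace inside each detection window. Because the
# threshold is relative, detections are invariant to amplitude scaling.

#' Detect R peaks
#'
#' @param trace an [ecg_trace()] with a known sampling rate.
#' @return integer sample indices of R peaks (strictly increasing).
#' @export
detect_r_peaks <- function(trace) {
  if (!inherits(trace, "ecg_trace")) abort_field("trace", "must be an ecg_trace")
  x <- trace$samples
  fs <- trace$sampling_rate
  int_w <- max(3L, round(0.150 * fs))
  if (length(x) <= int_w) {
    warning("trace shorter than the integration window: no peaks detected")
    return(integer(0))
  }
  # band emphasis: 20 ms smoothing (noise suppression) then first difference
  xs <- moving_mean(x, max(3L, round(0.020 * fs)))
  energy <- c(0, diff(xs))^2
  integ <- moving_mean(energy, int_w)
  if (max(integ) <= .Machine$double.eps) return(integer(0))

  refractory <- round(0.200 * fs)
  half_search <- max(1L, round(0.100 * fs))
  # candidate local maxima of the integrated signal
  n <- length(integ)
  is_peak <- integ > c(-Inf, integ[-n]) & integ >= c(integ[-1], -Inf)
  cand <- which(is_peak & integ > 1e-3 * max(integ))
  cand <- cand[order(cand)]

  peaks <- integer(0)
  accepted_heights <- numeric(0)
  thr <- 0.5 * max(integ)   # bootstrap from the global peak
  for (i in cand) {
    if (integ[i] < thr) next
    lo <- max(1L, i - half_search); hi <- min(length(x), i + half_search)
    r <- lo + which.max(x[lo:hi]) - 1L
    if (length(peaks) && r - peaks[length(peaks)] < refractory) {
      # within refractory: keep the larger raw amplitude
      if (x[r] > x[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- r
        accepted_heights[length(accepted_heights)] <- integ[i]
        thr <- 0.5 * mean(accepted_heights)
      }
      next
    }
    peaks <- c(peaks, r)
    accepted_heights <- c(accepted_heights, integ[i])
    thr <- 0.5 * mean(accepted_heights)
  }
  unique(peaks)
}

#' R-R intervals in seconds
#'
#' @param r_peak_indices strictly increasing sample indices.
#' @param sampling_rate Hz.
#' @return numeric vector of length `length(r_peak_indices) - 1` (empty for
#'   fewer than two peaks).
#' @export
compute_rr <- function(r_peak_indices, sampling_rate) {
  check_number(sampling_rate, "sampling_rate", 1e-9)
  if (length(r_peak_indices) < 2) return(numeric(0))
  diff(r_peak_indices) / sampling_rate
}

#' Locate per-beat wave features
#'
#' Per beat: P value = maximum amplitude in \[R - 200 ms, R - 80 ms); QRS
#' window = \[R - 60 ms, R + 60 ms\]; QRS value = peak-to-peak amplitude in
#' the QRS window; QRS max amplitude = maximum in the QRS window. Windows
#' clipped at record edges are shrunk, never wrapped.
#'
#' @param trace an [ecg_trace()].
#' @param r_peak_indices R-peak sample indices (from [detect_r_peaks()] or
#'   ground truth).
#' @return A `fiducial_set`: list with `r_peak_indices`, `rr_intervals`,
#'   `p_values`, `qrs_values`, `qrs_max_amplitudes`.
#' @export
locate_waves <- function(trace, r_peak_indices) {
  x <- trace$samples; fs <- trace$sampling_rate
  n <- length(x)
  win <- function(lo_s, hi_s, r) {
    lo <- max(1L, r + round(lo_s * fs)); hi <- min(n, r + round(hi_s * fs))
    if (lo > hi) integer(0) else lo:hi
  }
  p_values <- qrs_values <- qrs_max <- numeric(length(r_peak_indices))
  for (i in seq_along(r_peak_indices)) {
    r <- r_peak_indices[i]
    pw <- win(-0.200, -0.080, r)
    qw <- win(-0.060, 0.060, r)
    p_values[i] <- if (length(pw)) max(x[pw]) else 0
    qrs_values[i] <- if (length(qw)) diff(range(x[qw])) else 0
    qrs_max[i] <- if (length(qw)) max(x[qw]) else 0
  }
  structure(list(r_peak_indices = r_peak_indices,
                 rr_intervals = compute_rr(r_peak_indices, fs),
                 p_values = p_values, qrs_values = qrs_values,
                 qrs_max_amplitudes = qrs_max),
            class = "fiducial_set")
}

#' Assemble the zero-padded N x 5 feature matrix
#'
#' Columns: R-R intervals (s), P values, QRS (peak-to-peak) values, QRS peak
#' indices, QRS max amplitudes. `N` is the longest feature-list length;
#' shorter lists are zero-padded at the tail.
#'
#' @param f a `fiducial_set` from [locate_waves()].
#' @return numeric matrix `N x 5` with column names.
#' @export
build_feature_matrix <- function(f) {
  cols <- list(rr_interval = f$rr_intervals,
               p_value = f$p_values,
               qrs_value = f$qrs_values,
               qrs_peak_index = as.numeric(f$r_peak_indices),
               qrs_max_amplitude = f$qrs_max_amplitudes)
  n <- max(vapply(cols, length, integer(1)))
  if (n == 0) {
    warning("no beats detected: returning a 1 x 5 zero matrix")
    n <- 1L
  }
  m <- vapply(cols, function(v) c(v, rep(0, n - length(v))), numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(cols)))
  m
}

#' Trace-to-feature-matrix convenience wrapper
#'
#' @param trace an [ecg_trace()].
#' @return numeric matrix `N x 5` (see [build_feature_matrix()]).
#' @export
extract_features <- function(trace) {
  build_feature_matrix(locate_waves(trace, detect_r_peaks(trace)))
}
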