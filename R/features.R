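#' Time-domain sEMG features (Hudgins set)
#'
#' Per channel of a high-pass-filtered raw sEMG window: root mean square
#' (RMS), mean absolute value (MAV), zero crossings (ZC), slope sign changes
#' (SSC), waveform length (WL). ZC counts sign changes whose amplitude step
#' exceeds the deadband; SSC counts slope-sign changes where both adjacent
#' increments exceed it; both reject noise-floor chatter.
#'
#' @param window numeric matrix, channels x samples of high-pass-filtered
#'   raw sEMG for one analysis window.
#' @param deadband amplitude threshold in mV for ZC/SSC, default 0.01 (the
#'   generator noise-floor scale).
#' @return numeric vector of length `5 * nrow(window)`, ordered
#'   RMS, MAV, ZC, SSC, WL per channel, named like `rms_ch1`.
#' @export
extract_features <- function(window, deadband = 0.01) {
  window <- as.matrix(window)
  if (!all(is.finite(window))) stop("window contains non-finite samples")
  nch <- nrow(window)
  feats <- t(vapply(seq_len(nch), function(c) {
    x <- window[c, ]
    d <- diff(x)
    zc <- sum(x[-length(x)] * x[-1] < 0 & abs(d) > deadband)
    dd <- d[-length(d)] * d[-1]
    ssc <- sum(dd < 0 &
                 (abs(d[-length(d)]) > deadband | abs(d[-1]) > deadband))
    c(rms = sqrt(mean(x^2)), mav = mean(abs(x)),
      zc = zc, ssc = ssc, wl = sum(abs(d)))
  }, numeric(5)))
  out <- as.numeric(t(feats))
  names(out) <- as.vector(outer(c("rms", "mav", "zc", "ssc", "wl"),
                                seq_len(nch), function(f, c) paste0(f, "_ch", c)))
  out
}

# Sliding-window starts (in samples, 1-based) for a signal of n samples.
window_starts <- function(n, win, step) {
  if (n < win) return(integer(0))
  seq(1L, n - win + 1L, by = step)
}
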