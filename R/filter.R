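#' @include AllGenerics.R
#' @importFrom signal filtfilt
NULL

# 4th-order Bessel low-pass prototype: poles are the roots of the reverse
# Bessel polynomial s^4 + 10 s^3 + 45 s^2 + 105 s + 105 (unit-delay
# normalisation), rescaled so the -3 dB point sits at 1 rad/s.
.besselProto <- function() {
  poles <- polyroot(c(105, 105, 45, 10, 1))
  gain <- 105
  hmag2 <- function(w) {
    num <- Mod(gain)^2
    den <- prod(Mod(1i * w - poles)^2)
    num / den
  }
  w3 <- uniroot(function(w) hmag2(w) - 0.5, c(0.1, 10), tol = 1e-12)$root
  list(poles = poles / w3, gain = gain / w3^4)
}

# digital biquad cascade for a Bessel low-pass at fc Hz: bilinear transform
# with prewarping, conjugate pole pairs kept together for numerical
# robustness at fc << fs
.besselSections <- function(fc, fs, order = 4) {
  if (order != 4) stop("only the 4th-order Bessel design is provided")
  proto <- .besselProto()
  wc <- 2 * fs * tan(pi * fc / fs)          # prewarped analog cutoff (rad/s)
  p <- proto$poles * wc
  pz <- (1 + p / (2 * fs)) / (1 - p / (2 * fs))
  # pair conjugates: sort by imaginary part, take the two with Im > 0
  pos <- pz[Im(pz) > 0]
  if (length(pos) != 2) stop("unexpected pole configuration")
  lapply(pos, function(q) {
    a <- c(1, -2 * Re(q), Mod(q)^2)
    b <- c(1, 2, 1)
    b <- b * sum(a) / sum(b)                # DC gain 1 per section
    list(b = b, a = a)
  })
}

#' Zero-phase 10 Hz Bessel low-pass filter
#'
#' Removes spikes from current-clamp traces before duration measurements,
#' leaving slow depolarizations intact: a 4th-order Bessel low-pass with
#' -3 dB at `fc` (default 10 Hz), applied forward-backward
#' (zero-phase, so threshold-crossing times are not displaced) as a
#' cascade of biquad sections. DC gain is exactly 1.
#'
#' @param x A [VoltageTrace-class] or numeric vector.
#' @param fs Sampling rate (Hz); taken from the trace when `x` is a
#'   [VoltageTrace-class].
#' @param fc Cutoff (-3 dB) frequency, Hz.
#' @return Object of the same type as `x`, filtered.
#' @examples
#' lowpass10Hz(rep(-60, 5000), fs = 1000)[1]
#' @export
lowpass10Hz <- function(x, fs = NULL, fc = 10) {
  if (is(x, "VoltageTrace")) {
    v <- lowpass10Hz(x@v_mV, fs = x@fs, fc = fc)
    out <- x
    out@v_mV <- v
    return(out)
  }
  if (is.null(fs)) stop("fs is required for numeric input")
  if (fs < 20 * fc)
    stop("sampling rate must be well above the cutoff (fs >= 20*fc)")
  npad <- ceiling(3 * fs / fc)
  n <- length(x)
  if (n < npad + 1)
    stop("trace shorter than the filter warm-up (need >= ", npad + 1,
         " samples at fs = ", fs, " Hz)")
  # odd-reflection padding so the filter state matches the signal level at
  # both ends (filtfilt alone starts from zero state -> edge transients)
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- c(left, x, right)
  for (sec in .besselSections(fc, fs)) {
    y <- signal::filtfilt(sec$b, sec$a, y)
  }
  y[(npad + 1):(npad + n)]
}
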