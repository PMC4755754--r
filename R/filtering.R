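## Low-pass filtering of simulated currents.
##
## The recording system's analog anti-alias stage is emulated as a 4-pole
## low-pass Bessel filter, the standard choice in patch-clamp amplifiers
## because its near-linear phase preserves event edges without ringing. The
## analog prototype below is the magnitude-normalized (-3 dB at omega = 1)
## 4th-order Bessel pole set; it is mapped to the sampling rate by frequency
## pre-warping and the bilinear transform.

## 4th-order Bessel analog prototype, -3 dB magnitude-normalized
.BESSEL4_POLES <- c(
  complex(real = -0.995208764350, imaginary =  1.257105739455),
  complex(real = -0.995208764350, imaginary = -1.257105739455),
  complex(real = -1.370067830551, imaginary =  0.410249717494),
  complex(real = -1.370067830551, imaginary = -0.410249717494)
)
.BESSEL4_GAIN <- 5.258199010244

#' Digital 4-pole Bessel low-pass filter coefficients
#'
#' Designs the digital filter used for the emulated analog filtering stage:
#' the 4th-order Bessel analog prototype scaled to the requested cutoff
#' (-3 dB) and discretized by the bilinear transform with frequency
#' pre-warping so the -3 dB point lands on \code{cutoff_Hz}.
#'
#' @param cutoff_Hz -3 dB cutoff frequency, Hz.
#' @param samplingRate Sampling rate, Hz (must be > 2 * cutoff).
#' @return List with numerator \code{b} and denominator \code{a} coefficients.
#' @examples
#' co <- besselLowpassCoefficients(5000, 25000)
#' @export
besselLowpassCoefficients <- function(cutoff_Hz, samplingRate) {
  stopifnot(cutoff_Hz > 0, samplingRate > 2 * cutoff_Hz)
  ## pre-warp so the bilinear transform preserves the -3 dB frequency
  warped <- 2 * samplingRate * tan(pi * cutoff_Hz / samplingRate)
  poles <- .BESSEL4_POLES * warped
  gain <- .BESSEL4_GAIN * warped^4
  zp <- signal::bilinear(Sz = numeric(0), Sp = poles, Sg = gain,
                         T = 1 / samplingRate)
  ar <- signal::as.Arma(zp)
  b <- Re(ar$b)
  a <- Re(ar$a)
  ## normalize exact unity DC gain
  b <- b * (sum(a) / sum(b))
  list(b = b, a = a)
}

#' Apply the emulated analog low-pass filter to samples
#'
#' Causal application (as an analog filter would act), via
#' \code{signal::filter}. The first samples are primed with the initial value
#' to avoid a start-up transient from zero.
#'
#' @param x Numeric sample vector.
#' @param cutoff_Hz -3 dB cutoff, Hz.
#' @param samplingRate Hz.
#' @return Filtered samples, same length as \code{x}.
#' @export
besselLowpass <- function(x, cutoff_Hz, samplingRate) {
  if (!length(x)) return(x)
  co <- besselLowpassCoefficients(cutoff_Hz, samplingRate)
  pad <- min(length(x), ceiling(4 * samplingRate / cutoff_Hz))
  y <- signal::filter(signal::Arma(b = co$b, a = co$a),
                      c(rep(x[1L], pad), x))
  as.numeric(y)[-seq_len(pad)]
}

#' Block-average decimation
#'
#' Averages consecutive blocks of \code{factor} samples, the post hoc
#' averaging used to reduce oversampled ramp sweeps (e.g. 100 kHz recordings
#' averaged down to 10 kHz).
#'
#' @param x Numeric vector; its length must be a multiple of \code{factor}.
#' @param factor Integer decimation factor.
#' @return Vector of block means, length \code{length(x)/factor}.
#' @examples
#' decimateByAveraging(1:10, 5)
#' @export
decimateByAveraging <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (length(x) %% factor != 0L)
    stop("length of x must be a multiple of the decimation factor")
  if (factor == 1L) return(x)
  colMeans(matrix(x, nrow = factor))
}
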