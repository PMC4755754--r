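#' Estimate the closed-level baseline of a trace
#'
#' Returns the dominant closed-level current as the mode of the sample
#' density, which is robust as long as the record spends most of its time
#' (more than about 70 percent) at the closed level. If no dominant mode is
#' found (e.g. a trace that is open throughout, or drifting), a warning is
#' issued and the median is returned instead.
#'
#' @param trace A [CurrentTrace-class] or numeric vector of samples (pA).
#' @return Baseline current, pA.
#' @examples
#' estimateBaseline(rnorm(1000, mean = -3.3, sd = 0.5))
#' @export
estimateBaseline <- function(trace) {
  x <- if (is(trace, "CurrentTrace")) currentSamples(trace) else as.numeric(trace)
  if (!length(x)) stop("empty trace")
  if (length(x) < 10L || length(unique(x)) == 1L) return(stats::median(x))
  d <- stats::density(x, n = 2048)
  peak <- which.max(d$y)
  mode <- d$x[peak]
  ## width of the dominant peak: distance to half-maximum on each side
  half <- d$y[peak] / 2
  left <- which(d$y[seq_len(peak)] < half)
  right <- which(d$y[peak:length(d$y)] < half)
  hw <- max(
    if (length(left)) mode - d$x[max(left)] else diff(range(x)) / 20,
    if (length(right)) d$x[peak + min(right) - 1L] - mode else diff(range(x)) / 20
  )
  nearMode <- mean(abs(x - mode) < 3 * hw)
  if (nearMode < 0.4) {
    warning("ambiguous baseline (no dominant closed level); using median")
    return(stats::median(x))
  }
  mode
}

#' Idealize a trace by half-amplitude threshold crossing
#'
#' Converts a current trace into an ordered dwell table. After baseline
#' subtraction the (sign-rectified) current is quantized to integer multiples
#' of the unitary \code{amplitude} using the half-amplitude criterion, i.e.
#' a sample is assigned level \eqn{k} when it lies within half an amplitude
#' of \eqn{k \times} \code{amplitude}, which resolves stacked multi-channel
#' openings. Level runs shorter than \code{minDuration} are merged into their
#' neighbours. The per-event mean amplitude is the baseline-subtracted mean
#' over the event interior, excluding two samples at each edge (filter
#' transients), in the trace's original current polarity.
#'
#' @param trace A [CurrentTrace-class].
#' @param amplitude Unitary event amplitude, pA (> 0).
#' @param minDuration Shortest accepted dwell, ms.
#' @param baseline Baseline current, pA; estimated with [estimateBaseline()]
#'   when \code{NULL}.
#' @param direction +1 or -1: polarity of channel deflections relative to
#'   baseline. Defaults to the sign of the mean command voltage (channel
#'   current is negative at negative potentials).
#' @return An [IdealizedRecord-class] whose dwells (including level-0
#'   closures) tile the record.
#' @examples
#' rec <- makeScenario("parental", seed = 2, duration = 5)
#' detectEvents(rec$trace, amplitude = 4.3)
#' @export
detectEvents <- function(trace, amplitude, minDuration = 0.2,
                         baseline = NULL, direction = NULL) {
  stopifnot(is(trace, "CurrentTrace"))
  if (!is.numeric(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  fs <- samplingRate(trace)
  if (minDuration / 1000 < 1 / fs)
    stop("minDuration is below one sampling interval")
  x <- currentSamples(trace)
  n <- length(x)
  if (is.null(baseline)) baseline <- estimateBaseline(x)
  if (is.null(direction)) {
    vbar <- mean(protocolVoltage(protocol(trace), traceTimes(trace)))
    direction <- if (vbar < 0) -1 else 1
  }
  dev <- (x - baseline) * direction           # open deflections positive
  level <- pmax(0L, as.integer(floor(dev / amplitude + 0.5)))

  minSamples <- max(1L, round(minDuration / 1000 * fs))
  r <- rle(level)
  vals <- r$values; lens <- r$lengths
  ## merge sub-resolution runs into the preceding run, repeatedly
  repeat {
    short <- which(lens < minSamples)
    short <- short[short > 1L]
    if (!length(short)) break
    i <- short[1L]
    vals[i] <- vals[i - 1L]
    ## collapse equal neighbours
    keep <- c(TRUE, vals[-1L] != vals[-length(vals)])
    lens <- as.numeric(tapply(lens, cumsum(keep), sum))
    vals <- vals[keep]
  }
  if (length(vals) && lens[1L] < minSamples && length(vals) > 1L) {
    vals <- vals[-1L]; lens[2L] <- lens[2L] + lens[1L]; lens <- lens[-1L]
  }

  endsIdx <- cumsum(lens)
  startsIdx <- c(1, head(endsIdx, -1L) + 1)
  csum <- c(0, cumsum(x - baseline))
  meanAmp <- vapply(seq_along(vals), function(i) {
    if (vals[i] == 0L) return(NA_real_)
    a <- startsIdx[i]; b <- endsIdx[i]
    if (b - a + 1 > 4) { a <- a + 2; b <- b - 2 }   # drop filter edges
    (csum[b + 1] - csum[a]) / (b - a + 1)
  }, numeric(1))

  dw <- data.frame(level = as.integer(vals),
                   start_s = (startsIdx - 1) / fs,
                   duration_s = lens / fs,
                   mean_amplitude_pA = meanAmp,
                   stringsAsFactors = FALSE)
  new("IdealizedRecord", dwells = dw, totalTime = n / fs,
      baseline = baseline)
}

#' Partition detected events into large and small conductance classes
#'
#' Splits the open dwells of a record by the magnitude of their mean
#' amplitude: events at or above \code{cut} form the large
#' (claudin-2-dependent, ~9 pA) class, events below it the small
#' (claudin-2-independent, ~4.3 pA) class. The default cut of 6 pA is the
#' midpoint between the two amplitude populations at +/-100 mV.
#'
#' @param record An [IdealizedRecord-class].
#' @param cut Class boundary, pA.
#' @return List with [IdealizedRecord-class] elements \code{large} and
#'   \code{small}, each holding that class's open dwells (closed dwells are
#'   dropped); baseline and total time are preserved.
#' @export
classifyEvents <- function(record, cut = 6) {
  stopifnot(is(record, "IdealizedRecord"))
  op <- openDwells(record)
  isLarge <- abs(op$mean_amplitude_pA) >= cut
  mk <- function(d, label) {
    if (nrow(d)) d$class <- label
    else d$class <- character(0)
    rownames(d) <- NULL
    new("IdealizedRecord", dwells = d, totalTime = totalTime(record),
        baseline = baseline(record))
  }
  list(large = mk(op[isLarge, , drop = FALSE], "large"),
       small = mk(op[!isLarge, , drop = FALSE], "small"))
}

#' Channel activity NPo
#'
#' Open probability times channel number, computed from the dwell table as
#' the sum of open time weighted by the number of simultaneously open
#' channels, divided by the total record time:
#' \deqn{NP_o = \sum (\mathrm{open\ time} \times \mathrm{channels\ open}) /
#'       \mathrm{total\ time}.}
#'
#' @param record An [IdealizedRecord-class].
#' @return Dimensionless NPo in \code{[0, max level]}.
#' @examples
#' dw <- data.frame(level = c(1L, 0L, 2L), start_s = c(0, 1, 6),
#'                  duration_s = c(1, 5, 1), mean_amplitude_pA = c(-9, NA, -18))
#' rec <- new("IdealizedRecord", dwells = dw, totalTime = 10, baseline = 0)
#' computeNPo(rec)  # (1*1 + 2*1)/10 = 0.3
#' @export
computeNPo <- function(record) {
  stopifnot(is(record, "IdealizedRecord"))
  if (totalTime(record) <= 0) stop("total record time must be > 0")
  d <- dwells(record)
  sum(d$level * d$duration_s) / totalTime(record)
}

#' Percent reduction in NPo
#'
#' @param npo_a Reference NPo (> 0).
#' @param npo_b Comparison NPo.
#' @return Reduction in percent, \code{100 * (1 - npo_b / npo_a)}.
#' @examples
#' npoReduction(0.4, 0.05)  # 87.5
#' @export
npoReduction <- function(npo_a, npo_b) {
  if (!is.numeric(npo_a) || npo_a <= 0)
    stop("reference NPo must be > 0 for a defined reduction")
  100 * (1 - npo_b / npo_a)
}
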