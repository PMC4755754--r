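#' All-points amplitude histogram
#'
#' Histogram of every current sample at a fixed 0.1 pA bin width, with bin
#' edges aligned to multiples of the bin width and counts normalized to the
#' record duration (samples/s per bin), so that total histogram mass times
#' the sampling interval equals the record duration.
#'
#' @param trace A [CurrentTrace-class].
#' @param binWidth Bin width, pA.
#' @return An [AmplitudeHistogram-class] (components empty until
#'   [fitGaussianMixture()] is run).
#' @examples
#' rec <- makeScenario("parental", seed = 3, duration = 5)
#' allPointsHistogram(rec$trace)
#' @export
allPointsHistogram <- function(trace, binWidth = 0.1) {
  stopifnot(is(trace, "CurrentTrace"), binWidth > 0)
  x <- currentSamples(trace)
  if (!length(x)) stop("empty trace")
  lo <- floor(min(x) / binWidth) * binWidth
  hi <- ceiling(max(x) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  dur <- length(x) / samplingRate(trace)
  new("AmplitudeHistogram",
      breaks = breaks, counts = as.numeric(counts),
      density = counts / dur, samplingRate = samplingRate(trace),
      components = data.frame(mean = numeric(0), sd = numeric(0),
                              weight = numeric(0)))
}

#' @rdname AmplitudeHistogram-class
#' @export
setMethod("componentTable", "AmplitudeHistogram", function(x) x@components)

#' Fit a Gaussian mixture to an all-points histogram
#'
#' Maximum-likelihood Gaussian mixture fit to the binned sample density by
#' expectation-maximization at the bin centres, weighted by bin counts. The
#' fit is deterministic: five fixed starting configurations (weighted
#' quantiles, equal spacing over the occupied range, and shifted variants)
#' are run to convergence and the best likelihood is kept. Component
#' standard deviations are floored at one bin width; a fit hitting the floor
#' is flagged via the \code{"sdFloored"} attribute of the component table.
#'
#' @param hist An [AmplitudeHistogram-class].
#' @param k Number of components (1 to 3).
#' @return The histogram with its \code{components} slot filled
#'   (data.frame(mean, sd, weight), sorted by mean); weights sum to 1.
#' @export
fitGaussianMixture <- function(hist, k = 1) {
  stopifnot(is(hist, "AmplitudeHistogram"), k >= 1, k <= 3)
  mids <- (hist@breaks[-1L] + hist@breaks[-length(hist@breaks)]) / 2
  w <- hist@counts
  occ <- w > 0
  binWidth <- diff(hist@breaks[1:2])
  if (k > 1L && sum(occ) < 3L * k - 1L)
    stop("fewer occupied bins than mixture parameters")
  ## parameter count is 3k - 1 (weights sum to 1); k = 1 tolerates a single
  ## occupied bin, collapsing to the bin centre with the sd floored
  if (k == 1L && sum(occ) == 1L) {
    cmp <- data.frame(mean = mids[occ], sd = binWidth, weight = 1)
    attr(cmp, "sdFloored") <- TRUE
    attr(cmp, "logLik") <- sum(w[occ] * stats::dnorm(0, sd = binWidth, log = TRUE))
    hist@components <- cmp
    return(hist)
  }
  x <- mids[occ]; wx <- w[occ]
  sdFloor <- binWidth

  wq <- function(p) {                      # weighted quantile
    o <- order(x); cw <- cumsum(wx[o]) / sum(wx)
    x[o][pmax(1L, findInterval(p, cw) + 1L)]
  }
  rng <- range(x)
  starts <- list(
    wq((seq_len(k)) / (k + 1)),
    seq(rng[1], rng[2], length.out = k + 2)[2:(k + 1)],
    wq((seq_len(k) - 0.25) / k),
    wq((seq_len(k) - 0.75) / k + 0.25 / k),
    seq(rng[1], rng[2], length.out = k)
  )
  sd0 <- max(sqrt(stats::weighted.mean((x - stats::weighted.mean(x, wx))^2, wx)) / k,
             sdFloor)

  best <- NULL
  for (mu0 in starts) {
    fit <- .gaussMixEM(x, wx, mu = sort(unique(mu0)), sd0 = sd0, k = k,
                       sdFloor = sdFloor)
    if (is.null(best) || fit$logLik > best$logLik) best <- fit
  }
  cmp <- data.frame(mean = best$mu, sd = best$sd, weight = best$w)
  cmp <- cmp[order(cmp$mean), , drop = FALSE]
  rownames(cmp) <- NULL
  attr(cmp, "sdFloored") <- any(best$sd <= sdFloor * (1 + 1e-9))
  attr(cmp, "logLik") <- best$logLik
  hist@components <- cmp
  hist
}

.gaussMixEM <- function(x, wx, mu, sd0, k, sdFloor,
                        maxIter = 500L, tol = 1e-9) {
  if (length(mu) < k) mu <- seq(min(x), max(x), length.out = k)
  sdv <- rep(sd0, k)
  wk <- rep(1 / k, k)
  n <- sum(wx)
  ll0 <- -Inf
  for (iter in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j)
      wk[j] * stats::dnorm(x, mu[j], sdv[j]), numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(wx * log(tot))
    resp <- dens / tot
    for (j in seq_len(k)) {
      rj <- wx * resp[, j]
      sj <- sum(rj)
      if (sj <= 0) next
      wk[j] <- sj / n
      mu[j] <- sum(rj * x) / sj
      sdv[j] <- max(sqrt(sum(rj * (x - mu[j])^2) / sj), sdFloor)
    }
    if (is.finite(ll0) && abs(ll - ll0) < tol * (1 + abs(ll))) break
    ll0 <- ll
  }
  list(mu = mu, sd = sdv, w = wk / sum(wk), logLik = ll)
}

#' Log-binned dwell-duration histogram
#'
#' Bins dwell durations on a logarithmic axis with a fixed number of bins
#' per decade (default 2, chosen to sample prolonged closed durations
#' adequately). Counts are conserved.
#'
#' @param durations Dwell durations, s (> 0).
#' @param binsPerDecade Bins per factor-of-ten of duration.
#' @return data.frame(lower_s, upper_s, count); \code{sum(count)} equals
#'   \code{length(durations)}.
#' @examples
#' dwellHistogram(c(0.001, 0.01, 0.1))
#' @export
dwellHistogram <- function(durations, binsPerDecade = 2) {
  if (!length(durations)) stop("no durations")
  if (any(durations <= 0)) stop("durations must be > 0")
  lg <- log10(durations)
  step <- 1 / binsPerDecade
  lo <- floor(min(lg) / step) * step
  hi <- ceiling(max(lg) / step) * step
  if (hi <= lo) hi <- lo + step
  edges <- seq(lo, hi + step / 2, by = step)
  idx <- findInterval(lg, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(lower_s = 10^edges[-length(edges)],
             upper_s = 10^edges[-1L],
             count = counts)
}

#' Maximum-likelihood exponential fit of dwell durations
#'
#' Fits raw (unbinned) dwell durations to a single exponential or a
#' two-component exponential mixture by maximum likelihood. The
#' single-component estimate is the closed-form sample mean; the mixture is
#' fitted by expectation-maximization from a deterministic split of the data
#' at its geometric mean. When both models are fitted, the likelihood-ratio
#' statistic \eqn{2 \Delta \ell} is referred to a chi-squared distribution
#' with 2 degrees of freedom and carried as \code{lrtP}. Durations below the
#' detection dead time should be excluded by the caller; no missed-event
#' correction is applied.
#'
#' @param durations Dwell durations, s.
#' @param nComponents 1, 2, or \code{NULL} to select by likelihood-ratio
#'   test at level \code{alpha}.
#' @param stateClass Label carried in the result ("open" or "closed").
#' @param alpha Significance level of the 1-vs-2 component test.
#' @return A [DwellTimeFit-class].
#' @examples
#' set.seed(1)
#' fitDwellExponentials(rexp(500, 1000), nComponents = 1)
#' @export
fitDwellExponentials <- function(durations, nComponents = NULL,
                                 stateClass = "open", alpha = 0.01) {
  durations <- as.numeric(durations)
  if (any(durations <= 0)) stop("durations must be > 0")
  n <- length(durations)
  wanted <- if (is.null(nComponents)) NA_integer_ else as.integer(nComponents)
  if (!is.na(wanted) && !wanted %in% c(1L, 2L))
    stop("nComponents must be 1 or 2")
  needed <- if (identical(wanted, 2L)) 30L else 10L
  if (n < needed)
    stop("insufficient events: need at least 10 per free parameter")

  tau1 <- mean(durations)
  ll1 <- sum(stats::dexp(durations, 1 / tau1, log = TRUE))

  fit2 <- NULL; lrtP <- NA_real_
  if (identical(wanted, 2L) || (is.na(wanted) && n >= 30L)) {
    fit2 <- .expMixEM(durations)
    lrt <- 2 * (fit2$logLik - ll1)
    lrtP <- stats::pchisq(max(lrt, 0), df = 2, lower.tail = FALSE)
  }

  use2 <- if (is.na(wanted)) (!is.null(fit2) && lrtP < alpha)
          else wanted == 2L
  if (use2) {
    o <- order(fit2$tau)
    cmp <- data.frame(tau_s = fit2$tau[o], fraction = fit2$frac[o])
    ll <- fit2$logLik
  } else {
    cmp <- data.frame(tau_s = tau1, fraction = 1)
    ll <- ll1
  }
  new("DwellTimeFit", stateClass = stateClass, components = cmp,
      nEvents = n, logLik = ll, lrtP = lrtP)
}

## EM for a two-component exponential mixture; deterministic init from the
## split at the geometric mean of the data.
.expMixEM <- function(d, maxIter = 1000L, tol = 1e-12) {
  gm <- exp(mean(log(d)))
  loSel <- d <= gm
  if (all(loSel) || !any(loSel)) {
    med <- stats::median(d); loSel <- d <= med
    if (all(loSel) || !any(loSel)) loSel <- seq_along(d) <= length(d) / 2
  }
  tau <- c(mean(d[loSel]), mean(d[!loSel]))
  if (tau[1] == tau[2]) tau[2] <- tau[2] * 2
  w <- c(mean(loSel), 1 - mean(loSel))
  ll0 <- -Inf
  for (iter in seq_len(maxIter)) {
    dens <- cbind(w[1] / tau[1] * exp(-d / tau[1]),
                  w[2] / tau[2] * exp(-d / tau[2]))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    for (j in 1:2) {
      sj <- sum(resp[, j])
      if (sj <= 0) next
      w[j] <- sj / length(d)
      tau[j] <- sum(resp[, j] * d) / sj
    }
    if (is.finite(ll0) && abs(ll - ll0) < tol * (1 + abs(ll))) break
    ll0 <- ll
  }
  list(tau = tau, frac = w / sum(w), logLik = ll)
}

#' Extract dwell durations from an idealized record
#'
#' Returns open (level >= 1) or closed (level 0) dwell durations, excluding
#' the first and last dwell of the record (their durations are censored by
#' the record boundaries) and optionally durations below a dead time.
#'
#' @param record An [IdealizedRecord-class].
#' @param stateClass "open" or "closed".
#' @param deadTime Shortest duration retained, ms (0 keeps all).
#' @return Numeric vector of durations, s.
#' @export
dwellDurations <- function(record, stateClass = c("open", "closed"),
                           deadTime = 0) {
  stateClass <- match.arg(stateClass)
  d <- dwells(record)
  if (nrow(d) > 2L) d <- d[-c(1L, nrow(d)), , drop = FALSE]
  sel <- if (stateClass == "open") d$level >= 1L else d$level == 0L
  out <- d$duration_s[sel]
  out[out >= deadTime / 1000]
}

#' Summarize the kinetic scheme implied by dwell-time fits
#'
#' Reports one open state if the single exponential is preferred for open
#' durations (likelihood-ratio test at \code{alpha}) and two closed states
#' if the double exponential is preferred for closed durations; the fast and
#' slow closed components are labelled \code{c_transient} and
#' \code{c_stable}. Components with vanishing fraction collapse.
#'
#' @param openFit [DwellTimeFit-class] of open durations.
#' @param closedFit [DwellTimeFit-class] of closed durations.
#' @param alpha Significance level used when a fit carries an unspent
#'   likelihood-ratio comparison.
#' @return List with \code{nOpen}, \code{nClosed}, \code{openComponents} and
#'   \code{closedComponents} (the latter labelled when two closed states are
#'   present).
#' @export
classifyKineticStates <- function(openFit, closedFit, alpha = 0.01) {
  effective <- function(fit) {
    cmp <- componentTable(fit)
    cmp <- cmp[cmp$fraction > 1e-6, , drop = FALSE]
    ## distinct time constants only
    if (nrow(cmp) == 2L &&
        abs(cmp$tau_s[1] - cmp$tau_s[2]) < 1e-9 * cmp$tau_s[2])
      cmp <- cmp[2L, , drop = FALSE]
    cmp
  }
  oc <- effective(openFit)
  cc <- effective(closedFit)
  if (nrow(cc) == 2L)
    cc$state <- c("c_transient", "c_stable")   # sorted ascending by tau
  else if (nrow(cc) == 1L)
    cc$state <- "c_closed"
  if (nrow(oc) >= 1L) oc$state <- paste0("o", seq_len(nrow(oc)))
  list(nOpen = nrow(oc), nClosed = nrow(cc),
       openComponents = oc, closedComponents = cc)
}
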