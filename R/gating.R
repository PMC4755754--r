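#' Construct a gating model
#'
#' Builds a [GatingModel-class] from labelled off-diagonal transition rates.
#' Diagonal entries of the rate matrix are filled in as negative row sums so
#' that the matrix is a proper generator.
#'
#' @param stateLabels Character vector of state names.
#' @param stateClass Character vector "open"/"closed" per state.
#' @param rates Square matrix of transition rates in 1/s; diagonal ignored and
#'   recomputed. Dimnames, if present, must match \code{stateLabels}.
#' @param poreConductance Conductance in pS per state; closed states must be 0.
#' @param reversalPotential Channel reversal potential, mV.
#' @return A validated \code{GatingModel}.
#' @examples
#' m <- gatingModel(c("c", "o"), c("closed", "open"),
#'                  rates = matrix(c(0, 5, 1000, 0), 2, 2, byrow = TRUE),
#'                  poreConductance = c(0, 90))
#' stationaryDistribution(m)
#' @export
gatingModel <- function(stateLabels, stateClass, rates,
                        poreConductance, reversalPotential = 0) {
  rates <- as.matrix(rates)
  diag(rates) <- 0
  diag(rates) <- -rowSums(rates)
  dimnames(rates) <- list(stateLabels, stateLabels)
  new("GatingModel",
      stateLabels = stateLabels,
      stateClass = stateClass,
      rates = rates,
      poreConductance = poreConductance,
      reversalPotential = reversalPotential)
}

#' Default claudin-2 channel gating model
#'
#' Three-state linear scheme \code{c_stable <-> o <-> c_transient}: a single
#' open state whose brief sojourns (mean 0.6 ms) alternate with transient
#' closures (mean 1.2 ms) inside bursts, with bursts terminated by entry into
#' a stable closed state (mean 3 s). The rate split out of the open state
#' (1500/s to the transient closure vs ~167/s to the stable closure) gives a
#' mean of ten openings per burst. Unitary conductance defaults to 90 pS and
#' reversal potential to 0 mV.
#'
#' @param tauOpen Mean open dwell, s.
#' @param tauTransient Mean transient-closed dwell, s.
#' @param tauStable Mean stable-closed dwell, s.
#' @param openingsPerBurst Mean number of openings per burst (sets the split
#'   of the open-state exit rate between the two closed states).
#' @param conductance Open-state conductance, pS.
#' @param reversalPotential mV.
#' @return A [GatingModel-class].
#' @examples
#' claudin2Model()
#' @export
claudin2Model <- function(tauOpen = 6e-4, tauTransient = 1.2e-3,
                          tauStable = 3, openingsPerBurst = 10,
                          conductance = 90, reversalPotential = 0) {
  stopifnot(tauOpen > 0, tauTransient > 0, tauStable > 0, openingsPerBurst > 1)
  kOpenExit <- 1 / tauOpen
  kOtoCs <- kOpenExit / openingsPerBurst
  kOtoCt <- kOpenExit - kOtoCs
  r <- matrix(0, 3, 3)
  ## order: c_stable, o, c_transient
  r[1, 2] <- 1 / tauStable
  r[2, 1] <- kOtoCs
  r[2, 3] <- kOtoCt
  r[3, 2] <- 1 / tauTransient
  gatingModel(c("c_stable", "o", "c_transient"),
              c("closed", "open", "closed"),
              r, c(0, conductance, 0), reversalPotential)
}

#' Claudin-2-independent ~40 pS channel model
#'
#' Two-state model for the small (~4 pA at 100 mV) conductance class present
#' in all monolayers regardless of claudin-2 expression. Kinetics are not
#' characterized in detail; defaults give brief (2 ms) openings at a low
#' opening rate.
#'
#' @param conductance Open-state conductance, pS (default 43, i.e. 4.3 pA at
#'   100 mV).
#' @param tauOpen Mean open dwell, s.
#' @param openingRate Closed-to-open rate, 1/s.
#' @return A [GatingModel-class].
#' @export
independentChannelModel <- function(conductance = 43, tauOpen = 2e-3,
                                    openingRate = 0.5) {
  r <- matrix(0, 2, 2)
  r[1, 2] <- openingRate
  r[2, 1] <- 1 / tauOpen
  gatingModel(c("c", "o"), c("closed", "open"), r, c(0, conductance), 0)
}

#' Off-junction apical membrane channel model
#'
#' Small (< 2 pA) transmembrane channel seen only when the pipette is sealed
#' over apical membrane away from the junction; resolvable only after 500 Hz
#' low-pass filtering. Opening rate may be scaled to emulate the higher event
#' frequency at positive holding potentials.
#'
#' @param conductance pS (default 15, i.e. 1.5 pA at 100 mV).
#' @param tauOpen Mean open dwell, s.
#' @param openingRate Closed-to-open rate, 1/s.
#' @return A [GatingModel-class].
#' @export
membraneChannelModel <- function(conductance = 15, tauOpen = 5e-3,
                                 openingRate = 1) {
  r <- matrix(0, 2, 2)
  r[1, 2] <- openingRate
  r[2, 1] <- 1 / tauOpen
  gatingModel(c("c", "o"), c("closed", "open"), r, c(0, conductance), 0)
}

#' Scale all transition rates of a model
#'
#' Multiplies every rate by a common factor (phenomenological temperature
#' scaling: the stationary distribution is unchanged, all dwells stretch by
#' \code{1/factor}).
#'
#' @param model A [GatingModel-class].
#' @param factor Positive multiplier.
#' @return A rescaled \code{GatingModel}.
#' @export
scaleRates <- function(model, factor) {
  stopifnot(is(model, "GatingModel"), factor > 0)
  gatingModel(model@stateLabels, model@stateClass, model@rates * factor,
              model@poreConductance, model@reversalPotential)
}

#' Stationary distribution of a gating model
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum \pi = 1} for the generator's stationary
#' occupancy. Used as the analytic oracle for simulated occupancy and for
#' expected open probability.
#'
#' @param model A [GatingModel-class].
#' @return Named numeric vector of stationary state probabilities.
#' @examples
#' stationaryDistribution(claudin2Model())
#' @export
stationaryDistribution <- function(model) {
  stopifnot(is(model, "GatingModel"))
  q <- model@rates
  n <- nrow(q)
  a <- rbind(t(q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(a, b)
  names(pi) <- model@stateLabels
  pi
}

#' Stationary open probability of a single channel
#'
#' @param model A [GatingModel-class].
#' @return Probability that the channel is in an open state at stationarity.
#' @export
openProbability <- function(model) {
  sum(stationaryDistribution(model)[model@stateClass == "open"])
}

#' Simulate a gating state path
#'
#' Gillespie simulation of the continuous-time Markov chain defined by the
#' model's generator. Sojourn times in each state are exponential with mean
#' equal to the reciprocal of the state's total exit rate; the successor
#' state is drawn proportionally to the off-diagonal rates. The initial state
#' is drawn from the stationary distribution unless given.
#'
#' @param model A [GatingModel-class].
#' @param duration Path length, s.
#' @param seed Optional integer seed for reproducibility.
#' @param initState Optional initial state label; default stationary draw.
#' @return data.frame with columns \code{state}, \code{class}, \code{start_s},
#'   \code{duration_s}; sojourns abut and cover \code{[0, duration]}.
#' @examples
#' p <- simulateStatePath(claudin2Model(), duration = 5, seed = 1)
#' head(p)
#' @export
simulateStatePath <- function(model, duration, seed = NULL, initState = NULL) {
  stopifnot(is(model, "GatingModel"))
  validObject(model)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  q <- model@rates
  n <- nrow(q)
  exit <- -diag(q)
  if (any(exit < 0)) stop("invalid generator: negative exit rate")
  if (is.null(initState)) {
    ## a singular generator (e.g. no transitions) has no unique stationary
    ## law; start uniformly in that case
    p0 <- tryCatch(pmax(stationaryDistribution(model), 0),
                   error = function(e) rep(1 / n, n))
    state <- sample.int(n, 1L, prob = p0)
  } else {
    state <- match(initState, model@stateLabels)
    if (is.na(state)) stop("unknown initState: ", initState)
  }
  ## preallocate; grow if needed
  cap <- max(64L, ceiling(duration * sum(exit)) * 2L)
  states <- integer(cap); starts <- numeric(cap); durs <- numeric(cap)
  t <- 0; i <- 0L
  while (t < duration) {
    i <- i + 1L
    if (i > cap) {
      cap <- cap * 2L
      length(states) <- cap; length(starts) <- cap; length(durs) <- cap
    }
    states[i] <- state
    starts[i] <- t
    if (exit[state] <= 0) {           # absorbing: sojourn spans the record
      durs[i] <- duration - t
      t <- duration
      break
    }
    dt <- stats::rexp(1L, exit[state])
    durs[i] <- min(dt, duration - t)
    t <- t + dt
    if (t < duration) {
      p <- q[state, ]
      p[state] <- 0
      state <- sample.int(n, 1L, prob = p)
    }
  }
  idx <- seq_len(i)
  data.frame(state = model@stateLabels[states[idx]],
             class = model@stateClass[states[idx]],
             start_s = starts[idx],
             duration_s = durs[idx],
             stringsAsFactors = FALSE)
}

#' Empirical state occupancy of a simulated path
#'
#' @param path data.frame as returned by [simulateStatePath()].
#' @param labels Optional state labels fixing the output order.
#' @return Named numeric vector of time fractions per state.
#' @export
pathOccupancy <- function(path, labels = NULL) {
  tot <- sum(path$duration_s)
  occ <- tapply(path$duration_s, path$state, sum) / tot
  if (!is.null(labels)) {
    out <- stats::setNames(numeric(length(labels)), labels)
    out[names(occ)] <- occ
    return(out)
  }
  occ
}
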