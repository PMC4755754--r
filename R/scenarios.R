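## Named experimental scenarios: channel-class composition, block dynamics
## and protocol presets emulating the study conditions.

.SCENARIO_NAMES <- c("cldn2_induced", "cldn2_suppressed", "parental",
                     "caco2_control", "caco2_kd", "la3_block", "mtset_i66c",
                     "cooled", "off_junction")

#' Names of the built-in scenarios
#'
#' @return Character vector of scenario names accepted by [makeScenario()].
#' @export
scenarioNames <- function() .SCENARIO_NAMES

## Scale only closed -> open transition rates (changes open probability,
## unlike scaleRates which preserves it).
.scaleOpeningRates <- function(model, factor) {
  r <- model@rates
  closed <- which(model@stateClass == "closed")
  open <- which(model@stateClass == "open")
  r[closed, open] <- r[closed, open] * factor
  gatingModel(model@stateLabels, model@stateClass, r,
              model@poreConductance, model@reversalPotential)
}

## Lehmer (MINSTD) step: decorrelates the RNG streams of consecutive
## replicate seeds (the first draws after set.seed(s) and set.seed(s + 1)
## are strongly correlated otherwise). Multiplication by 48271 modulo the
## Mersenne prime 2^31 - 1 is a bijection on [1, 2^31 - 2] and stays exact
## in double arithmetic.
.scrambleSeed <- function(seed) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271) %% 2147483647)
}

.channelClass <- function(model, n, p_active = 1, class = "claudin2",
                          blockable = FALSE) {
  list(model = model, n = as.integer(n), p_active = p_active,
       class = class, blockable = blockable)
}

#' Build a scenario description
#'
#' Constructs the [Scenario-class] for one of the named experimental
#' conditions. Claudin-2-expressing monolayers carry 3 claudin-2 channel
#' slots plus one claudin-2-independent ~40 pS channel; suppression and
#' knockdown reduce the per-slot expression probability to 1/8 so the
#' expected NPo falls by 87.5%. Block scenarios deactivate the claudin-2
#' class after \code{blockOnset}: instantaneously for lanthanum, with an
#' exponentially decaying active count (timescale 7 s) for MTSET
#' derivatization of the I66C pore mutant. Cooling scales claudin-2 gating
#' rates and the expected active count by 0.63, leaving the cold-resistant
#' independent class untouched. The off-junction scenario contains only
#' sub-2 pA apical membrane channels, more active at +100 than at -100 mV.
#'
#' @param name One of [scenarioNames()].
#' @param duration Record duration, s.
#' @param config Optional [RecordingConfig-class]; a default is built from
#'   \code{duration}.
#' @return A [Scenario-class].
#' @export
scenarioDefinition <- function(name, duration = 30, config = NULL) {
  name <- match.arg(name, .SCENARIO_NAMES)
  if (is.null(config)) config <- recordingConfig(duration = duration)
  duration <- config@duration
  proto <- holdProtocol(-100, duration)
  cldn <- claudin2Model()
  indep <- .channelClass(independentChannelModel(), 1, 1, "independent")
  onset <- NA_real_; tscale <- NA_real_
  classes <- switch(name,
    cldn2_induced = list(
      .channelClass(cldn, 3, 1, "claudin2", blockable = TRUE), indep),
    cldn2_suppressed = list(
      .channelClass(cldn, 3, 1 / 8, "claudin2", blockable = TRUE), indep),
    parental = list(indep),
    caco2_control = list(
      .channelClass(claudin2Model(conductance = 82), 3, 1, "claudin2",
                    blockable = TRUE), indep),
    caco2_kd = list(
      .channelClass(claudin2Model(conductance = 82), 3, 1 / 8, "claudin2",
                    blockable = TRUE), indep),
    la3_block = {
      onset <- min(10, duration / 3); tscale <- 0
      list(.channelClass(cldn, 3, 1, "claudin2", blockable = TRUE), indep)
    },
    mtset_i66c = {
      onset <- min(10, duration / 3); tscale <- 7
      list(.channelClass(cldn, 3, 1, "claudin2", blockable = TRUE), indep)
    },
    cooled = {
      config@temperatureScale <- 0.63
      list(.channelClass(scaleRates(cldn, 0.63), 3, 0.63, "claudin2",
                         blockable = TRUE), indep)
    },
    off_junction = {
      proto <- voltageProtocol(data.frame(
        kind = "hold", start_mV = c(-100, 100), end_mV = c(-100, 100),
        duration_s = c(duration / 2, duration / 2)))
      list(.channelClass(membraneChannelModel(), 1, 1, "membrane"))
    })
  new("Scenario", name = name, channelClasses = classes,
      blockOnset = onset, blockTimescale = tscale,
      protocol = proto, config = config)
}

## Force a path into its first closed state from tBlock onwards.
.blockPathAt <- function(path, model, tBlock, duration) {
  if (tBlock >= duration) return(path)
  closedState <- model@stateLabels[model@stateClass == "closed"][1L]
  if (tBlock <= 0) {
    return(data.frame(state = closedState, class = "closed",
                      start_s = 0, duration_s = duration,
                      stringsAsFactors = FALSE))
  }
  keep <- path$start_s < tBlock
  p <- path[keep, , drop = FALSE]
  nlast <- nrow(p)
  p$duration_s[nlast] <- tBlock - p$start_s[nlast]
  rbind(p, data.frame(state = closedState, class = "closed",
                      start_s = tBlock, duration_s = duration - tBlock,
                      stringsAsFactors = FALSE))
}

## Multi-channel level trajectory of one class -> IdealizedRecord ground
## truth, including level-0 (closed) dwells; baseline 0 by construction.
.levelRecord <- function(paths, models, protocol, duration, class) {
  opens <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    op <- p[p$class == "open", , drop = FALSE]
    if (nrow(op)) {
      op$gamma <- models[[i]]@poreConductance[
        match(op$state, models[[i]]@stateLabels)]
      op$vrev <- models[[i]]@reversalPotential
      opens[[length(opens) + 1L]] <- op
    }
  }
  if (!length(opens)) {
    dw <- data.frame(level = 0L, start_s = 0, duration_s = duration,
                     mean_amplitude_pA = NA_real_, class = class,
                     stringsAsFactors = FALSE)
    return(new("IdealizedRecord", dwells = dw, totalTime = duration,
               baseline = 0))
  }
  op <- do.call(rbind, opens)
  edges <- sort(unique(c(0, duration,
                         pmin(op$start_s, duration),
                         pmin(op$start_s + op$duration_s, duration))))
  starts <- edges[-length(edges)]
  ends <- edges[-1L]
  mids <- (starts + ends) / 2
  level <- integer(length(mids))
  amp <- numeric(length(mids))
  vMid <- protocolVoltage(protocol, mids)
  for (k in seq_len(nrow(op))) {
    inside <- mids >= op$start_s[k] & mids < op$start_s[k] + op$duration_s[k]
    level[inside] <- level[inside] + 1L
    amp[inside] <- amp[inside] +
      .pA_from_pS_mV(op$gamma[k], vMid[inside] - op$vrev[k])
  }
  ## merge runs of equal level
  runEnds <- c(which(diff(level) != 0L), length(level))
  runStarts <- c(1L, head(runEnds, -1L) + 1L)
  dur <- ends - starts
  dw <- data.frame(
    level = level[runStarts],
    start_s = starts[runStarts],
    duration_s = ends[runEnds] - starts[runStarts],
    mean_amplitude_pA = vapply(seq_along(runStarts), function(j) {
      sel <- runStarts[j]:runEnds[j]
      if (level[runStarts[j]] == 0L) NA_real_
      else sum(amp[sel] * dur[sel]) / sum(dur[sel])
    }, numeric(1)),
    class = class,
    stringsAsFactors = FALSE)
  dw <- dw[dw$duration_s > 0, , drop = FALSE]
  rownames(dw) <- NULL
  new("IdealizedRecord", dwells = dw, totalTime = duration, baseline = 0)
}

#' Generate a scenario recording with ground truth
#'
#' Simulates every channel of a named scenario, renders the current trace and
#' returns exact per-class ground-truth dwell records for oracle testing.
#' All randomness (channel expression draws, gating paths, block times,
#' recording noise) derives from \code{seed}; identical calls reproduce
#' identical traces.
#'
#' @param name One of [scenarioNames()].
#' @param seed Integer seed.
#' @param duration Record duration, s (ignored when \code{config} is given).
#' @param config Optional [RecordingConfig-class].
#' @return List with elements \code{trace} ([CurrentTrace-class]),
#'   \code{groundTruth} (named list of [IdealizedRecord-class] per channel
#'   class present) and \code{scenario} ([Scenario-class]).
#' @examples
#' rec <- makeScenario("parental", seed = 1, duration = 5)
#' rec$trace
#' @export
makeScenario <- function(name, seed, duration = 30, config = NULL) {
  sc <- scenarioDefinition(name, duration = duration, config = config)
  config <- sc@config
  dur <- protocolDuration(sc@protocol)
  set.seed(.scrambleSeed(seed))

  paths <- list(); models <- list(); classes <- character()
  for (cc in sc@channelClasses) {
    nActive <- if (cc$p_active >= 1) cc$n
               else stats::rbinom(1L, cc$n, cc$p_active)
    if (nActive < 1L) next
    for (ch in seq_len(nActive)) {
      p <- .simulateScenarioPath(cc, sc, dur)
      if (cc$blockable && is.finite(sc@blockOnset)) {
        tBlock <- if (sc@blockTimescale <= 0) sc@blockOnset
                  else sc@blockOnset + stats::rexp(1L, 1 / sc@blockTimescale)
        p <- .blockPathAt(p, cc$model, tBlock, dur)
      }
      paths[[length(paths) + 1L]] <- p
      models[[length(models) + 1L]] <- cc$model
      classes <- c(classes, cc$class)
    }
  }

  trace <- renderCurrent(paths, sc@protocol, config, models,
                         metadata = list(scenario = name, seed = seed))

  gt <- list()
  for (cl in unique(vapply(sc@channelClasses, `[[`, "", "class"))) {
    sel <- classes == cl
    gt[[cl]] <- .levelRecord(paths[sel], models[sel], sc@protocol, dur, cl)
  }
  list(trace = trace, groundTruth = gt, scenario = sc)
}

## Simulate one channel path; the off-junction membrane class has a higher
## opening rate at positive potentials, handled segment-by-segment (the
## chain is memoryless, so restarting at each hold boundary is exact).
.simulateScenarioPath <- function(cc, sc, duration) {
  if (cc$class != "membrane")
    return(simulateStatePath(cc$model, duration))
  segs <- sc@protocol@segments
  ends <- cumsum(segs$duration_s)
  starts <- c(0, head(ends, -1L))
  out <- NULL; lastState <- NULL
  for (i in seq_len(nrow(segs))) {
    m <- if (segs$start_mV[i] > 0) .scaleOpeningRates(cc$model, 4) else cc$model
    p <- simulateStatePath(m, segs$duration_s[i], initState = lastState)
    lastState <- p$state[nrow(p)]
    p$start_s <- p$start_s + starts[i]
    out <- rbind(out, p)
  }
  out
}
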