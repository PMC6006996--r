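## Robustness-analysis harness: build a gold-standard model, degrade
## parameter knowledge to a random subset, re-balance, sample, simulate
## and score against the reference until the mean score converges.

#' Running convergence state for a score stream
#'
#' Tracks the mean and standard deviation of scores (Welford update) and
#' applies the convergence rule: after a burn-in of 25 samples, the run is
#' converged once the standard error of the score relative to its mean,
#' \eqn{(\sigma_s/\sqrt{n})/\mu_s}, drops below 0.05. Runs hitting the
#' sample cap are flagged unconverged.
#'
#' @param cap maximum number of samples (default 10000)
#' @return state list with fields \code{n}, \code{mean}, \code{sd},
#'   \code{converged}, \code{capped}
#' @export
convergenceState <- function(cap = 10000L) {
  list(n = 0L, mean = 0, M2 = 0, sd = 0, converged = FALSE,
       capped = FALSE, cap = as.integer(cap), burnin = 25L, relTol = 0.05)
}

#' Update a convergence state with one score
#' @param state a [convergenceState()]
#' @param score non-negative score
#' @return updated state
#' @export
updateConvergence <- function(state, score) {
  state$n <- state$n + 1L
  d <- score - state$mean
  state$mean <- state$mean + d / state$n
  state$M2 <- state$M2 + d * (score - state$mean)
  state$sd <- if (state$n > 1L) sqrt(state$M2 / (state$n - 1L)) else 0
  if (state$n > state$burnin) {
    rel <- if (state$mean > 0)
      (state$sd / sqrt(state$n)) / state$mean else 0
    state$converged <- is.finite(rel) && rel < state$relTol
  }
  if (!state$converged && state$n >= state$cap) state$capped <- TRUE
  state
}

#' Mean-square error between two trajectories
#'
#' Mean over all species and time points of the squared concentration
#' difference; optionally the relative form
#' \eqn{((x - x_{ref})/(x_{ref} + \epsilon))^2} for networks whose
#' concentration scales differ by orders of magnitude.
#'
#' @param trajectory,reference outputs of [simulateModel()] on the same
#'   grid and species order
#' @param relative use the relative form (default FALSE)
#' @param eps regularisation for the relative form (mM)
#' @return scalar score
#' @export
mseScore <- function(trajectory, reference, relative = FALSE,
                     eps = 1e-6) {
  if (length(trajectory$time) != length(reference$time) ||
      any(abs(trajectory$time - reference$time) > 1e-9) ||
      !identical(colnames(trajectory$conc), colnames(reference$conc)))
    stop("trajectory grids or species orders differ")
  d <- trajectory$conc - reference$conc
  if (relative) mean((d / (reference$conc + eps))^2) else mean(d^2)
}

#' Build the gold-standard reference model
#'
#' Balances the network with the complete ground-truth record pool, fixes
#' the posterior medians, and simulates the standard schedule (400 s,
#' multiplicative x10 pulse of one metabolite at 200 s by default) from
#' the balanced concentrations. The resulting trajectory is the reference
#' against which degraded-knowledge models are scored, and the record
#' pool is what subsets are drawn from.
#'
#' @param network a [MetabolicNetwork-class]
#' @param seed integer seed (drives the ground-truth draw when
#'   \code{records} is NULL)
#' @param records optional complete record pool; defaults to
#'   [drawTrueParameters()]
#' @param config a [balancingConfig()]
#' @param schedule optional [simulationSchedule()]; defaults to
#'   [standardSchedule()] pulsing \code{pulseMetabolite}
#' @param pulseMetabolite metabolite to pulse (default: first state
#'   species)
#' @return a [GoldStandard-class]
#' @export
makeGoldStandard <- function(network, seed = 1L, records = NULL,
                             config = balancingConfig(),
                             schedule = NULL, pulseMetabolite = NULL) {
  if (is.null(records))
    records <- drawTrueParameters(network, seed = seed, config = config)
  bal <- balanceNetwork(network, records, config)
  if (is.null(schedule)) {
    if (is.null(pulseMetabolite)) {
      m <- network@metabolites
      pulseMetabolite <- m$id[!m$boundary][1L]
    }
    schedule <- standardSchedule(pulseMetabolite)
  }
  model <- assembleOdeSystem(network, bal$balanced)
  conc <- balancedConcentrations(bal$balanced)
  reference <- simulateModel(model, schedule, initial = conc)
  new("GoldStandard", network = network, system = bal$system,
      posterior = bal$posterior, balanced = bal$balanced, model = model,
      reference = reference, schedule = schedule, records = records,
      config = config)
}

setMethod("show", "GoldStandard", function(object) {
  cat("GoldStandard:", nrow(object@records), "known records,",
      length(object@model@stateIds), "state species, schedule",
      object@schedule$tEnd, "s\n")
})

## Precomputed fast sampler for one posterior: draws the basic vector,
## derives the model parameter arrays and mutates a packed-model template.
.makeDrawEngine <- function(gold, posterior, system) {
  net <- gold@network
  tmpl <- gold@model@cmodel
  stateIds <- gold@model@stateIds
  rxns <- net@reactions$id
  nb <- nrow(system@basics)
  ch <- tryCatch(chol(posterior@cov), error = function(e)
    chol(posterior@cov + diag(1e-10 * max(mean(diag(posterior@cov)),
                                          1e-12), nb)))
  Dkf <- system@D[.depIndex(system, "lnkcatf", rxns,
                            rep(NA_character_, length(rxns))), ,
                  drop = FALSE]
  Dkr <- system@D[.depIndex(system, "lnkcatr", rxns,
                            rep(NA_character_, length(rxns))), ,
                  drop = FALSE]
  iU <- .basicIndex(system, rep("lnu", length(rxns)), rxns,
                    rep(NA_character_, length(rxns)))
  fullIds <- c(stateIds, names(gold@model@boundary))
  # map packed kM pairs back to basic indices
  pairRxnId <- rxns[tmpl$pairRxn + 1L]
  pairMetId <- fullIds[tmpl$pairMet + 1L]
  iPairKm <- .basicIndex(system, rep("lnkM", length(pairRxnId)),
                         pairRxnId, pairMetId)
  iRegKm <- if (length(tmpl$regRxn))
    .basicIndex(system, rep("lnkM", length(tmpl$regRxn)),
                rxns[tmpl$regRxn + 1L], fullIds[tmpl$regMet + 1L])
    else integer(0)
  mets <- net@metabolites$id
  iC <- .basicIndex(system, rep("lnc", length(mets)),
                    rep(NA_character_, length(mets)), mets)
  names(iC) <- mets
  irrev <- !net@reactions$reversible
  function(width, z) {
    q <- posterior@mean
    if (width > 0) q <- q + width * drop(crossprod(ch, z))
    cm <- tmpl
    cm$kcatf <- exp(drop(Dkf %*% q))
    kcatr <- exp(drop(Dkr %*% q))
    kcatr[irrev] <- 0
    cm$kcatr <- kcatr
    cm$u <- exp(q[iU])
    cm$pairKm <- exp(q[iPairKm])
    if (length(iRegKm)) cm$regKm <- exp(q[iRegKm])
    conc <- exp(q[iC]); names(conc) <- mets
    list(cm = cm, conc = conc, q = q)
  }
}

## simulate a packed model; returns trajectory or NULL on failure
.simulatePacked <- function(gold, cm, conc, control = list()) {
  mod <- gold@model
  mod@cmodel <- cm
  tryCatch(
    simulateModel(mod, gold@schedule, initial = conc,
                  rtol = if (is.null(control$rtol)) 1e-6 else control$rtol,
                  atol = if (is.null(control$atol)) 1e-9 else control$atol,
                  maxsteps = if (is.null(control$maxsteps)) 10000
                             else control$maxsteps),
    error = function(e) NULL, warning = function(w) NULL)
}

#' Score a random knowledge subset against the gold standard
#'
#' Implements one outer repetition of the robustness protocol: draw a
#' uniform random subset of \code{ceiling(fraction * pool)} known records,
#' re-balance the network with only those (everything else falls back to
#' the pseudo-priors), then repeatedly sample a full thermodynamically
#' consistent parameter set from the new posterior at the given sampling
#' width, simulate the standard schedule from the sampled concentrations,
#' and score the mean square error against the reference trajectory. The
#' stream of scores is monitored with the 25-sample/5-percent rule; runs
#' hitting the sample cap are flagged unconverged. A sample whose
#' simulation fails (non-finite parameters or integration breakdown)
#' scores a sentinel of 1e6 times the median successful score so far
#' (1e6 when none succeeded yet) so that low-information subsets are
#' penalised rather than dropped. At width 0 the posterior collapses to
#' its medians and the single deterministic sample is returned.
#'
#' @param gold a [GoldStandard-class]
#' @param fraction fraction of the known-record pool to keep, in [0, 1]
#' @param width posterior sampling-width multiplier
#' @param seed integer seed
#' @param maxSamples sample cap (default 10000)
#' @param relative use relative MSE (default FALSE)
#' @param simControl list of solver settings for the sampled simulations
#'   (\code{rtol}, \code{atol}, \code{maxsteps}); the defaults are the
#'   [simulateModel()] defaults. A lighter profile trades a little
#'   trajectory accuracy for speed; samples whose integration exceeds
#'   \code{maxsteps} count as failed and score the sentinel.
#' @return list: \code{fraction}, \code{width}, \code{score} (converged
#'   mean), \code{n}, \code{converged}, \code{seed}, \code{nKnown}
#' @export
subsetScore <- function(gold, fraction, width = 1, seed = 1L,
                        maxSamples = 10000L, relative = FALSE,
                        simControl = list()) {
  stopifnot(fraction >= 0, fraction <= 1, width >= 0)
  set.seed(as.integer(seed))
  pool <- gold@records
  nsel <- ceiling(fraction * nrow(pool))
  sel <- if (nsel > 0) sort(sample.int(nrow(pool), nsel)) else integer(0)
  sub <- pool[sel, , drop = FALSE]
  bal <- balanceNetwork(gold@network, sub, gold@config)
  engine <- .makeDrawEngine(gold, bal$posterior, bal$system)
  nb <- nrow(bal$system@basics)

  if (width == 0) {
    d <- engine(0, numeric(nb))
    traj <- .simulatePacked(gold, d$cm, d$conc, simControl)
    s <- if (is.null(traj)) 1e6 else
      mseScore(traj, gold@reference, relative = relative)
    return(list(fraction = fraction, width = width, score = s, n = 1L,
                converged = TRUE, seed = seed, nKnown = nsel))
  }

  state <- convergenceState(cap = maxSamples)
  good <- numeric(0)
  repeat {
    z <- stats::rnorm(nb)
    d <- engine(width, z)
    traj <- .simulatePacked(gold, d$cm, d$conc, simControl)
    s <- if (is.null(traj)) {
      if (length(good)) 1e6 * stats::median(good) else 1e6
    } else {
      sc <- mseScore(traj, gold@reference, relative = relative)
      good <- c(good, sc)
      sc
    }
    state <- updateConvergence(state, s)
    if (state$converged || state$capped) break
  }
  list(fraction = fraction, width = width, score = state$mean,
       n = state$n, converged = state$converged && !state$capped,
       seed = seed, nKnown = nsel)
}

#' Sweep the robustness protocol over fractions and widths
#'
#' Full factorial of [subsetScore()] over known-parameter fractions,
#' sampling widths and repetitions, with distinct per-cell seeds derived
#' from the master seed. Unconverged cells are retained but flagged, so
#' downstream summaries can keep only successfully converged subsets.
#'
#' @param gold a [GoldStandard-class]
#' @param fractions,widths numeric grids
#' @param repetitions outer repetitions per cell
#' @param seed master seed
#' @param maxSamples per-cell sample cap
#' @param relative use relative MSE
#' @param simControl solver settings passed to [subsetScore()]
#' @return data.frame with one row per (fraction, width, repetition)
#' @export
sweepRobustness <- function(gold, fractions, widths = 1,
                            repetitions = 20L, seed = 1L,
                            maxSamples = 10000L, relative = FALSE,
                            simControl = list()) {
  stopifnot(length(fractions) >= 1, length(widths) >= 1)
  rows <- list()
  idx <- 0L
  for (f in fractions) for (w in widths) for (rep in seq_len(repetitions)) {
    idx <- idx + 1L
    cellSeed <- as.integer((as.numeric(seed) + 7919 * idx) %% 2147483647)
    res <- subsetScore(gold, f, w, seed = cellSeed,
                       maxSamples = maxSamples, relative = relative,
                       simControl = simControl)
    rows[[idx]] <- data.frame(fraction = f, width = w, repetition = rep,
      seed = cellSeed, n_samples = res$n, converged = res$converged,
      score = res$score, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smallest sufficient known-parameter fraction
#'
#' Summarises a sweep at a single width: per fraction, the median score
#' over converged repetitions; returns the smallest fraction whose median
#' is within \code{factor} (default 2) of the full-information
#' (fraction 1) median -- the "how much do we need to know" headline of
#' the robustness analysis.
#'
#' @param scoreTable output of [sweepRobustness()]
#' @param factor allowed multiple of the full-information median error
#' @return list with \code{fraction} (smallest sufficient), and the
#'   per-fraction \code{medians}
#' @export
sufficientFraction <- function(scoreTable, factor = 2) {
  st <- scoreTable[scoreTable$converged, , drop = FALSE]
  if (!nrow(st)) stop("no converged cells in score table")
  meds <- stats::aggregate(score ~ fraction, data = st, FUN = stats::median)
  full <- meds$score[meds$fraction == max(meds$fraction)]
  if (!length(full)) stop("no converged full-information cells")
  ok <- meds$fraction[meds$score <= factor * full]
  list(fraction = min(ok), medians = meds)
}

#' Write a robustness score table as TSV
#' @param scoreTable output of [sweepRobustness()]
#' @param path output path
#' @export
writeScoreTable <- function(scoreTable, path) {
  utils::write.table(scoreTable, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
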