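## Translation of a network plus balanced parameters into common modular
## rate law fluxes and an ODE system dx/dt = S v(x, k), and its simulation.

## Reference (pure-R) evaluation of one reaction's rate law; returns the
## flux and its pieces. Used by buildRateLaw closures, the equilibrium
## check and the brute-force oracles; the compiled evaluator must agree.
.cmrlFluxR <- function(st, regs, p, conc, warnNegative = TRUE) {
  x <- conc[names(st)]
  if (any(x < 0)) {
    if (warnNegative)
      warning("negative concentration floored to 0 in rate-law evaluation")
    x <- pmax(x, 0)
  }
  h <- p$h
  kmAll <- p$kM
  s <- x / kmAll[names(st)]
  subs <- st < 0
  eSub <- h * abs(st[subs]); eProd <- h * st[!subs]
  fwd <- p$kcatf * prod(s[subs]^eSub)
  rev <- p$kcatr * prod(s[!subs]^eProd)
  denS <- prod((1 + s[subs])^eSub)
  denP <- prod((1 + s[!subs])^eProd)
  freg <- 1; dreg <- 0
  if (!is.null(regs) && nrow(regs)) {
    for (k in seq_len(nrow(regs))) {
      m <- regs$metabolite[k]
      xm <- max(conc[[m]], 0)
      r <- xm / p$kMreg[[m]]
      if (regs$mode[k] == "activator") {
        if (xm <= 0) { freg <- 0 } else {
          freg <- freg * r / (1 + r)
          dreg <- dreg + p$kMreg[[m]] / xm
        }
      } else {
        freg <- freg / (1 + r)
        dreg <- dreg + r
      }
    }
  }
  den <- denS + denP - 1 + dreg
  list(v = p$u * freg * (fwd - rev) / den,
       fwd = p$u * freg * fwd / den, rev = p$u * freg * rev / den,
       den = den, freg = freg)
}

.checkRateParams <- function(rid, st, regs, p) {
  bad <- function(what) stop("reaction ", rid, ": ", what)
  if (is.null(p$kcatf) || !is.finite(p$kcatf) || p$kcatf < 0)
    bad("missing or invalid kcat_forward")
  if (is.null(p$kcatr) || !is.finite(p$kcatr) || p$kcatr < 0)
    bad("missing or invalid kcat_reverse")
  if (p$kcatf == 0 && p$kcatr == 0) return(invisible()) # inert reaction
  need <- names(st)
  if (any(!need %in% names(p$kM)) || any(!is.finite(p$kM[need])))
    bad(paste("missing kM for", paste(setdiff(need, names(p$kM)),
                                      collapse = ", ")))
  if (any(p$kM[need] <= 0)) bad("non-positive kM")
  if (!is.null(regs) && nrow(regs)) {
    rneed <- regs$metabolite
    if (any(!rneed %in% names(p$kMreg)) ||
        any(!is.finite(p$kMreg[rneed])) || any(p$kMreg[rneed] <= 0))
      bad("missing or non-positive regulator kM")
  }
  if (is.null(p$u) || !is.finite(p$u) || p$u <= 0)
    bad("missing or non-positive enzyme concentration u")
  if (is.null(p$h) || p$h <= 0) bad("non-positive cooperativity h")
}

#' Build a rate-law closure for one reaction
#'
#' Returns the common modular rate law of the given reaction as a function
#' of a named concentration vector: saturable reversible Michaelis-Menten
#' numerator (forward minus reverse catalytic terms over the products of
#' scaled concentrations), saturation denominator, multiplied by the
#' enzyme concentration and the allosteric regulation factor f_reg, with
#' the specific regulation term D_reg added to the denominator. An
#' irreversible reaction is expressed by a zero reverse catalytic rate.
#' Cooperativity scales the exponents; at the default h = 1 the exponents
#' are the stoichiometric multiplicities.
#'
#' @param network a [MetabolicNetwork-class]
#' @param reactionId reaction id
#' @param params list with \code{kcatf}, \code{kcatr} (1/s), named
#'   \code{kM} (mM, participants), named \code{kMreg} (mM, regulators),
#'   \code{u} (mM), \code{h}
#' @return function(conc) -> flux (mmol/s); negative concentrations are
#'   floored to zero with a warning
#' @export
buildRateLaw <- function(network, reactionId, params) {
  st <- network@stoichiometry[[reactionId]]
  if (is.null(st)) stop("unknown reaction: ", reactionId)
  regs <- .regulators(network, reactionId)
  .checkRateParams(reactionId, st, regs, params)
  function(conc) .cmrlFluxR(st, regs, params, conc)$v
}

#' Extract per-reaction rate-law parameters from balanced output
#'
#' Takes balanced medians for kcat+/-, kM (participants and regulators)
#' and u; for irreversible reactions the reverse catalytic rate is fixed
#' to zero. Cooperativity comes from the network.
#'
#' @param balanced a [BalancedParameters-class]
#' @param network the corresponding [MetabolicNetwork-class]
#' @return named list (by reaction id) of parameter sets
#' @export
kineticParameters <- function(balanced, network) {
  out <- list()
  for (ri in seq_len(nrow(network@reactions))) {
    rid <- network@reactions$id[ri]
    st <- network@stoichiometry[[rid]]
    regs <- .regulators(network, rid)
    kM <- vapply(names(st), function(m)
      .medianOf(balanced, "kM", rid, m), 0)
    kMreg <- if (nrow(regs))
      vapply(unique(regs$metabolite), function(m)
        .medianOf(balanced, "kM", rid, m), 0) else numeric(0)
    out[[rid]] <- list(
      kcatf = .medianOf(balanced, "kcat_forward", rid),
      kcatr = if (network@reactions$reversible[ri])
        .medianOf(balanced, "kcat_reverse", rid) else 0,
      kM = kM, kMreg = kMreg,
      u = .medianOf(balanced, "u", rid),
      h = network@reactions$cooperativity[ri])
  }
  out
}

#' Assemble the ODE system of a network
#'
#' Builds a [KineticModel-class] from a complete per-reaction parameter
#' set (a [BalancedParameters-class], whose medians are used, or a named
#' list as produced by [kineticParameters()]). Boundary species are
#' excluded from the state and held at their fixed concentrations;
#' compartment volumes enter the right-hand side as
#' \eqn{dc_i/dt = (1/V_i) \sum_j n_{ij} v_j}, keeping cross-compartment
#' reactions mass-consistent. Non-integer stoichiometric coefficients are
#' accepted as real exponents in the rate law (a warning is logged).
#'
#' @param network a [MetabolicNetwork-class]
#' @param params [BalancedParameters-class] or named parameter list
#' @param boundaryConcentrations named vector of fixed concentrations for
#'   boundary species (default: network initial concentrations, falling
#'   back to balanced concentrations when \code{params} is balanced)
#' @return a [KineticModel-class]
#' @export
assembleOdeSystem <- function(network, params,
                              boundaryConcentrations = NULL) {
  if (is(params, "BalancedParameters")) {
    if (is.null(boundaryConcentrations)) {
      bc <- balancedConcentrations(params)
      boundaryConcentrations <-
        bc[network@metabolites$id[network@metabolites$boundary]]
    }
    params <- kineticParameters(params, network)
  }
  m <- network@metabolites
  stateIds <- m$id[!m$boundary]
  boundIds <- m$id[m$boundary]
  fullIds <- c(stateIds, boundIds)
  vol <- stats::setNames(network@compartments$volume,
                         network@compartments$id)
  mvol <- vol[m$compartment]; names(mvol) <- m$id

  if (is.null(boundaryConcentrations))
    boundaryConcentrations <- stats::setNames(
      m$initialConcentration[m$boundary], boundIds)
  bc <- boundaryConcentrations[boundIds]
  bc[!is.finite(bc)] <- 0
  names(bc) <- boundIds

  fracWarned <- FALSE
  pairRxn <- integer(); pairMet <- integer()
  pairCoef <- numeric(); pairKm <- numeric()
  regRxn <- integer(); regMet <- integer(); regMode <- integer()
  regKm <- numeric()
  sMet <- integer(); sRxn <- integer(); sCoef <- numeric()
  rxns <- network@reactions
  u <- kcatf <- kcatr <- h <- numeric(nrow(rxns))
  for (ri in seq_len(nrow(rxns))) {
    rid <- rxns$id[ri]
    p <- params[[rid]]
    if (is.null(p)) stop("missing rate-law parameters for reaction ", rid)
    st <- network@stoichiometry[[rid]]
    regs <- .regulators(network, rid)
    .checkRateParams(rid, st, regs, p)
    if (!fracWarned && any(abs(st - round(st)) > 1e-9)) {
      warning("non-integer stoichiometry treated as real exponents ",
              "(reaction ", rid, ")")
      fracWarned <- TRUE
    }
    u[ri] <- p$u; kcatf[ri] <- p$kcatf; kcatr[ri] <- p$kcatr
    h[ri] <- p$h
    for (met in names(st)) {
      pairRxn <- c(pairRxn, ri - 1L)
      pairMet <- c(pairMet, match(met, fullIds) - 1L)
      pairCoef <- c(pairCoef, st[[met]])
      pairKm <- c(pairKm, p$kM[[met]])
      si <- match(met, stateIds)
      if (!is.na(si)) {
        sMet <- c(sMet, si - 1L); sRxn <- c(sRxn, ri - 1L)
        sCoef <- c(sCoef, st[[met]] / mvol[[met]])
      }
    }
    if (nrow(regs)) for (k in seq_len(nrow(regs))) {
      met <- regs$metabolite[k]
      regRxn <- c(regRxn, ri - 1L)
      regMet <- c(regMet, match(met, fullIds) - 1L)
      regMode <- c(regMode, if (regs$mode[k] == "inhibitor") 1L else 0L)
      regKm <- c(regKm, p$kMreg[[met]])
    }
  }
  cmodel <- list(nState = length(stateIds), nBound = length(boundIds),
    nRxn = nrow(rxns), u = u, kcatf = kcatf, kcatr = kcatr, h = h,
    pairRxn = pairRxn, pairMet = pairMet, pairCoef = pairCoef,
    pairKm = pairKm, regRxn = regRxn, regMet = regMet, regMode = regMode,
    regKm = regKm, sMet = sMet, sRxn = sRxn, sCoef = sCoef,
    boundConc = as.numeric(bc))
  new("KineticModel", network = network, params = params,
      stateIds = stateIds, boundary = bc, cmodel = cmodel)
}

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel:", length(object@stateIds), "state species,",
      nrow(object@network@reactions), "reactions,",
      length(object@boundary), "boundary species\n")
})

.installModel <- function(model) {
  invisible(.Call(C_cmrl_set_model, model@cmodel))
}

#' Evaluate all reaction fluxes at a state
#'
#' @param model a [KineticModel-class]
#' @param conc named concentration vector over the state species (boundary
#'   species are taken from the model)
#' @return named flux vector (one entry per reaction)
#' @export
modelFluxes <- function(model, conc) {
  .installModel(model)
  v <- .Call(C_cmrl_flux, as.numeric(conc[model@stateIds]))
  stats::setNames(v, model@network@reactions$id)
}

#' Evaluate the ODE right-hand side at a state
#'
#' @param model a [KineticModel-class]
#' @param conc named state concentration vector
#' @return named derivative vector over state species
#' @export
modelRHS <- function(model, conc) {
  .installModel(model)
  d <- .Call(C_cmrl_rhs, as.numeric(conc[model@stateIds]))
  stats::setNames(d, model@stateIds)
}

#' Simulation schedule
#'
#' @param tEnd end time in seconds (default 400)
#' @param gridSize number of output points (default 401)
#' @param pulses data.frame with columns \code{time} (s, strictly inside
#'   (0, tEnd)), \code{metabolite}, \code{action} (\code{set}, \code{add}
#'   or \code{multiply}) and \code{amount} (mM, or a factor for
#'   \code{multiply})
#' @return schedule list
#' @export
simulationSchedule <- function(tEnd = 400, gridSize = 401, pulses = NULL) {
  if (is.null(pulses))
    pulses <- data.frame(time = numeric(), metabolite = character(),
                         action = character(), amount = numeric(),
                         stringsAsFactors = FALSE)
  stopifnot(gridSize >= 2, all(pulses$time > 0), all(pulses$time < tEnd),
            all(pulses$action %in% c("set", "add", "multiply")))
  list(tEnd = tEnd, gridSize = gridSize,
       pulses = pulses[order(pulses$time), , drop = FALSE])
}

#' Standard perturbation schedule
#'
#' The default experiment shape: a 400 s run with a multiplicative x10
#' pulse of one metabolite at 200 s.
#'
#' @param metabolite metabolite id to pulse
#' @param factor pulse factor (default 10)
#' @param tEnd,gridSize as in [simulationSchedule()]
#' @export
standardSchedule <- function(metabolite, factor = 10, tEnd = 400,
                             gridSize = 401) {
  simulationSchedule(tEnd = tEnd, gridSize = gridSize,
    pulses = data.frame(time = tEnd / 2, metabolite = metabolite,
                        action = "multiply", amount = factor,
                        stringsAsFactors = FALSE))
}

.applyPulse <- function(y, boundConc, pulse, stateIds, boundIds) {
  tgt <- pulse$metabolite
  mod <- function(v) switch(pulse$action,
    set = pulse$amount, add = v + pulse$amount,
    multiply = v * pulse$amount)
  if (tgt %in% stateIds) {
    y[tgt] <- mod(y[[tgt]])
  } else if (tgt %in% boundIds) {
    boundConc[tgt] <- mod(boundConc[[tgt]])
  } else stop("pulse target not in model: ", tgt)
  list(y = y, boundConc = boundConc)
}

#' Simulate a kinetic model
#'
#' Stiff-capable integration (lsoda, compiled right-hand side) of the
#' assembled ODE system on the schedule's output grid. Pulses are applied
#' as discontinuities: integration is restarted at each pulse time, and
#' the output row at a pulse time holds the post-pulse state. Boundary
#' species stay at their fixed concentrations (a pulse may also retarget
#' a boundary species).
#'
#' @param model a [KineticModel-class]
#' @param schedule a [simulationSchedule()]
#' @param initial named concentration vector; defaults to the network's
#'   initial concentrations. State species must be positive.
#' @param rtol,atol solver tolerances (defaults 1e-6, 1e-9 mM)
#' @param maxsteps maximum internal steps per output interval
#' @return list with \code{time}, \code{conc} (time x state matrix),
#'   \code{diagnostics}
#' @export
simulateModel <- function(model, schedule = simulationSchedule(),
                          initial = NULL, rtol = 1e-6, atol = 1e-9,
                          maxsteps = 10000) {
  m <- model@network@metabolites
  if (is.null(initial))
    initial <- stats::setNames(m$initialConcentration, m$id)
  y <- initial[model@stateIds]
  if (any(!is.finite(y)))
    stop("missing initial concentration for state species: ",
         paste(model@stateIds[!is.finite(y)], collapse = ", "))
  names(y) <- model@stateIds
  boundIds <- names(model@boundary)
  boundConc <- model@boundary
  if (any(boundIds %in% names(initial)))
    boundConc[intersect(boundIds, names(initial))] <-
      initial[intersect(boundIds, names(initial))]

  cm <- model@cmodel
  cm$boundConc <- as.numeric(boundConc)
  if (!all(is.finite(unlist(cm[c("u", "kcatf", "kcatr", "pairKm",
                                 "regKm", "boundConc")]))))
    stop("non-finite model parameters; cannot integrate")
  .Call(C_cmrl_set_model, cm)
  d0 <- .Call(C_cmrl_rhs, as.numeric(y))
  if (any(!is.finite(d0)))
    stop("right-hand side not finite at the initial state")

  times <- seq(0, schedule$tEnd, length.out = schedule$gridSize)
  pl <- schedule$pulses
  breaks <- unique(c(0, pl$time, schedule$tEnd))
  res <- matrix(NA_real_, length(times), length(y),
                dimnames = list(NULL, model@stateIds))
  diag <- list(steps = 0L, segments = length(breaks) - 1L)
  for (k in seq_len(length(breaks) - 1L)) {
    a <- breaks[k]; b <- breaks[k + 1L]
    segSel <- times >= a & (times < b | (b == schedule$tEnd & times <= b))
    segTimes <- unique(sort(c(a, times[segSel], b)))
    sol <- deSolve::ode(y = as.numeric(y), times = segTimes,
      func = "C_cmrl_derivs", dllname = "dynamet", initfunc = NULL,
      parms = NULL, method = "lsoda", rtol = rtol, atol = atol,
      maxsteps = maxsteps)
    istate <- attr(sol, "istate")
    if (is.null(istate) || istate[1L] != 2 || nrow(sol) < length(segTimes))
      stop("integration failed in segment [", a, ", ", b, "] near t = ",
           if (nrow(sol)) sol[nrow(sol), 1] else a,
           "; consider loosening rtol/atol or increasing maxsteps")
    rows <- match(times[segSel], sol[, 1])
    res[segSel, ] <- sol[rows, -1, drop = FALSE]
    yEnd <- sol[nrow(sol), -1]
    names(yEnd) <- model@stateIds
    y <- yEnd
    if (any(pl$time == b)) {
      for (pi in which(pl$time == b)) {
        up <- .applyPulse(y, boundConc, pl[pi, ], model@stateIds, boundIds)
        y <- up$y; boundConc <- up$boundConc
      }
      cm$boundConc <- as.numeric(boundConc)
      .Call(C_cmrl_set_model, cm)
      # output row at the pulse time holds the post-pulse state
      res[times == b, ] <- y
    }
  }
  if (any(!is.finite(res)))
    stop("non-finite concentrations in trajectory")
  if (any(res < -1e-8 * max(1, max(abs(res)))))
    diag$negativeFloor <- min(res)
  list(time = times, conc = res, diagnostics = diag)
}

#' Write a trajectory as CSV
#' @param trajectory output of [simulateModel()]
#' @param path output path
#' @export
writeTrajectory <- function(trajectory, path) {
  df <- data.frame(time = trajectory$time, trajectory$conc,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Flux residuals at thermodynamic equilibrium
#'
#' For every reversible reaction, constructs concentrations at which the
#' reaction affinity vanishes (each participant at
#' \eqn{c_i = \exp(-\mu^\circ_i / RT)}, so every chemical potential is
#' zero) and evaluates the relative net flux
#' \eqn{|v_f - v_r| / \max(v_f, v_r)} there. For a parameter set
#' satisfying the Haldane identity this vanishes to numerical precision.
#' Irreversible reactions are skipped.
#'
#' @param model a [KineticModel-class]
#' @param balanced the [BalancedParameters-class] the model was built from
#' @return named numeric vector of relative residuals (reversible
#'   reactions only)
#' @export
equilibriumFluxCheck <- function(model, balanced) {
  net <- model@network
  RT <- balanced@system@RT
  t <- balanced@table
  mu0 <- stats::setNames(t$mean[t$type == "mu0"],
                         t$metabolite[t$type == "mu0"])
  base <- balancedConcentrations(balanced)
  out <- numeric(0)
  for (ri in seq_len(nrow(net@reactions))) {
    if (!net@reactions$reversible[ri]) next
    rid <- net@reactions$id[ri]
    st <- net@stoichiometry[[rid]]
    conc <- base
    conc[names(st)] <- exp(-mu0[names(st)] / RT)
    f <- .cmrlFluxR(st, .regulators(net, rid), model@params[[rid]], conc,
                    warnNegative = FALSE)
    denom <- max(f$fwd, f$rev, .Machine$double.xmin)
    out[rid] <- abs(f$fwd - f$rev) / denom
  }
  out
}
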