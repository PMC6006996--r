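## Flux-based model reduction: FBA, flux variability analysis, iterative
## pruning of low-variability reactions, and compression of linear
## pathways into single effective reactions. Operates purely on the
## constraint-based view of the network.

## Bounded LP over fluxes: optimise c'v s.t. S_int v = 0, lb <= v <= ub,
## optional extra rows G v >= g. Shifted to non-negative variables
## w = v - lb with explicit slack/surplus columns and handed to the
## two-phase simplex.
.fluxLP <- function(network, objCoef, maximise = TRUE, extraG = NULL,
                    extrag = NULL, boundCap = 1000) {
  S <- stoichiometricMatrix(network)
  keep <- !attr(S, "boundary")
  Sint <- S[keep, , drop = FALSE]
  attr(Sint, "boundary") <- NULL
  r <- network@reactions
  lb <- pmax(r$lb, -boundCap); ub <- pmin(r$ub, boundCap)
  n <- nrow(r); m <- nrow(Sint)
  k <- if (is.null(extraG)) 0L else nrow(extraG)
  # columns: w (n), bound slacks (n), surplus for extra rows (k)
  A <- rbind(
    cbind(Sint, matrix(0, m, n + k)),
    cbind(diag(n), diag(n), matrix(0, n, k)),
    if (k) cbind(extraG, matrix(0, k, n), -diag(k)))
  b <- c(as.numeric(-Sint %*% lb), ub - lb,
         if (k) extrag - as.numeric(extraG %*% lb))
  res <- .simplexSolve(c(objCoef, numeric(n + k)), A, b,
                       maximise = maximise)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_, fluxes = NULL))
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", value = sum(objCoef * v),
       fluxes = stats::setNames(v, r$id))
}

#' Flux balance analysis optimum
#'
#' Maximises the objective reaction's flux subject to the steady-state
#' constraint S v = 0 over the internal (non-boundary) metabolites and the
#' flux bounds (defaulted/capped at +/-1000 mmol/s).
#'
#' @param network a [MetabolicNetwork-class]
#' @param objective objective reaction id (default: the network objective)
#' @return list with \code{status} (\code{"optimal"}/\code{"infeasible"}),
#'   \code{optimum} and the optimal \code{fluxes}
#' @export
fbaOptimum <- function(network, objective = objectiveReaction(network)) {
  if (!length(objective)) stop("no objective reaction set")
  r <- network@reactions
  if (!objective %in% r$id) stop("unknown objective reaction: ", objective)
  obj <- as.numeric(r$id == objective)
  res <- .fluxLP(network, obj, maximise = TRUE)
  if (res$status == "infeasible")
    stop("FBA infeasible for this network")
  if (res$status != "optimal")
    stop("FBA did not solve (unbounded or iteration limit)")
  list(status = res$status, optimum = res$value, fluxes = res$fluxes)
}

#' Flux variability analysis
#'
#' For each reaction, minimises and maximises its flux subject to the FBA
#' constraints plus the near-optimality requirement
#' \eqn{v_{obj} \ge fraction \cdot v_{obj}^{opt}}.
#'
#' @param network a [MetabolicNetwork-class]
#' @param objective objective reaction id
#' @param fraction required fraction of the FBA optimum (default 0.99)
#' @return data.frame with columns \code{reaction}, \code{min}, \code{max},
#'   \code{variability}
#' @export
fluxVariability <- function(network,
                            objective = objectiveReaction(network),
                            fraction = 0.99) {
  opt <- fbaOptimum(network, objective)$optimum
  r <- network@reactions
  G <- matrix(as.numeric(r$id == objective), nrow = 1)
  g <- fraction * opt
  mins <- maxs <- numeric(nrow(r))
  for (j in seq_len(nrow(r))) {
    cj <- as.numeric(seq_len(nrow(r)) == j)
    lo <- .fluxLP(network, cj, maximise = FALSE, extraG = G, extrag = g)
    hi <- .fluxLP(network, cj, maximise = TRUE, extraG = G, extrag = g)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem failed for reaction ", r$id[j],
           " (", lo$status, "/", hi$status, ")")
    mins[j] <- lo$value; maxs[j] <- hi$value
  }
  data.frame(reaction = r$id, min = mins, max = maxs,
             variability = maxs - mins, stringsAsFactors = FALSE)
}

#' Reduction specification
#'
#' @param objective objective reaction id
#' @param protectedReactions reaction ids never removed or lumped
#' @param protectedMetabolites metabolite ids never eliminated by
#'   compression
#' @param growthTolerance allowed relative loss of the objective optimum
#'   (default 0.01: growth within 1 percent of the full model)
#' @param fvaFraction near-optimality fraction for FVA (default 0.99)
#' @return spec list
#' @export
reductionSpec <- function(objective, protectedReactions = character(),
                          protectedMetabolites = character(),
                          growthTolerance = 0.01, fvaFraction = 0.99) {
  stopifnot(growthTolerance > 0, growthTolerance < 1)
  list(objective = objective,
       protectedReactions = unique(c(protectedReactions, objective)),
       protectedMetabolites = protectedMetabolites,
       growthTolerance = growthTolerance, fvaFraction = fvaFraction)
}

## drop reactions by id and clean orphan metabolites / dangling edges
.dropReactions <- function(network, rids) {
  r <- network@reactions
  keep <- !r$id %in% rids
  st <- network@stoichiometry[r$id[keep]]
  used <- unique(unlist(lapply(st, names)))
  m <- network@metabolites[network@metabolites$id %in% used, , drop = FALSE]
  reg <- network@regulation
  reg <- reg[reg$reaction %in% r$id[keep] & reg$metabolite %in% m$id, ,
             drop = FALSE]
  MetabolicNetwork(metabolites = m, reactions = r[keep, , drop = FALSE],
    stoichiometry = st, compartments = network@compartments,
    regulation = reg,
    xrefsMet = network@xrefsMet[names(network@xrefsMet) %in% m$id],
    xrefsRxn = network@xrefsRxn[names(network@xrefsRxn) %in% r$id[keep]],
    objective = network@objective)
}

.carriesFlux <- function(network, spec, optimum) {
  prot <- setdiff(spec$protectedReactions, spec$objective)
  prot <- intersect(prot, network@reactions$id)
  if (!length(prot)) return(TRUE)
  r <- network@reactions
  G <- matrix(as.numeric(r$id == spec$objective), nrow = 1)
  g <- (1 - spec$growthTolerance) * optimum
  for (p in prot) {
    cj <- as.numeric(r$id == p)
    hi <- .fluxLP(network, cj, maximise = TRUE, extraG = G, extrag = g)
    lo <- .fluxLP(network, cj, maximise = FALSE, extraG = G, extrag = g)
    ok <- (hi$status == "optimal" && hi$value > 1e-9) ||
          (lo$status == "optimal" && lo$value < -1e-9)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Prune low-variability reactions
#'
#' Iteratively removes the unprotected reaction with the smallest flux
#' variability (ties broken lexicographically by reaction id), keeping a
#' removal only when the reduced network's FBA optimum stays within the
#' growth tolerance of the full model's and protected reactions can still
#' carry flux; otherwise the reaction is marked unremovable. Stops when
#' every remaining reaction is protected or unremovable. Orphaned
#' metabolites are dropped.
#'
#' @param network a [MetabolicNetwork-class] (must be FBA-feasible)
#' @param spec a [reductionSpec()]
#' @return list with the reduced \code{network} and a removal \code{log}
#'   data.frame (\code{step}, \code{reaction}, \code{variability},
#'   \code{action}, \code{optimum})
#' @export
pruneNetwork <- function(network, spec) {
  fullOpt <- fbaOptimum(network, spec$objective)$optimum
  floorOpt <- (1 - spec$growthTolerance) * fullOpt
  unremovable <- character()
  log <- list()
  step <- 0L
  repeat {
    fva <- fluxVariability(network, spec$objective, spec$fvaFraction)
    cand <- fva[!(fva$reaction %in% spec$protectedReactions) &
                !(fva$reaction %in% unremovable), , drop = FALSE]
    if (!nrow(cand)) break
    cand <- cand[order(cand$variability, cand$reaction), , drop = FALSE]
    rid <- cand$reaction[1L]
    step <- step + 1L
    trial <- .dropReactions(network, rid)
    opt <- tryCatch(fbaOptimum(trial, spec$objective)$optimum,
                    error = function(e) -Inf)
    ok <- is.finite(opt) && opt >= floorOpt - 1e-9 &&
          .carriesFlux(trial, spec, opt)
    if (ok) {
      network <- trial
      log[[step]] <- data.frame(step = step, reaction = rid,
        variability = cand$variability[1L], action = "removed",
        optimum = opt, stringsAsFactors = FALSE)
    } else {
      unremovable <- c(unremovable, rid)
      log[[step]] <- data.frame(step = step, reaction = rid,
        variability = cand$variability[1L], action = "unremovable",
        optimum = if (is.finite(opt)) opt else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(network = network,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(step = integer(), reaction = character(),
                    variability = numeric(), action = character(),
                    optimum = numeric(), stringsAsFactors = FALSE))
}

#' Compress linear pathways
#'
#' Eliminates every internal, unprotected metabolite that occurs in
#' exactly two reactions -- one producing it (coefficient +p), one
#' consuming it (coefficient -q) -- by replacing the pair with the lumped
#' reaction q R1 + p R2 (the intermediate cancels; at steady state the two
#' fluxes are coupled as q v1 = p v2 prescribes). Applied iteratively, so
#' maximal chains collapse into single effective reactions whose ids
#' concatenate the members'. Lumped reactions are marked synthetic: the
#' parameter search skips them, since no database carries parameters for
#' an artificial composite reaction. The objective and protected reactions
#' are never lumped.
#'
#' @param network a [MetabolicNetwork-class]
#' @param spec a [reductionSpec()]
#' @return list with the compressed \code{network} and a lumping
#'   \code{log} data.frame (\code{metabolite}, \code{producer},
#'   \code{consumer}, \code{lumped})
#' @export
compressNetwork <- function(network, spec) {
  log <- list()
  repeat {
    m <- network@metabolites
    done <- TRUE
    for (mid in m$id[!m$boundary]) {
      if (mid %in% spec$protectedMetabolites) next
      touch <- names(Filter(function(st) mid %in% names(st),
                            network@stoichiometry))
      if (length(touch) != 2L) next
      c1 <- network@stoichiometry[[touch[1L]]][[mid]]
      c2 <- network@stoichiometry[[touch[2L]]][[mid]]
      if (c1 * c2 >= 0) next
      prod1 <- if (c1 > 0) touch[1L] else touch[2L]
      cons <- setdiff(touch, prod1)
      if (any(touch %in% spec$protectedReactions)) next
      p <- network@stoichiometry[[prod1]][[mid]]
      q <- -network@stoichiometry[[cons]][[mid]]
      stP <- network@stoichiometry[[prod1]]; stC <- network@stoichiometry[[cons]]
      mets <- union(names(stP), names(stC))
      lump <- stats::setNames(numeric(length(mets)), mets)
      lump[names(stP)] <- lump[names(stP)] + q * stP
      lump[names(stC)] <- lump[names(stC)] + p * stC
      lump <- lump[abs(lump) > 1e-12]
      if (!length(lump)) next
      r <- network@reactions
      iP <- match(prod1, r$id); iC <- match(cons, r$id)
      newId <- paste(prod1, cons, sep = "__")
      rev <- r$reversible[iP] && r$reversible[iC]
      lb <- max(r$lb[iP] / q, r$lb[iC] / p)
      ub <- min(r$ub[iP] / q, r$ub[iC] / p)
      newRow <- data.frame(id = newId,
        name = paste(r$name[iP], r$name[iC], sep = " + "),
        reversible = rev, enzymeConcentration = 0.01, cooperativity = 1,
        lb = if (rev) lb else max(0, lb), ub = ub, synthetic = TRUE,
        stringsAsFactors = FALSE)
      keep <- !r$id %in% touch
      reactions <- rbind(r[keep, , drop = FALSE], newRow)
      st <- network@stoichiometry[r$id[keep]]
      st[[newId]] <- lump
      used <- unique(unlist(lapply(st, names)))
      mets2 <- m[m$id %in% used, , drop = FALSE]
      reg <- network@regulation
      reg$reaction[reg$reaction %in% touch] <- newId
      reg <- reg[reg$metabolite %in% mets2$id, , drop = FALSE]
      reg <- unique(reg)
      network <- MetabolicNetwork(metabolites = mets2,
        reactions = reactions, stoichiometry = st,
        compartments = network@compartments, regulation = reg,
        xrefsMet = network@xrefsMet[names(network@xrefsMet) %in% mets2$id],
        xrefsRxn = network@xrefsRxn[names(network@xrefsRxn) %in%
                                    reactions$id],
        objective = network@objective)
      log[[length(log) + 1L]] <- data.frame(metabolite = mid,
        producer = prod1, consumer = cons, lumped = newId,
        stringsAsFactors = FALSE)
      done <- FALSE
      break
    }
    if (done) break
  }
  list(network = network,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(metabolite = character(), producer = character(),
                    consumer = character(), lumped = character(),
                    stringsAsFactors = FALSE))
}

#' Write a reduction log as TSV
#' @param log a removal or lumping log data.frame
#' @param path output path
#' @export
writeReductionLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
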