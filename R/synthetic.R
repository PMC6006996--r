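## Random mass-balanced test networks, ground-truth parameter sets and
## matching offline fixture databases, so the full pipeline is exercisable
## without any external resource.

#' Specification for a random network
#'
#' @param nMetabolites,nReactions network size (internal reactions;
#'   exchange reactions are added on top). At least half as many reactions
#'   as metabolites are required so every metabolite can participate.
#' @param maxSubstrates,maxProducts per-reaction participant caps
#'   (default 2)
#' @param pReversible probability a reaction is reversible (default 0.8)
#' @param pRegulation probability of a regulation edge per
#'   (metabolite, reaction) pair (default 0.05)
#' @param nCompartments number of unit-volume compartments filled
#'   round-robin (default 1)
#' @param nExchange number of one-sided exchange reactions (default 2,
#'   minimum 2 so flux balance has an open boundary)
#' @param maxCoef maximum stoichiometric coefficient (default 1; larger
#'   values make the rate-law exponents steeper)
#' @param seed integer seed; the generated network is a deterministic
#'   function of the spec
#' @return spec list
#' @export
networkSpec <- function(nMetabolites, nReactions, maxSubstrates = 2,
                        maxProducts = 2, pReversible = 0.8,
                        pRegulation = 0.05, nCompartments = 1,
                        nExchange = 2, maxCoef = 1, seed = 1L) {
  if (nReactions < nMetabolites / 2)
    stop("need at least nMetabolites/2 reactions to cover all metabolites")
  stopifnot(pReversible >= 0, pReversible <= 1, pRegulation >= 0,
            pRegulation <= 1, nExchange >= 2, maxCoef >= 1)
  list(nMetabolites = nMetabolites, nReactions = nReactions,
       maxSubstrates = maxSubstrates, maxProducts = maxProducts,
       pReversible = pReversible, pRegulation = pRegulation,
       nCompartments = nCompartments, nExchange = nExchange,
       maxCoef = maxCoef, seed = as.integer(seed))
}

#' Generate a random mass-balanced network
#'
#' Deterministic (seeded) generator: metabolites are assigned to
#' compartments round-robin; a spanning set of two-metabolite reactions
#' guarantees every metabolite participates; remaining reactions connect
#' disjoint random substrate/product sets; one-sided reversible exchange
#' reactions open the boundary; a repair step adds exchange reactions
#' until every metabolite has both a producer and a consumer (possibly
#' exceeding the requested reaction count); regulation edges are added
#' independently per (metabolite, reaction) pair. The first exchange
#' reaction is set as the objective for constraint-based operations.
#'
#' @param spec a [networkSpec()]
#' @return a [MetabolicNetwork-class]
#' @export
randomNetwork <- function(spec) {
  set.seed(spec$seed)
  n <- spec$nMetabolites
  mets <- sprintf("M%02d", seq_len(n))
  comps <- sprintf("comp%d", seq_len(spec$nCompartments))
  mdf <- data.frame(id = mets, name = paste("metabolite", mets),
    compartment = rep(comps, length.out = n),
    initialConcentration = NA_real_, boundary = FALSE,
    stringsAsFactors = FALSE)
  cdf <- data.frame(id = comps, volume = rep(1, length(comps)),
                    stringsAsFactors = FALSE)

  stoich <- list(); rrows <- list()
  addRxn <- function(id, st, reversible) {
    stoich[[id]] <<- st
    rrows[[length(rrows) + 1L]] <<- data.frame(id = id,
      name = paste("reaction", id), reversible = reversible,
      enzymeConcentration = 0.01, cooperativity = 1,
      lb = if (reversible) -1000 else 0, ub = 1000, synthetic = FALSE,
      stringsAsFactors = FALSE)
  }
  coef <- function() if (spec$maxCoef == 1) 1 else
    sample(seq_len(spec$maxCoef), 1L)

  # (b) spanning structure: consecutive pairs of a shuffled ordering
  perm <- sample(mets)
  k <- ceiling(n / 2)
  for (i in seq_len(k)) {
    a <- perm[2 * i - 1L]
    b <- if (2 * i <= n) perm[2 * i] else perm[1L]
    if (a == b) b <- perm[(2 * i) %% n + 1L]
    addRxn(sprintf("R%02d", i),
           stats::setNames(c(-coef(), coef()), c(a, b)),
           stats::runif(1) < spec$pReversible)
  }
  # (c) remaining reactions: random disjoint substrate/product sets
  for (i in seq(k + 1L, length.out = max(0L, spec$nReactions - k))) {
    ns <- sample(seq_len(spec$maxSubstrates), 1L)
    np <- sample(seq_len(spec$maxProducts), 1L)
    pick <- sample(mets, ns + np)
    st <- stats::setNames(c(-vapply(seq_len(ns), function(z) coef(), 0),
                            vapply(seq_len(np), function(z) coef(), 0)),
                          pick)
    addRxn(sprintf("R%02d", i), st, stats::runif(1) < spec$pReversible)
  }
  # (d) exchange reactions: one-sided, reversible (external pool implied)
  exMets <- sample(mets, min(spec$nExchange, n))
  for (m in exMets)
    addRxn(paste0("EX_", m), stats::setNames(-1, m), TRUE)
  # (e) repair: every metabolite needs a producer and a consumer; an
  # exchange reaction provides both (it can run either way)
  hasEx <- exMets
  repeat {
    prodOf <- consOf <- stats::setNames(logical(n), mets)
    for (id in names(stoich)) {
      st <- stoich[[id]]
      rev <- rrows[[match(id, vapply(rrows, function(r) r$id, ""))]]$reversible
      ex <- length(st) == 1L
      for (m in names(st)) {
        if (st[[m]] > 0 || rev || ex) prodOf[m] <- TRUE
        if (st[[m]] < 0 || rev || ex) consOf[m] <- TRUE
      }
    }
    lacking <- mets[!(prodOf & consOf)]
    lacking <- setdiff(lacking, hasEx)
    if (!length(lacking)) break
    m <- lacking[1L]
    addRxn(paste0("EX_", m), stats::setNames(-1, m), TRUE)
    hasEx <- c(hasEx, m)
  }
  rdf <- do.call(rbind, rrows)
  # (f) regulation edges; regulators must not participate in the reaction
  reg <- .emptyRegulation()
  if (spec$pRegulation > 0) {
    for (rid in rdf$id) {
      for (m in setdiff(mets, names(stoich[[rid]]))) {
        if (stats::runif(1) < spec$pRegulation)
          reg <- rbind(reg, data.frame(metabolite = m,
            mode = sample(c("activator", "inhibitor"), 1L),
            reaction = rid, stringsAsFactors = FALSE))
      }
    }
  }
  MetabolicNetwork(metabolites = mdf, reactions = rdf,
    stoichiometry = stoich, compartments = cdf, regulation = reg,
    objective = paste0("EX_", exMets[1L]))
}

## realistic generator spreads: reaction standard free energies of a few
## kJ/mol and roughly half-order-of-magnitude parameter scatter
.truthPriors <- function() list(
  mu0 = c(0, 10),            # kJ/mol, linear
  kM = c(0.1, log(10) / 2),  # mM
  kV = c(10, log(10) / 2),   # 1/s
  u = c(0.01, log(10) / 2),  # mM
  c = c(0.1, log(10) / 2))   # mM

#' Draw a complete ground-truth parameter set
#'
#' Draws one value for every basic quantity of the network (mu0, kM, kV,
#' u, c) from the generator's truth distributions and emits one parameter
#' record per basic quantity: kM, u, c and mu0 records directly, and one
#' kcat_forward record per reaction carrying the value derived through
#' the dependency rows (which pins kV). Because all catalytic and
#' equilibrium quantities descend from the same basic draw, the implied
#' keq/kcat set satisfies the Haldane and Wegscheider identities exactly.
#' Records carry the low uncertainty (log-std ln 1.1) used when they are
#' re-injected as "known" measurements.
#'
#' @param network a [MetabolicNetwork-class]
#' @param seed integer seed
#' @param config a [balancingConfig()] (fixes RT)
#' @param priors optional override of the truth distributions (named list
#'   of \code{c(median-or-mean, spread)})
#' @return data.frame of parameter records; the raw basic draw is
#'   attached as attribute \code{"draw"}
#' @export
drawTrueParameters <- function(network, seed = 1L,
                               config = balancingConfig(),
                               priors = NULL) {
  tp <- .truthPriors()
  for (nm in names(priors)) tp[[nm]] <- priors[[nm]]
  system <- buildQuantitySystem(network, config)
  b <- system@basics
  set.seed(as.integer(seed))
  q <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    p <- switch(b$type[i], mu0 = tp$mu0, lnkM = tp$kM, lnkV = tp$kV,
                lnu = tp$u, lnc = tp$c)
    q[i] <- if (b$scale[i] == "log")
      stats::rnorm(1, log(p[1]), p[2]) else stats::rnorm(1, p[1], p[2])
  }
  tight <- log(1.1)
  recs <- list()
  for (i in seq_len(nrow(b))) {
    qt <- switch(b$type[i], mu0 = "mu0", lnkM = "kM", lnu = "u",
                 lnc = "c", lnkV = NA_character_)
    if (is.na(qt)) next
    recs[[length(recs) + 1L]] <- parameterRecord(qt,
      value = if (b$scale[i] == "log") exp(q[i]) else q[i],
      reaction = b$reaction[i], metabolite = b$metabolite[i],
      logSd = tight, source = "truth")
  }
  for (r in network@reactions$id) {
    i <- .depIndex(system, "lnkcatf", r, NA_character_)
    recs[[length(recs) + 1L]] <- parameterRecord("kcat_forward",
      value = exp(drop(system@D[i, ] %*% q)), reaction = r,
      logSd = tight, source = "truth")
  }
  out <- .bindRecords(recs)
  attr(out, "draw") <- q
  out
}

#' Generate offline fixture databases for a network
#'
#' Writes a fixture directory that lets the exhaustive search recover a
#' controlled fraction of a ground-truth record set through genuine
#' multi-hop identifier translation. Two translation adapters map display
#' names into a first and then a second synthetic namespace
#' (\code{name -> dbA -> dbB}); quantity adapters (\code{db0}, \code{db1},
#' ...) hold the planted values keyed by the second namespace, so every
#' lookup requires at least two translation hops. A uniformly random
#' \code{coverage} fraction of the truth records is planted (round-robin
#' across quantity adapters) with multiplicative lognormal noise of the
#' given log-std (additive Gaussian, in kJ/mol, for chemical potentials).
#' The bookkeeping table \code{planted.tsv} in the root lists every
#' planted record for oracle checks.
#'
#' @param network a [MetabolicNetwork-class]
#' @param truth record data.frame from [drawTrueParameters()]
#' @param dir output directory (created)
#' @param coverage fraction of truth records to plant, in [0, 1]
#' @param noiseLogSd log-scale noise on planted values (0 = exact)
#' @param seed integer seed
#' @param nAdapters number of quantity-bearing adapters (default 2)
#' @return invisibly, a list with the planted record table and the
#'   adapter names (translators first)
#' @export
makeFixtureDatabases <- function(network, truth, dir, coverage = 1,
                                 noiseLogSd = 0, seed = 1L,
                                 nAdapters = 2L) {
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  set.seed(as.integer(seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  subjId <- ifelse(is.na(truth$reaction), truth$metabolite, truth$reaction)
  subjName <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (!is.na(truth$reaction[i]))
      subjName[i] <- network@reactions$name[
        network@reactions$id == truth$reaction[i]]
    else
      subjName[i] <- network@metabolites$name[
        network@metabolites$id == truth$metabolite[i]]
  }
  allIds <- unique(data.frame(id = subjId, name = subjName,
                              stringsAsFactors = FALSE))
  trA <- data.frame(from_namespace = "name", from_id = allIds$name,
    to_namespace = "dbA", to_id = paste0("dbA:", allIds$id),
    stringsAsFactors = FALSE)
  trB <- data.frame(from_namespace = "dbA",
    from_id = paste0("dbA:", allIds$id), to_namespace = "dbB",
    to_id = paste0("dbB:", allIds$id), stringsAsFactors = FALSE)

  nPlant <- round(coverage * nrow(truth))
  sel <- sort(sample.int(nrow(truth), nPlant))
  qnames <- sprintf("db%d", seq_len(nAdapters) - 1L)
  planted <- list()
  qtabs <- stats::setNames(vector("list", nAdapters), qnames)
  for (k in seq_along(sel)) {
    i <- sel[k]
    ad <- qnames[(k - 1L) %% nAdapters + 1L]
    v <- truth$value[i]
    noisy <- if (truth$quantityType[i] == "mu0")
      v + stats::rnorm(1, 0, noiseLogSd) else
      v * exp(stats::rnorm(1, 0, noiseLogSd))
    qtabs[[ad]] <- rbind(qtabs[[ad]], data.frame(namespace = "dbB",
      id = paste0("dbB:", subjId[i]), quantity_type = truth$quantityType[i],
      value = noisy, unit = .unitFor(truth$quantityType[i]),
      compound = ifelse(truth$quantityType[i] == "kM",
                        truth$metabolite[i], NA_character_),
      ph = NA_real_, temperature_k = NA_real_, organism = "synthetic",
      reference = "fixture", stringsAsFactors = FALSE))
    planted[[k]] <- data.frame(QuantityType = truth$quantityType[i],
      ReactionID = truth$reaction[i], CompoundID = truth$metabolite[i],
      TrueValue = v, PlantedValue = noisy, Adapter = ad,
      stringsAsFactors = FALSE)
  }
  wr <- function(ad, file, df) {
    d <- file.path(dir, ad)
    dir.create(d, showWarnings = FALSE)
    utils::write.table(df, file.path(d, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wr("xlatA", "translations.tsv", trA)
  wr("xlatB", "translations.tsv", trB)
  for (ad in qnames)
    wr(ad, "quantities.tsv", if (is.null(qtabs[[ad]]))
      data.frame(namespace = character(), id = character(),
        quantity_type = character(), value = numeric(), unit = character(),
        compound = character(), ph = numeric(), temperature_k = numeric(),
        organism = character(), reference = character(),
        stringsAsFactors = FALSE) else qtabs[[ad]])
  plantedTab <- if (length(planted)) do.call(rbind, planted) else
    data.frame(QuantityType = character(), ReactionID = character(),
               CompoundID = character(), TrueValue = numeric(),
               PlantedValue = numeric(), Adapter = character(),
               stringsAsFactors = FALSE)
  utils::write.table(plantedTab, file.path(dir, "planted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(list(planted = plantedTab,
                 adapters = c("xlatA", "xlatB", qnames)))
}

#' Registry over a fixture database directory
#'
#' Registers every adapter sub-directory of a fixture database root.
#'
#' @param dir fixture root directory
#' @return an [AdapterRegistry-class]
#' @export
fixtureRegistry <- function(dir) {
  reg <- newAdapterRegistry()
  for (ad in sort(list.dirs(dir, recursive = FALSE, full.names = FALSE)))
    reg <- registerAdapter(reg, fixtureAdapter(ad, dir))
  reg
}
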