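## Thermodynamically consistent Bayesian estimation of kinetic quantities
## (parameter balancing). All kinetic quantities are linear functions of a
## basic vector (mu0, ln kM, ln kV, ln u, ln c); the dependency rows encode
## the Haldane relationships, so every balanced output and every posterior
## draw is thermodynamically consistent by construction.

#' Balancing configuration
#'
#' Physical constants, temperature and the pseudo-prior table used when a
#' quantity has no measurement. Pseudo-prior medians/spreads are
#' implementation defaults, configurable per quantity type. The table also
#' carries pseudo-priors for the dependent quantities keq and kcat: these
#' are applied as soft pseudo-measurement rows by [balanceNetwork()]
#' (see [pseudoMeasurementRecords()]), keeping otherwise unconstrained
#' chemical-potential differences in a physically plausible range.
#'
#' @param temperature temperature in Kelvin (default 300)
#' @param R gas constant, J/mol/K
#' @param defaultLogSd measurement noise (log scale) used when a record
#'   carries none
#' @param pseudo named list overriding pseudo-prior entries; each entry is
#'   \code{c(median, logSd)} (for \code{mu0}: \code{c(mean, sd)} on the
#'   linear kJ/mol scale)
#' @return a config list
#' @export
balancingConfig <- function(temperature = 300, R = 8.314,
                            defaultLogSd = log(2), pseudo = list()) {
  pp <- list(
    kM   = c(0.1, log(10)),
    kV   = c(10, log(10)),
    u    = c(0.01, log(10)),
    c    = c(0.1, log(10)),
    mu0  = c(0, 500),
    keq  = c(1, log(10)),
    kcat = c(10, log(10)))
  for (nm in names(pseudo)) pp[[nm]] <- pseudo[[nm]]
  for (nm in names(pp)) if (pp[[nm]][2] <= 0)
    stop("pseudo-prior std must be > 0 for ", nm)
  if (temperature <= 0) stop("temperature must be > 0")
  list(R = R, T = temperature, RT = R * temperature / 1000,
       defaultLogSd = defaultLogSd, pseudo = pp)
}

## key helpers for locating entries of the basic / dependent index
.qkey <- function(type, reaction, metabolite)
  paste(type, reaction, metabolite, sep = "\r")

#' Build the quantity system of a network
#'
#' Constructs the basic-quantity index (mu0 per metabolite; ln kM per
#' reaction participant and per regulator; ln kV and ln u per reaction;
#' ln c per metabolite) and the dependency rows expressing
#' \eqn{\ln k^{eq}_j = -(1/RT)\sum_i n_{ij}\mu^\circ_i},
#' \eqn{\ln k^{cat\pm}_j = \ln k^V_j \mp (h_j/2)\sum_i n_{ij}(\mu^\circ_i/RT
#' + \ln k^M_{ji})} (sum over participants),
#' \eqn{\ln v^{max\pm}_j = \ln u_j + \ln k^{cat\pm}_j},
#' \eqn{\mu_i = \mu^\circ_i + RT \ln c_i} and
#' \eqn{R^A_j = -\sum_i n_{ij}\mu_i}, with RT in kJ/mol. The cooperativity
#' h_j is a fixed per-reaction constant, not a balanced quantity.
#'
#' @param network a [MetabolicNetwork-class]
#' @param config a [balancingConfig()]
#' @return a [QuantitySystem-class]
#' @export
buildQuantitySystem <- function(network, config = balancingConfig()) {
  RT <- config$RT
  mets <- network@metabolites$id
  rxns <- network@reactions$id
  hs <- stats::setNames(network@reactions$cooperativity, rxns)

  rows <- list()
  addB <- function(type, rxn, met, scale)
    rows[[length(rows) + 1L]] <<- data.frame(type = type, reaction = rxn,
      metabolite = met, scale = scale, stringsAsFactors = FALSE)
  for (m in mets) addB("mu0", NA_character_, m, "linear")
  for (r in rxns) {
    st <- network@stoichiometry[[r]]
    if (!length(st)) stop("reaction with no participants: ", r)
    pair <- names(st)
    regs <- .regulators(network, r)$metabolite
    for (m in unique(c(pair, regs))) addB("lnkM", r, m, "log")
  }
  for (r in rxns) addB("lnkV", r, NA_character_, "log")
  for (r in rxns) addB("lnu", r, NA_character_, "log")
  for (m in mets) addB("lnc", NA_character_, m, "log")
  basics <- do.call(rbind, rows)
  bkey <- .qkey(basics$type, basics$reaction, basics$metabolite)
  nb <- nrow(basics)
  bi <- function(type, rxn = NA_character_, met = NA_character_) {
    i <- match(.qkey(type, rxn, met), bkey)
    if (is.na(i)) stop("no basic quantity ", type, " ", rxn, " ", met)
    i
  }

  drows <- list(); dmeta <- list()
  addD <- function(type, rxn, met, scale, row) {
    drows[[length(drows) + 1L]] <<- row
    dmeta[[length(dmeta) + 1L]] <<- data.frame(type = type, reaction = rxn,
      metabolite = met, scale = scale, stringsAsFactors = FALSE)
  }
  zero <- numeric(nb)
  for (r in rxns) {
    st <- network@stoichiometry[[r]]
    h <- hs[[r]]
    keq <- zero
    for (m in names(st)) keq[bi("mu0", met = m)] <- -st[[m]] / RT
    addD("lnkeq", r, NA_character_, "log", keq)
    half <- zero
    for (m in names(st)) {
      half[bi("mu0", met = m)] <- half[bi("mu0", met = m)] + st[[m]] / RT
      half[bi("lnkM", r, m)] <- half[bi("lnkM", r, m)] + st[[m]]
    }
    kcatf <- zero; kcatf[bi("lnkV", r)] <- 1
    kcatf <- kcatf - (h / 2) * half
    kcatr <- zero; kcatr[bi("lnkV", r)] <- 1
    kcatr <- kcatr + (h / 2) * half
    addD("lnkcatf", r, NA_character_, "log", kcatf)
    addD("lnkcatr", r, NA_character_, "log", kcatr)
    vmf <- kcatf; vmf[bi("lnu", r)] <- vmf[bi("lnu", r)] + 1
    vmr <- kcatr; vmr[bi("lnu", r)] <- vmr[bi("lnu", r)] + 1
    addD("lnvmaxf", r, NA_character_, "log", vmf)
    addD("lnvmaxr", r, NA_character_, "log", vmr)
  }
  for (m in mets) {
    mu <- zero
    mu[bi("mu0", met = m)] <- 1
    mu[bi("lnc", met = m)] <- RT
    addD("mu", NA_character_, m, "linear", mu)
  }
  for (r in rxns) {
    st <- network@stoichiometry[[r]]
    ra <- zero
    for (m in names(st)) {
      ra[bi("mu0", met = m)] <- ra[bi("mu0", met = m)] - st[[m]]
      ra[bi("lnc", met = m)] <- ra[bi("lnc", met = m)] - st[[m]] * RT
    }
    addD("RA", r, NA_character_, "linear", ra)
  }
  D <- do.call(rbind, drows)
  dependent <- do.call(rbind, dmeta)
  rownames(D) <- .qkey(dependent$type, dependent$reaction,
                       dependent$metabolite)
  new("QuantitySystem", basics = basics, dependent = dependent, D = D,
      RT = RT, network = network)
}

setMethod("show", "QuantitySystem", function(object) {
  cat("QuantitySystem:", nrow(object@basics), "basic quantities,",
      nrow(object@dependent), "dependency rows, RT =",
      signif(object@RT, 6), "kJ/mol\n")
  print(table(object@basics$type))
})

## locate basic indices for vectors of (type, reaction, metabolite)
.basicIndex <- function(system, type, reaction, metabolite) {
  bkey <- .qkey(system@basics$type, system@basics$reaction,
                system@basics$metabolite)
  match(.qkey(type, reaction, metabolite), bkey)
}

.depIndex <- function(system, type, reaction, metabolite) {
  dkey <- .qkey(system@dependent$type, system@dependent$reaction,
                system@dependent$metabolite)
  match(.qkey(type, reaction, metabolite), dkey)
}

#' Assemble the Gaussian prior over the basic quantities
#'
#' Every basic quantity receives its pseudo-prior: the median is mapped to
#' the mean on the quantity's scale (log of the median for multiplicative
#' quantities; the stated mean for mu0) with the configured spread. The
#' prior covariance is diagonal. Optionally, records for basic quantities
#' can override individual pseudo-prior entries (mean from the measured
#' value, spread from the record's log-std).
#'
#' @param system a [QuantitySystem-class]
#' @param config a [balancingConfig()]
#' @param records optional data.frame of basic-quantity records
#'   (\code{kM}, \code{c}, \code{u}, \code{mu0}) used as priors
#' @return a [GaussianBelief-class] prior
#' @export
assemblePriors <- function(system, config = balancingConfig(),
                           records = NULL) {
  b <- system@basics
  pp <- config$pseudo
  mean <- numeric(nrow(b)); sd <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    p <- switch(b$type[i], mu0 = pp$mu0, lnkM = pp$kM, lnkV = pp$kV,
                lnu = pp$u, lnc = pp$c)
    if (b$scale[i] == "log") { mean[i] <- log(p[1]); sd[i] <- p[2] }
    else { mean[i] <- p[1]; sd[i] <- p[2] }
  }
  if (!is.null(records) && nrow(records)) {
    typeMap <- c(kM = "lnkM", c = "lnc", u = "lnu", mu0 = "mu0")
    for (k in seq_len(nrow(records))) {
      bt <- typeMap[records$quantityType[k]]
      if (is.na(bt)) next
      i <- .basicIndex(system, bt,
        if (bt %in% c("lnkM", "lnu")) records$reaction[k] else NA_character_,
        if (bt %in% c("lnkM", "lnc", "mu0")) records$metabolite[k]
        else NA_character_)
      if (is.na(i)) next
      mean[i] <- if (bt == "mu0") records$value[k] else log(records$value[k])
      sd[i] <- records$logSd[k]
    }
  }
  new("GaussianBelief", mean = mean, cov = diag(sd^2, nrow = length(sd)))
}

#' Map parameter records to measurement rows
#'
#' Each record becomes one linear observation of the basic vector: an
#' identity row for basic quantities (kM, c, u, mu0) or the corresponding
#' dependency row for dependent quantities (keq, kcat+/-, vmax+/-). Values
#' of multiplicative quantities are log-transformed; the noise variance is
#' the squared record log-std (or the configured default).
#'
#' @param system a [QuantitySystem-class]
#' @param records data.frame of parameter records
#' @param config a [balancingConfig()]
#' @return list with \code{Q} (rows x basics design matrix), \code{x}
#'   (observed values on analysis scale), \code{noiseVar}
#' @export
assembleMeasurements <- function(system, records,
                                 config = balancingConfig()) {
  nb <- nrow(system@basics)
  if (is.null(records) || !nrow(records))
    return(list(Q = matrix(0, 0, nb), x = numeric(), noiseVar = numeric()))
  net <- system@network
  offenders <- character()
  n <- nrow(records)
  Q <- matrix(0, n, nb)
  x <- numeric(n); nv <- numeric(n)
  for (k in seq_len(n)) {
    qt <- records$quantityType[k]
    rxn <- records$reaction[k]; met <- records$metabolite[k]
    if (!is.na(rxn) && !rxn %in% net@reactions$id) {
      offenders <- c(offenders, paste0("row ", k, ": unknown reaction ",
                                       rxn)); next
    }
    if (!is.na(met) && !met %in% net@metabolites$id) {
      offenders <- c(offenders, paste0("row ", k, ": unknown metabolite ",
                                       met)); next
    }
    if (qt == "kM" && is.na(met)) {
      offenders <- c(offenders, paste0("row ", k,
        ": kM record lacking metabolite id")); next
    }
    row <- switch(qt,
      kM = { i <- .basicIndex(system, "lnkM", rxn, met)
             if (is.na(i)) NA else { r <- numeric(nb); r[i] <- 1; r } },
      c  = { r <- numeric(nb)
             r[.basicIndex(system, "lnc", NA_character_, met)] <- 1; r },
      u  = { r <- numeric(nb)
             r[.basicIndex(system, "lnu", rxn, NA_character_)] <- 1; r },
      mu0 = { r <- numeric(nb)
              r[.basicIndex(system, "mu0", NA_character_, met)] <- 1; r },
      keq = system@D[.depIndex(system, "lnkeq", rxn, NA_character_), ],
      kcat_forward = system@D[.depIndex(system, "lnkcatf", rxn,
                                        NA_character_), ],
      kcat_reverse = system@D[.depIndex(system, "lnkcatr", rxn,
                                        NA_character_), ],
      vmax_forward = system@D[.depIndex(system, "lnvmaxf", rxn,
                                        NA_character_), ],
      vmax_reverse = system@D[.depIndex(system, "lnvmaxr", rxn,
                                        NA_character_), ],
      stop("unsupported quantity type in measurement: ", qt))
    if (length(row) == 1L && is.na(row)) {
      offenders <- c(offenders, paste0("row ", k, ": no kM entry for (",
                                       rxn, ", ", met, ")"))
      next
    }
    Q[k, ] <- row
    x[k] <- if (.multiplicative(qt)) log(records$value[k])
            else records$value[k]
    sdk <- records$logSd[k]
    nv[k] <- if (is.na(sdk)) config$defaultLogSd^2 else sdk^2
  }
  if (length(offenders))
    stop("invalid measurement records:\n  ",
         paste(offenders, collapse = "\n  "))
  list(Q = Q, x = x, noiseVar = nv)
}

#' Pseudo-measurement rows for dependent quantities
#'
#' Generates soft records encoding the pseudo-priors of keq and kcat+/-
#' per (non-synthetic) reaction. Used by [balanceNetwork()] to keep
#' unmeasured chemical-potential differences within a plausible range --
#' the dependent-quantity analogue of the basic pseudo-priors.
#'
#' @param system a [QuantitySystem-class]
#' @param config a [balancingConfig()]
#' @return data.frame of parameter records with source
#'   \code{"pseudo-prior"}
#' @export
pseudoMeasurementRecords <- function(system, config = balancingConfig()) {
  pp <- config$pseudo
  recs <- list()
  for (r in system@network@reactions$id) {
    recs[[length(recs) + 1L]] <- parameterRecord("keq", pp$keq[1],
      reaction = r, logSd = pp$keq[2], source = "pseudo-prior")
    recs[[length(recs) + 1L]] <- parameterRecord("kcat_forward",
      pp$kcat[1], reaction = r, logSd = pp$kcat[2],
      source = "pseudo-prior")
    recs[[length(recs) + 1L]] <- parameterRecord("kcat_reverse",
      pp$kcat[1], reaction = r, logSd = pp$kcat[2],
      source = "pseudo-prior")
  }
  .bindRecords(recs)
}

#' Linear-Gaussian balancing update
#'
#' Conjugate update of the prior by the measurement rows: posterior
#' covariance \eqn{(\Sigma_0^{-1} + Q^T \Sigma_x^{-1} Q)^{-1}} and mean
#' \eqn{\Sigma (\Sigma_0^{-1} q_0 + Q^T \Sigma_x^{-1} x)}, computed through
#' a symmetric (Cholesky) factorisation with a small jitter retry on
#' numerically singular systems. With zero measurement rows the posterior
#' is the prior, exactly.
#'
#' @param prior a [GaussianBelief-class]
#' @param measurements output of [assembleMeasurements()]
#' @return a [GaussianBelief-class] posterior
#' @export
balance <- function(prior, measurements) {
  nb <- length(prior@mean)
  if (!nrow(measurements$Q)) return(prior)
  stopifnot(ncol(measurements$Q) == nb,
            length(measurements$x) == nrow(measurements$Q))
  P0 <- diag(1 / diag(prior@cov), nrow = nb)
  W <- 1 / measurements$noiseVar
  Lam <- P0 + crossprod(measurements$Q * sqrt(W))
  b <- P0 %*% prior@mean + crossprod(measurements$Q, W * measurements$x)
  ch <- tryCatch(chol(Lam), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-10 * mean(diag(Lam))
    ch <- tryCatch(chol(Lam + diag(jit, nb)), error = function(e)
      stop("singular balancing system; consider tightening the prior ",
           "(larger precision) or removing degenerate measurements"))
  }
  cov <- chol2inv(ch)
  mean <- drop(cov %*% b)
  cov <- (cov + t(cov)) / 2
  new("GaussianBelief", mean = mean, cov = cov)
}

setMethod("show", "GaussianBelief", function(object) {
  cat("GaussianBelief over", length(object@mean), "quantities\n")
})

#' Derive balanced statistics for all quantities
#'
#' Computes mean, standard deviation and median for every basic and
#' dependent quantity from the posterior: means are linear maps of the
#' posterior mean, variances the corresponding quadratic forms, and the
#' median of a multiplicative quantity is exp(mean of its log). Balanced
#' concentrations (type \code{"c"}) are the initial conditions for
#' simulation.
#'
#' @param system a [QuantitySystem-class]
#' @param posterior a [GaussianBelief-class]
#' @return a [BalancedParameters-class]
#' @export
deriveAllQuantities <- function(system, posterior) {
  b <- system@basics
  typeOut <- c(mu0 = "mu0", lnkM = "kM", lnkV = "kV", lnu = "u",
               lnc = "c", lnkeq = "keq", lnkcatf = "kcat_forward",
               lnkcatr = "kcat_reverse", lnvmaxf = "vmax_forward",
               lnvmaxr = "vmax_reverse", mu = "mu", RA = "RA")
  basicTab <- data.frame(type = typeOut[b$type], reaction = b$reaction,
    metabolite = b$metabolite, mean = posterior@mean,
    sd = sqrt(pmax(diag(posterior@cov), 0)), scale = b$scale,
    stringsAsFactors = FALSE)
  d <- system@dependent
  dmean <- drop(system@D %*% posterior@mean)
  dvar <- rowSums((system@D %*% posterior@cov) * system@D)
  depTab <- data.frame(type = typeOut[d$type], reaction = d$reaction,
    metabolite = d$metabolite, mean = dmean, sd = sqrt(pmax(dvar, 0)),
    scale = d$scale, stringsAsFactors = FALSE)
  tab <- rbind(basicTab, depTab)
  tab$median <- ifelse(tab$scale == "log", exp(tab$mean), tab$mean)
  rownames(tab) <- NULL
  new("BalancedParameters", table = tab, system = system)
}

setMethod("show", "BalancedParameters", function(object) {
  cat("BalancedParameters:", nrow(object@table), "quantities\n")
  print(utils::head(object@table, 8))
  if (nrow(object@table) > 8) cat("  ...\n")
})

#' @describeIn BalancedParameters-class full statistics table accessor
#' @param x a \code{BalancedParameters}
#' @export
balancedTable <- function(x) x@table

## median lookup (vectorised over none; small tables)
.medianOf <- function(balanced, type, reaction = NA_character_,
                      metabolite = NA_character_) {
  t <- balanced@table
  i <- which(t$type == type &
             (is.na(reaction) & is.na(t$reaction) |
              !is.na(t$reaction) & !is.na(reaction) &
              t$reaction == reaction) &
             (is.na(metabolite) & is.na(t$metabolite) |
              !is.na(t$metabolite) & !is.na(metabolite) &
              t$metabolite == metabolite))
  if (!length(i)) stop("no balanced quantity ", type, " ", reaction, " ",
                       metabolite)
  t$median[i[1L]]
}

#' Balanced metabolite concentrations
#' @param balanced a [BalancedParameters-class]
#' @return named numeric vector of concentration medians (mM)
#' @export
balancedConcentrations <- function(balanced) {
  t <- balanced@table
  rows <- t[t$type == "c", ]
  stats::setNames(rows$median, rows$metabolite)
}

#' Write balanced parameters as TSV
#'
#' Columns QuantityType, ReactionID, CompoundID, Median, Mean, LogStd.
#' @param balanced a [BalancedParameters-class]
#' @param path output path
#' @export
writeBalancedParameters <- function(balanced, path) {
  t <- balanced@table
  out <- data.frame(QuantityType = t$type, ReactionID = t$reaction,
    CompoundID = t$metabolite, Median = t$median, Mean = t$mean,
    LogStd = t$sd, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Haldane residuals of a balanced parameter set
#'
#' Evaluates, on the balanced medians, the per-reaction identity
#' \eqn{h_j \ln k^{eq}_j - \ln k^{cat+}_j + \ln k^{cat-}_j -
#' h_j \sum_i n_{ij} \ln k^M_{ji}}; zero (to numerical precision) for any
#' output derived through the dependency rows.
#'
#' @param balanced a [BalancedParameters-class]
#' @param network the corresponding [MetabolicNetwork-class]
#' @return named numeric vector of residuals, one per reaction
#' @export
haldaneResiduals <- function(balanced, network) {
  out <- numeric(0)
  for (ri in seq_len(nrow(network@reactions))) {
    rid <- network@reactions$id[ri]
    h <- network@reactions$cooperativity[ri]
    st <- network@stoichiometry[[rid]]
    skm <- sum(vapply(names(st), function(m)
      st[[m]] * log(.medianOf(balanced, "kM", rid, m)), 0))
    res <- h * log(.medianOf(balanced, "keq", rid)) -
      log(.medianOf(balanced, "kcat_forward", rid)) +
      log(.medianOf(balanced, "kcat_reverse", rid)) - h * skm
    out[rid] <- res
  }
  out
}

#' Wegscheider cycle residuals
#'
#' For each basis vector of the right null space of the stoichiometric
#' matrix (rows over the metabolites carrying chemical potentials), the
#' log equilibrium constants must sum to zero around the cycle:
#' \eqn{\sum_j \gamma_j \ln k^{eq}_j = 0}. Returns the residuals together
#' with the basis used. An acyclic network yields an empty residual set.
#'
#' @param balanced a [BalancedParameters-class]
#' @param network the corresponding [MetabolicNetwork-class]
#' @return list with \code{residuals} (numeric) and \code{basis} (matrix,
#'   one column per null-space vector)
#' @export
wegscheiderResiduals <- function(balanced, network) {
  S <- stoichiometricMatrix(network)
  N <- MASS::Null(t(S))     # columns g with S g = 0
  if (!is.matrix(N) || ncol(N) == 0L)
    return(list(residuals = numeric(0),
                basis = matrix(0, ncol(S), 0)))
  lnkeq <- vapply(colnames(S), function(r)
    log(.medianOf(balanced, "keq", r)), 0)
  res <- drop(crossprod(N, lnkeq))
  list(residuals = res, basis = N)
}

#' Sample a thermodynamically consistent parameter set
#'
#' Draws the basic vector from the posterior Gaussian with covariance
#' scaled by \code{width^2} and derives every dependent quantity through
#' the dependency rows, so each draw satisfies the Haldane and Wegscheider
#' identities exactly. Width 0 reproduces the posterior means (the
#' balanced medians).
#'
#' @param system a [QuantitySystem-class]
#' @param posterior a [GaussianBelief-class]
#' @param width non-negative sampling-width multiplier
#' @param seed integer seed (reproducible draws)
#' @return a [BalancedParameters-class] holding the draw (sd column zero)
#' @export
sampleParameters <- function(system, posterior, width = 1, seed = 1L) {
  if (width < 0) stop("width must be >= 0")
  m <- posterior@mean
  if (width > 0) {
    set.seed(as.integer(seed))
    ch <- tryCatch(chol(posterior@cov), error = function(e)
      chol(posterior@cov + diag(1e-10 * mean(diag(posterior@cov)),
                                length(m))))
    m <- m + width * drop(crossprod(ch, stats::rnorm(length(m))))
  }
  point <- new("GaussianBelief", mean = m,
               cov = matrix(0, length(m), length(m)))
  deriveAllQuantities(system, point)
}

#' One-call balancing of a network
#'
#' Convenience wrapper: builds the quantity system, assembles priors and
#' measurement rows (appending dependent-quantity pseudo-measurements when
#' \code{dependentPseudo}), performs the update and derives all balanced
#' statistics.
#'
#' @param network a [MetabolicNetwork-class]
#' @param records data.frame of parameter records (may be empty)
#' @param config a [balancingConfig()]
#' @param dependentPseudo apply keq/kcat pseudo-priors as soft rows
#'   (default TRUE)
#' @return list with \code{system}, \code{prior}, \code{posterior},
#'   \code{balanced}
#' @export
balanceNetwork <- function(network, records = NULL,
                           config = balancingConfig(),
                           dependentPseudo = TRUE) {
  system <- buildQuantitySystem(network, config)
  prior <- assemblePriors(system, config)
  if (dependentPseudo) {
    pseudo <- pseudoMeasurementRecords(system, config)
    records <- if (is.null(records) || !nrow(records)) pseudo
               else rbind(records, pseudo)
  }
  meas <- assembleMeasurements(system, records, config)
  posterior <- balance(prior, meas)
  list(system = system, prior = prior, posterior = posterior,
       balanced = deriveAllQuantities(system, posterior))
}
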