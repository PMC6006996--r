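#' @import methods
NULL

#' MetabolicNetwork: a metabolic reaction network
#'
#' In-memory representation of a metabolic reaction network: metabolites
#' (with compartments, initial concentrations and boundary flags), reactions
#' (signed stoichiometry, reversibility, flux bounds, enzyme concentration,
#' cooperativity), allosteric/specific regulation edges, and cross-references
#' to external identifier namespaces. This is the single structural input to
#' parameter search, balancing, kinetic translation, reduction and the
#' robustness harness.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{initialConcentration} (mM; \code{NA} when the
#'   source document gives none), \code{boundary} (logical; fixed-concentration
#'   species excluded from the ODE state).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{reversible}, \code{enzymeConcentration} (mM),
#'   \code{cooperativity} (dimensionless Hill-type factor, default 1),
#'   \code{lb}, \code{ub} (flux bounds, mmol/s), \code{synthetic} (logical;
#'   marks lumped reactions produced by compression, skipped by the
#'   parameter search).
#' @slot stoichiometry named list (by reaction id) of named numeric vectors
#'   mapping metabolite id to the signed coefficient n_ij (negative =
#'   substrate, positive = product).
#' @slot regulation data.frame with columns \code{metabolite}, \code{mode}
#'   (\code{"activator"} or \code{"inhibitor"}), \code{reaction}.
#' @slot compartments data.frame with columns \code{id}, \code{volume}
#'   (litres, relative scale allowed).
#' @slot xrefsMet,xrefsRxn named lists (by metabolite / reaction id) of named
#'   character vectors mapping namespace to external identifier.
#' @slot objective character; id of the objective reaction for
#'   constraint-based operations (length 0 when unset).
#'
#' @seealso [readSBML()], [stoichiometricMatrix()], [validateNetwork()]
#' @export
setClass("MetabolicNetwork",
  representation(
    metabolites   = "data.frame",
    reactions     = "data.frame",
    stoichiometry = "list",
    regulation    = "data.frame",
    compartments  = "data.frame",
    xrefsMet      = "list",
    xrefsRxn      = "list",
    objective     = "character"
  )
)

#' AdapterRegistry: registered database adapters for parameter search
#'
#' Holds the set of registered database adapters together with the
#' identifier-translation graph implied by their capabilities. Each adapter
#' declares translation capabilities (from one namespace to another) and
#' quantity capabilities (a namespace in which it can look up a kinetic
#' quantity), plus query functions executing those capabilities.
#'
#' @slot adapters named list of adapter objects as built by
#'   [fixtureAdapter()] (or any list with the same contract: \code{name},
#'   \code{translations}, \code{quantities}, \code{translate(from, id, to)},
#'   \code{lookup(namespace, id, quantityType)}).
#' @export
setClass("AdapterRegistry", representation(adapters = "list"))

#' QuantitySystem: basic kinetic quantities and their dependency rows
#'
#' The minimal ("basic") parameter vector of a network -- standard chemical
#' potentials mu0 per metabolite (kJ/mol, linear scale), ln kM per
#' (reaction, reactant-or-regulator), ln kV (geometric mean catalytic rate),
#' ln u (enzyme concentration) per reaction and ln c per metabolite --
#' together with the linear dependency rows that express every other kinetic
#' quantity (ln keq, ln kcat+/-, ln vmax+/-, mu, reaction affinity R^A) as a
#' linear map over the basic vector. The dependency rows encode the Haldane
#' relationships and, through the stoichiometric structure of the keq rows,
#' the Wegscheider cycle conditions: any parameter set derived through them
#' is thermodynamically consistent by construction.
#'
#' @slot basics data.frame describing the basic vector: columns \code{type}
#'   (\code{mu0}, \code{lnkM}, \code{lnkV}, \code{lnu}, \code{lnc}),
#'   \code{reaction}, \code{metabolite} (NA where not applicable),
#'   \code{scale} (\code{"linear"} or \code{"log"}).
#' @slot dependent data.frame describing dependency rows (same columns;
#'   types \code{lnkeq}, \code{lnkcatf}, \code{lnkcatr}, \code{lnvmaxf},
#'   \code{lnvmaxr}, \code{mu}, \code{RA}).
#' @slot D numeric matrix, one dependency row per row of \code{dependent},
#'   columns aligned with \code{basics}.
#' @slot RT numeric, R*T in kJ/mol.
#' @slot network the [MetabolicNetwork-class] the system was built from.
#' @export
setClass("QuantitySystem",
  representation(
    basics    = "data.frame",
    dependent = "data.frame",
    D         = "matrix",
    RT        = "numeric",
    network   = "MetabolicNetwork"
  )
)

#' GaussianBelief: prior or posterior over the basic quantity vector
#'
#' Multivariate Gaussian over the basic vector of a [QuantitySystem-class].
#' Priors are diagonal; posteriors carry the full symmetric covariance
#' produced by the balancing update.
#'
#' @slot mean numeric vector (each entry on its quantity's declared scale).
#' @slot cov covariance matrix, symmetric positive semi-definite.
#' @export
setClass("GaussianBelief", representation(mean = "numeric", cov = "matrix"))

#' BalancedParameters: balanced statistics for every kinetic quantity
#'
#' Per-quantity posterior summary for every basic and dependent quantity:
#' mean (on the quantity's scale), log-scale (or linear, for mu0/mu/RA)
#' standard deviation, and median. Medians of multiplicative quantities are
#' exp(posterior mean of the log) and are the values used for simulation and
#' as initial conditions (concentrations c).
#'
#' @slot table data.frame with columns \code{type}, \code{reaction},
#'   \code{metabolite}, \code{mean}, \code{sd}, \code{median}, \code{scale}.
#' @slot system the generating [QuantitySystem-class].
#' @export
setClass("BalancedParameters",
  representation(table = "data.frame", system = "QuantitySystem"))

#' KineticModel: assembled ODE system dx/dt = S v(x, k)
#'
#' A network translated into common-modular-rate-law fluxes with a concrete
#' parameter set. Boundary species are held constant (part of the
#' environment, not the state); compartment volumes rescale species amounts
#' so cross-compartment reactions stay mass-consistent.
#'
#' @slot network the source [MetabolicNetwork-class].
#' @slot params named list (by reaction id) of rate-law parameter sets:
#'   \code{kcatf}, \code{kcatr} (1/s), \code{kM} (named, mM, participants),
#'   \code{kMreg} (named, mM, regulators), \code{u} (mM), \code{h}.
#' @slot stateIds character; non-boundary metabolite ids, in state order.
#' @slot boundary named numeric; fixed concentrations of boundary species.
#' @slot cmodel internal packed index representation consumed by the
#'   compiled right-hand side.
#' @export
setClass("KineticModel",
  representation(
    network  = "MetabolicNetwork",
    params   = "list",
    stateIds = "character",
    boundary = "numeric",
    cmodel   = "list"
  )
)

#' GoldStandard: fully parameterised reference model for robustness tests
#'
#' An idealised in-silico system in which every parameter is known: the
#' balanced posterior of a network given a complete set of ground-truth
#' measurements, the median parameter set, the reference trajectory on the
#' standard schedule, and the pool of "known" parameter records from which
#' the robustness protocol draws subsets.
#'
#' @slot network the [MetabolicNetwork-class].
#' @slot system the [QuantitySystem-class].
#' @slot posterior full-information [GaussianBelief-class].
#' @slot balanced [BalancedParameters-class] (medians fixed).
#' @slot model the median [KineticModel-class].
#' @slot reference reference trajectory (list with \code{time},
#'   \code{conc}) on the standard schedule.
#' @slot schedule the simulation schedule used.
#' @slot records the complete known-parameter record pool (data.frame).
#' @slot config the [balancingConfig()] used.
#' @export
setClass("GoldStandard",
  representation(
    network   = "MetabolicNetwork",
    system    = "QuantitySystem",
    posterior = "GaussianBelief",
    balanced  = "BalancedParameters",
    model     = "KineticModel",
    reference = "list",
    schedule  = "list",
    records   = "data.frame",
    config    = "list"
  )
)
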