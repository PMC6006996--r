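## Construction, accessors and structural checks for MetabolicNetwork.

.emptyMetabolites <- function() {
  data.frame(id = character(), name = character(), compartment = character(),
             initialConcentration = numeric(), boundary = logical(),
             stringsAsFactors = FALSE)
}

.emptyReactions <- function() {
  data.frame(id = character(), name = character(), reversible = logical(),
             enzymeConcentration = numeric(), cooperativity = numeric(),
             lb = numeric(), ub = numeric(), synthetic = logical(),
             stringsAsFactors = FALSE)
}

.emptyRegulation <- function() {
  data.frame(metabolite = character(), mode = character(),
             reaction = character(), stringsAsFactors = FALSE)
}

#' Construct a metabolic network
#'
#' Builds a [MetabolicNetwork-class] from plain data.frames, filling in
#' defaults for omitted columns. Flux-bound defaults are +/-1000 mmol/s for
#' reversible reactions and [0, 1000] for irreversible ones.
#'
#' @param metabolites data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{compartment}, \code{initialConcentration} (mM),
#'   \code{boundary}.
#' @param reactions data.frame with at least an \code{id} column; optional
#'   \code{name}, \code{reversible}, \code{enzymeConcentration} (mM),
#'   \code{cooperativity}, \code{lb}, \code{ub}, \code{synthetic}.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   mapping metabolite id to signed coefficient (negative = substrate).
#' @param compartments data.frame with \code{id} and \code{volume} columns;
#'   defaults to a single unit-volume compartment \code{"c"}.
#' @param regulation data.frame with \code{metabolite}, \code{mode}
#'   (\code{activator}/\code{inhibitor}), \code{reaction}.
#' @param xrefsMet,xrefsRxn named lists of named character vectors
#'   (namespace -> external id).
#' @param objective optional id of the objective reaction.
#' @return A [MetabolicNetwork-class] object.
#' @examples
#' net <- MetabolicNetwork(
#'   metabolites = data.frame(id = c("A", "B")),
#'   reactions = data.frame(id = "R1"),
#'   stoichiometry = list(R1 = c(A = -1, B = 1)))
#' stoichiometricMatrix(net)
#' @export
MetabolicNetwork <- function(metabolites, reactions, stoichiometry,
                             compartments = NULL, regulation = NULL,
                             xrefsMet = NULL, xrefsRxn = NULL,
                             objective = character()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(compartments))
    compartments <- data.frame(id = "c", volume = 1, stringsAsFactors = FALSE)
  if (is.null(regulation)) regulation <- .emptyRegulation()
  regulation <- as.data.frame(regulation, stringsAsFactors = FALSE)

  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- compartments$id[1L]
  if (is.null(metabolites$initialConcentration))
    metabolites$initialConcentration <- NA_real_
  if (is.null(metabolites$boundary)) metabolites$boundary <- FALSE
  metabolites <- metabolites[, c("id", "name", "compartment",
                                 "initialConcentration", "boundary")]

  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$reversible)) reactions$reversible <- TRUE
  if (is.null(reactions$enzymeConcentration))
    reactions$enzymeConcentration <- 0.01
  if (is.null(reactions$cooperativity)) reactions$cooperativity <- 1
  if (is.null(reactions$lb))
    reactions$lb <- ifelse(reactions$reversible, -1000, 0)
  if (is.null(reactions$ub)) reactions$ub <- 1000
  if (is.null(reactions$synthetic)) reactions$synthetic <- FALSE
  reactions <- reactions[, c("id", "name", "reversible",
                             "enzymeConcentration", "cooperativity",
                             "lb", "ub", "synthetic")]

  if (is.null(xrefsMet)) xrefsMet <- list()
  if (is.null(xrefsRxn)) xrefsRxn <- list()
  stoichiometry <- stoichiometry[reactions$id]

  new("MetabolicNetwork",
      metabolites = metabolites, reactions = reactions,
      stoichiometry = stoichiometry, regulation = regulation,
      compartments = as.data.frame(compartments, stringsAsFactors = FALSE),
      xrefsMet = xrefsMet, xrefsRxn = xrefsRxn,
      objective = as.character(objective))
}

setValidity("MetabolicNetwork", function(object) {
  msgs <- validateNetwork(object)
  # hard structural failures only; soft findings are reported, not fatal
  hard <- grep("^(duplicate|dangling|missing stoichiometry|empty stoichiometry)",
               msgs, value = TRUE)
  if (length(hard)) hard else TRUE
})

#' @describeIn MetabolicNetwork-class metabolite table accessor
#' @param x,object a \code{MetabolicNetwork}
#' @export
metabolites <- function(x) x@metabolites

#' @describeIn MetabolicNetwork-class reaction table accessor
#' @export
reactions <- function(x) x@reactions

#' @describeIn MetabolicNetwork-class compartment table accessor
#' @export
compartments <- function(x) x@compartments

#' @describeIn MetabolicNetwork-class regulation edge accessor
#' @export
regulation <- function(x) x@regulation

#' @describeIn MetabolicNetwork-class stoichiometry list accessor
#' @export
stoichiometry <- function(x) x@stoichiometry

#' @describeIn MetabolicNetwork-class objective reaction id (may be empty)
#' @export
objectiveReaction <- function(x) x@objective

#' Set the objective reaction
#' @param x a \code{MetabolicNetwork}
#' @param value reaction id
#' @export
`objectiveReaction<-` <- function(x, value) {
  stopifnot(value %in% x@reactions$id)
  x@objective <- as.character(value)
  x
}

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:", nrow(object@metabolites), "metabolites,",
      nrow(object@reactions), "reactions,",
      nrow(object@compartments), "compartment(s),",
      nrow(object@regulation), "regulation edge(s)\n")
  nb <- sum(object@metabolites$boundary)
  if (nb) cat("  boundary species:", nb, "\n")
  if (length(object@objective))
    cat("  objective:", object@objective, "\n")
})

#' Stoichiometric matrix of a network
#'
#' Assembles the (metabolites x reactions) matrix S with entry (i, j) equal
#' to the signed coefficient of metabolite i in reaction j. Row and column
#' names are metabolite and reaction ids. Boundary-species rows are flagged
#' through the \code{"boundary"} attribute so steady-state operations can
#' exclude them.
#'
#' @param network a [MetabolicNetwork-class]
#' @return numeric matrix with a logical \code{"boundary"} attribute marking
#'   boundary-metabolite rows.
#' @export
stoichiometricMatrix <- function(network) {
  mets <- network@metabolites$id
  rxns <- network@reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- network@stoichiometry[[rxns[j]]]
    S[names(st), j] <- st
  }
  attr(S, "boundary") <- stats::setNames(network@metabolites$boundary, mets)
  S
}

#' Validate a network against its structural invariants
#'
#' Checks identifier uniqueness, cross-reference resolution (compartments,
#' stoichiometry entries, regulation edges), nonzero coefficients, nonempty
#' stoichiometries, positive volumes/enzyme concentrations/cooperativities,
#' flux-bound ordering (and non-negative lower bounds for irreversible
#' reactions), non-negative initial concentrations, and orphan metabolites
#' that appear in no reaction. An empty report means all invariants hold.
#'
#' @param network a [MetabolicNetwork-class]
#' @return character vector of findings (empty when valid)
#' @export
validateNetwork <- function(network) {
  m <- network@metabolites; r <- network@reactions
  msgs <- character()
  add <- function(...) msgs <<- c(msgs, paste0(...))
  if (anyDuplicated(m$id)) add("duplicate metabolite ids: ",
    paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  if (anyDuplicated(r$id)) add("duplicate reaction ids: ",
    paste(unique(r$id[duplicated(r$id)]), collapse = ", "))
  bad <- setdiff(m$compartment, network@compartments$id)
  if (length(bad)) add("dangling compartment reference: ",
                       paste(bad, collapse = ", "))
  if (any(network@compartments$volume <= 0))
    add("non-positive compartment volume: ",
        paste(network@compartments$id[network@compartments$volume <= 0],
              collapse = ", "))
  if (nrow(r) == 0L) add("network has no reactions")
  for (id in r$id) {
    st <- network@stoichiometry[[id]]
    if (is.null(st)) { add("missing stoichiometry for reaction ", id); next }
    if (length(st) == 0L) { add("empty stoichiometry for reaction ", id); next }
    if (any(st == 0)) add("zero coefficient in reaction ", id)
    dang <- setdiff(names(st), m$id)
    if (length(dang)) add("dangling species reference in reaction ", id,
                          ": ", paste(dang, collapse = ", "))
  }
  extra <- setdiff(names(network@stoichiometry), r$id)
  if (length(extra)) add("stoichiometry for unknown reaction: ",
                         paste(extra, collapse = ", "))
  ok <- is.finite(m$initialConcentration)
  if (any(ok & m$initialConcentration < 0))
    add("negative initial concentration: ",
        paste(m$id[ok & m$initialConcentration < 0], collapse = ", "))
  if (any(r$enzymeConcentration <= 0))
    add("non-positive enzyme concentration: ",
        paste(r$id[r$enzymeConcentration <= 0], collapse = ", "))
  if (any(r$cooperativity <= 0))
    add("non-positive cooperativity: ",
        paste(r$id[r$cooperativity <= 0], collapse = ", "))
  if (any(r$lb > r$ub))
    add("lower bound above upper bound: ",
        paste(r$id[r$lb > r$ub], collapse = ", "))
  if (any(!r$reversible & r$lb < 0))
    add("irreversible reaction with negative lower bound: ",
        paste(r$id[!r$reversible & r$lb < 0], collapse = ", "))
  reg <- network@regulation
  if (nrow(reg)) {
    if (any(!reg$mode %in% c("activator", "inhibitor")))
      add("invalid regulation mode")
    dang <- setdiff(reg$metabolite, m$id)
    if (length(dang)) add("dangling regulator metabolite: ",
                          paste(dang, collapse = ", "))
    dang <- setdiff(reg$reaction, r$id)
    if (length(dang)) add("dangling regulated reaction: ",
                          paste(dang, collapse = ", "))
  }
  used <- unique(unlist(lapply(network@stoichiometry, names)))
  orphans <- setdiff(m$id, used)
  if (length(orphans)) add("orphan metabolites (in no reaction): ",
                           paste(orphans, collapse = ", "))
  if (length(network@objective) && !network@objective %in% r$id)
    add("dangling objective reaction: ", network@objective)
  msgs
}

## participants of a reaction, split by sign
.participants <- function(network, rid) {
  st <- network@stoichiometry[[rid]]
  list(sub = st[st < 0], prod = st[st > 0], all = st)
}

## regulator table for one reaction
.regulators <- function(network, rid) {
  reg <- network@regulation
  reg[reg$reaction == rid, , drop = FALSE]
}
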