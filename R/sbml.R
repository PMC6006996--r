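## SBML exchange: reader for Level 2 / Level 3 core (plus fbc bounds and
## objective), writer emitting Level 3 Version 1 with optional common
## modular rate law kineticLaw elements.

.attr1 <- function(node, ...) {
  for (a in c(...)) {
    v <- xml2::xml_attr(node, a)
    if (!is.na(v)) return(v)
  }
  NA_character_
}

.parseResource <- function(res) {
  # identifiers.org URL or urn:miriam URN -> c(namespace, id)
  m <- regmatches(res, regexec("identifiers\\.org/([^/]+)/(.+)$", res))[[1]]
  if (length(m) == 3L) return(c(m[2L], m[3L]))
  m <- regmatches(res, regexec("^urn:miriam:([^:]+):(.+)$", res))[[1]]
  if (length(m) == 3L) return(c(m[2L], utils::URLdecode(m[3L])))
  NULL
}

.readXrefs <- function(node) {
  ann <- xml2::xml_find_first(node, "./annotation")
  if (inherits(ann, "xml_missing")) return(character())
  lis <- xml2::xml_find_all(ann, ".//*[local-name()='li']")
  out <- character()
  for (li in lis) {
    res <- .attr1(li, "resource", "rdf:resource")
    if (is.na(res)) next
    p <- .parseResource(res)
    if (!is.null(p)) out[p[1L]] <- p[2L]
  }
  out
}

.sboActivator <- c("SBO:0000459", "SBO:0000461", "SBO:0000462", "SBO:0000021")
.sboInhibitor <- c("SBO:0000020", "SBO:0000206", "SBO:0000537", "SBO:0000536")

#' Read a metabolic network from an SBML document
#'
#' Parses a Level 2 or Level 3 SBML file into a [MetabolicNetwork-class].
#' Species become metabolites (the \code{boundaryCondition} attribute is
#' honoured); an \code{initialAmount} is converted to a concentration by
#' dividing by the compartment size; a missing initial concentration is
#' recorded as \code{NA}, never as zero. Reactions carry signed
#' stoichiometry, reversibility (irreversible reactions get a lower flux
#' bound of zero), and modifier species as regulation edges: SBO terms
#' distinguish activators from inhibitors, and a modifier without an SBO
#' term defaults to activator with a warning. Controlled-vocabulary
#' annotations (identifiers.org URLs and MIRIAM URNs) populate the xref
#' maps. Flux bounds and the objective are taken from the fbc package
#' attributes when present.
#'
#' @param path path to an SBML file
#' @return a [MetabolicNetwork-class]
#' @export
readSBML <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing"))
    stop("SBML parse error: no <model> element in ", path)

  comps <- xml2::xml_find_all(model, "./listOfCompartments/compartment")
  compartments <- data.frame(
    id = vapply(comps, function(n) .attr1(n, "id", "name"), ""),
    volume = vapply(comps, function(n) {
      v <- suppressWarnings(as.numeric(.attr1(n, "size", "volume")))
      if (is.na(v)) 1 else v
    }, 0), stringsAsFactors = FALSE)
  if (nrow(compartments) == 0L)
    compartments <- data.frame(id = "c", volume = 1, stringsAsFactors = FALSE)
  volOf <- stats::setNames(compartments$volume, compartments$id)

  spn <- xml2::xml_find_all(model, "./listOfSpecies/species")
  ids <- vapply(spn, function(n) .attr1(n, "id", "name"), "")
  mets <- data.frame(
    id = ids,
    name = vapply(spn, function(n) {
      v <- .attr1(n, "name"); if (is.na(v)) NA_character_ else v
    }, ""),
    compartment = vapply(spn, function(n) {
      v <- .attr1(n, "compartment")
      if (is.na(v)) compartments$id[1L] else v
    }, ""),
    stringsAsFactors = FALSE)
  mets$name <- ifelse(is.na(mets$name), mets$id, mets$name)
  mets$initialConcentration <- vapply(seq_along(spn), function(i) {
    n <- spn[[i]]
    conc <- suppressWarnings(as.numeric(.attr1(n, "initialConcentration")))
    if (!is.na(conc)) return(conc)
    amt <- suppressWarnings(as.numeric(.attr1(n, "initialAmount")))
    if (!is.na(amt)) {
      vol <- volOf[mets$compartment[i]]
      return(amt / ifelse(is.na(vol) || vol <= 0, 1, vol))
    }
    NA_real_
  }, 0)
  mets$boundary <- vapply(spn, function(n) {
    identical(.attr1(n, "boundaryCondition"), "true")
  }, TRUE)
  xrefsMet <- stats::setNames(lapply(spn, .readXrefs), ids)
  xrefsMet <- xrefsMet[vapply(xrefsMet, length, 0L) > 0L]

  # fbc v2 global parameters (bound values)
  parn <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  parVal <- stats::setNames(
    vapply(parn, function(n)
      suppressWarnings(as.numeric(.attr1(n, "value"))), 0),
    vapply(parn, function(n) .attr1(n, "id"), ""))

  rxn <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  rids <- vapply(rxn, function(n) .attr1(n, "id", "name"), "")
  stoich <- list(); regRows <- list(); xrefsRxn <- list()
  noSbo <- character()
  rdf <- data.frame(id = rids, stringsAsFactors = FALSE)
  rdf$name <- vapply(rxn, function(n) {
    v <- .attr1(n, "name"); if (is.na(v)) NA_character_ else v
  }, "")
  rdf$name <- ifelse(is.na(rdf$name), rdf$id, rdf$name)
  rdf$reversible <- vapply(rxn, function(n) {
    !identical(.attr1(n, "reversible"), "false")
  }, TRUE)
  rdf$lb <- ifelse(rdf$reversible, -1000, 0)
  rdf$ub <- 1000
  for (i in seq_along(rxn)) {
    n <- rxn[[i]]; id <- rids[i]
    st <- numeric()
    for (sr in xml2::xml_find_all(n, "./listOfReactants/speciesReference")) {
      sp <- .attr1(sr, "species")
      k <- suppressWarnings(as.numeric(.attr1(sr, "stoichiometry")))
      if (is.na(k)) k <- 1
      st[sp] <- ifelse(is.na(st[sp]), 0, st[sp]) - k
    }
    for (sr in xml2::xml_find_all(n, "./listOfProducts/speciesReference")) {
      sp <- .attr1(sr, "species")
      k <- suppressWarnings(as.numeric(.attr1(sr, "stoichiometry")))
      if (is.na(k)) k <- 1
      st[sp] <- ifelse(is.na(st[sp]), 0, st[sp]) + k
    }
    st <- st[st != 0]
    stoich[[id]] <- st
    for (md in xml2::xml_find_all(n,
        "./listOfModifiers/modifierSpeciesReference")) {
      sp <- .attr1(md, "species")
      sbo <- .attr1(md, "sboTerm")
      mode <- if (!is.na(sbo) && sbo %in% .sboInhibitor) "inhibitor"
              else if (!is.na(sbo) && sbo %in% .sboActivator) "activator"
              else { noSbo <- c(noSbo, sp); "activator" }
      regRows[[length(regRows) + 1L]] <-
        data.frame(metabolite = sp, mode = mode, reaction = id,
                   stringsAsFactors = FALSE)
    }
    xr <- .readXrefs(n)
    if (length(xr)) xrefsRxn[[id]] <- xr
    lbRef <- .attr1(n, "lowerFluxBound", "fbc:lowerFluxBound")
    ubRef <- .attr1(n, "upperFluxBound", "fbc:upperFluxBound")
    if (!is.na(lbRef) && lbRef %in% names(parVal)) rdf$lb[i] <- parVal[lbRef]
    if (!is.na(ubRef) && ubRef %in% names(parVal)) rdf$ub[i] <- parVal[ubRef]
  }
  if (length(noSbo))
    warning("modifier species without SBO term treated as activator: ",
            paste(unique(noSbo), collapse = ", "))

  dangling <- setdiff(unique(unlist(lapply(stoich, names))), mets$id)
  if (length(dangling))
    stop("SBML validation error: dangling speciesReference(s): ",
         paste(dangling, collapse = ", "))

  obj <- character()
  fr <- xml2::xml_find_first(model,
    ".//*[local-name()='fluxObjective']")
  if (!inherits(fr, "xml_missing")) {
    v <- .attr1(fr, "reaction", "fbc:reaction")
    if (!is.na(v) && v %in% rids) obj <- v
  }

  reg <- if (length(regRows)) do.call(rbind, regRows) else .emptyRegulation()
  MetabolicNetwork(metabolites = mets, reactions = rdf,
                   stoichiometry = stoich, compartments = compartments,
                   regulation = reg, xrefsMet = xrefsMet,
                   xrefsRxn = xrefsRxn, objective = obj)
}

.xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.num <- function(x) sprintf("%.17g", x)

.annotXml <- function(id, xrefs, indent) {
  if (!length(xrefs)) return(character())
  pre <- strrep(" ", indent)
  c(paste0(pre, "<annotation>"),
    paste0(pre, "  <rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\" xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">"),
    paste0(pre, "    <rdf:Description rdf:about=\"#", .xesc(id), "\">"),
    paste0(pre, "      <bqbiol:is>"),
    paste0(pre, "        <rdf:Bag>"),
    vapply(seq_along(xrefs), function(k) paste0(
      pre, "          <rdf:li rdf:resource=\"http://identifiers.org/",
      .xesc(names(xrefs)[k]), "/", .xesc(unname(xrefs[k])), "\"/>"),
      character(1)),
    paste0(pre, "        </rdf:Bag>"),
    paste0(pre, "      </bqbiol:is>"),
    paste0(pre, "    </rdf:Description>"),
    paste0(pre, "  </rdf:RDF>"),
    paste0(pre, "</annotation>"))
}

## --- MathML for the common modular rate law ------------------------------

.mmlCi <- function(x) paste0("<ci> ", .xesc(x), " </ci>")
.mmlCn <- function(x) paste0("<cn> ", .num(x), " </cn>")
.mmlApply <- function(op, args) {
  paste0("<apply><", op, "/>", paste0(args, collapse = ""), "</apply>")
}
.mmlPow <- function(base, expo) {
  if (abs(expo - 1) < 1e-12) return(base)
  .mmlApply("power", c(base, .mmlCn(expo)))
}
.mmlProd <- function(terms) {
  if (length(terms) == 0L) return(.mmlCn(1))
  if (length(terms) == 1L) return(terms)
  .mmlApply("times", terms)
}

.cmrlMathML <- function(rid, st, regs, p) {
  h <- p$h
  sat <- function(met) .mmlApply("divide", c(.mmlCi(met),
         .mmlCi(paste0("kM_", met))))
  subs <- names(st)[st < 0]; prods <- names(st)[st > 0]
  numSub <- .mmlProd(vapply(subs, function(m)
    .mmlPow(sat(m), h * abs(st[m])), ""))
  numProd <- .mmlProd(vapply(prods, function(m)
    .mmlPow(sat(m), h * st[m]), ""))
  num <- .mmlApply("minus", c(
    .mmlApply("times", c(.mmlCi("kcatf"), numSub)),
    .mmlApply("times", c(.mmlCi("kcatr"), numProd))))
  denTerm <- function(mets) .mmlProd(vapply(mets, function(m)
    .mmlPow(.mmlApply("plus", c(.mmlCn(1), sat(m))), h * abs(st[m])), ""))
  den <- c(denTerm(subs), denTerm(prods), .mmlApply("minus", list(.mmlCn(1))))
  fregs <- character(); dregs <- character()
  if (nrow(regs)) for (k in seq_len(nrow(regs))) {
    m <- regs$metabolite[k]
    r <- .mmlApply("divide", c(.mmlCi(m), .mmlCi(paste0("kM_", m))))
    if (regs$mode[k] == "activator") {
      fregs <- c(fregs, .mmlApply("divide",
        c(r, .mmlApply("plus", c(.mmlCn(1), r)))))
      dregs <- c(dregs, .mmlApply("divide",
        c(.mmlCi(paste0("kM_", m)), .mmlCi(m))))
    } else {
      fregs <- c(fregs, .mmlApply("divide",
        c(.mmlCn(1), .mmlApply("plus", c(.mmlCn(1), r)))))
      dregs <- c(dregs, r)
    }
  }
  den <- .mmlApply("plus", c(den, dregs))
  v <- .mmlApply("times", c(.mmlCn(p$u), fregs,
        .mmlApply("divide", c(num, den))))
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">", v, "</math>")
}

#' Write a network (optionally with kinetics) as SBML Level 3 Version 1
#'
#' Emits a deterministic L3V1 core document with fbc flux bounds and
#' objective. When a kinetic parameter set is supplied (named list by
#' reaction id, entries as in the \code{params} slot of
#' [KineticModel-class]), each reaction carries a \code{kineticLaw} holding
#' the common modular rate law in MathML with local parameters
#' \code{kcatf}, \code{kcatr} and one \code{kM_<species>} per participant
#' and per regulator; the enzyme concentration and cooperativity are
#' inlined as constants.
#'
#' @param network a [MetabolicNetwork-class]
#' @param path output file path
#' @param kinetics optional named list of per-reaction rate-law parameters
#' @return invisibly, \code{path}
#' @export
writeSBML <- function(network, path, kinetics = NULL) {
  m <- network@metabolites; r <- network@reactions
  L <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
      "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
      "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    "  <model id=\"model\" fbc:strict=\"false\">",
    "    <listOfCompartments>")
  for (i in seq_len(nrow(network@compartments)))
    L <- c(L, sprintf(
      "      <compartment id=\"%s\" size=\"%s\" constant=\"true\"/>",
      .xesc(network@compartments$id[i]),
      .num(network@compartments$volume[i])))
  L <- c(L, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(m))) {
    conc <- m$initialConcentration[i]
    concAttr <- if (is.finite(conc))
      sprintf(" initialConcentration=\"%s\"", .num(conc)) else ""
    xr <- network@xrefsMet[[m$id[i]]]
    open <- sprintf(paste0(
      "      <species id=\"%s\" name=\"%s\" compartment=\"%s\"%s ",
      "boundaryCondition=\"%s\" constant=\"%s\" ",
      "hasOnlySubstanceUnits=\"false\""),
      .xesc(m$id[i]), .xesc(m$name[i]), .xesc(m$compartment[i]), concAttr,
      tolower(m$boundary[i]), tolower(m$boundary[i]))
    if (length(xr)) {
      L <- c(L, paste0(open, ">"), .annotXml(m$id[i], xr, 8L),
             "      </species>")
    } else L <- c(L, paste0(open, "/>"))
  }
  L <- c(L, "    </listOfSpecies>", "    <listOfParameters>")
  for (i in seq_len(nrow(r))) {
    L <- c(L, sprintf(
      "      <parameter id=\"lb_%s\" value=\"%s\" constant=\"true\"/>",
      .xesc(r$id[i]), .num(r$lb[i])), sprintf(
      "      <parameter id=\"ub_%s\" value=\"%s\" constant=\"true\"/>",
      .xesc(r$id[i]), .num(r$ub[i])))
  }
  L <- c(L, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(r))) {
    rid <- r$id[i]
    st <- network@stoichiometry[[rid]]
    regs <- .regulators(network, rid)
    L <- c(L, sprintf(paste0(
      "      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" ",
      "fast=\"false\" fbc:lowerFluxBound=\"lb_%s\" ",
      "fbc:upperFluxBound=\"ub_%s\">"),
      .xesc(rid), .xesc(r$name[i]), tolower(r$reversible[i]),
      .xesc(rid), .xesc(rid)))
    xr <- network@xrefsRxn[[rid]]
    if (length(xr)) L <- c(L, .annotXml(rid, xr, 8L))
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs)) {
      L <- c(L, "        <listOfReactants>")
      for (k in seq_along(subs))
        L <- c(L, sprintf(paste0("          <speciesReference species=\"%s\"",
          " stoichiometry=\"%s\" constant=\"true\"/>"),
          .xesc(names(subs)[k]), .num(abs(subs[k]))))
      L <- c(L, "        </listOfReactants>")
    }
    if (length(prods)) {
      L <- c(L, "        <listOfProducts>")
      for (k in seq_along(prods))
        L <- c(L, sprintf(paste0("          <speciesReference species=\"%s\"",
          " stoichiometry=\"%s\" constant=\"true\"/>"),
          .xesc(names(prods)[k]), .num(prods[k])))
      L <- c(L, "        </listOfProducts>")
    }
    if (nrow(regs)) {
      L <- c(L, "        <listOfModifiers>")
      for (k in seq_len(nrow(regs)))
        L <- c(L, sprintf(paste0("          <modifierSpeciesReference ",
          "species=\"%s\" sboTerm=\"%s\"/>"), .xesc(regs$metabolite[k]),
          if (regs$mode[k] == "inhibitor") "SBO:0000020" else "SBO:0000459"))
      L <- c(L, "        </listOfModifiers>")
    }
    if (!is.null(kinetics) && !is.null(kinetics[[rid]])) {
      p <- kinetics[[rid]]
      L <- c(L, "        <kineticLaw>",
        paste0("          ", .cmrlMathML(rid, st, regs, p)),
        "          <listOfLocalParameters>",
        sprintf(paste0("            <localParameter id=\"kcatf\" ",
          "value=\"%s\"/>"), .num(p$kcatf)),
        sprintf(paste0("            <localParameter id=\"kcatr\" ",
          "value=\"%s\"/>"), .num(p$kcatr)))
      kmAll <- c(p$kM, p$kMreg)
      for (k in seq_along(kmAll))
        L <- c(L, sprintf(paste0("            <localParameter ",
          "id=\"kM_%s\" value=\"%s\"/>"),
          .xesc(names(kmAll)[k]), .num(kmAll[k])))
      L <- c(L, "          </listOfLocalParameters>", "        </kineticLaw>")
    }
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>")
  if (length(network@objective)) {
    L <- c(L,
      "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
      "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
      "        <fbc:listOfFluxObjectives>",
      sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"%s\" ",
        "fbc:coefficient=\"1\"/>"), .xesc(network@objective)),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  L <- c(L, "  </model>", "</sbml>")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write SBML to '", path, "': ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(L, con)
  invisible(path)
}
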