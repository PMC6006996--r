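## Exhaustive, provenance-tracked search for kinetic measurements across
## registered database adapters via identifier-translation path finding.

.quantityTypes <- c("kM", "kcat_forward", "kcat_reverse", "keq", "c", "u",
                    "vmax_forward", "vmax_reverse", "mu0")

.unitFor <- function(qt) {
  switch(qt,
    kM = "mM", c = "mM", u = "mM",
    kcat_forward = "1/s", kcat_reverse = "1/s",
    keq = "dimensionless",
    vmax_forward = "mmol/s", vmax_reverse = "mmol/s",
    mu0 = "kJ/mol",
    stop("unknown quantity type: ", qt))
}

.multiplicative <- function(qt) qt != "mu0"

#' Build a single parameter record
#'
#' A parameter record is one measured or asserted kinetic quantity with its
#' unit, uncertainty (log-scale standard deviation for multiplicative
#' quantities, linear for chemical potentials), source, provenance chain and
#' optional measurement conditions. Records are plain one-row data.frames
#' (with a list-column of provenance steps) so that sets of records can be
#' stacked with \code{rbind}.
#'
#' @param quantityType one of \code{kM}, \code{kcat_forward},
#'   \code{kcat_reverse}, \code{keq}, \code{c}, \code{u},
#'   \code{vmax_forward}, \code{vmax_reverse}, \code{mu0}.
#' @param value numeric value in the quantity's declared unit.
#' @param reaction,metabolite subject ids (\code{NA} where not applicable;
#'   \code{metabolite} is required for \code{kM} and \code{c}).
#' @param logSd uncertainty; the default multiplicative spread factor of 2
#'   corresponds to \code{log(2)} on the natural-log scale.
#' @param source adapter or origin name.
#' @param provenance data.frame of resolved path steps (may be empty for
#'   user-supplied records).
#' @param reference free-text literature citation.
#' @param ph,temperatureK optional measurement conditions.
#' @return one-row data.frame
#' @export
parameterRecord <- function(quantityType, value, reaction = NA_character_,
                            metabolite = NA_character_, logSd = log(2),
                            source = "user", provenance = NULL,
                            reference = NA_character_, ph = NA_real_,
                            temperatureK = NA_real_) {
  stopifnot(quantityType %in% .quantityTypes)
  if (.multiplicative(quantityType) && value <= 0)
    stop("value must be > 0 for multiplicative quantity ", quantityType)
  if (quantityType %in% c("kM", "c") && is.na(metabolite))
    stop(quantityType, " record requires a metabolite id")
  df <- data.frame(quantityType = quantityType, reaction = reaction,
                   metabolite = metabolite, value = value,
                   unit = .unitFor(quantityType), logSd = logSd,
                   source = source, reference = reference, ph = ph,
                   temperatureK = temperatureK, stringsAsFactors = FALSE)
  df$provenance <- list(if (is.null(provenance)) .emptyProvenance()
                        else provenance)
  df
}

.emptyProvenance <- function() {
  data.frame(adapter = character(), fromNs = character(),
             fromId = character(), toNs = character(), toId = character(),
             stringsAsFactors = FALSE)
}

.bindRecords <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (!length(lst)) {
    out <- parameterRecord("keq", 1)[0, ]
    return(out)
  }
  do.call(rbind, lst)
}

## --- adapters -------------------------------------------------------------

#' In-memory database adapter
#'
#' Builds an adapter from explicit capability tables. \code{translations}
#' has columns \code{from_namespace}, \code{from_id}, \code{to_namespace},
#' \code{to_id}; \code{quantities} has columns \code{namespace}, \code{id},
#' \code{quantity_type}, \code{value}, \code{unit} and optionally
#' \code{compound} (model-level metabolite id, required for kM rows so the
#' measurement can be attached to the right reactant), \code{ph},
#' \code{temperature_k}, \code{organism}, \code{reference}.
#'
#' @param name unique adapter name
#' @param translations,quantities data.frames as described
#' @return adapter object (list with query closures)
#' @export
memoryAdapter <- function(name, translations = NULL, quantities = NULL) {
  if (is.null(translations))
    translations <- data.frame(from_namespace = character(),
      from_id = character(), to_namespace = character(),
      to_id = character(), stringsAsFactors = FALSE)
  if (is.null(quantities))
    quantities <- data.frame(namespace = character(), id = character(),
      quantity_type = character(), value = numeric(), unit = character(),
      stringsAsFactors = FALSE)
  for (col in c("compound", "organism", "reference"))
    if (is.null(quantities[[col]]))
      quantities[[col]] <- rep(NA_character_, nrow(quantities))
  for (col in c("ph", "temperature_k"))
    if (is.null(quantities[[col]]))
      quantities[[col]] <- rep(NA_real_, nrow(quantities))
  structure(list(
    name = name,
    translations = translations,
    quantities = quantities,
    translate = function(from, id, to) {
      tr <- translations
      tr$to_id[tr$from_namespace == from & tr$from_id == id &
               tr$to_namespace == to]
    },
    lookup = function(namespace, id, quantityType) {
      q <- quantities
      q[q$namespace == namespace & q$id == id &
        q$quantity_type == quantityType, , drop = FALSE]
    }), class = "dbAdapter")
}

#' Fixture-database adapter
#'
#' Reads one adapter's offline fixture tables from
#' \code{<dir>/<name>/translations.tsv} and \code{<dir>/<name>/quantities.tsv}
#' (either file may be absent). The resulting adapter answers translation
#' and quantity queries synchronously from the loaded tables, so it is a
#' drop-in stand-in for a live database client.
#'
#' @param name adapter (sub-directory) name
#' @param dir fixture database root directory
#' @return adapter object
#' @export
fixtureAdapter <- function(name, dir) {
  base <- file.path(dir, name)
  rd <- function(f) {
    p <- file.path(base, f)
    if (!file.exists(p)) return(NULL)
    utils::read.delim(p, stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  tr <- rd("translations.tsv")
  q <- rd("quantities.tsv")
  if (!is.null(q)) {
    q$value <- as.numeric(q$value)
    for (col in c("ph", "temperature_k"))
      if (!is.null(q[[col]])) q[[col]] <- as.numeric(q[[col]])
  }
  memoryAdapter(name, tr, q)
}

#' Create an empty adapter registry
#' @return an [AdapterRegistry-class] with no adapters
#' @export
newAdapterRegistry <- function() new("AdapterRegistry", adapters = list())

#' Register a database adapter
#'
#' Adds an adapter to the registry; its translation capabilities become
#' edges of the identifier-translation graph and its quantity capabilities
#' become terminal lookup steps. Adapter names must be unique.
#'
#' @param registry an [AdapterRegistry-class]
#' @param adapter an adapter from [memoryAdapter()] or [fixtureAdapter()]
#' @return the updated registry
#' @export
registerAdapter <- function(registry, adapter) {
  stopifnot(is(registry, "AdapterRegistry"), inherits(adapter, "dbAdapter"))
  if (adapter$name %in% names(registry@adapters))
    stop("adapter already registered: ", adapter$name)
  registry@adapters[[adapter$name]] <- adapter
  registry
}

#' Translation edges of a registry
#'
#' @param registry an [AdapterRegistry-class]
#' @return data.frame with columns \code{adapter}, \code{from}, \code{to}:
#'   the distinct namespace-translation capabilities of all adapters.
#' @export
translationEdges <- function(registry) {
  rows <- lapply(registry@adapters, function(a) {
    tr <- unique(a$translations[, c("from_namespace", "to_namespace")])
    if (!nrow(tr)) return(NULL)
    data.frame(adapter = a$name, from = tr$from_namespace,
               to = tr$to_namespace, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(adapter = character(),
    from = character(), to = character(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  unique(out)
}

#' Quantity-lookup capabilities of a registry
#' @param registry an [AdapterRegistry-class]
#' @return data.frame with columns \code{adapter}, \code{namespace},
#'   \code{quantityType}.
#' @export
quantityCapabilities <- function(registry) {
  rows <- lapply(registry@adapters, function(a) {
    q <- unique(a$quantities[, c("namespace", "quantity_type")])
    if (!nrow(q)) return(NULL)
    data.frame(adapter = a$name, namespace = q$namespace,
               quantityType = q$quantity_type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(adapter = character(),
    namespace = character(), quantityType = character(),
    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  unique(out)
}

setMethod("show", "AdapterRegistry", function(object) {
  cat("AdapterRegistry:", length(object@adapters), "adapter(s):",
      paste(names(object@adapters), collapse = ", "), "\n")
  cat("  translation edges:", nrow(translationEdges(object)),
      "| quantity capabilities:", nrow(quantityCapabilities(object)), "\n")
})

## --- tasks ----------------------------------------------------------------

#' Enumerate parameter-search tasks for a network
#'
#' Lists, in deterministic network order, the quantities to search for: per
#' reaction one task per requested catalytic/equilibrium quantity and one
#' kM task per participant and per regulator; per metabolite one task for
#' concentrations when
#' \code{"c"} is requested; per reaction one task for enzyme concentrations
#' when \code{"u"} is requested. Reactions marked synthetic (lumped by
#' compression) are skipped -- no database holds parameters for them.
#'
#' @param network a [MetabolicNetwork-class]
#' @param wanted character vector of quantity types
#' @return data.frame with columns \code{subject}, \code{subjectKind},
#'   \code{wanted}, \code{metabolite}
#' @export
enumerateTasks <- function(network,
                           wanted = c("kM", "kcat_forward", "keq")) {
  stopifnot(all(wanted %in% .quantityTypes))
  rows <- list()
  for (rid in network@reactions$id) {
    if (network@reactions$synthetic[network@reactions$id == rid]) next
    st <- network@stoichiometry[[rid]]
    kmMets <- unique(c(names(st), .regulators(network, rid)$metabolite))
    for (w in wanted) {
      if (w == "kM") {
        for (met in kmMets)
          rows[[length(rows) + 1L]] <- data.frame(subject = rid,
            subjectKind = "reaction", wanted = "kM", metabolite = met,
            stringsAsFactors = FALSE)
      } else if (w %in% c("kcat_forward", "kcat_reverse", "keq", "u",
                          "vmax_forward", "vmax_reverse")) {
        rows[[length(rows) + 1L]] <- data.frame(subject = rid,
          subjectKind = "reaction", wanted = w, metabolite = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (w in intersect(wanted, c("c", "mu0")))
    for (met in network@metabolites$id)
      rows[[length(rows) + 1L]] <- data.frame(subject = met,
        subjectKind = "compound", wanted = w, metabolite = met,
        stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(data.frame(subject = character(),
    subjectKind = character(), wanted = character(),
    metabolite = character(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

## --- path search ----------------------------------------------------------

## All simple translation paths from any start namespace to a quantity
## lookup, shortest first, ties broken lexicographically by the adapter
## sequence. Depth counts translation steps plus the final lookup step.
.findPathsNs <- function(startNs, wanted, registry, maxDepth) {
  edges <- translationEdges(registry)
  caps <- quantityCapabilities(registry)
  caps <- caps[caps$quantityType == wanted, , drop = FALSE]
  caps <- caps[order(caps$adapter), , drop = FALSE]
  found <- list()
  emit <- function(steps, ns) {
    hit <- caps[caps$namespace == ns, , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      if (length(steps) + 1L > maxDepth) next
      found[[length(found) + 1L]] <<- rbind(
        if (length(steps)) do.call(rbind, steps) else
          data.frame(adapter = character(), from = character(),
                     to = character(), kind = character(),
                     stringsAsFactors = FALSE),
        data.frame(adapter = hit$adapter[k], from = ns, to = wanted,
                   kind = "quantity", stringsAsFactors = FALSE))
    }
  }
  dfs <- function(ns, visited, steps) {
    emit(steps, ns)
    if (length(steps) + 1L >= maxDepth) return(invisible())
    nxt <- edges[edges$from == ns & !(edges$to %in% visited), , drop = FALSE]
    if (!nrow(nxt)) return(invisible())
    nxt <- nxt[order(nxt$to, nxt$adapter), , drop = FALSE]
    for (k in seq_len(nrow(nxt))) {
      step <- data.frame(adapter = nxt$adapter[k], from = ns,
                         to = nxt$to[k], kind = "translation",
                         stringsAsFactors = FALSE)
      dfs(nxt$to[k], c(visited, nxt$to[k]), c(steps, list(step)))
    }
  }
  for (ns in startNs) dfs(ns, ns, list())
  if (!length(found)) return(found)
  len <- vapply(found, nrow, 0L)
  key <- vapply(found, function(p) paste(p$adapter, collapse = "\r"), "")
  found[order(len, key)]
}

#' Find identifier-translation paths for a search task
#'
#' Enumerates all simple paths (no namespace revisited) of length at most
#' \code{maxDepth} from any namespace present in the subject's xrefs (plus
#' its display name, namespace \code{"name"}) to any adapter that can look
#' up the wanted quantity type. For example, a reaction known only by name
#' can reach an equilibrium constant through
#' name -> MetaCyc id -> Rhea id -> KEGG reaction id -> keq lookup.
#' Paths are returned shortest first; ties are ordered lexicographically by
#' the adapter sequence along the path.
#'
#' @param task one row of [enumerateTasks()] output (or a list with
#'   \code{subject}, \code{subjectKind}, \code{wanted}, \code{metabolite})
#' @param network the [MetabolicNetwork-class] the task refers to
#' @param registry an [AdapterRegistry-class]
#' @param maxDepth maximum number of steps, including the final quantity
#'   lookup (default 6)
#' @return list of path data.frames with columns \code{adapter},
#'   \code{from}, \code{to}, \code{kind}
#' @export
findPaths <- function(task, network, registry, maxDepth = 6L) {
  stopifnot(maxDepth >= 1L)
  startNs <- names(.subjectStartIds(task, network))
  .findPathsNs(unique(startNs), task$wanted, registry, maxDepth)
}

## Start identifiers by namespace for a task subject: xrefs plus name.
.subjectStartIds <- function(task, network) {
  if (task$subjectKind == "reaction") {
    xr <- network@xrefsRxn[[task$subject]]
    nm <- network@reactions$name[network@reactions$id == task$subject]
  } else {
    xr <- network@xrefsMet[[task$subject]]
    nm <- network@metabolites$name[network@metabolites$id == task$subject]
  }
  out <- c(stats::setNames(as.character(nm), "name"), xr)
  out[!is.na(out) & nzchar(out)]
}

## --- search execution -----------------------------------------------------

#' Execute the exhaustive parameter search
#'
#' Runs every task's paths to exhaustion against the registered adapters,
#' following all translation branches, and collects one parameter record
#' per distinct (quantity, subject, source, value) with its full resolved
#' provenance chain. Multiple distinct values for the same rate are all
#' retained (the balancer uses every measurement); only exact duplicates
#' -- the same value for the same rate from the same source reached by
#' different paths -- collapse to a single record. Adapter query failures
#' are logged and the offending path skipped.
#'
#' @param network a [MetabolicNetwork-class]
#' @param registry an [AdapterRegistry-class]
#' @param wanted quantity types to search for (default kM, kcat_forward,
#'   keq)
#' @param maxDepth maximum path length (see [findPaths()])
#' @param defaultLogSd log-scale uncertainty assigned when the source gives
#'   none (default \code{log(2)}: a multiplicative spread factor of 2)
#' @param conditions optional list with elements \code{phRange} and/or
#'   \code{temperatureRange} (two-element numeric); records whose reported
#'   conditions fall outside are dropped. Off by default.
#' @return data.frame of parameter records (see [parameterRecord()])
#' @export
executeSearch <- function(network, registry,
                          wanted = c("kM", "kcat_forward", "keq"),
                          maxDepth = 6L, defaultLogSd = log(2),
                          conditions = NULL) {
  if (!length(registry@adapters)) stop("registry has no adapters")
  tasks <- enumerateTasks(network, wanted)
  recs <- list()
  for (ti in seq_len(nrow(tasks))) {
    task <- tasks[ti, ]
    starts <- .subjectStartIds(task, network)
    paths <- .findPathsNs(unique(names(starts)), task$wanted, registry,
                          maxDepth)
    for (path in paths) {
      res <- tryCatch(
        .executePath(path, task, starts, registry, defaultLogSd),
        error = function(e) {
          message("adapter query failed on path (",
                  paste(path$adapter, collapse = " > "), "): ",
                  conditionMessage(e))
          NULL
        })
      if (length(res)) recs <- c(recs, res)
    }
  }
  out <- .bindRecords(recs)
  if (!is.null(conditions)) out <- .filterConditions(out, conditions)
  .dedupRecords(out)
}

.executePath <- function(path, task, starts, registry, defaultLogSd) {
  startNs <- path$from[1L]
  frontier <- list(list(id = unname(starts[[startNs]]),
                        prov = .emptyProvenance()))
  nsteps <- nrow(path)
  for (k in seq_len(nsteps - 1L)) {
    ad <- registry@adapters[[path$adapter[k]]]
    nxt <- list()
    for (f in frontier) {
      toIds <- ad$translate(path$from[k], f$id, path$to[k])
      for (tid in toIds) {
        prov <- rbind(f$prov, data.frame(adapter = ad$name,
          fromNs = path$from[k], fromId = f$id, toNs = path$to[k],
          toId = tid, stringsAsFactors = FALSE))
        nxt[[length(nxt) + 1L]] <- list(id = tid, prov = prov)
      }
    }
    frontier <- nxt
    if (!length(frontier)) return(NULL)
  }
  qa <- registry@adapters[[path$adapter[nsteps]]]
  ns <- path$from[nsteps]
  out <- list()
  for (f in frontier) {
    hits <- qa$lookup(ns, f$id, task$wanted)
    if (task$wanted == "kM" && nrow(hits))
      hits <- hits[!is.na(hits$compound) &
                   hits$compound == task$metabolite, , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      prov <- rbind(f$prov, data.frame(adapter = qa$name, fromNs = ns,
        fromId = f$id, toNs = task$wanted, toId = "<quantity>",
        stringsAsFactors = FALSE))
      out[[length(out) + 1L]] <- parameterRecord(
        quantityType = task$wanted, value = hits$value[r],
        reaction = if (task$subjectKind == "reaction") task$subject
                   else NA_character_,
        metabolite = task$metabolite, logSd = defaultLogSd,
        source = qa$name, provenance = prov,
        reference = hits$reference[r], ph = hits$ph[r],
        temperatureK = hits$temperature_k[r])
    }
  }
  out
}

.filterConditions <- function(records, conditions) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(conditions$phRange)) {
    ok <- is.na(records$ph) |
      (records$ph >= conditions$phRange[1] &
       records$ph <= conditions$phRange[2])
    keep <- keep & ok
  }
  if (!is.null(conditions$temperatureRange)) {
    ok <- is.na(records$temperatureK) |
      (records$temperatureK >= conditions$temperatureRange[1] &
       records$temperatureK <= conditions$temperatureRange[2])
    keep <- keep & ok
  }
  records[keep, , drop = FALSE]
}

.dedupRecords <- function(records) {
  if (!nrow(records)) return(records)
  key <- paste(records$quantityType, records$reaction, records$metabolite,
               records$source, sprintf("%.15g", records$value), sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- balancing table ------------------------------------------------------

.provToString <- function(prov) {
  if (is.null(prov) || !nrow(prov)) return("")
  paste(sprintf("%s:%s:%s>%s:%s", prov$adapter, prov$fromNs, prov$fromId,
                prov$toNs, prov$toId), collapse = "|")
}

.provFromString <- function(s) {
  if (is.na(s) || !nzchar(s)) return(.emptyProvenance())
  steps <- strsplit(s, "|", fixed = TRUE)[[1L]]
  parts <- lapply(steps, function(st) {
    halves <- strsplit(st, ">", fixed = TRUE)[[1L]]
    a <- strsplit(halves[1L], ":", fixed = TRUE)[[1L]]
    b <- strsplit(halves[2L], ":", fixed = TRUE)[[1L]]
    data.frame(adapter = a[1L], fromNs = a[2L],
               fromId = paste(a[-(1:2)], collapse = ":"),
               toNs = b[1L], toId = paste(b[-1L], collapse = ":"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Write parameter records as a balancing input table
#'
#' Serialises records to the TSV consumed by the balancing stage, with
#' columns QuantityType, ReactionID, CompoundID, Value, Unit, LogStd,
#' Source, Provenance, Reference, pH, TemperatureK, one row per record in
#' deterministic (input) order. Unit consistency with the quantity type is
#' enforced.
#'
#' @param records data.frame of parameter records
#' @param path output TSV path
#' @return invisibly, \code{path}
#' @export
writeBalancingTable <- function(records, path) {
  if (nrow(records)) {
    expect <- vapply(records$quantityType, .unitFor, "")
    bad <- which(records$unit != expect)
    if (length(bad))
      stop("unit inconsistency in rows ", paste(bad, collapse = ", "),
           ": expected ", paste(unique(expect[bad]), collapse = "/"))
  }
  out <- data.frame(
    QuantityType = records$quantityType,
    ReactionID = records$reaction,
    CompoundID = records$metabolite,
    Value = records$value,
    Unit = records$unit,
    LogStd = records$logSd,
    Source = records$source,
    Provenance = vapply(records$provenance, .provToString, ""),
    Reference = records$reference,
    pH = records$ph,
    TemperatureK = records$temperatureK,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a balancing input table
#'
#' Inverse of [writeBalancingTable()]. SBtab-style column aliases
#' (\code{Quantity}, \code{Reaction}, \code{Compound}, \code{Mean},
#' \code{Std}) are accepted.
#'
#' @param path TSV path
#' @return data.frame of parameter records
#' @export
readBalancingTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  alias <- c(Quantity = "QuantityType", Reaction = "ReactionID",
             Compound = "CompoundID", Mean = "Value", Std = "LogStd")
  for (a in names(alias))
    if (is.null(df[[alias[a]]]) && !is.null(df[[a]]))
      names(df)[names(df) == a] <- alias[a]
  recs <- lapply(seq_len(nrow(df)), function(i) {
    parameterRecord(
      quantityType = df$QuantityType[i],
      value = df$Value[i],
      reaction = if (is.null(df$ReactionID)) NA_character_
                 else as.character(df$ReactionID[i]),
      metabolite = if (is.null(df$CompoundID)) NA_character_
                   else as.character(df$CompoundID[i]),
      logSd = if (is.null(df$LogStd) || is.na(df$LogStd[i])) log(2)
              else df$LogStd[i],
      source = if (is.null(df$Source)) "table" else df$Source[i],
      provenance = .provFromString(
        if (is.null(df$Provenance)) "" else df$Provenance[i]),
      reference = if (is.null(df$Reference)) NA_character_
                  else df$Reference[i],
      ph = if (is.null(df$pH)) NA_real_ else df$pH[i],
      temperatureK = if (is.null(df$TemperatureK)) NA_real_
                     else df$TemperatureK[i])
  })
  .bindRecords(recs)
}
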