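# Shared fixture builders. Everything is generated in code; heavier
# objects are built lazily once per session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# minimal A <-> B network (one reversible reaction, one compartment)
toyAB <- function(reversible = TRUE) {
  MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(id = "R1", reversible = reversible),
    stoichiometry = list(R1 = c(A = -1, B = 1)))
}

# linear chain EX_A -> A -> B -> biomass sink, for constraint-based tests
toyChain <- function(uptake = 10) {
  MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(id = c("EX_A", "R1", "BIO"),
      reversible = c(TRUE, FALSE, FALSE),
      lb = c(-uptake, 0, 0), ub = c(uptake, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 1),
                         BIO = c(B = -1)),
    objective = "BIO")
}

# triangle A <-> B <-> C <-> A plus an exchange: one stoichiometric cycle
triangleNet <- function() {
  MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("RAB", "RBC", "RCA", "EX_A")),
    stoichiometry = list(RAB = c(A = -1, B = 1), RBC = c(B = -1, C = 1),
                         RCA = c(C = -1, A = 1), EX_A = c(A = -1)))
}

# small balanced random network + its balancing results, cached
smallBalanced <- function(seed = 2) {
  cached(paste0("bal", seed), function() {
    net <- randomNetwork(networkSpec(6, 6, seed = seed,
                                     pRegulation = 0.1))
    truth <- drawTrueParameters(net, seed = seed)
    bal <- balanceNetwork(net, truth)
    list(net = net, truth = truth, bal = bal)
  })
}

# gold standard on a small network, cached (used across robustness tests)
smallGold <- function(seed = 2) {
  cached(paste0("gold", seed), function() {
    net <- randomNetwork(networkSpec(6, 6, seed = seed))
    makeGoldStandard(net, seed = seed)
  })
}

# fixture database chain reproducing the printed worked example:
# name -> MetaCyc id -> Rhea id -> KEGG reaction id -> equilibrium constant
g6piFixtureDir <- function() {
  dir <- tempfile("g6pi")
  wr <- function(ad, file, df) {
    d <- file.path(dir, ad)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write.table(df, file.path(d, file), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  }
  wr("MetaCyc", "translations.tsv", data.frame(
    from_namespace = "name", from_id = "Glucose-6-phosphate isomerase",
    to_namespace = "metacyc", to_id = "ENZRXN-2863"))
  wr("Rhea", "translations.tsv", data.frame(
    from_namespace = "metacyc", from_id = "ENZRXN-2863",
    to_namespace = "rhea", to_id = "11816"))
  wr("MetaNetX", "translations.tsv", data.frame(
    from_namespace = "rhea", from_id = "11816",
    to_namespace = "kegg_reaction", to_id = "R00771"))
  wr("eQuilibrator", "quantities.tsv", data.frame(
    namespace = "kegg_reaction", id = "R00771", quantity_type = "keq",
    value = 0.361, unit = "dimensionless", compound = NA,
    ph = NA, temperature_k = NA, organism = NA,
    reference = "eQuilibrator"))
  dir
}

# one-reaction network whose single reaction carries the G6P isomerase name
g6piNetwork <- function() {
  MetabolicNetwork(
    metabolites = data.frame(id = c("g6p", "f6p")),
    reactions = data.frame(id = "PGI",
      name = "Glucose-6-phosphate isomerase"),
    stoichiometry = list(PGI = c(g6p = -1, f6p = 1)))
}

# independent second validator, written directly from the invariant list
recheckNetwork <- function(net) {
  m <- metabolites(net); r <- reactions(net); st <- stoichiometry(net)
  findings <- 0L
  if (anyDuplicated(m$id)) findings <- findings + 1L
  if (anyDuplicated(r$id)) findings <- findings + 1L
  if (length(setdiff(m$compartment, compartments(net)$id)))
    findings <- findings + 1L
  for (id in r$id) {
    s <- st[[id]]
    if (is.null(s) || !length(s)) { findings <- findings + 1L; next }
    if (any(s == 0)) findings <- findings + 1L
    if (length(setdiff(names(s), m$id))) findings <- findings + 1L
  }
  if (length(setdiff(m$id, unique(unlist(lapply(st, names))))))
    findings <- findings + 1L
  reg <- regulation(net)
  if (nrow(reg)) {
    if (length(setdiff(reg$metabolite, m$id))) findings <- findings + 1L
    if (length(setdiff(reg$reaction, r$id))) findings <- findings + 1L
  }
  findings
}
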