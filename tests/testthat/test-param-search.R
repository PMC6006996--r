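test_that("adapter registration builds the capability graph", {
  ad <- memoryAdapter("m", translations = data.frame(
    from_namespace = c("name", "metacyc"), from_id = c("x", "y"),
    to_namespace = c("metacyc", "rhea"), to_id = c("y", "z")))
  reg <- registerAdapter(newAdapterRegistry(), ad)
  expect_equal(nrow(translationEdges(reg)), 2)
  expect_error(registerAdapter(reg, memoryAdapter("m")),
               "already registered")
})

test_that("registry capability graph equals brute-force union", {
  dir <- g6piFixtureDir()
  reg <- fixtureRegistry(dir)
  edges <- translationEdges(reg)
  # brute-force union over descriptor tables
  manual <- unique(do.call(rbind, lapply(reg@adapters, function(a) {
    tr <- a$translations
    if (!nrow(tr)) return(NULL)
    data.frame(adapter = a$name, from = tr$from_namespace,
               to = tr$to_namespace, stringsAsFactors = FALSE)
  })))
  expect_setequal(paste(edges$adapter, edges$from, edges$to),
                  paste(manual$adapter, manual$from, manual$to))
  caps <- quantityCapabilities(reg)
  expect_equal(nrow(caps), 1)
  expect_equal(caps$quantityType, "keq")
})

test_that("task enumeration follows network order and counts", {
  net <- toyAB()
  tasks <- enumerateTasks(net, c("kM", "kcat_forward", "keq"))
  expect_equal(nrow(tasks), 4)   # 2 kM + 1 kcat + 1 keq
  expect_equal(sum(tasks$wanted == "kM"), 2)

  expect_equal(nrow(enumerateTasks(net, character(0))), 0)

  # default wanted set on a regulation-free random network
  net2 <- randomNetwork(networkSpec(8, 9, seed = 3, pRegulation = 0))
  tasks2 <- enumerateTasks(net2)
  expected <- sum(vapply(stoichiometry(net2), length, 0L)) +
    2L * nrow(reactions(net2))
  expect_equal(nrow(tasks2), expected)
})

test_that("the printed worked identifier chain is found and executed", {
  dir <- g6piFixtureDir()
  reg <- fixtureRegistry(dir)
  net <- g6piNetwork()
  task <- enumerateTasks(net, "keq")
  paths <- findPaths(task[1, ], net, reg, maxDepth = 6)
  expect_gte(length(paths), 1)
  chain <- paths[[1]]
  expect_equal(nrow(chain), 4)
  expect_equal(chain$adapter,
               c("MetaCyc", "Rhea", "MetaNetX", "eQuilibrator"))
  expect_equal(chain$from, c("name", "metacyc", "rhea", "kegg_reaction"))

  recs <- executeSearch(net, reg, wanted = "keq")
  expect_equal(nrow(recs), 1)
  expect_identical(recs$value, 0.361)
  expect_equal(nrow(recs$provenance[[1]]), 4)
  expect_equal(recs$provenance[[1]]$toId[1:3],
               c("ENZRXN-2863", "11816", "R00771"))
})

test_that("a direct quantity capability yields a single length-1 path", {
  ad <- memoryAdapter("direct", quantities = data.frame(
    namespace = "name", id = "Glucose-6-phosphate isomerase",
    quantity_type = "keq", value = 0.5, unit = "dimensionless"))
  reg <- registerAdapter(newAdapterRegistry(), ad)
  task <- enumerateTasks(g6piNetwork(), "keq")[1, ]
  paths <- findPaths(task, g6piNetwork(), reg)
  expect_length(paths, 1)
  expect_equal(nrow(paths[[1]]), 1)
  expect_equal(paths[[1]]$kind, "quantity")
})

test_that("path enumeration matches an exhaustive graph-search oracle", {
  skip_if_not_installed("igraph")
  set.seed(42)
  nss <- c("name", paste0("ns", 1:6))
  for (rep in 1:5) {
    # random translation graph over <= 7 namespaces, one quantity sink
    edges <- expand.grid(from = nss, to = nss,
                         stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to, ]
    edges <- edges[runif(nrow(edges)) < 0.25, ]
    qns <- sample(nss, 2)
    ad <- memoryAdapter("g", translations = if (nrow(edges))
      data.frame(from_namespace = edges$from, from_id = "x",
                 to_namespace = edges$to, to_id = "x") else NULL,
      quantities = data.frame(namespace = qns, id = "x",
        quantity_type = "keq", value = 1, unit = "dimensionless"))
    reg <- registerAdapter(newAdapterRegistry(), ad)
    task <- enumerateTasks(g6piNetwork(), "keq")[1, ]
    got <- findPaths(task, g6piNetwork(), reg, maxDepth = 7)
    gotKeys <- sort(vapply(got, function(p)
      paste(c(p$from, p$to[nrow(p)]), collapse = ">"), ""))

    # oracle: igraph simple paths from "name" to each quantity namespace
    g <- igraph::graph_from_data_frame(
      rbind(edges, data.frame(from = nss, to = nss)[0, ]),
      vertices = data.frame(name = nss))
    oracle <- character()
    for (q in qns) {
      if (q == "name") { oracle <- c(oracle, "name>keq"); next }
      sp <- igraph::all_simple_paths(g, from = "name", to = q,
                                     mode = "out")
      for (p in sp) {
        nm <- igraph::as_ids(p)
        if (length(nm) <= 6)   # translation hops + lookup <= 7
          oracle <- c(oracle, paste(c(nm, "keq"), collapse = ">"))
      }
    }
    expect_setequal(gotKeys, sort(oracle))
  }
})

test_that("search is exhaustive, deduplicated and idempotent", {
  net <- randomNetwork(networkSpec(6, 6, seed = 9, pRegulation = 0.1))
  truth <- drawTrueParameters(net, seed = 9)
  dir <- tempfile()
  fx <- makeFixtureDatabases(net, truth, dir, coverage = 1,
                             noiseLogSd = 0, seed = 1)
  reg <- fixtureRegistry(dir)
  wanted <- c("kM", "kcat_forward", "keq", "c", "u", "mu0")
  recs <- executeSearch(net, reg, wanted = wanted)
  # lossless round trip at coverage 1, noise 0
  expect_equal(nrow(recs), nrow(truth))
  m <- merge(recs, fx$planted,
             by.x = c("quantityType", "reaction", "metabolite"),
             by.y = c("QuantityType", "ReactionID", "CompoundID"))
  expect_equal(nrow(m), nrow(truth))
  expect_lt(max(abs(m$value - m$PlantedValue)), 1e-9)
  # idempotence
  recs2 <- executeSearch(net, reg, wanted = wanted)
  expect_identical(recs[order(recs$value), -which(names(recs) ==
                   "provenance")],
                   recs2[order(recs2$value), -which(names(recs2) ==
                   "provenance")])
  # empty record list when no quantity adapters exist
  regT <- registerAdapter(newAdapterRegistry(),
                          fixtureAdapter("xlatA", dir))
  expect_equal(nrow(executeSearch(net, regT, wanted = wanted)), 0)
})

test_that("provenance chains replay to the recorded value", {
  net <- randomNetwork(networkSpec(5, 5, seed = 12))
  truth <- drawTrueParameters(net, seed = 12)
  dir <- tempfile()
  makeFixtureDatabases(net, truth, dir, coverage = 0.5, noiseLogSd = 0.2,
                       seed = 3)
  reg <- fixtureRegistry(dir)
  recs <- executeSearch(net, reg,
                        wanted = c("kM", "kcat_forward", "keq", "c"))
  for (i in seq_len(min(nrow(recs), 10))) {
    prov <- recs$provenance[[i]]
    id <- prov$fromId[1]
    for (k in seq_len(nrow(prov) - 1)) {
      ad <- reg@adapters[[prov$adapter[k]]]
      nxt <- ad$translate(prov$fromNs[k], id, prov$toNs[k])
      expect_true(prov$toId[k] %in% nxt)
      id <- prov$toId[k]
    }
    last <- prov[nrow(prov), ]
    hits <- reg@adapters[[last$adapter]]$lookup(last$fromNs, id,
                                                recs$quantityType[i])
    expect_true(recs$value[i] %in% hits$value)
  }
})

test_that("fixture coverage bookkeeping is exact", {
  net <- randomNetwork(networkSpec(6, 7, seed = 5, pRegulation = 0))
  truth <- drawTrueParameters(net, seed = 5)
  # choose a coverage giving an integral planted count
  n <- nrow(truth)
  cov <- round(0.4 * n) / n
  dir <- tempfile()
  fx <- makeFixtureDatabases(net, truth, dir, coverage = cov,
                             noiseLogSd = 0, seed = 7)
  reg <- fixtureRegistry(dir)
  recs <- executeSearch(net, reg,
    wanted = c("kM", "kcat_forward", "keq", "c", "u", "mu0"))
  expect_equal(nrow(recs) / nrow(truth), cov)
  expect_equal(nrow(fx$planted), round(cov * n))
  # every record reached its value through at least two translation hops
  hops <- vapply(recs$provenance, function(p)
    sum(p$toNs != recs$quantityType[1] &
        seq_len(nrow(p)) < nrow(p)) + 1L, 0L)
  expect_gte(mean(hops >= 2), 0.9)
})

test_that("balancing table round-trips records and enforces units", {
  x <- smallBalanced()
  recs <- x$truth[1:5, ]
  f <- tempfile(fileext = ".tsv")
  writeBalancingTable(recs, f)
  back <- readBalancingTable(f)
  expect_equal(back$quantityType, recs$quantityType)
  expect_equal(back$value, recs$value, tolerance = 1e-12)
  expect_equal(back$reaction, recs$reaction)
  expect_equal(back$metabolite, recs$metabolite)
  expect_equal(back$logSd, recs$logSd)

  # header-only file for an empty record set
  f2 <- tempfile(fileext = ".tsv")
  writeBalancingTable(recs[0, ], f2)
  expect_length(readLines(f2), 1)
  expect_equal(nrow(readBalancingTable(f2)), 0)

  # unit inconsistency rejected with row numbers
  bad <- recs
  bad$unit[2] <- "1/s"
  expect_error(writeBalancingTable(bad, f), "unit inconsistency.*2")
})

test_that("condition filters drop out-of-range records when enabled", {
  ad <- memoryAdapter("q", quantities = data.frame(
    namespace = "name", id = rep("Glucose-6-phosphate isomerase", 2),
    quantity_type = "keq", value = c(1, 2), unit = "dimensionless",
    ph = c(7, 2), temperature_k = c(300, 360)))
  reg <- registerAdapter(newAdapterRegistry(), ad)
  net <- g6piNetwork()
  all <- executeSearch(net, reg, wanted = "keq")
  expect_equal(nrow(all), 2)
  filt <- executeSearch(net, reg, wanted = "keq",
    conditions = list(phRange = c(5, 9)))
  expect_equal(filt$value, 1)
})
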