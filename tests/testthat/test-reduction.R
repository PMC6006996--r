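# Brute-force LP oracle: enumerate candidate vertices of
# {S v = 0, lb <= v <= ub} by fixing (n - rank) free variables at bounds
# and solving the equality system for the rest; return the best feasible
# objective value. Only viable for tiny networks.
vertexOracle <- function(network, objCoef, maximise = TRUE,
                         extraG = NULL, extrag = NULL) {
  S <- stoichiometricMatrix(network)
  Sint <- S[!attr(S, "boundary"), , drop = FALSE]
  r <- reactions(network)
  lb <- pmax(r$lb, -1000); ub <- pmin(r$ub, 1000)
  n <- ncol(Sint)
  best <- NULL
  qrS <- qr(Sint)
  nfree <- n - qrS$rank
  combos <- utils::combn(n, nfree, simplify = FALSE)
  for (fix in combos) {
    grid <- expand.grid(rep(list(c(1, 2)), nfree))
    for (g in seq_len(nrow(grid))) {
      v <- rep(NA_real_, n)
      v[fix] <- ifelse(grid[g, ] == 1, lb[fix], ub[fix])
      rest <- setdiff(seq_len(n), fix)
      A <- Sint[, rest, drop = FALSE]
      b <- -Sint[, fix, drop = FALSE] %*% v[fix]
      sol <- tryCatch(qr.solve(A, b, tol = 1e-10),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v[rest] <- sol
      if (max(abs(Sint %*% v)) > 1e-6) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      if (!is.null(extraG) &&
          any(extraG %*% v < extrag - 1e-7)) next
      val <- sum(objCoef * v)
      if (is.null(best) || (maximise && val > best) ||
          (!maximise && val < best)) best <- val
    }
  }
  best
}

test_that("FBA finds the bottleneck optimum on a linear chain", {
  expect_equal(fbaOptimum(toyChain(uptake = 10))$optimum, 10,
               tolerance = 1e-9)
  # objective with no feasible path carries zero flux
  blocked <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(id = c("EX_A", "BIO"),
      reversible = c(TRUE, FALSE), lb = c(-10, 0), ub = c(10, 1000)),
    stoichiometry = list(EX_A = c(A = 1), BIO = c(B = -1)),
    objective = "BIO")
  expect_equal(fbaOptimum(blocked)$optimum, 0, tolerance = 1e-9)
})

test_that("FBA optimum matches the vertex-enumeration oracle", {
  for (seed in c(2, 5, 9)) {
    net <- randomNetwork(networkSpec(4, 4, seed = seed))
    obj <- as.numeric(reactions(net)$id == objectiveReaction(net))
    got <- fbaOptimum(net)$optimum
    want <- vertexOracle(net, obj)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("FVA ranges match enumeration on structured toys", {
  # single route: min = max at full optimality requirement
  fva <- fluxVariability(toyChain(), fraction = 1)
  expect_equal(fva$min, fva$max, tolerance = 1e-8)
  expect_equal(fva$variability, rep(0, 3), tolerance = 1e-8)

  # dead-end side branch is pinned to zero
  net <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("EX_A", "R1", "DEAD", "BIO"),
      reversible = c(TRUE, FALSE, FALSE, FALSE),
      lb = c(-10, 0, 0, 0), ub = c(10, 1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 1),
                         DEAD = c(A = -1, C = 1), BIO = c(B = -1)),
    objective = "BIO")
  fva2 <- fluxVariability(net, fraction = 1)
  dead <- fva2[fva2$reaction == "DEAD", ]
  expect_equal(c(dead$min, dead$max), c(0, 0), tolerance = 1e-8)

  # two redundant routes share the optimum: ranges match the oracle
  net2 <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B")),
    reactions = data.frame(id = c("EX_A", "P1", "P2", "BIO"),
      reversible = c(TRUE, FALSE, FALSE, FALSE),
      lb = c(-10, 0, 0, 0), ub = c(10, 1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = 1), P1 = c(A = -1, B = 1),
                         P2 = c(A = -1, B = 1), BIO = c(B = -1)),
    objective = "BIO")
  fva3 <- fluxVariability(net2, fraction = 1)
  for (j in seq_len(nrow(fva3))) {
    cj <- as.numeric(seq_len(4) == j)
    G <- matrix(as.numeric(reactions(net2)$id == "BIO"), 1)
    expect_equal(fva3$min[j],
      vertexOracle(net2, cj, FALSE, G, 10), tolerance = 1e-6)
    expect_equal(fva3$max[j],
      vertexOracle(net2, cj, TRUE, G, 10), tolerance = 1e-6)
  }
  expect_equal(fva3[fva3$reaction == "P1", "max"], 10, tolerance = 1e-7)
  expect_equal(fva3[fva3$reaction == "P1", "min"], 0, tolerance = 1e-7)
})

test_that("pruning removes futile reactions first and preserves growth", {
  net <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("EX_A", "R1", "DEAD", "BIO"),
      reversible = c(TRUE, FALSE, FALSE, FALSE),
      lb = c(-10, 0, 0, 0), ub = c(10, 1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 1),
                         DEAD = c(A = -1, C = 1), BIO = c(B = -1)),
    objective = "BIO")
  full <- fbaOptimum(net)$optimum
  pr <- pruneNetwork(net, reductionSpec("BIO"))
  expect_equal(pr$log$reaction[1], "DEAD")
  expect_equal(pr$log$action[1], "removed")
  expect_false("DEAD" %in% reactions(pr$network)$id)
  expect_false("C" %in% metabolites(pr$network)$id)  # orphan dropped
  expect_gte(fbaOptimum(pr$network)$optimum, 0.99 * full)

  # fully protected network is untouched
  spec <- reductionSpec("BIO",
    protectedReactions = reactions(net)$id)
  pr2 <- pruneNetwork(net, spec)
  expect_identical(reactions(pr2$network)$id, reactions(net)$id)
})

test_that("greedy pruning replays deterministically on a toy", {
  net <- randomNetwork(networkSpec(6, 8, seed = 13))
  spec <- reductionSpec(objectiveReaction(net))
  full <- fbaOptimum(net)$optimum
  pr <- pruneNetwork(net, spec)
  expect_gte(fbaOptimum(pr$network, spec$objective)$optimum,
             (1 - spec$growthTolerance) * full - 1e-9)
  # replaying the removal log reproduces the reduced network
  pr2 <- pruneNetwork(net, spec)
  expect_identical(reactions(pr2$network)$id,
                   reactions(pr$network)$id)
  expect_identical(pr2$log, pr$log)
  # removed reactions had the smallest variability among candidates at
  # their step (greedy rule; ties lexicographic)
  expect_true(all(pr$log$action %in% c("removed", "unremovable")))
})

test_that("compression lumps linear chains with multiplier handling", {
  # A -> B -> C with unit coefficients collapses to A -> C
  net <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("EX_A", "R1", "R2", "BIO"),
      reversible = c(TRUE, FALSE, FALSE, FALSE),
      lb = c(-10, 0, 0, 0), ub = c(10, 1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 1),
                         R2 = c(B = -1, C = 1), BIO = c(C = -1)),
    objective = "BIO")
  spec <- reductionSpec("BIO")
  full <- fbaOptimum(net)$optimum
  cp <- compressNetwork(net, spec)
  # the maximal chain EX_A -> A -> B collapses; C feeds the protected
  # objective and survives
  expect_false("B" %in% metabolites(cp$network)$id)
  expect_false("A" %in% metabolites(cp$network)$id)
  lumped <- grep("__", reactions(cp$network)$id, value = TRUE)
  expect_identical(lumped, "EX_A__R1__R2")
  expect_equal(stoichiometry(cp$network)[[lumped]], c(C = 1))
  expect_true(reactions(cp$network)$synthetic[
    reactions(cp$network)$id == lumped])
  # lumped reactions are skipped by the parameter search
  expect_false(lumped %in% enumerateTasks(cp$network)$subject)
  # optimum identical before and after compression
  expect_equal(fbaOptimum(cp$network)$optimum, full, tolerance = 1e-9)

  # A -> 2B, B -> C: lump is 1 R1 + 2 R2 (steady-state coupling v2 = 2 v1)
  net2 <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("EX_A", "R1", "R2", "BIO"),
      reversible = c(TRUE, FALSE, FALSE, FALSE),
      lb = c(-10, 0, 0, 0), ub = c(10, 1000, 1000, 1000)),
    stoichiometry = list(EX_A = c(A = 1), R1 = c(A = -1, B = 2),
                         R2 = c(B = -1, C = 1), BIO = c(C = -1)),
    objective = "BIO")
  cp2 <- compressNetwork(net2, reductionSpec("BIO"))
  lumped2 <- grep("__", reactions(cp2$network)$id, value = TRUE)
  # chain-lumping with multipliers: 1 (EX_A + R1) then 1:2 with R2
  expect_equal(stoichiometry(cp2$network)[[lumped2]], c(C = 2))
  expect_equal(fbaOptimum(cp2$network)$optimum,
               fbaOptimum(net2)$optimum, tolerance = 1e-9)

  # the B -> C step alone: protected A keeps the front of the chain
  cpB <- compressNetwork(net2, reductionSpec("BIO",
    protectedMetabolites = "A"))
  expect_equal(stoichiometry(cpB$network)[["R1__R2"]],
               c(A = -1, C = 2))

  # protected metabolites block lumping entirely
  cp3 <- compressNetwork(net, reductionSpec("BIO",
    protectedMetabolites = c("A", "B")))
  expect_identical(reactions(cp3$network)$id, reactions(net)$id)
})

test_that("prune + compress keeps growth within tolerance end to end", {
  for (seed in c(4, 11)) {
    net <- randomNetwork(networkSpec(7, 9, seed = seed))
    spec <- reductionSpec(objectiveReaction(net))
    full <- fbaOptimum(net)$optimum
    pr <- pruneNetwork(net, spec)
    cp <- compressNetwork(pr$network, spec)
    expect_gte(fbaOptimum(pr$network, spec$objective)$optimum,
               (1 - spec$growthTolerance) * full - 1e-9)
    expect_equal(fbaOptimum(cp$network, spec$objective)$optimum,
                 fbaOptimum(pr$network, spec$objective)$optimum,
                 tolerance = 1e-9)
    expect_lte(nrow(reactions(cp$network)), nrow(reactions(net)))
  }
})
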