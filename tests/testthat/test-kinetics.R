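irrevParams <- function(u = 0.02, kcatf = 5, kM_A = 0.1, kM_B = 0.2) {
  list(kcatf = kcatf, kcatr = 0, kM = c(A = kM_A, B = kM_B),
       kMreg = numeric(0), u = u, h = 1)
}

test_that("rate law closed forms: half-saturation, saturation, regulation", {
  net <- toyAB(reversible = FALSE)
  p <- irrevParams()
  v <- buildRateLaw(net, "R1", p)
  # a = kM, b = 0: v = u kcat+ ((a/kM)=1) / (2 + 1 - 1) = u kcat+ / 2
  expect_equal(v(c(A = 0.1, B = 0)), p$u * p$kcatf / 2,
               tolerance = 1e-12)
  # saturation limit a -> infinity
  expect_equal(v(c(A = 1e9, B = 0)), p$u * p$kcatf, tolerance = 1e-6)

  # one activator at x = kM: f_reg factor 1/2, D_reg term 1
  netA <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B", "X")),
    reactions = data.frame(id = "R1", reversible = FALSE),
    stoichiometry = list(R1 = c(A = -1, B = 1)),
    regulation = data.frame(metabolite = "X", mode = "activator",
                            reaction = "R1"))
  pA <- irrevParams()
  pA$kMreg <- c(X = 0.5)
  vA <- buildRateLaw(netA, "R1", pA)
  # at a = kM and x = kM_X: v = u f_reg kcat+ / (2 + 1 - 1 + D_reg)
  #                           = u (1/2) kcat+ / 3
  expect_equal(vA(c(A = 0.1, B = 0, X = 0.5)),
               p$u * 0.5 * p$kcatf / 3, tolerance = 1e-12)

  netI <- netA
  netI@regulation$mode <- "inhibitor"
  vI <- buildRateLaw(netI, "R1", pA)
  # inhibitor at x = kM: f_reg = 1/2, D_reg = 1
  expect_equal(vI(c(A = 0.1, B = 0, X = 0.5)),
               p$u * 0.5 * p$kcatf / 3, tolerance = 1e-12)

  # zero kM is a construction error; negative concentrations floor with
  # a warning
  bad <- p; bad$kM["A"] <- 0
  expect_error(buildRateLaw(net, "R1", bad), "kM")
  expect_warning(v(c(A = -1, B = 0)), "floored")
})

test_that("reversible flux vanishes at equilibrium concentrations", {
  # parameters built to satisfy the Haldane identity exactly
  net <- toyAB()
  kM <- c(A = 0.2, B = 0.4)
  kV <- 3; u <- 0.01
  mu0 <- c(A = 2, B = -1)
  RT <- balancingConfig()$RT
  lnkeq <- (mu0[["A"]] - mu0[["B"]]) / RT
  half <- (mu0[["B"]] - mu0[["A"]]) / RT + log(kM[["B"]]) - log(kM[["A"]])
  p <- list(kcatf = exp(log(kV) - half / 2),
            kcatr = exp(log(kV) + half / 2),
            kM = kM, kMreg = numeric(0), u = u, h = 1)
  v <- buildRateLaw(net, "R1", p)
  a <- 0.3
  b <- a * exp(lnkeq)         # b/a = keq
  expect_lt(abs(v(c(A = a, B = b))) /
            (p$u * p$kcatf * (a / kM[["A"]])), 1e-12)
})

test_that("compiled flux evaluator agrees with the reference rate law", {
  x <- smallBalanced()
  model <- assembleOdeSystem(x$net, x$bal$balanced)
  set.seed(5)
  for (rep in 1:20) {
    conc <- stats::setNames(runif(nrow(metabolites(x$net)), 0.001, 5),
                            metabolites(x$net)$id)
    vC <- modelFluxes(model, conc)
    for (rid in reactions(x$net)$id) {
      vR <- buildRateLaw(x$net, rid, model@params[[rid]])(conc)
      expect_equal(vC[[rid]], vR, tolerance = 1e-12)
    }
    # RHS equals brute-force S v
    S <- stoichiometricMatrix(x$net)
    expect_equal(unname(modelRHS(model, conc)),
                 unname(drop(S %*% vC)), tolerance = 1e-10)
  }
})

test_that("closed two-species system conserves mass along trajectories", {
  net <- toyAB()
  p <- list(R1 = list(kcatf = 2, kcatr = 1, kM = c(A = 0.5, B = 0.5),
                      kMreg = numeric(0), u = 0.05, h = 1))
  model <- assembleOdeSystem(net, p)
  traj <- simulateModel(model, simulationSchedule(tEnd = 50,
                        gridSize = 51), initial = c(A = 1, B = 0.2))
  tot <- rowSums(traj$conc)
  expect_lt(max(abs(tot - tot[1])), 1e-6)
})

test_that("compartment volumes keep cross-compartment amounts balanced", {
  net <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B"),
                             compartment = c("c1", "c2")),
    reactions = data.frame(id = "R1"),
    stoichiometry = list(R1 = c(A = -1, B = 1)),
    compartments = data.frame(id = c("c1", "c2"), volume = c(1, 2)))
  p <- list(R1 = list(kcatf = 2, kcatr = 1, kM = c(A = 0.5, B = 0.5),
                      kMreg = numeric(0), u = 0.05, h = 1))
  model <- assembleOdeSystem(net, p)
  traj <- simulateModel(model, simulationSchedule(tEnd = 50,
                        gridSize = 51), initial = c(A = 1, B = 0.2))
  amount <- traj$conc[, "A"] * 1 + traj$conc[, "B"] * 2
  expect_lt(max(abs(amount - amount[1])), 1e-6)
})

test_that("inert models stay constant and pulses act discontinuously", {
  net <- toyAB()
  p0 <- list(R1 = list(kcatf = 0, kcatr = 0, kM = c(A = 1, B = 1),
                       kMreg = numeric(0), u = 0.01, h = 1))
  model <- assembleOdeSystem(net, p0)
  sched <- standardSchedule("A", tEnd = 40, gridSize = 41)
  traj <- simulateModel(model, sched, initial = c(A = 2, B = 1))
  # constant except for the x10 pulse of A at t = 20
  expect_equal(unname(traj$conc[traj$time < 20, "A"]),
               rep(2, sum(traj$time < 20)))
  expect_equal(unname(traj$conc[traj$time >= 20, "A"]),
               rep(20, sum(traj$time >= 20)))
  expect_equal(unname(traj$conc[, "B"]), rep(1, 41))
})

test_that("pulse multiplies the pre-pulse level of a live model by 10", {
  x <- smallBalanced()
  model <- assembleOdeSystem(x$net, x$bal$balanced)
  conc <- balancedConcentrations(x$bal$balanced)
  met <- model@stateIds[1]
  sched <- standardSchedule(met, tEnd = 100, gridSize = 101)
  with_pulse <- simulateModel(model, sched, initial = conc)
  without <- simulateModel(model, simulationSchedule(tEnd = 100,
                           gridSize = 101), initial = conc)
  # trajectories agree up to the pulse; at the pulse time the stored
  # (post-pulse) value is 10x the unperturbed (pre-pulse) one
  pre <- with_pulse$time < 50
  expect_equal(with_pulse$conc[pre, ], without$conc[pre, ],
               tolerance = 1e-6)
  i <- which(with_pulse$time == 50)
  expect_equal(with_pulse$conc[i, met], 10 * without$conc[i, met],
               tolerance = 1e-6)
})

test_that("near-linear regime matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  # A -> B -> C with concentrations far below kM: v_j ~ (u kcat+/kM) a
  net <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("R1", "R2"),
                           reversible = c(FALSE, FALSE)),
    stoichiometry = list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1)))
  kM <- 1; u <- 0.01; kcat <- c(2, 3)
  p <- list(
    R1 = list(kcatf = kcat[1], kcatr = 0, kM = c(A = kM, B = kM),
              kMreg = numeric(0), u = u, h = 1),
    R2 = list(kcatf = kcat[2], kcatr = 0, kM = c(B = kM, C = kM),
              kMreg = numeric(0), u = u, h = 1))
  model <- assembleOdeSystem(net, p)
  x0 <- c(A = 1e-6, B = 0, C = 0)
  traj <- simulateModel(model, simulationSchedule(tEnd = 1,
                        gridSize = 11), initial = x0,
                        rtol = 1e-10, atol = 1e-14)
  k <- u * kcat / kM
  J <- matrix(c(-k[1], 0, 0,  k[1], -k[2], 0,  0, k[2], 0),
              3, 3, byrow = TRUE)
  for (ti in c(5, 11)) {
    expected <- as.numeric(Matrix::expm(J * traj$time[ti]) %*% x0)
    expect_equal(unname(traj$conc[ti, ]), expected, tolerance = 1e-6)
  }
})

test_that("trajectories from positive starts stay non-negative", {
  for (seed in c(3, 8)) {
    net <- randomNetwork(networkSpec(8, 8, seed = seed,
                                     pRegulation = 0.1))
    bal <- balanceNetwork(net, drawTrueParameters(net, seed = seed))
    model <- assembleOdeSystem(net, bal$balanced)
    traj <- simulateModel(model,
      standardSchedule(model@stateIds[1], tEnd = 200, gridSize = 101),
      initial = balancedConcentrations(bal$balanced))
    expect_gte(min(traj$conc), -1e-8)
    # left null-space conservation laws hold along the trajectory
    S <- stoichiometricMatrix(net)
    W <- MASS::Null(S)     # w with w' S = 0
    if (is.matrix(W) && ncol(W)) {
      tot <- traj$conc %*% W
      drift <- apply(tot, 2, function(z) max(abs(z - z[1])))
      expect_lt(max(drift), 1e-5)
    }
  }
})

test_that("equilibrium flux residuals vanish for balanced models only", {
  x <- smallBalanced()
  model <- assembleOdeSystem(x$net, x$bal$balanced)
  res <- equilibriumFluxCheck(model, x$bal$balanced)
  rev <- reactions(x$net)$id[reactions(x$net)$reversible]
  expect_setequal(names(res), rev)        # irreversible skipped
  expect_lt(max(res), 1e-10)

  broken <- model
  rid <- names(res)[1]
  broken@params[[rid]]$kcatf <- 2 * broken@params[[rid]]$kcatf
  res2 <- equilibriumFluxCheck(broken, x$bal$balanced)
  expect_gt(res2[[rid]], 1e-3)
})

test_that("boundary species stay fixed and can be pulsed", {
  net <- MetabolicNetwork(
    metabolites = data.frame(id = c("E", "A"),
                             boundary = c(TRUE, FALSE)),
    reactions = data.frame(id = "R1"),
    stoichiometry = list(R1 = c(E = -1, A = 1)))
  p <- list(R1 = list(kcatf = 1, kcatr = 0.5, kM = c(E = 1, A = 1),
                      kMreg = numeric(0), u = 0.1, h = 1))
  model <- assembleOdeSystem(net, p,
                             boundaryConcentrations = c(E = 2))
  expect_identical(model@stateIds, "A")
  traj <- simulateModel(model, simulationSchedule(tEnd = 400),
                        initial = c(A = 0.01, E = 2))
  # A relaxes towards the fixed-E equilibrium, monotonically rising
  expect_true(all(diff(traj$conc[, "A"]) > -1e-9))
  expect_gt(traj$conc[401, "A"], traj$conc[1, "A"])
})

test_that("missing parameters are reported with reaction and quantity", {
  net <- toyAB()
  p <- list(R1 = list(kcatf = 1, kcatr = 1, kM = c(A = 1),
                      kMreg = numeric(0), u = 0.1, h = 1))
  expect_error(assembleOdeSystem(net, p), "R1.*kM")
  expect_error(assembleOdeSystem(net, list()), "missing rate-law")
})
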