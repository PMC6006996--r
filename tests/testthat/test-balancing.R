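cfg <- balancingConfig()
RT <- cfg$RT

test_that("dependency rows reproduce the defining identities on A<->B", {
  net <- toyAB()
  sys <- buildQuantitySystem(net, cfg)
  b <- sys@basics
  # ln keq row: +1/RT on mu0_A, -1/RT on mu0_B, zero elsewhere
  keqRow <- sys@D[which(sys@dependent$type == "lnkeq"), ]
  expect_equal(keqRow[b$type == "mu0" & b$metabolite == "A"], 1 / RT)
  expect_equal(keqRow[b$type == "mu0" & b$metabolite == "B"], -1 / RT)
  expect_equal(sum(keqRow != 0), 2)

  # ln kcat+ row at h = 1: lnkV - (1/2)[(mu0_B - mu0_A)/RT + lnkM_B - lnkM_A]
  kfRow <- sys@D[which(sys@dependent$type == "lnkcatf"), ]
  expect_equal(kfRow[b$type == "lnkV"], 1, ignore_attr = TRUE)
  expect_equal(kfRow[b$type == "mu0" & b$metabolite == "A"], 1 / (2 * RT))
  expect_equal(kfRow[b$type == "mu0" & b$metabolite == "B"], -1 / (2 * RT))
  expect_equal(kfRow[b$type == "lnkM" & b$metabolite == "A"], 1 / 2)
  expect_equal(kfRow[b$type == "lnkM" & b$metabolite == "B"], -1 / 2)

  # vmax rows add ln u to the kcat rows
  vmRow <- sys@D[which(sys@dependent$type == "lnvmaxf"), ]
  expect_equal(vmRow - kfRow,
               as.numeric(b$type == "lnu"), ignore_attr = TRUE)
})

test_that("Haldane identity holds for the rows of random networks", {
  for (seed in 1:3) {
    net <- randomNetwork(networkSpec(8, 8, seed = seed,
                                     pRegulation = 0.1))
    sys <- buildQuantitySystem(net, cfg)
    d <- sys@dependent
    set.seed(seed)
    for (rep in 1:100) {
      q <- rnorm(nrow(sys@basics), 0, 3)
      vals <- drop(sys@D %*% q)
      for (ri in seq_len(nrow(reactions(net)))) {
        rid <- reactions(net)$id[ri]
        h <- reactions(net)$cooperativity[ri]
        st <- stoichiometry(net)[[rid]]
        lnkM <- vapply(names(st), function(m)
          q[sys@basics$type == "lnkM" & sys@basics$reaction == rid &
            sys@basics$metabolite == m], 0)
        lhs <- h * vals[d$type == "lnkeq" & d$reaction == rid]
        rhs <- vals[d$type == "lnkcatf" & d$reaction == rid] -
               vals[d$type == "lnkcatr" & d$reaction == rid] +
               h * sum(st * lnkM)
        expect_lt(abs(lhs - rhs), 1e-10)
      }
    }
  }
})

test_that("prior assembly: dimension, medians, diagonal covariance", {
  net <- toyAB()
  sys <- buildQuantitySystem(net, cfg)
  # 2 mu0 + 2 kM + 1 kV + 1 u + 2 c = 8 basic quantities
  expect_equal(nrow(sys@basics), 8)
  prior <- assemblePriors(sys, cfg)
  expect_length(prior@mean, 8)
  expect_true(all(prior@cov[!diag(8) == 1] == 0))

  cfg2 <- balancingConfig(pseudo = list(kM = c(1, log(10))))
  prior2 <- assemblePriors(sys, cfg2)
  expect_equal(prior2@mean[sys@basics$type == "lnkM"], c(0, 0))
  expect_error(balancingConfig(pseudo = list(kM = c(1, -1))), "std")
})

test_that("measurement rows map records onto the dependency structure", {
  net <- toyAB()
  sys <- buildQuantitySystem(net, cfg)
  rec <- parameterRecord("keq", 2, reaction = "R1")
  meas <- assembleMeasurements(sys, rec, cfg)
  expect_equal(meas$Q[1, ],
               sys@D[which(sys@dependent$type == "lnkeq"), ],
               ignore_attr = TRUE)
  expect_equal(meas$x, log(2))
  expect_equal(meas$noiseVar, log(2)^2)

  empty <- assembleMeasurements(sys, NULL, cfg)
  expect_equal(nrow(empty$Q), 0)

  # stacking equals the row-by-row oracle
  x <- smallBalanced()
  sys2 <- buildQuantitySystem(x$net, cfg)
  recs <- x$truth[sample.int(nrow(x$truth), 10), ]
  all <- assembleMeasurements(sys2, recs, cfg)
  for (i in seq_len(10)) {
    one <- assembleMeasurements(sys2, recs[i, ], cfg)
    expect_equal(all$Q[i, ], one$Q[1, ])
    expect_equal(all$x[i], one$x[1])
  }

  # offender reporting
  bad <- parameterRecord("keq", 1, reaction = "nope")
  expect_error(assembleMeasurements(sys, bad, cfg), "unknown reaction")
  badKm <- parameterRecord("kM", 1, reaction = "R1", metabolite = "A")
  badKm$metabolite <- NA_character_
  expect_error(assembleMeasurements(sys, badKm, cfg), "kM record")
})

test_that("balancing update: conjugate identities", {
  net <- toyAB()
  sys <- buildQuantitySystem(net, cfg)
  prior <- assemblePriors(sys, cfg)
  # zero measurements: posterior is the prior, exactly
  post <- balance(prior, assembleMeasurements(sys, NULL, cfg))
  expect_identical(post@mean, prior@mean)
  expect_identical(post@cov, prior@cov)

  # single measurement of a basic quantity: precision-weighted average
  rec <- parameterRecord("c", 0.5, metabolite = "A", logSd = 0.3)
  meas <- assembleMeasurements(sys, rec, cfg)
  post1 <- balance(prior, meas)
  i <- which(sys@basics$type == "lnc" & sys@basics$metabolite == "A")
  s0 <- prior@cov[i, i]; q0 <- prior@mean[i]
  expected <- (q0 / s0 + log(0.5) / 0.3^2) / (1 / s0 + 1 / 0.3^2)
  expect_equal(post1@mean[i], expected, tolerance = 1e-12)
  expect_equal(post1@cov[i, i], 1 / (1 / s0 + 1 / 0.3^2),
               tolerance = 1e-12)
})

test_that("measurements never inflate variance; precise data dominate", {
  x <- smallBalanced()
  sys <- buildQuantitySystem(x$net, cfg)
  prior <- assemblePriors(sys, cfg)
  meas <- assembleMeasurements(sys, x$truth, cfg)
  post <- balance(prior, meas)
  set.seed(1)
  for (k in 1:25) {
    v <- rnorm(length(prior@mean))
    expect_lte(drop(v %*% post@cov %*% v),
               drop(v %*% prior@cov %*% v) + 1e-8)
  }
  # noise -> 0 on a full-rank basic set pins the posterior means
  basics <- x$truth[x$truth$quantityType %in% c("kM", "c", "u", "mu0"), ]
  basics$logSd <- 1e-6
  post2 <- balance(prior, assembleMeasurements(sys, basics, cfg))
  for (i in seq_len(nrow(basics))) {
    bt <- c(kM = "lnkM", c = "lnc", u = "lnu", mu0 = "mu0")[
      basics$quantityType[i]]
    idx <- which(sys@basics$type == bt &
      (is.na(basics$reaction[i]) | !sys@basics$type %in%
         c("lnkM", "lnu") |
         (!is.na(sys@basics$reaction) &
          sys@basics$reaction == basics$reaction[i])) &
      (is.na(basics$metabolite[i]) |
         (!is.na(sys@basics$metabolite) &
          sys@basics$metabolite == basics$metabolite[i])))
    target <- if (bt == "mu0") basics$value[i] else log(basics$value[i])
    expect_equal(post2@mean[idx[1]], target, tolerance = 1e-4)
  }
})

test_that("derived statistics: symmetry, non-negative variance, medians", {
  net <- toyAB()
  sys <- buildQuantitySystem(net, cfg)
  prior <- assemblePriors(sys, cfg)
  # pin both chemical potentials to the same value with tight records
  recs <- rbind(parameterRecord("mu0", 5, metabolite = "A", logSd = 1e-5),
                parameterRecord("mu0", 5, metabolite = "B", logSd = 1e-5))
  post <- balance(prior, assembleMeasurements(sys, recs, cfg))
  bp <- deriveAllQuantities(sys, post)
  t <- balancedTable(bp)
  expect_equal(t$median[t$type == "keq"], 1, tolerance = 1e-6)
  expect_true(all(t$sd >= 0))
  expect_true(all(t$median[t$scale == "log"] > 0))
})

test_that("residual checks flag broken parameter sets and pass balanced ones", {
  x <- smallBalanced()
  res <- haldaneResiduals(x$bal$balanced, x$net)
  expect_lt(max(abs(res)), 1e-9)

  # doubling one kcat+ shifts that reaction's residual by exactly -ln 2
  tampered <- x$bal$balanced
  i <- which(tampered@table$type == "kcat_forward")[1]
  rid <- tampered@table$reaction[i]
  tampered@table$median[i] <- 2 * tampered@table$median[i]
  res2 <- haldaneResiduals(tampered, x$net)
  expect_equal(res2[[rid]], -log(2), tolerance = 1e-9)
  expect_lt(max(abs(res2[names(res2) != rid])), 1e-9)
})

test_that("Wegscheider cycle sums vanish on cycles and flag tampering", {
  net <- triangleNet()
  truth <- drawTrueParameters(net, seed = 3)
  bal <- balanceNetwork(net, truth)
  w <- wegscheiderResiduals(bal$balanced, net)
  expect_gte(ncol(w$basis), 1)
  expect_lt(max(abs(w$residuals)), 1e-9)

  # acyclic conversion chain: no null-space vector, empty residual set
  chain <- MetabolicNetwork(
    metabolites = data.frame(id = c("A", "B", "C")),
    reactions = data.frame(id = c("R1", "R2")),
    stoichiometry = list(R1 = c(A = -1, B = 1), R2 = c(B = -1, C = 1)))
  balc <- balanceNetwork(chain, NULL)
  wc <- wegscheiderResiduals(balc$balanced, chain)
  expect_length(wc$residuals, 0)

  # a through-pathway over exchange reactions is a null vector too, and
  # its keq log-sum also vanishes on balanced output
  balx <- balanceNetwork(toyChain(), NULL)
  wx <- wegscheiderResiduals(balx$balanced, toyChain())
  expect_gte(length(wx$residuals), 1)
  expect_lt(max(abs(wx$residuals)), 1e-9)

  # scaling one keq by 10 shifts the cycle sum by gamma_j ln 10
  tam <- bal$balanced
  i <- which(tam@table$type == "keq" & tam@table$reaction == "RAB")
  tam@table$median[i] <- 10 * tam@table$median[i]
  w2 <- wegscheiderResiduals(tam, net)
  g <- w2$basis[which(colnames(stoichiometricMatrix(net)) == "RAB"), ]
  expect_equal(abs(w2$residuals), abs(g * log(10)), tolerance = 1e-9)
})

test_that("posterior sampling is seeded, width-scaled and consistent", {
  x <- smallBalanced()
  sys <- x$bal$system; post <- x$bal$posterior
  d0 <- sampleParameters(sys, post, width = 0, seed = 1)
  expect_equal(balancedTable(d0)$median,
               balancedTable(x$bal$balanced)$median, tolerance = 1e-12)
  dA <- sampleParameters(sys, post, width = 1, seed = 7)
  dB <- sampleParameters(sys, post, width = 1, seed = 7)
  expect_identical(balancedTable(dA)$median, balancedTable(dB)$median)
  expect_false(identical(balancedTable(dA)$median,
                         balancedTable(d0)$median))
  expect_error(sampleParameters(sys, post, width = -1), "width")

  # every draw satisfies the thermodynamic identities exactly
  for (s in 1:5) {
    dr <- sampleParameters(sys, post, width = 2, seed = s)
    expect_lt(max(abs(haldaneResiduals(dr, x$net))), 1e-9)
    wr <- wegscheiderResiduals(dr, x$net)
    if (length(wr$residuals)) expect_lt(max(abs(wr$residuals)), 1e-9)
  }
})

test_that("sample covariance of the basic vector matches the posterior", {
  net <- toyAB()
  sys <- buildQuantitySystem(net, cfg)
  prior <- assemblePriors(sys, balancingConfig(
    pseudo = list(mu0 = c(0, 5))))
  rec <- parameterRecord("keq", 2, reaction = "R1", logSd = 0.5)
  post <- balance(prior, assembleMeasurements(sys, rec, cfg))
  n <- 10000
  draws <- matrix(0, n, length(post@mean))
  for (k in seq_len(n)) {
    bp <- sampleParameters(sys, post, width = 1, seed = k)
    draws[k, ] <- balancedTable(bp)$mean[seq_len(length(post@mean))]
  }
  S <- stats::cov(draws)
  relF <- norm(S - post@cov, "F") / norm(post@cov, "F")
  expect_lt(relF, 0.05)
})
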