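test_that("basic chain matches the per-state transition rule", {
  # frozen from direct evaluation of the entry formula at N = 3, p = 0.1
  ch <- basicChain(ChainParams(N = 3, p = 0.1))
  expect_equal(unname(transitionMatrix(ch)),
               rbind(c(0.9, 0.05, 0),
                     c(0.1, 0.80, 0.1),
                     c(0.0, 0.15, 0.7)))
  expect_equal(unname(deathMass(ch)), c(0.05, 0, 0.15))

  p <- 0.0123
  ch8 <- basicChain(ChainParams(N = 8, p = p))
  T <- transitionMatrix(ch8)
  expect_equal(T["2", "1"], p)          # row 2: p, 1-2p, p
  expect_equal(T["2", "2"], 1 - 2 * p)
  expect_equal(T["7", "8"], 7 * p / 2)
  expect_equal(deathMass(ch8)[["8"]], 4 * p)
  expect_equal(deathMass(ch8)[["1"]], p / 2)

  ch0 <- basicChain(ChainParams(N = 3, p = 0))
  expect_equal(unname(transitionMatrix(ch0)), diag(3))
  expect_equal(unname(deathMass(ch0)), rep(0, 3))
})

test_that("M = I + pJ holds entrywise, including the death component", {
  for (N in c(1L, 2L, 5L, 8L, 16L, 32L)) {
    J <- driftMatrix(N)
    for (p in c(1e-4, 1e-2, 1 / N)) {
      ch <- basicChain(ChainParams(N = N, p = p))
      expect_equal(unname(transitionMatrix(ch)),
                   diag(N) + p * unname(transitionMatrix(J)),
                   tolerance = 1e-14)
      expect_equal(unname(deathMass(ch)), p * unname(deathMass(J)),
                   tolerance = 1e-14)
    }
    expect_equal(unname(transitionMatrix(J)), oracleJ(N))
  }
  expect_equal(unname(transitionMatrix(driftMatrix(1))),
               matrix(-1, 1, 1))
  expect_equal(unname(transitionMatrix(driftMatrix(2))),
               rbind(c(-1, 1 / 2), c(1, -2)))
})

test_that("scored chain is the survival scaling D applied to M", {
  # D = I collapses to the basic chain
  chB <- basicChain(ChainParams(N = 6, p = 0.01))
  chS <- scoredChain(ChainParams(N = 6, p = 0.01, mu = 1, C = 1))
  expect_equal(transitionMatrix(chS), transitionMatrix(chB))
  expect_equal(deathMass(chS), deathMass(chB))

  # entrywise formula and the explicit 2x2 product D %*% M
  p <- 0.01; mu <- 1.0004
  ch2 <- suppressWarnings(scoredChain(ChainParams(N = 2, p = p, mu = mu)))
  M2 <- rbind(c(1 - p, p / 2), c(p, 1 - 2 * p))
  D2 <- diag(c(mu, mu^2))
  expect_equal(unname(transitionMatrix(ch2)), D2 %*% M2,
               tolerance = 1e-15)

  ch <- scoredChain(ChainParams(N = 8, p = 0.0025, mu = 0.9996, C = 0.9))
  expect_equal(unname(transitionMatrix(ch)),
               oracleA(8, 0.0025, 0.9996, 0.9), tolerance = 1e-14)
  # death mass covers missegregation loss plus spontaneous death
  q <- 0.9 * 0.9996^(1:8)
  M <- oracleM(8, 0.0025)
  expect_equal(unname(deathMass(ch)), 1 - q * rowSums(M),
               tolerance = 1e-14)
})

test_that("duplication chain implements the genome-duplication rule", {
  par0 <- ChainParams(N = 8, p = 0.005, pGd = 0)
  expect_equal(transitionMatrix(duplicationChain(par0)),
               transitionMatrix(basicChain(par0)))

  pgd <- 0.002
  ch <- duplicationChain(ChainParams(N = 8, p = 0.005, pGd = pgd))
  chB <- basicChain(ChainParams(N = 8, p = 0.005))
  T <- transitionMatrix(ch); TB <- transitionMatrix(chB)
  expect_equal(T["3", "6"], TB["3", "6"] + pgd / 2)
  expect_equal(T["3", "3"], TB["3", "3"] - pgd)
  # 2i > N: the duplicated daughter is dead
  expect_equal(deathMass(ch)[["5"]],
               deathMass(chB)[["5"]] + pgd / 2 + pgd / 2)
  # 2i <= N: only the never-created daughter adds death mass
  expect_equal(deathMass(ch)[["3"]], deathMass(chB)[["3"]] + pgd / 2)

  # per-state rates: e.g. tenfold duplication rate from 3 copies up
  pv <- c(1e-4, 1e-4, rep(1e-3, 6))
  chv <- duplicationChain(ChainParams(N = 8, p = 0.005, pGd = pv))
  Tv <- transitionMatrix(chv)
  expect_equal(Tv["2", "4"], TB["2", "4"] + 1e-4 / 2)
  expect_equal(Tv["4", "8"], TB["4", "8"] + 1e-3 / 2)

  expect_error(duplicationChain(ChainParams(N = 8, p = 0.124, pGd = 0.1)),
               "negative diagonal")
})

test_that("inactivation chain reproduces the sigma/tau entries", {
  p <- 0.001; mr <- 1e-6
  ch <- inactivationChain(ChainParams(N = 8, p = p, mR = mr))
  T <- transitionMatrix(ch)
  ns <- (1 - p)^46
  q2 <- 1                                  # mu = C = 1
  expect_equal(T["sigma", "sigma"], (ns - 2 * mr) * q2)
  expect_equal(T["sigma", "tau"], 2 * mr * q2)
  expect_equal(T["tau", "sigma"], 0)
  expect_equal(T["tau", "tau"], (ns - mr) * q2)
  expect_equal(T["tau", "1"], (p / 2) * q2)
  expect_equal(T["tau", "2"], mr * q2)
  expect_equal(unname(T["sigma", as.character(1:8)]), rep(0, 8))
  expect_equal(unname(T[as.character(1:8), "sigma"]), rep(0, 8))
  expect_equal(unname(T[as.character(1:8), "tau"]), rep(0, 8))
  expect_equal(unname(T["tau", as.character(3:8)]), rep(0, 6))
  # the copy-number block is the score chain
  expect_equal(unname(T[as.character(1:8), as.character(1:8)]),
               unname(transitionMatrix(scoredChain(
                 ChainParams(N = 8, p = p)))))
  # row sums from summing the printed entries
  expect_equal(sum(T["sigma", ]), ns * q2)
  expect_equal(sum(T["tau", ]), (ns + p / 2) * q2)

  # no missegregation, no mutation: sigma and tau are absorbing
  ch0 <- inactivationChain(ChainParams(N = 8, p = 0, mR = 0))
  expect_equal(transitionMatrix(ch0)["sigma", "sigma"], 1)
  expect_equal(transitionMatrix(ch0)["tau", "tau"], 1)

  expect_error(inactivationChain(ChainParams(N = 8, p = 0.2, mR = 0.4)),
               "negative")
})

test_that("every built chain conserves probability row by row", {
  params <- list(
    basicChain(ChainParams(N = 8, p = 0.0025)),
    basicChain(ChainParams(N = 16, p = 1 / 16)),
    scoredChain(ChainParams(N = 8, p = 0.001, mu = 1.0012, C = 0.99)),
    scoredChain(ChainParams(N = 12, p = 0.01, mu = 0.9994)),
    duplicationChain(ChainParams(N = 8, p = 0.0025, pGd = 1e-3,
                                 mu = 0.9996)),
    duplicationChain(ChainParams(N = 9, p = 0.005,
                                 pGd = c(rep(1e-4, 2), rep(1e-3, 7)))),
    inactivationChain(ChainParams(N = 8, p = 0.0025, mR = 1e-4)))
  for (ch in params) {
    tot <- rowSums(transitionMatrix(ch)) + deathMass(ch)
    expect_equal(unname(tot), rep(1, length(chainStates(ch))),
                 tolerance = 1e-14)
    expect_true(all(transitionMatrix(ch) >= 0))
  }
})

test_that("extended builders collapse to the basic chain", {
  par <- ChainParams(N = 8, p = 0.0025, mu = 1, C = 1, pGd = 0, mR = 0)
  base <- basicChain(par)
  expect_equal(transitionMatrix(scoredChain(par)),
               transitionMatrix(base))
  expect_equal(transitionMatrix(duplicationChain(par)),
               transitionMatrix(base))
  axT <- transitionMatrix(inactivationChain(par))
  expect_equal(unname(axT[as.character(1:8), as.character(1:8)]),
               unname(transitionMatrix(base)))
})

test_that("survival factors multiply to the karyotype survival", {
  expect_equal(survivalFactor(ChainParams(N = 8, mu = 1, C = 1), 5), 1)
  cc <- -0.036132164
  expect_equal(survivalFactor(ChainParams(N = 8, C = exp(cc / 23)), 2),
               exp(cc / 23))

  st <- stdScores()
  # score-free limit: Q_surv = e^c for any karyotype
  st0 <- ScoreTable(score = rep(0, 23))
  expect_equal(karyotypeSurvival(st0, rep(2, 23)), exp(st0@c))
  expect_equal(karyotypeSurvival(st0, c(rep(1, 10), rep(8, 13))),
               exp(st0@c))

  # diploid cell against a direct scalar evaluation
  expect_equal(karyotypeSurvival(st, rep(2, 23)),
               exp(st@c + 2 * st@d * sum(st@score)), tolerance = 1e-15)

  # factorisation: product of 23 per-chromosome factors with C = e^{c/23}
  set.seed(42)
  mu <- muValues(st)
  for (rep in 1:100) {
    kar <- sample(1:8, 23, replace = TRUE)
    direct <- karyotypeSurvival(st, kar)
    viaMu <- exp(st@c + sum(kar * log(mu)))
    factors <- exp(st@c / 23) * mu^kar
    expect_equal(prod(factors), viaMu, tolerance = 1e-12)
    # mu carries 9 printed decimals, so the two routes agree to ~1e-7
    expect_equal(viaMu, direct, tolerance = 1e-6)
  }
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(basicChain(ChainParams(N = 8, p = 0.2)), "state")
  expect_error(basicChain(ChainParams(N = 8, p = 0.2)), "1/8")
  expect_error(ChainParams(N = 0), "N must be")
  expect_error(ChainParams(p = -0.1), "probability")
  expect_error(ChainParams(mu = -1), "positive")
  expect_error(ChainParams(mR = 2), "probability")
  expect_warning(scoredChain(ChainParams(N = 8, p = 0.001, mu = 1.001)),
                 "exceeds 1")
  expect_warning(survivalFactor(ChainParams(N = 8, mu = 1.1), 8),
                 "exceeds 1")
})
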