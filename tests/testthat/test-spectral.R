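test_that("minor recurrence matches a dense determinant oracle", {
  skip_if_not_installed("pracma")
  # basic, N = 4: coefficients of det(xI - J)
  cp <- charPolyBasic(4)
  oracle <- rev(pracma::charpoly(oracleJ(4)))   # ascending
  expect_equal(cp@polys[[5]], oracle, tolerance = 1e-12)

  # scored, N = 3
  p <- 0.01; mu <- 1.0004
  cps <- charPolyScored(3, p, mu)
  oracleS <- rev(pracma::charpoly(oracleA(3, p, mu)))
  expect_equal(cps@polys[[4]], oracleS, tolerance = 1e-9)

  # printed initial conditions
  expect_equal(charPolyBasic(1)@polys[[2]], c(1, 1))          # x + 1
  expect_equal(charPolyScored(1, p, mu)@polys[[2]],
               c(-mu * (1 - p), 1))                           # x - mu(1-p)
})

test_that("largest root agrees with closed forms and the eigensolver", {
  expect_equal(largestRoot(charPolyBasic(1)), -1)
  expect_equal(largestRoot(charPolyBasic(2)), (-3 + sqrt(3)) / 2,
               tolerance = 1e-12)
  for (N in c(4, 8, 16)) {
    alpha <- largestRoot(charPolyBasic(N))
    expect_equal(alpha, max(eigen(oracleJ(N))$values),
                 tolerance = 1e-9)
  }
  p <- 0.0025
  for (mu in c(0.9994, 1, 1.0012)) {
    cps <- charPolyScored(8, p, mu)
    ev <- sort(eigen(oracleA(8, p, mu))$values, decreasing = TRUE)
    expect_equal(largestRoot(cps), ev[1], tolerance = 1e-9)
    expect_equal(largestRoot(cps, which = 2), ev[2], tolerance = 1e-9)
    expect_equal(largestRoot(cps, which = 8), ev[8], tolerance = 1e-9)
  }
  # eigenvalue shift: roots of the scored recurrence at mu = 1 are
  # 1 + p * (roots of the basic recurrence)
  for (k in 1:4)
    expect_equal(largestRoot(charPolyScored(6, p, 1), which = k),
                 1 + p * largestRoot(charPolyBasic(6), which = k),
                 tolerance = 1e-10)
})

test_that("limiting distribution is p-independent and matches eigen", {
  for (N in c(4L, 6L, 8L, 12L, 16L)) {
    closed <- limitingBasic(N)
    expect_true(all(limitDist(closed) > 0))
    for (p in c(1e-5, 1e-3, 0.1 / N)) {
      num <- quasiStationary(basicChain(ChainParams(N = N, p = p)))
      expect_equal(unname(limitDist(num)), unname(limitDist(closed)),
                   tolerance = 1e-9)
    }
    # against the raw oracle too
    expect_equal(unname(limitDist(closed)),
                 oracleQSD(oracleM(N, 1e-3))$v, tolerance = 1e-9)
  }
})

test_that("eigenvector formula from the minor sequence spans the spectrum", {
  for (N in c(3L, 6L, 10L)) {
    J <- oracleJ(N)
    ev <- eigen(t(J))
    cp <- charPolyBasic(N)
    for (k in seq_len(N)) {
      lam <- Re(ev$values[k])
      # v_i = P_{i-1}(lambda) / prod_{j=2}^{i} a_{j,j-1}, a_{j,j-1} = j/2
      vi <- vapply(seq_len(N), function(i) {
        Pim1 <- sum(cp@polys[[i]] * lam^(seq_along(cp@polys[[i]]) - 1))
        denom <- if (i == 1) 1 else prod((2:i) / 2)
        Pim1 / denom
      }, numeric(1))
      ref <- Re(ev$vectors[, k])
      vi <- vi / sqrt(sum(vi^2))
      ref <- ref / sqrt(sum(ref^2))
      if (sum(vi * ref) < 0) ref <- -ref
      expect_equal(vi, ref, tolerance = 1e-6)
    }
  }
})

test_that("full spectrum shifts as 1 + p*lambda between J and M", {
  N <- 8; p <- 0.0071
  lamJ <- sort(eigen(oracleJ(N))$values)
  lamM <- sort(eigen(unname(transitionMatrix(
    basicChain(ChainParams(N = N, p = p))))) $values)
  expect_equal(lamM, 1 + p * lamJ, tolerance = 1e-10)
})

test_that("limiting mean copy number increases with the bound N", {
  means <- vapply(6:16, function(N) meanCopies(limitingBasic(N)),
                  numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("score-chain limiting distribution behaves with p, mu and C", {
  ps <- c(0.001, 0.0025, 0.005, 0.01)
  # oncogenic chromosome: mean decreases as missegregation increases
  mOn <- vapply(ps, function(p) meanCopies(limitingScored(8, p, 1.0004)),
                numeric(1))
  expect_true(all(diff(mOn) < 0))
  # tumor-suppressive chromosome: mean increases with p
  mOff <- vapply(ps, function(p) meanCopies(limitingScored(8, p, 0.9996)),
                 numeric(1))
  expect_true(all(diff(mOff) > 0))

  # mu = 1 collapses to the basic model for every p
  for (p in ps)
    expect_equal(unname(limitDist(limitingScored(8, p, 1))),
                 unname(limitDist(limitingBasic(8))), tolerance = 1e-10)

  # the constant C rescales the chain but not its limit
  for (C in c(0.5, 1)) {
    num <- suppressWarnings(quasiStationary(
      scoredChain(ChainParams(N = 8, p = 0.0025, mu = 1.0004, C = C))))
    expect_equal(unname(limitDist(num)),
                 unname(limitDist(limitingScored(8, 0.0025, 1.0004))),
                 tolerance = 1e-9)
  }
})

test_that("second eigenvalue and mixing estimate match the eigen route", {
  qs <- limitingBasic(8, p = 0.004)
  ev <- sort(eigen(oracleM(8, 0.004))$values, decreasing = TRUE)
  expect_equal(qs@rho, ev[1], tolerance = 1e-10)
  expect_equal(qs@rhoTilde, max(abs(ev[-1])), tolerance = 1e-10)
  expect_equal(mixingEstimate(qs), 1 / (1 - ev[2] / ev[1]),
               tolerance = 1e-7)
  num <- quasiStationary(basicChain(ChainParams(N = 8, p = 0.004)))
  expect_equal(mixingEstimate(num), mixingEstimate(qs),
               tolerance = 1e-7)
})

test_that("growth rate and culling threshold", {
  expect_equal(growthRate(limitingBasic(8), p = 0)[["rate"]], 2)
  expect_equal(growthRate(limitingBasic(8), p = 0)[["threshold"]], 0.5)

  # basic: monotone decreasing in p, matching the eigensolver pointwise
  qs <- limitingBasic(8)
  ps <- 10^seq(-5, -1.2, length.out = 12)
  rates <- vapply(ps, function(p) growthRate(qs, p)[["rate"]],
                  numeric(1))
  expect_true(all(diff(rates) < 0))
  for (p in c(1e-4, 1e-2)) {
    rhoEig <- oracleQSD(oracleM(8, p))$rho
    expect_equal(growthRate(qs, p)[["rate"]], 2 * rhoEig^23,
                 tolerance = 1e-9)
  }

  # full model with probability-valued survival factors never beats
  # the score-free chain
  mod <- KaryotypeModel(stdScores(), p = 0.0025, founder = 4)
  alphas <- vapply(mod@chains, function(ch) quasiStationary(ch)@rho,
                   numeric(1))
  full <- growthRate(alphas)
  expect_lte(full[["rate"]], growthRate(qs, 0.0025)[["rate"]] + 1e-12)
  expect_equal(full[["threshold"]], 1 / full[["rate"]])
})
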