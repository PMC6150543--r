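test_that("karyotype probability is a product of per-chain entries", {
  mod <- KaryotypeModel(stdScores(), p = 0.0025, N = 8, founder = 4)
  # generation 0: point mass at the founder karyotype
  expect_equal(karyotypeProbability(mod, rep(4, 23), 0), 1)
  expect_equal(karyotypeProbability(mod, c(3, rep(4, 22)), 0), 0)

  # small-g product against explicit matrix powers of each chain
  g <- 3
  set.seed(11)
  for (rep in 1:5) {
    kar <- pmin(pmax(rnorm(23, 4, 1), 1), 8)
    kar <- as.integer(round(kar))
    manual <- prod(vapply(1:23, function(k) {
      T <- unname(transitionMatrix(mod@chains[[k]]))
      Tg <- T %*% T %*% T
      Tg[4, kar[k]]
    }, numeric(1)))
    expect_equal(karyotypeProbability(mod, kar, g), manual,
                 tolerance = 1e-12)
  }

  # conditional variant divides by the survival product
  kar <- rep(4, 23)
  sProd <- exp(sum(vapply(mod@chains, function(ch)
    survivingFraction(ch, 4, g, log = TRUE), numeric(1))))
  expect_equal(karyotypeProbability(mod, kar, g, conditional = TRUE),
               karyotypeProbability(mod, kar, g) / sProd,
               tolerance = 1e-12)
})

test_that("expected population matches the survival-product identity", {
  # score-free, deathless limit: pure doubling
  st0 <- ScoreTable(score = rep(0, 23), c = 0)
  mod0 <- KaryotypeModel(st0, p = 0, founder = 2)
  expect_equal(expectedPopulation(mod0, 12, log = FALSE), 2^12)

  # the split of c across chromosomes is immaterial
  st <- stdScores()
  g <- 400
  even <- suppressWarnings(KaryotypeModel(st, p = 0.0025, founder = 4,
                                          cSplit = "even"))
  auto <- KaryotypeModel(st, p = 0.0025, founder = 4)
  lopsided <- suppressWarnings(KaryotypeModel(
    st, p = 0.0025, founder = 4, cSplit = c(st@c, rep(0, 22))))
  expect_equal(expectedPopulation(even, g), expectedPopulation(auto, g),
               tolerance = 1e-10)
  expect_equal(expectedPopulation(lopsided, g),
               expectedPopulation(auto, g), tolerance = 1e-10)

  # identity with per-chain surviving fractions
  direct <- g * log(2) + sum(vapply(1:23, function(k)
    survivingFraction(auto@chains[[k]], 4, g, log = TRUE), numeric(1)))
  expect_equal(expectedPopulation(auto, g), direct, tolerance = 1e-12)
})

test_that("diversity index is an entropy over marginals", {
  # degenerate marginals carry no diversity
  point <- matrix(0, 23, 8); point[, 3] <- 1
  expect_equal(diversityIndex(point), 0)
  # maximum entropy: uniform copy numbers on all chromosomes
  expect_equal(diversityIndex(matrix(1 / 8, 23, 8)), 23 * log(8))
  # additivity: one fair coin among point masses
  coin <- point; coin[7, ] <- c(0.5, 0.5, rep(0, 6))
  expect_equal(diversityIndex(coin), log(2))
  # additivity against per-row entropies on random marginals
  set.seed(3)
  a <- matrix(rgamma(23 * 8, 1), 23, 8)
  a <- a / rowSums(a)
  expect_equal(diversityIndex(a), sum(apply(a, 1, rowEntropy)))
  expect_error(diversityIndex(-a), "nonnegative")
  expect_error(diversityIndex(a * 2), "sum to 1")
})

test_that("diversity surface converges to the limiting diversity", {
  st <- stdScores()
  mod <- KaryotypeModel(st, p = 0.001, founder = 4)
  ds <- diversitySurface(mod, gGrid = c(100L, 100000L),
                         pGrid = c(1e-3, 1e-2))
  # marginals are proper distributions and K obeys the entropy bound
  expect_true(all(abs(apply(ds@marginals, c(1, 2, 3), sum) - 1) < 1e-12))
  expect_true(all(ds@K >= 0 & ds@K <= 23 * log(8) + 1e-9))

  # large-g column equals the limiting-distribution diversity
  for (j in 1:2) {
    p <- ds@pGrid[j]
    limK <- sum(vapply(muValues(st), function(mu)
      rowEntropy(unname(limitDist(limitingScored(8, p, mu)))),
      numeric(1)))
    expect_equal(ds@K[2, j], limK, tolerance = 1e-6)
  }

  # near-stability along pg = const while g is moderate
  modF <- KaryotypeModel(st, p = 0.001, founder = 4)
  dsc <- diversitySurface(modF, gGrid = c(100L, 1000L),
                          pGrid = c(1e-2, 1e-3))
  expect_lt(abs(dsc@K[1, 1] - dsc@K[2, 2]) /
              max(dsc@K[1, 1], dsc@K[2, 2]), 0.10)
})

test_that("generation of maximal diversity shifts earlier as p grows", {
  mod <- KaryotypeModel(stdScores(), p = 0.001, founder = 4)
  gGrid <- as.integer(round(10^seq(1, 4.5, by = 0.25)))
  ds <- diversitySurface(mod, gGrid = gGrid,
                         pGrid = c(1e-3, 3e-3, 1e-2))
  gOpt <- gGrid[apply(ds@K, 2, which.max)]
  expect_true(all(diff(gOpt) <= 0))
})

test_that("optimal p for survival: degenerate and scored cases", {
  # deathless score-free model: survival decreases in p, smallest wins
  st0 <- ScoreTable(score = rep(0, 23), c = 0)
  mod0 <- KaryotypeModel(st0, p = 0.001, founder = 4)
  grid <- 10^seq(-4, -2, by = 0.5)
  op0 <- optimalP(mod0, g = 200, objective = "surviving", pGrid = grid,
                  refine = FALSE)
  expect_equal(op0$p, min(grid))

  # with the human scores the optimum is interior and moves left with g
  mod <- KaryotypeModel(stdScores(), p = 0.001, founder = 4)
  p500 <- optimalP(mod, g = 500, objective = "surviving",
                   pGrid = 10^seq(-5, -2, by = 0.5))$p
  p2000 <- optimalP(mod, g = 2000, objective = "surviving",
                    pGrid = 10^seq(-5, -2, by = 0.5))$p
  expect_lte(p2000, p500)
  # the combined surviving x diversity objective is also interior
  opK <- optimalP(mod, g = 500, objective = "survivingK",
                  pGrid = 10^seq(-5, -2, by = 0.5))
  expect_gt(opK$p, 1e-5)
  expect_lt(opK$p, 1e-2)
})

test_that("per-chromosome marginals factorise exactly", {
  mod <- KaryotypeModel(stdScores(), p = 0.0025, founder = 2)
  g <- 40
  mm <- karyoMC:::modelMarginals(mod, g)
  for (k in c(1L, 7L, 23L)) {
    tr <- propagate(mod@chains[[k]], 2, g)
    expect_equal(mm$marginals[k, ], unname(conditionalDist(tr, g)),
                 tolerance = 1e-12)
  }
})
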