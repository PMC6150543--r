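## The 23-chromosome product chain.  All population-level quantities
## factorise over the per-chromosome chains (karyotype probabilities,
## surviving fractions, diversity), so the N^23 joint state space is
## never enumerated.

#' Construct a 23-chromosome karyotype model
#'
#' Builds the product of 23 per-chromosome score chains sharing
#' \code{N}, \code{p} and \code{pGd}, with the survival multiplier
#' \eqn{\mu_k} of each chromosome taken from a score table.  The
#' per-chromosome survival constants default to the even split
#' \eqn{c_k = c/23}; any split summing to \eqn{c} yields the same
#' product-chain law.
#'
#' @param scores a [ScoreTable-class] (e.g. [hg23Scores()]).
#' @param p missegregation rate.
#' @param N maximum allowed copy number (default 8).
#' @param founder founder karyotype: a single copy number recycled to
#'   all chromosomes, or a 23-vector.
#' @param pGd genome-duplication rate (scalar or per-state vector);
#'   0 disables duplication.
#' @param cSplit per-chromosome constants \eqn{c_k}: \code{"auto"}
#'   (default) chooses a split with every \eqn{q_k(i) \le 1} so the
#'   per-chromosome factors are probabilities, \code{"even"} uses
#'   \eqn{c_k = c/23} (which can push \eqn{q_k(i)} above 1 for strongly
#'   oncogenic chromosomes), or a numeric 23-vector.  Any split summing
#'   to \eqn{c} gives the same product-chain law.
#' @return A [KaryotypeModel-class].
#' @examples
#' mod <- KaryotypeModel(hg23Scores(), p = 0.0025, founder = 4)
#' @export
KaryotypeModel <- function(scores, p, N = 8, founder = 2,
                           pGd = 0, cSplit = c("auto", "even")) {
  stopifnot(is(scores, "ScoreTable"))
  if (is.character(cSplit))
    cSplit <- switch(match.arg(cSplit),
                     auto = feasibleCSplit(scores, N),
                     even = rep(scores@c / 23, 23))
  if (abs(sum(cSplit) - scores@c) > 1e-12 * max(1, abs(scores@c)))
    stop("cSplit must sum to the score table's constant c", call. = FALSE)
  founder <- as.integer(rep_len(founder, 23L))
  ord <- order(scores@chromosome)
  mu <- scores@mu[ord]
  chains <- vector("list", 23L)
  for (k in 1:23) {
    par <- ChainParams(N = N, p = p, mu = mu[k], C = exp(cSplit[k]),
                       pGd = pGd)
    chains[[k]] <- if (any(pGd > 0)) duplicationChain(par)
                   else scoredChain(par)
  }
  new("KaryotypeModel", chains = chains, founder = founder,
      scoreTable = scores, N = as.integer(N), p = p,
      pGd = as.numeric(pGd))
}

## a constant split with q_k(i) = e^{c_k} mu_k^i <= 1 for all i in
## [1, N]: set c_k = -max_i(i log mu_k) and spread the (negative)
## remainder of c evenly; feasible whenever Q_surv <= 1 for all valid
## karyotypes.  Built from the table's mu values so that tiny rounding
## differences between mu and e^{d s} cannot push any q above 1.
feasibleCSplit <- function(scores, N) {
  ord <- order(scores@chromosome)
  lmu <- log(scores@mu[ord])
  ck <- -pmax(N * lmu, lmu)
  r <- scores@c - sum(ck)
  if (r > 1e-9)
    stop("survival constant c is too large: Q_surv exceeds 1 for some ",
         "valid karyotype, no probability split exists", call. = FALSE)
  ck + r / 23
}

#' Probability of a karyotype after g generations
#'
#' The probability that a random surviving lineage started from the
#' model's founder karyotype has exactly the given karyotype after
#' \code{g} generations, as a product over chromosomes of the
#' \eqn{(f_k \to n_k)} entries of the g-th matrix powers.  The
#' unnormalised value is a fraction of the \eqn{2^g} cells an undying
#' population would have; the conditional variant divides by the
#' product of surviving fractions \eqn{\prod_k s_g^{(k)}(f_k)}.
#'
#' @param model a [KaryotypeModel-class].
#' @param karyotype integer 23-vector of copy numbers in \code{[1, N]}.
#' @param g number of generations.
#' @param conditional condition on lineage viability.
#' @return A probability.
#' @export
karyotypeProbability <- function(model, karyotype, g,
                                 conditional = FALSE) {
  stopifnot(is(model, "KaryotypeModel"), length(karyotype) == 23L,
            all(karyotype >= 1), all(karyotype <= model@N))
  logp <- 0
  for (k in 1:23) {
    ch <- model@chains[[k]]
    r <- powerStep(ch, resolveInitial(ch, model@founder[k]), g)
    pk <- r$cond[match(as.character(karyotype[k]), ch@states)]
    if (pk <= 0) return(0)
    logp <- logp + log(pk) + if (conditional) 0 else r$logSurv
  }
  exp(logp)
}

#' Expected viable population size
#'
#' The expected number of viable cells after \code{g} generations,
#' \eqn{2^g \prod_k s_g^{(k)}(f_k)}, returned in log space (natural
#' log) by default.  The value is independent of how the survival
#' constant \eqn{c} is split across chromosomes.
#'
#' @param model a [KaryotypeModel-class].
#' @param g number of generations.
#' @param log return the natural log (default); \code{FALSE} returns
#'   the linear value, which may overflow for large \code{g}.
#' @return Expected population size (log or linear).
#' @export
expectedPopulation <- function(model, g, log = TRUE) {
  stopifnot(is(model, "KaryotypeModel"), g >= 0)
  ls <- vapply(seq_len(23L), function(k) {
    ch <- model@chains[[k]]
    powerStep(ch, resolveInitial(ch, model@founder[k]), g)$logSurv
  }, numeric(1))
  out <- g * log(2) + sum(ls)
  if (log) out else exp(out)
}

#' Karyotype diversity index
#'
#' The summed Shannon entropy (natural log) of the per-chromosome
#' copy-number fractions among viable cells:
#' \eqn{K = -\sum_k \sum_j a_{k,j} \ln a_{k,j}}, with
#' \eqn{0 \ln 0 = 0}.  \eqn{K} ranges from 0 (every chromosome's copy
#' number is deterministic) to \eqn{23 \ln N} (all marginals uniform).
#'
#' @param marginals numeric matrix, one row per chromosome, of viable
#'   copy-number fractions; each row must sum to 1.
#' @return The diversity index \eqn{K}.
#' @examples
#' diversityIndex(matrix(1/8, 23, 8))  # maximum: 23 * log(8)
#' @export
diversityIndex <- function(marginals) {
  marginals <- as.matrix(marginals)
  if (any(marginals < 0))
    stop("marginals must be nonnegative", call. = FALSE)
  if (any(abs(rowSums(marginals) - 1) > 1e-9))
    stop("each marginal must sum to 1", call. = FALSE)
  terms <- ifelse(marginals > 0, marginals * log(marginals), 0)
  -sum(terms)
}

## 23 x N matrix of conditional copy-number marginals at generation g,
## plus the summed log surviving fraction
modelMarginals <- function(model, g) {
  a <- matrix(0, 23L, model@N)
  logS <- 0
  for (k in 1:23) {
    ch <- model@chains[[k]]
    r <- powerStep(ch, resolveInitial(ch, model@founder[k]), g)
    a[k, ] <- r$cond
    logS <- logS + r$logSurv
  }
  list(marginals = a, logSurviving = logS)
}

#' Karyotype diversity surface K(g, p)
#'
#' Evaluates the diversity index and the surviving fraction on a grid
#' of generation counts and missegregation rates, rebuilding the
#' model's chains for each \code{p}.  Matrix powers by repeated
#' squaring make generation counts up to \eqn{10^6} cheap.  As
#' \eqn{g \to \infty} each column of \code{K} converges to the
#' diversity of the limiting distribution at that \code{p}.
#'
#' @param model a [KaryotypeModel-class] (its \code{p} is ignored; the
#'   grid supplies it).
#' @param gGrid integer vector of generation counts.
#' @param pGrid numeric vector of missegregation rates in
#'   \code{(0, 1/N]}.
#' @return A [DiversitySurface-class].
#' @export
diversitySurface <- function(model, gGrid, pGrid) {
  stopifnot(is(model, "KaryotypeModel"),
            length(gGrid) >= 1L, length(pGrid) >= 1L)
  gGrid <- as.integer(gGrid)
  K <- matrix(NA_real_, length(gGrid), length(pGrid),
              dimnames = list(gGrid, pGrid))
  logS <- K
  marg <- array(NA_real_,
                dim = c(length(gGrid), length(pGrid), 23L, model@N))
  for (j in seq_along(pGrid)) {
    mj <- KaryotypeModel(model@scoreTable, p = pGrid[j], N = model@N,
                         founder = model@founder, pGd = model@pGd)
    for (i in seq_along(gGrid)) {
      mm <- modelMarginals(mj, gGrid[i])
      K[i, j] <- diversityIndex(mm$marginals)
      logS[i, j] <- mm$logSurviving
      marg[i, j, , ] <- mm$marginals
    }
  }
  new("DiversitySurface", gGrid = gGrid, pGrid = pGrid, K = K,
      logSurviving = logS, marginals = marg)
}

#' Optimal missegregation rate
#'
#' Finds the missegregation rate maximising the chosen objective after
#' \code{g} generations: the surviving fraction, the diversity index
#' \eqn{K}, or their product (the fitness-by-heterogeneity trade-off).
#' A grid search is refined by golden-section on \eqn{\log p}; ties go
#' to the smaller rate.
#'
#' @param model a [KaryotypeModel-class].
#' @param g number of generations.
#' @param objective \code{"surviving"}, \code{"K"} or
#'   \code{"survivingK"}.
#' @param pGrid candidate rates in \code{(0, 1/N]}, increasing.
#' @param refine golden-section refinement (default TRUE).
#' @return list with \code{p} (the maximiser) and \code{value}.
#' @export
optimalP <- function(model, g,
                     objective = c("surviving", "K", "survivingK"),
                     pGrid, refine = TRUE) {
  objective <- match.arg(objective)
  stopifnot(all(pGrid > 0), all(pGrid <= 1 / model@N),
            !is.unsorted(pGrid))
  obj <- function(p) {
    mj <- KaryotypeModel(model@scoreTable, p = p, N = model@N,
                         founder = model@founder, pGd = model@pGd)
    mm <- modelMarginals(mj, g)
    switch(objective,
           surviving = mm$logSurviving,
           K = log(max(diversityIndex(mm$marginals), 1e-300)),
           survivingK = mm$logSurviving +
             log(max(diversityIndex(mm$marginals), 1e-300)))
  }
  vals <- vapply(pGrid, obj, numeric(1))
  i <- which.max(vals)                 # first max: smaller p wins ties
  pBest <- pGrid[i]; vBest <- vals[i]
  if (refine && length(pGrid) >= 2L) {
    lo <- log(pGrid[max(1L, i - 1L)])
    hi <- log(pGrid[min(length(pGrid), i + 1L)])
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- obj(exp(x1)); f2 <- obj(exp(x2))
    for (it in 1:40) {
      if (f1 < f2) {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- obj(exp(x2))
      } else {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- obj(exp(x1))
      }
      if (hi - lo < 1e-4) break
    }
    xm <- (lo + hi) / 2
    fm <- obj(exp(xm))
    if (fm > vBest) { pBest <- exp(xm); vBest <- fm }
  }
  value <- if (objective == "surviving") exp(vBest)
           else if (objective == "K") exp(vBest)
           else exp(vBest)
  list(p = pBest, value = value, objective = objective)
}

#' @describeIn meanCopyTrajectory per-chromosome mean copy numbers over
#'   generations for a 23-chromosome model, plus their across-chromosome
#'   average.
#' @export
setMethod("meanCopyTrajectory", "KaryotypeModel",
  function(object, g, ...) {
  per <- matrix(NA_real_, 23L, g + 1L,
                dimnames = list(1:23, 0:g))
  for (k in 1:23)
    per[k, ] <- meanCopyTrajectory(object@chains[[k]],
                                   object@founder[k], g)
  list(perChromosome = per, average = colMeans(per))
})
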