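#' @import methods
NULL

#' Parameters of a single-chromosome missegregation chain
#'
#' Scalar model parameters for the copy-number Markov chain of one
#' chromosome.  The chain lives on copy-number states \eqn{1..N}; a cell
#' dies (absorbing state) when the copy number leaves that range, or, in
#' the score-bearing model, spontaneously with probability
#' \eqn{1 - q(i)} where \eqn{q(i) = C \mu^i}.
#'
#' @slot N maximum allowed copy number (viability bound).
#' @slot p missegregation rate per chromosome copy per division.
#' @slot mu per-copy survival multiplier \eqn{\mu = e^{d s_k}}; values
#'   above 1 mark oncogenic chromosomes, below 1 tumor-suppressive ones.
#' @slot Ck per-chromosome survival constant \eqn{C = e^{c_k}};
#'   immaterial to conditional (limiting) distributions, it only
#'   rescales the chain.
#' @slot pGd whole-genome-duplication rate; either a scalar or one value
#'   per copy-number state (length \code{N}).
#' @slot mR inactivating mutation rate of the tolerance-gating gene
#'   (used only by the early-growth chain with states sigma/tau).
#'
#' @seealso [ChainParams()], [basicChain()], [scoredChain()]
#' @export
setClass("ChainParams",
  representation(N = "integer", p = "numeric", mu = "numeric",
                 Ck = "numeric", pGd = "numeric", mR = "numeric"),
  prototype(N = 8L, p = 0, mu = 1, Ck = 1, pGd = 0, mR = 0))

setValidity("ChainParams", function(object) {
  msg <- character()
  if (length(object@N) != 1L || is.na(object@N) || object@N < 1L)
    msg <- c(msg, "N must be a single integer >= 1")
  if (length(object@p) != 1L || is.na(object@p) ||
      object@p < 0 || object@p > 1)
    msg <- c(msg, "p must be a probability in [0, 1]")
  if (length(object@mu) != 1L || is.na(object@mu) || object@mu <= 0)
    msg <- c(msg, "mu must be a positive real")
  if (length(object@Ck) != 1L || is.na(object@Ck) || object@Ck <= 0)
    msg <- c(msg, "C must be a positive real")
  if (!length(object@pGd) %in% c(1L, object@N) ||
      any(is.na(object@pGd)) || any(object@pGd < 0) || any(object@pGd > 1))
    msg <- c(msg, "pGd must be a probability (scalar or one per state)")
  if (length(object@mR) != 1L || is.na(object@mR) ||
      object@mR < 0 || object@mR > 1)
    msg <- c(msg, "mR must be a probability in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Chromosome score table
#'
#' Per-chromosome fitness scores \eqn{s_k} and the derived survival
#' multipliers \eqn{\mu_k = e^{d s_k}}, together with the global survival
#' constants \eqn{c < 0} and \eqn{d > 0} of the cell-survival model
#' \eqn{Q_{surv} = e^{c + d S}}, \eqn{S = \sum_k s_k n_k}.
#'
#' @slot chromosome integer chromosome labels 1..23 (23 denotes the sex
#'   chromosome, score 0).
#' @slot score signed chromosome scores \eqn{s_k}; positive means the
#'   chromosome carries a net excess of oncogenes.
#' @slot mu derived multipliers \eqn{e^{d s_k}}.
#' @slot c global survival constant (negative).
#' @slot d score-to-survival scale (positive).
#'
#' @seealso [hg23Scores()], [readScoreTable()]
#' @export
setClass("ScoreTable",
  representation(chromosome = "integer", score = "numeric",
                 mu = "numeric", c = "numeric", d = "numeric"))

setValidity("ScoreTable", function(object) {
  msg <- character()
  n <- length(object@chromosome)
  if (length(object@score) != n || length(object@mu) != n)
    msg <- c(msg, "chromosome, score and mu must have equal length")
  if (!identical(sort(object@chromosome), seq_len(23L)))
    msg <- c(msg, "chromosome labels must be exactly 1..23")
  if (length(object@d) != 1L || object@d <= 0)
    msg <- c(msg, "d must be a single positive real")
  if (length(object@c) != 1L || is.na(object@c))
    msg <- c(msg, "c must be a single real")
  if (!length(msg)) {
    rel <- abs(object@mu - exp(object@d * object@score)) /
      pmax(abs(object@mu), 1e-300)
    if (any(rel > 1e-9))
      msg <- c(msg, sprintf(
        "mu inconsistent with exp(d * score) for chromosome(s) %s",
        paste(object@chromosome[rel > 1e-9], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' A built transition matrix over non-absorbing states
#'
#' Holds the sub-stochastic transition matrix \code{T} over the
#' non-absorbing states of one chromosome's chain, plus the explicit
#' per-state mass of the transition into the absorbing dead state, so
#' that each row of \code{T} plus its death mass sums to exactly 1
#' (except for the signed drift generator, kind \code{"drift"}).
#'
#' States are the copy numbers \code{1..N}; the early-growth chain
#' (kind \code{"ax"}) prepends the two tolerance states \code{"sigma"}
#' (two active copies of the gating gene) and \code{"tau"} (one active,
#' one mutated copy).
#'
#' @slot kind one of \code{"basic"}, \code{"drift"}, \code{"scored"},
#'   \code{"gd"}, \code{"ax"}.
#' @slot states character labels of the non-absorbing states, in matrix
#'   order.
#' @slot T square transition-weight matrix over the non-absorbing states.
#' @slot deathMass per-state transition weight into the absorbing state.
#' @slot params the [ChainParams-class] the chain was built from.
#'
#' @seealso [basicChain()], [scoredChain()], [duplicationChain()],
#'   [inactivationChain()], [driftMatrix()]
#' @export
setClass("MissegChain",
  representation(kind = "character", states = "character",
                 T = "matrix", deathMass = "numeric",
                 params = "ChainParams"))

setValidity("MissegChain", function(object) {
  msg <- character()
  n <- length(object@states)
  if (!identical(dim(object@T), c(n, n)))
    msg <- c(msg, "T must be square with one row per state")
  if (length(object@deathMass) != n)
    msg <- c(msg, "deathMass must have one entry per state")
  if (!object@kind %in% c("basic", "drift", "scored", "gd", "ax"))
    msg <- c(msg, "unknown chain kind")
  if (object@kind != "drift" && !length(msg)) {
    if (any(object@T < 0))
      msg <- c(msg, "transition weights must be nonnegative")
    ## deathMass may go (slightly) negative when an arbitrary constant
    ## split makes some q(i) > 1; the builders warn in that case
    tot <- rowSums(object@T) + object@deathMass
    if (any(abs(tot - 1) > 1e-12))
      msg <- c(msg, "row sums of T plus deathMass must equal 1")
  }
  if (length(msg)) msg else TRUE
})

#' Characteristic-polynomial sequence of a tridiagonal chain
#'
#' The monic characteristic polynomials \eqn{P_0, \ldots, P_N} of the
#' leading principal minors of a tridiagonal chain matrix, generated by
#' the three-term recurrence
#' \eqn{P_n(x) = (x - a_{n,n}) P_{n-1}(x) - a_{n,n-1} a_{n-1,n} P_{n-2}(x)}.
#'
#' For the basic model the recurrence is applied to the drift generator
#' \code{J} and all coefficients are dyadic rationals, held exactly in
#' double precision for the sizes supported (\code{N <= 26}).
#'
#' @slot polys list of numeric coefficient vectors in ascending degree;
#'   element \code{n + 1} holds \eqn{P_n}.
#' @slot N highest degree computed.
#' @slot kind \code{"basic"} (polynomials of \code{J}) or \code{"scored"}
#'   (polynomials of the score chain \code{A} with \code{C = 1}).
#' @slot p,mu parameters of the scored recurrence (unused for basic).
#' @export
setClass("CharPolySeq",
  representation(polys = "list", N = "integer", kind = "character",
                 p = "numeric", mu = "numeric"))

setValidity("CharPolySeq", function(object) {
  msg <- character()
  if (length(object@polys) != object@N + 1L)
    msg <- c(msg, "polys must contain P_0 .. P_N")
  degs <- lengths(object@polys) - 1L
  if (!identical(degs, 0:object@N))
    msg <- c(msg, "P_n must have degree exactly n")
  lead <- vapply(object@polys, function(p) p[length(p)], numeric(1))
  if (any(abs(lead - 1) > 1e-12))
    msg <- c(msg, "polynomials must be monic")
  if (length(msg)) msg else TRUE
})

#' Quasi-stationary (limiting) distribution of a chain
#'
#' The limiting distribution of an absorbing chain conditional on
#' non-absorption: the left Perron eigenvector of the non-absorbing
#' block, normalised to sum 1, together with the leading eigenpair data
#' that govern growth and mixing.
#'
#' @slot alpha largest eigenvalue of the underlying generator: of
#'   \code{J} for the basic model (so the chain's Perron eigenvalue is
#'   \eqn{1 + p\alpha}), or of the score matrix \code{A} with
#'   \eqn{C = 1} for the scored model.
#' @slot rho Perron eigenvalue of the chain's transition matrix
#'   (\code{NA} for the basic closed form unless a \code{p} is supplied).
#' @slot rhoTilde second-largest eigenvalue modulus.
#' @slot v limiting probability vector over non-absorbing states.
#' @slot states state labels matching \code{v}.
#' @slot meanCopies mean copy number \eqn{\sum_i i v_i} (over copy-number
#'   states only).
#' @slot mode modal copy number (smallest on ties).
#' @slot mixingEstimate \eqn{(1 - \tilde\rho/\rho)^{-1}}, a proxy for the
#'   number of generations needed to approach the limit.
#' @slot method \code{"charpoly"} (closed form) or \code{"eigen"}.
#' @slot reducible flag set when the numeric Perron vector has zero
#'   entries (chain not irreducible on its non-absorbing states).
#' @export
setClass("QuasiStationary",
  representation(alpha = "numeric", rho = "numeric", rhoTilde = "numeric",
                 v = "numeric", states = "character",
                 meanCopies = "numeric", mode = "integer",
                 mixingEstimate = "numeric", method = "character",
                 reducible = "logical"))

setValidity("QuasiStationary", function(object) {
  msg <- character()
  if (length(object@v) != length(object@states))
    msg <- c(msg, "v and states must have equal length")
  if (any(object@v < -1e-12))
    msg <- c(msg, "limiting distribution must be nonnegative")
  if (abs(sum(object@v) - 1) > 1e-9)
    msg <- c(msg, "limiting distribution must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Finite-generation trajectory of a chain
#'
#' Per-generation state masses (as fractions of an undying doubling
#' population), surviving fractions, and the conditional-on-viable
#' distributions obtained by renormalising the masses.
#'
#' @slot generations integer vector \code{0..g}.
#' @slot masses matrix, one row per generation: unnormalised row
#'   \eqn{v T^g} of the propagated initial distribution.  When
#'   propagation is renormalised (the default) these rows are rescaled;
#'   the true mass is \code{conditional * exp(logSurviving)}.
#' @slot conditional matrix of conditional-on-viable distributions.
#' @slot logSurviving per-generation log surviving fraction
#'   \eqn{\log s_g}; kept in log space so propagation is safe to
#'   \eqn{g = 10^6}.
#' @slot states state labels (matrix columns).
#' @slot truncated TRUE when all mass died before generation \code{g}
#'   and the trajectory was cut short.
#' @export
setClass("Trajectory",
  representation(generations = "integer", masses = "matrix",
                 conditional = "matrix", logSurviving = "numeric",
                 states = "character", truncated = "logical"))

setValidity("Trajectory", function(object) {
  msg <- character()
  g <- length(object@generations)
  if (nrow(object@conditional) != g || length(object@logSurviving) != g)
    msg <- c(msg, "per-generation slots must align with generations")
  if (ncol(object@conditional) != length(object@states))
    msg <- c(msg, "state dimension mismatch")
  if (length(msg)) msg else TRUE
})

#' A 23-chromosome product-chain model
#'
#' The product of 23 independent single-chromosome chains sharing
#' \code{N}, \code{p} and \code{pGd}, with per-chromosome survival
#' multipliers \eqn{\mu_k} taken from a [ScoreTable-class].  Karyotype
#' probabilities, expected population sizes and diversity indices all
#' factorise over the 23 chains; the \eqn{N^{23}} joint state space is
#' never enumerated.
#'
#' @slot chains list of 23 [MissegChain-class] objects.
#' @slot founder founder karyotype (23 copy numbers).
#' @slot scoreTable the score table the chains were built from.
#' @slot N,p,pGd shared chain parameters.
#' @seealso [KaryotypeModel()]
#' @export
setClass("KaryotypeModel",
  representation(chains = "list", founder = "integer",
                 scoreTable = "ScoreTable", N = "integer",
                 p = "numeric", pGd = "numeric"))

setValidity("KaryotypeModel", function(object) {
  msg <- character()
  if (length(object@chains) != 23L)
    msg <- c(msg, "a karyotype model holds 23 chains")
  if (length(object@founder) != 23L ||
      any(object@founder < 1L) || any(object@founder > object@N))
    msg <- c(msg, "founder must be 23 copy numbers in [1, N]")
  if (!all(vapply(object@chains, function(ch)
        is(ch, "MissegChain") && ch@params@N == object@N &&
        ch@params@p == object@p, logical(1))))
    msg <- c(msg, "all chains must share N and p")
  if (length(msg)) msg else TRUE
})

#' Karyotype diversity surface K(g, p)
#'
#' The karyotype diversity index
#' \eqn{K = -\sum_k \sum_j a_{k,j} \ln a_{k,j}} evaluated on a grid of
#' generation counts and missegregation rates, with the per-chromosome
#' copy-number marginals \eqn{a_{k,j}} and log surviving fractions kept
#' alongside.
#'
#' @slot gGrid,pGrid the evaluation grids.
#' @slot K matrix of diversity values, \code{length(gGrid)} rows by
#'   \code{length(pGrid)} columns.
#' @slot logSurviving matrix of log surviving fractions on the same grid.
#' @slot marginals 4-d array \code{[g, p, chromosome, copy number]} of
#'   viable-cell copy-number fractions.
#' @export
setClass("DiversitySurface",
  representation(gGrid = "integer", pGrid = "numeric", K = "matrix",
                 logSurviving = "matrix", marginals = "array"))

setValidity("DiversitySurface", function(object) {
  msg <- character()
  if (!identical(dim(object@K),
                 c(length(object@gGrid), length(object@pGrid))))
    msg <- c(msg, "K must be a gGrid x pGrid matrix")
  if (any(object@K < -1e-9))
    msg <- c(msg, "K must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' A sample of simulated cell lineages
#'
#' Terminal states of independently simulated random lineages of the
#' branching cell-division process (one random daughter followed per
#' division), the direct stochastic counterpart of the Markov chain.
#'
#' @slot nLineages number of simulated lineages.
#' @slot seed RNG seed used (runs are reproducible bit-for-bit).
#' @slot g number of generations simulated.
#' @slot rule \code{"linearized"} (at most one missegregation per
#'   chromosome per division) or \code{"binomial"} (every copy
#'   missegregates independently).
#' @slot model chain kind simulated.
#' @slot founder founder copy number(s).
#' @slot finalStates integer matrix (lineages x chromosomes) of terminal
#'   copy numbers, \code{NA} for dead lineages.  For the early-growth
#'   chain, 0 codes state sigma and -1 state tau.
#' @slot viableCounts per-state tallies of surviving lineages
#'   (chromosomes x states).
#' @export
setClass("LineageSample",
  representation(nLineages = "integer", seed = "integer", g = "integer",
                 rule = "character", model = "character",
                 founder = "integer", finalStates = "matrix",
                 viableCounts = "matrix"))

setValidity("LineageSample", function(object) {
  alive <- sum(stats::complete.cases(object@finalStates))
  if (nrow(object@viableCounts) >= 1L &&
      sum(object@viableCounts[1L, ]) != alive)
    return("viableCounts must tally the surviving lineages")
  TRUE
})
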