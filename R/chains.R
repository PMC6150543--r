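#' Construct chain parameters
#'
#' Convenience constructor for [ChainParams-class].  All parameters have
#' the neutral defaults of the basic model: no score effect
#' (\code{mu = 1}, \code{C = 1}), no genome duplication, no gating-gene
#' mutation.
#'
#' @param N maximum allowed copy number (default 8).
#' @param p missegregation rate per chromosome copy per division.
#' @param mu per-copy survival multiplier \eqn{e^{d s_k}}.
#' @param C per-chromosome survival constant \eqn{e^{c_k}}.
#' @param pGd genome-duplication rate, scalar or one value per state.
#' @param mR gating-gene inactivating mutation rate.
#' @return A [ChainParams-class].
#' @examples
#' ChainParams(N = 8, p = 0.0025)
#' @export
ChainParams <- function(N = 8, p = 0, mu = 1, C = 1, pGd = 0, mR = 0) {
  new("ChainParams", N = as.integer(N), p = as.numeric(p),
      mu = as.numeric(mu), Ck = as.numeric(C), pGd = as.numeric(pGd),
      mR = as.numeric(mR))
}

## per-state survival factors q(i) = C mu^i, with the interpretability
## caveat (q > 1 cannot be read as a probability) surfaced as a warning
qVec <- function(params, warn = TRUE) {
  i <- seq_len(params@N)
  q <- params@Ck * params@mu^i
  if (warn && any(q > 1 + 1e-8))
    warning("C * mu^i exceeds 1 for state(s) ",
            paste(i[q > 1 + 1e-8], collapse = ", "),
            "; q(i) is not interpretable as a probability ",
            "(limiting distributions are unaffected)", call. = FALSE)
  q
}

#' Per-chromosome survival factor
#'
#' The contribution \eqn{q_k(i) = C \mu^i} of one chromosome with
#' \eqn{i} copies to the cell survival probability.  Values above 1 are
#' allowed (the constant split across chromosomes is arbitrary) but
#' trigger a warning since they are no longer probabilities.
#'
#' @param params a [ChainParams-class].
#' @param i copy number, \code{1 <= i <= N}.
#' @return \eqn{C \mu^i}.
#' @export
survivalFactor <- function(params, i) {
  stopifnot(is(params, "ChainParams"), all(i >= 1), all(i <= params@N))
  q <- params@Ck * params@mu^i
  if (any(q > 1 + 1e-8))
    warning("survival factor exceeds 1; not interpretable as a probability",
            call. = FALSE)
  q
}

newChain <- function(kind, T, deathMass, params,
                     states = as.character(seq_len(ncol(T)))) {
  dimnames(T) <- list(states, states)
  new("MissegChain", kind = kind, states = states, T = T,
      deathMass = stats::setNames(deathMass, states), params = params)
}

## tridiagonal core of the basic chain: diag 1 - ip, off-diagonals ip/2
basicT <- function(N, p) {
  T <- matrix(0, N, N)
  for (i in seq_len(N)) {
    T[i, i] <- 1 - i * p
    if (i > 1L) T[i, i - 1L] <- i * p / 2
    if (i < N) T[i, i + 1L] <- i * p / 2
  }
  T
}

checkDiagonal <- function(N, p) {
  bad <- which(1 - seq_len(N) * p < 0)
  if (length(bad))
    stop("p = ", p, " exceeds 1/N: transition matrix has negative ",
         "diagonal at state(s) ", paste(bad, collapse = ", "),
         " (require p <= 1/", N, ")", call. = FALSE)
}

#' Basic missegregation chain
#'
#' The transition matrix of the basic model over copy-number states
#' \code{1..N}: a cell with \eqn{i} copies keeps them with probability
#' \eqn{1 - ip} and moves to \eqn{i \pm 1} with probability \eqn{ip/2}
#' each (one missegregation per chromosome per division; terms quadratic
#' in \eqn{p} are neglected).  Mass leaving the range \eqn{[1, N]} goes
#' to the explicit death component.
#'
#' @param params a [ChainParams-class]; only \code{N} and \code{p} are
#'   used.  Requires \code{p <= 1/N} so the diagonal stays nonnegative.
#' @return A [MissegChain-class] of kind \code{"basic"}.
#' @examples
#' ch <- basicChain(ChainParams(N = 3, p = 0.1))
#' transitionMatrix(ch)
#' deathMass(ch)   # p/2 at state 1, Np/2 at state N
#' @export
basicChain <- function(params) {
  stopifnot(is(params, "ChainParams"))
  N <- params@N; p <- params@p
  checkDiagonal(N, p)
  T <- basicT(N, p)
  death <- numeric(N)
  death[1L] <- p / 2
  death[N] <- death[N] + N * p / 2
  newChain("basic", T, death, params)
}

#' Drift generator J of the basic chain
#'
#' The generator in the decomposition \eqn{M = I + pJ}:
#' \eqn{J_{ii} = -i}, \eqn{J_{i,i\pm1} = i/2}.  Its left Perron
#' eigenvector is the limiting distribution of the basic chain for every
#' missegregation rate \eqn{p > 0}.  The death component holds the
#' signed death drift, so that death mass of the basic chain equals
#' \eqn{p} times this component.
#'
#' @param N maximum allowed copy number.
#' @return A [MissegChain-class] of kind \code{"drift"} (rows sum to
#'   the negated death drift, not to 1).
#' @export
driftMatrix <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  J <- matrix(0, N, N)
  for (i in seq_len(N)) {
    J[i, i] <- -i
    if (i > 1L) J[i, i - 1L] <- i / 2
    if (i < N) J[i, i + 1L] <- i / 2
  }
  death <- numeric(N)
  death[1L] <- 1 / 2
  death[N] <- death[N] + N / 2
  newChain("drift", J, death, ChainParams(N = N))
}

#' Chromosome-score chain
#'
#' The score-bearing chain \eqn{A = DM} where \eqn{D} is diagonal with
#' \eqn{D_{ii} = q(i) = C\mu^i}: before dividing as in the basic model a
#' cell in state \eqn{i} survives with probability \eqn{q(i)}.  The
#' death component covers both missegregation death and spontaneous
#' death \eqn{1 - q(i)}.
#'
#' @param params a [ChainParams-class] (\code{N}, \code{p}, \code{mu},
#'   \code{C} used).
#' @return A [MissegChain-class] of kind \code{"scored"}.
#' @examples
#' ch <- scoredChain(ChainParams(N = 8, p = 0.0025, mu = 0.9996))
#' @export
scoredChain <- function(params) {
  stopifnot(is(params, "ChainParams"))
  N <- params@N; p <- params@p
  checkDiagonal(N, p)
  q <- qVec(params)
  M <- basicT(N, p)
  T <- q * M            # row scaling: D %*% M
  death <- 1 - q * rowSums(M)
  newChain("scored", T, death, params)
}

#' Chain with whole genome duplication
#'
#' Adds the genome-duplication generator \eqn{G} to the basic matrix
#' (\eqn{M_{gd} = M + G}, or \eqn{A_{gd} = D M_{gd}} with scores):
#' at each generation a cell in state \eqn{i} duplicates its genome with
#' probability \eqn{p_{gd}(i)}, which contributes a transition
#' \eqn{i \to 2i} with weight \eqn{p_{gd}(i)/2} (to death when
#' \eqn{2i > N}) and a matching weight \eqn{p_{gd}(i)/2} to death for
#' the daughter that is never created.  \code{pGd} may be a per-state
#' vector, e.g. to raise the duplication rate once a chromosome reaches
#' 3 or more copies.
#'
#' @param params a [ChainParams-class]; \code{pGd} scalar or length
#'   \code{N}.
#' @param scored apply the survival scaling \eqn{D} (default TRUE; with
#'   \code{mu = C = 1} the scaling is the identity).
#' @return A [MissegChain-class] of kind \code{"gd"}.
#' @export
duplicationChain <- function(params, scored = TRUE) {
  stopifnot(is(params, "ChainParams"))
  N <- params@N; p <- params@p
  pgd <- rep_len(params@pGd, N)
  bad <- which(1 - seq_len(N) * p - pgd < 0)
  if (length(bad))
    stop("p + pGd too large: negative diagonal at state(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  checkDiagonal(N, p)
  T <- basicT(N, p)
  death <- numeric(N)
  death[1L] <- p / 2
  death[N] <- death[N] + N * p / 2
  for (i in seq_len(N)) {
    T[i, i] <- T[i, i] - pgd[i]
    if (2L * i <= N) T[i, 2L * i] <- T[i, 2L * i] + pgd[i] / 2
    else death[i] <- death[i] + pgd[i] / 2
    death[i] <- death[i] + pgd[i] / 2   # the uncreated daughter
  }
  if (scored) {
    q <- qVec(params)
    death <- 1 - q * rowSums(T)
    T <- q * T
  }
  newChain("gd", T, death, params)
}

#' Early-tumor-growth chain with a tolerance-gating gene
#'
#' Extends the score chain with two pre-tolerance states for a diploid
#' cell carrying the aneuploidy-gating gene: \code{sigma} (two active
#' copies) and \code{tau} (one active, one inactivated by mutation).
#' While an active copy remains, any missegregation among the cell's 46
#' chromosome copies is lethal, so the no-missegregation factor
#' \eqn{(1-p)^{46}} enters the sigma/tau rows; active copies mutate at
#' rate \code{mR}, and from \code{tau} a missegregation of the active
#' copy can release the cell into copy-number state 1.  Once all active
#' copies are lost the chain proceeds as the score chain on states
#' \code{1..N}.
#'
#' @param params a [ChainParams-class]; uses \code{mR} in addition to
#'   the score-chain parameters.  Requires
#'   \eqn{(1-p)^{46} - 2 m_R \ge 0}.
#' @return A [MissegChain-class] of kind \code{"ax"} with states
#'   \code{("sigma", "tau", 1..N)}.
#' @export
inactivationChain <- function(params) {
  stopifnot(is(params, "ChainParams"))
  N <- params@N; p <- params@p; mr <- params@mR
  nosplit <- (1 - p)^46
  if (nosplit - 2 * mr < 0)
    stop("(1 - p)^46 - 2*mR is negative; sigma-row probabilities invalid",
         call. = FALSE)
  q <- qVec(params)
  q2 <- q[min(2L, N)]
  if (N < 2L)
    stop("the early-growth chain needs N >= 2 (diploid founder state)",
         call. = FALSE)
  inner <- scoredChain(params)
  n <- N + 2L
  T <- matrix(0, n, n)
  T[3:n, 3:n] <- inner@T
  T[1L, 1L] <- (nosplit - 2 * mr) * q2       # sigma -> sigma
  T[1L, 2L] <- 2 * mr * q2                   # sigma -> tau
  T[2L, 2L] <- (nosplit - mr) * q2           # tau -> tau
  T[2L, 2L + 1L] <- (p / 2) * q2             # tau -> one copy, none active
  T[2L, 2L + 2L] <- mr * q2                  # tau -> two copies, none active
  death <- 1 - rowSums(T)
  states <- c("sigma", "tau", as.character(seq_len(N)))
  newChain("ax", T, death, params, states = states)
}

#' @rdname accessors
#' @export
setMethod("transitionMatrix", "MissegChain", function(object) object@T)

#' @rdname accessors
#' @export
setMethod("deathMass", "MissegChain", function(object) object@deathMass)

#' @rdname accessors
#' @export
setMethod("chainStates", "MissegChain", function(object) object@states)

#' @rdname accessors
#' @export
setMethod("chainKind", "MissegChain", function(object) object@kind)

#' @rdname accessors
#' @export
setMethod("chainParams", "MissegChain", function(object) object@params)

## indices of the copy-number states (drops sigma/tau for the ax chain)
copyStates <- function(chain) {
  idx <- suppressWarnings(as.integer(chain@states))
  which(!is.na(idx))
}
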