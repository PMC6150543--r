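## Quasi-stationary (limiting conditional) distributions: closed forms
## from the minor-sequence recurrences, and a dense eigensolver route
## used both in production for the extended chains and as a cross-check.

qsResult <- function(alpha, rho, rhoTilde, v, states, method,
                     reducible = FALSE) {
  idx <- suppressWarnings(as.integer(states))
  copy <- which(!is.na(idx))
  w <- v[copy] / sum(v[copy])
  meanCopies <- sum(idx[copy] * w)
  mode <- idx[copy][which.max(w)]   # which.max takes the first: smallest wins ties
  mixing <- if (is.finite(rho) && is.finite(rhoTilde) && rho != 0)
    1 / (1 - rhoTilde / rho) else NA_real_
  new("QuasiStationary", alpha = alpha, rho = rho, rhoTilde = rhoTilde,
      v = stats::setNames(v, states), states = states,
      meanCopies = meanCopies, mode = as.integer(mode),
      mixingEstimate = mixing, method = method, reducible = reducible)
}

#' Limiting copy-number distribution of the basic chain
#'
#' Closed-form quasi-stationary distribution of the basic
#' missegregation chain: \eqn{v_i \propto \frac{2^{i-1}}{i!} P_{i-1}(\alpha)}
#' with \eqn{\alpha} the largest eigenvalue of the drift generator
#' \code{J}.  The distribution is the same for every missegregation
#' rate \eqn{p > 0} and every founder karyotype; only the approach to it
#' depends on them.
#'
#' @param N maximum allowed copy number.
#' @param p optional missegregation rate; when given, the chain's Perron
#'   eigenvalue \eqn{\rho = 1 + p\alpha}, the second eigenvalue and the
#'   mixing estimate \eqn{(1-\tilde\rho/\rho)^{-1}} are filled in.
#' @return A [QuasiStationary-class].
#' @examples
#' qs <- limitingBasic(8)
#' round(limitDist(qs), 5)  # modal copy number is 1
#' meanCopies(qs)           # close to 3
#' @export
limitingBasic <- function(N, p = NULL) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  roots <- leadingRoots("basic", N)
  alpha <- roots$alpha
  sq <- evalMinorSeq("basic", N, NA_real_, NA_real_, alpha)
  i <- seq_len(N)
  ## interlacing puts alpha above every root of P_0..P_{N-1}: all positive
  logu <- (i - 1) * log(2) - lgamma(i + 1) + sq$logAbs[i]
  v <- exp(logu - max(logu))
  v <- v / sum(v)
  if (is.null(p)) {
    rho <- NA_real_; rhoTilde <- NA_real_
  } else {
    stopifnot(p > 0, p <= 1 / N)
    rho <- 1 + p * alpha
    rhoTilde <- max(abs(1 + p * roots$second), abs(1 + p * roots$smallest))
  }
  qsResult(alpha, rho, rhoTilde, v, as.character(i), "charpoly")
}

#' Limiting copy-number distribution of the score chain
#'
#' Closed-form quasi-stationary distribution of the score chain
#' \code{A}:
#' \eqn{v_i \propto \frac{2^{i-1}}{i!\, p^{i-1} \mu^{(i^2+i-2)/2}} P_{i-1}(\alpha)}
#' with \eqn{\alpha} the largest eigenvalue of \code{A} at \eqn{C = 1}
#' (the result does not depend on \eqn{C}).  Unlike the basic model the
#' distribution depends on \eqn{p}: small \eqn{p} lets the score
#' dominate (for \eqn{\mu > 1} the mass shifts towards high copy
#' numbers), large \eqn{p} pushes it back towards the basic-model shape.
#'
#' @param N maximum allowed copy number.
#' @param p missegregation rate, \code{0 < p <= 1/N}.
#' @param mu survival multiplier \eqn{e^{d s_k}}.
#' @return A [QuasiStationary-class]; \code{alpha} and \code{rho} both
#'   hold the Perron eigenvalue of \code{A} (at \eqn{C = 1}).
#' @examples
#' qs <- limitingScored(8, p = 0.0025, mu = 1.0004)
#' meanCopies(qs); modalCopy(qs)
#' @export
limitingScored <- function(N, p, mu) {
  N <- as.integer(N)
  stopifnot(N >= 1L, p > 0, p <= 1 / N, mu > 0)
  roots <- leadingRoots("scored", N, p, mu)
  alpha <- roots$alpha
  sq <- evalMinorSeq("scored", N, p, mu, alpha)
  i <- seq_len(N)
  logu <- (i - 1) * log(2) - lgamma(i + 1) - (i - 1) * log(p) -
    (i^2 + i - 2) / 2 * log(mu) + sq$logAbs[i]
  v <- exp(logu - max(logu))
  v <- v / sum(v)
  rhoTilde <- max(abs(roots$second), abs(roots$smallest))
  qsResult(alpha, alpha, rhoTilde, v, as.character(i), "charpoly")
}

#' @describeIn quasiStationary dense-eigensolver quasi-stationary
#'   distribution of any built chain: the left Perron eigenpair of the
#'   non-absorbing block, eigenvector normalised to sum 1.  For chains
#'   that are not irreducible on the non-absorbing states (e.g. the
#'   early-growth chain, whose sigma/tau states are transient) the
#'   Perron vector may have zero entries; the result is then flagged
#'   \code{reducible} rather than failing.
#' @export
setMethod("quasiStationary", "MissegChain", function(object, ...) {
  if (object@kind == "drift")
    stop("the drift generator is not a stochastic chain; analyse ",
         "basicChain() or use limitingBasic()", call. = FALSE)
  T <- object@T
  e <- eigen(t(T))
  vals <- e$values
  k <- which.max(Re(vals))
  rho <- Re(vals[k])
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  scale <- max(abs(v))
  if (min(v) < -1e-8 * scale)
    stop("Perron eigenvector has mixed signs; numerical failure",
         call. = FALSE)
  v[v < 0] <- 0
  v <- v / sum(v)
  reducible <- any(v < 1e-12)
  rhoTilde <- sort(Mod(vals[-k]), decreasing = TRUE)[1L]
  if (length(vals) == 1L) rhoTilde <- NA_real_
  alpha <- if (object@kind == "basic" && object@params@p > 0)
    (rho - 1) / object@params@p else rho
  qsResult(alpha, rho, rhoTilde, v, object@states, "eigen",
           reducible = reducible)
})

#' @rdname accessors
#' @export
setMethod("limitDist", "QuasiStationary", function(object) object@v)

#' @rdname accessors
#' @export
setMethod("meanCopies", "QuasiStationary", function(object) {
  object@meanCopies
})

#' @rdname accessors
#' @export
setMethod("modalCopy", "QuasiStationary", function(object) object@mode)

#' @rdname accessors
#' @export
setMethod("mixingEstimate", "QuasiStationary", function(object) {
  object@mixingEstimate
})

#' Limiting population growth rate
#'
#' The per-generation multiplication factor of the expected viable-cell
#' count once karyotypes follow the limiting distribution, and the
#' culling threshold: if only a fraction \eqn{F} of cells were allowed
#' to survive each generation, the population grows without bound
#' exactly when \eqn{F} exceeds the reciprocal of the growth rate.
#'
#' For the basic model the rate is \eqn{2 (1 + p\alpha)^{23}} with
#' \eqn{\alpha} the largest eigenvalue of \code{J}; for the full model
#' it is \eqn{2 \prod_{k=1}^{23} \alpha_k} with \eqn{\alpha_k} the
#' per-chromosome Perron eigenvalues of the score chains (at their true
#' constants \eqn{C_k}, jointly contributing \eqn{e^c}).
#'
#' @param x either a [QuasiStationary-class] from [limitingBasic()]
#'   (then \code{p} is required) or a numeric vector of per-chromosome
#'   Perron eigenvalues.
#' @param p missegregation rate (basic model only).
#' @param nChromosomes number of chromosome types (default 23).
#' @return named vector \code{c(rate, threshold)}.
#' @examples
#' growthRate(limitingBasic(8), p = 0)['rate']  # pure doubling: 2
#' @export
growthRate <- function(x, p = NULL, nChromosomes = 23) {
  if (is(x, "QuasiStationary")) {
    if (is.null(p))
      stop("supply p for the basic-model growth rate 2(1 + p*alpha)^23",
           call. = FALSE)
    rate <- 2 * (1 + p * x@alpha)^nChromosomes
  } else if (is.numeric(x)) {
    rate <- 2 * prod(x)
  } else stop("x must be a QuasiStationary or a numeric vector")
  c(rate = rate, threshold = 1 / rate)
}
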