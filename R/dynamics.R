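## Finite-generation propagation.  Distributions are renormalised every
## generation and the surviving fraction is accumulated in log space, so
## propagation is numerically safe out to millions of generations; when
## only the final generation is wanted and g is large, matrix powers by
## repeated squaring (with the same log-space scaling) are used instead.

resolveInitial <- function(chain, initial) {
  states <- chain@states
  n <- length(states)
  if (length(initial) == 1L) {
    k <- match(as.character(initial), states)
    if (is.na(k))
      stop("unknown founder state '", initial, "'", call. = FALSE)
    v <- numeric(n); v[k] <- 1
    return(v)
  }
  if (length(initial) != n)
    stop("initial distribution must have one entry per state", call. = FALSE)
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-9)
    stop("initial distribution must be nonnegative and sum to 1",
         call. = FALSE)
  as.numeric(initial)
}

## conditional distribution and log surviving fraction after exactly g
## generations, by repeated squaring with per-square renormalisation
powerStep <- function(chain, init, g) {
  T <- chain@T
  v <- init
  logS <- 0
  B <- T                      # B = T^(2^k) / exp(logB)
  logB <- 0
  gg <- g
  while (gg > 0) {
    if (gg %% 2 == 1) {
      v <- as.numeric(v %*% B)
      s <- sum(v)
      if (s <= 0) return(list(cond = v * 0, logSurv = -Inf, dead = TRUE))
      logS <- logS + log(s) + logB
      v <- v / s
    }
    gg <- gg %/% 2
    if (gg > 0) {
      B <- B %*% B
      m <- max(B)
      if (m <= 0) return(list(cond = v * 0, logSurv = -Inf, dead = TRUE))
      B <- B / m
      logB <- 2 * logB + log(m)
    }
  }
  list(cond = v, logSurv = logS, dead = FALSE)
}

#' @describeIn propagate propagate an initial copy-number distribution
#'   through a built chain for \code{g} generations.
#'
#' @param initial a probability vector over the chain's states, or a
#'   single founder state (copy number, or \code{"sigma"}/\code{"tau"}
#'   for the early-growth chain).
#' @param g number of generations.
#' @param renormalize renormalise the state masses every generation
#'   (default).  When \code{FALSE}, raw masses \eqn{v T^g} are carried,
#'   which underflow for large \code{g}; intended for cross-checks.
#' @return A [Trajectory-class].
#' @examples
#' ch <- basicChain(ChainParams(N = 8, p = 0.0025))
#' tr <- propagate(ch, initial = 2, g = 100)
#' survivingFraction(tr)[101]        # s_100(2)
#' conditionalDist(tr, 100)
#' @export
setMethod("propagate", "MissegChain",
  function(object, initial, g, renormalize = TRUE, ...) {
  if (object@kind == "drift")
    stop("the drift generator cannot be propagated; use basicChain()",
         call. = FALSE)
  g <- as.integer(g)
  stopifnot(g >= 0L)
  v <- resolveInitial(object, initial)
  n <- length(v)
  T <- object@T
  cond <- matrix(0, g + 1L, n)
  logS <- numeric(g + 1L)
  cond[1L, ] <- v
  truncated <- FALSE
  last <- g
  if (g > 0L) for (t in seq_len(g)) {
    v <- as.numeric(v %*% T)
    s <- sum(v)
    if (s <= 0) {                       # all mass absorbed: truncate
      truncated <- TRUE
      last <- t - 1L
      break
    }
    if (renormalize) {
      logS[t + 1L] <- logS[t] + log(s)
      v <- v / s
      cond[t + 1L, ] <- v
    } else {
      logS[t + 1L] <- log(sum(v))
      cond[t + 1L, ] <- v / s
    }
  }
  keep <- seq_len(last + 1L)
  cond <- cond[keep, , drop = FALSE]
  logS <- logS[keep]
  colnames(cond) <- object@states
  masses <- cond * exp(logS)
  new("Trajectory", generations = 0:last, masses = masses,
      conditional = cond, logSurviving = logS, states = object@states,
      truncated = truncated)
})

#' @describeIn accessors conditional-on-viable distribution at one
#'   generation of a trajectory.
#' @param generation generation index (0-based).
#' @export
setMethod("conditionalDist", "Trajectory", function(object, generation) {
  k <- match(generation, object@generations)
  if (is.na(k))
    stop("generation ", generation, " not in trajectory", call. = FALSE)
  stats::setNames(object@conditional[k, ], object@states)
})

#' @describeIn survivingFraction per-generation surviving-fraction
#'   series of a trajectory.
#' @param log return log surviving fractions.
#' @export
setMethod("survivingFraction", "Trajectory", function(object, log = FALSE) {
  if (log) object@logSurviving else exp(object@logSurviving)
})

#' @describeIn survivingFraction surviving fraction \eqn{s_g(i)} of a
#'   chain: the probability that a lineage started from \code{founder}
#'   is still viable after \code{g} generations (the founder row sum of
#'   the g-th matrix power).
#' @param founder founder state.
#' @param g number of generations.
#' @param series return the whole series \eqn{s_0 \ldots s_g} instead of
#'   the final value.
#' @export
setMethod("survivingFraction", "MissegChain",
  function(object, founder, g, series = FALSE, log = FALSE) {
  g <- as.integer(g)
  if (!series && g > 10000L) {
    r <- powerStep(object, resolveInitial(object, founder), g)
    return(if (log) r$logSurv else exp(r$logSurv))
  }
  tr <- propagate(object, founder, g)
  ls <- tr@logSurviving
  if (tr@truncated)
    ls <- c(ls, rep(-Inf, g - max(tr@generations)))
  out <- if (series) ls else ls[g + 1L]
  if (log) out else exp(out)
})

#' @describeIn meanCopyTrajectory per-generation mean copy number of a
#'   single chain, \eqn{\sum_j j \, a_j(g)} over the conditional
#'   distribution (for the early-growth chain, conditional on having
#'   left the sigma/tau states).
#' @param initial founder state or initial distribution.
#' @param g number of generations.
#' @export
setMethod("meanCopyTrajectory", "MissegChain",
  function(object, initial, g, ...) {
  tr <- propagate(object, initial, g)
  idx <- suppressWarnings(as.integer(object@states))
  copy <- which(!is.na(idx))
  w <- tr@conditional[, copy, drop = FALSE]
  tot <- rowSums(w)
  out <- as.numeric(w %*% idx[copy]) / ifelse(tot > 0, tot, NA_real_)
  stats::setNames(out, tr@generations)
})

#' Generations until the gating gene is inactivated
#'
#' For the early-growth chain, the number of generations until more
#' than half of the (viable) cells carry no active copy of the gating
#' gene, i.e. until the conditional mass on the copy-number states
#' \code{1..N} first exceeds 1/2, starting from a diploid founder with
#' two active copies (state sigma).
#'
#' @param chain a [MissegChain-class] of kind \code{"ax"}.
#' @param gMax give up after this many generations.
#' @param conditional measure the proportion among viable cells
#'   (default); \code{FALSE} measures raw unconditional mass.
#' @return The first such generation, or \code{NA} if not reached by
#'   \code{gMax}.
#' @examples
#' ch <- inactivationChain(ChainParams(N = 8, p = 0.0025, mR = 1e-4))
#' timeToInactivation(ch, gMax = 2000)
#' @export
timeToInactivation <- function(chain, gMax, conditional = TRUE) {
  stopifnot(is(chain, "MissegChain"))
  if (chain@kind != "ax")
    stop("timeToInactivation needs an early-growth ('ax') chain",
         call. = FALSE)
  v <- resolveInitial(chain, "sigma")
  T <- chain@T
  idx <- suppressWarnings(as.integer(chain@states))
  copy <- which(!is.na(idx))
  logS <- 0
  for (t in seq_len(gMax)) {
    v <- as.numeric(v %*% T)
    s <- sum(v)
    if (s <= 0) return(NA_integer_)
    logS <- logS + log(s)
    v <- v / s
    frac <- sum(v[copy])
    if (!conditional) frac <- frac * exp(logS)
    if (frac > 0.5) return(t)
  }
  NA_integer_
}
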