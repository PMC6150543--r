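## Direct stochastic simulation of the branching cell-division process,
## in random-lineage form: one random daughter is followed at each
## division, which is exactly the process the Markov chain describes.
## Used as an independent oracle for every built transition matrix.

## one division step for a vector of copy numbers (NA = dead lineage):
## returns the random daughter's copy numbers, NA when outside [1, N]
divideStep <- function(s, p, N, rule) {
  alive <- which(!is.na(s))
  if (!length(alive)) return(s)
  si <- s[alive]
  if (rule == "linearized") {
    ## at most one missegregation per chromosome per division:
    ## event probability i*p, direction +1/-1 equally likely
    ev <- stats::runif(length(si)) < si * p
    dir <- ifelse(stats::runif(length(si)) < 0.5, 1L, -1L)
    sj <- si + ifelse(ev, dir, 0L)
  } else {
    ## every copy independently contributes 0, 1 or 2 copies to the
    ## random daughter with probabilities p/2, 1-p, p/2
    gains <- stats::rbinom(length(si), si, p / 2)
    losses <- stats::rbinom(length(si), si - gains, (p / 2) / (1 - p / 2))
    sj <- si + gains - losses
  }
  sj[sj < 1L | sj > N] <- NA_integer_
  s[alive] <- sj
  s
}

## spontaneous-death step: survive with probability q(i)
surviveStep <- function(s, q) {
  alive <- which(!is.na(s))
  if (!length(alive)) return(s)
  qi <- q[s[alive]]
  s[alive][stats::runif(length(alive)) >= qi] <- NA_integer_
  s
}

## genome-duplication step (process form): with probability pgd(i) the
## cell duplicates instead of dividing; the random "daughter" is the
## duplicated cell or the never-created one, equally likely
gdStep <- function(s, pgd, N) {
  alive <- which(!is.na(s))
  if (!length(alive)) return(list(s = s, dup = logical(length(s))))
  si <- s[alive]
  pg <- rep_len(pgd, N)[si]
  ev <- stats::runif(length(si)) < pg
  coin <- stats::runif(length(si)) < 0.5
  out <- si
  out[ev & coin] <- 2L * si[ev & coin]
  out[ev & !coin] <- NA_integer_
  out[out > N & !is.na(out)] <- NA_integer_
  s[alive] <- out
  dup <- logical(length(s))
  dup[alive] <- ev
  list(s = s, dup = dup)
}

checkSimParams <- function(params, model) {
  q <- params@Ck * params@mu^seq_len(params@N)
  if (model != "basic" && any(q > 1 + 1e-8))
    stop("cannot simulate: survival factors C*mu^i exceed 1; choose a ",
         "constant split with q(i) <= 1 (e.g. C = exp(c/23))",
         call. = FALSE)
  q
}

#' @describeIn simulateLineages simulate lineages of a single
#'   chromosome's chain.
#'
#' @param model chain kind to simulate: \code{"basic"},
#'   \code{"scored"}, \code{"gd"} or \code{"ax"}.
#' @param founder founder copy number; for \code{"ax"} the founder
#'   gating state, \code{"sigma"} (default) or \code{"tau"}.
#' @param g number of generations.
#' @param nLineages number of independent lineages.
#' @param seed RNG seed; results are reproducible bit-for-bit.
#' @param rule \code{"linearized"} (the chain's division rule: at most
#'   one missegregation per chromosome per division) or
#'   \code{"binomial"} (every copy missegregates independently; the
#'   unlinearised process, for quantifying the neglected O(p^2) terms).
#' @return A [LineageSample-class].
#' @examples
#' sm <- simulateLineages(ChainParams(N = 8, p = 0.01), model = "basic",
#'                        founder = 4, g = 5, nLineages = 1000, seed = 1)
#' sm@viableCounts
#' @export
setMethod("simulateLineages", "ChainParams",
  function(object, model = c("basic", "scored", "gd", "ax"),
           founder = 2, g, nLineages, seed,
           rule = c("linearized", "binomial"), ...) {
  model <- match.arg(model)
  rule <- match.arg(rule)
  N <- object@N; p <- object@p
  stopifnot(nLineages >= 1, g >= 0)
  if (rule == "linearized" && N * p > 1)
    stop("linearized rule needs i*p <= 1 for all states", call. = FALSE)
  q <- checkSimParams(object, model)
  set.seed(as.integer(seed))
  if (model == "ax") {
    start <- if (identical(founder, "tau")) -1L else 0L
    s <- simulateAx(object, g, nLineages, q, start)
    states <- c("sigma", "tau", as.character(seq_len(N)))
    codes <- c(0L, -1L, seq_len(N))
    founder <- 2L                     # both gating states are diploid
  } else {
    founder <- as.integer(founder)
    stopifnot(founder >= 1L, founder <= N)
    s <- rep(founder, nLineages)
    for (t in seq_len(g)) {
      if (model %in% c("scored", "gd")) s <- surviveStep(s, q)
      if (model == "gd") {
        r <- gdStep(s, object@pGd, N)
        s <- r$s
        dup <- r$dup
      } else dup <- logical(length(s))
      nodiv <- dup | is.na(s)
      s[!nodiv] <- divideStep(s[!nodiv], p, N, rule)
      if (all(is.na(s))) break
    }
    states <- as.character(seq_len(N))
    codes <- seq_len(N)
  }
  counts <- vapply(codes, function(cd) sum(s == cd, na.rm = TRUE),
                   integer(1))
  viable <- matrix(counts, nrow = 1L, dimnames = list(NULL, states))
  new("LineageSample", nLineages = as.integer(nLineages),
      seed = as.integer(seed), g = as.integer(g), rule = rule,
      model = model, founder = as.integer(rep_len(founder, 1L)),
      finalStates = matrix(s, ncol = 1L), viableCounts = viable)
})

## early-growth chain: sigma/tau rows follow the chain's linearized
## event semantics (any missegregation among the 46 chromosome copies
## is lethal while an active gating-gene copy remains); codes 0 = sigma,
## -1 = tau, 1..N = copy-number states with no active copy
simulateAx <- function(params, g, nLineages, q, start = 0L) {
  N <- params@N; p <- params@p; mr <- params@mR
  nosplit <- (1 - p)^46
  if (nosplit - 2 * mr < 0)
    stop("(1 - p)^46 - 2*mR is negative", call. = FALSE)
  q2 <- q[min(2L, N)]
  s <- rep(start, nLineages)     # 0 = sigma (default founder), -1 = tau
  for (t in seq_len(g)) {
    pre <- which(!is.na(s) & s <= 0L)
    if (length(pre)) {
      u <- stats::runif(length(pre))
      si <- s[pre]
      out <- si
      ## survival factor q(2) applies in both gating states
      dead <- u >= q2
      u2 <- stats::runif(length(pre))
      isSigma <- si == 0L
      ## sigma: death unless no missegregation among 46 copies;
      ## either active copy may mutate (prob ~ 2 mr) -> tau
      out[isSigma & (u2 < 2 * mr)] <- -1L
      out[isSigma & (u2 >= 2 * mr) & (u2 < 2 * mr + (1 - nosplit))] <-
        NA_integer_
      ## tau: active copy mutates (mr) -> state 2; active copy
      ## missegregates away (p/2) -> state 1; other missegregation
      ## is lethal
      isTau <- si == -1L
      out[isTau & (u2 < mr)] <- 2L
      out[isTau & (u2 >= mr) & (u2 < mr + p / 2)] <- 1L
      out[isTau & (u2 >= mr + p / 2) &
            (u2 < mr + p / 2 + (1 - nosplit - p / 2))] <- NA_integer_
      out[dead] <- NA_integer_
      s[pre] <- out
    }
    post <- !is.na(s) & s > 0L
    if (any(post)) {
      sp <- s[post]
      sp <- surviveStep(sp, q)
      sp <- divideStep(sp, p, N, "linearized")
      s[post] <- sp
    }
    if (all(is.na(s))) break
  }
  s
}

#' @describeIn simulateLineages simulate full 23-chromosome karyotype
#'   lineages of a product-chain model; the cell survival probability
#'   is the joint \eqn{Q_{surv} = e^{c + dS}} of the current karyotype.
#' @export
setMethod("simulateLineages", "KaryotypeModel",
  function(object, g, nLineages, seed,
           rule = c("linearized", "binomial"), ...) {
  rule <- match.arg(rule)
  stopifnot(nLineages >= 1, g >= 0)
  set.seed(as.integer(seed))
  N <- object@N; p <- object@p
  ord <- order(object@scoreTable@chromosome)
  sc <- object@scoreTable@score[ord]
  cc <- object@scoreTable@c; d <- object@scoreTable@d
  S <- matrix(rep(object@founder, each = nLineages), nLineages, 23L)
  alive <- rep(TRUE, nLineages)
  for (t in seq_len(g)) {
    idx <- which(alive)
    if (!length(idx)) break
    qs <- exp(cc + d * as.numeric(S[idx, , drop = FALSE] %*% sc))
    die <- stats::runif(length(idx)) >= qs
    alive[idx[die]] <- FALSE
    idx <- idx[!die]
    if (!length(idx)) break
    if (any(object@pGd > 0)) {
      if (length(object@pGd) != 1L)
        stop("karyotype-level simulation supports a scalar pGd only",
             call. = FALSE)
      ## genome duplication doubles every chromosome simultaneously
      ev <- stats::runif(length(idx)) < object@pGd
      coin <- stats::runif(length(idx)) < 0.5
      dupidx <- idx[ev & coin]
      alive[idx[ev & !coin]] <- FALSE
      if (length(dupidx)) {
        S[dupidx, ] <- 2L * S[dupidx, ]
        over <- rowSums(S[dupidx, , drop = FALSE] > N) > 0L
        alive[dupidx[over]] <- FALSE
      }
      idx <- setdiff(which(alive), dupidx)
    }
    for (k in 1:23) {
      sk <- divideStep(S[idx, k], p, N, rule)
      dead <- is.na(sk)
      S[idx[!dead], k] <- sk[!dead]
      alive[idx[dead]] <- FALSE
      idx <- idx[!dead]
      if (!length(idx)) break
    }
  }
  S[!alive, ] <- NA_integer_
  viable <- t(vapply(1:23, function(k)
    vapply(seq_len(N), function(j) sum(S[, k] == j, na.rm = TRUE),
           integer(1)), integer(N)))
  colnames(viable) <- as.character(seq_len(N))
  new("LineageSample", nLineages = as.integer(nLineages),
      seed = as.integer(seed), g = as.integer(g), rule = rule,
      model = "karyotype", founder = object@founder,
      finalStates = S, viableCounts = viable)
})

#' Time to gating-gene inactivation by direct simulation
#'
#' Monte-Carlo counterpart of [timeToInactivation()]: simulates a
#' population of early-growth lineages and reports the first generation
#' at which more than half of the viable ones have no active copy of
#' the gating gene.  Because raw lineage survival to the inactivation
#' time is typically astronomically small, the conditional-on-viable
#' law is estimated by a particle method: each generation, lineages
#' that die are replaced by copies of uniformly chosen survivors
#' (Fleming-Viot resampling), whose empirical distribution converges to
#' the conditional law of the chain.
#'
#' @param params a [ChainParams-class] (uses \code{p}, \code{mR},
#'   \code{mu}, \code{C}).
#' @param gMax give up after this many generations.
#' @param nLineages number of particles.
#' @param seed RNG seed.
#' @return First such generation, or \code{NA}.
#' @export
simulateInactivationTime <- function(params, gMax, nLineages, seed) {
  stopifnot(is(params, "ChainParams"))
  q <- checkSimParams(params, "ax")
  N <- params@N; p <- params@p; mr <- params@mR
  nosplit <- (1 - p)^46
  if (nosplit - 2 * mr < 0)
    stop("(1 - p)^46 - 2*mR is negative", call. = FALSE)
  set.seed(as.integer(seed))
  q2 <- q[min(2L, N)]
  s <- rep(0L, nLineages)
  for (t in seq_len(gMax)) {
    pre <- which(!is.na(s) & s <= 0L)
    if (length(pre)) {
      u <- stats::runif(length(pre)); u2 <- stats::runif(length(pre))
      si <- s[pre]; out <- si
      isSigma <- si == 0L; isTau <- si == -1L
      out[isSigma & (u2 < 2 * mr)] <- -1L
      out[isSigma & (u2 >= 2 * mr) & (u2 < 2 * mr + (1 - nosplit))] <-
        NA_integer_
      out[isTau & (u2 < mr)] <- 2L
      out[isTau & (u2 >= mr) & (u2 < mr + p / 2)] <- 1L
      out[isTau & (u2 >= mr + p / 2) &
            (u2 < mr + p / 2 + (1 - nosplit - p / 2))] <- NA_integer_
      out[u >= q2] <- NA_integer_
      s[pre] <- out
    }
    post <- !is.na(s) & s > 0L
    if (any(post)) {
      sp <- surviveStep(s[post], q)
      s[post] <- divideStep(sp, p, N, "linearized")
    }
    dead <- which(is.na(s))
    alive <- which(!is.na(s))
    if (!length(alive)) return(NA_integer_)
    if (length(dead))    # Fleming-Viot: respawn on a random survivor
      s[dead] <- s[alive[sample.int(length(alive), length(dead),
                                    replace = TRUE)]]
    if (sum(s > 0L) / length(s) > 0.5) return(t)
  }
  NA_integer_
}

#' Compare empirical lineage frequencies with the chain
#'
#' Goodness-of-fit report between a lineage sample's terminal viable
#' states and the chain trajectory's conditional distribution at the
#' same generation: chi-square statistic and p-value, per-state
#' z-scores, and the surviving-fraction comparison with its binomial
#' standard error.
#'
#' @param sample a [LineageSample-class] (single chromosome).
#' @param trajectory a [Trajectory-class] propagated to
#'   \code{sample@g} from the matching founder.
#' @return list with elements \code{chisq}, \code{df}, \code{pValue},
#'   \code{zScores}, \code{survivingEmpirical},
#'   \code{survivingExpected}, \code{survivingZ} and \code{flag}.
#' @export
empiricalVsChain <- function(sample, trajectory) {
  stopifnot(is(sample, "LineageSample"), is(trajectory, "Trajectory"))
  if (ncol(sample@finalStates) != 1L)
    stop("empiricalVsChain compares single-chromosome samples",
         call. = FALSE)
  g <- sample@g
  if (!g %in% trajectory@generations)
    stop("trajectory does not reach generation ", g, call. = FALSE)
  k <- match(g, trajectory@generations)
  expCond <- trajectory@conditional[k, ]
  obs <- as.numeric(sample@viableCounts[1L, ])
  nAlive <- sum(obs)
  sExp <- exp(trajectory@logSurviving[k])
  sEmp <- nAlive / sample@nLineages
  zSurv <- (sEmp - sExp) /
    sqrt(max(sExp * (1 - sExp), 1e-300) / sample@nLineages)
  if (nAlive == 0L)
    return(list(chisq = NA_real_, df = NA_integer_, pValue = NA_real_,
                zScores = rep(NA_real_, length(obs)),
                survivingEmpirical = 0, survivingExpected = sExp,
                survivingZ = zSurv, flag = "no surviving lineages"))
  keep <- expCond > 0
  expected <- nAlive * expCond[keep] / sum(expCond[keep])
  chisq <- sum((obs[keep] - expected)^2 / expected)
  df <- sum(keep) - 1L
  z <- (obs - nAlive * expCond) /
    sqrt(pmax(nAlive * expCond * (1 - expCond), 1e-300))
  list(chisq = chisq, df = df,
       pValue = stats::pchisq(chisq, df, lower.tail = FALSE),
       zScores = stats::setNames(z, trajectory@states),
       survivingEmpirical = sEmp, survivingExpected = sExp,
       survivingZ = zSurv, flag = "ok")
}
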