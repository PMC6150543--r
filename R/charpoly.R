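## Characteristic polynomials of the tridiagonal chain matrices via the
## three-term recurrence of leading principal minors, plus Sturm-sequence
## root isolation.  Both chain matrices are diagonally similar to a
## symmetric tridiagonal matrix (the products of paired off-diagonal
## entries are positive), so their spectra are real and simple and the
## minor sequence P_0 .. P_N is a Sturm sequence.

## multiply an ascending-coefficient polynomial by x
polyShift <- function(coef) c(0, coef)

polyAdd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  a + b
}

#' Characteristic polynomials of the drift generator
#'
#' Runs the three-term recurrence
#' \eqn{P_n(x) = (x + n) P_{n-1}(x) - \frac{n(n-1)}{4} P_{n-2}(x)},
#' with \eqn{P_0 = 1}, \eqn{P_1 = x + 1}, giving the characteristic
#' polynomials of the leading principal minors of the drift generator
#' \code{J}.  The subtracted second term follows from expanding the
#' tridiagonal determinant along its last row
#' (\eqn{a_{n,n-1} a_{n-1,n} = n(n-1)/4}).
#'
#' All coefficients are dyadic rationals and are represented exactly in
#' double precision up to \code{N = 26}; beyond that the leading
#' coefficients exceed 2^53 and the result would silently round, so
#' larger \code{N} is refused (root finding at large \code{N} uses the
#' scalar recurrence instead and is not affected).
#'
#' @param N highest degree to compute (1 to 26).
#' @return A [CharPolySeq-class] holding \eqn{P_0 \ldots P_N}.
#' @examples
#' cp <- charPolyBasic(8)
#' cp@polys[[9]]  # constant term 2835/2, all terms exact
#' @export
charPolyBasic <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 1L)
  if (N > 26L)
    stop("coefficients are no longer exact in double precision beyond ",
         "N = 26; use largestRoot()/limitingBasic(), which evaluate the ",
         "recurrence pointwise", call. = FALSE)
  polys <- vector("list", N + 1L)
  polys[[1L]] <- 1
  polys[[2L]] <- c(1, 1)
  if (N >= 2L) for (n in 2:N) {
    a <- polys[[n]]        # P_{n-1}
    b <- polys[[n - 1L]]   # P_{n-2}
    polys[[n + 1L]] <- polyAdd(polyAdd(polyShift(a), n * a),
                               -n * (n - 1) / 4 * b)
  }
  new("CharPolySeq", polys = polys, N = N, kind = "basic",
      p = NA_real_, mu = NA_real_)
}

#' Characteristic polynomials of the score chain
#'
#' Runs the recurrence
#' \eqn{P_n(x) = (x - \mu^n(1 - np)) P_{n-1}(x)
#'   - \mu^{2n-1} p^2 \frac{n(n-1)}{4} P_{n-2}(x)},
#' \eqn{P_0 = 1}, \eqn{P_1 = x - \mu(1-p)}, for the score chain
#' \code{A} with \eqn{C = 1} (the constant \eqn{C} rescales the whole
#' matrix and is irrelevant to conditional distributions).
#'
#' @param N highest degree to compute.
#' @param p missegregation rate, \code{0 < p <= 1/N}.
#' @param mu survival multiplier.
#' @return A [CharPolySeq-class].
#' @export
charPolyScored <- function(N, p, mu) {
  N <- as.integer(N)
  stopifnot(N >= 1L, p > 0, p <= 1 / N, mu > 0)
  polys <- vector("list", N + 1L)
  polys[[1L]] <- 1
  polys[[2L]] <- c(-mu * (1 - p), 1)
  if (N >= 2L) for (n in 2:N) {
    a <- polys[[n]]
    b <- polys[[n - 1L]]
    polys[[n + 1L]] <- polyAdd(
      polyAdd(polyShift(a), -mu^n * (1 - n * p) * a),
      -mu^(2 * n - 1) * p^2 * n * (n - 1) / 4 * b)
  }
  new("CharPolySeq", polys = polys, N = N, kind = "scored",
      p = p, mu = mu)
}

## recurrence coefficients: P_n = (x - diag_n) P_{n-1} - off_n P_{n-2}
recurCoefs <- function(kind, n, p, mu) {
  if (kind == "basic")
    list(diag = -n, off = n * (n - 1) / 4)
  else
    list(diag = mu^n * (1 - n * p), off = mu^(2 * n - 1) * p^2 * n * (n - 1) / 4)
}

## evaluate the full minor sequence at scalar x with log-scaling;
## returns signs and log absolute values of P_0(x) .. P_N(x)
evalMinorSeq <- function(kind, N, p, mu, x) {
  logAbs <- numeric(N + 1L)
  sgn <- integer(N + 1L)
  s <- 0                      # shared log scale of (a, b)
  b <- 1                      # P_{n-2} (scaled)
  a <- x - recurCoefs(kind, 1L, p, mu)$diag  # P_1 at n = 1
  if (kind == "basic") a <- x + 1
  logAbs[1L] <- 0; sgn[1L] <- 1L
  logAbs[2L] <- if (a == 0) -Inf else log(abs(a)); sgn[2L] <- sign(a)
  if (N >= 2L) for (n in 2:N) {
    co <- recurCoefs(kind, n, p, mu)
    cc <- (x - co$diag) * a - co$off * b
    b <- a; a <- cc
    m <- max(abs(a), abs(b))
    if (m > 1e100 || (m < 1e-100 && m > 0)) {
      a <- a / m; b <- b / m; s <- s + log(m)
    }
    logAbs[n + 1L] <- if (a == 0) -Inf else log(abs(a)) + s
    sgn[n + 1L] <- sign(a)
  }
  list(logAbs = logAbs, sign = sgn)
}

## Sturm count: the number of sign changes along the minor sequence
## P_0(x) .. P_N(x) equals the number of eigenvalues strictly above x
## (zeros take the opposite sign of their predecessor)
sturmAbove <- function(kind, N, p, mu, x) {
  sq <- evalMinorSeq(kind, N, p, mu, x)$sign
  prev <- 1L
  count <- 0L
  for (i in seq_len(N) + 1L) {
    s <- sq[i]
    if (s == 0L) s <- -prev
    if (s != prev) count <- count + 1L
    prev <- s
  }
  count
}

## k-th largest root: bisection on the Sturm count, then Newton polish
## on P_N (all roots are simple)
sturmRoot <- function(kind, N, p, mu, k, lo, hi) {
  flo <- sturmAbove(kind, N, p, mu, lo)
  fhi <- sturmAbove(kind, N, p, mu, hi)
  if (flo < k || fhi >= k)
    stop("root bracket failed (internal error)", call. = FALSE)
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (sturmAbove(kind, N, p, mu, mid) >= k) lo <- mid else hi <- mid
    if (hi - lo <= 1e-13 * max(1, abs(hi))) break
  }
  root <- (lo + hi) / 2
  ## Newton refinement with a derivative recurrence, scale-invariant
  for (iter in 1:8) {
    pv <- 1; dv <- 0                      # P_0, P_0'
    av <- if (kind == "basic") root + 1 else root - mu * (1 - p)
    ad <- 1                               # P_1, P_1'
    if (N >= 2L) for (n in 2:N) {
      co <- recurCoefs(kind, n, p, mu)
      nv <- (root - co$diag) * av - co$off * pv
      nd <- av + (root - co$diag) * ad - co$off * dv
      pv <- av; dv <- ad; av <- nv; ad <- nd
      m <- max(abs(av), abs(pv), abs(ad), abs(dv))
      if (m > 1e100) { av <- av / m; pv <- pv / m; ad <- ad / m; dv <- dv / m }
    }
    if (ad == 0) break
    step <- av / ad
    cand <- root - step
    if (!is.finite(cand) || cand < lo - (hi - lo) || cand > hi + (hi - lo))
      break
    root <- cand
    if (abs(step) <= 1e-15 * max(1, abs(root))) break
  }
  root
}

## spectral bracket from Gershgorin discs of the tridiagonal matrix
spectrumBracket <- function(kind, N, p, mu) {
  i <- seq_len(N)
  if (kind == "basic") {
    centers <- -i; radii <- i
  } else {
    centers <- mu^i * (1 - i * p); radii <- i * p * mu^i
  }
  c(min(centers - radii) - 1, max(centers + radii) + 1)
}

#' Largest real root of a characteristic polynomial
#'
#' Finds the largest eigenvalue of the underlying tridiagonal matrix as
#' the largest root of \eqn{P_N}, by bisection on the Sturm sign count
#' of the minor sequence (bracketed by Gershgorin bounds) followed by
#' Newton refinement.  The spectrum is real and simple because the
#' matrix is diagonally similar to a symmetric tridiagonal one.
#'
#' @param cp a [CharPolySeq-class] from [charPolyBasic()] or
#'   [charPolyScored()].
#' @param which rank of the root from above (1 = largest, 2 = second
#'   largest, ..., N = smallest).
#' @return The requested real root.
#' @examples
#' largestRoot(charPolyBasic(1))            # -1 exactly
#' round(largestRoot(charPolyBasic(2)), 7)  # (-3 + sqrt(3))/2
#' @export
largestRoot <- function(cp, which = 1L) {
  stopifnot(is(cp, "CharPolySeq"), which >= 1L, which <= cp@N)
  br <- spectrumBracket(cp@kind, cp@N, cp@p, cp@mu)
  sturmRoot(cp@kind, cp@N, cp@p, cp@mu, k = as.integer(which),
            lo = br[1L], hi = br[2L])
}

## root finding without materialising coefficient vectors (any N)
leadingRoots <- function(kind, N, p = NA_real_, mu = NA_real_) {
  br <- spectrumBracket(kind, N, p, mu)
  alpha <- sturmRoot(kind, N, p, mu, k = 1L, lo = br[1L], hi = br[2L])
  second <- if (N >= 2L)
    sturmRoot(kind, N, p, mu, k = 2L, lo = br[1L], hi = br[2L])
  else NA_real_
  smallest <- if (N >= 2L)
    sturmRoot(kind, N, p, mu, k = N, lo = br[1L], hi = br[2L])
  else alpha
  list(alpha = alpha, second = second, smallest = smallest)
}
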