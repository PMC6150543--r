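# Independent oracle constructions: matrices are written out from the
# per-entry rules directly (no shared code with the builders), spectra
# come from base eigen(), determinants from pracma.

oracleJ <- function(N) {
  J <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) J[i, j] <- -i
    else if (abs(i - j) == 1) J[i, j] <- i / 2
  }
  J
}

oracleM <- function(N, p) diag(N) + p * oracleJ(N)

oracleA <- function(N, p, mu, C = 1) {
  A <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    q <- C * mu^i
    if (i == j) A[i, j] <- (1 - i * p) * q
    else if (abs(i - j) == 1) A[i, j] <- i * p * q / 2
  }
  A
}

# left Perron eigenvector of a matrix, normalised to sum 1
oracleQSD <- function(T) {
  e <- eigen(t(T))
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  list(rho = Re(e$values[k]), v = v / sum(v))
}

tvDist <- function(a, b) sum(abs(a - b)) / 2

rowEntropy <- function(a) {
  -sum(ifelse(a > 0, a * log(a), 0))
}

# chi-square goodness of fit of counts against probabilities
gofPValue <- function(counts, probs) {
  keep <- probs > 0
  n <- sum(counts)
  expected <- n * probs[keep] / sum(probs[keep])
  stat <- sum((counts[keep] - expected)^2 / expected)
  stats::pchisq(stat, sum(keep) - 1L, lower.tail = FALSE)
}

stdScores <- function() hg23Scores()
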