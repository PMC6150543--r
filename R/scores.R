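#' Construct a chromosome score table
#'
#' Builds a [ScoreTable-class] from the 23 chromosome scores \eqn{s_k},
#' deriving the survival multipliers \eqn{\mu_k = e^{d s_k}}.  Defaults
#' for \code{c} and \code{d} are the estimates used throughout the model
#' (\code{c} chosen so that the survival probability never exceeds 1 for
#' valid karyotypes, \code{d} fitted from experimental data).
#'
#' @param score numeric vector of 23 chromosome scores.
#' @param c global survival constant (default -0.036132164).
#' @param d score-to-survival scale (default 0.00039047).
#' @param chromosome integer chromosome labels (default 1..23).
#' @return A [ScoreTable-class].
#' @examples
#' st <- ScoreTable(score = rep(0, 23))
#' muValues(st)  # all 1: no score effect
#' @export
ScoreTable <- function(score, c = -0.036132164, d = 0.00039047,
                       chromosome = seq_along(score)) {
  new("ScoreTable", chromosome = as.integer(chromosome),
      score = as.numeric(score), mu = exp(d * as.numeric(score)),
      c = c, d = d)
}

#' Read a chromosome score table from TSV
#'
#' Expects a header row and three tab-separated columns
#' \code{chromosome}, \code{score}, \code{mu}.  The \code{mu} column is
#' validated against \eqn{e^{d s_k}} to 1e-9 relative.
#'
#' @param path path to the TSV file.
#' @param c,d survival constants (defaults as in [ScoreTable()]).
#' @return A [ScoreTable-class].
#' @export
readScoreTable <- function(path, c = -0.036132164, d = 0.00039047) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 3L)
    stop("score table must have exactly 3 columns (chromosome, score, mu), ",
         "found ", ncol(tab))
  names(tab) <- c("chromosome", "score", "mu")
  for (col in names(tab)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad))
      stop("non-numeric '", col, "' in row ", bad[1L])
  }
  chrom <- as.integer(tab$chromosome)
  dup <- chrom[duplicated(chrom)]
  if (length(dup))
    stop("duplicate chromosome label(s): ", paste(unique(dup), collapse = ", "))
  missing <- setdiff(1:23, chrom)
  if (length(missing))
    stop("missing chromosome(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(chrom, 1:23)
  if (length(extra))
    stop("unexpected chromosome label(s): ", paste(extra, collapse = ", "))
  new("ScoreTable", chromosome = chrom, score = as.numeric(tab$score),
      mu = as.numeric(tab$mu), c = c, d = d)
}

#' Built-in human chromosome scores
#'
#' The packaged table of experimentally derived scores for the 23 human
#' chromosomes (the sex chromosome, label 23, has score 0), with the
#' corresponding survival multipliers \eqn{\mu_k}.
#'
#' @return A [ScoreTable-class] with 23 rows.
#' @examples
#' st <- hg23Scores()
#' muValues(st)[7]  # chromosome 7, the most oncogenic
#' @export
hg23Scores <- function() {
  path <- system.file("extdata", "chromosome_scores.tsv",
                      package = "karyoMC", mustWork = TRUE)
  readScoreTable(path)
}

#' Write a score table as TSV
#'
#' Inverse of [readScoreTable()]; values are written with full precision
#' so a round trip reproduces the in-memory table exactly.
#'
#' @param object a [ScoreTable-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoreTable <- function(object, path) {
  stopifnot(is(object, "ScoreTable"))
  tab <- data.frame(chromosome = object@chromosome,
                    score = formatC(object@score, format = "g", digits = 17),
                    mu = formatC(object@mu, format = "g", digits = 17))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("chromosomeScores", "ScoreTable", function(object) {
  stats::setNames(object@score, object@chromosome)
})

#' @rdname accessors
#' @export
setMethod("muValues", "ScoreTable", function(object) {
  stats::setNames(object@mu, object@chromosome)
})

#' @rdname accessors
#' @export
setMethod("survivalConstants", "ScoreTable", function(object) {
  c(c = object@c, d = object@d)
})

#' Cell survival probability of a karyotype
#'
#' Computes \eqn{Q_{surv} = e^{c + d \sum_k s_k n_k}}, the probability
#' that a cell with the given karyotype survives (does not spontaneously
#' die) at a given generation.  By the factorisation
#' \eqn{Q_{surv} = \prod_k q_k(n_k)} this equals the product of the 23
#' per-chromosome factors [survivalFactor()] with \eqn{C = e^{c/23}}.
#'
#' @param scores a [ScoreTable-class].
#' @param karyotype integer vector of 23 copy numbers.
#' @return survival probability in (0, 1].
#' @examples
#' st <- hg23Scores()
#' karyotypeSurvival(st, rep(2, 23))  # a diploid cell
#' @export
karyotypeSurvival <- function(scores, karyotype) {
  stopifnot(is(scores, "ScoreTable"), length(karyotype) == 23L)
  ord <- order(scores@chromosome)
  S <- sum(scores@score[ord] * karyotype)
  exp(scores@c + scores@d * S)
}
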