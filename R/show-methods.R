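#' @describeIn ChainParams-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "ChainParams", function(object) {
  cat("ChainParams: N =", object@N, ", p =", object@p,
      ", mu =", object@mu, ", C =", object@Ck, "\n")
  if (any(object@pGd > 0))
    cat("  genome duplication pGd =",
        paste(signif(object@pGd, 4), collapse = " "), "\n")
  if (object@mR > 0) cat("  gating-gene mutation mR =", object@mR, "\n")
})

#' @describeIn ScoreTable-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable with", length(object@chromosome), "chromosomes",
      "(c =", object@c, ", d =", object@d, ")\n")
  cat("  mu range:", format(min(object@mu), digits = 7), "..",
      format(max(object@mu), digits = 7), "\n")
})

#' @describeIn MissegChain-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "MissegChain", function(object) {
  cat("MissegChain (", object@kind, "): ",
      length(object@states), " non-absorbing states, p = ",
      object@params@p, "\n", sep = "")
  cat("  total death mass:", signif(sum(object@deathMass), 4), "\n")
})

#' @describeIn QuasiStationary-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "QuasiStationary", function(object) {
  cat("Quasi-stationary distribution (", object@method, ")\n", sep = "")
  print(round(object@v, 5))
  cat("  mean copies:", round(object@meanCopies, 4),
      " mode:", object@mode, "\n")
  if (is.finite(object@rho))
    cat("  rho:", format(object@rho, digits = 8),
        " rho~:", format(object@rhoTilde, digits = 8),
        " mixing ~", signif(object@mixingEstimate, 4), "\n")
  if (object@reducible)
    cat("  note: chain not irreducible on non-absorbing states\n")
})

#' @describeIn Trajectory-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "Trajectory", function(object) {
  g <- max(object@generations)
  cat("Trajectory over", g, "generations,",
      length(object@states), "states\n")
  cat("  final surviving fraction:",
      format(exp(object@logSurviving[length(object@logSurviving)]),
             digits = 6), "\n")
  if (object@truncated) cat("  truncated: all mass absorbed\n")
})

#' @describeIn KaryotypeModel-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "KaryotypeModel", function(object) {
  cat("KaryotypeModel: 23 chromosomes, N =", object@N,
      ", p =", object@p, "\n")
  cat("  founder karyotype:", paste(object@founder, collapse = " "), "\n")
  if (any(object@pGd > 0))
    cat("  genome duplication pGd =",
        paste(signif(object@pGd, 4), collapse = " "), "\n")
})

#' @describeIn DiversitySurface-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "DiversitySurface", function(object) {
  cat("DiversitySurface:", length(object@gGrid), "generations x",
      length(object@pGrid), "rates\n")
  cat("  K range:", signif(min(object@K), 4), "..",
      signif(max(object@K), 4), "\n")
})

#' @describeIn LineageSample-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "LineageSample", function(object) {
  alive <- sum(stats::complete.cases(object@finalStates))
  cat("LineageSample:", object@nLineages, "lineages,",
      object@g, "generations (", object@model, ",", object@rule,
      ", seed", object@seed, ")\n")
  cat("  surviving:", alive,
      sprintf("(%.3f)", alive / object@nLineages), "\n")
})

#' @describeIn CharPolySeq-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "CharPolySeq", function(object) {
  cat("CharPolySeq (", object@kind, "): P_0 .. P_",
      object@N, "\n", sep = "")
  cat("  P_", object@N, " coefficients (ascending): ",
      paste(format(object@polys[[object@N + 1L]]), collapse = ", "),
      "\n", sep = "")
})
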