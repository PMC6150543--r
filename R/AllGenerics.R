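#' Accessors for chain and result objects
#'
#' Small generic accessors used across the package's S4 classes.
#'
#' @param object a package object.
#' @param ... passed to methods.
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) {
  standardGeneric("transitionMatrix")
})

#' @rdname accessors
#' @export
setGeneric("deathMass", function(object) standardGeneric("deathMass"))

#' @rdname accessors
#' @export
setGeneric("chainStates", function(object) standardGeneric("chainStates"))

#' @rdname accessors
#' @export
setGeneric("chainKind", function(object) standardGeneric("chainKind"))

#' @rdname accessors
#' @export
setGeneric("chainParams", function(object) standardGeneric("chainParams"))

#' @rdname accessors
#' @export
setGeneric("limitDist", function(object) standardGeneric("limitDist"))

#' @rdname accessors
#' @export
setGeneric("meanCopies", function(object) standardGeneric("meanCopies"))

#' @rdname accessors
#' @export
setGeneric("modalCopy", function(object) standardGeneric("modalCopy"))

#' @rdname accessors
#' @export
setGeneric("mixingEstimate", function(object) {
  standardGeneric("mixingEstimate")
})

#' @rdname accessors
#' @export
setGeneric("chromosomeScores", function(object) {
  standardGeneric("chromosomeScores")
})

#' @rdname accessors
#' @export
setGeneric("muValues", function(object) standardGeneric("muValues"))

#' @rdname accessors
#' @export
setGeneric("survivalConstants", function(object) {
  standardGeneric("survivalConstants")
})

#' @rdname accessors
#' @export
setGeneric("conditionalDist", function(object, ...) {
  standardGeneric("conditionalDist")
})

#' Quasi-stationary distribution of a built chain
#'
#' @param object the object to analyse.
#' @param ... passed to methods.
#' @export
setGeneric("quasiStationary", function(object, ...) {
  standardGeneric("quasiStationary")
})

#' Propagate a copy-number distribution over generations
#'
#' @param object a chain or model.
#' @param ... passed to methods.
#' @export
setGeneric("propagate", function(object, ...) standardGeneric("propagate"))

#' Surviving fraction after g generations
#'
#' @param object a chain or trajectory.
#' @param ... passed to methods.
#' @export
setGeneric("survivingFraction", function(object, ...) {
  standardGeneric("survivingFraction")
})

#' Per-generation mean copy number
#'
#' @param object a chain or karyotype model.
#' @param ... passed to methods.
#' @export
setGeneric("meanCopyTrajectory", function(object, ...) {
  standardGeneric("meanCopyTrajectory")
})

#' Simulate random cell lineages
#'
#' @param object chain parameters or a karyotype model.
#' @param ... passed to methods.
#' @export
setGeneric("simulateLineages", function(object, ...) {
  standardGeneric("simulateLineages")
})
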