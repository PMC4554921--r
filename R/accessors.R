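#' @rdname PeptideProteinMap-class
#' @param x,object a \linkS4class{PeptideProteinMap} or
#'   \linkS4class{ProteinGroupSet}.
#' @export
setGeneric("peptideMap", function(x) standardGeneric("peptideMap"))

#' @rdname PeptideProteinMap-class
#' @export
setMethod("peptideMap", "PeptideProteinMap", function(x) x@map)

#' @rdname PeptideProteinMap-class
#' @export
setGeneric("orphanPeptides", function(x) standardGeneric("orphanPeptides"))

#' @rdname PeptideProteinMap-class
#' @export
setMethod("orphanPeptides", "PeptideProteinMap", function(x) x@orphans)

#' @rdname ProteinGroupSet-class
#' @export
setMethod("orphanPeptides", "ProteinGroupSet", function(x) x@orphans)

setMethod("length", "PeptideProteinMap", function(x) length(x@map))

setMethod("show", "PeptideProteinMap", function(object) {
  cat(sprintf("PeptideProteinMap: %d peptide(s), %d orphan(s)\n",
              length(object@map), length(object@orphans)))
})

#' @rdname ProteinGroupSet-class
#' @param x,object a \linkS4class{ProteinGroupSet}.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname ProteinGroupSet-class
#' @export
setMethod("representatives", "ProteinGroupSet", function(x) x@representative)

#' @rdname ProteinGroupSet-class
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))

#' @rdname ProteinGroupSet-class
#' @export
setMethod("groupMembers", "ProteinGroupSet", function(x) {
  stats::setNames(x@members, x@representative)
})

#' @rdname ProteinGroupSet-class
#' @export
setGeneric("uniquePeptides", function(x) standardGeneric("uniquePeptides"))

#' @rdname ProteinGroupSet-class
#' @export
setMethod("uniquePeptides", "ProteinGroupSet", function(x) {
  stats::setNames(x@uniquePeptides, x@representative)
})

#' @rdname ProteinGroupSet-class
#' @export
setGeneric("sharedPeptides", function(x) standardGeneric("sharedPeptides"))

#' @rdname ProteinGroupSet-class
#' @export
setMethod("sharedPeptides", "ProteinGroupSet", function(x) {
  stats::setNames(x@sharedPeptides, x@representative)
})

setMethod("length", "ProteinGroupSet", function(x) length(x@representative))

setMethod("show", "ProteinGroupSet", function(object) {
  nu <- sum(lengths(object@uniquePeptides))
  ns <- length(unique(unlist(object@sharedPeptides)))
  cat(sprintf(paste0("ProteinGroupSet: %d group(s), %d unique peptide(s), ",
                     "%d shared peptide(s), %d orphan(s)\n"),
              length(object), nu, ns, length(object@orphans)))
  if (length(object)) {
    k <- min(5L, length(object))
    for (i in seq_len(k))
      cat(sprintf("  %s [%d member(s); %d unique, %d shared]\n",
                  object@representative[i], length(object@members[[i]]),
                  length(object@uniquePeptides[[i]]),
                  length(object@sharedPeptides[[i]])))
    if (length(object) > k) cat(sprintf("  ... and %d more\n",
                                        length(object) - k))
  }
})

setMethod("show", "GoldScene", function(object) {
  cat(sprintf("GoldScene '%s' (animal %s, dilution %s%s)\n",
              object@sceneId, object@animal, object@dilution,
              if (object@isControl) ", control" else ""))
  comp <- vapply(object@structures, `[[`, character(1), "compartment")
  cat(sprintf("  %d structure(s): %s\n", length(object@structures),
              paste(sprintf("%s x%d", names(table(comp)), table(comp)),
                    collapse = ", ")))
  cat(sprintf("  %d particle(s)\n", nrow(object@particles)))
})

#' @rdname GoldScene-class
#' @param x a \linkS4class{GoldScene}.
#' @export
setGeneric("sceneStructures", function(x) standardGeneric("sceneStructures"))

#' @rdname GoldScene-class
#' @export
setMethod("sceneStructures", "GoldScene", function(x) x@structures)

#' @rdname GoldScene-class
#' @export
setGeneric("sceneParticles", function(x) standardGeneric("sceneParticles"))

#' @rdname GoldScene-class
#' @export
setMethod("sceneParticles", "GoldScene", function(x) x@particles)

#' @rdname GoldScene-class
#' @export
setGeneric("isControl", function(x) standardGeneric("isControl"))

#' @rdname GoldScene-class
#' @export
setMethod("isControl", "GoldScene", function(x) x@isControl)

#' Replicate-averaged fraction profile of a FractionQuant
#'
#' Per-fraction arithmetic mean and sample standard deviation (n - 1
#' denominator; 0 when n = 1) of the percent-of-total values across
#' replicates.
#'
#' @param x a \linkS4class{FractionQuant}.
#' @return list with matrices \code{mean} and \code{sd} (group x fraction)
#'   and integer vector \code{n} (replicates per fraction).
#' @export
setGeneric("fractionProfile", function(x) standardGeneric("fractionProfile"))

#' @rdname fractionProfile
#' @export
setMethod("fractionProfile", "FractionQuant", function(x) {
  S4Vectors::metadata(x)$profile
})
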