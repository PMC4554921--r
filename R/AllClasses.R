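#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom jsonlite read_json write_json
#' @importFrom stats setNames rpois rmultinom runif rnorm sd dist hclust
#'   as.dist cor rlnorm
#' @importFrom utils read.delim write.table head packageVersion
NULL

#' Peptide-to-protein map
#'
#' Maps each peptide sequence to the set of database accessions whose amino
#' acid sequence contains it as an exact substring. Peptides matching no
#' database entry are kept apart as orphans; they are reported and excluded
#' from inference and quantification.
#'
#' @slot map named list; each element is a character vector of accessions
#'   containing that peptide.
#' @slot orphans character vector of peptides matching no database sequence.
#'
#' @seealso [mapPeptides()], [inferMinimalSet()]
#' @exportClass PeptideProteinMap
setClass("PeptideProteinMap",
  representation(map = "list", orphans = "character"))

setValidity("PeptideProteinMap", function(object) {
  msg <- character()
  if (length(object@map) > 0L) {
    if (is.null(names(object@map)) || anyNA(names(object@map)) ||
        any(names(object@map) == ""))
      msg <- c(msg, "every peptide in 'map' must be named")
    n <- lengths(object@map)
    if (any(n < 1L))
      msg <- c(msg, "every mapped peptide must have >= 1 accession")
  }
  if (any(object@orphans %in% names(object@map)))
    msg <- c(msg, "orphans must not appear in 'map'")
  if (length(msg)) msg else TRUE
})

#' Minimal-set protein groups
#'
#' The result of parsimony protein inference: the minimum set of protein
#' groups that explains every confidently matched (non-orphan) peptide.
#' Each group has a representative accession, a member set (proteins with
#' identical peptide evidence, plus proteins whose evidence is a strict
#' subset of the group's), and its peptide evidence split into peptides
#' unique to the group and peptides shared with other retained groups.
#'
#' @slot representative character vector, one representative accession per
#'   group (lexicographically smallest member with full evidence).
#' @slot members list of character vectors of member accessions.
#' @slot uniquePeptides list of character vectors; peptides contained only
#'   in this group's members among all retained groups.
#' @slot sharedPeptides list of character vectors; peptides contained in
#'   two or more retained groups.
#' @slot orphans character vector of peptides excluded because they match
#'   no database protein.
#'
#' @seealso [inferMinimalSet()], [classifyPeptides()]
#' @exportClass ProteinGroupSet
setClass("ProteinGroupSet",
  representation(representative = "character", members = "list",
                 uniquePeptides = "list", sharedPeptides = "list",
                 orphans = "character"))

setValidity("ProteinGroupSet", function(object) {
  msg <- character()
  n <- length(object@representative)
  if (length(object@members) != n || length(object@uniquePeptides) != n ||
      length(object@sharedPeptides) != n)
    msg <- c(msg, "slot lengths disagree")
  if (anyDuplicated(object@representative))
    msg <- c(msg, "duplicated representative accessions")
  for (i in seq_len(n)) {
    if (!(object@representative[i] %in% object@members[[i]]))
      msg <- c(msg, sprintf("representative %s not among its members",
                            object@representative[i]))
    if (length(object@uniquePeptides[[i]]) +
        length(object@sharedPeptides[[i]]) < 1L)
      msg <- c(msg, sprintf("group %s has no peptide evidence",
                            object@representative[i]))
    if (length(intersect(object@uniquePeptides[[i]],
                         object@sharedPeptides[[i]])) > 0L)
      msg <- c(msg, sprintf("group %s: unique and shared peptides overlap",
                            object@representative[i]))
  }
  if (length(msg)) msg else TRUE
})

#' Fraction-resolved quantification matrix
#'
#' A \linkS4class{SummarizedExperiment} holding protein-group by sample
#' spectral-count quantification. Assays: \code{rawUnique} (integer counts
#' from unique peptides), \code{apportioned} (counts after proportional
#' allocation of shared spectra; fractional values permitted) and
#' \code{percent} (percent of total apportioned counts per sample).
#' \code{colData} carries \code{fraction} and \code{replicate};
#' \code{metadata} carries the replicate-averaged \code{profile} (per
#' fraction mean, s.d. and n of the percent values).
#'
#' @seealso [quantifySpectra()], [fractionProfile()]
#' @exportClass FractionQuant
setClass("FractionQuant", contains = "SummarizedExperiment")

setValidity("FractionQuant", function(object) {
  msg <- character()
  need <- c("rawUnique", "apportioned", "percent")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have))
    msg <- c(msg, paste("missing assay(s):",
                        paste(setdiff(need, have), collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("fraction", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'fraction' and 'replicate'")
  if ("percent" %in% have && ncol(object) > 0L && nrow(object) > 0L) {
    cs <- colSums(SummarizedExperiment::assay(object, "percent"))
    if (any(abs(cs - 100) > 1e-9))
      msg <- c(msg, "percent columns must each sum to 100 (within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' One immunogold micrograph scene
#'
#' Membrane traces and gold-particle coordinates digitized from a single
#' electron micrograph, in nanometres (image convention: origin top left, y
#' increasing downward). Structures are polylines labelled with a
#' compartment (\code{plasma_membrane}, \code{cisterna} or \code{flagellum})
#' and a section kind (\code{cross} or \code{oblique}); closed polylines
#' bound a region so distances to them can be signed (negative =
#' intracellular side).
#'
#' @slot sceneId character scalar identifier.
#' @slot animal character scalar; the source animal label.
#' @slot dilution character scalar; primary-antibody dilution label,
#'   e.g. \code{"1:5"}.
#' @slot isControl logical scalar; \code{TRUE} for no-primary-antibody
#'   control micrographs.
#' @slot structures list of structures; each a list with elements
#'   \code{compartment}, \code{sectionKind}, \code{closed} (logical) and
#'   \code{coords} (numeric n x 2 matrix, nm).
#' @slot particles data.frame with columns \code{x}, \code{y} (nm) and
#'   \code{truth} (character, \code{NA} when the generating compartment is
#'   unknown, as for real data).
#'
#' @seealso [generateGoldScenes()], [classifyParticles()],
#'   [zoneDistribution()]
#' @exportClass GoldScene
setClass("GoldScene",
  representation(sceneId = "character", animal = "character",
                 dilution = "character", isControl = "logical",
                 structures = "list", particles = "data.frame"))

.validCompartments <- c("plasma_membrane", "cisterna", "flagellum")
.validSectionKinds <- c("cross", "oblique")

setValidity("GoldScene", function(object) {
  msg <- character()
  for (s in c("sceneId", "animal", "dilution")) {
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("'%s' must be a single string", s))
  }
  if (length(object@isControl) != 1L || is.na(object@isControl))
    msg <- c(msg, "'isControl' must be TRUE or FALSE")
  comps <- character()
  for (i in seq_along(object@structures)) {
    st <- object@structures[[i]]
    if (!all(c("compartment", "sectionKind", "closed", "coords") %in%
             names(st))) {
      msg <- c(msg, sprintf("structure %d incomplete", i)); next
    }
    if (!(st$compartment %in% .validCompartments))
      msg <- c(msg, sprintf("structure %d: unknown compartment '%s'", i,
                            st$compartment))
    if (!(st$sectionKind %in% .validSectionKinds))
      msg <- c(msg, sprintf("structure %d: unknown section kind '%s'", i,
                            st$sectionKind))
    if (!is.matrix(st$coords) || ncol(st$coords) != 2L ||
        nrow(st$coords) < 2L)
      msg <- c(msg, sprintf("structure %d: polyline needs >= 2 vertices", i))
    else if (!all(is.finite(st$coords)))
      msg <- c(msg, sprintf("structure %d: non-finite coordinates", i))
    comps <- c(comps, st$compartment)
  }
  if (!isTRUE(object@isControl) && !("plasma_membrane" %in% comps))
    msg <- c(msg, "non-control scenes need >= 1 plasma_membrane structure")
  p <- object@particles
  if (!all(c("x", "y", "truth") %in% colnames(p)))
    msg <- c(msg, "particles need columns x, y, truth")
  else if (nrow(p) > 0L && !all(is.finite(p$x) & is.finite(p$y)))
    msg <- c(msg, "non-finite particle coordinates")
  if (length(msg)) msg else TRUE
})
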