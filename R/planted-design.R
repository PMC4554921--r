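#' Planted fraction-abundance design
#'
#' Builds an abundance matrix with a known enrichment structure: a block
#' of proteins enriched in the target fraction by a fixed planted fold, a
#' block enriched in the reference fractions by the same fold, and a flat
#' block, all scaled by log-normal per-protein magnitudes shared across
#' fractions. Because the planted fold acts on within-column weights, the
#' expected percent-of-total ratio between target and references equals
#' the planted fold up to the (small) imbalance of the magnitude draws.
#'
#' @param accessions protein accessions; length must equal
#'   \code{nEnriched + nReference + nFlat}.
#' @param fractions ordered fraction labels; the first is the target.
#' @param nEnriched,nReference,nFlat block sizes.
#' @param plantedFold within-column weight ratio for the enriched blocks
#'   (default 6).
#' @param sdlog log-normal s.d. of the per-protein magnitudes
#'   (default 0.4).
#' @param seed integer seed.
#' @return list with \code{abundance} (protein x fraction, columns sum to
#'   1) and \code{truth} (character vector: \code{enriched},
#'   \code{reference}, \code{flat}).
#' @export
plantedAbundance <- function(accessions,
                             fractions = c("HermesBody", "TestisGolgi",
                                           "LiverGolgi", "LiverER",
                                           "COPI"),
                             nEnriched = 10L, nReference = 10L,
                             nFlat = 10L, plantedFold = 6,
                             sdlog = 0.4, seed = 1L) {
  n <- nEnriched + nReference + nFlat
  stopifnot(length(accessions) == n, length(fractions) >= 2L)
  set.seed(childSeed(seed, "plant"))
  truth <- rep(c("enriched", "reference", "flat"),
               c(nEnriched, nReference, nFlat))
  b <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  w <- matrix(1, n, length(fractions),
              dimnames = list(accessions, fractions))
  w[truth == "enriched", 1L] <- plantedFold
  w[truth == "reference", -1L] <- plantedFold
  a <- w * b
  a <- sweep(a, 2L, colSums(a), "/")
  list(abundance = a, truth = stats::setNames(truth, accessions))
}

#' Random functional-category annotation
#'
#' Assigns each accession a category drawn uniformly from the closed
#' 22-name vocabulary; used by the synthetic pipeline so category rollups
#' have known input.
#'
#' @param accessions character vector.
#' @param seed integer seed.
#' @return data.frame with \code{accession} and \code{category}.
#' @export
randomAnnotation <- function(accessions, seed = 1L) {
  set.seed(childSeed(seed, "annotation"))
  data.frame(accession = accessions,
             category = sample(functionalCategories(),
                               length(accessions), replace = TRUE),
             stringsAsFactors = FALSE)
}
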