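#' Describe a subcellular fractionation experiment
#'
#' Fixes the sampling design under which synthetic spectral counts are
#' drawn: the ordered fraction labels, each protein's relative abundance in
#' each fraction (columns sum to 1), the number of biological replicates
#' per fraction, and the expected sequencing depth (total spectra) per
#' replicate.
#'
#' @param abundance numeric protein x fraction matrix with rownames
#'   (accessions) and colnames (fraction labels); every column must sum to
#'   1 within 1e-9 and entries must be non-negative.
#' @param replicates replicates per fraction, a single integer in 1..10
#'   recycled over fractions, or one integer per fraction.
#' @param depth expected total spectra per replicate (Poisson mean, >= 1).
#' @param seed integer seed for the spectral sampling.
#' @return a \code{FractionDesign} list.
#' @examples
#' ab <- cbind(A = c(0.9, 0.1), B = c(0.2, 0.8))
#' rownames(ab) <- c("SYN0001", "SYN0002")
#' fractionDesign(ab, replicates = 3, depth = 1000, seed = 1)
#' @export
fractionDesign <- function(abundance, replicates = 3L, depth = 10000,
                           seed = 1L) {
  if (!is.matrix(abundance) || is.null(rownames(abundance)) ||
      is.null(colnames(abundance)))
    stop("'abundance' must be a matrix with row and column names",
         call. = FALSE)
  if (any(abundance < 0))
    stop("'abundance' entries must be non-negative", call. = FALSE)
  cs <- colSums(abundance)
  if (any(abs(cs - 1) > 1e-9))
    stop("each 'abundance' column must sum to 1 (within 1e-9); offending: ",
         paste(colnames(abundance)[abs(cs - 1) > 1e-9], collapse = ", "),
         call. = FALSE)
  nf <- ncol(abundance)
  if (length(replicates) == 1L) replicates <- rep(replicates, nf)
  if (length(replicates) != nf || any(replicates < 1L | replicates > 10L))
    stop("'replicates' must be in 1..10, one value (or one per fraction)",
         call. = FALSE)
  .assertScalarNumber(depth, "depth", lower = 1)
  structure(list(fractionNames = colnames(abundance), abundance = abundance,
                 replicates = as.integer(replicates), depth = depth,
                 seed = as.integer(seed)),
            class = "FractionDesign")
}

#' Simulate PSM tables by multinomial spectral sampling
#'
#' For every fraction x replicate, draws a Poisson total number of spectra
#' at the design depth, allocates them to proteins multinomially according
#' to the fraction's abundance column, and within each protein uniformly
#' over its tryptic peptides in the configured length window. Each
#' resulting peptide-spectrum match carries a synthetic confidence at or
#' above the pipeline's default acceptance threshold (0.95). All draws are
#' seeded per fraction/replicate via [childSeed()], so tables are
#' reproducible individually and byte-identical on rerun.
#'
#' @param proteome a \code{GroundTruthProteome} from [generateProteome()].
#' @param design a \code{FractionDesign}; every accession in its abundance
#'   matrix must exist in the proteome, and every accession with positive
#'   abundance must yield at least one peptide in the length window.
#' @return named list of data.frames (one per fraction x replicate, named
#'   \code{<fraction>.<replicate>}) with columns \code{peptide},
#'   \code{sample}, \code{replicate}, \code{confidence}; one row per
#'   spectrum.
#' @export
generatePSMTables <- function(proteome, design) {
  stopifnot(inherits(proteome, "GroundTruthProteome"),
            inherits(design, "FractionDesign"))
  acc <- rownames(design$abundance)
  missing <- setdiff(acc, names(proteome$proteins))
  if (length(missing))
    stop("design proteins absent from proteome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pepsOf <- lapply(as.character(proteome$proteins[acc]), digestSequence,
                   minLen = proteome$minLen, maxLen = proteome$maxLen)
  names(pepsOf) <- acc
  used <- acc[rowSums(design$abundance) > 0]
  empty <- used[lengths(pepsOf[used]) == 0L]
  if (length(empty))
    stop("protein(s) without peptides in the digest length window: ",
         paste(empty, collapse = ", "), call. = FALSE)

  out <- list()
  for (fi in seq_along(design$fractionNames)) {
    f <- design$fractionNames[fi]
    p <- design$abundance[, f]
    for (r in seq_len(design$replicates[fi])) {
      set.seed(childSeed(design$seed, paste0("psm:", f, ":", r)))
      total <- stats::rpois(1L, design$depth)
      perProt <- if (total > 0L)
        as.vector(stats::rmultinom(1L, total, p)) else integer(length(p))
      pep <- character(0)
      for (i in seq_along(acc)) {
        if (perProt[i] > 0L)
          pep <- c(pep, sample(pepsOf[[acc[i]]], perProt[i],
                               replace = TRUE))
      }
      # shuffle so spectra are not grouped by protein, as in a real run
      if (length(pep)) pep <- sample(pep)
      conf <- round(0.95 + 0.05 * stats::runif(length(pep)), 4)
      out[[.sampleKey(f, r)]] <- data.frame(
        peptide = pep, sample = rep(f, length(pep)),
        replicate = rep(r, length(pep)), confidence = conf,
        stringsAsFactors = FALSE)
    }
  }
  out
}
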