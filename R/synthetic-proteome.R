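#' Generate a ground-truth proteome with redundancy structure
#'
#' Builds a synthetic protein database whose redundancy mirrors what
#' parsimony inference must resolve in real search results: families of
#' sequence-related proteins (near-identical homologues, truncated/partial
#' sequences realized as prefixes, and splice-like variants realized as
#' internal block deletions) that share tryptic peptides, alongside
#' unrelated singleton proteins. Sequences are built from whole tryptic
#' peptides (every segment ends in K or R and never starts with P), so the
#' digest of a family member is an exact sub-multiset of its parent's
#' digest where intended.
#'
#' @param nProteins total number of proteins (>= 2).
#' @param nFamilies number of redundancy families (>= 0); each family uses
#'   2-3 of the \code{nProteins} slots.
#' @param seed integer seed; output is fully determined by it.
#' @param minLen,maxLen tryptic peptide length window used to build the
#'   peptide map (defaults 6 and 30).
#' @param peptidesPerProtein number of tryptic segments per base protein.
#' @return a \code{GroundTruthProteome}: list with \code{proteins} (a named
#'   \link[Biostrings]{AAStringSet}), \code{families} (list of accession
#'   vectors), and \code{peptideMap} (named list: peptide -> accessions
#'   containing it as a substring).
#' @examples
#' gp <- generateProteome(10, nFamilies = 2, seed = 1)
#' names(gp$proteins)
#' @export
generateProteome <- function(nProteins, nFamilies = 0L, seed = 1L,
                             minLen = 6L, maxLen = 30L,
                             peptidesPerProtein = 12L) {
  .assertScalarNumber(nProteins, "nProteins", lower = 2)
  .assertScalarNumber(nFamilies, "nFamilies", lower = 0)
  .assertScalarNumber(peptidesPerProtein, "peptidesPerProtein", lower = 6)
  if (3 * nFamilies > nProteins)
    stop("too many families for 'nProteins' (each needs up to 3 slots)",
         call. = FALSE)
  set.seed(childSeed(seed, "proteome"))
  # amino acids without K, R (segment terminators) and P (never first)
  aa <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]

  rpep <- function(len) {
    # one clean tryptic segment: body without K/R, no leading P, ends K/R
    body <- sample(aa, len - 1L, replace = TRUE)
    paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
  }
  rseq <- function(npep) {
    lens <- sample(seq.int(minLen, min(maxLen, 20L)), npep, replace = TRUE)
    paste(vapply(lens, rpep, character(1)), collapse = "")
  }

  acc <- sprintf("SYN%04d", seq_len(nProteins))
  seqs <- character(nProteins)
  families <- vector("list", nFamilies)
  slot <- 1L
  famKinds <- c("truncation", "splice", "homolog")
  for (f in seq_len(nFamilies)) {
    kind <- famKinds[((f - 1L) %% 3L) + 1L]
    size <- if (slot + 2L <= nProteins - (nFamilies - f) * 3L) 3L else 2L
    base <- rseq(peptidesPerProtein)
    segs <- digestSequence(base, minLen = 1L, maxLen = .Machine$integer.max)
    members <- acc[slot:(slot + size - 1L)]
    seqs[slot] <- base
    for (m in 2:size) {
      seqs[slot + m - 1L] <- switch(kind,
        truncation = {
          # keep a prefix ending on a cleavage boundary
          k <- sample(seq.int(3L, length(segs) - 2L), 1L)
          paste(segs[seq_len(k)], collapse = "")
        },
        splice = {
          # drop an internal exon-like block of whole segments
          from <- sample(seq.int(3L, length(segs) - 3L), 1L)
          paste(segs[-(from:(from + 1L))], collapse = "")
        },
        homolog = {
          # replace two internal segments, keeping the rest identical
          s2 <- segs
          idx <- sample(seq.int(2L, length(segs) - 1L), 2L)
          for (i in idx) {
            w <- nchar(s2[i])
            s2[i] <- rpep(max(w, minLen))
          }
          paste(s2, collapse = "")
        })
    }
    families[[f]] <- members
    slot <- slot + size
  }
  while (slot <= nProteins) {
    seqs[slot] <- rseq(peptidesPerProtein)
    slot <- slot + 1L
  }
  names(seqs) <- acc

  peps <- sort(unique(unlist(lapply(seqs, digestSequence, minLen = minLen,
                                    maxLen = maxLen))))
  pmap <- lapply(peps, function(p) acc[vapply(
    seqs, function(s) grepl(p, s, fixed = TRUE), logical(1))])
  names(pmap) <- peps

  structure(list(proteins = Biostrings::AAStringSet(seqs),
                 families = families, peptideMap = pmap,
                 minLen = as.integer(minLen), maxLen = as.integer(maxLen)),
            class = "GroundTruthProteome")
}

#' @export
print.GroundTruthProteome <- function(x, ...) {
  cat(sprintf(
    "GroundTruthProteome: %d protein(s), %d familie(s), %d peptide(s)\n",
    length(x$proteins), length(x$families), length(x$peptideMap)))
  invisible(x)
}
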