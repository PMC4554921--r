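# expected percent-of-total per retained group under the generative
# model: peptide-level expected spectra from the digest and abundances,
# with shared peptides allocated by expected unique evidence. Serves as
# the generating-truth oracle for recovery tests; independent of the
# spectral counting path.
expectedGroupPercent <- function(gp, abundance, groups, classification) {
  acc <- rownames(abundance)
  pepsOf <- lapply(stats::setNames(as.character(gp$proteins[acc]), acc),
                   digestSequence, gp$minLen, gp$maxLen)
  peps <- names(classification)
  epep <- matrix(0, length(peps), ncol(abundance),
                 dimnames = list(peps, colnames(abundance)))
  for (i in acc) {
    ni <- length(pepsOf[[i]])
    for (p in pepsOf[[i]]) if (p %in% peps)
      epep[p, ] <- epep[p, ] + abundance[i, ] / ni
  }
  reps <- representatives(groups)
  eu <- matrix(0, length(reps), ncol(abundance),
               dimnames = list(reps, colnames(abundance)))
  for (r in reps)
    for (p in uniquePeptides(groups)[[r]]) eu[r, ] <- eu[r, ] + epep[p, ]
  eg <- eu
  shared <- unique(unlist(sharedPeptides(groups)))
  for (p in shared) {
    gs <- classification[[p]]
    den <- colSums(eu[gs, , drop = FALSE])
    for (f in seq_len(ncol(eg))) {
      w <- if (den[f] > 0) eu[gs, f] / den[f]
        else rep(1 / length(gs), length(gs))
      eg[gs, f] <- eg[gs, f] + epep[p, f] * w
    }
  }
  sweep(eg, 2L, colSums(eg), "/") * 100
}
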