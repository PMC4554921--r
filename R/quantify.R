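#' Tabulate spectral counts per group and sample
#'
#' Counts every peptide-spectrum match exactly once: spectra of unique
#' peptides increment their group's cell directly; spectra of shared
#' peptides are tallied per (peptide, sample) pending apportionment.
#' Spectral counting is order-invariant in the PSM rows.
#'
#' @param psms data.frame of PSM records (columns \code{peptide},
#'   \code{sample}, \code{replicate}, \code{confidence}); every peptide
#'   must be classified (filter orphans first).
#' @param groups a \linkS4class{ProteinGroupSet}.
#' @param classification optional precomputed [classifyPeptides()] result.
#' @return list with \code{rawUnique} (group x sample integer matrix),
#'   \code{rawShared} (group x sample totals of shared-peptide spectra
#'   involving the group, informational), \code{sharedCounts} (data.frame
#'   peptide/sample/count), \code{uniquePepCounts} (group x sample counts
#'   of distinct unique peptides observed), \code{samples} (data.frame
#'   fraction/replicate in first-appearance order) and
#'   \code{classification}.
#' @export
countSpectra <- function(psms, groups, classification = NULL) {
  stopifnot(is.data.frame(psms),
            all(c("peptide", "sample", "replicate") %in% colnames(psms)))
  if (is.null(classification)) classification <- classifyPeptides(groups)
  bad <- setdiff(unique(psms$peptide), names(classification))
  if (length(bad))
    stop("unclassified peptide(s) in PSM table: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  reps <- representatives(groups)
  samples <- unique(psms[, c("sample", "replicate")])
  samples <- samples[order(match(samples$sample, unique(psms$sample)),
                           samples$replicate), , drop = FALSE]
  rownames(samples) <- NULL
  keys <- .sampleKey(samples$sample, samples$replicate)
  psmKey <- .sampleKey(psms$sample, psms$replicate)

  zero <- matrix(0, length(reps), length(keys),
                 dimnames = list(reps, keys))
  rawUnique <- rawShared <- uniquePep <- zero
  nHold <- lengths(classification[psms$peptide])
  isUnique <- nHold == 1L
  if (any(isUnique)) {
    g <- vapply(classification[psms$peptide[isUnique]], `[`, character(1),
                1L)
    t1 <- table(factor(g, levels = reps),
                factor(psmKey[isUnique], levels = keys))
    rawUnique <- rawUnique + unclass(t1)
    up <- unique(data.frame(g = g, k = psmKey[isUnique],
                            p = psms$peptide[isUnique]))
    t2 <- table(factor(up$g, levels = reps), factor(up$k, levels = keys))
    uniquePep <- uniquePep + unclass(t2)
  }
  sharedCounts <- data.frame(peptide = character(0), sample = character(0),
                             count = integer(0), stringsAsFactors = FALSE)
  if (any(!isUnique)) {
    sh <- psms[!isUnique, , drop = FALSE]
    shKey <- psmKey[!isUnique]
    tt <- table(sh$peptide, factor(shKey, levels = keys))
    idx <- which(tt > 0, arr.ind = TRUE)
    sharedCounts <- data.frame(peptide = rownames(tt)[idx[, 1L]],
                               sample = colnames(tt)[idx[, 2L]],
                               count = as.integer(tt[idx]),
                               stringsAsFactors = FALSE)
    sharedCounts <- sharedCounts[order(sharedCounts$peptide,
                                       sharedCounts$sample), , drop = FALSE]
    rownames(sharedCounts) <- NULL
    for (i in seq_len(nrow(sharedCounts))) {
      gs <- classification[[sharedCounts$peptide[i]]]
      rawShared[gs, sharedCounts$sample[i]] <-
        rawShared[gs, sharedCounts$sample[i]] + sharedCounts$count[i]
    }
  }
  list(rawUnique = rawUnique, rawShared = rawShared,
       sharedCounts = sharedCounts, uniquePepCounts = uniquePep,
       samples = samples, classification = classification)
}

#' Apportion shared spectra to cognate protein groups
#'
#' For each shared peptide with \eqn{s} spectra in a sample, group
#' \eqn{g} among the groups containing it receives \eqn{s u_g / \sum_h
#' u_h}, where \eqn{u_g} is the group's unique evidence in that same
#' sample: its unique spectral counts (default) or its distinct unique
#' peptide count (\code{method = "peptides"}). When no involved group has
#' unique evidence in the sample, the spectra are split equally. Fractional
#' allocations are expected; the allocation to the last involved group is
#' computed as the remainder so per-sample totals are conserved exactly.
#'
#' @param counts result of [countSpectra()].
#' @param method \code{"spectra"} (unique spectral counts, default) or
#'   \code{"peptides"} (distinct unique peptides).
#' @return numeric group x sample matrix of apportioned counts
#'   (\code{rawUnique} plus all shared allocations).
#' @export
apportionShared <- function(counts, method = c("spectra", "peptides")) {
  method <- match.arg(method)
  u <- switch(method, spectra = counts$rawUnique,
              peptides = counts$uniquePepCounts)
  apportioned <- counts$rawUnique + 0
  sc <- counts$sharedCounts
  for (i in seq_len(nrow(sc))) {
    gs <- sort(counts$classification[[sc$peptide[i]]])
    s <- sc$count[i]
    ui <- u[gs, sc$sample[i]]
    w <- if (sum(ui) > 0) ui / sum(ui) else rep(1 / length(gs), length(gs))
    alloc <- s * w
    alloc[length(alloc)] <- s - sum(alloc[-length(alloc)])
    apportioned[gs, sc$sample[i]] <-
      apportioned[gs, sc$sample[i]] + alloc
  }
  apportioned
}

#' Percent of total apportioned counts per sample
#'
#' @param apportioned numeric group x sample matrix.
#' @return matrix of the same shape; each column sums to 100.
#' @export
percentTotal <- function(apportioned) {
  tot <- colSums(apportioned)
  if (any(tot <= 0))
    stop("sample(s) with no counts: ",
         paste(colnames(apportioned)[tot <= 0], collapse = ", "),
         call. = FALSE)
  sweep(apportioned, 2L, tot, "/") * 100
}

#' Average percent values over biological replicates
#'
#' Per-fraction arithmetic mean and sample standard deviation (n - 1
#' denominator; 0 when n = 1) of each group's percent-of-total values.
#' Groups absent from a replicate contribute 0 for that replicate.
#'
#' @param percent group x sample percent matrix.
#' @param samples data.frame with \code{sample} (fraction) and
#'   \code{replicate} matching the matrix columns (in column order).
#' @return list of group x fraction matrices \code{mean} and \code{sd},
#'   plus integer vector \code{n} of replicates per fraction.
#' @export
averageReplicates <- function(percent, samples) {
  stopifnot(ncol(percent) == nrow(samples))
  fr <- unique(samples$sample)
  mean <- sd <- matrix(0, nrow(percent), length(fr),
                       dimnames = list(rownames(percent), fr))
  n <- stats::setNames(integer(length(fr)), fr)
  for (f in fr) {
    cols <- which(samples$sample == f)
    n[f] <- length(cols)
    sub <- percent[, cols, drop = FALSE]
    mean[, f] <- rowMeans(sub)
    sd[, f] <- if (length(cols) > 1L) apply(sub, 1L, stats::sd) else 0
  }
  list(mean = mean, sd = sd, n = n)
}

#' Run the full spectral-count quantification
#'
#' Drops PSMs of orphan peptides (reported), counts spectra, apportions
#' shared spectra, normalizes each sample to percent of total, averages
#' over replicates, and assembles a \linkS4class{FractionQuant}. Groups
#' left with zero total evidence are dropped and reported. Rows are
#' ordered by descending overall mean percent, then accession.
#'
#' @param psms data.frame of PSM records for all samples.
#' @param groups a \linkS4class{ProteinGroupSet}.
#' @param method apportionment mode, see [apportionShared()].
#' @return a \linkS4class{FractionQuant}.
#' @export
quantifySpectra <- function(psms, groups,
                            method = c("spectra", "peptides")) {
  method <- match.arg(method)
  orphan <- psms$peptide %in% orphanPeptides(groups)
  if (any(orphan)) {
    message(sum(orphan), " PSM(s) of orphan peptides dropped")
    psms <- psms[!orphan, , drop = FALSE]
  }
  if (nrow(psms) == 0L) stop("no PSMs left to quantify", call. = FALSE)
  counts <- countSpectra(psms, groups)
  apportioned <- apportionShared(counts, method = method)
  keep <- rowSums(apportioned) > 0
  if (any(!keep))
    message(sum(!keep), " group(s) with zero evidence dropped: ",
            paste(rownames(apportioned)[!keep], collapse = ", "))
  gi <- match(rownames(apportioned)[keep], representatives(groups))
  apportioned <- apportioned[keep, , drop = FALSE]
  rawUnique <- counts$rawUnique[keep, , drop = FALSE]
  percent <- percentTotal(apportioned)
  profile <- averageReplicates(percent, counts$samples)
  ord <- order(-rowMeans(profile$mean), rownames(percent))
  apportioned <- apportioned[ord, , drop = FALSE]
  rawUnique <- rawUnique[ord, , drop = FALSE]
  percent <- percent[ord, , drop = FALSE]
  profile$mean <- profile$mean[ord, , drop = FALSE]
  profile$sd <- profile$sd[ord, , drop = FALSE]
  gi <- gi[ord]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rawUnique = rawUnique, apportioned = apportioned,
                  percent = percent),
    rowData = S4Vectors::DataFrame(
      representative = rownames(percent),
      nMembers = lengths(groups@members[gi]),
      nUniquePeptides = lengths(groups@uniquePeptides[gi]),
      nSharedPeptides = lengths(groups@sharedPeptides[gi])),
    colData = S4Vectors::DataFrame(
      fraction = counts$samples$sample,
      replicate = counts$samples$replicate,
      row.names = colnames(percent)))
  S4Vectors::metadata(se)$profile <- profile
  S4Vectors::metadata(se)$apportionMethod <- method
  S4Vectors::metadata(se)$nPSMs <- nrow(psms)
  new("FractionQuant", se)
}
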