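#' The closed functional-category vocabulary
#'
#' The 22 functional categories used to annotate identifications from
#' secretory-pathway fraction proteomics.
#'
#' @return character vector of the 22 category names.
#' @export
functionalCategories <- function() {
  c("biosynthetic cargo", "blood + other cells",
    "calcium transport/binding", "coat", "cytoskeleton", "detoxification",
    "GTPase", "likely contaminants", "lysosome", "metabolism",
    "mitochondria", "nucleus", "peroxisome", "plasma membrane",
    "proteasome/ubiquitin", "protein modification",
    "protein synthesis/folding", "signalling", "tethering/docking/fusion",
    "traffic", "trypsin", "unknown")
}

# uncentred correlation distance: 1 - sum(xy) / (||x|| ||y||); rows with
# zero norm get distance 1 to everything (with a warning), matching the
# Cluster 3.0 zero-variance convention.
.uncenteredDistance <- function(m) {
  norms <- sqrt(rowSums(m^2))
  zero <- norms == 0
  if (any(zero)) {
    warning("zero-norm row(s) under uncentred correlation; distance set ",
            "to 1: ", paste(rownames(m)[zero], collapse = ", "),
            call. = FALSE)
    norms[zero] <- 1
  }
  s <- (m %*% t(m)) / tcrossprod(norms)
  d <- 1 - s
  d[zero, ] <- 1; d[, zero] <- 1
  diag(d) <- 0
  d[d < 0] <- 0  # guard tiny negative rounding
  d
}

#' Hierarchically cluster fraction profiles
#'
#' Agglomerative clustering of protein groups (rows) over their
#' replicate-averaged fraction profiles, with the Cluster 3.0 defaults:
#' uncentred correlation distance and average linkage. Percentages are
#' first log10-transformed with a pseudocount of half the smallest
#' non-zero value (profiles span orders of magnitude), unless disabled.
#' Rows are put in lexicographic accession order before clustering, so the
#' result is invariant to input row order.
#'
#' @param profile numeric group x fraction matrix (typically
#'   \code{fractionProfile(fq)$mean}).
#' @param distance \code{"uncentered"} (default), \code{"correlation"}
#'   (centred) or \code{"euclidean"}.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default \code{"average"}).
#' @param logTransform log10(x + pseudocount) before clustering (default
#'   \code{TRUE}).
#' @return a \code{ClusterResult}: list with \code{leafOrder} (accessions
#'   in dendrogram order), \code{hclust} (the merge tree),
#'   \code{distanceMatrix}, \code{distanceName}, \code{linkageName} and
#'   \code{matrix} (the clustered, possibly transformed matrix in
#'   canonical row order).
#' @export
clusterProfiles <- function(profile, distance = c("uncentered",
                                                  "correlation",
                                                  "euclidean"),
                            linkage = "average", logTransform = TRUE) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(profile), nrow(profile) >= 2L,
            !is.null(rownames(profile)))
  if (!all(is.finite(profile))) stop("non-finite profile values",
                                     call. = FALSE)
  m <- profile[order(rownames(profile)), , drop = FALSE]
  if (logTransform) {
    nz <- m[m > 0]
    p <- if (length(nz)) min(nz) / 2 else 1
    m <- log10(m + p)
  }
  d <- switch(distance,
    uncentered = .uncenteredDistance(m),
    correlation = 1 - stats::cor(t(m)),
    euclidean = as.matrix(stats::dist(m)))
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(leafOrder = rownames(m)[hc$order], hclust = hc,
                 distanceMatrix = d, distanceName = distance,
                 linkageName = linkage, matrix = m),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d leaves, %s distance, %s linkage\n",
              length(x$leafOrder), x$distanceName, x$linkageName))
  invisible(x)
}

#' Classify groups by enrichment in a target fraction
#'
#' Compares each group's mean percent in the target fraction against its
#' best (maximum) mean percent over the reference fractions:
#' \code{unique_to_target} when every reference mean is 0 and the target
#' mean is positive; \code{enriched_in_target} when the fold (target /
#' best reference) is at least the threshold; \code{depleted_in_target}
#' when at most its reciprocal; \code{shared_with_reference} otherwise.
#' Groups that are zero everywhere are excluded and reported.
#'
#' @param profile group x fraction mean-percent matrix.
#' @param target target fraction name.
#' @param references reference fraction names (disjoint from target).
#' @param foldThreshold enrichment fold threshold (default 2).
#' @return data.frame with \code{group}, \code{label}, \code{fold}
#'   (\code{Inf} for unique-to-target); excluded groups in attribute
#'   \code{"excluded"}.
#' @export
classifyEnrichment <- function(profile, target, references,
                               foldThreshold = 2) {
  stopifnot(is.matrix(profile), target %in% colnames(profile),
            all(references %in% colnames(profile)),
            !(target %in% references), length(references) >= 1L)
  .assertScalarNumber(foldThreshold, "foldThreshold", lower = 1)
  t <- profile[, target]
  r <- apply(profile[, references, drop = FALSE], 1L, max)
  excl <- t == 0 & r == 0
  if (any(excl))
    message(sum(excl), " all-zero group(s) excluded from enrichment: ",
            paste(rownames(profile)[excl], collapse = ", "))
  g <- rownames(profile)[!excl]
  t <- t[!excl]; r <- r[!excl]
  fold <- ifelse(r > 0, t / r, Inf)
  label <- ifelse(r == 0 & t > 0, "unique_to_target",
           ifelse(fold >= foldThreshold, "enriched_in_target",
           ifelse(fold <= 1 / foldThreshold, "depleted_in_target",
                  "shared_with_reference")))
  out <- data.frame(group = g, label = label, fold = fold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- rownames(profile)[excl]
  out
}

#' Rank groups by abundance in one fraction
#'
#' @param profile group x fraction mean-percent matrix.
#' @param fraction fraction name.
#' @return character vector of accessions, descending mean percent, ties
#'   broken by accession.
#' @export
rankByAbundance <- function(profile, fraction) {
  stopifnot(is.matrix(profile), fraction %in% colnames(profile))
  rownames(profile)[order(-profile[, fraction], rownames(profile))]
}

#' Read a protein-to-category annotation table
#'
#' Tab-separated file with columns \code{accession} and \code{category};
#' every category must belong to the closed 22-name vocabulary
#' ([functionalCategories()]). Accessions absent from any later profile
#' are permitted.
#'
#' @param path file path.
#' @return data.frame with \code{accession} and \code{category}.
#' @export
readCategoryTable <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "category")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(ann$category), functionalCategories())
  if (length(bad))
    stop("category outside the 22-name vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ann[, need]
}

#' Roll percent profiles up into functional categories
#'
#' Sums the mean percent of all groups of each category per fraction.
#' Groups without an annotation are pooled under \code{"unknown"};
#' annotation rows for accessions absent from the profile are reported,
#' not fatal. The per-fraction rollup total equals the profile's column
#' total.
#'
#' @param profile group x fraction mean-percent matrix.
#' @param annotation data.frame with \code{accession} and \code{category}
#'   (categories must be in the 22-name vocabulary).
#' @return category x fraction matrix (categories in vocabulary order;
#'   only categories present appear).
#' @export
categoryRollup <- function(profile, annotation) {
  stopifnot(is.matrix(profile),
            all(c("accession", "category") %in% colnames(annotation)))
  bad <- setdiff(unique(annotation$category), functionalCategories())
  if (length(bad))
    stop("category outside the 22-name vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  extra <- setdiff(annotation$accession, rownames(profile))
  if (length(extra))
    message(length(extra), " annotated accession(s) not in profile: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
  cat <- annotation$category[match(rownames(profile),
                                   annotation$accession)]
  cat[is.na(cat)] <- "unknown"
  lev <- intersect(functionalCategories(), unique(cat))
  out <- rowsum(profile, factor(cat, levels = lev))
  out[lev, , drop = FALSE]
}
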